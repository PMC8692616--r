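#' Greedy low-correlation descriptor subset
#'
#' Walks the descriptor columns in stored order and keeps a column only if
#' its absolute Pearson correlation with every already-kept column stays
#' below `r_max`, producing a subset whose pairwise correlations are all
#' below the bound. With `scope = "per_modality"` the walk runs separately
#' within each modality (the convention for single-technique overviews,
#' bound 0.4); with `scope = "all"` one pooled walk is used (bound 0.3).
#' Constant columns are excluded with a warning. `order_by = "variance"`
#' walks columns in decreasing variance instead of stored order; the
#' pairwise bound holds either way, only the kept set differs.
#'
#' @param table a `descriptor_table`.
#' @param r_max correlation bound in (0, 1); default 0.3 pooled, 0.4 per
#'   modality.
#' @param scope `"all"` or `"per_modality"`.
#' @param order_by `"stored"` or `"variance"`.
#' @return filtered `descriptor_table`.
#' @export
correlation_filter <- function(table, r_max = if (scope == "all") 0.3 else 0.4,
                               scope = c("all", "per_modality"),
                               order_by = c("stored", "variance")) {
  scope <- match.arg(scope); order_by <- match.arg(order_by)
  stopifnot(r_max > 0, r_max < 1)
  X <- table$matrix
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant descriptor column(s) excluded")
  }
  groups <- if (scope == "all") list(which(v > 0))
            else split(which(v > 0), table$meta$modality[v > 0])
  kept <- integer(0)
  for (g in groups) {
    ord <- if (order_by == "variance") g[order(-v[g])] else g
    g_kept <- integer(0)
    for (j in ord) {
      if (length(g_kept) == 0 ||
          max(abs(stats::cor(X[, j], X[, g_kept]))) < r_max)
        g_kept <- c(g_kept, j)
    }
    kept <- c(kept, g_kept)
  }
  kept <- sort(kept)
  subset_descriptors(table, colnames(X)[kept])
}

#' Correlation filter sized for a canonical correlation analysis
#'
#' CCorA needs fewer variables than samples in each block. Starting from the
#' requested bound, the filter threshold is tightened geometrically until the
#' surviving descriptor count fits `n_max`; the threshold actually used is
#' attached as attribute `r_used`.
#'
#' @param table a `descriptor_table`.
#' @param n_max maximum surviving columns (typically samples - properties - 1).
#' @param r_max starting correlation bound (default 0.3).
#' @param scope passed to [correlation_filter()].
#' @return filtered `descriptor_table` with attribute `r_used`.
#' @export
ccora_filter <- function(table, n_max, r_max = 0.3, scope = "all") {
  r <- r_max
  repeat {
    out <- suppressWarnings(correlation_filter(table, r_max = r, scope = scope))
    if (ncol(out$matrix) <= n_max || r < 0.02) break
    r <- r * 0.85
  }
  attr(out, "r_used") <- r
  out
}

#' Canonical correlation analysis of descriptors against properties
#'
#' Both blocks are standardised internally (zero mean, unit sd), then the
#' canonical correlations and variable scores are computed from the singular
#' value decomposition of the whitened cross-correlation matrix
#' Rxx^(-1/2) Rxy Ryy^(-1/2). Variable scores are the correlations of each
#' original variable with the canonical variates (structure coefficients).
#' Each axis's sign is set so the property with the largest absolute score
#' is positive. Requires more samples than variables in the smaller block
#' and full-rank Y; use [correlation_filter()] first when p > n.
#'
#' @param X numeric matrix, samples x descriptors.
#' @param Y numeric matrix, samples x properties.
#' @return object of class `ccora_result` with `canonical_correlations`,
#'   `property_scores`, `descriptor_scores`.
#' @export
ccora <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  if (n <= max(ncol(X), ncol(Y)))
    stop("need more samples than variables in each block; pre-filter the descriptors")
  Xs <- scale(X); Ys <- scale(Y)
  if (any(!is.finite(Xs)) || any(!is.finite(Ys)))
    stop("constant column in X or Y")
  Rxx <- stats::cor(X); Ryy <- stats::cor(Y); Rxy <- stats::cor(X, Y)
  inv_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < max(e$values) * 1e-10)
      stop("rank-deficient block; canonical directions undefined")
    e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*% t(e$vectors)
  }
  Wx <- inv_sqrt(Rxx); Wy <- inv_sqrt(Ryy)
  sv <- svd(Wx %*% Rxy %*% Wy)
  d <- min(ncol(X), ncol(Y), n - 1)
  rho <- pmin(pmax(sv$d[seq_len(d)], 0), 1)
  A <- Wx %*% sv$u[, seq_len(d), drop = FALSE]   # X weights
  B <- Wy %*% sv$v[, seq_len(d), drop = FALSE]   # Y weights
  U <- Xs %*% A; V <- Ys %*% B
  xs <- stats::cor(X, U); ys <- stats::cor(Y, V)
  for (k in seq_len(d)) {
    s <- sign(ys[which.max(abs(ys[, k])), k])
    if (s < 0) { ys[, k] <- -ys[, k]; xs[, k] <- -xs[, k] }
  }
  structure(list(canonical_correlations = rho,
                 property_scores = ys, descriptor_scores = xs),
            class = "ccora_result")
}

#' @export
print.ccora_result <- function(x, ...) {
  cat("<ccora_result> canonical correlations:",
      paste(signif(x$canonical_correlations, 4), collapse = ", "), "\n")
  invisible(x)
}
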