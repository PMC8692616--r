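#' Default descriptor configuration
#'
#' Bin layout per modality and derivative order, plus PCA and deconvolution
#' settings. Bin ids follow the `<modality>.<n>` / `<modality>.2der.<n>`
#' convention, numbering bins consecutively across a block's regions (so a
#' block with an excluded gap keeps one running index). Counts were chosen to
#' keep the characteristic peaks of each modality resolved at the default
#' synthetic templates: roughly 4 ppm bins for the 200-ppm wide-line span,
#' 0.3 / 0.15 ppm bins for nonderivative / second-derivative MAS spectra,
#' 1.8 ppm bins for CP-MAS, ~19.7 cm-1 bins for FT-IR, 10 C bins for raw DTG
#' and ~6.2 C for its sharpened second derivative, and 40 logarithmic bins
#' for the solid-echo decays. On the default synthetic dataset the full
#' configuration yields 902 descriptor columns.
#'
#' @param mas_2der_bins bin count for the second-derivative MAS block; the
#'   one free count used to balance the default total.
#' @return nested list with `bins`, `pca`, `deconv` sections.
#' @export
default_descriptor_config <- function(mas_2der_bins = 94L) {
  list(
    bins = list(
      list(modality = "h1_wideline", deriv = 0L, prefix = "wideline",
           regions = list(c(-102, 102)), n = 51L),
      list(modality = "h1_wideline", deriv = 2L, prefix = "wideline.2der",
           regions = list(c(-102, 102)), n = 51L),
      list(modality = "h1_mas", deriv = 0L, prefix = "mas",
           regions = list(c(-8, 14.2)), n = 74L),
      list(modality = "h1_mas", deriv = 2L, prefix = "mas.2der",
           regions = list(c(-8, 14.2)), n = as.integer(mas_2der_bins)),
      list(modality = "c13_cpmas", deriv = 0L, prefix = "cpmas",
           regions = list(c(2.8, 185.2)), n = 100L),
      list(modality = "c13_cpmas", deriv = 2L, prefix = "cpmas.2der",
           regions = list(c(2.8, 185.2)), n = 100L),
      list(modality = "ftir", deriv = 2L, prefix = "ftir.2der",
           regions = list(c(660, 1711), c(2669, 3400)), n = c(54L, 37L)),
      list(modality = "dtg", deriv = 0L, prefix = "dtg",
           regions = list(c(44, 494)), n = 45L),
      list(modality = "dtg", deriv = 2L, prefix = "dtg.2der",
           regions = list(c(49, 492.01)), n = 72L)
    ),
    td_bins = list(n = 40L, t_max = 1e-3),
    pca = list(var_threshold = 0.01),
    deconv = list(voigt_prefix = "wideline.deconv", td_prefix = "tdnmr.deconv"),
    sg_window = 11L,
    ftir_exclude = list(c(1711, 2669), c(3400, 4000)),
    snr_note = "bins are left-closed; last bin of each region right-closed"
  )
}

bin_edges_for <- function(region, n) seq(region[1], region[2], length.out = n + 1)

#' Even-step binning of a profile region
#'
#' Splits `[lo, hi]` into `n_bins` equal-width intervals (left-closed; the
#' last one closed) and returns the mean intensity within each as one
#' descriptor. An empty bin is an error: it means the bin width undercuts the
#' axis step and fewer bins must be configured.
#'
#' @param profile a `spectrum`.
#' @param region numeric `c(lo, hi)` inside the profile span.
#' @param n_bins number of bins, >= 1.
#' @param prefix descriptor id prefix (e.g. `"cpmas"`, `"ftir.2der"`).
#' @param start_index id number of the first bin (used to continue numbering
#'   across multi-region blocks).
#' @return list with `values` (length `n_bins`) and `meta` data.frame
#'   (id, modality, processing, derivative_order, axis_lo, axis_hi).
#' @export
bin_even <- function(profile, region, n_bins, prefix = profile$modality,
                     start_index = 1L) {
  stopifnot(n_bins >= 1, region[1] < region[2])
  edges <- bin_edges_for(region, n_bins)
  idx <- findInterval(profile$axis, edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx <= n_bins
  vals <- tapply(profile$intensity[ok], factor(idx[ok], levels = seq_len(n_bins)), mean)
  if (anyNA(vals))
    stop(sprintf("empty bin in %s [%g,%g]/%d: use fewer bins (bin width must exceed the axis step)",
                 prefix, region[1], region[2], n_bins))
  ids <- paste0(prefix, ".", start_index - 1L + seq_len(n_bins))
  list(values = stats::setNames(as.numeric(vals), ids),
       meta = data.frame(id = ids, modality = profile$modality, processing = "bin",
                         derivative_order = profile$derivative_order,
                         axis_lo = edges[-length(edges)], axis_hi = edges[-1]))
}

bin_block <- function(profile, block) {
  out_v <- numeric(0); out_m <- NULL
  start <- 1L
  for (i in seq_along(block$regions)) {
    n <- if (length(block$n) > 1) block$n[i] else block$n
    b <- bin_even(profile, block$regions[[i]], n, prefix = block$prefix,
                  start_index = start)
    out_v <- c(out_v, b$values)
    out_m <- rbind(out_m, b$meta)
    start <- start + n
  }
  list(values = out_v, meta = out_m)
}

#' Logarithmic binning of a decay curve
#'
#' Splits a relaxation decay into `n_bins` bins whose edges are log-spaced
#' from the first positive sample time up to `t_max`; the t = 0 point is
#' assigned to the first bin. The bin value is the mean intensity. If the
#' sampling is too coarse for the narrow early bins, empty bins are merged
#' rightward and the merge recorded in the meta table (`note` column).
#'
#' @param decay a `spectrum` of modality `tdnmr`.
#' @param n_bins number of bins (default 40).
#' @param t_max upper time bound in seconds (default 1 ms).
#' @param prefix id prefix.
#' @return list with `values` and `meta` as in [bin_even()].
#' @export
bin_log_decay <- function(decay, n_bins = 40L, t_max = 1e-3, prefix = "tdnmr") {
  t <- decay$axis
  tpos <- t[t > 0]
  if (length(tpos) == 0) stop("decay has no positive time points")
  t1 <- min(tpos)
  edges <- exp(seq(log(t1), log(t_max), length.out = n_bins + 1))
  idx <- findInterval(t, edges, rightmost.closed = TRUE)
  idx[t <= t1] <- 1L          # t = 0 (and the first sample) into bin 1
  ok <- idx >= 1 & idx <= n_bins
  counts <- tabulate(idx[ok], nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(decay$intensity[ok][idx[ok] == b]), 0)
  note <- character(n_bins)
  for (b in seq_len(n_bins)) {     # merge empties rightward
    if (counts[b] == 0) {
      nb <- b + 1L
      while (nb <= n_bins && counts[nb] == 0) nb <- nb + 1L
      if (nb > n_bins) stop("trailing empty logarithmic bin cannot be merged rightward")
      sums[b] <- sums[nb]; counts[b] <- counts[nb]
      note[b] <- sprintf("merged_with_bin_%d", nb)
    }
  }
  vals <- sums / counts
  ids <- paste0(prefix, ".", seq_len(n_bins))
  list(values = stats::setNames(vals, ids),
       meta = data.frame(id = ids, modality = "tdnmr", processing = "bin",
                         derivative_order = 0L,
                         axis_lo = edges[-length(edges)], axis_hi = edges[-1],
                         note = note))
}

#' PCA score descriptors under the >1 percent variance rule
#'
#' Mean-centres the columns (no scaling), runs PCA, and keeps the scores of
#' every principal component whose proportion of variance exceeds
#' `var_threshold`, ordered by variance. Component signs are fixed so the
#' loading of largest magnitude is positive.
#'
#' @param data numeric matrix, samples x points.
#' @param var_threshold retention threshold on the proportion of variance
#'   (default 0.01).
#' @param prefix id prefix, e.g. `"mas.2der.pca"`.
#' @param modality modality token for the meta table.
#' @param derivative_order 0 or 2, for the meta table.
#' @return list with `scores` (samples x kept), `meta`, `var_prop` (all
#'   proportions of variance).
#' @export
pca_descriptors <- function(data, var_threshold = 0.01, prefix = "pca",
                            modality = NA_character_, derivative_order = 0L) {
  if (nrow(data) < 2) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(data, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) stop("zero-variance data; no principal components")
  prop <- v / sum(v)
  keep <- which(prop > var_threshold)
  if (length(keep) == 0) stop("no principal component exceeds the variance threshold")
  flip <- vapply(keep, function(j) {
    l <- pc$rotation[, j]; sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(pc$x[, keep, drop = FALSE], 2, flip, `*`)
  ids <- paste0(prefix, ".", keep)
  colnames(scores) <- ids
  list(scores = scores,
       meta = data.frame(id = ids, modality = modality, processing = "pca",
                         derivative_order = derivative_order,
                         component_index = keep,
                         var_prop = prop[keep]),
       var_prop = prop)
}

#' Derived transforms of deconvolution parameters
#'
#' For each positive parameter p: 1/p, exp(p), ln(p); for each ordered pair
#' (p, q): p/q. Nonpositive parameters have their log/inverse (and ratios
#' with them as denominator) dropped with a warning rather than emitting
#' NaN. Ratios are taken within one fit's parameter family only.
#'
#' @param params named numeric vector (e.g. area proportions and FWHMs of one
#'   Voigt fit, or proportions and relaxation times of one TD fit).
#' @param prefix id prefix, e.g. `"wideline.deconv"`.
#' @param modality modality token for metadata.
#' @return list with `values` (named) and `meta` (`formula` column records
#'   the expression).
#' @export
derived_transforms <- function(params, prefix = "deconv", modality = NA_character_) {
  nm <- names(params)
  stopifnot(!is.null(nm), !anyDuplicated(nm))
  vals <- numeric(0); forms <- character(0)
  for (i in seq_along(params)) {
    p <- params[i]
    if (p > 0) {
      vals <- c(vals, 1 / p, exp(p), log(p))
      forms <- c(forms, paste0(c("inv(", "exp(", "ln("), nm[i], ")"))
    } else {
      warning(sprintf("parameter %s <= 0: inverse/log transforms dropped", nm[i]))
      vals <- c(vals, exp(p))
      forms <- c(forms, paste0("exp(", nm[i], ")"))
    }
  }
  for (i in seq_along(params)) for (j in seq_along(params)) {
    if (i == j) next
    if (params[j] == 0) {
      warning(sprintf("parameter %s = 0: ratio denominators dropped", nm[j]))
      next
    }
    vals <- c(vals, params[i] / params[j])
    forms <- c(forms, paste0(nm[i], "/", nm[j]))
  }
  ids <- paste0(prefix, ".", forms)
  list(values = stats::setNames(vals, ids),
       meta = data.frame(id = ids, modality = modality, processing = "derived",
                         derivative_order = 0L, formula = forms))
}

#' Assemble descriptor blocks into one table
#'
#' Column-concatenates per-sample descriptor blocks into a samples x
#' descriptors matrix with a per-column metadata table. Every block must
#' cover the identical ordered sample set; duplicate ids or non-finite
#' entries are errors.
#'
#' @param blocks list; each element is a list with `matrix` (samples x p,
#'   with column names = ids) and `meta` (data.frame with at least an `id`
#'   column, one row per descriptor).
#' @param sample_ids ordered character vector of sample ids (row order).
#' @return object of class `descriptor_table`: list(sample_ids, matrix, meta,
#'   config_hash).
#' @export
assemble_table <- function(blocks, sample_ids, config = NULL) {
  mats <- lapply(blocks, function(b) {
    stopifnot(nrow(b$matrix) == length(sample_ids))
    if (!is.null(rownames(b$matrix)) && !identical(rownames(b$matrix), sample_ids))
      stop("block sample set does not match the requested sample order")
    b$matrix
  })
  X <- do.call(cbind, mats)
  meta_cols <- c("id", "modality", "processing", "derivative_order")
  meta <- do.call(rbind, lapply(blocks, function(b) {
    m <- b$meta
    for (col in meta_cols) if (!col %in% names(m)) m[[col]] <- NA
    m[, meta_cols]
  }))
  if (anyDuplicated(meta$id)) stop("duplicate descriptor ids: ",
    paste(unique(meta$id[duplicated(meta$id)])[1:5], collapse = ", "))
  if (!identical(colnames(X), meta$id)) stop("column names and meta ids disagree")
  if (!all(is.finite(X))) stop("non-finite descriptor values")
  rownames(X) <- sample_ids
  structure(list(sample_ids = sample_ids, matrix = X, meta = meta,
                 config_hash = if (is.null(config)) NA_character_ else config_hash(config)),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table %d samples x %d descriptors>\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(table(x$meta$modality, x$meta$processing))
  invisible(x)
}

#' Subset a descriptor table by descriptor ids
#' @param table a `descriptor_table`.
#' @param ids descriptor ids to keep (order preserved as given).
#' @return `descriptor_table`.
#' @export
subset_descriptors <- function(table, ids) {
  stopifnot(all(ids %in% colnames(table$matrix)))
  table$matrix <- table$matrix[, ids, drop = FALSE]
  table$meta <- table$meta[match(ids, table$meta$id), ]
  table
}

#' Locate the bin descriptor id covering an axis position
#'
#' Maps (modality, derivative order, axis position) to the id of the default
#' config's bin containing that position; used to translate planted spectral
#' features into descriptor ids for the synthetic ground truth.
#'
#' @param config descriptor config (see [default_descriptor_config()]).
#' @param modality modality token.
#' @param deriv derivative order, 0 or 2.
#' @param x axis position.
#' @return descriptor id string.
#' @export
bin_id_at <- function(config, modality, deriv, x) {
  for (block in config$bins) {
    if (block$modality != modality || block$deriv != deriv) next
    start <- 1L
    for (i in seq_along(block$regions)) {
      r <- block$regions[[i]]
      n <- if (length(block$n) > 1) block$n[i] else block$n
      if (x >= r[1] && x <= r[2]) {
        edges <- bin_edges_for(r, n)
        k <- min(findInterval(x, edges, rightmost.closed = TRUE), n)
        return(paste0(block$prefix, ".", start - 1L + k))
      }
      start <- start + n
    }
  }
  stop(sprintf("no bin block covers %s d%d at %g", modality, deriv, x))
}
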