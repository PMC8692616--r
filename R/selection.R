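#' Model specification for property prediction
#'
#' @param algo `"rf"` (random forest) or `"plsr"` (partial least squares
#'   regression, PLS1).
#' @param n_trees trees per forest (default 1000).
#' @param mtry predictors tried per split; NULL = randomForest regression
#'   default (p/3).
#' @param max_components PLSR latent-variable cap; the fitted count is chosen
#'   per training fold by minimum PRESS under an inner 10-fold CV, never
#'   exceeding min(max_components, n_train - 2, p).
#' @param importance_mode `"oob"` (the forest's out-of-bag permutation
#'   importance) or `"heldout"` (permute each column in the held-out fold and
#'   measure the increase in squared error). PLSR importance is always the
#'   component-weight importance (see [plsr_importance()]).
#' @param standardize_scope `"train"` fits the standardisation of X on the
#'   training folds only (no leakage); `"global"` standardises once on the
#'   full matrix, reproducing the conventional whole-dataset workflow.
#' @param seed integer seed; all fold assignments and forests derive from it.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(algo = c("rf", "plsr"), n_trees = 1000L, mtry = NULL,
                       max_components = 20L,
                       importance_mode = c("oob", "heldout"),
                       standardize_scope = c("train", "global"),
                       seed = 1L) {
  algo <- match.arg(algo)
  structure(list(algo = algo, n_trees = as.integer(n_trees), mtry = mtry,
                 max_components = as.integer(max_components),
                 importance_mode = match.arg(importance_mode),
                 standardize_scope = match.arg(standardize_scope),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# ---- PLS1 (NIPALS) ---------------------------------------------------------

#' Fit a univariate-response PLS regression (NIPALS)
#'
#' Predictors are standardised and the response mean-centred using the
#' supplied (training) statistics. Components are nested, so one fit serves
#' all component counts up to `ncomp`.
#'
#' @param X training matrix (samples x p).
#' @param y training response.
#' @param ncomp number of latent variables.
#' @param center,scale_,y_center optional pre-computed statistics (defaults:
#'   from `X`, `y`).
#' @return list of class `pls1_fit` with weights `W`, loadings `P`,
#'   regression scalars `q`, score norms `tt`, per-component explained
#'   response sum of squares `ssy`, and the centring/scaling used.
#' @export
pls1_fit <- function(X, y, ncomp, center = NULL, scale_ = NULL, y_center = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  center <- center %||% colMeans(X)
  scale_ <- scale_ %||% col_sds(X)
  scale_[scale_ == 0] <- 1
  y_center <- y_center %||% mean(y)
  Xc <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  yc <- y - y_center
  W <- P <- matrix(0, p, ncomp)
  q <- tt <- ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt[a] <- sum(t_^2)
    if (tt[a] < 1e-300) { ncomp <- a - 1L; break }
    P[, a] <- drop(crossprod(Xc, t_)) / tt[a]
    q[a] <- sum(t_ * yc) / tt[a]
    Xc <- Xc - tcrossprod(t_, P[, a])
    yc <- yc - q[a] * t_
    ssy[a] <- q[a]^2 * tt[a]
    W[, a] <- w
  }
  if (ncomp == 0) stop("PLS found no usable component (zero covariance)")
  structure(list(W = W[, seq_len(ncomp), drop = FALSE],
                 P = P[, seq_len(ncomp), drop = FALSE],
                 q = q[seq_len(ncomp)], tt = tt[seq_len(ncomp)],
                 ssy = ssy[seq_len(ncomp)],
                 center = center, scale = scale_, y_center = y_center,
                 ncomp = ncomp), class = "pls1_fit")
}

#' Predict from a PLS1 fit
#' @param object a `pls1_fit`; @param newX matrix; @param ncomp components to
#'   use (default all fitted); @param ... unused.
#' @return numeric predictions.
#' @export
predict.pls1_fit <- function(object, newX, ncomp = object$ncomp, ...) {
  pls1_predict_all(object, newX)[, min(ncomp, object$ncomp)]
}

#' Predictions of a PLS1 fit for every component count
#'
#' Computes test scores by sequential deflation (one pass over the
#' components), giving the cumulative predictions for 1..ncomp latent
#' variables — what PRESS-based component selection needs.
#'
#' @param object a `pls1_fit`; @param newX matrix.
#' @return matrix (rows of `newX` x ncomp).
#' @export
pls1_predict_all <- function(object, newX) {
  Xc <- sweep(sweep(as.matrix(newX), 2, object$center), 2, object$scale, `/`)
  n <- nrow(Xc)
  out <- matrix(0, n, object$ncomp)
  acc <- rep(object$y_center, n)
  for (a in seq_len(object$ncomp)) {
    t_ <- drop(Xc %*% object$W[, a])
    acc <- acc + object$q[a] * t_
    out[, a] <- acc
    Xc <- Xc - tcrossprod(t_, object$P[, a])
  }
  out
}

#' Component-weight importance of a PLSR model
#'
#' Importance of descriptor j is the squared loading weights summed over
#' components, each weighted by the response sum of squares that component
#' explains: imp_j = sum_a w_ja^2 ssy_a / sum_a ssy_a (the weighted-w^2
#' convention used for PLS variable importance in caret's varImp).
#'
#' @param fit a `pls1_fit`.
#' @param ncomp components included (default all fitted).
#' @return named numeric importance per descriptor.
#' @export
plsr_importance <- function(fit, ncomp = fit$ncomp) {
  idx <- seq_len(min(ncomp, fit$ncomp))
  w2 <- fit$W[, idx, drop = FALSE]^2
  drop(w2 %*% fit$ssy[idx]) / sum(fit$ssy[idx])
}

#' Pick the PLSR component count by minimum PRESS
#'
#' Inner k-fold cross-validation on the training data only: for each
#' component count up to `max_comp`, the predicted residual error sum of
#' squares (PRESS) over the inner held-out folds; the count with minimum
#' PRESS wins (ties to fewer components).
#'
#' @param X,y training data.
#' @param max_comp maximum latent variables considered.
#' @param k inner folds (default 10).
#' @return integer component count.
#' @export
choose_ncomp_press <- function(X, y, max_comp = 20L, k = 10L) {
  n <- nrow(X)
  max_comp <- max(1L, min(max_comp, n - 2L, ncol(X)))
  folds <- sample(rep(seq_len(k), length.out = n))
  press <- numeric(max_comp)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (sum(tr) < 3 || sum(!tr) < 1) next
    fit <- pls1_fit(X[tr, , drop = FALSE], y[tr],
                    ncomp = min(max_comp, sum(tr) - 1L))
    preds <- pls1_predict_all(fit, X[!tr, , drop = FALSE])
    for (a in seq_len(max_comp)) {
      pa <- preds[, min(a, fit$ncomp)]
      press[a] <- press[a] + sum((y[!tr] - pa)^2)
    }
  }
  which.min(press)
}

# ---- Random forest ---------------------------------------------------------

rf_fit <- function(X, y, spec) {
  mtry <- spec$mtry %||% max(floor(ncol(X) / 3), 1)
  randomForest::randomForest(
    X, y, ntree = spec$n_trees, mtry = min(mtry, ncol(X)),
    importance = spec$importance_mode == "oob")
}

#' Held-out permutation importance of a fitted forest
#'
#' For each descriptor, its column in the held-out fold is permuted (one
#' draw) and the increase in held-out mean squared error over the intact
#' prediction is recorded. All permuted copies are stacked into a single
#' prediction call. A column the forest never uses changes the error by
#' exactly zero.
#'
#' @param fit a randomForest fit.
#' @param X_heldout,y_heldout held-out fold.
#' @return named numeric importance (increase in MSE).
#' @export
rf_importance_heldout <- function(fit, X_heldout, y_heldout) {
  X_heldout <- as.matrix(X_heldout)
  m <- nrow(X_heldout); p <- ncol(X_heldout)
  base_pred <- predict(fit, X_heldout)
  base_mse <- mean((y_heldout - base_pred)^2)
  perms <- lapply(seq_len(p), function(j) {
    Xp <- X_heldout
    Xp[, j] <- Xp[sample.int(m), j]
    Xp
  })
  big <- do.call(rbind, perms)
  pred <- predict(fit, big)
  mse <- colMeans(matrix((rep(y_heldout, p) - pred)^2, nrow = m))
  stats::setNames(mse - base_mse, colnames(X_heldout))
}

# ---- Repeated k-fold CV ----------------------------------------------------

#' Repeated k-fold cross-validation with importance averaging
#'
#' Per repeat, a fresh random k-partition of the samples; per fold, the model
#' is trained on k-1 parts and predicts the held-out part. RMSE and R^2 are
#' computed on the pooled held-out predictions of each repeat
#' (R^2 = 1 - SSE/SST with SST about the overall response mean), then
#' averaged (+/- sd) over repeats. Descriptor importance is averaged over
#' every fitted model. Explanatory variables are standardised (training
#' statistics by default) for PLSR; the response is mean-centred inside the
#' PLS fit.
#'
#' @param spec a [model_spec()].
#' @param X samples x descriptors matrix (or `descriptor_table`).
#' @param y response vector (property pool means).
#' @param k folds (default 10); @param repeats repeats (default 100).
#' @return list of class `cv_result`: rmse_mean/sd, r2_mean/sd,
#'   `importance_mean`, per-repeat vectors `rmse`, `r2`, plus the pooled
#'   predictions of the last repeat (`last_predictions`) for auditing.
#' @export
repeated_cv_evaluate <- function(spec, X, y, k = 10L, repeats = 100L) {
  if (inherits(X, "descriptor_table")) X <- X$matrix
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < k) stop("fewer samples than folds")
  if (stats::sd(y) == 0) stop("constant response: R^2 undefined")
  imp_sum <- stats::setNames(numeric(ncol(X)), colnames(X))
  n_fits <- 0L
  rmse <- r2 <- numeric(repeats)
  sst <- sum((y - mean(y))^2)
  last_pred <- NULL
  with_seed(derive_seed(spec$seed, paste0("cv", ncol(X))), {
    for (rep_i in seq_len(repeats)) {
      folds <- sample(rep(seq_len(k), length.out = n))
      pred <- numeric(n)
      for (f in seq_len(k)) {
        tr <- folds != f
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
        if (spec$algo == "plsr") {
          if (spec$standardize_scope == "global") {
            ctr <- colMeans(X); scl <- col_sds(X)
          } else {
            ctr <- colMeans(Xtr); scl <- col_sds(Xtr)
          }
          nc <- choose_ncomp_press(Xtr, y[tr], max_comp = spec$max_components)
          fit <- pls1_fit(Xtr, y[tr], ncomp = nc, center = ctr, scale_ = scl)
          pred[!tr] <- predict(fit, Xte)
          imp_sum <- imp_sum + plsr_importance(fit)
        } else {
          fit <- rf_fit(Xtr, y[tr], spec)
          pred[!tr] <- predict(fit, Xte)
          imp_sum <- imp_sum + if (spec$importance_mode == "oob")
            randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
          else rf_importance_heldout(fit, Xte, y[!tr])
        }
        n_fits <- n_fits + 1L
      }
      sse <- sum((y - pred)^2)
      rmse[rep_i] <- sqrt(sse / n)
      r2[rep_i] <- 1 - sse / sst
      last_pred <- pred
    }
  })
  structure(list(rmse_mean = mean(rmse), rmse_sd = stats::sd(rmse),
                 r2_mean = mean(r2), r2_sd = stats::sd(r2),
                 importance_mean = imp_sum / n_fits,
                 rmse = rmse, r2 = r2, n_repeats = repeats, k = k,
                 last_predictions = last_pred, y = y), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %dx%d-fold | RMSE %.4g +/- %.2g | R2 %.4g +/- %.2g>\n",
              x$n_repeats, x$k, x$rmse_mean, x$rmse_sd, x$r2_mean, x$r2_sd))
  invisible(x)
}

#' Step sizes of the 90 percent retention schedule
#'
#' Starting from p descriptors, each step keeps ceiling(retention * p) of the
#' higher-ranked ones, always at least one fewer, stopping before the count
#' would fall below `floor`.
#'
#' @param p starting descriptor count.
#' @param retention fraction kept per step (default 0.9).
#' @param floor smallest allowed set (default 2).
#' @return integer vector of step sizes, starting at `p`.
#' @export
retention_sizes <- function(p, retention = 0.9, floor = 2L) {
  sizes <- as.integer(p)
  while (TRUE) {
    nxt <- as.integer(min(ceiling(retention * sizes[length(sizes)]),
                          sizes[length(sizes)] - 1L))
    if (nxt < floor) break
    sizes <- c(sizes, nxt)
  }
  sizes
}

#' Importance-guided recursive descriptor elimination
#'
#' The core selection loop: evaluate the current descriptor set by repeated
#' k-fold CV, rank descriptors by averaged importance (ties broken by id),
#' keep the top `retention` fraction, and repeat down to the floor. The best
#' step is the one with the highest mean R^2; ties go to the smaller set.
#'
#' @param spec a [model_spec()].
#' @param X a `descriptor_table` (or plain matrix with column names).
#' @param y response vector.
#' @param retention fraction kept per step (default 0.9).
#' @param k,repeats CV shape.
#' @param floor smallest set evaluated.
#' @param property label stored in the trace.
#' @param verbose print per-step progress.
#' @return object of class `selection_trace`: `steps` (list of
#'   list(ids, cv)), `best_index`, `property`, `algo`.
#' @export
recursive_select <- function(spec, X, y, retention = 0.9, k = 10L,
                             repeats = 100L, floor = 2L, property = "y",
                             verbose = FALSE) {
  M <- if (inherits(X, "descriptor_table")) X$matrix else as.matrix(X)
  if (ncol(M) < 2) stop("need at least 2 descriptors")
  sizes <- retention_sizes(ncol(M), retention, floor)
  ids <- colnames(M)
  steps <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    ids <- ids[seq_len(sizes[s])]   # already ranked from previous step
    cv <- repeated_cv_evaluate(spec, M[, ids, drop = FALSE], y,
                               k = k, repeats = repeats)
    steps[[s]] <- list(ids = ids, cv = cv)
    if (verbose)
      message(sprintf("step %2d: p=%4d R2=%.3f RMSE=%.4g",
                      s, length(ids), cv$r2_mean, cv$rmse_mean))
    imp <- cv$importance_mean
    ids <- ids[order(-imp[ids], ids)]   # rank desc, ties lexicographic
  }
  r2s <- vapply(steps, function(st) st$cv$r2_mean, 0)
  best <- length(r2s) - which.max(rev(r2s)) + 1L   # ties -> smaller set
  structure(list(steps = steps, best_index = best,
                 property = property, algo = spec$algo,
                 retention = retention, sizes = sizes),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace %s/%s: %d steps %d..%d, best step %d (p=%d, R2=%.3f)>\n",
              x$property, x$algo, length(x$steps), x$sizes[1],
              x$sizes[length(x$sizes)], x$best_index,
              length(x$steps[[x$best_index]]$ids),
              x$steps[[x$best_index]]$cv$r2_mean))
  invisible(x)
}

#' Best descriptor set of a selection trace
#'
#' @param trace a `selection_trace`.
#' @return list with `ids`, `cv`, `n` (Table-style report row:
#'   count, RMSE +/- sd, R^2 +/- sd).
#' @export
best_set <- function(trace) {
  st <- trace$steps[[trace$best_index]]
  list(ids = st$ids, cv = st$cv, n = length(st$ids),
       report = data.frame(
         property = trace$property, algo = trace$algo,
         n_selected = length(st$ids),
         rmse = st$cv$rmse_mean, rmse_sd = st$cv$rmse_sd,
         r2 = st$cv$r2_mean, r2_sd = st$cv$r2_sd))
}

#' Consensus of the top-k descriptors under RF and PLSR
#'
#' Takes the k descriptors of highest averaged importance at each trace's
#' best step and reports both rankings and their intersection — the
#' descriptors two different algorithms agree on.
#'
#' @param trace_rf,trace_plsr selection traces for the same property.
#' @param k top size (default 20), clipped with a warning if a best set is
#'   smaller.
#' @return list of class `consensus_result`: `property`, `rf_top`,
#'   `plsr_top`, `common`.
#' @export
consensus_topk <- function(trace_rf, trace_plsr, k = 20L) {
  stopifnot(identical(trace_rf$property, trace_plsr$property))
  top_of <- function(trace) {
    st <- trace$steps[[trace$best_index]]
    kk <- k
    if (length(st$ids) < k) {
      warning("best set smaller than k; clipping")
      kk <- length(st$ids)
    }
    imp <- st$cv$importance_mean[st$ids]
    st$ids[order(-imp, st$ids)][seq_len(kk)]
  }
  rf_top <- top_of(trace_rf); plsr_top <- top_of(trace_plsr)
  structure(list(property = trace_rf$property, rf_top = rf_top,
                 plsr_top = plsr_top, common = intersect(rf_top, plsr_top)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus %s: %d common of top-%d>\n  %s\n", x$property,
              length(x$common), length(x$rf_top),
              paste(x$common, collapse = ", ")))
  invisible(x)
}
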