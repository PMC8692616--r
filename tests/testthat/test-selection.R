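test_that("PLS1 predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  n <- 30; p <- 8
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p)))
  y <- drop(X %*% c(2, -1, 0.5, rep(0, p - 3))) + rnorm(n, 0, 0.3)
  A <- 3
  fit <- pls1_fit(X, y, ncomp = A)
  newX <- matrix(rnorm(10 * p), 10, dimnames = list(NULL, colnames(X)))
  ours <- predict(fit, newX, ncomp = A)
  mo <- mixOmics::pls(X, y, ncomp = A, mode = "regression", scale = TRUE)
  theirs <- predict(mo, newX)$predict[, 1, A]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("PLSR importance is the explained-variance-weighted squared weight", {
  set.seed(22)
  X <- matrix(rnorm(25 * 3), 25, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(25, 0, 0.2)
  fit <- pls1_fit(X, y, ncomp = 2)
  imp <- plsr_importance(fit)
  hand <- drop(fit$W[, 1]^2 * fit$ssy[1] + fit$W[, 2]^2 * fit$ssy[2]) /
    sum(fit$ssy[1:2])
  expect_equal(unname(imp), unname(hand), tolerance = 1e-12)

  # single component: importance proportional to |loading weight|
  f1 <- pls1_fit(X, y, ncomp = 1)
  expect_equal(order(plsr_importance(f1)), order(f1$W[, 1]^2))

  # duplicated columns share importance
  Xd <- cbind(X, a2 = X[, 1])
  fd <- pls1_fit(Xd, y, ncomp = 2)
  impd <- plsr_importance(fd)
  expect_equal(impd[1], impd[4], tolerance = 1e-9)
})

test_that("held-out permutation importance is zero for unused constant columns and top for the response copy", {
  set.seed(23)
  n <- 60
  X <- cbind(sig = rnorm(n), matrix(rnorm(n * 9), n,
                                    dimnames = list(NULL, paste0("n", 1:9))))
  y <- X[, "sig"]
  spec <- model_spec("rf", n_trees = 200, seed = 1)
  rf <- mdselect:::rf_fit(X[1:50, ], y[1:50], spec)
  imp <- rf_importance_heldout(rf, X[51:60, ], y[51:60])
  expect_equal(names(which.max(imp)), "sig")

  Xc <- cbind(X, flat = rep(1, n))
  rf2 <- mdselect:::rf_fit(Xc[1:50, ], y[1:50], spec)
  imp2 <- rf_importance_heldout(rf2, Xc[51:60, ], y[51:60])
  expect_identical(unname(imp2["flat"]), 0)
})

test_that("noise columns have near-zero mean held-out importance", {
  set.seed(24)
  n <- 60
  X <- cbind(sig = rnorm(n), matrix(rnorm(n * 9), n,
                                    dimnames = list(NULL, paste0("n", 1:9))))
  y <- X[, "sig"] + rnorm(n, 0, 0.1)
  spec <- model_spec("rf", n_trees = 100, seed = 2)
  rf <- mdselect:::rf_fit(X[1:50, ], y[1:50], spec)
  draws <- replicate(50, rf_importance_heldout(rf, X[51:60, ], y[51:60]))
  m <- rowMeans(draws)
  # noise columns average far below the signal column's importance
  expect_lt(max(abs(m[-1])), 0.2 * m["sig"])
})

test_that("repeated CV reports pooled R2 consistent with its logged predictions", {
  set.seed(25)
  n <- 20
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
  y <- drop(X %*% c(1, 2, 0, 0, 0)) + rnorm(n, 0, 0.2)
  spec <- model_spec("plsr", seed = 3)
  cv <- repeated_cv_evaluate(spec, X, y, k = 5, repeats = 3)
  sse <- sum((cv$y - cv$last_predictions)^2)
  sst <- sum((cv$y - mean(cv$y))^2)
  expect_equal(cv$r2[3], 1 - sse / sst, tolerance = 1e-12)
  expect_equal(cv$rmse[3], sqrt(sse / n), tolerance = 1e-12)
  expect_equal(cv$r2_mean, mean(cv$r2))

  # noiseless linear response on one descriptor: essentially exact recovery
  y1 <- 3 * X[, 1]
  cv1 <- repeated_cv_evaluate(model_spec("plsr", seed = 4),
                              X[, 1, drop = FALSE], y1, k = 5, repeats = 2)
  expect_gte(cv1$r2_mean, 0.999)

  expect_error(repeated_cv_evaluate(spec, X, rep(1, n), k = 5, repeats = 2),
               "constant response")
})

test_that("the retention schedule follows the ceiling recursion with guaranteed decrease", {
  s <- retention_sizes(902)
  expect_equal(s[1:5], c(902L, 812L, 731L, 658L, 593L))
  expect_true(all(diff(s) < 0))
  oracle <- 902
  expect_true(length(s) > 10)
  for (i in 2:length(s)) {
    oracle <- min(ceiling(0.9 * oracle), oracle - 1)
    expect_equal(s[i], oracle)
  }
  expect_equal(s[length(s)], 2)

  expect_equal(retention_sizes(4, retention = 0.5), c(4L, 2L))
})

test_that("recursive selection keeps a planted single predictor to the floor", {
  set.seed(26)
  n <- 40
  X <- matrix(rnorm(n * 30), n, dimnames = list(NULL, sprintf("d%02d", 1:30)))
  y <- 2 * X[, "d07"] + rnorm(n, 0, 0.1)
  spec <- model_spec("rf", n_trees = 150, seed = 5)
  tr <- recursive_select(spec, X, y, k = 5, repeats = 3)
  expect_true(all(vapply(tr$steps, function(st) "d07" %in% st$ids, TRUE)))
  # nesting invariant
  for (i in 2:length(tr$steps))
    expect_true(all(tr$steps[[i]]$ids %in% tr$steps[[i - 1]]$ids))
  expect_equal(vapply(tr$steps, function(st) length(st$ids), 0L),
               retention_sizes(30))
  # trace is reproducible under the same seed
  tr2 <- recursive_select(spec, X, y, k = 5, repeats = 3)
  expect_identical(lapply(tr$steps, `[[`, "ids"), lapply(tr2$steps, `[[`, "ids"))
})

test_that("best-set selection takes the highest R2 with ties to the smaller set", {
  fake_step <- function(ids, r2) list(ids = ids, cv = list(r2_mean = r2,
    r2_sd = 0, rmse_mean = 1 - r2, rmse_sd = 0,
    importance_mean = stats::setNames(seq_along(ids), ids)))
  mk_trace <- function(r2s) {
    ids <- sprintf("d%02d", 1:8)
    steps <- lapply(seq_along(r2s), function(i)
      fake_step(ids[seq_len(8 - i + 1)], r2s[i]))
    best <- length(r2s) - which.max(rev(r2s)) + 1L
    structure(list(steps = steps, best_index = best, property = "y",
                   algo = "rf", retention = 0.9,
                   sizes = sapply(steps, function(s) length(s$ids))),
              class = "selection_trace")
  }
  tr_up <- mk_trace(c(0.1, 0.2, 0.3))
  expect_equal(best_set(tr_up)$n, 6)     # monotone rise: last step wins
  tr_tie <- mk_trace(c(0.5, 0.3, 0.5))
  expect_equal(best_set(tr_tie)$n, 6)    # tie resolved to the smaller set
  expect_equal(best_set(tr_tie)$ids, tr_tie$steps[[3]]$ids)
})

test_that("top-k consensus intersects the two algorithms' rankings", {
  mk <- function(ids, imp) structure(list(
    steps = list(list(ids = ids,
                      cv = list(r2_mean = 1, importance_mean = imp))),
    best_index = 1L, property = "y", algo = "rf"), class = "selection_trace")
  ids <- sprintf("d%02d", 1:40)
  imp <- stats::setNames(40:1, ids)
  same <- consensus_topk(mk(ids, imp), mk(ids, imp), k = 20)
  expect_length(same$common, 20)

  # adversarially disjoint top-20s
  imp_rev <- stats::setNames(1:40, ids)
  disj <- consensus_topk(mk(ids, imp), mk(ids, imp_rev), k = 20)
  expect_length(disj$common, 0)
})
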