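make_table <- function(X, modality = "ftir") {
  ids <- colnames(X)
  structure(list(sample_ids = rownames(X) %||% as.character(seq_len(nrow(X))),
                 matrix = X,
                 meta = data.frame(id = ids, modality = modality,
                                   processing = "bin", derivative_order = 0L),
                 config_hash = NA_character_), class = "descriptor_table")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the correlation filter keeps one of identical columns and all orthogonal ones", {
  set.seed(1)
  z <- rnorm(30)
  X <- cbind(a = z, b = z, c = rnorm(30))
  out <- correlation_filter(make_table(X), r_max = 0.9, scope = "all")
  expect_true(sum(c("a", "b") %in% colnames(out$matrix)) == 1)

  Q <- qr.Q(qr(matrix(rnorm(30 * 5), 30)))
  colnames(Q) <- paste0("q", 1:5)
  out2 <- correlation_filter(make_table(Q), r_max = 0.3, scope = "all")
  expect_equal(ncol(out2$matrix), 5)
})

test_that("every surviving pair respects the correlation bound (all-pairs oracle)", {
  set.seed(42)
  n <- 40
  base <- matrix(rnorm(n * 4), n)
  X <- cbind(base,
             base[, 1] + rnorm(n, 0, 0.3),
             base[, 2] + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 6), n))
  colnames(X) <- paste0("d", seq_len(ncol(X)))
  for (rmax in c(0.3, 0.4, 0.6)) {
    out <- correlation_filter(make_table(X), r_max = rmax, scope = "all")
    C <- abs(cor(out$matrix)); diag(C) <- 0
    expect_lt(max(C), rmax)
  }
  # the bound also holds when walking in variance order
  outv <- correlation_filter(make_table(X), r_max = 0.4, scope = "all",
                             order_by = "variance")
  Cv <- abs(cor(outv$matrix)); diag(Cv) <- 0
  expect_lt(max(Cv), 0.4)

  Xc <- cbind(X, const = rep(1, n))
  expect_warning(correlation_filter(make_table(Xc), r_max = 0.4), "constant")
})

test_that("canonical correlations reduce to |Pearson r| and to 1 for exact maps", {
  set.seed(5)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  cc <- ccora(cbind(x), cbind(y))
  expect_equal(cc$canonical_correlations[1], abs(cor(x, y)), tolerance = 1e-10)

  X <- matrix(rnorm(40 * 3), 40)
  B <- matrix(c(1, 2, 0, -1, 0.5, 3), 3, 2)
  Y <- X %*% B
  cc2 <- ccora(X, Y)
  expect_equal(cc2$canonical_correlations, c(1, 1), tolerance = 1e-8)

  expect_error(ccora(X, cbind(Y, Y[, 1])), "rank-deficient")
})

test_that("the first canonical correlation matches a numeric maximisation oracle", {
  set.seed(9)
  X <- matrix(rnorm(30 * 3), 30)
  Y <- cbind(X %*% c(1, -0.5, 0.2) + rnorm(30), rnorm(30))
  cc <- ccora(X, Y)
  # random-restart direct search over unit directions
  best <- 0
  for (i in 1:40) {
    par0 <- rnorm(5)
    opt <- optim(par0, function(p) {
      u <- drop(scale(X) %*% p[1:3]); v <- drop(scale(Y) %*% p[4:5])
      if (sd(u) == 0 || sd(v) == 0) return(0)
      -abs(cor(u, v))
    }, control = list(maxit = 500))
    best <- max(best, -opt$value)
  }
  expect_equal(cc$canonical_correlations[1], best, tolerance = 1e-4)
  # and matches the base-R canonical correlation routine
  expect_equal(cc$canonical_correlations,
               cancor(scale(X), scale(Y))$cor, tolerance = 1e-8)
})

test_that("canonical correlations are invariant to invertible affine transforms", {
  set.seed(13)
  X <- matrix(rnorm(35 * 3), 35)
  Y <- cbind(X %*% c(0.5, 1, -1) + rnorm(35), X[, 1] + rnorm(35))
  A <- matrix(c(2, 1, 0, 0, 1, 3, 1, 0, 1), 3, 3)
  cc1 <- ccora(X, Y)
  cc2 <- ccora(sweep(X %*% A, 2, c(1, -2, 5), `+`), Y)
  expect_equal(cc1$canonical_correlations, cc2$canonical_correlations,
               tolerance = 1e-8)
})

test_that("canonical correlations agree with the community-standard implementation", {
  skip_if_not_installed("vegan")
  set.seed(19)
  X <- matrix(rnorm(30 * 4), 30)
  Y <- cbind(X %*% c(1, 0, -1, 0.5) + rnorm(30), rnorm(30), X[, 2] + rnorm(30))
  ours <- ccora(X, Y)
  theirs <- vegan::CCorA(scale(Y), scale(X))
  expect_equal(ours$canonical_correlations, unname(theirs$CanCorr),
               tolerance = 1e-8)
})
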