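test_that("even binning averages within bins and preserves mass in the mean", {
  x <- seq(0, 10, by = 0.1)
  sp_const <- new_spectrum(x, rep(4.2, length(x)), "dtg", sample_weight = 1)
  b <- bin_even(sp_const, c(0, 10), 5, prefix = "dtg")
  expect_equal(unname(b$values), rep(4.2, 5))
  expect_equal(b$meta$id, paste0("dtg.", 1:5))

  # profile = axis itself: bin means sit at the interval midpoints +- half step
  sp_lin <- new_spectrum(x, x, "dtg", sample_weight = 1)
  bl <- bin_even(sp_lin, c(0, 10), 5, prefix = "dtg")
  oracle <- sapply(0:4, function(k) {
    lo <- 2 * k; hi <- 2 * (k + 1)
    keep <- if (k < 4) x >= lo & x < hi else x >= lo & x <= hi
    mean(x[keep])
  })
  expect_equal(unname(bl$values), oracle)

  # mass preservation: point-count-weighted mean of bin values = raw mean
  y <- sin(x) + 0.3 * x
  spy <- new_spectrum(x, y, "dtg", sample_weight = 1)
  by <- bin_even(spy, c(0, 10), 5)
  counts <- sapply(0:4, function(k) {
    lo <- 2 * k; hi <- 2 * (k + 1)
    sum(if (k < 4) x >= lo & x < hi else x >= lo & x <= hi)
  })
  expect_equal(sum(by$values * counts) / sum(counts), mean(y), tolerance = 1e-12)

  expect_error(bin_even(sp_const, c(0, 10), 500), "fewer bins")
})

test_that("logarithmic decay binning yields 40 bins with constant edge ratio", {
  t <- seq(0, 1e-3, 2e-6)
  sp <- new_spectrum(t, rep(1, length(t)), "tdnmr")
  b <- bin_log_decay(sp)
  expect_length(b$values, 40)
  expect_equal(unname(b$values), rep(1, 40))
  ratios <- b$meta$axis_hi / b$meta$axis_lo
  expect_lt(diff(range(ratios)), 1e-9)
  expect_equal(b$meta$axis_hi[40], 1e-3, tolerance = 1e-12)
})

test_that("PCA retention follows the variance-proportion threshold exactly", {
  props <- c(0.70, 0.25, 0.045, 0.005)
  X <- matrix_with_var_props(props, n = 40, p = 8)
  pc <- pca_descriptors(X, var_threshold = 0.01, prefix = "toy")
  expect_equal(ncol(pc$scores), 3)
  expect_equal(pc$var_prop[1:4], props, tolerance = 1e-8)

  # rank-2 split 80/20 retains both components
  X2 <- matrix_with_var_props(c(0.8, 0.2), n = 30, p = 6, seed = 7)
  expect_equal(ncol(pca_descriptors(X2)$scores), 2)

  # scores match a covariance eigendecomposition oracle up to sign
  set.seed(3)
  Xr <- matrix(rnorm(25 * 6), 25, 6)
  pcr <- pca_descriptors(Xr, var_threshold = 0.01)
  Xc <- scale(Xr, scale = FALSE)
  ev <- eigen(cov(Xr), symmetric = TRUE)
  oracle <- Xc %*% ev$vectors
  for (j in seq_len(ncol(pcr$scores))) {
    d <- min(max(abs(pcr$scores[, j] - oracle[, j])),
             max(abs(pcr$scores[, j] + oracle[, j])))
    expect_lt(d, 1e-8)
  }

  # threshold monotonicity: raising the threshold never retains more
  ks <- sapply(c(0.001, 0.01, 0.05, 0.2), function(th)
    ncol(pca_descriptors(X, var_threshold = th)$scores))
  expect_true(all(diff(ks) <= 0))

  expect_error(pca_descriptors(matrix(1, 10, 4)), "zero-variance")
})

test_that("derived transforms enumerate inverses, exponentials, logs and ordered ratios", {
  tr <- derived_transforms(c(a = 1), prefix = "p")
  expect_equal(unname(tr$values[c("p.inv(a)", "p.exp(a)", "p.ln(a)")]),
               c(1, exp(1), 0))

  tr2 <- derived_transforms(c(a = 2, b = 4), prefix = "p")
  expect_equal(unname(tr2$values[c("p.a/b", "p.b/a")]), c(0.5, 2))

  for (k in c(2, 4, 6)) {
    params <- stats::setNames(seq_len(k) + 0.5, letters[seq_len(k)])
    trk <- derived_transforms(params)
    expect_length(trk$values, 3 * k + k * (k - 1))
  }
  # ln(exp(p)) identity on the emitted values
  p <- c(u = 0.7)
  trv <- derived_transforms(p)
  expect_equal(log(unname(trv$values["deconv.exp(u)"])), 0.7)

  expect_warning(derived_transforms(c(a = -1, b = 2)), "dropped")
})

test_that("table assembly concatenates blocks, enforcing ids and alignment", {
  sids <- c("s1", "s2", "s3")
  mk <- function(ids) {
    m <- matrix(rnorm(3 * length(ids)), 3, dimnames = list(sids, ids))
    list(matrix = m, meta = data.frame(id = ids, modality = "ftir",
                                       processing = "bin",
                                       derivative_order = 2L))
  }
  tab <- assemble_table(list(mk(paste0("a.", 1:3)), mk(paste0("b.", 1:4))), sids)
  expect_equal(ncol(tab$matrix), 7)
  expect_identical(tab$meta$id, colnames(tab$matrix))

  expect_error(assemble_table(list(mk("x.1"), mk("x.1")), sids), "duplicate")
  bad <- mk("c.1"); rownames(bad$matrix) <- c("s1", "s2", "zz")
  expect_error(assemble_table(list(bad), sids), "sample")
})

test_that("descriptor ids are stable across runs with an identical config", {
  cfg <- default_descriptor_config()
  t1 <- default_ground_truth(cfg)$informative_descriptor_ids
  t2 <- default_ground_truth(cfg)$informative_descriptor_ids
  expect_identical(t1, t2)
  expect_identical(bin_id_at(cfg, "c13_cpmas", 0L, 176), "cpmas.95")
  expect_identical(bin_id_at(cfg, "dtg", 0L, 250), "dtg.21")
})

test_that("the full descriptor table on a small panel is finite with unique ids", {
  ds <- simulate_dataset(n_samples = 5, seed = 12)
  tab <- build_descriptor_table(ds)
  expect_true(all(is.finite(tab$matrix)))
  expect_false(anyDuplicated(tab$meta$id) > 0)
  expect_identical(tab$sample_ids, ds$latents$sample_id)
  # bin + deconvolution column count is predicted exactly by the config
  npca <- sum(tab$meta$processing == "pca")
  expect_equal(ncol(tab$matrix), predicted_descriptor_count(ds$config, npca))
})
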