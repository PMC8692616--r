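test_that("latent panels are deterministic, clustered and within bounds", {
  a <- sample_latents(20, seed = 5)
  b <- sample_latents(20, seed = 5)
  expect_identical(a, b)

  lat <- sample_latents(63, seed = 1)
  expect_equal(nrow(lat), 63)
  expect_equal(as.vector(table(lat$species)[c("cat", "cow", "human", "pig")]),
               c(9L, 12L, 21L, 21L))
  frac <- c("alpha_helix_fraction", "lipid_content", "bound_water",
            "thermal_resistance")
  for (f in frac) expect_true(all(lat[[f]] >= 0 & lat[[f]] <= 1))
  expect_true(all(lat$cross_section_area > 0))
  # cluster structure: species means of alpha-helix fraction differ
  mu <- tapply(lat$alpha_helix_fraction, lat$species, mean)
  expect_gt(diff(range(mu)), 0.1)

  expect_error(sample_latents(3), "at least 4")
  expect_error(sample_latents(10, species_mix = c(cat = 0.5, cow = 0.4,
                                                  human = 0.05, pig = 0.02)),
               "sum to 1")
})

test_that("large panels reproduce the configured species-weighted latent means", {
  lat <- sample_latents(1000, seed = 2)
  sm <- species_latent_means()
  mix <- default_species_mix()
  target <- sum(sm$alpha_helix_fraction * mix[sm$species])
  se <- sd(lat$alpha_helix_fraction) / sqrt(1000)
  expect_lt(abs(mean(lat$alpha_helix_fraction) - target), 3 * se)
})

test_that("templates respond to their latents and only there", {
  # zero lipid: the MAS lipid peak sits at the background level
  lo <- ref_latent(lipid_content = 0)
  hi <- ref_latent(lipid_content = 1)
  base <- ref_latent(lipid_content = 0)
  base_level <- render_template("h1_mas", lo)
  at <- which.min(abs(base_level$axis - 1.40))
  resp_lo <- render_template("h1_mas", lo)$intensity[at]
  resp_hi <- render_template("h1_mas", hi)$intensity[at]
  expect_gt(resp_hi - resp_lo, 0.2)

  # carbonyl band integral strictly increases with the alpha-helix fraction
  ints <- sapply(c(0.2, 0.5, 0.8), function(a) {
    sp <- render_template("c13_cpmas", ref_latent(alpha_helix_fraction = a))
    keep <- sp$axis >= 165 & sp$axis <= 178
    sum(sp$intensity[keep]) * 0.25
  })
  expect_true(all(diff(ints) > 0))

  expect_error(render_spectra(tiny_latents(4), modalities = "xrd"), "unknown modality")
})

test_that("replicate structure follows the measurement protocol", {
  lat <- tiny_latents(4, seed = 2)
  spectra <- render_spectra(lat, seed = 2)
  tab <- table(vapply(spectra, `[[`, "", "modality"),
               vapply(spectra, `[[`, "", "sample_id"))
  expect_true(all(tab["tdnmr", ] == 5))
  expect_true(all(tab["ftir", ] >= 3))
  expect_true(all(tab >= 1))
})

test_that("rendered spectra are deterministic under a fixed seed", {
  lat <- tiny_latents(4, seed = 9)
  s1 <- render_spectra(lat, seed = 7)
  s2 <- render_spectra(lat, seed = 7)
  expect_identical(s1, s2)
})

test_that("property replicates have the planted noise level and structure", {
  lat <- sample_latents(8, seed = 6)
  truth <- default_ground_truth()

  # zero noise: replicates are identical
  t0 <- truth; t0$noise_sd[] <- 0
  p0 <- render_properties(lat, t0, seed = 1)
  v <- tapply(p0$breaking_force_N, p0$sample_id, var)
  expect_true(all(v < 1e-20))
  expect_equal(sum(p0$sample_id == p0$sample_id[1]), 10)

  # noise sd recovered within 20% over many replicates
  p1 <- render_properties(lat, truth, seed = 2, n_replicates = 1000)
  sds <- tapply(p1$yield_strength_MPa, p1$sample_id, sd)
  expect_lt(abs(mean(sds) - truth$noise_sd[["yield_strength_MPa"]]) /
              truth$noise_sd[["yield_strength_MPa"]], 0.2)
})

test_that("breaking force tracks cross-section area and the species pattern", {
  ds <- simulate_dataset(n_samples = 24, seed = 4)
  pm <- property_pool_means(ds$properties)
  rho <- cor(pm$breaking_force_N, ds$latents$cross_section_area,
             method = "spearman")
  expect_gt(rho, 0.9)
  med <- tapply(pm$breaking_force_N, ds$latents$species, median)
  expect_gt(med[["pig"]], med[["cat"]])
})

test_that("ground truth lists 20 unique informative descriptor ids", {
  truth <- default_ground_truth()
  expect_length(truth$informative_descriptor_ids, 20)
  expect_false(anyDuplicated(truth$informative_descriptor_ids) > 0)
  expect_setequal(truth$informative_for$yield_strength_MPa,
                  truth$informative_descriptor_ids)
})

test_that("datasets round-trip through the plain-text writers", {
  ds <- simulate_dataset(n_samples = 4, seed = 8)
  dir <- tempfile("mdds")
  man <- write_dataset(ds, dir)
  expect_equal(man$seed, 8)
  expect_error(write_dataset(ds, dir), "manifest already exists")

  back <- read_dataset(dir)
  expect_equal(back$properties$breaking_force_N,
               ds$properties$breaking_force_N, tolerance = 1e-12)
  expect_equal(length(back$spectra), length(ds$spectra))
  # match one spectrum by identity key and compare curves
  key <- function(sp) paste(sp$sample_id, sp$replicate, sp$modality)
  orig <- ds$spectra[[10]]
  match_i <- which(vapply(back$spectra, key, "") == key(orig))
  expect_length(match_i, 1)
  expect_equal(back$spectra[[match_i]]$intensity, orig$intensity,
               tolerance = 1e-12)

  # row count equals sum over spectra of axis lengths
  long <- utils::read.csv(file.path(dir, "spectra.csv"))
  expect_equal(nrow(long),
               sum(vapply(ds$spectra, function(s) length(s$axis), 0L)))
  unlink(dir, recursive = TRUE)
})
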