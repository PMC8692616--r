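#' Species-level latent composition means
#'
#' Cluster centres of the latent compositional variables for the four hair
#' sources. Values are design choices anchored to the qualitative species
#' contrasts the measurements show: pig bristle is thick with a high
#' crystalline alpha-keratin fraction; cat hair is fine and lipid-rich; cow
#' hair is stiff with heat-resistant cuticle; human hair holds the most
#' bound water. Cross-section areas (mm^2) correspond to typical fibre
#' diameters (cat ~40 um ... pig ~230 um).
#'
#' @return data.frame keyed by species.
#' @export
species_latent_means <- function() {
  data.frame(
    species = c("cat", "cow", "human", "pig"),
    alpha_helix_fraction = c(0.45, 0.55, 0.60, 0.75),
    lipid_content        = c(0.70, 0.40, 0.35, 0.15),
    bound_water          = c(0.45, 0.55, 0.62, 0.50),
    thermal_resistance   = c(0.40, 0.70, 0.35, 0.55),
    cross_section_area   = c(0.0014, 0.020, 0.0045, 0.040))
}

#' Default species mix (pool counts 9 cat / 12 cow / 21 human / 21 pig)
#' @return named proportions summing to 1.
#' @export
default_species_mix <- function() {
  c(cat = 9, cow = 12, human = 21, pig = 21) / 63
}

#' Draw latent compositions for a panel of sample pools
#'
#' Each sample pool gets a species (deterministic largest-remainder
#' allocation of `n_samples` to `species_mix`), a donor (two pools per donor,
#' mimicking repeated collections from one individual), and latent
#' compositional variables = species mean + donor effect + pool jitter,
#' truncated to (0, 1). Cross-section areas are log-normal around the
#' species mean.
#'
#' @param n_samples number of sample pools, >= 4.
#' @param species_mix named proportions over cat/cow/human/pig, summing to 1.
#' @param seed integer seed.
#' @param donor_sd,pool_sd standard deviations of the donor effect and the
#'   pool-level jitter on the fractional latents.
#' @return data.frame of latent compositions, one row per pool.
#' @export
sample_latents <- function(n_samples = 63L, species_mix = default_species_mix(),
                           seed = 1L, donor_sd = 0.05, pool_sd = 0.035) {
  if (n_samples < 4) stop("need at least 4 sample pools")
  if (abs(sum(species_mix) - 1) > 1e-8) stop("species_mix must sum to 1")
  sm <- species_latent_means()
  species_mix <- species_mix[sm$species[sm$species %in% names(species_mix)]]
  raw <- species_mix * n_samples
  counts <- floor(raw)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  with_seed(derive_seed(seed, "latents"), {
    rows <- NULL
    for (s in names(counts)) {
      k <- counts[[s]]
      if (k == 0) next
      mu <- sm[sm$species == s, ]
      n_donors <- max(1L, ceiling(k / 2))
      donor_of <- rep(seq_len(n_donors), each = 2L, length.out = k)
      de <- matrix(stats::rnorm(n_donors * 4, 0, donor_sd), n_donors, 4)
      for (i in seq_len(k)) {
        fr <- as.numeric(mu[, 2:5]) + de[donor_of[i], ] + stats::rnorm(4, 0, pool_sd)
        fr <- pmin(pmax(fr, 0.02), 0.98)
        bg <- exp(stats::rnorm(9, 0, 0.08))
        bkeys <- informative_band_table()$key
        bz <- stats::setNames(as.list(stats::rnorm(3 * length(bkeys))),
                              paste0("bz_", rep(bkeys, each = 3), "_",
                                     c("a", "w", "c")))
        nl <- stats::setNames(
          as.list(exp(stats::rnorm(nrow(nuisance_line_table()), 0, 0.45))),
          paste0("nl_", nuisance_line_table()$key))
        rows <- rbind(rows, data.frame(
          species = s,
          donor = sprintf("%s_d%02d", s, donor_of[i]),
          alpha_helix_fraction = fr[1], lipid_content = fr[2],
          bound_water = fr[3], thermal_resistance = fr[4],
          cross_section_area = mu$cross_section_area *
            exp(stats::rnorm(1, 0, 0.22)),
          # nuisance amplitude factors of property-unrelated template bands
          # (sample-to-sample morphology/composition variability that gives
          # the profiles realistic structured variance)
          bg_wl = bg[1], bg_mas = bg[2], bg_ha = bg[3], bg_aliph = bg[4],
          bg_arom = bg[5], bg_amideA = bg[6], bg_finger = bg[7],
          bg_water = bg[8], bg_cortex = bg[9], bz, nl))
      }
    }
    rows$sample_id <- sprintf("pool%02d", seq_len(nrow(rows)))
    rows[, c("sample_id", "species", "donor", "alpha_helix_fraction",
             "lipid_content", "bound_water", "thermal_resistance",
             "cross_section_area",
             grep("^bg_|^bz_|^nl_", names(rows), value = TRUE))]
  })
}

gaussian_band <- function(x, center, sd, amp) amp * exp(-0.5 * ((x - center) / sd)^2)

skewed_band <- function(x, center, sd, skew, amp) {
  u <- (x - center) / sd
  amp * 2 * exp(-0.5 * u^2) * stats::pnorm(skew * u)
}

#' Informative band definitions
#'
#' The twelve physical bands planted to respond to the three property-linked
#' latents. Band amplitude is `a0 + a1 * latent` plus a band-specific
#' amplitude jitter; width and centre also jitter per sample (fractional sd
#' 0.08, and 0.06 or 0.15 sigma for the centre). The jitters emulate
#' band-shape variability; they matter for the selection benchmark:
#' sibling descriptors of one band (nonderivative vs second-derivative bins,
#' left vs right flank bins) stay decorrelated enough that each carries its
#' own share of the latent signal.
#'
#' @return data.frame (key, modality, center, sigma, a0, a1, latent).
#' @export
informative_band_table <- function() {
  data.frame(
    key = c("cp_co", "cp_ca", "mas_a1", "mas_a2", "mas_l1", "mas_l2",
            "mas_l3", "ft_l1", "ft_l2", "dtg_t1", "dtg_t2", "ft_tr"),
    modality = c("c13_cpmas", "c13_cpmas", "h1_mas", "h1_mas", "h1_mas",
                 "h1_mas", "h1_mas", "ftir", "ftir", "dtg", "dtg", "ftir"),
    center = c(175.1, 51.1, 3.47, 6.13, 0.85, 1.40, 2.00, 2855, 2955,
               270, 364, 1640),
    sigma = c(1.0, 0.8, 0.13, 0.14, 0.10, 0.12, 0.10, 8, 8, 7, 10, 8),
    a0 = c(0.06, 0.03, 0.02, 0.02, 0.03, 0.04, 0.015, 0.02, 0.02,
           0.06, 0.05, 0.04),
    a1 = c(0.30, 0.28, 0.12, 0.12, 0.30, 0.35, 0.10, 0.22, 0.25,
           0.35, 0.30, 0.28),
    latent = c("alpha_helix_fraction", "alpha_helix_fraction",
               "alpha_helix_fraction", "alpha_helix_fraction",
               "lipid_content", "lipid_content", "lipid_content",
               "lipid_content", "lipid_content",
               "thermal_resistance", "thermal_resistance",
               "thermal_resistance"))
}

#' Yield-strength weights of the band-level structure variables
#'
#' Beyond the compositional latents, yield strength depends on the
#' band-level variables themselves: amplitude jitters (trace-constituent
#' variation, all twelve bands), width jitters (structural disorder,
#' readable only by combining a band's nonderivative and second-derivative
#' bins) and centre jitters (conformational shifts, readable only from a
#' band's flank-bin pair). This makes every listed informative bin carry a
#' share of the property signal that no other descriptor duplicates.
#'
#' @return data.frame (key, w_amp, w_width, w_center) in MPa per jitter sd.
#' @export
band_structure_weights <- function() {
  bt <- informative_band_table()
  both_deriv <- c("cp_co", "cp_ca", "mas_l1", "mas_l2", "dtg_t1", "dtg_t2")
  flank_pair <- c("dtg_t1", "dtg_t2")
  data.frame(key = bt$key,
             w_amp = rep(6, nrow(bt)),
             w_width = ifelse(bt$key %in% both_deriv, 4, 0),
             w_center = ifelse(bt$key %in% flank_pair, 4, 0))
}

# amplitude jitter scale relative to a1 (roughly one latent sd) and width
# jitter scale; centre jitter is per band (large only for the flank-pair
# bands whose centre shift is meant to be read from the bin pair)
.band_amp_jitter <- 0.12
.band_width_jitter <- 0.08
.band_center_jitter <- function(key) if (key %in% c("dtg_t1", "dtg_t2")) 0.15 else 0.06

#' Nuisance line definitions
#'
#' Narrow minor bands whose intensities vary between samples independently of
#' every property-linked latent (trace constituents, minor mass-loss events).
#' Because they are narrow they survive second-order differentiation, giving
#' the derivative profiles realistic property-unrelated structured variance.
#'
#' @return data.frame (key, modality, center, sigma, amp).
#' @export
nuisance_line_table <- function() {
  data.frame(
    key = paste0("nl", 1:28),
    modality = c("h1_mas", "h1_mas", "h1_mas",
                 "c13_cpmas", "c13_cpmas", "c13_cpmas",
                 "ftir", "ftir", "ftir", "dtg", "dtg",
                 # crowding lines flanking the informative bands
                 "c13_cpmas", "c13_cpmas", "c13_cpmas", "c13_cpmas",
                 "h1_mas", "h1_mas", "h1_mas", "h1_mas", "h1_mas", "h1_mas",
                 "ftir", "ftir", "ftir", "ftir",
                 "dtg", "dtg", "dtg"),
    center = c(-2.0, 8.5, 11.0, 20.0, 36.5, 141, 890, 1085, 3105, 142, 438,
               173.2, 177.0, 49.3, 53.0,
               0.62, 1.12, 1.75, 3.85, 6.45, 5.70,
               2815, 2995, 1663, 1612,
               281, 344, 386),
    sigma = c(0.10, 0.12, 0.10, 0.8, 0.7, 0.9, 8, 8, 25, 8, 10,
              0.5, 0.5, 0.5, 0.5,
              0.08, 0.08, 0.08, 0.10, 0.10, 0.10,
              8, 8, 7, 7,
              5, 6, 6),
    amp = c(0.08, 0.10, 0.06, 0.12, 0.10, 0.08, 0.10, 0.12, 0.12, 0.10, 0.08,
            0.06, 0.06, 0.05, 0.05,
            0.04, 0.04, 0.03, 0.04, 0.04, 0.03,
            0.05, 0.05, 0.08, 0.06,
            0.06, 0.05, 0.05))
}

reference_latent <- function() {
  data.frame(sample_id = "ref", alpha_helix_fraction = 0.5,
             lipid_content = 0.5, bound_water = 0.5,
             thermal_resistance = 0.5, cross_section_area = 0.01)
}

# process a raw template curve through the branch's pre-treatment chain
process_branch <- function(sp, deriv, config) {
  regions <- list(h1_wideline = c(-102, 102), h1_mas = c(-8, 14.2),
                  c13_cpmas = c(2.8, 185.2))
  w <- config$sg_window
  if (sp$modality %in% names(regions)) {
    if (deriv == 2L) sp <- sg_second_derivative(sp, w)
    r <- regions[[sp$modality]]
    normalize_total_area(truncate_spectrum(sp, r[1], r[2]))
  } else if (sp$modality == "ftir") {
    normalize_total_area(exclude_regions(sg_second_derivative(sp, w),
                                         config$ftir_exclude))
  } else if (sp$modality == "dtg") {
    sp$sample_weight <- 1
    sp <- dtg_prepare(sp)
    if (deriv == 2L) sp <- sg_second_derivative(sp, w)
    sp
  } else stop("no branch for ", sp$modality)
}

#' Bin sensitivity of one informative band
#'
#' Response of every configured bin of `(modality, deriv)` to a unit bump of
#' the band's amplitude, evaluated on the noiseless reference template and
#' propagated through the actual pre-treatment chain (differentiation,
#' truncation/exclusion, area normalisation, DTG preparation). Used to
#' locate the bins that carry a band's signal.
#'
#' @param config descriptor config.
#' @param key band key from [informative_band_table()].
#' @param deriv branch, 0 or 2.
#' @return named response vector (absolute values, one per bin id).
#' @export
band_bin_sensitivity <- function(config, key, deriv) {
  bt <- informative_band_table()
  b <- bt[bt$key == key, ]
  lat <- reference_latent()
  base <- render_template(b$modality, lat)
  bump <- base
  bump$intensity <- bump$intensity +
    gaussian_band(base$axis, b$center, b$sigma, 0.05)
  p0 <- process_branch(base, deriv, config)
  p1 <- process_branch(bump, deriv, config)
  block <- NULL
  for (blk in config$bins)
    if (blk$modality == b$modality && blk$deriv == deriv) block <- blk
  if (is.null(block)) stop("no bin block for ", b$modality, " d", deriv)
  v0 <- bin_block(p0, block)$values
  v1 <- bin_block(p1, block)$values
  abs(v1 - v0)
}

# listed-bin budget per band and branch (totals 20)
informative_bin_budget <- function() {
  data.frame(
    key   = c("cp_co", "cp_co", "cp_ca", "cp_ca", "mas_a1", "mas_a2",
              "mas_l1", "mas_l1", "mas_l2", "mas_l2", "mas_l3",
              "ft_l1", "ft_l2", "ft_tr", "dtg_t1", "dtg_t1",
              "dtg_t2", "dtg_t2"),
    deriv = c(0L, 2L, 0L, 2L, 2L, 2L, 0L, 2L, 0L, 2L, 2L,
              2L, 2L, 2L, 0L, 2L, 0L, 2L),
    n     = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
              1L, 1L, 1L, 1L, 2L, 2L, 1L))
}

sum_nuisance_lines <- function(x, latent, modality) {
  nt <- nuisance_line_table()
  nt <- nt[nt$modality == modality, , drop = FALSE]
  y <- 0
  for (i in seq_len(nrow(nt))) {
    f <- latent[[paste0("nl_", nt$key[i])]] %||% 1
    y <- y + gaussian_band(x, nt$center[i], nt$sigma[i], nt$amp[i] * f)
  }
  y
}

informative_bands_for <- function(latent, modality) {
  bt <- informative_band_table()
  bt <- bt[bt$modality == modality, , drop = FALSE]
  if (nrow(bt) == 0) return(bt)
  bt$amp <- bt$center_eff <- bt$sigma_eff <- NA_real_
  for (i in seq_len(nrow(bt))) {
    za <- latent[[paste0("bz_", bt$key[i], "_a")]] %||% 0
    zw <- latent[[paste0("bz_", bt$key[i], "_w")]] %||% 0
    zc <- latent[[paste0("bz_", bt$key[i], "_c")]] %||% 0
    bt$amp[i] <- max(bt$a0[i] + bt$a1[i] * latent[[bt$latent[i]]] +
                       .band_amp_jitter * bt$a1[i] * za, 0.001)
    bt$sigma_eff[i] <- bt$sigma[i] * exp(.band_width_jitter * zw)
    bt$center_eff[i] <- bt$center[i] +
      .band_center_jitter(bt$key[i]) * bt$sigma[i] * zc
  }
  bt
}

sum_informative_bands <- function(x, latent, modality) {
  bt <- informative_bands_for(latent, modality)
  y <- 0
  for (i in seq_len(nrow(bt)))
    y <- y + gaussian_band(x, bt$center_eff[i], bt$sigma_eff[i], bt$amp[i])
  y
}

#' Planted Voigt peaks of the wide-line 1H template
#'
#' Three Voigt components: a broad rigid-proton envelope (~100 ppm span), an
#' intermediate component, and a narrow mobile-proton peak near 0 ppm whose
#' amplitude grows with bound water.
#'
#' @param latent one row of [sample_latents()] output.
#' @return 3x4 matrix (center, sigma, gamma, amplitude).
#' @export
wideline_true_peaks <- function(latent) {
  bg <- if ("bg_wl" %in% names(latent)) latent$bg_wl else 1
  matrix(c(0.0, 35, 8, 0.80 * bg,
           0.2, 6, 2, 0.15,
           0.8, 1.5, 0.5, 0.06 + 0.16 * latent$bound_water),
         nrow = 3, byrow = TRUE,
         dimnames = list(NULL, c("center", "sigma", "gamma", "amplitude")))
}

#' Planted TD-NMR components
#'
#' One Abragam (rigid) plus two exponential (intermediate, mobile)
#' components; the rigid/mobile partition and the mobile relaxation time
#' shift with bound water. Proportions sum to one.
#'
#' @param latent one row of [sample_latents()] output.
#' @return data.frame (proportion, relaxation_time, shape, abragam_b).
#' @export
td_true_components <- function(latent) {
  bw <- latent$bound_water
  data.frame(
    proportion = c(0.62 - 0.18 * bw, 0.23, 0.15 + 0.18 * bw),
    relaxation_time = c(14e-6, 9e-5, 4.2e-4 * (1 + 0.5 * (bw - 0.5))),
    shape = c("abragam", "exponential", "exponential"),
    abragam_b = c(1.8e5, 0, 0))
}

#' Noiseless measurement templates
#'
#' Evaluates the parametric template of one modality for one latent
#' composition. Templates are sums of Voigt/Gaussian bands (NMR, FT-IR),
#' skewed-Gaussian mass-loss events (DTG) or Abragam/exponential decay
#' mixtures (TD-NMR); they aim at line-shape realism for pipeline testing,
#' not spectral physics. DTG intensities are mass-loss rate per unit mass;
#' [render_spectra()] multiplies by the drawn sample weight.
#'
#' @param modality modality token.
#' @param latent one row of [sample_latents()] output.
#' @param axis optional axis override.
#' @return `spectrum` (noiseless; replicate 0).
#' @export
render_template <- function(modality, latent, axis = NULL) {
  modality <- match.arg(modality, spectrum_modalities())
  al <- latent$alpha_helix_fraction; lip <- latent$lipid_content
  bw <- latent$bound_water; tr <- latent$thermal_resistance
  for (nm in c("bg_wl", "bg_mas", "bg_ha", "bg_aliph", "bg_arom",
               "bg_amideA", "bg_finger", "bg_water", "bg_cortex"))
    if (is.null(latent[[nm]])) latent[[nm]] <- 1
  if (modality == "h1_wideline") {
    x <- axis %||% seq(-130, 130, by = 1)
    pk <- wideline_true_peaks(latent)
    y <- voigt_profile(x, pk[1, 1], pk[1, 2], pk[1, 3], pk[1, 4]) +
      voigt_profile(x, pk[2, 1], pk[2, 2], pk[2, 3], pk[2, 4]) +
      voigt_profile(x, pk[3, 1], pk[3, 2], pk[3, 3], pk[3, 4])
  } else if (modality == "h1_mas") {
    x <- axis %||% seq(-12, 16, by = 0.05)
    y <- gaussian_band(x, 4, 5, 0.35 * latent$bg_mas) +
      gaussian_band(x, 4.6, 1.1, 0.5 * latent$bg_ha) +
      sum_informative_bands(x, latent, "h1_mas") +
      sum_nuisance_lines(x, latent, "h1_mas")
  } else if (modality == "c13_cpmas") {
    x <- axis %||% seq(-5, 195, by = 0.25)
    y <- gaussian_band(x, 25, 8, 0.50 * latent$bg_aliph) +
      gaussian_band(x, 33, 4, 0.25 * latent$bg_aliph) +
      gaussian_band(x, 52, 4, 0.35) +
      gaussian_band(x, 130, 9, 0.18 * latent$bg_arom) +
      gaussian_band(x, 124, 2, 0.02 + 0.10 * bw) +
      sum_informative_bands(x, latent, "c13_cpmas") +
      sum_nuisance_lines(x, latent, "c13_cpmas")
  } else if (modality == "ftir") {
    x <- axis %||% seq(650, 4000, by = 2)
    y <- gaussian_band(x, 3277, 60, 0.35 * latent$bg_amideA) +
      gaussian_band(x, 1634, 14, 0.60) +
      gaussian_band(x, 1516, 12, 0.45) +
      gaussian_band(x, 1234, 12, 0.25 * latent$bg_finger) +
      gaussian_band(x, 1255, 8, 0.03 + 0.30 * bw) +
      gaussian_band(x, 1450, 10, 0.15) +
      gaussian_band(x, 1080, 20, 0.10 * latent$bg_finger) +
      sum_informative_bands(x, latent, "ftir") +
      sum_nuisance_lines(x, latent, "ftir")
  } else if (modality == "dtg") {
    x <- axis %||% seq(40, 500, by = 0.5)
    y <- skewed_band(x, 85, 22, 2, 0.35 * latent$bg_water) +
      skewed_band(x, 238, 13, -1, 1.0 * latent$bg_cortex) +
      gaussian_band(x, 253, 7, 0.05 + 0.45 * bw) +
      sum_informative_bands(x, latent, "dtg") +
      sum_nuisance_lines(x, latent, "dtg")
  } else { # tdnmr
    x <- axis %||% seq(0, 1e-3, by = 2e-6)
    comp <- td_true_components(latent)
    y <- 0
    for (i in 1:3)
      y <- y + comp$proportion[i] *
        abragam_component(x, comp$relaxation_time[i], comp$shape[i],
                          comp$abragam_b[i])
  }
  new_spectrum(x, y, modality, sample_id = latent$sample_id, replicate = 0L)
}

#' Default replicate counts per modality
#' @return named integer vector.
#' @export
default_replicates <- function() {
  c(h1_wideline = 2L, h1_mas = 2L, c13_cpmas = 2L, tdnmr = 5L, ftir = 3L, dtg = 1L)
}

#' Render replicate measurement curves for a latent panel
#'
#' Per modality and replicate, curve = template(latent) * per-replicate scale
#' factor + additive Gaussian point noise with sd = max(template)/snr. The
#' scale factor (sd `scale_sd`) emulates the intensity drift that total-area
#' normalisation later removes. TD-NMR gets 5 replicates and FT-IR 3 by
#' default; DTG curves are multiplied by a sample weight drawn in 10-25 mg.
#'
#' @param latents data.frame from [sample_latents()].
#' @param seed integer seed.
#' @param snr signal-to-noise ratio of added point noise (default 200).
#' @param scale_sd sd of the per-replicate multiplicative drift.
#' @param replicates named replicate counts (see [default_replicates()]).
#' @param modalities modalities to render.
#' @param noise set FALSE for noiseless renders (still applies weights).
#' @return list of `spectrum` objects.
#' @export
render_spectra <- function(latents, seed = 1L, snr = 2000, scale_sd = 0.02,
                           replicates = default_replicates(),
                           modalities = spectrum_modalities(), noise = TRUE) {
  stopifnot(nrow(latents) >= 1)
  bad <- setdiff(modalities, spectrum_modalities())
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "))
  with_seed(derive_seed(seed, "spectra"), {
    out <- list()
    weights <- stats::runif(nrow(latents), 10, 25)
    for (si in seq_len(nrow(latents))) {
      latent <- latents[si, ]
      for (m in modalities) {
        tmpl <- render_template(m, latent)
        nrep <- replicates[[m]] %||% 1L
        w <- if (m == "dtg") weights[si] else NA_real_
        for (r in seq_len(nrep)) {
          y <- tmpl$intensity
          if (noise) {
            y <- y * (1 + stats::rnorm(1, 0, scale_sd)) +
              stats::rnorm(length(y), 0, max(tmpl$intensity) / snr)
          }
          if (m == "dtg") y <- y * w
          out[[length(out) + 1]] <- new_spectrum(
            tmpl$axis, y, m, sample_id = latent$sample_id, replicate = r,
            sample_weight = w)
        }
      }
    }
    out
  })
}

#' Default ground truth: property weights, noise, informative descriptors
#'
#' The four tensile properties are linear/monotone functions of the latents
#' (breaking force additionally proportional to cross-section area, in
#' MPa x mm^2 = N), with coefficients placing the species medians near the
#' qualitative pattern of real hair panels: breaking force high for pig and
#' low for cat; elastic modulus highest for cow; extension highest for
#' human; yield strength high for cow and low for cat.
#'
#' Twenty descriptor ids are informative by design: the bins of the default
#' config covering the planted bands of the three latents that drive yield
#' strength (alpha-helix fraction, thermal resistance, lipid content), each
#' band narrow enough to live in essentially one bin. Yield strength is the
#' benchmark property for selection-power studies: it depends on exactly
#' those latents, so its signal is carried by the 20 listed bins and by
#' nothing else. Bound water shapes the TD-NMR decays, the wide-line narrow
#' peak and several further bands; the descriptors responding to it drive
#' extension and elastic modulus but are deliberately outside the listed
#' set (their information is duplicated by the decay-fit parameters, so no
#' single descriptor id can be called their unique carrier).
#'
#' @param config descriptor config used to resolve bin ids.
#' @return list (class `md_truth`) with `property_weights`, `noise_sd`,
#'   `informative_features`, `informative_descriptor_ids`, `informative_for`.
#' @export
default_ground_truth <- function(config = default_descriptor_config()) {
  weights <- list(
    breaking_force_N = list(intercept = 110, times_csa = TRUE,
                            coef = c(alpha_helix_fraction = 90)),
    elastic_modulus_GPa = list(intercept = 1.5, times_csa = FALSE,
                               coef = c(thermal_resistance = 4.5,
                                        bound_water = -1.5,
                                        alpha_helix_fraction = 0.8)),
    extension_pct = list(intercept = 20, times_csa = FALSE,
                         coef = c(bound_water = 60, lipid_content = 15,
                                  thermal_resistance = -10)),
    yield_strength_MPa = list(intercept = 30, times_csa = FALSE,
                              coef = c(alpha_helix_fraction = 120,
                                       thermal_resistance = 160,
                                       lipid_content = -80),
                              band_weights = band_structure_weights()))
  noise_sd <- c(breaking_force_N = 0.6, elastic_modulus_GPa = 0.8,
                extension_pct = 12, yield_strength_MPa = 25)
  bt <- informative_band_table()
  budget <- informative_bin_budget()
  feats <- NULL
  for (i in seq_len(nrow(budget))) {
    sens <- band_bin_sensitivity(config, budget$key[i], budget$deriv[i])
    top <- names(sort(sens, decreasing = TRUE))[seq_len(budget$n[i])]
    b <- bt[bt$key == budget$key[i], ]
    feats <- rbind(feats, data.frame(
      band = budget$key[i], modality = b$modality, deriv = budget$deriv[i],
      position = b$center, latent = b$latent, id = top))
  }
  if (anyDuplicated(feats$id)) stop("informative features map to duplicate bins")
  structure(list(
    property_weights = weights,
    noise_sd = noise_sd,
    informative_features = feats,
    informative_descriptor_ids = feats$id,
    informative_for = list(
      breaking_force_N = feats$id[feats$latent == "alpha_helix_fraction"],
      elastic_modulus_GPa = feats$id[feats$latent %in%
        c("thermal_resistance", "alpha_helix_fraction")],
      extension_pct = feats$id[feats$latent %in%
        c("lipid_content", "thermal_resistance")],
      yield_strength_MPa = feats$id)), class = "md_truth")
}

#' Expected (noiseless) property values for a latent panel
#' @param latents data.frame from [sample_latents()].
#' @param weights `property_weights` element of a ground truth.
#' @return data.frame sample x property.
#' @export
property_means <- function(latents, weights) {
  out <- data.frame(sample_id = latents$sample_id)
  for (p in names(weights)) {
    w <- weights[[p]]
    m <- rep(w$intercept, nrow(latents))
    for (l in names(w$coef)) m <- m + w$coef[[l]] * latents[[l]]
    if (!is.null(w$band_weights)) {
      bw_ <- w$band_weights
      for (i in seq_len(nrow(bw_))) {
        key <- bw_$key[i]
        za <- latents[[paste0("bz_", key, "_a")]]
        zw <- latents[[paste0("bz_", key, "_w")]]
        zc <- latents[[paste0("bz_", key, "_c")]]
        if (!is.null(za)) m <- m + bw_$w_amp[i] * za
        if (!is.null(zw)) m <- m + bw_$w_width[i] * zw
        if (!is.null(zc)) m <- m + bw_$w_center[i] * zc
      }
    }
    if (isTRUE(w$times_csa)) m <- m * latents$cross_section_area
    out[[p]] <- m
  }
  out
}

#' Render tensile-test replicate tables
#'
#' Ten fibres per sample pool by default; replicate value = latent-determined
#' pool mean + Gaussian noise with the per-property `noise_sd` of the ground
#' truth (same units as the property).
#'
#' @param latents data.frame from [sample_latents()].
#' @param truth ground truth (see [default_ground_truth()]).
#' @param seed integer seed.
#' @param n_replicates fibres tested per pool.
#' @return data.frame sample_id, replicate, and the four property columns.
#' @export
render_properties <- function(latents, truth, seed = 1L, n_replicates = 10L) {
  mu <- property_means(latents, truth$property_weights)
  with_seed(derive_seed(seed, "properties"), {
    out <- NULL
    for (si in seq_len(nrow(mu))) {
      reps <- data.frame(sample_id = mu$sample_id[si],
                         replicate = seq_len(n_replicates))
      for (p in names(truth$property_weights))
        reps[[p]] <- mu[[p]][si] +
          stats::rnorm(n_replicates, 0, truth$noise_sd[[p]])
      out <- rbind(out, reps)
    }
    out
  })
}

#' Simulate a complete multimodal dataset
#'
#' Latent panel, all measurement replicates, tensile replicate table and the
#' planted ground truth, all derived from one master seed.
#'
#' @param n_samples number of sample pools (default 63, mirroring a
#'   9/12/21/21 cat/cow/human/pig panel).
#' @param species_mix named proportions.
#' @param seed master seed.
#' @param snr spectral signal-to-noise (default 2000).
#' @param config descriptor config (resolves informative bin ids).
#' @param noise logical; FALSE gives noiseless spectra and properties.
#' @return object of class `md_dataset`.
#' @export
simulate_dataset <- function(n_samples = 63L, species_mix = default_species_mix(),
                             seed = 1L, snr = 2000,
                             config = default_descriptor_config(),
                             noise = TRUE) {
  latents <- sample_latents(n_samples, species_mix, seed = seed)
  truth <- default_ground_truth(config)
  if (!noise) truth$noise_sd[] <- 0
  spectra <- render_spectra(latents, seed = seed, snr = snr, noise = noise)
  properties <- render_properties(latents, truth, seed = seed)
  structure(list(latents = latents, spectra = spectra, properties = properties,
                 truth = truth, seed = seed, config = config),
            class = "md_dataset")
}

#' @export
print.md_dataset <- function(x, ...) {
  cat(sprintf("<md_dataset %d pools (%s), %d spectra, %d property rows, seed %d>\n",
              nrow(x$latents),
              paste(names(table(x$latents$species)), table(x$latents$species),
                    sep = ":", collapse = " "),
              length(x$spectra), nrow(x$properties), x$seed))
  invisible(x)
}

#' Write a dataset to plain-text files
#'
#' Emits `spectra.csv` (long format), `properties.csv`, `truth.json` and
#' `manifest.json` (seed, config hash, row counts) in `directory`.
#'
#' @param dataset an `md_dataset`.
#' @param directory output directory (created if needed).
#' @param overwrite allow replacing an existing manifest.
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(dataset, directory, overwrite = FALSE) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  man_path <- file.path(directory, "manifest.json")
  if (file.exists(man_path) && !overwrite)
    stop("manifest already exists in ", directory, " (use overwrite = TRUE)")
  long <- spectra_to_long(dataset$spectra)
  utils::write.csv(long, file.path(directory, "spectra.csv"), row.names = FALSE)
  utils::write.csv(dataset$properties, file.path(directory, "properties.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$latents, file.path(directory, "latents.csv"),
                   row.names = FALSE)
  truth <- dataset$truth
  jsonlite::write_json(list(
    property_weights = truth$property_weights,
    noise_sd = as.list(truth$noise_sd),
    informative_features = truth$informative_features,
    informative_descriptor_ids = truth$informative_descriptor_ids,
    informative_for = truth$informative_for),
    file.path(directory, "truth.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = dataset$seed,
                   config_hash = config_hash(dataset$config),
                   n_samples = nrow(dataset$latents),
                   n_spectra = length(dataset$spectra),
                   spectra_rows = nrow(long),
                   property_rows = nrow(dataset$properties))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory dataset directory.
#' @return list with `latents`, `spectra`, `properties`, `truth`, `manifest`.
#' @export
read_dataset <- function(directory) {
  long <- utils::read.csv(file.path(directory, "spectra.csv"))
  list(latents = utils::read.csv(file.path(directory, "latents.csv")),
       spectra = long_to_spectra(long),
       properties = utils::read.csv(file.path(directory, "properties.csv")),
       truth = jsonlite::read_json(file.path(directory, "truth.json"),
                                   simplifyVector = TRUE),
       manifest = jsonlite::read_json(file.path(directory, "manifest.json"),
                                      simplifyVector = TRUE))
}
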