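#' Pre-treat all spectra of a dataset into per-sample profiles
#'
#' Applies the per-modality recipes and averages replicates, yielding one
#' profile per sample for every (modality, derivative-order) combination the
#' descriptor stage consumes:
#'
#' * NMR (`h1_wideline`, `h1_mas`, `c13_cpmas`): differentiate (2der branch)
#'   -> truncate to the informative region -> normalise to unit total area
#'   -> average replicates. The nonderivative branch skips differentiation.
#' * `ftir`: SG second derivative -> excise the crystal-interference windows
#'   (1711-2669, 3400-4000 cm-1) -> area-normalise -> average.
#' * `dtg`: rebin to 1 C and divide by sample weight; the second-derivative
#'   branch differentiates the prepared curve to sharpen mass-loss events.
#' * `tdnmr`: fit each replicate decay as three components, normalise so the
#'   fitted intensity at t = 0 is one, average the five replicate decays
#'   (`td_prefit`) and the five fitted model curves (`td_fitted`), and
#'   average the fitted parameters (`td_params`).
#'
#' @param dataset an `md_dataset` (or list with `spectra`, `latents`).
#' @param config descriptor config.
#' @param verbose print stage progress.
#' @return list of per-sample profile lists, plus `td_params` (per-sample
#'   averaged `td_fit`) and `voigt_fits` (per-sample `voigt_fit` on the
#'   averaged normalised wide-line profile), and `sample_ids`.
#' @export
pretreat_dataset <- function(dataset, config = default_descriptor_config(),
                             verbose = FALSE) {
  spectra <- dataset$spectra
  sample_ids <- unique(vapply(spectra, `[[`, "", "sample_id"))
  by_sm <- split(spectra, interaction(
    vapply(spectra, `[[`, "", "sample_id"),
    vapply(spectra, `[[`, "", "modality"), drop = TRUE))
  regions <- list(h1_wideline = c(-102, 102), h1_mas = c(-8, 14.2),
                  c13_cpmas = c(2.8, 185.2))
  w <- config$sg_window
  out <- list(sample_ids = sample_ids)
  grab <- function(sid, mod) by_sm[[paste(sid, mod, sep = ".")]]

  for (mod in c("h1_wideline", "h1_mas", "c13_cpmas")) {
    r <- regions[[mod]]
    out[[paste0(mod, "_d0")]] <- lapply(sample_ids, function(sid) {
      reps <- lapply(grab(sid, mod), function(sp)
        normalize_total_area(truncate_spectrum(sp, r[1], r[2])))
      average_replicates(reps)
    })
    out[[paste0(mod, "_d2")]] <- lapply(sample_ids, function(sid) {
      reps <- lapply(grab(sid, mod), function(sp)
        normalize_total_area(truncate_spectrum(sg_second_derivative(sp, w), r[1], r[2])))
      average_replicates(reps)
    })
    if (verbose) message("pretreated ", mod)
  }

  out$ftir_d2 <- lapply(sample_ids, function(sid) {
    reps <- lapply(grab(sid, "ftir"), function(sp)
      normalize_total_area(exclude_regions(sg_second_derivative(sp, w),
                                           config$ftir_exclude)))
    average_replicates(reps)
  })
  if (verbose) message("pretreated ftir")

  out$dtg_d0 <- lapply(sample_ids, function(sid) {
    average_replicates(lapply(grab(sid, "dtg"), dtg_prepare))
  })
  out$dtg_d2 <- lapply(sample_ids, function(sid) {
    average_replicates(lapply(grab(sid, "dtg"), function(sp)
      sg_second_derivative(dtg_prepare(sp), w)))
  })
  if (verbose) message("pretreated dtg")

  td_prefit <- td_fitted <- td_params <- list()
  for (sid in sample_ids) {
    reps <- grab(sid, "tdnmr")
    fits <- lapply(reps, fit_td3)
    norm <- mapply(td_normalize, reps, fits, SIMPLIFY = FALSE)
    td_prefit[[sid]] <- average_replicates(norm)
    fitted_curves <- mapply(function(sp, f) {
      new_spectrum(sp$axis, f$fitted / sum(f$amplitudes), "tdnmr",
                   sample_id = sid, replicate = sp$replicate)
    }, reps, fits, SIMPLIFY = FALSE)
    td_fitted[[sid]] <- average_replicates(fitted_curves)
    td_params[[sid]] <- average_fit_params(fits)
  }
  out$td_prefit <- td_prefit
  out$td_fitted <- td_fitted
  out$td_params <- td_params
  if (verbose) message("fitted tdnmr (", length(sample_ids), " samples x 5 reps)")

  out$voigt_fits <- lapply(seq_along(sample_ids), function(i)
    fit_voigt3(out$h1_wideline_d0[[i]]))
  names(out$voigt_fits) <- sample_ids
  if (verbose) message("voigt-3 deconvolution done")
  out
}

profile_matrix <- function(profiles) {
  t(vapply(profiles, `[[`, numeric(length(profiles[[1]]$axis)), "intensity"))
}

profile_key <- function(modality, deriv) {
  if (modality == "ftir") return("ftir_d2")
  paste0(modality, "_d", deriv)
}

#' Build the full descriptor table of a dataset
#'
#' Runs [pretreat_dataset()] and converts the per-sample profiles into the
#' descriptor table: even-step bins per configured block, 40 logarithmic
#' TD-NMR bins, PCA scores (>1 percent variance rule) of every profile
#' family including the pre-fitted and fitted decay curves, and the
#' deconvolution parameters (Voigt area proportions and FWHMs; TD intensity
#' proportions and relaxation times) with their inverse/exp/log/ratio
#' transforms.
#'
#' @param dataset an `md_dataset`.
#' @param config descriptor config.
#' @param pre optional pre-computed [pretreat_dataset()] result.
#' @param verbose print stage progress.
#' @return a `descriptor_table`.
#' @export
build_descriptor_table <- function(dataset, config = default_descriptor_config(),
                                   pre = NULL, verbose = FALSE) {
  pre <- pre %||% pretreat_dataset(dataset, config, verbose = verbose)
  sids <- pre$sample_ids
  blocks <- list()

  for (block in config$bins) {
    key <- profile_key(block$modality, block$deriv)
    rows <- lapply(pre[[key]], function(sp) bin_block(sp, block))
    mat <- do.call(rbind, lapply(rows, function(r) r$values))
    rownames(mat) <- sids
    blocks[[length(blocks) + 1]] <- list(matrix = mat, meta = rows[[1]]$meta)
  }

  td_rows <- lapply(pre$td_prefit, function(sp)
    bin_log_decay(sp, config$td_bins$n, config$td_bins$t_max))
  td_mat <- do.call(rbind, lapply(td_rows, function(r) r$values))
  rownames(td_mat) <- sids
  blocks[[length(blocks) + 1]] <- list(matrix = td_mat,
                                       meta = td_rows[[1]]$meta)
  if (verbose) message("binning done")

  pca_specs <- list(
    c("h1_wideline_d0", "wideline.pca", "h1_wideline", 0),
    c("h1_wideline_d2", "wideline.2der.pca", "h1_wideline", 2),
    c("h1_mas_d0", "mas.pca", "h1_mas", 0),
    c("h1_mas_d2", "mas.2der.pca", "h1_mas", 2),
    c("c13_cpmas_d0", "cpmas.pca", "c13_cpmas", 0),
    c("c13_cpmas_d2", "cpmas.2der.pca", "c13_cpmas", 2),
    c("ftir_d2", "ftir.2der.pca", "ftir", 2),
    c("dtg_d0", "dtg.pca", "dtg", 0),
    c("dtg_d2", "dtg.2der.pca", "dtg", 2),
    c("td_prefit", "tdnmr.prefit.pca", "tdnmr", 0),
    c("td_fitted", "tdnmr.fitted.pca", "tdnmr", 0))
  for (ps in pca_specs) {
    pc <- pca_descriptors(profile_matrix(pre[[ps[1]]]),
                          var_threshold = config$pca$var_threshold,
                          prefix = ps[2], modality = ps[3],
                          derivative_order = as.integer(ps[4]))
    rownames(pc$scores) <- sids
    blocks[[length(blocks) + 1]] <- list(matrix = pc$scores, meta = pc$meta)
  }
  if (verbose) message("pca done")

  deconv_block <- function(param_list, prefix, modality) {
    rows <- lapply(param_list, function(par) {
      raw <- list(values = par,
                  meta = data.frame(id = paste0(prefix, ".", names(par)),
                                    modality = modality, processing = "deconv",
                                    derivative_order = 0L, formula = names(par)))
      names(raw$values) <- raw$meta$id
      der <- derived_transforms(par, prefix = prefix, modality = modality)
      list(values = c(raw$values, der$values),
           meta = rbind(raw$meta, der$meta))
    })
    mat <- do.call(rbind, lapply(rows, function(r) r$values))
    rownames(mat) <- sids
    list(matrix = mat, meta = rows[[1]]$meta)
  }

  voigt_params <- lapply(pre$voigt_fits, function(f)
    stats::setNames(c(f$area_proportions, f$fwhm),
                    c("p1", "p2", "p3", "f1", "f2", "f3")))
  blocks[[length(blocks) + 1]] <- deconv_block(
    voigt_params, config$deconv$voigt_prefix, "h1_wideline")

  td_pars <- lapply(pre$td_params, function(f)
    stats::setNames(c(f$components$proportion, f$components$relaxation_time),
                    c("p1", "p2", "p3", "t1", "t2", "t3")))
  blocks[[length(blocks) + 1]] <- deconv_block(
    td_pars, config$deconv$td_prefix, "tdnmr")
  if (verbose) message("deconvolution descriptors done")

  assemble_table(blocks, sids, config = config)
}

#' Predicted descriptor-column count of a config
#'
#' Bin and deconvolution counts follow from the config arithmetically; PCA
#' counts are data-dependent (>1 percent rule) and are passed in.
#'
#' @param config descriptor config.
#' @param pca_counts integer vector of retained components per PCA block.
#' @return integer column count.
#' @export
predicted_descriptor_count <- function(config, pca_counts = 0L) {
  nbin <- sum(vapply(config$bins, function(b) sum(b$n), 0))
  ndeconv <- 2L * (6L + 3L * 6L + 6L * 5L)   # raw + transforms, two families
  nbin + config$td_bins$n + ndeconv + sum(pca_counts)
}
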