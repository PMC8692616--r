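#' Measurement curve container
#'
#' A `spectrum` holds one replicate measurement curve of one modality together
#' with its processing lineage. Modalities and their axis units:
#'
#' * `h1_wideline` — static (anisotropic) 1H NMR, ppm
#' * `h1_mas`      — 1H magic-angle-spinning NMR, ppm
#' * `c13_cpmas`   — 13C CP-MAS NMR, ppm
#' * `tdnmr`       — time-domain NMR solid-echo decay, seconds
#' * `ftir`        — ATR FT-IR, wavenumber cm-1
#' * `dtg`         — derivative thermogravimetry, degrees C
#'
#' The axis must be strictly monotone increasing; `lineage` is an append-only
#' record of the processing steps applied; `derivative_order` is 0 for raw
#' profiles and 2 once Savitzky-Golay second-order differentiation has run.
#'
#' @param axis numeric, strictly increasing.
#' @param intensity numeric, same length.
#' @param modality one of the six modality tokens.
#' @param sample_id character sample pool id.
#' @param replicate integer replicate index (NA for aggregates).
#' @param sample_weight sample mass in mg (DTG only).
#' @param lineage character vector of processing tokens.
#' @param derivative_order 0 or 2.
#' @return object of class `spectrum`.
#' @export
new_spectrum <- function(axis, intensity, modality,
                         sample_id = "s", replicate = 1L,
                         sample_weight = NA_real_,
                         lineage = character(), derivative_order = 0L) {
  modality <- match.arg(modality, spectrum_modalities())
  axis <- as.numeric(axis); intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("axis and intensity lengths differ")
  if (length(axis) >= 2 && any(diff(axis) <= 0))
    stop("axis must be strictly increasing")
  if (!derivative_order %in% c(0L, 2L)) stop("derivative_order must be 0 or 2")
  structure(
    list(axis = axis, intensity = intensity, modality = modality,
         sample_id = as.character(sample_id), replicate = replicate,
         sample_weight = sample_weight,
         lineage = as.character(lineage),
         derivative_order = as.integer(derivative_order)),
    class = "spectrum")
}

#' Recognised measurement modalities
#' @return character vector of modality tokens.
#' @export
spectrum_modalities <- function() {
  c("h1_wideline", "h1_mas", "c13_cpmas", "tdnmr", "ftir", "dtg")
}

#' Axis unit of a modality
#' @param modality modality token.
#' @return unit string.
#' @export
axis_unit <- function(modality) {
  switch(match.arg(modality, spectrum_modalities()),
         h1_wideline = "ppm", h1_mas = "ppm", c13_cpmas = "ppm",
         tdnmr = "s", ftir = "cm-1", dtg = "degC")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s | %s rep %s | %d pts [%.4g, %.4g] %s | d%d>\n",
              x$modality, x$sample_id, as.character(x$replicate),
              length(x$axis), min(x$axis), max(x$axis),
              axis_unit(x$modality), x$derivative_order))
  if (length(x$lineage)) cat("  lineage:", paste(x$lineage, collapse = " -> "), "\n")
  invisible(x)
}

append_lineage <- function(sp, token) {
  sp$lineage <- c(sp$lineage, token)
  sp
}

#' Convert a list of spectra to one long-format data frame
#' @param spectra list of `spectrum`.
#' @return data.frame with columns sample_id, replicate, modality, axis_value,
#'   intensity, axis_unit, sample_weight_mg.
#' @export
spectra_to_long <- function(spectra) {
  do.call(rbind, lapply(spectra, function(sp) {
    data.frame(sample_id = sp$sample_id, replicate = sp$replicate,
               modality = sp$modality, axis_value = sp$axis,
               intensity = sp$intensity, axis_unit = axis_unit(sp$modality),
               sample_weight_mg = sp$sample_weight)
  }))
}

#' Rebuild spectrum objects from a long-format data frame
#' @param df data frame as produced by [spectra_to_long()].
#' @return list of `spectrum`.
#' @export
long_to_spectra <- function(df) {
  key <- interaction(df$sample_id, df$replicate, df$modality, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$axis_value), ]
    new_spectrum(d$axis_value, d$intensity, d$modality[1],
                 sample_id = d$sample_id[1], replicate = d$replicate[1],
                 sample_weight = d$sample_weight_mg[1])
  })
}
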