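# shared small fixtures, built in code

tiny_latents <- function(n = 6, seed = 3) sample_latents(n, seed = seed)

# a single reference latent row with all jitters at their defaults
ref_latent <- function(bound_water = 0.5, lipid_content = 0.5,
                       alpha_helix_fraction = 0.5, thermal_resistance = 0.5) {
  data.frame(sample_id = "ref",
             alpha_helix_fraction = alpha_helix_fraction,
             lipid_content = lipid_content, bound_water = bound_water,
             thermal_resistance = thermal_resistance,
             cross_section_area = 0.01)
}

# planted three-component decay with additive noise at the given SNR
planted_decay <- function(bound_water = 0.5, snr = Inf,
                          t = seq(0, 1e-3, 2e-6)) {
  comp <- td_true_components(data.frame(bound_water = bound_water))
  y <- 0
  for (j in 1:3)
    y <- y + comp$proportion[j] *
      abragam_component(t, comp$relaxation_time[j], comp$shape[j],
                        comp$abragam_b[j])
  if (is.finite(snr)) y <- y + stats::rnorm(length(t), 0, 1 / snr)
  list(decay = new_spectrum(t, y, "tdnmr"), components = comp)
}

# data matrix whose sample covariance has the requested variance proportions
matrix_with_var_props <- function(props, n = 40, p = 8, seed = 5) {
  stopifnot(length(props) <= min(n - 1, p))
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * length(props)), n))))[, -1, drop = FALSE]
  v <- qr.Q(qr(matrix(rnorm(p * length(props)), p)))
  d <- sqrt(props * (n - 1))
  q %*% diag(d, length(props)) %*% t(v)
}
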