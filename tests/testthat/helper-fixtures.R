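# Small fixtures shared across tests; everything is generated in code.

# three-class recipe on small patches for fast unit tests
tiny_recipe <- function(noise_sd = 0.03, seed = 1L) {
  cp <- list(
    crop_phenology(0L, 0.10, 0.25, 130, 250, 0.05, noise_sd),
    crop_phenology(1L, 0.15, 0.85, 150, 260, 0.12, noise_sd),
    crop_phenology(2L, 0.16, 0.70, 105, 195, 0.12, noise_sd))
  scene_recipe(cp, class_proportions = c(0.4, 0.35, 0.25),
               parcel_min = 4L, parcel_max = 6L,
               dates = seq(100, 250, by = 30), seed = seed)
}

# matching miniature network configuration (6 dates, 12 px patches)
tiny_config <- function(use_sa = TRUE, radix = 2L) {
  safpn_config(stage_channels = c(8L, 8L, 16L, 16L), pyramid_channels = 8L,
               n_classes = 3L, n_dates = 6L, n_bands = 4L, patch_size = 12L,
               stem_channels = 4L, use_sa = use_sa,
               sa = sa_config(radix = radix))
}

tiny_loss <- function(...) {
  loss_config(alpha = c(0.2, 0.5, 0.5), ...)
}

# independent scalar double-logistic evaluation (oracle for phenology_curve)
dl_oracle <- function(base, peak, gu, sen, rate, d) {
  sig <- function(z) 1 / (1 + exp(-z))
  base + (peak - base) * (sig(rate * (d - gu)) - sig(rate * (d - sen)))
}
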