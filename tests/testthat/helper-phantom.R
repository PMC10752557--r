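## Small, fast phantom parameter sets used throughout the suite. Same
## generative structure as the defaults, scaled down for grid size.
small_params <- function(...) {
  defaults <- list(image_matrix = 96L, pixel_spacing = 1.5,
                   kidney_axes = c(40, 70), psoas_axes = c(18, 34),
                   n_cysts = 5L, cyst_radius_range = c(2.5, 6))
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

## No site effect, no noise: useful when a test needs exact tissue means.
clean_params <- function(...) {
  defaults <- list(site_scale_range = c(1, 1), site_offset_range = c(0, 0),
                   noise_sd = 0)
  do.call(small_params, utils::modifyList(defaults, list(...)))
}
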