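# Shared shortcuts for simulated fields.

noise_off <- function(...) {
  simulation_params(..., poisson_noise = FALSE, read_noise_sd = 0)
}

# background-derived fixed thresholds per analysis channel of a simulation
field_thresholds <- function(sim) {
  proj <- max_project(sim$stack)
  bg <- !truth_mask(sim$truth, "cell")
  list(
    enzyme = background_threshold(channel_image(proj, "enzyme"), bg),
    golgi_marker = background_threshold(channel_image(proj, "golgi_marker"), bg),
    er_marker = background_threshold(channel_image(proj, "er_marker"), bg),
    glycan = background_threshold(channel_image(proj, "glycan"), bg))
}

# minimal CLI config for simulated five-channel fields
write_cfg <- function(path, extra = list()) {
  cfg <- utils::modifyList(list(
    channels = list("nuclei", "golgi_marker", "er_marker", "enzyme", "glycan"),
    pixel_size = 0.1,
    page_order = "channel-major",
    threshold = list(method = "fixed",
                     values = list(nuclei = 750, golgi_marker = 20,
                                   er_marker = 8, enzyme = 8, glycan = 8)),
    segmentation = list(min_nucleus_size = 20),
    simulate = list(n_cells = 4, relocation_fraction = 0.3, seed = 1)),
    extra)
  yaml::write_yaml(cfg, path)
  path
}
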