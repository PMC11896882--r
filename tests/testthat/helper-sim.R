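# Shared fixtures, built in code. The small world: two 4-ha plots, sixteen
# quadrats each, generated once and reused read-only across test files.

small_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_plots = 2, plot_side = 200,
               quadrat_spacing = 50, tree_density = 450, liana_density = 700,
               n_tree_species = 12, n_liana_taxa = 20, mound_density = 2.5)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# all effect knobs off: the neutral world used by calibration checks
neutral_config <- function(seed = 11, ...) {
  small_config(seed = seed, beta_structure = c(QMD_T = 0),
               env_response_sd = 0, theta_host_sdlog = 0,
               trait_niche_cor = 0, ...)
}

shared_sim <- simulate_community(small_config())

# canopy height at arbitrary points of a plot (nearest-cell lookup)
chm_at <- function(landscape_plot, x, y) {
  dem <- landscape_plot$dem; dsm <- landscape_plot$dsm
  cc <- raster_coords(dem)
  jx <- findInterval(x, cc$x - dem$cell_size / 2)
  iy <- findInterval(y, cc$y - dem$cell_size / 2)
  pmax(dsm$values - dem$values, 0)[cbind(iy, jx)]
}
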