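#' Environment variable names used throughout the workflow
#'
#' Quadrat-scale predictors: tree abundance (N_T, stems/ha), tree basal area
#' (BA_T, m2/ha), tree quadratic mean diameter (QMD_T, cm), tree mean wood
#' density (WD_T, g/cm3), basal-area change between censuses (dBA_T, m2),
#' mean top-of-canopy height (meanTCH, m), giant-herb foliar cover (GHFC,
#' index 1-3) and relative slope position (RSP, 0-1).
#' @export
ENV_VARS <- c("N_T", "BA_T", "QMD_T", "WD_T", "dBA_T", "meanTCH", "GHFC", "RSP")

#' Trait names and plausible ranges for the liana trait table
#'
#' Leaf thickness (mm), specific leaf area (mm2/mg), leaf carbon, nitrogen,
#' phosphate and potassium concentrations (%), and stem tissue density
#' (g/cm3). Default ranges are those observed for the 44 trait-covered taxa
#' at the study site.
#' @export
TRAIT_RANGES <- list(
  Thick = c(0.04, 0.2),
  SLA   = c(13.0, 64.7),
  C     = c(38.9, 48.2),
  N     = c(2.1, 5.8),
  PO4   = c(0.07, 0.27),
  K     = c(0.3, 2.2),
  TD    = c(0.16, 0.59)
)

#' Simulation configuration
#'
#' Collects every knob of the synthetic census generator. Defaults describe
#' the field design the analyses assume: four 9-ha plots (300 x 300 m) each
#' holding 36 20 x 20-m liana quadrats (4/ha, 50-m centres) with a 10-m
#' buffer for tree windows; ~450 trees/ha above 10 cm DBH; ~1077 liana
#' stems/ha dominated by 1-2 cm stems; 1.5-3 large termite mounds per ha
#' with radius 9.9 +/- 3.3 m and height 4.1 +/- 1.5 m on a low-relief
#' terrain (total relief well under 23 m).
#'
#' Effect-size knobs (`beta_structure`, `env_response_sd`,
#' `trait_niche_cor`, `theta_host`) control how much signal the generated
#' community carries; setting them to zero yields a fully neutral world used
#' by the calibration tests.
#'
#' @param seed integer seed; all stochastic draws flow from it.
#' @param n_plots number of square plots.
#' @param plot_side plot edge length (m); must be divisible by `quadrat_side`.
#' @param quadrat_side liana quadrat edge (m).
#' @param buffer buffer added on each side for tree windows (m).
#' @param cell_size raster resolution (m).
#' @param quadrat_spacing distance between quadrat centres (m).
#' @param tree_density,liana_density stems per hectare.
#' @param mound_density termite mounds per hectare.
#' @param mound_radius_mean_sd,mound_height_mean_sd length-2 numeric,
#'   mean and sd of mound radius and height (m).
#' @param base_relief amplitude (m) of the smooth background terrain.
#' @param canopy_max maximum canopy height (m).
#' @param canopy_smooth Gaussian smoothing bandwidth (m) of the canopy field.
#' @param gap_fraction fraction of the area covered by canopy gaps.
#' @param gap_radius typical gap radius (m).
#' @param n_tree_species,n_liana_taxa numbers of taxa.
#' @param dominance Dirichlet concentration of the rank-abundance draw;
#'   small values give strong hyperdominance.
#' @param beta_structure named numeric vector (subset of [ENV_VARS]) of
#'   log-linear effects of the standardized environment on expected liana
#'   counts per quadrat.
#' @param env_response optional `n_liana_taxa x 8` matrix of per-taxon niche
#'   coefficients; if `NULL`, drawn with sd `env_response_sd`.
#' @param env_response_sd sd of drawn niche coefficients.
#' @param theta_host optional `n_liana_taxa x n_tree_species` nonnegative
#'   host preference weight matrix; if `NULL`, drawn log-normal with sdlog
#'   `theta_host_sdlog` (0 = neutral host choice).
#' @param theta_host_sdlog sdlog of drawn host preference weights.
#' @param second_host_fraction fraction of lianas assigned a second host.
#' @param trait_ranges named list of `c(min, max)` per trait.
#' @param trait_niche_cor correlation between a taxon's trait value and its
#'   canopy-height niche coefficient (the trait-environment signal knob).
#' @param herb_coef decrease of the giant-herb latent cover index per metre
#'   of canopy height (herbs favour gaps).
#' @param growth_mean,growth_sd diameter increment (cm) between censuses.
#' @param mortality_rate per-stem probability of dying before census 2.
#' @param recruitment_rate expected recruits as a fraction of initial stems.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_plots = 4L,
                       plot_side = 300,
                       quadrat_side = 20,
                       buffer = 10,
                       cell_size = 1,
                       quadrat_spacing = 50,
                       tree_density = 450,
                       liana_density = 1077,
                       mound_density = 2.25,
                       mound_radius_mean_sd = c(9.9, 3.3),
                       mound_height_mean_sd = c(4.1, 1.5),
                       base_relief = 12,
                       canopy_max = 45,
                       canopy_smooth = 8,
                       gap_fraction = 0.05,
                       gap_radius = 10,
                       n_tree_species = 60L,
                       n_liana_taxa = 82L,
                       dominance = 0.08,
                       beta_structure = c(QMD_T = -0.16, meanTCH = -0.15,
                                          WD_T = -0.14, dBA_T = -0.06,
                                          GHFC = -0.08),
                       env_response = NULL,
                       env_response_sd = 0.3,
                       theta_host = NULL,
                       theta_host_sdlog = 0.5,
                       second_host_fraction = 0.1,
                       trait_ranges = TRAIT_RANGES,
                       trait_niche_cor = 0.5,
                       herb_coef = 0.08,
                       growth_mean = 0.5,
                       growth_sd = 0.4,
                       mortality_rate = 0.02,
                       recruitment_rate = 0.03) {
  cfg <- as.list(environment())
  if (cfg$plot_side %% cfg$quadrat_side != 0)
    stop("plot_side must be divisible by quadrat_side")
  for (nm in c("tree_density", "liana_density", "cell_size"))
    if (cfg[[nm]] <= 0) stop(nm, " must be > 0")
  if (cfg$mound_density < 0) stop("mound_density must be >= 0")
  if (cfg$quadrat_spacing < cfg$quadrat_side)
    stop("quadrat_spacing must be at least quadrat_side")
  bad <- setdiff(names(cfg$beta_structure), ENV_VARS)
  if (length(bad)) stop("unknown beta_structure names: ", paste(bad, collapse = ", "))
  for (nm in names(cfg$trait_ranges)) {
    rg <- cfg$trait_ranges[[nm]]
    if (length(rg) != 2 || rg[1] >= rg[2])
      stop("trait range for ", nm, " must be c(min, max) with min < max")
  }
  if (!is.null(cfg$theta_host)) {
    th <- cfg$theta_host
    if (any(th < 0)) stop("theta_host must be nonnegative")
    if (any(rowSums(th) == 0)) stop("theta_host rows must not be all zero")
    if (nrow(th) != cfg$n_liana_taxa || ncol(th) != cfg$n_tree_species)
      stop("theta_host must be n_liana_taxa x n_tree_species")
  }
  if (!is.null(cfg$env_response)) {
    er <- cfg$env_response
    if (nrow(er) != cfg$n_liana_taxa || ncol(er) != length(ENV_VARS))
      stop("env_response must be n_liana_taxa x ", length(ENV_VARS))
  }
  if (abs(cfg$trait_niche_cor) > 1) stop("trait_niche_cor must be in [-1, 1]")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Plot origins for a multi-plot design
#'
#' Plots are laid out on a grid with 200-m gaps so that inter-quadrat
#' distances across plots resemble a real landscape of scattered permanent
#' plots.
#' @param config a [sim_config].
#' @return data.frame with `plot_id`, `origin_x`, `origin_y` (m).
#' @export
plot_layout <- function(config) {
  n <- config$n_plots
  ncol_grid <- ceiling(sqrt(n))
  step <- config$plot_side + 200
  idx <- seq_len(n) - 1L
  data.frame(
    plot_id = paste0("P", seq_len(n)),
    origin_x = (idx %% ncol_grid) * step,
    origin_y = (idx %/% ncol_grid) * step
  )
}

#' Quadrat frame for a simulated design
#'
#' Lays out `(plot_side / quadrat_spacing)^2` quadrats per plot at regular
#' `quadrat_spacing` centres, with plot-local bounds and the buffered
#' (window) bounds used for tree metrics and host choice.
#'
#' @param config a [sim_config].
#' @return data.frame of class `quadrat_frame`: `quadrat_id`, `plot_id`,
#'   local bounds `xmin..ymax`, buffered bounds `bxmin..bymax`, global
#'   centres `gx`, `gy`.
#' @export
quadrat_frame <- function(config) {
  lay <- plot_layout(config)
  per_side <- floor(config$plot_side / config$quadrat_spacing)
  off <- (config$plot_side - (per_side - 1) * config$quadrat_spacing) / 2
  centers <- off + (seq_len(per_side) - 1) * config$quadrat_spacing
  half <- config$quadrat_side / 2
  buf <- config$buffer
  out <- do.call(rbind, lapply(seq_len(nrow(lay)), function(p) {
    gg <- expand.grid(cx = centers, cy = centers)
    data.frame(
      quadrat_id = sprintf("%s_Q%02d", lay$plot_id[p], seq_len(nrow(gg))),
      plot_id = lay$plot_id[p],
      xmin = gg$cx - half, xmax = gg$cx + half,
      ymin = gg$cy - half, ymax = gg$cy + half,
      bxmin = gg$cx - half - buf, bxmax = gg$cx + half + buf,
      bymin = gg$cy - half - buf, bymax = gg$cy + half + buf,
      gx = lay$origin_x[p] + gg$cx,
      gy = lay$origin_y[p] + gg$cy
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("quadrat_frame", "data.frame")
  out
}
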