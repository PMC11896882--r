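# Synthetic stem-level census generator. The generator produces the raw
# structure the quadrat-level analyses assume: a low-relief terrain dotted
# with termite mounds, a spatially autocorrelated canopy with gaps, a
# two-census tree inventory, a giant-herb cover grid, liana stems with host
# links, and a trait table -- together with the ground-truth parameters used
# by the recovery tests.

# Gaussian smoothing of a matrix (separable kernel, reflected edges).
gauss_filter <- function(m, sigma_cells) {
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  smooth1 <- function(mm) {
    n <- nrow(mm)
    pad_top <- mm[pmin(half:1, n), , drop = FALSE]
    pad_bot <- mm[pmax(n - (1:half) + 1, 1), , drop = FALSE]
    mp <- rbind(pad_top, mm, pad_bot)
    f <- stats::filter(mp, k, sides = 2)
    matrix(f[(half + 1):(half + n), ], n, ncol(mm))
  }
  t(smooth1(t(smooth1(m))))
}

rescale01 <- function(m) {
  rg <- range(m)
  if (rg[1] == rg[2]) return(m * 0)
  (m - rg[1]) / (rg[2] - rg[1])
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- x < lower
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower
  }
  x
}

#' Simulate terrain and canopy rasters for every plot
#'
#' The terrain (DEM) is a smooth low-relief background field plus Gaussian
#' bumps for termite mounds at Poisson locations (density, radius and height
#' from the configuration). The surface model (DSM) adds a spatially
#' autocorrelated canopy height field in `[0, canopy_max]` with circular gap
#' patches (canopy near zero) covering `gap_fraction` of the area.
#'
#' @param config a [sim_config]. Call inside a seeded context (see
#'   [simulate_community]) for reproducibility.
#' @return named list per plot of `list(dem, dsm)` [ls_raster]s in
#'   plot-local coordinates.
#' @export
simulate_landscape <- function(config) {
  lay <- plot_layout(config)
  side <- config$plot_side
  cs <- config$cell_size
  ncell <- ceiling(side / cs)
  if (ncell < 2) stop("plot has zero area at this cell size")
  area_ha <- side^2 / 10000
  cc <- (seq_len(ncell) - 0.5) * cs
  out <- list()
  for (p in seq_len(nrow(lay))) {
    base <- gauss_filter(matrix(rnorm(ncell^2), ncell, ncell), 40 / cs)
    dem <- rescale01(base) * config$base_relief
    n_mound <- rpois(1, config$mound_density * area_ha)
    if (n_mound > 0) {
      mx <- runif(n_mound, 0, side)
      my <- runif(n_mound, 0, side)
      mr <- rtrunc_norm(n_mound, config$mound_radius_mean_sd[1],
                        config$mound_radius_mean_sd[2], 2)
      mh <- rtrunc_norm(n_mound, config$mound_height_mean_sd[1],
                        config$mound_height_mean_sd[2], 0.5)
      for (m in seq_len(n_mound)) {
        d2 <- outer(cc - my[m], cc - mx[m], function(a, b) a^2 + b^2)
        s2 <- (mr[m] / 2)^2
        dem <- dem + mh[m] * exp(-d2 / (2 * s2))
      }
    }
    canopy <- rescale01(gauss_filter(matrix(rnorm(ncell^2), ncell, ncell),
                                     config$canopy_smooth / cs)) * config$canopy_max
    if (config$gap_fraction > 0) {
      n_gap <- rpois(1, config$gap_fraction * side^2 / (pi * config$gap_radius^2))
      if (n_gap > 0) {
        gx <- runif(n_gap, 0, side); gy <- runif(n_gap, 0, side)
        gr <- config$gap_radius * runif(n_gap, 0.6, 1.4)
        for (g in seq_len(n_gap)) {
          d2 <- outer(cc - gy[g], cc - gx[g], function(a, b) a^2 + b^2)
          canopy[d2 <= gr[g]^2] <- runif(sum(d2 <= gr[g]^2), 0, 1)
        }
      }
    }
    out[[lay$plot_id[p]]] <- list(
      dem = ls_raster(dem, 0, 0, cs),
      dsm = ls_raster(dem + pmax(canopy, 0), 0, 0, cs),
      n_mounds = n_mound
    )
  }
  out
}

# Rank-abundance profile: sorted draw from a symmetric Dirichlet.
rank_abundance <- function(n_taxa, concentration) {
  g <- rgamma(n_taxa, shape = concentration, rate = 1)
  if (all(g == 0)) g[1] <- 1
  sort(g / sum(g), decreasing = TRUE)
}

#' Simulate a two-census tree inventory
#'
#' Stems get uniform positions, species from a Dirichlet-multinomial
#' rank-abundance profile, first-census DBH from a shifted exponential
#' (>= 10 cm), and per-species wood densities. The second census applies
#' growth increments, random mortality and recruitment at the 10-cm
#' threshold, so basal-area change varies among windows.
#'
#' @param config a [sim_config].
#' @param landscape output of [simulate_landscape] (defines plot extent).
#' @return data.frame stem table: `stem_id`, `plot_id`, `species`, `x`,
#'   `y`, `dbh_census1`, `dbh_census2`, `wood_density`. Dead stems have
#'   `dbh_census2 = NA`; recruits have `dbh_census1 = NA`.
#' @export
simulate_trees <- function(config, landscape) {
  side <- config$plot_side
  area_ha <- side^2 / 10000
  n_per_plot <- round(config$tree_density * area_ha)
  if (n_per_plot < 1) stop("tree density implies < 1 stem per plot")
  S <- config$n_tree_species
  probs <- rank_abundance(S, 0.5)
  species_pool <- sprintf("T%03d", seq_len(S))
  wd_pool <- pmin(pmax(rnorm(S, 0.6, 0.15), 0.1), 1.2)
  tabs <- lapply(names(landscape), function(pid) {
    sp <- sample.int(S, n_per_plot, replace = TRUE, prob = probs)
    dbh1 <- 10 + rexp(n_per_plot, rate = 1 / 15)
    dead <- runif(n_per_plot) < config$mortality_rate
    growth <- pmax(rnorm(n_per_plot, config$growth_mean, config$growth_sd), 0)
    dbh2 <- ifelse(dead, NA_real_, dbh1 + growth)
    n_rec <- rpois(1, config$recruitment_rate * n_per_plot)
    rec_sp <- if (n_rec) sample.int(S, n_rec, replace = TRUE, prob = probs) else integer()
    data.frame(
      plot_id = pid,
      species = species_pool[c(sp, rec_sp)],
      x = runif(n_per_plot + n_rec, 0, side),
      y = runif(n_per_plot + n_rec, 0, side),
      dbh_census1 = c(dbh1, rep(NA_real_, n_rec)),
      dbh_census2 = c(dbh2, if (n_rec) 10 + rexp(n_rec, 1 / 3) else numeric()),
      wood_density = wd_pool[c(sp, rec_sp)]
    )
  })
  out <- do.call(rbind, tabs)
  out <- cbind(stem_id = sprintf("S%06d", seq_len(nrow(out))), out)
  attr(out, "species_probs") <- setNames(probs, species_pool)
  out
}

#' Simulate the giant-herb cover point grid
#'
#' A 10-m lattice (100 points/ha) carrying an ordinal cover index in
#' `{1, 2, 3}` from an ordered-probit model whose latent mean decreases
#' with local canopy height: giant herbs favour gaps. With `herb_coef = 0`
#' the index is marginally distributed as `base_probs`.
#'
#' @param config a [sim_config].
#' @param landscape output of [simulate_landscape].
#' @param base_probs marginal probabilities of index 1, 2, 3 when canopy
#'   has no effect.
#' @return data.frame with `plot_id`, `x`, `y`, `index`.
#' @export
simulate_giant_herbs <- function(config, landscape,
                                 base_probs = c(0.4, 0.35, 0.25)) {
  stopifnot(length(base_probs) == 3, abs(sum(base_probs) - 1) < 1e-8)
  side <- config$plot_side
  pts <- seq(5, side - 5, by = 10)
  cut1 <- qnorm(base_probs[1])
  cut2 <- qnorm(base_probs[1] + base_probs[2])
  out <- lapply(names(landscape), function(pid) {
    g <- expand.grid(x = pts, y = pts)
    dem <- landscape[[pid]]$dem
    dsm <- landscape[[pid]]$dsm
    cc <- raster_coords(dem)
    jx <- findInterval(g$x, cc$x - dem$cell_size / 2)
    iy <- findInterval(g$y, cc$y - dem$cell_size / 2)
    chm <- pmax(dsm$values - dem$values, 0)[cbind(iy, jx)]
    latent <- -config$herb_coef * (chm - mean(chm)) + rnorm(nrow(g))
    data.frame(plot_id = pid, x = g$x, y = g$y,
               index = 1L + (latent > cut1) + (latent > cut2))
  })
  do.call(rbind, out)
}

# Shifted two-component exponential mixture for liana diameters (cm),
# truncated at dmax; calibrated once to the observed size structure
# (62% of stems in 1-2 cm, ~94% in 1-5 cm).
rliana_diameter <- function(n, w = 0.63, rate1 = 1.4, rate2 = 0.5, dmax = 27) {
  draw <- function(k) {
    comp <- runif(k) < w
    1 + ifelse(comp, rexp(k, rate1), rexp(k, rate2))
  }
  d <- draw(n)
  bad <- d > dmax
  while (any(bad)) {
    d[bad] <- draw(sum(bad))
    bad <- d > dmax
  }
  d
}

#' Simulate the liana census with host links
#'
#' Per-quadrat liana counts follow a log-linear model in the standardized
#' environment with coefficients `beta_structure` (normalised so the mean
#' density matches `liana_density`). Each stem gets a taxon (probability
#' proportional to base abundance times `exp(env_response . env)`), a
#' diameter from the calibrated size mixture, and a host tree drawn from
#' the stems of its buffered 40 x 40-m window with probability proportional
#' to `theta_host[taxon, species]`; a configurable fraction gets a second
#' host. Lianas in a window without trees are left host-less and flagged.
#'
#' @param config a [sim_config].
#' @param trees stem table from [simulate_trees].
#' @param env environment table from [env_table] (same quadrat order as
#'   `frame`).
#' @param frame a [quadrat_frame].
#' @param base_abund,env_response,theta_host ground-truth parameter draws
#'   (see [simulate_community]); `base_abund` is the taxon rank-abundance
#'   vector, `env_response` the taxa x 8 niche matrix, `theta_host` the
#'   taxa x tree-species preference matrix.
#' @param mechanisms character vector per taxon (`"active"`/`"passive"`).
#' @return data.frame liana table: `liana_id`, `taxon`, `quadrat_id`,
#'   `plot_id`, `diameter`, `host1_stem_id`, `host2_stem_id`, `mechanism`,
#'   `hostless` flag.
#' @export
simulate_lianas <- function(config, trees, env, frame, base_abund,
                            env_response, theta_host, mechanisms) {
  z <- standardize_env(env)
  nq <- nrow(frame)
  beta <- setNames(rep(0, length(ENV_VARS)), ENV_VARS)
  if (length(config$beta_structure))
    beta[names(config$beta_structure)] <- config$beta_structure
  lin <- as.vector(z %*% beta)
  q_area_ha <- (frame$xmax - frame$xmin) * (frame$ymax - frame$ymin) / 10000
  lambda <- config$liana_density * q_area_ha * exp(lin) / mean(exp(lin))
  counts <- rpois(nq, lambda)
  taxa_pool <- sprintf("L%03d", seq_along(base_abund))
  tree_species_idx <- as.integer(factor(trees$species,
                                        levels = sort(unique(trees$species))))
  sp_levels <- sort(unique(trees$species))
  # map generated species labels T001.. to theta columns by label order
  theta_cols <- match(sp_levels, sprintf("T%03d", seq_len(config$n_tree_species)))
  rows <- vector("list", nq)
  for (i in seq_len(nq)) {
    k <- counts[i]
    if (k == 0) next
    # taxon draw under the quadrat's environment
    wts <- base_abund * exp(as.vector(env_response %*% z[i, ]))
    taxon <- sample.int(length(base_abund), k, replace = TRUE, prob = wts)
    # trees available in the buffered window (alive at liana census)
    inw <- which(trees$plot_id == frame$plot_id[i] &
                   trees$x >= frame$bxmin[i] & trees$x < frame$bxmax[i] &
                   trees$y >= frame$bymin[i] & trees$y < frame$bymax[i] &
                   !is.na(trees$dbh_census2))
    h1 <- h2 <- rep(NA_character_, k)
    hostless <- rep(FALSE, k)
    if (length(inw)) {
      wsp <- theta_cols[tree_species_idx[inw]]
      for (s in seq_len(k)) {
        pw <- theta_host[taxon[s], wsp]
        if (all(pw == 0)) pw <- rep(1, length(pw))
        pick <- if (length(inw) == 1) inw else sample(inw, 1, prob = pw)
        h1[s] <- trees$stem_id[pick]
        if (runif(1) < config$second_host_fraction && length(inw) > 1) {
          rest <- setdiff(inw, pick)
          pw2 <- theta_host[taxon[s], theta_cols[tree_species_idx[rest]]]
          if (all(pw2 == 0)) pw2 <- rep(1, length(pw2))
          h2[s] <- trees$stem_id[if (length(rest) == 1) rest else
            sample(rest, 1, prob = pw2)]
        }
      }
    } else hostless[] <- TRUE
    rows[[i]] <- data.frame(
      taxon = taxa_pool[taxon], quadrat_id = frame$quadrat_id[i],
      plot_id = frame$plot_id[i], diameter = rliana_diameter(k),
      host1_stem_id = h1, host2_stem_id = h2,
      mechanism = mechanisms[taxon], hostless = hostless
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no lianas generated; increase liana_density")
  cbind(liana_id = sprintf("V%06d", seq_len(nrow(out))), out)
}

#' Simulate the taxon trait table
#'
#' Trait values are drawn within the configured ranges with a configurable
#' correlation `trait_niche_cor` to each taxon's canopy-height niche
#' coefficient, so a genuine trait-environment signal exists. Conservative
#' traits (tissue density, carbon, thickness) correlate positively with the
#' tall-canopy niche; acquisitive traits (SLA, PO4, N, K) negatively. Only
#' the `n_covered` most abundant taxa are covered, mimicking incomplete
#' trait campaigns.
#'
#' @param config a [sim_config].
#' @param env_response taxa x 8 niche matrix (ground truth).
#' @param base_abund taxon rank-abundance vector.
#' @param n_covered number of most-abundant taxa with measured traits.
#' @return data.frame with `taxon` and one column per trait.
#' @export
simulate_traits <- function(config, env_response, base_abund,
                            n_covered = min(44L, config$n_liana_taxa)) {
  S <- config$n_liana_taxa
  niche <- env_response[, which(ENV_VARS == "meanTCH")]
  zn <- if (sd(niche) > 0) as.vector(scale(niche)) else rep(0, S)
  rho <- config$trait_niche_cor
  sign_of <- c(Thick = 1, SLA = -1, C = 1, N = -1, PO4 = -1, K = -1, TD = 1)
  vals <- lapply(names(config$trait_ranges), function(tr) {
    rg <- config$trait_ranges[[tr]]
    s <- if (tr %in% names(sign_of)) sign_of[[tr]] else 1
    latent <- s * rho * zn + sqrt(max(0, 1 - rho^2)) * rnorm(S)
    rg[1] + (rg[2] - rg[1]) * pnorm(latent)
  })
  out <- data.frame(taxon = sprintf("L%03d", seq_len(S)))
  out[names(config$trait_ranges)] <- vals
  covered <- order(base_abund, decreasing = TRUE)[seq_len(n_covered)]
  out[sort(covered), , drop = FALSE]
}

#' Generate a full synthetic census with ground truth
#'
#' Runs the whole generator chain (landscape, trees, herbs, environment,
#' lianas, traits) from the single seed in the configuration. Regenerating
#' with the same configuration reproduces identical tables.
#'
#' @param config a [sim_config].
#' @return list with `config`, `quadrats`, `landscape`, `trees`, `herbs`,
#'   `env`, `lianas`, `traits` and `ground_truth` (list of `base_abund`,
#'   `env_response`, `theta_host`, `beta_structure`, `mechanisms`, trait
#'   table of the generating draw).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  frame <- quadrat_frame(config)
  landscape <- simulate_landscape(config)
  trees <- simulate_trees(config, landscape)
  herbs <- simulate_giant_herbs(config, landscape)
  env <- env_table(trees, herbs, landscape, frame)
  S <- config$n_liana_taxa
  base_abund <- rank_abundance(S, config$dominance)
  env_response <- config$env_response
  if (is.null(env_response)) {
    env_response <- matrix(rnorm(S * length(ENV_VARS), 0, config$env_response_sd),
                           S, length(ENV_VARS), dimnames = list(NULL, ENV_VARS))
  }
  theta_host <- config$theta_host
  if (is.null(theta_host)) {
    theta_host <- matrix(rlnorm(S * config$n_tree_species, 0,
                                config$theta_host_sdlog),
                         S, config$n_tree_species)
  }
  mechanisms <- sample(c("active", "passive"), S, replace = TRUE)
  lianas <- simulate_lianas(config, trees, env, frame, base_abund,
                            env_response, theta_host, mechanisms)
  traits <- simulate_traits(config, env_response, base_abund)
  list(
    config = config, quadrats = frame, landscape = landscape,
    trees = trees, herbs = herbs, env = env, lianas = lianas,
    traits = traits,
    ground_truth = list(
      base_abund = base_abund, env_response = env_response,
      theta_host = theta_host,
      beta_structure = config$beta_structure,
      mechanisms = mechanisms
    )
  )
}
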