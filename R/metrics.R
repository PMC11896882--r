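#' Basal area of a stem
#'
#' Cross-sectional area at measurement height of a stem of diameter `d` cm,
#' in m2: `pi * (d / 200)^2`.
#'
#' @param d stem diameter(s) in cm; must be > 0.
#' @return basal area(s) in m2.
#' @export
stem_basal_area <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameters must be positive")
  pi * (d / 200)^2
}

#' Quadratic mean diameter
#' @param d stem diameters (cm).
#' @return `sqrt(mean(d^2))`, or `NA` for an empty vector.
#' @export
qmd <- function(d) if (length(d) == 0) NA_real_ else sqrt(mean(d^2))

#' Per-quadrat liana community structure
#'
#' Liana abundance N_L (stems/ha), total basal area BA_L (m2/ha) and
#' quadratic mean diameter QMD_L (cm) at the (unbuffered) quadrat scale.
#' Empty quadrats get N_L = 0, BA_L = 0 and QMD_L = NA (flagged via the
#' `empty` column).
#'
#' @param lianas a liana table with `quadrat_id` and `diameter` (cm).
#' @param frame a [quadrat_frame].
#' @return data.frame keyed by `quadrat_id` with `N_L`, `BA_L`, `QMD_L`,
#'   `empty`.
#' @export
quadrat_liana_structure <- function(lianas, frame) {
  area_m2 <- (frame$xmax - frame$xmin) * (frame$ymax - frame$ymin)
  per_ha <- 10000 / area_m2
  out <- data.frame(quadrat_id = frame$quadrat_id,
                    N_L = 0, BA_L = 0, QMD_L = NA_real_, empty = TRUE)
  sp <- split(lianas$diameter, factor(lianas$quadrat_id, levels = frame$quadrat_id))
  n <- vapply(sp, length, 0L)
  out$N_L <- n * per_ha
  out$BA_L <- vapply(sp, function(d) sum(stem_basal_area(d)), 0) * per_ha
  out$QMD_L <- vapply(sp, qmd, 0)
  out$empty <- n == 0L
  out
}

#' Tree metrics over buffered quadrat windows
#'
#' Tree abundance (N_T, stems/ha), total basal area (BA_T, m2/ha),
#' quadratic mean diameter (QMD_T, cm) and unweighted mean wood density
#' (WD_T, g/cm3), computed from the `census` inventory (default the later
#' census, matching the liana inventory year) over the 40 x 40-m buffered
#' window of each quadrat; plus the absolute basal-area change dBA_T (m2,
#' census 2 minus census 1, not per ha) over the same window.
#'
#' @param trees a stem table (`plot_id`, `x`, `y`, `dbh_census1`,
#'   `dbh_census2`, `wood_density`).
#' @param frame a [quadrat_frame].
#' @param census which census (1 or 2) the stand variables are computed on.
#' @return data.frame keyed by `quadrat_id` with `N_T`, `BA_T`, `QMD_T`,
#'   `WD_T`, `dBA_T` and an `empty_window` flag.
#' @export
window_tree_metrics <- function(trees, frame, census = 2) {
  dcol <- if (census == 2) "dbh_census2" else "dbh_census1"
  out <- data.frame(quadrat_id = frame$quadrat_id, N_T = 0, BA_T = 0,
                    QMD_T = NA_real_, WD_T = NA_real_, dBA_T = 0,
                    empty_window = TRUE)
  for (i in seq_len(nrow(frame))) {
    inw <- trees$plot_id == frame$plot_id[i] &
      trees$x >= frame$bxmin[i] & trees$x < frame$bxmax[i] &
      trees$y >= frame$bymin[i] & trees$y < frame$bymax[i]
    w <- trees[inw, , drop = FALSE]
    area_ha <- (frame$bxmax[i] - frame$bxmin[i]) *
      (frame$bymax[i] - frame$bymin[i]) / 10000
    d <- w[[dcol]]
    alive <- !is.na(d)
    if (any(alive)) {
      out$N_T[i] <- sum(alive) / area_ha
      out$BA_T[i] <- sum(stem_basal_area(d[alive])) / area_ha
      out$QMD_T[i] <- qmd(d[alive])
      out$WD_T[i] <- mean(w$wood_density[alive])
      out$empty_window[i] <- FALSE
    }
    ba2 <- sum(stem_basal_area(w$dbh_census2[!is.na(w$dbh_census2)]))
    ba1 <- sum(stem_basal_area(w$dbh_census1[!is.na(w$dbh_census1)]))
    out$dBA_T[i] <- ba2 - ba1
  }
  out
}

#' Mean top-of-canopy height per buffered window
#'
#' Canopy height is the surface model minus the terrain model; negative
#' differences are clipped to zero and nodata cells are excluded.
#'
#' @param dsm,dem [ls_raster] objects on the same grid (one plot).
#' @param frame a [quadrat_frame] restricted to that plot (plot-local
#'   coordinates).
#' @return data.frame with `quadrat_id` and `meanTCH` (m).
#' @export
mean_tch <- function(dsm, dem, frame) {
  if (dsm$cell_size != dem$cell_size || any(dim(dsm$values) != dim(dem$values)))
    stop("DSM and DEM rasters are not aligned")
  chm <- dsm
  chm$values <- pmax(dsm$values - dem$values, 0)
  v <- vapply(seq_len(nrow(frame)), function(i) {
    cells <- raster_window_values(chm, frame$bxmin[i], frame$bxmax[i],
                                  frame$bymin[i], frame$bymax[i])
    cells <- cells[is.finite(cells)]
    if (!length(cells)) stop("window ", frame$quadrat_id[i], " is all nodata")
    mean(cells)
  }, 0)
  data.frame(quadrat_id = frame$quadrat_id, meanTCH = v)
}

#' Giant-herb foliar cover per quadrat
#'
#' Mean of the herb cover index (1-3) over the sampling points falling in
#' each quadrat (boundary-inclusive so a 20-m quadrat on the 10-m herb grid
#' holds a full 3 x 3 block). Quadrats with fewer points than expected are
#' flagged but still averaged over the available points.
#'
#' @param herbs data.frame with `plot_id`, `x`, `y`, `index`.
#' @param frame a [quadrat_frame].
#' @param expected_points number of points a complete quadrat holds.
#' @return data.frame with `quadrat_id`, `GHFC`, `n_points`, `incomplete`.
#' @export
ghfc <- function(herbs, frame, expected_points = 9) {
  out <- data.frame(quadrat_id = frame$quadrat_id, GHFC = NA_real_,
                    n_points = 0L, incomplete = TRUE)
  for (i in seq_len(nrow(frame))) {
    inq <- herbs$plot_id == frame$plot_id[i] &
      herbs$x >= frame$xmin[i] & herbs$x <= frame$xmax[i] &
      herbs$y >= frame$ymin[i] & herbs$y <= frame$ymax[i]
    idx <- herbs$index[inq]
    out$n_points[i] <- length(idx)
    if (length(idx)) out$GHFC[i] <- mean(idx)
    out$incomplete[i] <- length(idx) < expected_points
  }
  out
}

# ---- D8 terrain analysis -------------------------------------------------

# Fill single-cell pits: any interior cell with no strictly lower neighbour
# is raised to its lowest neighbour + eps until none remain. Border cells
# act as outlets and are never raised.
fill_pits <- function(e, eps = 1e-6, max_iter = 100) {
  nr <- nrow(e); nc <- ncol(e)
  if (nr < 3 || nc < 3) return(e)
  for (iter in seq_len(max_iter)) {
    nbr_min <- matrix(Inf, nr, nc)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh <- matrix(Inf, nr, nc)
      ri <- max(1, 1 + di):min(nr, nr + di)
      rj <- max(1, 1 + dj):min(nc, nc + dj)
      sh[ri, rj] <- e[ri - di, rj - dj]
      nbr_min <- pmin(nbr_min, sh)
    }
    pit <- e <= nbr_min
    pit[c(1, nr), ] <- FALSE
    pit[, c(1, nc)] <- FALSE
    if (!any(pit)) break
    e[pit] <- nbr_min[pit] + eps
  }
  e
}

# D8 steepest-descent routing. Returns, per cell (linear index), the linear
# index of the steepest strictly-lower neighbour (NA at outlets/pits) and
# the flow accumulation (number of cells draining through, self included).
d8_route <- function(e, cell_size = 1) {
  nr <- nrow(e); nc <- ncol(e)
  best_slope <- matrix(-Inf, nr, nc)
  down <- matrix(NA_integer_, nr, nc)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    dist <- cell_size * sqrt(di^2 + dj^2)
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    sl <- matrix(-Inf, nr, nc)
    nb <- matrix(NA_integer_, nr, nc)
    sl[ri, rj] <- (e[ri, rj] - e[ri - di, rj - dj]) / dist
    nb[ri, rj] <- idx[ri - di, rj - dj]
    take <- sl > best_slope
    best_slope[take] <- sl[take]
    down[take] <- nb[take]
  }
  down[best_slope <= 0] <- NA_integer_
  ord <- order(e, decreasing = TRUE)
  acc <- rep(1L, nr * nc)
  dn <- as.integer(down)
  for (c0 in ord) {
    d <- dn[c0]
    if (!is.na(d)) acc[d] <- acc[d] + acc[c0]
  }
  list(down = dn, acc = acc, elev_order = ord)
}

# Height above the channel network: channels are cells whose accumulation
# reaches `threshold`; every other cell takes the elevation of the channel
# cell its D8 path reaches (outlets without a channel act as their own).
height_above_channel <- function(e, route, threshold) {
  n <- length(e)
  channel <- route$acc >= threshold
  chel <- rep(NA_real_, n)
  ev <- as.vector(e)
  up <- rev(route$elev_order) # increasing elevation: downslope cell resolved first
  for (c0 in up) {
    if (channel[c0] || is.na(route$down[c0])) chel[c0] <- ev[c0]
    else chel[c0] <- chel[route$down[c0]]
  }
  pmax(ev - chel, 0)
}

#' Relative slope position from a DEM
#'
#' RSP = AACL / (AACL + ABRL), where AACL is the altitude above the channel
#' network (D8 flow accumulation over a pit-filled DEM, channels = cells
#' draining at least `channel_frac` of the grid) and ABRL is the altitude
#' below the ridge network, obtained by the identical construction on the
#' inverted DEM. Channel cells score 0, ridge/summit cells score 1, and
#' cells that are both (flat degenerate case, 0/0) score 0.5.
#'
#' @param dem an [ls_raster].
#' @param channel_frac fraction of the grid's cells a cell must drain to be
#'   a channel (ridge) cell; default 1%.
#' @return an [ls_raster] of RSP values in `[0, 1]`.
#' @export
rsp_raster <- function(dem, channel_frac = 0.01) {
  e <- dem$values
  if (any(!is.finite(e))) stop("RSP needs a complete (no-nodata) DEM")
  n <- length(e)
  threshold <- max(2, ceiling(channel_frac * n))
  if (threshold > n) stop("channel threshold exceeds cell count")
  ef <- fill_pits(e)
  r1 <- d8_route(ef, dem$cell_size)
  aacl <- height_above_channel(ef, r1, threshold)
  ei <- fill_pits(-e)
  r2 <- d8_route(ei, dem$cell_size)
  abrl <- height_above_channel(ei, r2, threshold)
  tot <- aacl + abrl
  rsp <- ifelse(tot > 0, aacl / tot, 0.5)
  out <- dem
  out$values <- matrix(rsp, nrow(e), ncol(e))
  out
}

#' Window-mean RSP per quadrat
#'
#' @param rsp an [ls_raster] of RSP values (see [rsp_raster]).
#' @param frame a [quadrat_frame] for the same plot (plot-local coordinates).
#' @return data.frame with `quadrat_id` and `RSP` (window mean over the
#'   buffered 40 x 40-m window).
#' @export
window_rsp <- function(rsp, frame) {
  v <- vapply(seq_len(nrow(frame)), function(i) {
    cells <- raster_window_values(rsp, frame$bxmin[i], frame$bxmax[i],
                                  frame$bymin[i], frame$bymax[i])
    mean(cells[is.finite(cells)])
  }, 0)
  data.frame(quadrat_id = frame$quadrat_id, RSP = v)
}

# ---- environment table ---------------------------------------------------

#' Assemble the quadrat-scale environment table
#'
#' Joins the tree-window metrics, canopy height, giant-herb cover and RSP
#' into one table over [ENV_VARS], one row per quadrat.
#'
#' @param trees stem table.
#' @param herbs herb point grid.
#' @param landscape named list (per plot) of `list(dem, dsm)` rasters, as
#'   returned by [simulate_landscape]; RSP rasters are derived per plot.
#' @param frame a [quadrat_frame].
#' @param channel_frac passed to [rsp_raster].
#' @return data.frame keyed by `quadrat_id` with the eight environment
#'   columns plus `plot_id`.
#' @export
env_table <- function(trees, herbs, landscape, frame, channel_frac = 0.01) {
  tm <- window_tree_metrics(trees, frame)
  gh <- ghfc(herbs, frame)
  tchv <- rep(NA_real_, nrow(frame))
  rspv <- rep(NA_real_, nrow(frame))
  for (pid in unique(frame$plot_id)) {
    sel <- frame$plot_id == pid
    sub <- frame[sel, , drop = FALSE]
    tchv[sel] <- mean_tch(landscape[[pid]]$dsm, landscape[[pid]]$dem, sub)$meanTCH
    rr <- rsp_raster(landscape[[pid]]$dem, channel_frac)
    rspv[sel] <- window_rsp(rr, sub)$RSP
  }
  data.frame(quadrat_id = frame$quadrat_id, plot_id = frame$plot_id,
             N_T = tm$N_T, BA_T = tm$BA_T, QMD_T = tm$QMD_T,
             WD_T = tm$WD_T, dBA_T = tm$dBA_T,
             meanTCH = tchv, GHFC = gh$GHFC, RSP = rspv)
}

#' Standardize environment columns to mean 0, sd 1
#'
#' @param env data.frame containing (at least) the columns in `vars`.
#' @param vars which columns to standardize.
#' @return numeric matrix of standardized predictors, row order preserved.
#' @export
standardize_env <- function(env, vars = ENV_VARS) {
  vars <- intersect(vars, names(env))
  m <- as.matrix(env[, vars, drop = FALSE])
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) stop("constant environment column: ",
                          paste(vars[sds == 0], collapse = ", "))
  scale(m)[, , drop = FALSE]
}

#' Pairwise correlation screen of predictors
#'
#' Flags predictor pairs whose absolute Pearson correlation reaches the
#' cutoff (0.7 by default), the usual collinearity screen before the model
#' selection stage.
#'
#' @param env data.frame or matrix of predictors.
#' @param cutoff absolute correlation at or above which a pair is flagged.
#' @param vars columns to screen.
#' @return data.frame with `var1`, `var2`, `r`, `flagged`.
#' @export
correlation_screen <- function(env, cutoff = 0.7, vars = ENV_VARS) {
  if (is.data.frame(env)) {
    vars <- intersect(vars, names(env))
    m <- as.matrix(env[, vars, drop = FALSE])
  } else m <- as.matrix(env)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) stop("constant column: ",
                          paste(colnames(m)[sds == 0], collapse = ", "))
  r <- cor(m)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(var1 = colnames(r)[pairs[, 1]],
                    var2 = colnames(r)[pairs[, 2]],
                    r = r[pairs])
  out$flagged <- abs(out$r) >= cutoff
  out
}
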