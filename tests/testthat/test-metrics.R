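test_that("stem basal area follows dendrometry", {
  expect_equal(stem_basal_area(2), 3.1416e-4, tolerance = 1e-4)
  expect_error(stem_basal_area(0), "positive")
  d <- sort(runif(20, 1, 50))
  expect_true(all(diff(stem_basal_area(d)) > 0))
})

test_that("quadrat liana structure scales to the hectare", {
  cfg <- small_config()
  fr <- quadrat_frame(cfg)[1:2, ]
  li <- data.frame(liana_id = sprintf("V%02d", 1:44),
                   taxon = "La",
                   quadrat_id = c(rep(fr$quadrat_id[1], 43), fr$quadrat_id[2]),
                   diameter = c(runif(43, 1, 3), 10))
  st <- quadrat_liana_structure(li, fr)
  expect_equal(st$N_L[1], 43 * 25)       # 43 stems in 400 m2
  expect_equal(st$QMD_L[2], 10)          # single stem d = 10
  expect_false(any(st$empty[1:2]))
  # empty quadrat flagged with zero structure
  st0 <- quadrat_liana_structure(li[0, ], fr)
  expect_true(all(st0$empty))
  expect_true(all(st0$N_L == 0) && all(st0$BA_L == 0) && all(is.na(st0$QMD_L)))
  # conservation: pooled basal area equals quadrat-sum basal area
  stc <- quadrat_liana_structure(shared_sim$lianas, shared_sim$quadrats)
  expect_equal(sum(stc$BA_L) * 0.04, sum(stem_basal_area(shared_sim$lianas$diameter)))
})

test_that("tree window metrics match hand formulas", {
  fr <- quadrat_frame(small_config())[1, , drop = FALSE]
  tr <- data.frame(stem_id = c("S1", "S2"), plot_id = fr$plot_id,
                   species = "A",
                   x = fr$bxmin + c(1, 2), y = fr$bymin + c(1, 2),
                   dbh_census1 = c(3, 4), dbh_census2 = c(3, 4),
                   wood_density = c(0.4, 0.8))
  m <- window_tree_metrics(tr, fr)
  expect_equal(m$QMD_T, sqrt(12.5))
  expect_equal(m$WD_T, 0.6)
  expect_equal(m$dBA_T, 0)               # identical censuses
  expect_equal(m$N_T, 2 / 0.16)
  # empty window flagged
  m0 <- window_tree_metrics(tr[0, ], fr)
  expect_true(m0$empty_window)
})

test_that("mean canopy height averages the clipped surface-terrain difference", {
  cfg <- small_config()
  fr <- quadrat_frame(cfg)[1, , drop = FALSE]
  n <- cfg$plot_side
  dem <- ls_raster(matrix(400, n, n))
  dsm0 <- dem
  expect_equal(mean_tch(dsm0, dem, fr)$meanTCH, 0)
  dsm30 <- ls_raster(matrix(430, n, n))
  expect_equal(mean_tch(dsm30, dem, fr)$meanTCH, 30)
  # half the window at 10 m, half at 20 m
  v <- matrix(410, n, n)
  cc <- raster_coords(dem)
  v[, cc$x >= (fr$bxmin + fr$bxmax) / 2] <- 420
  expect_equal(mean_tch(ls_raster(v), dem, fr)$meanTCH, 15)
})

test_that("giant-herb cover averages the in-quadrat points and flags gaps", {
  fr <- shared_sim$quadrats
  g <- ghfc(shared_sim$herbs, fr)
  expect_true(all(g$n_points == 9))
  expect_false(any(g$incomplete))
  expect_true(all(g$GHFC >= 1 & g$GHFC <= 3))
  # drop one point: flagged, mean over the remaining 8
  h1 <- shared_sim$herbs
  inq <- h1$plot_id == fr$plot_id[1] &
    h1$x >= fr$xmin[1] & h1$x <= fr$xmax[1] &
    h1$y >= fr$ymin[1] & h1$y <= fr$ymax[1]
  g1 <- ghfc(h1[-which(inq)[1], ], fr)
  expect_true(g1$incomplete[1])
  expect_equal(g1$GHFC[1], mean(h1$index[which(inq)[-1]]))
})

test_that("relative slope position hits its analytic limits", {
  n <- 60
  cc <- (1:n) - 0.5
  base <- outer(cc, cc, function(y, x) 0.01 * x)
  mound <- outer(cc, cc, function(y, x)
    5 * exp(-((x - 30)^2 + (y - 30)^2) / (2 * 16)))
  dem <- ls_raster(base + mound)
  r <- rsp_raster(dem)
  expect_true(all(r$values >= 0 & r$values <= 1))
  summit <- which(dem$values == max(dem$values))
  expect_true(all(r$values[summit] == 1)) # ridge cell: ABRL = 0
  route <- lianascape:::d8_route(lianascape:::fill_pits(dem$values), 1)
  expect_equal(r$values[which.max(route$acc)], 0)  # channel cell: AACL = 0
  # symmetry: RSP of the inverted DEM complements the original
  dem_inv <- dem; dem_inv$values <- -dem$values
  expect_equal(rsp_raster(dem_inv)$values, 1 - r$values, tolerance = 1e-10)
  expect_error(rsp_raster(dem, channel_frac = 2), "threshold")
})

test_that("the correlation screen flags collinear predictor pairs", {
  set.seed(77)
  env <- as.data.frame(matrix(rnorm(144 * 4), 144, 4))
  names(env) <- c("N_T", "BA_T", "QMD_T", "WD_T")
  sc <- correlation_screen(env, vars = names(env))
  expect_false(any(sc$flagged))          # independent columns at n = 144
  env$BA_T <- env$N_T                    # duplicated column
  sc2 <- correlation_screen(env, vars = names(env))
  expect_true(sc2$flagged[sc2$var1 == "N_T" & sc2$var2 == "BA_T"])
  sc3 <- correlation_screen(env, cutoff = 0, vars = names(env))
  expect_true(all(sc3$flagged))
  env$WD_T <- 1
  expect_error(correlation_screen(env, vars = names(env)), "constant")
})
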