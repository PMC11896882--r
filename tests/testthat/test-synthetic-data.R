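# The generator is first-class code: these tests pin down the statistical
# structure the downstream analyses assume.

test_that("terrain model: canopy is nonnegative, relief bounded, mounds Poisson", {
  cfg0 <- small_config(seed = 5, mound_density = 0)
  set.seed(cfg0$seed)
  land0 <- simulate_landscape(cfg0)
  for (pl in land0) {
    expect_true(all(pl$dsm$values - pl$dem$values >= 0))
    expect_lte(diff(range(pl$dem$values)), cfg0$base_relief + 1e-9)
    expect_identical(pl$n_mounds, 0L)
  }
  # mound counts over 10 one-ha plots at 3/ha: Poisson(30) in total
  cfg1 <- sim_config(seed = 6, n_plots = 10, plot_side = 100,
                     quadrat_spacing = 50, mound_density = 3,
                     base_relief = 0.5, n_tree_species = 5, n_liana_taxa = 5)
  set.seed(cfg1$seed)
  land1 <- simulate_landscape(cfg1)
  n_mounds <- sum(vapply(land1, `[[`, 0L, "n_mounds"))
  expect_gte(n_mounds, qpois(0.001, 30))
  expect_lte(n_mounds, qpois(0.999, 30))
  # with negligible background relief, the highest DEM cell is a mound
  # summit and a local maximum of its neighbourhood
  pl <- land1[[which(vapply(land1, `[[`, 0L, "n_mounds") > 0)[1]]]
  ij <- which(pl$dem$values == max(pl$dem$values), arr.ind = TRUE)[1, ]
  nb <- pl$dem$values[ij[1] + (-1:1), ij[2] + (-1:1)]
  expect_true(all(pl$dem$values[ij[1], ij[2]] >= nb))
})

test_that("the generator reproduces bit-for-bit from its seed", {
  s2 <- simulate_community(small_config())
  expect_identical(s2$trees, shared_sim$trees)
  expect_identical(s2$lianas, shared_sim$lianas)
  expect_identical(s2$traits, shared_sim$traits)
  expect_identical(s2$ground_truth, shared_sim$ground_truth)
})

test_that("tree censuses: static dynamics give zero basal-area change and
           frequencies follow the configured rank abundance", {
  cfg <- small_config(seed = 21, growth_mean = 0, growth_sd = 0,
                      mortality_rate = 0, recruitment_rate = 0)
  set.seed(cfg$seed)
  tr <- simulate_trees(cfg, simulate_landscape(cfg))
  expect_true(all(abs(window_tree_metrics(tr, quadrat_frame(cfg))$dBA_T) < 1e-12))
  # law of large numbers on the species draw
  cfgB <- sim_config(seed = 22, n_plots = 1, plot_side = 300,
                     tree_density = 2000, n_tree_species = 10, n_liana_taxa = 5)
  set.seed(cfgB$seed)
  trB <- simulate_trees(cfgB, simulate_landscape(cfgB))
  probs <- attr(trB, "species_probs")
  emp <- as.vector(table(factor(trB$species, names(probs)))) / nrow(trB)
  expect_lt(max(abs(emp - probs)), 0.015)
})

test_that("giant herbs: 100 points/ha, base marginals at zero coefficient,
           and more cover in canopy gaps under a strong coefficient", {
  cfgS <- shared_sim$config
  area_ha <- cfgS$n_plots * (cfgS$plot_side / 100)^2
  expect_equal(nrow(shared_sim$herbs), area_ha * 100)
  cfg <- small_config(seed = 31, herb_coef = 0)
  set.seed(cfg$seed)
  land <- simulate_landscape(cfg)
  h0 <- simulate_giant_herbs(cfg, land, base_probs = c(0.4, 0.35, 0.25))
  emp <- tabulate(h0$index, 3) / nrow(h0)
  expect_lt(max(abs(emp - c(0.4, 0.35, 0.25))), 0.07)
  cfg2 <- small_config(seed = 32, herb_coef = 0.5)
  set.seed(cfg2$seed)
  land2 <- simulate_landscape(cfg2)
  h2 <- simulate_giant_herbs(cfg2, land2)
  h2p1 <- h2[h2$plot_id == "P1", ]
  ch <- chm_at(land2$P1, h2p1$x, h2p1$y)
  gap <- ch < median(ch)
  expect_gt(mean(h2p1$index[gap]), mean(h2p1$index[!gap]))
})

test_that("liana counts are Poisson-homogeneous when structure effects are off", {
  cfg <- sim_config(seed = 41, n_plots = 1, plot_side = 300,
                    quadrat_spacing = 50, n_tree_species = 12,
                    n_liana_taxa = 15, liana_density = 900,
                    beta_structure = c(QMD_T = 0), env_response_sd = 0,
                    theta_host_sdlog = 0, trait_niche_cor = 0)
  sim <- simulate_community(cfg)
  counts <- as.vector(table(factor(sim$lianas$quadrat_id,
                                   sim$quadrats$quadrat_id)))
  dispersion <- var(counts) / mean(counts)
  expect_gt(dispersion, 0.5)
  expect_lt(dispersion, 1.7)
})

test_that("host choice honours the preference matrix", {
  # every generated host lies in its liana's buffered window
  links <- expect_silent(build_links(shared_sim$lianas, shared_sim$trees,
                                     shared_sim$quadrats))
  expect_identical(attr(links, "n_rejected"), 0L)
  # planted 10x preference of taxon 1 for tree species 1 inflates its links
  # over the neutral (availability) expectation
  theta <- matrix(1, 20, 12)
  theta[1, 1] <- 10
  cfg <- small_config(seed = 42, theta_host = theta, env_response_sd = 0,
                      second_host_fraction = 0)
  sim <- simulate_community(cfg)
  links <- build_links(sim$lianas, sim$trees, sim$quadrats)
  l1 <- links[links$taxon == "L001", ]
  expect_gt(nrow(l1), 50)
  obs_share <- mean(l1$host_species == "T001")
  # availability of T001 among window trees, averaged over taxon-1 links
  fr <- sim$quadrats
  avail <- vapply(unique(l1$quadrat_id), function(q) {
    i <- match(q, fr$quadrat_id)
    tw <- sim$trees[sim$trees$plot_id == fr$plot_id[i] &
                      sim$trees$x >= fr$bxmin[i] & sim$trees$x < fr$bxmax[i] &
                      sim$trees$y >= fr$bymin[i] & sim$trees$y < fr$bymax[i] &
                      !is.na(sim$trees$dbh_census2), ]
    c(mean(tw$species == "T001"), sum(l1$quadrat_id == q))
  }, numeric(2))
  neutral_share <- sum(avail[1, ] * avail[2, ]) / sum(avail[2, ])
  expect_gt(obs_share, 1.5 * neutral_share)
})

test_that("traits stay in their configured ranges and carry the niche signal", {
  tr <- shared_sim$traits
  expect_true(all(tr$TD >= 0.16 & tr$TD <= 0.59))
  expect_true(all(tr$SLA >= 13 & tr$SLA <= 64.7))
  # coverage restricted to the most abundant taxa
  gt <- shared_sim$ground_truth
  t5 <- simulate_traits(shared_sim$config, gt$env_response, gt$base_abund,
                        n_covered = 5)
  expect_identical(nrow(t5), 5L)
  top5 <- sprintf("L%03d", order(gt$base_abund, decreasing = TRUE)[1:5])
  expect_setequal(t5$taxon, top5)
  # strong coupling knob: tissue density tracks the canopy-height niche
  cfg <- small_config(seed = 51, n_liana_taxa = 40, trait_niche_cor = 0.9)
  er <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, ENV_VARS))
  set.seed(cfg$seed)
  tt <- simulate_traits(cfg, er, rep(1 / 40, 40), n_covered = 40)
  expect_gt(cor(tt$TD, er[, "meanTCH"]), 0.7)
  expect_lt(cor(tt$SLA, er[, "meanTCH"]), -0.7)
})
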