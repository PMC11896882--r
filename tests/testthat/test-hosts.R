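# Small deterministic worlds for the host randomization machinery.
# One quadrat frame with two quadrats and hand-placed trees.
host_toy <- local({
  cfg <- sim_config(seed = 1, n_plots = 1, plot_side = 100,
                    quadrat_spacing = 50, n_tree_species = 4, n_liana_taxa = 3)
  frame <- quadrat_frame(cfg)
  frame <- frame[1:2, ]
  trees <- data.frame(
    stem_id = sprintf("S%02d", 1:10), plot_id = "P1",
    species = c("X", "X", "X", "Y", "Y", "X", "Y", "Y", "Y", "Z"),
    x = c(frame$bxmin[1] + c(1, 2, 3, 4, 5), frame$bxmin[2] + c(1, 2, 3, 4, 5)),
    y = c(frame$bymin[1] + c(1, 2, 3, 4, 5), frame$bymin[2] + c(1, 2, 3, 4, 5)),
    dbh_census1 = 20, dbh_census2 = 21, wood_density = 0.6)
  list(cfg = cfg, frame = frame, trees = trees)
})

test_that("RV coefficient: identity, rotation invariance and p convention", {
  set.seed(401)
  X <- matrix(rnorm(20 * 4), 20, 4)
  t1 <- rv_test(X, X, n_perm = 99)
  expect_equal(t1$rv, 1, tolerance = 1e-12)
  R <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  t2 <- rv_test(X, X %*% R, n_perm = 99)
  expect_equal(t2$rv, 1, tolerance = 1e-10)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  t3 <- rv_test(X, Y, n_perm = 99)
  expect_true(t3$rv >= 0 && t3$rv <= 1)
  expect_true(t3$p_value > 0 && t3$p_value <= 1)
  expect_error(rv_test(X, matrix(1, 20, 2)), "zero-variance")
})

test_that("link building keeps identified hosts and tallies the rest", {
  lianas <- data.frame(
    liana_id = paste0("V", 1:5), taxon = c("A", "A", "B", "B", "B"),
    quadrat_id = host_toy$frame$quadrat_id[1],
    diameter = 2,
    host1_stem_id = c("S01", "S02", "S03", NA, "S04"),
    host2_stem_id = c("S05", NA, NA, NA, NA),
    mechanism = "active")
  links <- build_links(lianas, host_toy$trees, host_toy$frame)
  expect_equal(nrow(links), 5)           # 4 primary + 1 secondary
  expect_equal(sum(links$liana_id == "V1"), 2)
  expect_identical(attr(links, "n_hostless"), 1L)
  # a host outside the window is rejected with a warning
  lianas2 <- lianas
  lianas2$host1_stem_id[3] <- "S10"      # tree sits in the other quadrat
  expect_warning(l2 <- build_links(lianas2, host_toy$trees, host_toy$frame),
                 "window")
  expect_identical(attr(l2, "n_rejected"), 1L)
  expect_equal(nrow(l2), 4)
})

test_that("association classification matches the published conventions", {
  expect_equal(classify_association(43, 7, 18), "attraction")
  expect_equal(classify_association(0, 3, 12), "repulsion")
  expect_equal(classify_association(18, 7, 19), "ns")
  expect_equal(classify_association(6, 0, 6), "ns")  # inclusive bound
  expect_error(classify_association(1, 5, 2), "exceeds")
})

test_that("host randomization: exact enumeration and expectation oracles", {
  # single liana in a window of 2 trees (X, Y), observed on X:
  # null count on X ~ Binomial(1, 1/2), envelope [0, 1], class ns
  frame <- host_toy$frame[1, , drop = FALSE]
  trees2 <- host_toy$trees[c(1, 4), ]
  links1 <- data.frame(liana_id = "V1", taxon = "A", mechanism = "active",
                       quadrat_id = frame$quadrat_id,
                       host_stem_id = "S01", host_species = "X")
  set.seed(402)
  res <- host_randomization_test(links1, trees2, frame, liana_min = 0,
                                 tree_min = 0, n_rep = 999)
  rx <- res[res$tree_species == "X", ]
  expect_equal(rx$observed, 1L)
  expect_equal(c(rx$lo, rx$hi), c(0L, 1L))
  expect_equal(rx$class, "ns")
  expect_lt(abs(attr(res, "null_mean")["A", "X"] - 0.5), 0.07)
  # null mean matches the exact availability expectation; counts conserve
  # the links per taxon
  links <- data.frame(
    liana_id = paste0("V", 1:8),
    taxon = c("A", "A", "A", "B", "B", "A", "A", "B"),
    mechanism = ifelse(c("A", "A", "A", "B", "B", "A", "A", "B") == "A",
                       "active", "passive"),
    quadrat_id = host_toy$frame$quadrat_id[c(1, 1, 1, 1, 1, 2, 2, 2)],
    host_stem_id = c("S01", "S02", "S04", "S03", "S05", "S06", "S07", "S10"),
    host_species = c("X", "X", "Y", "X", "Y", "X", "Y", "Z"))
  set.seed(403)
  res2 <- host_randomization_test(links, host_toy$trees, host_toy$frame,
                                  liana_min = 0, tree_min = 0, n_rep = 2000)
  nm <- attr(res2, "null_mean")
  # window 1 is 3 X / 2 Y, window 2 is 1 X / 3 Y / 1 Z
  expect_lt(abs(nm["A", "X"] - (3 * 3 / 5 + 2 * 1 / 5)), 0.1)
  expect_lt(abs(nm["B", "Z"] - (2 * 0 + 1 * 1 / 5)), 0.04)
  expect_equal(unname(rowSums(nm)), c(5, 3), tolerance = 1e-9)
  # mechanisms carried through per taxon
  expect_equal(unname(vapply(c("A", "B"), function(t)
    res2$mechanism[match(t, res2$taxon)], "")), c("active", "passive"))
})

test_that("association summaries reproduce the published census tallies", {
  fix <- read_association_fixture()
  fix$class <- classify_association(fix$observed, fix$lo, fix$hi)
  s <- summarize_associations(fix)
  expect_equal(s$n_pairs, 240)
  expect_equal(s$n_attraction, 23)
  expect_equal(s$n_repulsion, 22)
  expect_equal(s$percent_significant, 19)
  expect_true(!is.null(s$by_mechanism))
  # all-ns input
  allns <- data.frame(class = rep("ns", 6), mechanism = "active")
  s0 <- summarize_associations(allns)
  expect_equal(s0$n_significant, 0)
  expect_equal(s0$percent_significant, 0)
})
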