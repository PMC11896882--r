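rand_counts <- function(nr, nc, lambda = 4) {
  matrix(rpois(nr * nc, lambda), nr, nc,
         dimnames = list(paste0("s", seq_len(nr)), paste0("t", seq_len(nc))))
}

test_that("NSCA: inertia formula, degenerate cases and orthogonality", {
  # identical site profiles carry no inertia
  A0 <- matrix(rep(c(2, 4, 6), each = 4) * rep(1:4, 3), 4, 3)
  dimnames(A0) <- list(paste0("s", 1:4), paste0("t", 1:3))
  expect_lt(nsca(A0)$total_inertia, 1e-14)
  # 2x2 diagonal: inertia 0.5 on a single positive axis
  o2 <- nsca(matrix(c(10, 0, 0, 10), 2, 2,
                    dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(o2$total_inertia, 0.5)
  expect_equal(o2$eigenvalues[1], 0.5)
  expect_lt(o2$eigenvalues[2], 1e-12)
  # eigenvalue sum equals the direct double-sum formula on random counts
  set.seed(201)
  for (k in 1:5) {
    A <- rand_counts(10, 6)
    P <- A / sum(A); r <- rowSums(P); cm <- colSums(P)
    direct <- sum(r * rowSums(sweep(P / r, 2, cm, "-")^2))
    o <- nsca(A, n_axes = 6)
    expect_equal(sum(o$eigenvalues), direct, tolerance = 1e-10)
    expect_equal(o$total_inertia, direct, tolerance = 1e-10)
    expect_true(all(diff(o$eigenvalues) <= 1e-12))
    # site scores orthogonal under the row-weight metric
    G <- t(o$site_scores) %*% (o$row_weights * o$site_scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-10)
  }
  expect_error(nsca(matrix(1, 1, 3)), "2 rows")
  expect_error(nsca(rbind(c(1, 2), c(0, 0))), "zero-total")
})

test_that("NSCA separates taxa along a planted compositional gradient", {
  set.seed(202)
  grad <- seq(-2, 2, length.out = 30)
  resp <- c(1.2, 0, -1.2) # taxon niche slopes
  A <- sapply(resp, function(b) rpois(30, 40 * exp(b * grad) / mean(exp(b * grad))))
  dimnames(A) <- list(paste0("s", 1:30), c("pos", "flat", "neg"))
  o <- nsca(A)
  sgn <- sign(cor(o$site_scores[, 1], grad))
  expect_gt(sgn * (o$taxon_scores["pos", 1] - o$taxon_scores["neg", 1]), 0)
  expect_true(abs(o$taxon_scores["flat", 1]) <
                max(abs(o$taxon_scores[c("pos", "neg"), 1])))
})

test_that("NSCAIV: saturation, projection monotonicity and p-value convention", {
  # two exact site profiles perfectly predicted by one dummy predictor
  A <- rbind(matrix(rep(c(30, 10, 10), 5), 5, 3, byrow = TRUE),
             matrix(rep(c(5, 20, 25), 5), 5, 3, byrow = TRUE))
  dimnames(A) <- list(paste0("s", 1:10), paste0("t", 1:3))
  E <- matrix(rep(c(0, 1), each = 5), dimnames = list(NULL, "grp"))
  os <- nscaiv(A, E, n_perm = 99)
  expect_equal(os$constrained_fraction, 1, tolerance = 1e-10)
  expect_true(os$p_value > 0 && os$p_value <= 1)
  set.seed(203)
  A2 <- rand_counts(20, 8)
  E2 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  f3 <- nscaiv(A2, E2, n_perm = 0)$constrained_fraction
  f2 <- nscaiv(A2, E2[, 1:2], n_perm = 0)$constrained_fraction
  expect_gte(f3 + 1e-12, f2)
  expect_true(f3 >= 0 && f3 <= 1)
  # explained + residual inertia decompose the total
  os3 <- nscaiv(A2, E2, n_perm = 0)
  expect_equal(os3$constrained_inertia + sum(os3$residuals^2),
               os3$total_inertia, tolerance = 1e-10)
  expect_error(nscaiv(A2, cbind(E2, d = E2[, 1] + E2[, 2])), "collinear")
})

test_that("PCCA agrees with the vegan CCA oracle, with and without conditioning", {
  skip_if_not_installed("vegan")
  set.seed(204)
  A <- rand_counts(20, 8)
  E <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("e1", "e2")))
  co <- matrix(runif(40, 0, 100), 20, 2)
  # no conditioning: plain CCA
  p0 <- pcca(A, E, Z = NULL, n_perm = 0)
  v0 <- vegan::cca(A ~ e1 + e2, data = as.data.frame(E))
  expect_equal(p0$constrained_inertia, unname(v0$CCA$tot.chi), tolerance = 1e-10)
  expect_equal(p0$total_inertia, unname(v0$tot.chi), tolerance = 1e-10)
  expect_equal(unname(p0$eigenvalues[1:2]), unname(v0$CCA$eig[1:2]),
               tolerance = 1e-10)
  # with a second-order spatial conditioning table
  Z <- poly2_coords(co)
  p1 <- pcca(A, E, Z = Z, n_perm = 99)
  dd <- data.frame(E, Z)
  v1 <- vegan::cca(A ~ e1 + e2 + Condition(x + y + x2 + xy + y2), data = dd)
  expect_equal(p1$constrained_inertia, unname(v1$CCA$tot.chi), tolerance = 1e-10)
  expect_equal(p1$conditional_inertia, unname(v1$pCCA$tot.chi), tolerance = 1e-10)
  expect_true(p1$p_value > 0 && p1$p_value <= 1)
  # predictors inside the conditioning span explain nothing extra
  pz <- pcca(A, Z[, 1:2], Z = Z, n_perm = 0)
  expect_lt(pz$constrained_inertia, 1e-10)
  # projection decomposition: cond(Z) + constr(E | Z) == constr(Z u E)
  pall <- pcca(A, cbind(E, Z), Z = NULL, n_perm = 0)
  expect_lte(p1$conditional_inertia + p1$constrained_inertia,
             pall$constrained_inertia + 1e-8)
  expect_equal(p1$conditional_inertia + p1$constrained_inertia,
               pall$constrained_inertia, tolerance = 1e-8)
})

test_that("variogram permutation test: formula cases and envelope behaviour", {
  co4 <- cbind(c(0, 1, 50, 51), c(0, 0, 0, 0))
  # constant scores: zero semivariance in every class
  v0 <- variogram_permutation_test(rep(2, 4), co4, n_classes = 2, n_perm = 99)
  expect_true(all(v0$classes$gamma == 0))
  # an isolated pair with values 0 and 1 gives gamma = 0.5 in its class
  co3 <- cbind(c(0, 1, 100), c(0, 0, 0))
  v1 <- variogram_permutation_test(c(0, 1, 7), co3, n_classes = 3, n_perm = 99)
  expect_equal(v1$classes$gamma[1], 0.5)
  expect_true(all(v1$classes$lo <= v1$classes$hi))
  expect_true(all(v1$classes$p_value > 0 & v1$classes$p_value <= 1))
  # empty classes are merged with a message
  co_far <- cbind(c(0, 1, 2, 100), 0)
  expect_message(
    variogram_permutation_test(rnorm(4), co_far, n_classes = 10,
                               n_perm = 49),
    "merging")
})
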