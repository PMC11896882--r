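# Trait-environment analysis: Hill-N2 weighted community-weighted-mean
# (CWM) and species-niche-centroid (SNC) regressions combined by the
# max-test, the resulting fourth-corner correlation table, and the
# trait-shuffle null for CWM vs ordination-axis correlations.

#' Hill number of order 2
#'
#' Effective number of categories, `(sum w)^2 / sum(w^2)` (inverse Simpson
#' concentration). Equal weights over S categories give S; a single
#' category gives 1.
#'
#' @param w nonnegative weights, not all zero.
#' @return the effective number.
#' @export
hill_n2 <- function(w) {
  if (any(w < 0)) stop("weights must be nonnegative")
  s <- sum(w)
  if (s == 0) stop("all-zero weight vector")
  s^2 / sum(w^2)
}

# align an abundance matrix with a trait table: subset to covered taxa
align_traits <- function(A, traits) {
  common <- intersect(colnames(A), traits$taxon)
  if (!length(common)) stop("no taxa shared between abundance matrix and traits")
  list(A = A[, common, drop = FALSE],
       T = as.matrix(traits[match(common, traits$taxon),
                            setdiff(names(traits), "taxon"), drop = FALSE]))
}

#' Community weighted means
#'
#' `CWM_k = sum_j a_kj t_j / sum_j a_kj` over the trait-covered taxa.
#' Sites with zero covered abundance get `NA` (flagged in attributes).
#'
#' @param A abundance matrix (sites x taxa).
#' @param traits trait table (`taxon` + numeric columns).
#' @return sites x traits matrix with attribute `empty_sites`.
#' @export
cwm <- function(A, traits) {
  al <- align_traits(A, traits)
  tot <- rowSums(al$A)
  out <- (al$A %*% al$T) / ifelse(tot > 0, tot, NA)
  attr(out, "empty_sites") <- rownames(A)[tot == 0]
  out
}

#' Species niche centroids
#'
#' `SNC_j = sum_k a_kj e_k / sum_k a_kj`: the abundance-weighted mean
#' environment of each taxon.
#'
#' @param A abundance matrix (sites x taxa).
#' @param env numeric matrix/data.frame of environment values (rows = sites).
#' @return taxa x environment-variables matrix.
#' @export
snc <- function(A, env) {
  env <- as.matrix(env)
  tot <- colSums(A)
  out <- (t(A) %*% env) / ifelse(tot > 0, tot, NA)
  out
}

# weighted Pearson correlation; returns 0 when either side is constant
wcor <- function(x, y, w) {
  w <- w / sum(w)
  xc <- x - sum(w * x)
  yc <- y - sum(w * y)
  vx <- sum(w * xc^2); vy <- sum(w * yc^2)
  if (vx <= 0 || vy <= 0) return(0)
  sum(w * xc * yc) / sqrt(vx * vy)
}

#' N2-weighted fourth-corner correlation
#'
#' The trait is standardized over taxa with abundance weights (column
#' totals), the environment over sites with abundance weights (row totals);
#' the correlation between the CWM of the standardized trait and the
#' standardized environment is then computed with Hill-N2 site weights.
#' Affine transformations of trait or environment leave it unchanged.
#'
#' @param A abundance matrix (sites x taxa, already restricted/aligned).
#' @param trait numeric vector per taxon.
#' @param env numeric vector per site.
#' @return the correlation in `[-1, 1]`.
#' @export
fourth_corner_r <- function(A, trait, env) {
  K <- colSums(A); R <- rowSums(A)
  keep <- R > 0
  A <- A[keep, , drop = FALSE]; env <- env[keep]; R <- R[keep]
  wk <- K / sum(K)
  tm <- sum(wk * trait); tsd <- sqrt(sum(wk * (trait - tm)^2))
  if (tsd == 0) return(0)
  tstar <- (trait - tm) / tsd
  wr <- R / sum(R)
  em <- sum(wr * env); esd <- sqrt(sum(wr * (env - em)^2))
  if (esd == 0) return(0)
  estar <- (env - em) / esd
  cwm_t <- as.vector((A %*% tstar) / R)
  n2_site <- apply(A, 1, hill_n2)
  wcor(cwm_t, estar, n2_site)
}

#' CWM/SNC max-test of trait-environment association
#'
#' For every trait x environment pair: (i) the CWM of the trait is
#' regressed on the environment with Hill-N2 site weights and tested by
#' permuting sites; (ii) the SNC of the environment variable is regressed
#' on the trait with Hill-N2 species weights and tested by permuting trait
#' values among species; the final p-value is the maximum of the two, which
#' protects against both spurious site-level and species-level signal.
#'
#' @param A abundance matrix (sites x taxa).
#' @param traits trait table (`taxon` + numeric columns).
#' @param env data.frame/matrix of environment variables (rows = sites).
#' @param n_perm permutations per component test.
#' @return data.frame of class `ls_traitenv`: `trait`, `env`, `r`
#'   (fourth-corner, N2-weighted), `p_site`, `p_species`, `p_max`.
#' @export
maxtest <- function(A, traits, env, n_perm = 999) {
  al <- align_traits(A, traits)
  env <- as.matrix(env)
  keep <- rowSums(al$A) > 0
  A2 <- al$A[keep, , drop = FALSE]
  env <- env[keep, , drop = FALSE]
  n_site <- nrow(A2); n_sp <- ncol(A2)
  n2_site <- apply(A2, 1, hill_n2)
  n2_sp <- apply(A2, 2, hill_n2)
  R <- rowSums(A2)
  res <- list()
  for (tr in colnames(al$T)) {
    tvals <- al$T[, tr]
    if (sd(tvals) == 0) {
      for (ev in colnames(env))
        res[[length(res) + 1]] <- data.frame(trait = tr, env = ev, r = 0,
                                             p_site = 1, p_species = 1, p_max = 1)
      next
    }
    cwm_t <- as.vector((A2 %*% tvals) / R)
    for (ev in colnames(env)) {
      e <- env[, ev]
      if (sd(e) == 0) stop("constant environment column: ", ev)
      snc_e <- as.vector((t(A2) %*% e) / colSums(A2))
      r_site_obs <- abs(wcor(cwm_t, e, n2_site))
      null_site <- vapply(seq_len(n_perm), function(k)
        abs(wcor(cwm_t, e[sample.int(n_site)], n2_site)), 0)
      p_site <- (1 + sum(null_site >= r_site_obs)) / (n_perm + 1)
      r_sp_obs <- abs(wcor(snc_e, tvals, n2_sp))
      null_sp <- vapply(seq_len(n_perm), function(k)
        abs(wcor(snc_e, tvals[sample.int(n_sp)], n2_sp)), 0)
      p_species <- (1 + sum(null_sp >= r_sp_obs)) / (n_perm + 1)
      res[[length(res) + 1]] <- data.frame(
        trait = tr, env = ev,
        r = fourth_corner_r(A2, tvals, e),
        p_site = p_site, p_species = p_species,
        p_max = max(p_site, p_species)
      )
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("ls_traitenv", "data.frame")
  out
}

#' Trait-shuffle null for CWM vs ordination-axis correlations
#'
#' Observed Pearson correlation between the CWM of each trait and a vector
#' of site ordination scores, against a null built by randomizing trait
#' values among taxa and recomputing the CWM.
#'
#' @param A abundance matrix (sites x taxa).
#' @param traits trait table.
#' @param axis_scores numeric site scores aligned with rows of `A`.
#' @param n_perm number of trait shuffles.
#' @return data.frame with `trait`, `r`, `p_value` (two-sided).
#' @export
cwm_axis_null <- function(A, traits, axis_scores, n_perm = 999) {
  al <- align_traits(A, traits)
  keep <- rowSums(al$A) > 0
  A2 <- al$A[keep, , drop = FALSE]
  sc <- axis_scores[keep]
  R <- rowSums(A2)
  out <- lapply(colnames(al$T), function(tr) {
    tvals <- al$T[, tr]
    cwm_t <- as.vector((A2 %*% tvals) / R)
    if (sd(cwm_t) == 0 || sd(tvals) == 0)
      return(data.frame(trait = tr, r = 0, p_value = 1))
    r_obs <- cor(cwm_t, sc)
    null_r <- vapply(seq_len(n_perm), function(k) {
      ct <- as.vector((A2 %*% tvals[sample.int(length(tvals))]) / R)
      if (sd(ct) == 0) 0 else cor(ct, sc)
    }, 0)
    data.frame(trait = tr, r = r_obs,
               p_value = (1 + sum(abs(null_r) >= abs(r_obs))) / (n_perm + 1))
  })
  do.call(rbind, out)
}
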