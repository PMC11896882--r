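# Ordination of site x taxa abundance matrices. NSCA weights sites by
# their abundance totals and decomposes deviations of site profiles from
# the mean profile under the identity column metric, which gives abundant
# taxa more influence than classical correspondence analysis. NSCAIV is
# its constrained (instrumental-variables) version; PCCA is classical
# chi-square CCA with a conditioning table partialled out first.

# Orthogonal projection of the columns of Yw onto the column span of Xw
# (both already in weighted coordinates).
proj_cols <- function(Yw, Xw) {
  if (is.null(Xw) || ncol(Xw) == 0) return(Yw * 0)
  qq <- qr(Xw)
  qr.fitted(qq, Yw)
}

# Deterministic axis orientation: the taxon with the largest |loading| on
# each axis is made positive.
orient_axes <- function(site_scores, taxon_scores) {
  for (a in seq_len(ncol(taxon_scores))) {
    j <- which.max(abs(taxon_scores[, a]))
    if (taxon_scores[j, a] < 0) {
      taxon_scores[, a] <- -taxon_scores[, a]
      site_scores[, a] <- -site_scores[, a]
    }
  }
  list(site = site_scores, taxon = taxon_scores)
}

nsca_core <- function(A) {
  if (nrow(A) < 2 || ncol(A) < 2) stop("need at least 2 rows and 2 columns")
  if (any(A < 0)) stop("abundances must be nonnegative")
  tot <- sum(A)
  if (tot == 0) stop("empty abundance matrix")
  P <- A / tot
  r <- rowSums(P)
  if (any(r == 0)) stop("zero-total rows must be dropped before ordination")
  cm <- colSums(P)
  Q <- sweep(P / r, 2, cm, "-")
  Qw <- sqrt(r) * Q
  list(P = P, r = r, cm = cm, Q = Q, Qw = Qw, inertia = sum(Qw^2))
}

finish_nsca <- function(Qw, r, n_axes, site_names, taxon_names) {
  s <- svd(Qw)
  pos <- which(s$d^2 > max(s$d^2, 0) * 1e-12)
  n_axes <- min(n_axes, length(pos))
  ax <- seq_len(n_axes)
  eig <- s$d[ax]^2
  site <- (s$u[, ax, drop = FALSE] %*% diag(s$d[ax], n_axes)) / sqrt(r)
  taxon <- s$v[, ax, drop = FALSE]
  o <- orient_axes(site, taxon)
  dimnames(o$site) <- list(site_names, paste0("Axis", ax))
  dimnames(o$taxon) <- list(taxon_names, paste0("Axis", ax))
  list(eigenvalues = s$d^2, site_scores = o$site, taxon_scores = o$taxon)
}

#' Non-symmetric correspondence analysis
#'
#' Sites are rows (profiles of taxa within sites). With `P = A / sum(A)`,
#' row masses `r`, column masses `c`, the analysis decomposes
#' `q_ij = p_ij / r_i - c_j` under the row metric `diag(r)` and the
#' identity column metric; total inertia is `sum_i r_i sum_j q_ij^2`
#' (Goodman-Kruskal tau numerator).
#'
#' @param A abundance matrix (sites x taxa), no zero-total rows.
#' @param n_axes number of axes to return.
#' @return list of class `ls_ordination`: `eigenvalues` (all, nonincreasing),
#'   `total_inertia`, `site_scores`, `taxon_scores`, `row_weights`.
#' @export
nsca <- function(A, n_axes = 2) {
  A <- as.matrix(A)
  core <- nsca_core(A)
  dec <- finish_nsca(core$Qw, core$r, n_axes, rownames(A), colnames(A))
  structure(list(
    method = "NSCA",
    eigenvalues = dec$eigenvalues,
    total_inertia = core$inertia,
    site_scores = dec$site_scores,
    taxon_scores = dec$taxon_scores,
    row_weights = core$r
  ), class = "ls_ordination")
}

#' @export
print.ls_ordination <- function(x, ...) {
  cat(sprintf("<%s> total inertia %.4f", x$method, x$total_inertia))
  if (!is.null(x$constrained_fraction))
    cat(sprintf(", constrained fraction %.3f", x$constrained_fraction))
  if (!is.null(x$p_value)) cat(sprintf(", p = %.4f", x$p_value))
  cat(sprintf("\n  eigenvalues: %s\n",
              paste(signif(utils::head(x$eigenvalues, 4), 4), collapse = ", ")))
  invisible(x)
}

#' NSCA with instrumental variables (constrained NSCA)
#'
#' Projects the NSCA deviation table onto the span of the (standardized)
#' environmental predictors under the row-weight metric, decomposes the
#' projection, and tests the explained inertia fraction by permuting the
#' rows of the predictor table.
#'
#' @param A abundance matrix (sites x taxa).
#' @param E numeric matrix/data.frame of predictors (rows = sites).
#' @param n_axes axes to return.
#' @param n_perm permutations for the test (0 to skip).
#' @return `ls_ordination` with `constrained_inertia`,
#'   `constrained_fraction`, `p_value`, `null_fractions`, and `residuals`
#'   (the unexplained deviation table in row-weighted coordinates, sites x
#'   taxa, usable for residual co-inertia analyses).
#' @export
nscaiv <- function(A, E, n_axes = 2, n_perm = 999) {
  A <- as.matrix(A)
  E <- as.matrix(E)
  if (nrow(E) != nrow(A)) stop("E must have one row per site")
  if (qr(cbind(1, E))$rank < ncol(E) + 1) stop("collinear predictor table")
  core <- nsca_core(A)
  sw <- sqrt(core$r)
  frac_for <- function(Em) {
    Xw <- sw * cbind(1, Em)
    sum(proj_cols(core$Qw, Xw)^2) / core$inertia
  }
  Xw <- sw * cbind(1, E)
  Qhat_w <- proj_cols(core$Qw, Xw)
  frac_obs <- sum(Qhat_w^2) / core$inertia
  dec <- finish_nsca(Qhat_w, core$r, n_axes, rownames(A), colnames(A))
  p <- NULL; null_fracs <- NULL
  if (n_perm > 0) {
    null_fracs <- vapply(seq_len(n_perm), function(k)
      frac_for(E[sample.int(nrow(E)), , drop = FALSE]), 0)
    p <- (1 + sum(null_fracs >= frac_obs)) / (n_perm + 1)
  }
  structure(list(
    method = "NSCAIV",
    eigenvalues = dec$eigenvalues,
    total_inertia = core$inertia,
    constrained_inertia = frac_obs * core$inertia,
    constrained_fraction = frac_obs,
    site_scores = dec$site_scores,
    taxon_scores = dec$taxon_scores,
    row_weights = core$r,
    residuals = core$Qw - Qhat_w,
    p_value = p,
    null_fractions = null_fracs
  ), class = "ls_ordination")
}

ca_core <- function(A) {
  if (nrow(A) < 2 || ncol(A) < 2) stop("need at least 2 rows and 2 columns")
  tot <- sum(A)
  if (tot == 0) stop("empty abundance matrix")
  P <- A / tot
  r <- rowSums(P); cm <- colSums(P)
  if (any(r == 0)) stop("zero-total rows must be dropped before ordination")
  if (any(cm == 0)) stop("zero-total columns must be dropped before ordination")
  Ybar <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  list(r = r, cm = cm, Ybar = Ybar, inertia = sum(Ybar^2))
}

# weighted centering of a design matrix
w_center <- function(X, r) {
  X <- as.matrix(X)
  sweep(X, 2, colSums(X * r) / sum(r), "-")
}

#' (Partial) canonical correspondence analysis
#'
#' Chi-square-metric CA triplet: the conditioning table `Z` is partialled
#' out by weighted regression, the residual deviation table is constrained
#' on `E`, and the constrained inertia fraction is tested by permuting the
#' rows of `E`. With `Z = NULL` this is plain CCA.
#'
#' @param A abundance matrix (sites x taxa).
#' @param E predictor table (rows = sites).
#' @param Z conditioning table (e.g. second-order polynomial of quadrat
#'   coordinates; see [poly2_coords]), or `NULL`.
#' @param n_axes axes to return.
#' @param n_perm permutations (0 to skip the test).
#' @return `ls_ordination` with `constrained_inertia` (after conditioning),
#'   `conditional_inertia`, `constrained_fraction` (of total), `p_value`.
#' @export
pcca <- function(A, E, Z = NULL, n_axes = 2, n_perm = 999) {
  A <- as.matrix(A)
  E <- as.matrix(E)
  core <- ca_core(A)
  r <- core$r
  sw <- sqrt(r)
  Yw <- core$Ybar
  cond_inertia <- 0
  if (!is.null(Z) && ncol(as.matrix(Z)) > 0) {
    Zw <- sw * w_center(Z, r)
    fitZ <- proj_cols(Yw, Zw)
    cond_inertia <- sum(fitZ^2)
    Yres <- Yw - fitZ
    resid_design <- function(Em) {
      Ew <- sw * w_center(Em, r)
      R <- Ew - proj_cols(Ew, Zw)
      # directions numerically absorbed by the conditioning table would
      # otherwise re-enter as noise axes through the QR projection
      keep <- sqrt(colSums(R^2)) > 1e-8 * pmax(sqrt(colSums(Ew^2)), 1e-12)
      R[, keep, drop = FALSE]
    }
  } else {
    Yres <- Yw
    resid_design <- function(Em) sw * w_center(Em, r)
  }
  stat_for <- function(Em) {
    Xw <- resid_design(Em)
    sum(proj_cols(Yres, Xw)^2)
  }
  Xw <- resid_design(E)
  Yhat <- proj_cols(Yres, Xw)
  constr <- sum(Yhat^2)
  s <- svd(Yhat)
  pos <- which(s$d^2 > max(s$d^2, 0) * 1e-12)
  nax <- min(n_axes, max(length(pos), 1))
  ax <- seq_len(nax)
  site <- (s$u[, ax, drop = FALSE] %*% diag(s$d[ax], nax)) / sw
  taxon <- s$v[, ax, drop = FALSE] / sqrt(core$cm)
  o <- orient_axes(site, taxon)
  dimnames(o$site) <- list(rownames(A), paste0("Axis", ax))
  dimnames(o$taxon) <- list(colnames(A), paste0("Axis", ax))
  p <- NULL
  if (n_perm > 0) {
    null_stats <- vapply(seq_len(n_perm), function(k)
      stat_for(E[sample.int(nrow(E)), , drop = FALSE]), 0)
    p <- (1 + sum(null_stats >= constr)) / (n_perm + 1)
  }
  structure(list(
    method = if (cond_inertia > 0 || !is.null(Z)) "PCCA" else "CCA",
    eigenvalues = s$d^2,
    total_inertia = core$inertia,
    conditional_inertia = cond_inertia,
    constrained_inertia = constr,
    constrained_fraction = constr / core$inertia,
    site_scores = o$site,
    taxon_scores = o$taxon,
    row_weights = r,
    p_value = p
  ), class = "ls_ordination")
}

#' Second-order polynomial of site coordinates
#'
#' Builds the centred `(x, y, x^2, xy, y^2)` conditioning table used to
#' absorb broad spatial trends in partial ordination.
#'
#' @param coords two-column matrix/data.frame of site coordinates.
#' @return numeric matrix with 5 centred columns.
#' @export
poly2_coords <- function(coords) {
  coords <- as.matrix(coords)
  x <- coords[, 1]; y <- coords[, 2]
  m <- cbind(x = x, y = y, x2 = x^2, xy = x * y, y2 = y^2)
  scale(m, center = TRUE, scale = FALSE)
}

#' Permutation test for a spatial variogram of ordination scores
#'
#' Empirical semivariance `gamma(class) = 0.5 * mean (s_i - s_j)^2` over
#' site pairs in equal-width distance classes, with a pointwise 95%
#' envelope obtained by permuting scores over locations. Classes without
#' pairs are merged with their right neighbour (logged via a message).
#'
#' @param scores numeric vector of site scores.
#' @param coords two-column matrix of site coordinates.
#' @param n_classes number of distance classes (before merging).
#' @param n_perm number of permutations.
#' @return list of class `ls_variogram`: data.frame `classes` (bounds,
#'   `n_pairs`, `gamma`, `lo`, `hi`, `outside`, `p_value`) and settings.
#' @export
variogram_permutation_test <- function(scores, coords, n_classes = 11,
                                       n_perm = 9999) {
  coords <- as.matrix(coords)
  n <- length(scores)
  stopifnot(nrow(coords) == n, n >= 3)
  pr <- t(combn(n, 2))
  d <- sqrt((coords[pr[, 1], 1] - coords[pr[, 2], 1])^2 +
              (coords[pr[, 1], 2] - coords[pr[, 2], 2])^2)
  breaks <- seq(0, max(d) * (1 + 1e-10), length.out = n_classes + 1)
  cls <- findInterval(d, breaks, rightmost.closed = TRUE)
  # merge empty classes rightward
  counts <- tabulate(cls, n_classes)
  while (any(counts == 0) && length(breaks) > 2) {
    k <- which(counts == 0)[1]
    message("merging empty distance class ", k, " with its neighbour")
    breaks <- breaks[-(k + if (k < length(counts)) 1 else 0)]
    cls <- findInterval(d, breaks, rightmost.closed = TRUE)
    counts <- tabulate(cls, length(breaks) - 1)
  }
  ncls <- length(breaks) - 1
  gamma_of <- function(s) {
    d2 <- (s[pr[, 1]] - s[pr[, 2]])^2
    0.5 * as.vector(rowsum(d2, cls, reorder = TRUE)) / counts
  }
  g_obs <- gamma_of(scores)
  null <- matrix(0, n_perm, ncls)
  chunk <- 500L
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    Sm <- vapply(seq_len(k), function(i) scores[sample.int(n)], numeric(n))
    D2 <- (Sm[pr[, 1], , drop = FALSE] - Sm[pr[, 2], , drop = FALSE])^2
    null[done + seq_len(k), ] <- t(0.5 * rowsum(D2, cls, reorder = TRUE) / counts)
    done <- done + k
  }
  j_lo <- ceiling(0.025 * (n_perm + 1))
  j_hi <- floor(0.975 * (n_perm + 1))
  lo <- apply(null, 2, function(v) sort(v)[j_lo])
  hi <- apply(null, 2, function(v) sort(v)[j_hi])
  p <- vapply(seq_len(ncls), function(k) {
    below <- (1 + sum(null[, k] <= g_obs[k])) / (n_perm + 1)
    above <- (1 + sum(null[, k] >= g_obs[k])) / (n_perm + 1)
    min(1, 2 * min(below, above))
  }, 0)
  structure(list(
    classes = data.frame(
      lower = breaks[-length(breaks)], upper = breaks[-1],
      n_pairs = counts, gamma = g_obs, lo = lo, hi = hi,
      outside = g_obs < lo | g_obs > hi, p_value = p
    ),
    n_perm = n_perm
  ), class = "ls_variogram")
}

#' @export
print.ls_variogram <- function(x, ...) {
  cat(sprintf("<variogram permutation test> %d classes, %d permutations, %d outside envelope\n",
              nrow(x$classes), x$n_perm, sum(x$classes$outside)))
  invisible(x)
}
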