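# Host specificity: co-inertia RV permutation test between liana and tree
# composition, and the within-quadrat host randomization test classifying
# liana-taxon x tree-species pairs as attraction, repulsion or neutral.

#' RV coefficient permutation test
#'
#' `RV = trace(X'Y Y'X) / sqrt(trace((X'X)^2) * trace((Y'Y)^2))` on
#' column-centred tables sharing rows; the null permutes the rows of `Y`.
#' RV is 1 when `Y` is a rotation of `X` and near 0 for unrelated tables.
#'
#' @param X,Y numeric matrices with the same rows (sites).
#' @param n_perm number of row permutations.
#' @return list of class `ls_rv_test`: `rv`, `p_value`, `null_rv`.
#' @export
rv_test <- function(X, Y, n_perm = 999) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y must share rows")
  den_x <- sum(crossprod(X)^2)
  den_y <- sum(crossprod(Y)^2)
  if (den_x == 0 || den_y == 0) stop("zero-variance table")
  rv_of <- function(Yp) sum(crossprod(X, Yp)^2) / sqrt(den_x * den_y)
  rv <- rv_of(Y)
  null_rv <- vapply(seq_len(n_perm), function(k)
    rv_of(Y[sample.int(nrow(Y)), , drop = FALSE]), 0)
  structure(list(rv = rv,
                 p_value = (1 + sum(null_rv >= rv)) / (n_perm + 1),
                 null_rv = null_rv),
            class = "ls_rv_test")
}

#' @export
print.ls_rv_test <- function(x, ...) {
  cat(sprintf("RV = %.4f, p = %.4f (%d permutations)\n",
              x$rv, x$p_value, length(x$null_rv)))
  invisible(x)
}

#' Build the liana-host link table
#'
#' One row per identified liana-host link (primary and, when present,
#' secondary). Lianas without any identified host contribute no link and
#' are tallied; links whose host tree does not lie in the liana's buffered
#' window are rejected with a warning.
#'
#' @param lianas liana table.
#' @param trees stem table.
#' @param frame a [quadrat_frame].
#' @return data.frame (`liana_id`, `taxon`, `mechanism`, `quadrat_id`,
#'   `host_stem_id`, `host_species`) with attributes `n_hostless` and
#'   `n_rejected`.
#' @export
build_links <- function(lianas, trees, frame) {
  long <- rbind(
    data.frame(liana_id = lianas$liana_id, taxon = lianas$taxon,
               mechanism = lianas$mechanism, quadrat_id = lianas$quadrat_id,
               host_stem_id = lianas$host1_stem_id),
    data.frame(liana_id = lianas$liana_id, taxon = lianas$taxon,
               mechanism = lianas$mechanism, quadrat_id = lianas$quadrat_id,
               host_stem_id = lianas$host2_stem_id)
  )
  n_hostless <- sum(is.na(lianas$host1_stem_id) & is.na(lianas$host2_stem_id))
  long <- long[!is.na(long$host_stem_id), , drop = FALSE]
  ti <- match(long$host_stem_id, trees$stem_id)
  if (any(is.na(ti))) stop("unresolved host stem id(s)")
  long$host_species <- trees$species[ti]
  qi <- match(long$quadrat_id, frame$quadrat_id)
  inside <- trees$plot_id[ti] == frame$plot_id[qi] &
    trees$x[ti] >= frame$bxmin[qi] & trees$x[ti] < frame$bxmax[qi] &
    trees$y[ti] >= frame$bymin[qi] & trees$y[ti] < frame$bymax[qi]
  n_rejected <- sum(!inside)
  if (n_rejected) {
    warning(n_rejected, " link(s) rejected: host outside the 40x40-m window")
    long <- long[inside, , drop = FALSE]
  }
  rownames(long) <- NULL
  attr(long, "n_hostless") <- n_hostless
  attr(long, "n_rejected") <- n_rejected
  long
}

#' Classify an observed link count against a null envelope
#'
#' Attraction when the observed count exceeds the upper bound, repulsion
#' when it falls below the lower bound; the bounds themselves are inclusive
#' (a count on the bound is not significant).
#'
#' @param observed,lo,hi integer vectors (recycled).
#' @return character vector in `{"attraction", "repulsion", "ns"}`.
#' @export
classify_association <- function(observed, lo, hi) {
  if (any(lo > hi)) stop("lower bound exceeds upper bound")
  ifelse(observed > hi, "attraction",
         ifelse(observed < lo, "repulsion", "ns"))
}

#' Within-quadrat host randomization test
#'
#' Each replicate independently redraws, for every retained link, a host
#' uniformly among the tree stems of that link's buffered quadrat window
#' (the observed host may be redrawn). Counts are aggregated per liana
#' taxon x tree species; the null envelope uses the order statistics at
#' ranks `ceil(0.025 (n+1))` and `floor(0.975 (n+1))` (25 and 975 for
#' n = 999), giving integer bounds.
#'
#' Only liana taxa with more than `liana_min` individuals and tree species
#' with more than `tree_min` stems (in the full tables) are reported.
#'
#' @param links link table from [build_links].
#' @param trees stem table.
#' @param frame a [quadrat_frame].
#' @param liana_min individuals a liana taxon must exceed to be tested.
#' @param tree_min stems a tree species must exceed to be reported.
#' @param n_rep number of randomization replicates.
#' @param census tree census defining the available stems.
#' @return data.frame of class `ls_associations`: `taxon`, `mechanism`,
#'   `tree_species`, `observed`, `lo`, `hi`, `class`, plus attribute
#'   `null_mean` (matrix of null expectations).
#' @export
host_randomization_test <- function(links, trees, frame, liana_min = 60,
                                    tree_min = 100, n_rep = 999, census = 2) {
  dcol <- if (census == 2) "dbh_census2" else "dbh_census1"
  trees <- trees[!is.na(trees[[dcol]]), , drop = FALSE]
  n_ind <- tapply(links$liana_id, links$taxon, function(v) length(unique(v)))
  taxa_keep <- names(n_ind)[n_ind > liana_min]
  if (!length(taxa_keep)) stop("no liana taxon passes the abundance filter")
  sp_count <- table(trees$species)
  species_keep <- names(sp_count)[sp_count > tree_min]
  if (!length(species_keep)) stop("no tree species passes the abundance filter")
  links <- links[links$taxon %in% taxa_keep, , drop = FALSE]
  sp_levels <- sort(unique(trees$species))
  taxa_keep <- sort(taxa_keep)
  species_keep <- sort(species_keep)
  mech <- tapply(links$mechanism, links$taxon, function(v) v[1])[taxa_keep]
  nt <- length(taxa_keep); ns <- length(sp_levels)
  obs <- matrix(0L, nt, ns, dimnames = list(taxa_keep, sp_levels))
  tab_obs <- table(factor(links$taxon, taxa_keep),
                   factor(links$host_species, sp_levels))
  obs[] <- as.integer(tab_obs)
  null_counts <- array(0L, c(nt, ns, n_rep),
                       dimnames = list(taxa_keep, sp_levels, NULL))
  for (q in unique(links$quadrat_id)) {
    i <- match(q, frame$quadrat_id)
    inw <- which(trees$plot_id == frame$plot_id[i] &
                   trees$x >= frame$bxmin[i] & trees$x < frame$bxmax[i] &
                   trees$y >= frame$bymin[i] & trees$y < frame$bymax[i])
    lq <- which(links$quadrat_id == q)
    if (!length(inw)) stop("window of ", q, " holds no tree; cannot randomize")
    wsp <- match(trees$species[inw], sp_levels)
    for (tx in unique(links$taxon[lq])) {
      k <- sum(links$taxon[lq] == tx)
      draws <- matrix(wsp[sample.int(length(inw), k * n_rep, replace = TRUE)],
                      k, n_rep)
      ti <- match(tx, taxa_keep)
      # per-replicate species counts for this taxon/quadrat block
      cnt <- apply(draws, 2, tabulate, nbins = ns)
      null_counts[ti, , ] <- null_counts[ti, , ] + cnt
    }
  }
  j_lo <- ceiling(0.025 * (n_rep + 1))
  j_hi <- floor(0.975 * (n_rep + 1))
  res <- list()
  null_mean <- matrix(NA_real_, nt, length(species_keep),
                      dimnames = list(taxa_keep, species_keep))
  for (ti in seq_len(nt)) for (sp in species_keep) {
    si <- match(sp, sp_levels)
    nv <- sort(null_counts[ti, si, ])
    lo <- nv[j_lo]; hi <- nv[j_hi]
    null_mean[ti, sp] <- mean(null_counts[ti, si, ])
    res[[length(res) + 1]] <- data.frame(
      taxon = taxa_keep[ti], mechanism = unname(mech[ti]), tree_species = sp,
      observed = obs[ti, si], lo = lo, hi = hi,
      class = classify_association(obs[ti, si], lo, hi)
    )
  }
  out <- do.call(rbind, res)
  attr(out, "null_mean") <- null_mean
  class(out) <- c("ls_associations", "data.frame")
  out
}

#' Summarize an association table
#'
#' Totals of attraction / repulsion / non-significant pairs, the percent of
#' tested pairs that are significant (rounded to an integer), and a
#' cross-tabulation of significant associations by climbing mechanism.
#'
#' @param results association table with `class` and optionally `mechanism`.
#' @return list with `n_pairs`, `n_attraction`, `n_repulsion`,
#'   `n_significant`, `percent_significant`, `by_mechanism`.
#' @export
summarize_associations <- function(results) {
  if (!nrow(results)) stop("empty association table")
  cl <- results$class
  n_att <- sum(cl == "attraction")
  n_rep <- sum(cl == "repulsion")
  n_sig <- n_att + n_rep
  by_mech <- if ("mechanism" %in% names(results)) {
    sig <- results[cl != "ns", , drop = FALSE]
    table(mechanism = sig$mechanism, class = sig$class)
  } else NULL
  list(n_pairs = nrow(results),
       n_attraction = n_att,
       n_repulsion = n_rep,
       n_significant = n_sig,
       percent_significant = round(100 * n_sig / nrow(results)),
       by_mechanism = by_mech)
}

#' Packaged transcription of the published host-association table
#'
#' Observed link counts and null envelopes for the 10 most abundant liana
#' taxa crossed with the 24 most abundant tree species at the study site,
#' as printed in the source census study; used to check the classification
#' and summary conventions against the published tallies.
#'
#' @return data.frame with `tree_species`, `taxon`, `mechanism`,
#'   `observed`, `lo`, `hi`.
#' @export
read_association_fixture <- function() {
  path <- system.file("extdata", "table4_fixture.csv", package = "lianascape",
                      mustWork = TRUE)
  utils::read.csv(path, fileEncoding = "UTF-8")
}
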