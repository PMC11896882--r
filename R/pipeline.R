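# End-to-end orchestration: simulate -> metrics -> structure models ->
# ordination -> trait-environment -> host specificity, writing CSV/JSON
# artifacts per stage. Each stage seeds its own stream from the run seed,
# so a run is reproducible stage by stage.

PIPELINE_STAGES <- c("simulate", "metrics", "structure", "ordination",
                     "traitenv", "hosts")

#' Run the analysis pipeline on a synthetic census
#'
#' Executes the enabled stages in dependency order on one generated
#' community and writes per-stage artifacts (CSV tables, ASCII rasters,
#' `report.json`, a mirrored configuration and a line-oriented log) under
#' `out_dir`. Rerunning with the same configuration and seed reproduces
#' identical outputs.
#'
#' @param config a [sim_config].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param stages subset of `PIPELINE_STAGES` to run (dependencies checked).
#' @param n_perm permutations for ordination/trait/host tests.
#' @param n_perm_variogram permutations for the variogram envelopes.
#' @param host_liana_min,host_tree_min abundance filters of the host test.
#' @param ranef_alpha significance level of the random-intercept check.
#' @param write_rasters also write the DEM/DSM grids as ESRI ASCII files
#'   (off by default: they are large and regenerable from config + seed).
#' @return list with the simulated data and every stage result.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = NULL,
                         stages = PIPELINE_STAGES,
                         n_perm = 999,
                         n_perm_variogram = 9999,
                         host_liana_min = 60,
                         host_tree_min = 100,
                         ranef_alpha = 0.1,
                         write_rasters = FALSE) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  if (n_perm < 99) stop("n_perm must be at least 99")
  t0 <- Sys.time()
  log_lines <- character()
  note <- function(stage, msg) {
    line <- sprintf("[%s] seed=%d %s: %s",
                    format(Sys.time(), "%H:%M:%S"), config$seed, stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  needs <- function(stage, dep, object) {
    if (is.null(object))
      stop("stage '", stage, "' needs stage '", dep,
           "' to be enabled in the same run")
  }
  res <- list(config = config)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if ("simulate" %in% stages) {
    note("simulate", "generating landscape, trees, herbs, lianas, traits")
    res$sim <- simulate_community(config)
    if (!is.null(out_dir)) {
      write_stem_table(res$sim$trees, file.path(out_dir, "trees.csv"))
      write_liana_table(res$sim$lianas, file.path(out_dir, "lianas.csv"))
      write_trait_table(res$sim$traits, file.path(out_dir, "traits.csv"))
      utils::write.csv(res$sim$herbs, file.path(out_dir, "herbs.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(res$sim$quadrats),
                       file.path(out_dir, "quadrats.csv"), row.names = FALSE)
      if (write_rasters) {
        for (pid in names(res$sim$landscape)) {
          write_ascii_grid(res$sim$landscape[[pid]]$dem,
                           file.path(out_dir, paste0("dem_", pid, ".asc")))
          write_ascii_grid(res$sim$landscape[[pid]]$dsm,
                           file.path(out_dir, paste0("dsm_", pid, ".asc")))
        }
      }
      gt <- res$sim$ground_truth
      gt$theta_host <- NULL # large; regenerate from config/seed when needed
      jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      cfg <- res$sim$config
      jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                           file.path(out_dir, "config.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("metrics" %in% stages) {
    needs("metrics", "simulate", res$sim)
    note("metrics", "liana structure and environment tables")
    res$liana_structure <- quadrat_liana_structure(res$sim$lianas,
                                                   res$sim$quadrats)
    res$env <- res$sim$env
    res$env_screen <- correlation_screen(res$env)
    if (!is.null(out_dir)) {
      utils::write.csv(res$liana_structure,
                       file.path(out_dir, "liana_structure.csv"), row.names = FALSE)
      utils::write.csv(res$env, file.path(out_dir, "env.csv"), row.names = FALSE)
    }
  }

  if ("structure" %in% stages) {
    needs("structure", "metrics", res$env)
    note("structure", "REML pseudo-replication check and stepwise selection")
    set.seed(config$seed + 1L)
    z <- as.data.frame(standardize_env(res$env))
    qf <- res$sim$quadrats
    cx <- (qf$xmin + qf$xmax) / 2; cy <- (qf$ymin + qf$ymax) / 2
    grp_1ha <- paste(qf$plot_id, floor(cx / 100), floor(cy / 100))
    grp_9ha <- qf$plot_id
    res$structure <- list()
    for (resp in c("N_L", "BA_L", "QMD_L")) {
      y <- res$liana_structure[[resp]]
      ok <- is.finite(y)
      ranef <- list(
        `1-ha` = lr_test_random_effect(y[ok], z[ok, , drop = FALSE],
                                       grp_1ha[ok], level = "1-ha"),
        `9-ha` = lr_test_random_effect(y[ok], z[ok, , drop = FALSE],
                                       grp_9ha[ok], level = "9-ha")
      )
      fit <- stepwise_select(y[ok], z[ok, , drop = FALSE], response = resp)
      res$structure[[resp]] <- list(ranef = ranef, fit = fit)
      sig <- vapply(ranef, function(r) r$p_value < ranef_alpha, TRUE)
      if (any(sig))
        note("structure", paste0(resp, ": random intercept significant at ",
                                 paste(names(sig)[sig], collapse = "/"),
                                 " level; fixed-effects model kept for parsimony"))
    }
    if (!is.null(out_dir)) {
      tab <- do.call(rbind, lapply(names(res$structure), function(resp) {
        f <- res$structure[[resp]]$fit
        cbind(response = resp, f$coefficients,
              r_squared = f$r_squared, f_statistic = f$f_statistic, n = f$n)
      }))
      utils::write.csv(tab, file.path(out_dir, "models.csv"), row.names = FALSE)
    }
  }

  if ("ordination" %in% stages) {
    needs("ordination", "metrics", res$env)
    note("ordination", "NSCA, variogram tests, NSCAIV, PCCA")
    set.seed(config$seed + 2L)
    A <- build_abundance_matrix(res$sim$lianas, res$sim$quadrats, "quadrat")
    occ <- rowSums(A) > 0
    A <- A[occ, , drop = FALSE]
    env_occ <- res$env[occ, , drop = FALSE]
    z <- standardize_env(env_occ)
    coords <- cbind(res$sim$quadrats$gx, res$sim$quadrats$gy)[occ, , drop = FALSE]
    res$nsca <- nsca(A, n_axes = 2)
    res$variogram <- lapply(1:2, function(a)
      variogram_permutation_test(res$nsca$site_scores[, a], coords,
                                 n_classes = 11, n_perm = n_perm_variogram))
    res$nscaiv <- nscaiv(A, z, n_axes = 2, n_perm = n_perm)
    res$pcca <- pcca(A, z, Z = poly2_coords(coords), n_axes = 2, n_perm = n_perm)
    res$ordination_sites <- occ
    if (!is.null(out_dir)) {
      utils::write.csv(data.frame(quadrat_id = rownames(A),
                                  res$nsca$site_scores),
                       file.path(out_dir, "ordination_scores.csv"), row.names = FALSE)
      utils::write.csv(data.frame(axis = seq_along(res$nsca$eigenvalues),
                                  eigenvalue = res$nsca$eigenvalues),
                       file.path(out_dir, "eigenvalues.csv"), row.names = FALSE)
      utils::write.csv(cbind(axis = rep(1:2, vapply(res$variogram, function(v)
        nrow(v$classes), 0L)),
        do.call(rbind, lapply(res$variogram, `[[`, "classes"))),
        file.path(out_dir, "variogram.csv"), row.names = FALSE)
    }
  }

  if ("traitenv" %in% stages) {
    needs("traitenv", "metrics", res$env)
    needs("traitenv", "ordination", res$nsca)
    note("traitenv", "CWM/SNC max-tests and trait-shuffle axis nulls")
    set.seed(config$seed + 3L)
    A <- build_abundance_matrix(res$sim$lianas, res$sim$quadrats, "quadrat")
    occ <- res$ordination_sites
    A <- A[occ, , drop = FALSE]
    z <- standardize_env(res$env[occ, , drop = FALSE])
    res$trait_env <- maxtest(A, res$sim$traits, z, n_perm = n_perm)
    res$cwm_axis <- lapply(1:2, function(a)
      cwm_axis_null(A, res$sim$traits, res$nsca$site_scores[, a],
                    n_perm = n_perm))
    if (!is.null(out_dir))
      utils::write.csv(res$trait_env, file.path(out_dir, "trait_env.csv"),
                       row.names = FALSE)
  }

  if ("hosts" %in% stages) {
    needs("hosts", "metrics", res$env)
    note("hosts", "co-inertia RV tests and host randomization")
    set.seed(config$seed + 4L)
    AL <- build_abundance_matrix(res$sim$lianas, res$sim$quadrats, "quadrat")
    AT <- build_abundance_matrix(res$sim$trees, res$sim$quadrats, "buffered")
    occ <- rowSums(AL) > 0 & rowSums(AT) > 0
    res$rv <- rv_test(AL[occ, ], AT[occ, ], n_perm = n_perm)
    z <- standardize_env(res$env[occ, , drop = FALSE])
    rl <- nscaiv(AL[occ, , drop = FALSE], z, n_perm = 0)$residuals
    rt <- nscaiv(AT[occ, , drop = FALSE], z, n_perm = 0)$residuals
    res$rv_residual <- rv_test(rl, rt, n_perm = n_perm)
    res$links <- build_links(res$sim$lianas, res$sim$trees, res$sim$quadrats)
    res$associations <- host_randomization_test(
      res$links, res$sim$trees, res$sim$quadrats,
      liana_min = host_liana_min, tree_min = host_tree_min, n_rep = n_perm)
    res$association_summary <- summarize_associations(res$associations)
    if (!is.null(out_dir))
      utils::write.csv(as.data.frame(res$associations),
                       file.path(out_dir, "associations.csv"), row.names = FALSE)
  }

  note("done", sprintf("elapsed %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run.log"))
    report <- list(seed = config$seed, stages = stages)
    if (!is.null(res$structure))
      report$structure <- lapply(res$structure, function(s) list(
        predictors = s$fit$predictors, r_squared = s$fit$r_squared,
        f_statistic = s$fit$f_statistic))
    if (!is.null(res$nscaiv))
      report$nscaiv <- list(fraction = res$nscaiv$constrained_fraction,
                            p = res$nscaiv$p_value)
    if (!is.null(res$pcca))
      report$pcca <- list(fraction = res$pcca$constrained_fraction,
                          p = res$pcca$p_value)
    if (!is.null(res$trait_env))
      report$trait_env_significant <-
        sum(res$trait_env$p_max < 0.05)
    if (!is.null(res$rv))
      report$rv <- list(rv = res$rv$rv, p = res$rv$p_value,
                        rv_residual = res$rv_residual$rv,
                        p_residual = res$rv_residual$p_value)
    if (!is.null(res$association_summary))
      report$associations <- res$association_summary[
        c("n_pairs", "n_attraction", "n_repulsion", "percent_significant")]
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
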