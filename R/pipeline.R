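# Orchestration: soil ordination -> trait ordination -> trait assemblages ->
# within-plot dispersion tests -> turnover suite, from one config, with one
# master seed from which all stage seeds are derived.

#' Soil variables defining soil distance
#'
#' Z-scores the soil table, eliminates collinear variables by iterative VIF,
#' runs the correlation-matrix PCA on the survivors and returns the
#' variables significantly correlated (Pearson, `alpha`) with axis 1 — the
#' set over which soil distance is computed.
#'
#' @param env an [environment_table()].
#' @param vif_threshold VIF elimination threshold (default 10).
#' @param alpha significance level for axis-1 correlations (default 0.05).
#' @return list: `variables` (the axis-1 set), `vif` (elimination result),
#'   `pca` (the soil `pca_result`), `correlations` (axis-1 table).
#' @export
select_soil_variables <- function(env, vif_threshold = 10, alpha = 0.05) {
  vf <- vif_eliminate(zscore(env$soil), threshold = vif_threshold)
  kept <- env$soil[, vf$retained, drop = FALSE]
  pca <- pca_correlation(kept)
  tab <- axis_variable_correlations(pca, zscore(kept), alpha = alpha,
                                    axes = 1L)
  list(variables = select_trait_assemblage(tab, 1L), vif = vf, pca = pca,
       correlations = tab)
}

#' Resource-use-trait assemblages per retained PCA axis
#'
#' Correlation-matrix PCA on the z-scored trait table; for each requested
#' axis (default the first three), the assemblage is the set of traits
#' significantly correlated with that axis's scores. Axes with no
#' significant trait are dropped with a warning rather than erroring the
#' whole run.
#'
#' @param rut a [continuous_trait_matrix()].
#' @param alpha significance level (default 0.05).
#' @param axes axis indices to screen (default 1:3).
#' @return list: `assemblages` (named list `axis1`, `axis2`, ...), `pca`,
#'   `correlations`.
#' @export
rut_axis_assemblages <- function(rut, alpha = 0.05, axes = 1:3) {
  z <- zscore(unclass(rut))
  pca <- pca_correlation(z, standardize = FALSE)
  axes <- axes[axes <= ncol(z)]
  tab <- axis_variable_correlations(pca, z, alpha = alpha, axes = axes)
  asm <- list()
  for (a in axes) {
    sel <- tryCatch(select_trait_assemblage(tab, a), error = function(e) NULL)
    if (is.null(sel)) {
      warning("no trait significantly correlated with axis ", a,
              "; axis dropped", call. = FALSE)
    } else {
      asm[[paste0("axis", a)]] <- sel
    }
  }
  list(assemblages = asm, pca = pca, correlations = tab)
}

#' Analysis run configuration
#'
#' @param input_dir directory holding `occurrence.csv`, `sm.csv`, `rut.csv`,
#'   `env.csv` (the [write_bundle()] layout), or NULL to simulate.
#' @param simulate a [synthetic_config()] used when `input_dir` is NULL.
#' @param alpha significance level (default 0.05).
#' @param reps_within null-model replicates (default 1000).
#' @param perms_mantel Mantel permutations (default 999).
#' @param residualize_soil report the spatially residualized soil-distance
#'   Mantel tests as the headline soil result (both variants are always
#'   computed; default FALSE).
#' @param replace null-model multiset variant flag (default FALSE: distinct
#'   species per plot; see [median_difference_test()]).
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir = NULL, simulate = synthetic_config(),
                       alpha = 0.05, reps_within = 1000, perms_mantel = 999,
                       residualize_soil = FALSE, replace = FALSE,
                       seed = NULL) {
  stopifnot(reps_within >= 1, perms_mantel >= 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate the bundle; soil VIF + PCA and soil-variable
#' selection; trait PCA and axis assemblages; within-plot dispersion tests
#' (metabolites for divergence, trait assemblages for convergence); turnover
#' suite against log spatial and soil distance. Deterministic given
#' `config$seed`.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: report JSON, summary CSVs and the
#'   tau-vs-distance scatter data are written there.
#' @return a `run_report` list: `coverage`, `soil`, `rut`, `within_plot`,
#'   `turnover`, `provenance`.
#' @export
run_full <- function(config = run_config(), out_dir = NULL) {
  seeds <- derive_seeds(if (is.null(config$seed)) 0L else config$seed, 3L)
  bundle <- if (!is.null(config$input_dir)) {
    d <- config$input_dir
    load_bundle(file.path(d, "occurrence.csv"), file.path(d, "sm.csv"),
                file.path(d, "rut.csv"), file.path(d, "env.csv"))
  } else {
    cfg <- config$simulate
    cfg$seed <- if (is.null(config$seed)) cfg$seed else seeds[[1L]]
    generate_dataset(cfg)$bundle
  }
  soil <- select_soil_variables(bundle$env, alpha = config$alpha)
  rut <- rut_axis_assemblages(bundle$rut, alpha = config$alpha)
  within <- run_all_trait_tests(bundle, rut$assemblages,
                                R = config$reps_within, seed = seeds[[2L]],
                                replace = config$replace)
  turn <- run_turnover_suite(bundle, rut$assemblages, soil$variables,
                             permutations = config$perms_mantel,
                             seed = seeds[[3L]])
  report <- structure(list(
    coverage = bundle$coverage,
    soil = list(variables = soil$variables, vif_retained = soil$vif$retained,
                vif_removed = soil$vif$removed,
                variance_proportions = soil$pca$variance_proportions,
                retained_axes = which(soil$pca$retained)),
    rut = list(assemblages = rut$assemblages,
               variance_proportions = rut$pca$variance_proportions,
               retained_axes = which(rut$pca$retained)),
    within_plot = within,
    turnover = turn,
    provenance = list(seed = config$seed, alpha = config$alpha,
                      reps_within = config$reps_within,
                      perms_mantel = config$perms_mantel,
                      residualize_soil = config$residualize_soil,
                      replace = config$replace,
                      config_hash = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("traitdisp")))
  ), class = "run_report")
  if (!is.null(out_dir)) write_report(report, bundle, out_dir)
  report
}

# Hash of the analysis-relevant config fields (md5 of their deparsed form).
#' @noRd
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[sort(names(config))]), f)
  unname(tools::md5sum(f))
}

#' @noRd
write_report <- function(report, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$within_plot$summary,
                   file.path(out_dir, "within_plot_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$turnover$summary,
                   file.path(out_dir, "turnover_tests.csv"), row.names = FALSE)
  # tau vs distance scatter data for plotting
  spat <- spatial_distance(bundle$env$coords)
  rows <- list()
  for (nm in names(report$turnover$tau)) {
    tau <- as.matrix(report$turnover$tau[[nm]]$tau)
    ut <- upper.tri(tau)
    rows[[nm]] <- data.frame(assemblage = nm,
                             plot_i = rownames(tau)[row(tau)[ut]],
                             plot_j = colnames(tau)[col(tau)[ut]],
                             tau = tau[ut], log_spatial_km = spat[ut])
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "tau_scatter.csv"), row.names = FALSE)
  slim <- report
  slim$within_plot <- list(summary = report$within_plot$summary)
  slim$turnover <- list(summary = report$turnover$summary)
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' Within-plot test summary with significance stars
#'
#' One row per trait assemblage with the O-E effect size (mean and SD of the
#' replicate medians), the p-value, and star coding: `***` p <= 0.001,
#' `**` p <= 0.01, `*` p <= 0.05, `ns` otherwise.
#'
#' @param report a [run_full()] report (or a [run_all_trait_tests()] result).
#' @return data.frame: assemblage, alternative, o_e_mean, o_e_sd, p, stars.
#' @export
summarize_figure1 <- function(report) {
  s <- if (inherits(report, "run_report")) report$within_plot$summary
       else report$summary
  s$stars <- ifelse(s$p <= 0.001, "***",
             ifelse(s$p <= 0.01, "**",
             ifelse(s$p <= 0.05, "*", "ns")))
  s
}

#' Reproduce the full study analysis from its appendix-style tables
#'
#' Given a directory containing `occurrence.csv`, `sm.csv`, `rut.csv` and
#' `env.csv` in the [write_bundle()] layout (the study's supplementary
#' tables recast as CSV), runs every stage and returns the headline
#' quantities: mean metabolites per species, VIF-surviving soil variables,
#' soil and trait PCA variance percentages, dual-coverage plot count, the
#' within-plot test table and the turnover Mantel table.
#'
#' @param dir directory with the four CSV files.
#' @param reps_within,perms_mantel,seed analysis parameters.
#' @return list of headline quantities plus the full `run_report`.
#' @export
reproduce_study <- function(dir, reps_within = 1000, perms_mantel = 999,
                            seed = 1L) {
  report <- run_full(run_config(input_dir = dir, reps_within = reps_within,
                                perms_mantel = perms_mantel, seed = seed))
  b <- load_bundle(file.path(dir, "occurrence.csv"), file.path(dir, "sm.csv"),
                   file.path(dir, "rut.csv"), file.path(dir, "env.csv"))
  list(
    mean_metabolites_per_species = mean(rowSums(unclass(b$sm))),
    soil_variables_retained = report$soil$vif_retained,
    pca_soil_axis1_pct = 100 * report$soil$variance_proportions[1L],
    pca_rut_pct = 100 * report$rut$variance_proportions,
    plots_with_dual_coverage = length(b$coverage$plots_both),
    within_plot = summarize_figure1(report),
    turnover = report$turnover$summary,
    report = report
  )
}

# ---- command-line interface -------------------------------------------------

#' @noRd
cli_opts <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        out[[key]] <- TRUE
      } else {
        out[[key]] <- args[i + 1L]
        i <- i + 1L
      }
    } else out$positional <- c(out$positional, a)
    i <- i + 1L
  }
  out
}

#' @noRd
cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) {
    raw <- if (grepl("\\.json$", opts$config)) {
      jsonlite::read_json(opts$config, simplifyVector = TRUE)
    } else yaml::read_yaml(opts$config)
    sim <- do.call(synthetic_config,
                   raw$simulate %||% list())
    do.call(run_config, c(raw[setdiff(names(raw), "simulate")],
                          list(simulate = sim)))
  } else run_config()
  if (!is.null(opts$input)) cfg$input_dir <- opts$input
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$reps)) cfg$reps_within <- as.integer(opts$reps)
  if (!is.null(opts$perms)) cfg$perms_mantel <- as.integer(opts$perms)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `validate --input DIR`; `simulate --seed S --out DIR
#' [--config cfg.yaml]`; `soil-pca --input DIR`; `rut-pca --input DIR`;
#' `within-plot-test --input DIR --traits {sm|rut-axis1|...} --reps R
#' --seed S`; `turnover --input DIR --perms P --seed S`; `run [--config
#' cfg.yaml] [--input DIR] --seed S --out DIR`. Config files may be YAML or
#' JSON.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly (0 success, 1 failure).
#' @export
traitdisp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: traitdisp <validate|simulate|soil-pca|rut-pca|within-plot-test|turnover|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- cli_opts(args[-1L])
  status <- tryCatch({
    switch(cmd,
      validate = {
        d <- opts$input
        b <- load_bundle(file.path(d, "occurrence.csv"),
                         file.path(d, "sm.csv"), file.path(d, "rut.csv"),
                         file.path(d, "env.csv"))
        print(b)
        cat(jsonlite::toJSON(b$coverage, auto_unbox = TRUE, pretty = TRUE),
            "\n")
        0L
      },
      simulate = {
        cfg <- cli_config(opts)$simulate
        if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
        write_dataset(generate_dataset(cfg), opts$out %||% ".")
        cat("dataset written to", opts$out %||% ".", "\n")
        0L
      },
      `soil-pca` = ,
      `rut-pca` = {
        cfg <- cli_config(opts)
        d <- cfg$input_dir
        b <- load_bundle(file.path(d, "occurrence.csv"),
                         file.path(d, "sm.csv"), file.path(d, "rut.csv"),
                         file.path(d, "env.csv"))
        res <- if (cmd == "soil-pca") select_soil_variables(b$env)
               else rut_axis_assemblages(b$rut)
        print(res$pca)
        print(res$correlations)
        0L
      },
      `within-plot-test` = {
        cfg <- cli_config(opts)
        rep_ <- run_full(cfg)
        s <- summarize_figure1(rep_)
        if (!is.null(opts$traits)) {
          nm <- if (tolower(opts$traits) == "sm") "SM"
                else sub("^rut-", "", tolower(opts$traits))
          s <- s[s$assemblage == nm, , drop = FALSE]
        }
        print(s)
        0L
      },
      turnover = {
        cfg <- cli_config(opts)
        rep_ <- run_full(cfg)
        s <- rep_$turnover$summary
        if (!is.null(opts$traits)) {
          nm <- if (tolower(opts$traits) == "sm") "SM"
                else sub("^rut-", "", tolower(opts$traits))
          s <- s[s$assemblage == nm, , drop = FALSE]
        }
        if (!is.null(opts$against)) {
          keep <- if (identical(opts$against, "soil")) {
            if (isTRUE(cfg$residualize_soil) ||
                identical(opts$residualize_soil, "on")) "soil_residual"
            else "soil"
          } else "spatial"
          s <- s[s$predictor == keep, , drop = FALSE]
        }
        print(s)
        0L
      },
      run = {
        cfg <- cli_config(opts)
        rep_ <- run_full(cfg, out_dir = opts$out)
        print(summarize_figure1(rep_))
        print(rep_$turnover$summary)
        0L
      },
      { cat("unknown subcommand:", cmd, "\n"); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
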