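# Within-plot dispersion test: observed mean pairwise trait distance among
# co-occurring species versus a randomization null that refills each plot
# with N species drawn (with replacement) from the covered species pool,
# keeping trait values intact. The test statistic per replicate is the
# median over plots of (observed - expected); its replicate distribution
# yields the p-value.

#' Mean pairwise trait distance within each plot
#'
#' For each plot, the mean of d(s, t) over all unordered pairs of distinct
#' co-occurring species that are covered by the distance matrix. Plots with
#' fewer than two covered species are excluded with a warning.
#'
#' @param occurrence an [occurrence_matrix()].
#' @param dist a species-level [distance_matrix()].
#' @return named numeric vector of per-plot means (usable plots only), with
#'   excluded plot ids in attribute `"excluded"`.
#' @export
mean_within_plot_distance <- function(occurrence, dist) {
  sp <- intersect(colnames(occurrence), rownames(dist))
  occ <- unclass(occurrence)[, sp, drop = FALSE]
  n <- rowSums(occ)
  excluded <- rownames(occ)[n < 2L]
  if (length(excluded))
    warning("plot(s) with <2 covered species excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  usable <- rownames(occ)[n >= 2L]
  if (!length(usable)) stop("no usable plots", call. = FALSE)
  D <- as.matrix(dist)
  out <- vapply(usable, function(p) {
    s <- sp[occ[p, ] == 1L]
    m <- D[s, s]
    mean(m[upper.tri(m)])
  }, numeric(1))
  attr(out, "excluded") <- excluded
  out
}

#' One null-model randomization of the community
#'
#' Replaces each plot's N observed species by N uniform draws from `pool`
#' (each species equally weighted), preserving per-plot richness. The
#' default draws distinct species; `replace = TRUE` gives multisets (a
#' species can be drawn twice into the same plot).
#'
#' @param occurrence an [occurrence_matrix()].
#' @param pool character vector of candidate species ids.
#' @param replace sample with replacement within plots (default FALSE).
#' @return named list: one character vector of length N per plot.
#' @export
null_replicate <- function(occurrence, pool, replace = FALSE) {
  occ <- unclass(occurrence)
  lapply(stats::setNames(rownames(occ), rownames(occ)), function(p) {
    n <- sum(occ[p, ])
    sample(pool, n, replace = replace)
  })
}

# Expected mean pairwise distance per replicate for one plot, vectorized
# over replicates: idx is an R x N matrix of row indices into D. Duplicate
# draws hit the zero diagonal and contribute 0 to the mean.
#' @noRd
replicate_means <- function(D, idx) {
  n <- ncol(idx)
  pairs <- utils::combn(n, 2L)
  acc <- numeric(nrow(idx))
  for (k in seq_len(ncol(pairs)))
    acc <- acc + D[cbind(idx[, pairs[1L, k]], idx[, pairs[2L, k]])]
  acc / ncol(pairs)
}

#' Median-of-differences null-model dispersion test
#'
#' For each of `R` replicates, every plot's species are replaced by an
#' equal-size random draw from the pool and the expected mean pairwise
#' distance is recomputed; the replicate statistic is the median over plots
#' of (observed - expected). The p-value is the proportion of replicate
#' medians contradicting the alternative (<= 0 for `"divergence"`, >= 0 for
#' `"convergence"`), with the (k + 1)/(R + 1) correction so p is never 0.
#'
#' By default each plot receives N *distinct* species (uniform subsets of
#' the pool — the richness-preserving randomization under which the test is
#' calibrated; species are reused freely across plots). `replace = TRUE`
#' gives the literal multiset variant in which a plot can draw the same
#' species twice and the duplicate pair contributes distance 0; that
#' variant's expected distances are biased low by roughly mean(d)/pool_size,
#' which inflates apparent divergence, so it is provided for sensitivity
#' analysis only.
#'
#' @param occurrence an [occurrence_matrix()].
#' @param dist species-level [distance_matrix()].
#' @param pool candidate species ids; default: all species covered by `dist`
#'   that appear in the occurrence matrix.
#' @param R number of replicates (default 1000).
#' @param alternative `"divergence"` (observed > expected) or
#'   `"convergence"` (observed < expected).
#' @param seed optional integer seed for reproducibility.
#' @param replace FALSE (default): distinct species per plot; TRUE: literal
#'   multiset sampling with replacement (see Details).
#' @param outlier_control if TRUE, plots whose observed minus mean-expected
#'   difference lies beyond 1.5 x IQR of those differences are dropped before
#'   the medians are computed (labelled sensitivity variant; default FALSE).
#' @return object of class `nullmodel_result`: observed per-plot means,
#'   R x plots expected matrix, replicate medians, their mean/SD (the O-E
#'   effect size), p, and bookkeeping fields.
#' @export
median_difference_test <- function(occurrence, dist, pool = NULL, R = 1000,
                                   alternative = c("divergence", "convergence"),
                                   seed = NULL, replace = FALSE,
                                   outlier_control = FALSE) {
  alternative <- match.arg(alternative)
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- intersect(colnames(occurrence), rownames(dist))
  if (!length(pool)) stop("empty species pool", call. = FALSE)
  if (length(bad <- setdiff(pool, rownames(dist))))
    stop("pool species missing from distance matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  obs <- mean_within_plot_distance(occurrence, dist)
  plots <- names(obs)
  D <- as.matrix(dist)[pool, pool]
  richness <- rowSums(unclass(occurrence)[plots,
                        intersect(colnames(occurrence), rownames(as.matrix(dist))),
                        drop = FALSE])
  expected <- matrix(NA_real_, R, length(plots),
                     dimnames = list(NULL, plots))
  for (p in plots) {
    n <- richness[[p]]
    idx <- if (replace) {
      matrix(sample.int(length(pool), R * n, replace = TRUE), R, n)
    } else {
      if (n > length(pool))
        stop("richness exceeds pool size; cannot sample without replacement",
             call. = FALSE)
      t(vapply(seq_len(R), function(i) sample.int(length(pool), n),
               integer(n)))
    }
    expected[, p] <- replicate_means(D, idx)
  }
  keep <- plots
  if (outlier_control) {
    diffs <- obs - colMeans(expected)
    qs <- stats::quantile(diffs, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    keep <- plots[diffs >= qs[1] - 1.5 * iqr & diffs <= qs[2] + 1.5 * iqr]
  }
  dmat <- matrix(obs[keep], R, length(keep), byrow = TRUE) -
    expected[, keep, drop = FALSE]
  medians <- apply(dmat, 1L, stats::median)
  k <- if (alternative == "divergence") sum(medians <= 0) else sum(medians >= 0)
  structure(list(
    observed = obs,
    expected = expected,
    medians = medians,
    o_e_mean = mean(medians),
    o_e_sd = stats::sd(medians),
    p = (k + 1) / (R + 1),
    alternative = alternative,
    R = R, seed = seed, replace = replace,
    plots_used = keep,
    plots_excluded = attr(obs, "excluded"),
    outlier_control = outlier_control
  ), class = "nullmodel_result")
}

#' @export
print.nullmodel_result <- function(x, ...) {
  cat(sprintf(
    "nullmodel_result (%s, %s replacement): O-E = %.4g +/- %.4g, p = %.4g (R = %d, %d plots)\n",
    x$alternative, if (x$replace) "with" else "without",
    x$o_e_mean, x$o_e_sd, x$p, x$R, length(x$plots_used)))
  invisible(x)
}

#' Run the within-plot dispersion tests for all trait assemblages
#'
#' The metabolite profiles are tested for divergence (shared-enemy
#' hypothesis) using Jaccard dissimilarity over the shared-filtered binary
#' matrix; each resource-use-trait axis assemblage is tested for convergence
#' (habitat filtering) using Euclidean distance over its z-scored traits.
#'
#' @param bundle an `analysis_bundle`.
#' @param assemblages named list of RUT trait-name vectors, e.g. the output
#'   of [rut_axis_assemblages()]; names become result labels.
#' @param R replicates per test (default 1000).
#' @param seed master seed; per-test seeds are derived from it.
#' @param replace passed to [median_difference_test()].
#' @return list with `results` (named list of `nullmodel_result`) and
#'   `summary` (data.frame: assemblage, alternative, o_e_mean, o_e_sd, p).
#' @export
run_all_trait_tests <- function(bundle, assemblages, R = 1000, seed = NULL,
                                replace = FALSE) {
  seeds <- derive_seeds(seed, length(assemblages) + 1L)
  results <- list()
  occ_sm <- restrict_to_trait_coverage(bundle, "SM")
  d_sm <- jaccard_dissimilarity(filter_shared_columns(bundle$sm))
  results$SM <- suppressWarnings(median_difference_test(
    occ_sm, d_sm, R = R, alternative = "divergence", seed = seeds[[1L]],
    replace = replace))
  rut_z <- zscore(unclass(bundle$rut))
  occ_rut <- restrict_to_trait_coverage(bundle, "RUT")
  for (i in seq_along(assemblages)) {
    nm <- names(assemblages)[i]
    d <- euclidean_distance(rut_z, assemblages[[i]])
    results[[nm]] <- suppressWarnings(median_difference_test(
      occ_rut, d, R = R, alternative = "convergence", seed = seeds[[i + 1L]],
      replace = replace))
  }
  summary <- data.frame(
    assemblage = names(results),
    alternative = vapply(results, `[[`, "", "alternative"),
    o_e_mean = vapply(results, `[[`, 0, "o_e_mean"),
    o_e_sd = vapply(results, `[[`, 0, "o_e_sd"),
    p = vapply(results, `[[`, 0, "p"),
    row.names = NULL
  )
  list(results = results, summary = summary)
}

# Deterministic per-stage seeds below 2^31 derived from one master seed.
#' @noRd
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(as.integer((as.numeric(seed) * 1000003 + 7919 * seq_len(n)) %%
                       2147483629))
}
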