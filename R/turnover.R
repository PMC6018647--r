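# Among-plot functional turnover: TAU_st = 1 - Dw/Da per plot pair, where Dw
# is the mean trait distance between distinct species within the two plots
# (pooled) and Da the mean distance between distinct species across them.
# Positive tau = clustering (species from different plots are more distant
# than plot-mates); negative = overdispersion. Turnover is related to spatial
# and soil distance with Mantel permutation tests.

#' Turnover between one pair of plots
#'
#' @param sp_i,sp_j character vectors of species present in each plot.
#' @param dist species-level [distance_matrix()].
#' @param dw_weighting `"pooled"` (all within-plot pairs of the two plots
#'   weighted equally; default) or `"per_plot"` (each plot's mean weighted
#'   equally).
#' @return list with `tau`, `Dw`, `Da`; all NA when the pair is unusable
#'   (a plot with < 2 covered species, no distinct cross pair, or Da = 0).
#' @export
tau_st_pair <- function(sp_i, sp_j, dist,
                        dw_weighting = c("pooled", "per_plot")) {
  dw_weighting <- match.arg(dw_weighting)
  D <- as.matrix(dist)
  sp_i <- intersect(sp_i, rownames(D))
  sp_j <- intersect(sp_j, rownames(D))
  masked <- list(tau = NA_real_, Dw = NA_real_, Da = NA_real_)
  if (length(sp_i) < 2L || length(sp_j) < 2L) return(masked)
  within <- function(s) {
    m <- D[s, s]
    m[upper.tri(m)]
  }
  wi <- within(sp_i); wj <- within(sp_j)
  Dw <- if (dw_weighting == "pooled") mean(c(wi, wj))
        else mean(c(mean(wi), mean(wj)))
  cross <- D[sp_i, sp_j, drop = FALSE]
  distinct <- outer(sp_i, sp_j, "!=")      # drop conspecific cross pairs
  if (!any(distinct)) return(masked)
  Da <- mean(cross[distinct])
  if (Da == 0) return(masked)
  list(tau = 1 - Dw / Da, Dw = Dw, Da = Da)
}

#' Pairwise TAU_st matrix over all plot pairs
#'
#' @param occurrence an [occurrence_matrix()].
#' @param dist species-level [distance_matrix()].
#' @param dw_weighting see [tau_st_pair()].
#' @return object of class `turnover_result`: `tau` (a `distance_matrix`
#'   with metric `"tau"`, NA-masked diagonal and unusable pairs), `Dw`, `Da`
#'   matrices, and the masked pair count.
#' @export
tau_st_matrix <- function(occurrence, dist,
                          dw_weighting = c("pooled", "per_plot")) {
  dw_weighting <- match.arg(dw_weighting)
  occ <- unclass(occurrence)
  plots <- rownames(occ)
  sp_list <- lapply(plots, function(p) colnames(occ)[occ[p, ] == 1L])
  names(sp_list) <- plots
  n <- length(plots)
  tau <- Dw <- Da <- matrix(NA_real_, n, n, dimnames = list(plots, plots))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    r <- tau_st_pair(sp_list[[i]], sp_list[[j]], dist, dw_weighting)
    tau[i, j] <- tau[j, i] <- r$tau
    Dw[i, j] <- Dw[j, i] <- r$Dw
    Da[i, j] <- Da[j, i] <- r$Da
  }
  masked <- sum(is.na(tau[upper.tri(tau)]))
  if (masked)
    warning(masked, " plot pair(s) masked (unusable for this trait set)",
            call. = FALSE)
  structure(list(tau = distance_matrix(tau, "tau"), Dw = Dw, Da = Da,
                 n_masked_pairs = masked), class = "turnover_result")
}

#' Mantel permutation test between two plot-level distance matrices
#'
#' Pearson correlation of the vectorized upper triangles; significance by
#' simultaneously permuting rows and columns of `m2`. One-tailed in the
#' direction of the observed r: p = (#\{permuted r at least as extreme\} + 1)
#' / (permutations + 1). NA-masked pairs are dropped pairwise-consistently
#' (for each permutation, a pair enters if neither matrix masks it).
#'
#' With `alternative = "observed"` (default) the tail follows the sign of
#' the observed r — the convention used when reporting exploratory
#' correlations, whose null rejection rate at nominal alpha is ~2 alpha.
#' Calibration and hypothesis-driven tests should fix the direction with
#' `"greater"` or `"less"`.
#'
#' @param m1,m2 square matrices with identical plot id sets.
#' @param permutations number of random permutations (default 999).
#' @param seed optional integer seed.
#' @param alternative `"observed"`, `"greater"` or `"less"`.
#' @return list `r`, `p`, `permutations`, `n_pairs`, `seed`.
#' @export
mantel_test <- function(m1, m2, permutations = 999, seed = NULL,
                        alternative = c("observed", "greater", "less")) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!setequal(rownames(m1), rownames(m2)))
    stop("matrices must share plot ids", call. = FALSE)
  m2 <- m2[rownames(m1), rownames(m1)]
  n <- nrow(m1)
  if (n < 4L) stop("need at least 4 plots for a Mantel test", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(m1)
  pair_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  v1 <- m1[ut]
  r_obs <- pair_cor(v1, m2[ut])
  if (is.na(r_obs)) stop("too few unmasked pairs", call. = FALSE)
  r_perm <- vapply(seq_len(permutations), function(i) {
    pm <- sample.int(n)
    pair_cor(v1, m2[pm, pm][ut])
  }, numeric(1))
  dir_up <- switch(alternative, observed = r_obs >= 0,
                   greater = TRUE, less = FALSE)
  k <- if (dir_up) sum(r_perm >= r_obs, na.rm = TRUE)
       else sum(r_perm <= r_obs, na.rm = TRUE)
  list(r = r_obs, p = (k + 1) / (permutations + 1),
       permutations = permutations, n_pairs = sum(!is.na(v1)), seed = seed)
}

#' Turnover suite: TAU_st of each trait assemblage vs spatial and soil
#' distance
#'
#' Builds the TAU_st matrix for the metabolite profiles (Jaccard) and for
#' each resource-use-trait axis assemblage (Euclidean over z-scored traits),
#' then Mantel-tests each against log spatial distance and soil distance —
#' the latter both plain and residualized on log spatial distance.
#'
#' @param bundle an `analysis_bundle`.
#' @param assemblages named list of RUT trait-name vectors.
#' @param soil_vars soil variables defining soil distance (e.g. those
#'   significantly correlated with soil PCA axis 1; see
#'   [select_soil_variables()]).
#' @param permutations Mantel permutations (default 999).
#' @param seed master seed; per-test seeds derived from it.
#' @param dw_weighting see [tau_st_pair()].
#' @return list with `tau` (named list of `turnover_result`) and `summary`
#'   (data.frame: assemblage, predictor, r, p).
#' @export
run_turnover_suite <- function(bundle, assemblages, soil_vars,
                               permutations = 999, seed = NULL,
                               dw_weighting = "pooled") {
  spat <- spatial_distance(bundle$env$coords, log_transform = TRUE)
  soil <- soil_distance(bundle$env, soil_vars)
  soil_res <- soil_distance(bundle$env, soil_vars, residualize_on = spat)
  sets <- c(list(SM = NULL), assemblages)
  seeds <- derive_seeds(seed, 3L * length(sets))
  rut_z <- if (nrow(bundle$rut)) zscore(unclass(bundle$rut)) else NULL
  tau_list <- list()
  rows <- list()
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    if (nm == "SM") {
      d <- jaccard_dissimilarity(filter_shared_columns(bundle$sm))
      occ <- restrict_to_trait_coverage(bundle, "SM")
    } else {
      d <- euclidean_distance(rut_z, sets[[i]])
      occ <- restrict_to_trait_coverage(bundle, "RUT")
    }
    tr <- suppressWarnings(tau_st_matrix(occ, d, dw_weighting))
    tau_list[[nm]] <- tr
    preds <- list(spatial = spat, soil = soil, soil_residual = soil_res)
    for (k in seq_along(preds)) {
      mt <- mantel_test(tr$tau, preds[[k]], permutations,
                        seed = seeds[[3L * (i - 1L) + k]])
      rows[[length(rows) + 1L]] <- data.frame(
        assemblage = nm, predictor = names(preds)[k],
        r = mt$r, p = mt$p, n_pairs = mt$n_pairs)
    }
  }
  list(tau = tau_list, summary = do.call(rbind, rows))
}
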