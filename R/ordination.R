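# Standardization, collinearity screening and correlation-matrix PCA with
# broken-stick axis retention. Sample (n-1) standard deviations throughout.

#' Column-wise z-scoring
#'
#' @param x numeric matrix.
#' @return matrix with each column centered to mean 0 and scaled to sample
#'   standard deviation 1.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  sdv <- apply(x, 2L, stats::sd)
  if (any(sdv == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sdv == 0], collapse = ", "), call. = FALSE)
  scale(x, center = TRUE, scale = sdv)[, , drop = FALSE]
}

#' Variance inflation factor of one variable against a set of peers
#' @noRd
vif_one <- function(x, j) {
  fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
  ssr <- sum(fit$residuals^2)
  sst <- sum((x[, j] - mean(x[, j]))^2)
  r2 <- 1 - ssr / sst
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' Iterative VIF-based collinearity elimination
#'
#' Repeatedly removes the single variable with the largest variance inflation
#' factor (VIF_j = 1 / (1 - R^2_j), variable j regressed on all other
#' retained variables) while that VIF exceeds `threshold`. Perfectly collinear
#' variables have infinite VIF and go first. Ties are broken by removing the
#' lexicographically smallest variable id, so the result does not depend on
#' input column order.
#'
#' @param x numeric matrix (observations x variables), >= 2 variables.
#' @param threshold VIF above which a variable is eliminated (default 10).
#' @return list with `retained` (ids, input order), `removed` (ids, removal
#'   order) and `log` (data.frame: step, candidate VIFs at that step, removed
#'   variable).
#' @export
vif_eliminate <- function(x, threshold = 10) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 variables", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  keep <- colnames(x)
  removed <- character(0)
  log <- list()
  step <- 0L
  repeat {
    if (length(keep) < 2L) break
    m <- x[, keep, drop = FALSE]
    if (nrow(m) <= length(keep))
      stop("fewer observations than retained variables; VIF undefined",
           call. = FALSE)
    v <- vapply(seq_along(keep), function(j) vif_one(m, j), numeric(1))
    names(v) <- keep
    step <- step + 1L
    if (max(v) <= threshold) {
      log[[step]] <- data.frame(step = step, variable = keep, vif = unname(v),
                                removed = FALSE)
      break
    }
    worst <- sort(keep[v == max(v)])[1L]  # lexicographic tie-break
    log[[step]] <- data.frame(step = step, variable = keep, vif = unname(v),
                              removed = keep == worst)
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  list(retained = keep, removed = removed, log = do.call(rbind, log))
}

#' Broken-stick expected eigenvalue proportions
#'
#' `b_k = (1/p) * sum_{i=k..p} 1/i`, the expected fraction of total variance
#' on the k-th largest piece when a stick is broken into p random pieces.
#'
#' @param p number of components (>= 1).
#' @return numeric vector of length `p`, strictly decreasing, summing to 1.
#' @export
broken_stick <- function(p) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("p must be a positive integer", call. = FALSE)
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' PCA on the correlation matrix with broken-stick retention
#'
#' Eigendecomposition of the correlation matrix of `x` (z-scored internally
#' unless `standardize = FALSE`, in which case `x` must already be
#' standardized). Total inertia equals the number of variables. Axes whose
#' variance proportion strictly exceeds the broken-stick expectation are
#' retained. Eigenvector signs are fixed so the loading of largest absolute
#' value on each axis is positive, making results reproducible.
#'
#' @param x numeric matrix (observations x variables), >= 3 rows.
#' @param standardize z-score columns before the decomposition (default TRUE).
#' @return object of class `pca_result`: `eigenvalues`,
#'   `variance_proportions`, `scores`, `loadings` (eigenvectors),
#'   `broken_stick`, `retained` (logical mask).
#' @export
pca_correlation <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("degenerate ordination: fewer than 3 rows",
                         call. = FALSE)
  if (ncol(x) < 2L) stop("need at least 2 variables", call. = FALSE)
  z <- if (standardize) zscore(x) else x
  ev <- eigen(stats::cor(z), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors
  for (k in seq_len(ncol(vecs))) {            # sign convention
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  rownames(vecs) <- colnames(x)
  colnames(vecs) <- paste0("axis", seq_len(ncol(vecs)))
  scores <- z %*% vecs
  rownames(scores) <- rownames(x)
  prop <- vals / ncol(x)
  bs <- broken_stick(ncol(x))
  structure(list(
    eigenvalues = vals,
    variance_proportions = prop,
    scores = scores,
    loadings = vecs,
    broken_stick = bs,
    retained = prop > bs
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- sum(x$retained)
  cat(sprintf("pca_result: %d axes, %d retained above broken stick\n",
              length(x$eigenvalues), k))
  cat("variance %:", paste0(sprintf("%.1f", 100 * x$variance_proportions),
                            ifelse(x$retained, "*", "")), "\n")
  invisible(x)
}

#' Pearson correlations between variables and PCA axis scores
#'
#' Two-sided p-values from the t distribution on n - 2 degrees of freedom.
#' Significance is flagged at `alpha`, uncorrected for multiple tests.
#'
#' @param pca a [pca_correlation()] result.
#' @param x variable matrix, rows aligned with `pca$scores`.
#' @param alpha significance level (default 0.05).
#' @param axes axis indices to test (default: retained axes).
#' @return data.frame with columns variable, axis, r, p, significant.
#' @export
axis_variable_correlations <- function(pca, x, alpha = 0.05,
                                       axes = which(pca$retained)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (n != nrow(pca$scores)) stop("rows of x must align with PCA scores",
                                  call. = FALSE)
  out <- expand.grid(variable = colnames(x), axis = axes,
                     stringsAsFactors = FALSE)
  rp <- mapply(function(v, k) {
    r <- stats::cor(x[, v], pca$scores[, k])
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r = r, p = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE))
  }, out$variable, out$axis)
  out$r <- rp["r", ]
  out$p <- rp["p", ]
  out$significant <- out$p <= alpha
  out
}

#' Trait assemblage significantly correlated with one PCA axis
#'
#' @param tab an [axis_variable_correlations()] table.
#' @param axis axis index.
#' @return character vector of variable ids flagged significant on that axis.
#' @export
select_trait_assemblage <- function(tab, axis) {
  sel <- tab$variable[tab$axis == axis & tab$significant]
  if (!length(sel))
    stop("no variable significantly correlated with axis ", axis,
         "; axis unusable for distance computation", call. = FALSE)
  sel
}
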