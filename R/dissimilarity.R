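# Distance structures: species-level Jaccard (binary metabolite profiles) and
# Euclidean (z-scored trait subsets); plot-level haversine spatial and
# Euclidean soil distances, with optional residualization of soil distance on
# log spatial distance.

#' Distance matrix container
#'
#' Square symmetric nonnegative matrix with zero diagonal and a metric tag.
#' Residualized soil distances are exempt from nonnegativity (OLS residuals
#' may be negative); they carry the tag `"soil_residual"`.
#'
#' @param m square numeric matrix with matching row/column names.
#' @param metric one of `"jaccard"`, `"euclidean"`, `"log_km"`, `"km"`,
#'   `"soil"`, `"soil_residual"`, `"tau"`.
#' @return a `distance_matrix`.
#' @export
distance_matrix <- function(m, metric) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop("distance matrix must be square with matching dimnames",
         call. = FALSE)
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12)
    stop("distance matrix not symmetric", call. = FALSE)
  if (any(diag(m) != 0, na.rm = TRUE))
    stop("distance matrix diagonal must be 0", call. = FALSE)
  # residuals and log-km (pairs closer than 1 km) may be legitimately negative
  if (!metric %in% c("soil_residual", "tau", "log_km") &&
      any(m < 0, na.rm = TRUE))
    stop("negative distances", call. = FALSE)
  if (metric == "jaccard" && any(m > 1 + 1e-12, na.rm = TRUE))
    stop("Jaccard dissimilarities must lie in [0, 1]", call. = FALSE)
  attr(m, "metric") <- metric
  class(m) <- c("distance_matrix", class(m))
  m
}

#' Drop metabolites not shared by at least `min_species` species
#'
#' Shared compounds are the common currency of species that share natural
#' enemies; singletons only add noise to between-species dissimilarity.
#'
#' @param sm a [binary_trait_matrix()].
#' @param min_species minimum column sum to retain a metabolite (default 2).
#' @return filtered `binary_trait_matrix`.
#' @export
filter_shared_columns <- function(sm, min_species = 2) {
  keep <- colSums(sm) >= min_species
  binary_trait_matrix(unclass(sm)[, keep, drop = FALSE])
}

#' Jaccard dissimilarity between binary profiles
#'
#' `d(a, b) = 1 - |A intersect B| / |A union B|` over the metabolite sets of
#' each species pair.
#'
#' @param sm a [binary_trait_matrix()]; every row must have at least one
#'   present metabolite.
#' @return species-by-species `distance_matrix` (metric `"jaccard"`).
#' @export
jaccard_dissimilarity <- function(sm) {
  m <- unclass(sm)
  if (any(rowSums(m) == 0))
    stop("all-zero profile(s), Jaccard undefined: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  inter <- tcrossprod(m)
  uni <- outer(rowSums(m), rowSums(m), "+") - inter
  d <- (uni - inter) / uni   # = 1 - |A^B|/|AuB|, exact for small rationals
  diag(d) <- 0
  distance_matrix(d, "jaccard")
}

#' Euclidean distance over a z-scored trait subset
#'
#' Distances are computed on the raw standardized trait columns named in
#' `trait_subset` (not on PCA scores).
#'
#' @param rut a standardized [continuous_trait_matrix()] (or any numeric
#'   matrix with z-scored columns).
#' @param trait_subset trait column names to use (default: all).
#' @return species-by-species `distance_matrix` (metric `"euclidean"`).
#' @export
euclidean_distance <- function(rut, trait_subset = colnames(rut)) {
  if (!length(trait_subset)) stop("empty trait subset", call. = FALSE)
  missing <- setdiff(trait_subset, colnames(rut))
  if (length(missing))
    stop("trait(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- unclass(rut)[, trait_subset, drop = FALSE]
  d <- as.matrix(stats::dist(m))
  distance_matrix(d, "euclidean")
}

#' Great-circle distance between plots
#'
#' Haversine distance on a sphere of radius 6371 km; with
#' `log_transform = TRUE` the natural log is applied to off-diagonal entries
#' (the diagonal stays 0).
#'
#' @param coords data.frame with `longitude` and `latitude` in decimal
#'   degrees, row names = plot ids.
#' @param log_transform apply natural log off-diagonal (default TRUE).
#' @return plot-by-plot `distance_matrix` (metric `"log_km"` or `"km"`).
#' @export
spatial_distance <- function(coords, log_transform = TRUE) {
  lon <- coords$longitude * pi / 180
  lat <- coords$latitude * pi / 180
  n <- length(lon)
  dlat <- outer(lat, lat, "-") / 2
  dlon <- outer(lon, lon, "-") / 2
  a <- sin(dlat)^2 + outer(cos(lat), cos(lat)) * sin(dlon)^2
  d <- 2 * 6371 * asin(pmin(sqrt(a), 1))
  dimnames(d) <- list(rownames(coords), rownames(coords))
  diag(d) <- 0
  if (log_transform) {
    off <- upper.tri(d) | lower.tri(d)
    if (any(d[off] <= 0))
      stop("coincident plots: log spatial distance undefined", call. = FALSE)
    d[off] <- log(d[off])
    return(distance_matrix(d, "log_km"))
  }
  distance_matrix(d, "km")
}

#' Euclidean soil distance, optionally residualized on spatial distance
#'
#' The selected soil variables are re-z-scored within the subset, then plot
#' pairs get their Euclidean distance. When `residualize_on` is supplied
#' (typically the log spatial distance matrix), each off-diagonal entry is
#' replaced by the residual of the ordinary-least-squares fit of soil
#' distance on the companion distance, computed over the vectorized upper
#' triangle — removing the spatial trend from the soil-distance signal.
#'
#' @param env an [environment_table()].
#' @param variable_subset soil variable names (default: all).
#' @param residualize_on optional companion `distance_matrix` over the same
#'   plots.
#' @return plot-by-plot `distance_matrix` (metric `"soil"` or
#'   `"soil_residual"`).
#' @export
soil_distance <- function(env, variable_subset = colnames(env$soil),
                          residualize_on = NULL) {
  missing <- setdiff(variable_subset, colnames(env$soil))
  if (length(missing))
    stop("soil variable(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  z <- zscore(env$soil[, variable_subset, drop = FALSE])
  d <- as.matrix(stats::dist(z))
  if (is.null(residualize_on)) return(distance_matrix(d, "soil"))
  comp <- as.matrix(residualize_on)
  if (!identical(rownames(comp), rownames(d)))
    stop("companion distance matrix plots do not match", call. = FALSE)
  ut <- upper.tri(d)
  fit <- stats::lm(d[ut] ~ comp[ut])
  r <- d
  r[ut] <- stats::residuals(fit)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- 0
  distance_matrix(r, "soil_residual")
}
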