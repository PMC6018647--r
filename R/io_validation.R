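# ---- constructors -----------------------------------------------------------

check_ids <- function(ids, what) {
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(what, " identifiers contain missing/empty entries", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  ids
}

check_binary_cells <- function(m, what) {
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("non-binary cell in %s at row '%s', column '%s' (value %s)",
                 what, rownames(m)[i[1]], colnames(m)[i[2]],
                 format(m[bad[1L]])), call. = FALSE)
  }
  invisible(m)
}

#' Plot-by-species occurrence matrix
#'
#' Presence/absence community table: rows are plots, columns species, cells
#' in \{0, 1\}. Plots with fewer than two occurring species are flagged in the
#' `"flagged_plots"` attribute (kept, not dropped), because within-plot
#' dispersion tests need at least one species pair.
#'
#' @param m numeric matrix with plot row names and species column names.
#' @return an `occurrence_matrix` (a binary matrix with attributes).
#' @export
occurrence_matrix <- function(m) {
  m <- as.matrix(m)
  rownames(m) <- check_ids(rownames(m), "plot")
  colnames(m) <- check_ids(colnames(m), "species")
  check_binary_cells(m, "occurrence matrix")
  storage.mode(m) <- "integer"
  attr(m, "flagged_plots") <- rownames(m)[rowSums(m) < 2L]
  class(m) <- c("occurrence_matrix", class(m))
  m
}

#' Species-by-trait binary matrix (secondary-metabolite profiles)
#'
#' @param m numeric 0/1 matrix, rows = species, columns = metabolite codes.
#' @return a `binary_trait_matrix`.
#' @export
binary_trait_matrix <- function(m) {
  m <- as.matrix(m)
  rownames(m) <- check_ids(rownames(m), "species")
  colnames(m) <- check_ids(colnames(m), "trait")
  check_binary_cells(m, "binary trait matrix")
  storage.mode(m) <- "integer"
  class(m) <- c("binary_trait_matrix", class(m))
  m
}

#' Species-by-trait continuous matrix (resource-use traits)
#'
#' Rows with any missing value are rejected: species without complete trait
#' coverage must be excluded upstream rather than imputed.
#'
#' @param m numeric matrix, rows = species, columns = trait names.
#' @param standardized logical; assert that columns are z-scored
#'   (mean 0, sample SD 1, tolerance 1e-9).
#' @return a `continuous_trait_matrix` with a `"standardized"` attribute.
#' @export
continuous_trait_matrix <- function(m, standardized = FALSE) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  rownames(m) <- check_ids(rownames(m), "species")
  colnames(m) <- check_ids(colnames(m), "trait")
  if (anyNA(m)) {
    bad <- rownames(m)[apply(m, 1L, anyNA)]
    stop("missing continuous trait value(s) for species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (standardized) {
    mu <- colMeans(m); sdv <- apply(m, 2L, stats::sd)
    if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9))
      stop("matrix declared standardized but columns are not z-scored",
           call. = FALSE)
  }
  attr(m, "standardized") <- standardized
  class(m) <- c("continuous_trait_matrix", class(m))
  m
}

#' Plot-level environment table with coordinates
#'
#' @param soil numeric matrix of soil variables, rows = plots.
#' @param coords data.frame/matrix with columns `longitude`, `latitude`
#'   (decimal degrees), one row per plot, same order as `soil`.
#' @return an `environment_table`: list with elements `soil` and `coords`.
#' @export
environment_table <- function(soil, coords) {
  soil <- as.matrix(soil)
  storage.mode(soil) <- "double"
  rownames(soil) <- check_ids(rownames(soil), "plot")
  colnames(soil) <- check_ids(colnames(soil), "soil variable")
  coords <- as.data.frame(coords)
  if (!all(c("longitude", "latitude") %in% names(coords)))
    stop("coords must have columns 'longitude' and 'latitude'", call. = FALSE)
  if (nrow(coords) != nrow(soil))
    stop("one coordinate row per plot required", call. = FALSE)
  rownames(coords) <- rownames(soil)
  if (any(coords$longitude < -180 | coords$longitude > 180) ||
      any(coords$latitude < -90 | coords$latitude > 90))
    stop("coordinates outside valid decimal-degree ranges", call. = FALSE)
  tex <- intersect(c("sand", "silt", "clay"), colnames(soil))
  if (length(tex)) {
    v <- soil[, tex, drop = FALSE]
    if (any(v < 0 | v > 100))
      stop("texture percentages must lie in [0, 100]", call. = FALSE)
  }
  structure(list(soil = soil, coords = coords), class = "environment_table")
}

# ---- bundle -----------------------------------------------------------------

#' Assemble and cross-validate the analysis bundle
#'
#' Aligns the four tables on shared plot and species identifiers and checks
#' the containment invariants: every trait-table species must occur in the
#' occurrence matrix, and the environment table must cover exactly the
#' occurrence plots.
#'
#' @param occurrence an [occurrence_matrix()].
#' @param sm a [binary_trait_matrix()] of metabolite profiles.
#' @param rut a [continuous_trait_matrix()] of resource-use traits.
#' @param env an [environment_table()].
#' @return an `analysis_bundle` list with the four components and a
#'   `coverage` report (see [coverage_report()]).
#' @export
analysis_bundle <- function(occurrence, sm, rut, env) {
  sp <- colnames(occurrence)
  extra_sm <- setdiff(rownames(sm), sp)
  if (length(extra_sm))
    stop("SM table species absent from occurrence matrix: ",
         paste(extra_sm, collapse = ", "), call. = FALSE)
  extra_rut <- setdiff(rownames(rut), sp)
  if (length(extra_rut))
    stop("RUT table species absent from occurrence matrix: ",
         paste(extra_rut, collapse = ", "), call. = FALSE)
  if (!setequal(rownames(env$soil), rownames(occurrence)))
    stop("environment table plots must equal occurrence plots", call. = FALSE)
  env$soil <- env$soil[rownames(occurrence), , drop = FALSE]
  env$coords <- env$coords[rownames(occurrence), , drop = FALSE]
  b <- structure(list(occurrence = occurrence, sm = sm, rut = rut, env = env),
                 class = "analysis_bundle")
  b$coverage <- coverage_report(b)
  b
}

#' Species/plot coverage report for a bundle
#'
#' @param bundle an `analysis_bundle` (the `coverage` element is ignored).
#' @return list of counts and identifier sets: species totals per trait set,
#'   the dual-covered set, and plots usable (>= 2 covered species) per trait
#'   set.
#' @export
coverage_report <- function(bundle) {
  occ <- bundle$occurrence
  sp <- colnames(occ)
  sm_sp <- intersect(sp, rownames(bundle$sm))
  rut_sp <- intersect(sp, rownames(bundle$rut))
  both <- intersect(sm_sp, rut_sp)
  plots_ok <- function(keep) {
    n <- rowSums(occ[, keep, drop = FALSE])
    rownames(occ)[n >= 2L]
  }
  list(
    n_plots = nrow(occ), n_species = length(sp),
    n_sm_species = length(sm_sp), n_rut_species = length(rut_sp),
    n_both = length(both),
    sm_species = sm_sp, rut_species = rut_sp, both_species = both,
    plots_sm = plots_ok(sm_sp), plots_rut = plots_ok(rut_sp),
    plots_both = plots_ok(both)
  )
}

#' Read a delimited table as a row-identified numeric matrix
#' @noRd
read_id_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Load and validate an analysis bundle from four CSV files
#'
#' Each file is UTF-8 CSV with a header row of column identifiers and the
#' first column holding row identifiers. The environment file must contain
#' `longitude` and `latitude` columns beside the soil variables.
#'
#' @param occurrence_path,sm_path,rut_path,env_path file paths.
#' @return a validated `analysis_bundle`.
#' @export
load_bundle <- function(occurrence_path, sm_path, rut_path, env_path) {
  occ <- occurrence_matrix(read_id_matrix(occurrence_path))
  sm <- binary_trait_matrix(read_id_matrix(sm_path))
  rutm <- read_id_matrix(rut_path)
  rut <- continuous_trait_matrix(rutm[stats::complete.cases(rutm), , drop = FALSE])
  envm <- read_id_matrix(env_path)
  cc <- c("longitude", "latitude")
  if (!all(cc %in% colnames(envm)))
    stop("environment file must contain 'longitude' and 'latitude' columns",
         call. = FALSE)
  env <- environment_table(envm[, setdiff(colnames(envm), cc), drop = FALSE],
                           as.data.frame(envm[, cc, drop = FALSE]))
  analysis_bundle(occ, sm, rut, env)
}

#' Write an analysis bundle back to CSV files
#'
#' Inverse of [load_bundle()]: writes `occurrence.csv`, `sm.csv`, `rut.csv`
#' and `env.csv` (soil variables plus longitude/latitude) under `dir`.
#'
#' @param bundle an `analysis_bundle`.
#' @param dir output directory, created if needed.
#' @return invisibly, the four file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, file, id_name) {
    df <- data.frame(rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE)
    names(df)[1L] <- id_name
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    file.path(dir, file)
  }
  envm <- cbind(bundle$env$soil,
                longitude = bundle$env$coords$longitude,
                latitude = bundle$env$coords$latitude)
  invisible(c(
    wr(bundle$occurrence, "occurrence.csv", "plot"),
    wr(bundle$sm, "sm.csv", "species"),
    wr(bundle$rut, "rut.csv", "species"),
    wr(envm, "env.csv", "plot")
  ))
}

#' Restrict the occurrence matrix to species covered by a trait set
#'
#' @param bundle an `analysis_bundle`.
#' @param trait_set `"SM"`, `"RUT"`, or a character vector of species ids
#'   (e.g. a RUT axis assemblage's covered species).
#' @return an [occurrence_matrix()] over the covered species; plots left with
#'   fewer than two species are flagged (attribute `"flagged_plots"`), not
#'   dropped.
#' @export
restrict_to_trait_coverage <- function(bundle, trait_set = c("SM", "RUT")) {
  sp <- if (is.character(trait_set) && length(trait_set) == 1L &&
            trait_set %in% c("SM", "RUT")) {
    if (trait_set == "SM") bundle$coverage$sm_species
    else bundle$coverage$rut_species
  } else {
    missing <- setdiff(trait_set, colnames(bundle$occurrence))
    if (length(missing))
      stop("unknown species in trait_set: ", paste(missing, collapse = ", "),
           call. = FALSE)
    trait_set
  }
  out <- occurrence_matrix(bundle$occurrence[, sp, drop = FALSE])
  usable <- setdiff(rownames(out), attr(out, "flagged_plots"))
  if (length(usable) < 2L)
    stop("restriction leaves fewer than 2 usable plots", call. = FALSE)
  out
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cv <- x$coverage
  cat(sprintf(
    "analysis_bundle: %d plots x %d species\n  SM: %d species (%d metabolites), %d usable plots\n  RUT: %d species (%d traits), %d usable plots\n  both trait sets: %d species, present in %d plots\n",
    cv$n_plots, cv$n_species, cv$n_sm_species, ncol(x$sm),
    length(cv$plots_sm), cv$n_rut_species, ncol(x$rut),
    length(cv$plots_rut), cv$n_both, length(cv$plots_both)))
  invisible(x)
}
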