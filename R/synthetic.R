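# Synthetic community-assembly generator with known ground truth. The world
# it emulates: plots in distinct river basins spanning ~0.5-200 km, a bimodal
# edaphic gradient (nutrient-poor white sand vs clay terra firme), soil
# variables that are affine responses to the latent habitat score (with a
# built-in collinear texture triple summing to 100), species with niche
# optima on the habitat axis, continuous resource-use traits partly aligned
# with those optima (habitat filtering has something to act on), and binary
# metabolite profiles whose per-column occupancy guarantees every metabolite
# is shared by >= 2 species. Assembly combines Gaussian habitat filtering
# (sigma_filt) and an exponential reward on mean chemical dissimilarity to
# residents (lambda_div); sigma_filt = Inf and lambda_div = 0 gives neutral
# assembly, the null world used for type-I calibration.

#' Configuration for the synthetic community generator
#'
#' Defaults mirror the emulated study design: 19 plots (9 white-sand,
#' 10 clay terra firme) in 3 basins spanning 0.5-200 km, 29 species,
#' 189 metabolites averaging ~31.4 per species, 14 continuous traits,
#' 9 soil variables, partial trait coverage (27/29 species with metabolite
#' data, 16/29 with trait data). Effect strengths default to the moderate
#' grid point of [effect_grid()].
#'
#' @param n_plots,n_species,n_metabolites,n_traits,n_soil_vars design sizes.
#' @param n_basins number of spatial clusters.
#' @param n_white_sand plots assigned to the white-sand habitat class; the
#'   rest are clay terra firme.
#' @param extent_km c(min separation, overall extent) in km.
#' @param mean_richness target mean species per plot (Poisson, floored at 2).
#' @param sigma_filt SD of the Gaussian trait-environment match; `Inf`
#'   disables habitat filtering.
#' @param lambda_div strength (>= 0) of the limiting-similarity reward on
#'   mean Jaccard dissimilarity to residents; 0 disables it.
#' @param mean_metabolites_per_species calibration target for mean profile
#'   size.
#' @param sm_sharing in \[0, 1\]; 1 forces identical (all-present) profiles.
#' @param n_chemotypes number of latent chemical syndromes; metabolites are
#'   enriched in their preferred chemotype so within-chemotype profiles are
#'   more similar than between — the similarity variance limiting
#'   similarity needs to act on.
#' @param chemotype_strength enrichment strength in \[0, 1\): 0 removes the
#'   chemotype structure (independent profiles).
#' @param sm_coverage,rut_coverage fraction of species with metabolite /
#'   trait data.
#' @param soil_noise SD of soil-variable noise around the habitat response.
#' @param trait_signal correlation strength between habitat-linked traits
#'   and the species niche optimum.
#' @param seed integer seed consumed by [generate_dataset()].
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_plots = 19, n_species = 29,
                             n_metabolites = 189, n_traits = 14,
                             n_soil_vars = 9, n_basins = 3,
                             n_white_sand = 9,
                             extent_km = c(0.5, 200), mean_richness = 7,
                             sigma_filt = 0.5, lambda_div = 4,
                             mean_metabolites_per_species = 31.4,
                             sm_sharing = 0,
                             n_chemotypes = 3, chemotype_strength = 0.8,
                             sm_coverage = 27 / 29, rut_coverage = 16 / 29,
                             soil_noise = 0.6, trait_signal = 0.7,
                             seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_plots >= 4, n_species >= 3, n_metabolites >= 2, n_traits >= 2,
            n_soil_vars == 9, n_basins >= 1, n_white_sand < n_plots,
            mean_richness >= 2, lambda_div >= 0, sigma_filt > 0,
            sm_sharing >= 0, sm_sharing <= 1,
            n_chemotypes >= 1, chemotype_strength >= 0,
            chemotype_strength < 1,
            sm_coverage > 0, sm_coverage <= 1,
            rut_coverage > 0, rut_coverage <= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Three-point effect-strength grid
#'
#' Fixed a priori: `neutral` (no filtering, no divergence), `moderate`
#' (the generator default) and `strong`. Used by the calibration and power
#' tests and by monotonicity checks.
#'
#' @return data.frame with columns level, sigma_filt, lambda_div.
#' @export
effect_grid <- function() {
  data.frame(level = c("neutral", "moderate", "strong"),
             sigma_filt = c(Inf, 0.5, 0.25),
             lambda_div = c(0, 4, 20))
}

#' Generate plot coordinates and soil table
#'
#' Plots sit in `n_basins` spatial clusters laid out along a ~`extent_km[2]`
#' km transect near the equator; within-cluster jitter keeps any two plots
#' at least `extent_km[1]` km apart and well below the between-cluster
#' distance. Habitat classes (white sand h = -1, clay h = +1, small jitter)
#' alternate across basins. The nine soil variables are affine in the
#' latent habitat score plus Gaussian noise; sand/silt/clay sum to 100 and
#' Mg tracks Ca, so the collinearity screen has work to do.
#'
#' @param config a [synthetic_config()].
#' @return list: `env` (an [environment_table()]), `habitat` (latent score
#'   per plot), `class` (habitat class labels).
#' @export
generate_environment <- function(config) {
  n <- config$n_plots
  plots <- sprintf("plot%02d", seq_len(n))
  basin <- rep(seq_len(config$n_basins), length.out = n)
  lat0 <- -4; lon0 <- -73
  km_lon <- 111.32 * cos(lat0 * pi / 180)
  centers_km <- seq(0, config$extent_km[2] * 0.95, length.out =
                      max(config$n_basins, 2))[seq_len(config$n_basins)]
  repeat {
    lon <- lon0 + (centers_km[basin] + stats::runif(n, -4, 4)) / km_lon
    lat <- lat0 + stats::runif(n, -4, 4) / 110.57
    coords <- data.frame(longitude = lon, latitude = lat, row.names = plots)
    d <- spatial_distance(coords, log_transform = FALSE)
    if (min(d[upper.tri(d)]) >= config$extent_km[1]) break
  }
  # both habitat classes occur in every basin (plot index cycles over
  # basins), so soil and space are only partially confounded
  cls <- rep("clay", n)
  white <- seq(1L, n, by = 2L)
  if (length(white) < config$n_white_sand)
    white <- c(white, setdiff(seq_len(n), white))
  cls[white[seq_len(config$n_white_sand)]] <- "white_sand"
  h <- ifelse(cls == "white_sand", -1, 1) + stats::rnorm(n, 0, 0.1)
  # noise scales with each variable's habitat response so that, once the
  # built-in collinear structures (texture simplex, Mg tracking Ca) are
  # eliminated, the survivors sit below the VIF threshold
  ns <- config$soil_noise
  rsp <- function(base, slope) base + slope * h +
    stats::rnorm(n, 0, ns * abs(slope) + 1e-3)
  sand <- pmin(95, pmax(5, rsp(60, -25)))
  clay <- pmin(90, pmax(2, rsp(20, 15)))
  silt <- pmax(2, 100 - sand - clay)
  tot <- (sand + clay + silt) / 100      # renormalize onto the simplex
  sand <- sand / tot; clay <- clay / tot; silt <- silt / tot
  Ca <- rsp(5, 2.0)
  Mg <- 0.5 * Ca + stats::rnorm(n, 0, 0.2 * ns + 1e-3)
  K <- rsp(2, 0.8)
  CN <- rsp(14, -2.5)
  P <- rsp(6, 2.2)
  NO3 <- rsp(8, 3.0)
  soil <- cbind(sand = sand, silt = silt, clay = clay, Ca = Ca, Mg = Mg,
                K = K, CN = CN, P = P, NO3 = NO3)
  rownames(soil) <- plots
  list(env = environment_table(soil, coords), habitat = stats::setNames(h, plots),
       class = stats::setNames(cls, plots))
}

#' Generate the species pool: niche optima, traits and metabolite profiles
#'
#' Niche optima are uniform on the habitat axis. Half of the continuous
#' traits track the optimum (signal `trait_signal`), a second block tracks
#' an independent latent axis, the rest are noise — giving the trait PCA a
#' dominant habitat-linked axis. Metabolite columns get occupancy
#' probabilities calibrated so the mean profile size matches
#' `mean_metabolites_per_species`; each column is resampled until present
#' in >= 2 species, and every species keeps a nonempty profile.
#'
#' @param config a [synthetic_config()].
#' @return list: `sm` ([binary_trait_matrix()], all species), `rut`
#'   ([continuous_trait_matrix()], all species), `optima` (named vector).
#' @export
generate_species_pool <- function(config) {
  ns <- config$n_species
  species <- sprintf("sp%02d", seq_len(ns))
  mu <- stats::setNames(stats::runif(ns, -1, 1), species)
  nt <- config$n_traits
  b <- config$trait_signal
  u <- stats::rnorm(ns)
  n1 <- ceiling(nt / 2); n2 <- floor(nt / 4)
  traits <- sapply(seq_len(nt), function(t) {
    if (t <= n1) b * mu + sqrt(1 - b^2) * stats::rnorm(ns)
    else if (t <= n1 + n2) b * u + sqrt(1 - b^2) * stats::rnorm(ns)
    else stats::rnorm(ns)
  })
  dimnames(traits) <- list(species, sprintf("trait%02d", seq_len(nt)))
  s <- config$sm_sharing
  target <- config$mean_metabolites_per_species / config$n_metabolites
  q_raw <- stats::rbeta(config$n_metabolites, 2, 10)  # mean 1/6
  scale <- max(0, (target - s)) / ((1 - s) * (1 / 6) + 1e-12)
  q <- pmin(1, s + (1 - s) * q_raw * scale)
  # latent chemical syndromes: each metabolite is enriched in one preferred
  # chemotype and depleted elsewhere, with the multipliers balanced so the
  # mean occupancy stays q; this creates within- vs between-chemotype
  # Jaccard contrast for the divergence mechanism to act on
  K <- config$n_chemotypes
  a <- config$chemotype_strength
  chemotype <- stats::setNames(rep(seq_len(K), length.out = ns)[sample.int(ns)],
                               species)
  met_pref <- sample.int(K, config$n_metabolites, replace = TRUE)
  mult_match <- 1 + a * (K - 1)
  mult_miss <- 1 - a
  sm <- sapply(seq_along(q), function(m) {
    pm <- q[m] * ifelse(chemotype == met_pref[m], mult_match, mult_miss)
    pm <- pmin(pm, 1)
    repeat {
      col <- stats::rbinom(ns, 1L, pm)
      if (sum(col) >= 2L) return(col)
    }
  })
  dimnames(sm) <- list(species, sprintf("met%03d", seq_len(config$n_metabolites)))
  for (i in which(rowSums(sm) == 0))   # keep Jaccard defined everywhere
    sm[i, sample.int(ncol(sm), 2L)] <- 1L
  list(sm = binary_trait_matrix(sm),
       rut = continuous_trait_matrix(traits),
       optima = mu, chemotype = chemotype)
}

#' Assemble plot communities under filtering and limiting similarity
#'
#' Each plot draws a Poisson richness (floored at 2) and is filled
#' sequentially without replacement: candidate s enters plot p with
#' probability proportional to
#' `exp(-(mu_s - h_p)^2 / (2 sigma_filt^2)) *
#'  exp(lambda_div * meanJaccard(s, residents))`.
#' With `sigma_filt = Inf` and `lambda_div = 0` this is uniform (neutral)
#' assembly.
#'
#' @param pool a [generate_species_pool()] result.
#' @param env_gen a [generate_environment()] result.
#' @param config a [synthetic_config()].
#' @return an [occurrence_matrix()].
#' @export
assemble_communities <- function(pool, env_gen, config) {
  species <- names(pool$optima)
  ns <- length(species)
  plots <- names(env_gen$habitat)
  jac <- as.matrix(jaccard_dissimilarity(pool$sm))
  occ <- matrix(0L, length(plots), ns, dimnames = list(plots, species))
  if (config$mean_richness > ns)
    stop("target richness exceeds species pool size", call. = FALSE)
  for (p in plots) {
    target <- min(ns, stats::rpois(1L, config$mean_richness - 2) + 2L)
    wfilt <- if (is.finite(config$sigma_filt)) {
      exp(-(pool$optima - env_gen$habitat[[p]])^2 /
            (2 * config$sigma_filt^2))
    } else stats::setNames(rep(1, ns), species)
    wfilt <- pmax(wfilt, 1e-12)
    residents <- character(0)
    for (k in seq_len(target)) {
      cand <- setdiff(species, residents)
      w <- wfilt[cand]
      if (config$lambda_div > 0 && length(residents)) {
        mj <- colMeans(jac[residents, cand, drop = FALSE])
        w <- w * exp(config$lambda_div * mj)
      }
      residents <- c(residents, sample(cand, 1L, prob = w))
    }
    occ[p, residents] <- 1L
  }
  occurrence_matrix(occ)
}

#' Generate a full synthetic dataset
#'
#' Seeds the RNG from `config$seed` (deterministic output for a given
#' config), generates environment, species pool and communities, applies the
#' trait-coverage censoring (species without metabolite / trait data), and
#' returns the validated bundle plus ground truth.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_dataset`: `bundle`
#'   (an `analysis_bundle`), `truth` (niche optima, habitat scores, habitat
#'   classes, config).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  env_gen <- generate_environment(config)
  pool <- generate_species_pool(config)
  occ <- assemble_communities(pool, env_gen, config)
  species <- colnames(occ)
  n_sm <- round(config$sm_coverage * config$n_species)
  n_rut <- round(config$rut_coverage * config$n_species)
  sm_sp <- sort(sample(species, n_sm))
  rut_sp <- sort(sample(species, n_rut))
  bundle <- analysis_bundle(
    occ,
    binary_trait_matrix(unclass(pool$sm)[sm_sp, , drop = FALSE]),
    continuous_trait_matrix(unclass(pool$rut)[rut_sp, , drop = FALSE]),
    env_gen$env)
  structure(list(
    bundle = bundle,
    truth = list(optima = pool$optima, chemotype = pool$chemotype,
                 habitat = env_gen$habitat,
                 habitat_class = env_gen$class, config = config)
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Bundle CSVs via [write_bundle()] plus a `truth.json` sidecar with the
#' ground truth and configuration.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  write_bundle(dataset$bundle, dir)
  truth <- dataset$truth
  truth$config <- unclass(truth$config)
  truth$config$extent_km <- as.numeric(truth$config$extent_km)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
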