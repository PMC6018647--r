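# Fixtures are built in code; oracles here are deliberately brute-force and
# independent of the package's computational paths.

toy_occ <- function() {
  m <- rbind(
    p1 = c(1, 1, 1, 0, 0, 0),
    p2 = c(0, 1, 1, 1, 1, 0),
    p3 = c(1, 0, 0, 0, 1, 1),
    p4 = c(0, 0, 0, 1, 0, 1))
  colnames(m) <- paste0("sp", 1:6)
  occurrence_matrix(m)
}

toy_sm <- function() {
  m <- rbind(
    sp1 = c(1, 1, 0, 0, 1, 0),
    sp2 = c(1, 0, 1, 0, 0, 1),
    sp3 = c(0, 1, 1, 1, 0, 0),
    sp4 = c(0, 0, 1, 1, 1, 0),
    sp5 = c(1, 1, 0, 1, 0, 1))
  colnames(m) <- sprintf("met%d", 1:6)
  binary_trait_matrix(m)
}

toy_rut <- function() {
  m <- rbind(sp1 = c(1, 5, 2), sp2 = c(2, 3, 8),
             sp3 = c(4, 1, 4), sp4 = c(7, 2, 6))
  colnames(m) <- c("sla", "wood_density", "leaf_n")
  continuous_trait_matrix(m)
}

toy_env <- function() {
  soil <- rbind(
    p1 = c(70, 20, 10, 3.2, 1.5, 1.1, 16.0, 4.1, 5.2),
    p2 = c(65, 22, 13, 3.8, 1.9, 1.4, 15.1, 4.8, 6.1),
    p3 = c(40, 25, 35, 6.9, 3.4, 2.7, 11.8, 8.0, 10.5),
    p4 = c(35, 28, 37, 7.4, 3.7, 3.0, 11.2, 8.6, 11.3))
  colnames(soil) <- c("sand", "silt", "clay", "Ca", "Mg", "K", "CN", "P",
                      "NO3")
  coords <- data.frame(longitude = c(-73.40, -73.35, -72.60, -72.55),
                       latitude = c(-4.10, -4.05, -3.60, -3.55))
  environment_table(soil, coords)
}

toy_bundle <- function() analysis_bundle(toy_occ(), toy_sm(), toy_rut(),
                                         toy_env())

# reduced-size generator config shared by the calibration and power tests
desk_config <- function(seed, sigma_filt = Inf, lambda_div = 0) {
  synthetic_config(
    n_plots = 10, n_species = 15, n_metabolites = 60, n_traits = 8,
    n_white_sand = 5, mean_richness = 5,
    sigma_filt = sigma_filt, lambda_div = lambda_div,
    mean_metabolites_per_species = 10, sm_coverage = 1, rut_coverage = 1,
    seed = seed)
}

rand_binary_matrix <- function(n, m, p = 0.4) {
  x <- matrix(rbinom(n * m, 1, p), n, m,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("t", seq_len(m))))
  x[rowSums(x) == 0, 1] <- 1
  x
}

# brute-force mean pairwise distance over a species multiset (loops, no
# matrix indexing tricks)
oracle_mean_pairs <- function(ids, D) {
  tot <- 0; k <- 0
  for (a in seq_along(ids)) for (b in seq_along(ids)) if (a < b) {
    tot <- tot + if (ids[a] == ids[b]) 0 else D[ids[a], ids[b]]
    k <- k + 1
  }
  tot / k
}

# exhaustive-enumeration oracle for the median-difference test on small
# worlds: returns exact P(median <= 0) and P(median >= 0) over all equally
# likely joint draws (distinct subsets, or multisets when replace = TRUE)
oracle_nullmodel <- function(occurrence, D, pool, replace = FALSE) {
  occ <- unclass(occurrence)
  plots <- rownames(occ)
  obs <- vapply(plots, function(p) {
    oracle_mean_pairs(colnames(occ)[occ[p, ] == 1], D)
  }, numeric(1))
  draws <- lapply(plots, function(p) {
    n <- sum(occ[p, ])
    if (replace) {
      g <- do.call(expand.grid, rep(list(seq_along(pool)), n))
      apply(g, 1, function(i) oracle_mean_pairs(pool[i], D))
    } else {
      apply(utils::combn(length(pool), n), 2,
            function(i) oracle_mean_pairs(pool[i], D))
    }
  })
  joint <- do.call(expand.grid, lapply(draws, seq_along))
  med <- apply(joint, 1, function(ix) {
    stats::median(vapply(seq_along(draws),
                         function(p) obs[p] - draws[[p]][ix[p]], numeric(1)))
  })
  list(p_le = mean(med <= 0), p_ge = mean(med >= 0))
}

# brute-force turnover oracle: explicit pair loops
oracle_tau <- function(sp_i, sp_j, D) {
  w <- c()
  for (s in list(sp_i, sp_j))
    for (a in seq_along(s)) for (b in seq_along(s)) if (a < b)
      w <- c(w, D[s[a], s[b]])
  x <- c()
  for (a in sp_i) for (b in sp_j) if (a != b) x <- c(x, D[a, b])
  1 - mean(w) / mean(x)
}

# exhaustive Mantel oracle over all n! simultaneous row/column permutations
oracle_mantel_exact <- function(m1, m2, upper_tail = TRUE) {
  n <- nrow(m1)
  perms <- gtools_permutations(n)
  ut <- upper.tri(m1)
  r_obs <- cor(m1[ut], m2[ut])
  rs <- apply(perms, 1, function(pm) cor(m1[ut], m2[pm, pm][ut]))
  p <- if (upper_tail) mean(rs >= r_obs - 1e-12)
       else mean(rs <= r_obs + 1e-12)
  list(r = r_obs, p = p)
}

# all permutations of 1..n without external dependencies
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}
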