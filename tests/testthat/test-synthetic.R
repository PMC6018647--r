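test_that("generate_dataset is deterministic and matches the design shape", {
  d1 <- generate_dataset(synthetic_config(seed = 42))
  d2 <- generate_dataset(synthetic_config(seed = 42))
  expect_identical(unclass(d1$bundle$occurrence)[, ],
                   unclass(d2$bundle$occurrence)[, ])
  expect_identical(d1$truth$optima, d2$truth$optima)
  b <- d1$bundle
  expect_equal(dim(b$occurrence), c(19L, 29L))
  expect_equal(ncol(b$sm), 189L)
  expect_equal(ncol(b$rut), 14L)
  expect_equal(nrow(b$sm), 27L)          # round(27/29 * 29)
  expect_equal(nrow(b$rut), 16L)
  expect_equal(ncol(b$env$soil), 9L)
  # byte-identical files from the same seed
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  write_dataset(d1, t1); write_dataset(d2, t2)
  for (f in list.files(t1))
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)))
})

test_that("environment generator: clusters, texture simplex, habitat link", {
  set.seed(20)
  cfg <- synthetic_config()
  g <- generate_environment(cfg)
  soil <- g$env$soil
  expect_true(all(abs(rowSums(soil[, c("sand", "silt", "clay")]) - 100)
                  < 1e-9))
  expect_true(all(soil[, c("sand", "silt", "clay")] >= 0))
  # near-zero noise: monotone responses to the habitat score
  g0 <- generate_environment(synthetic_config(soil_noise = 1e-6))
  for (v in c("Ca", "K", "P", "NO3"))
    expect_gt(cor(g0$env$soil[, v], g0$habitat, method = "spearman"), 0.999)
  expect_lt(cor(g0$env$soil[, "CN"], g0$habitat, method = "spearman"),
            -0.999)
  # within-cluster distances sit below the between-cluster minimum
  d <- spatial_distance(g$env$coords, log_transform = FALSE)
  basin <- rep(seq_len(cfg$n_basins), length.out = cfg$n_plots)
  same <- outer(basin, basin, "==") & upper.tri(d)
  diff <- (!outer(basin, basin, "==")) & upper.tri(d)
  expect_lt(max(d[same]), min(d[diff]))
  # habitat classes have the configured split
  expect_equal(sum(g$class == "white_sand"), 9)
})

test_that("soil PCA axis 1 beats the broken stick on default worlds", {
  for (s in c(1, 2, 3)) {
    g <- generate_dataset(synthetic_config(seed = s))
    p <- pca_correlation(g$bundle$env$soil)
    expect_true(p$retained[1])
  }
})

test_that("species pool: profile calibration, sharing limit, coverage", {
  set.seed(30)
  cfg <- synthetic_config()
  pool <- generate_species_pool(cfg)
  counts <- rowSums(unclass(pool$sm))
  expect_lt(abs(mean(counts) - 31.4) / 31.4, 0.2)
  expect_true(all(colSums(unclass(pool$sm)) >= 2))
  expect_true(all(counts >= 1))
  # sharing at (near) maximum: profiles collapse to identity, Jaccard -> 0
  poolmax <- generate_species_pool(synthetic_config(sm_sharing = 1,
                                                    chemotype_strength = 0))
  jd <- jaccard_dissimilarity(poolmax$sm)
  expect_true(all(as.matrix(jd) == 0))
  # chemotype structure: same-chemotype species are chemically closer
  j <- as.matrix(jaccard_dissimilarity(pool$sm))
  ct <- pool$chemotype[rownames(j)]
  same <- outer(ct, ct, "==") & upper.tri(j)
  diff <- (!outer(ct, ct, "==")) & upper.tri(j)
  expect_lt(mean(j[same]), mean(j[diff]))
  # exact coverage counts in the emitted bundle
  ds <- generate_dataset(synthetic_config(seed = 8))
  expect_equal(nrow(ds$bundle$sm), round(27 / 29 * 29))
  expect_equal(nrow(ds$bundle$rut), 16)
})

test_that("neutral assembly is uniform; effects push dispersion as built", {
  cfg <- desk_config(1)
  set.seed(50)
  env_gen <- generate_environment(cfg)
  pool <- generate_species_pool(cfg)
  # neutral: per-species occupancy uniform within chi-square tolerance
  tally <- numeric(cfg$n_species)
  n_assemblies <- 300
  for (i in seq_len(n_assemblies))
    tally <- tally + colSums(unclass(assemble_communities(pool, env_gen, cfg)))
  expect_gt(chisq.test(tally)$p.value, 0.001)
  # divergence reward raises within-plot chemical dissimilarity
  cfg_div <- desk_config(1, lambda_div = 20)
  jd <- jaccard_dissimilarity(pool$sm)
  mean_j <- function(cfg, n = 40) {
    mean(vapply(seq_len(n), function(i) {
      occ <- assemble_communities(pool, env_gen, cfg)
      mean(suppressWarnings(mean_within_plot_distance(occ, jd)))
    }, numeric(1)))
  }
  expect_gt(mean_j(cfg_div), mean_j(cfg))
  # filtering lowers within-plot trait variance below neutral
  cfg_filt <- desk_config(1, sigma_filt = 0.25)
  z <- zscore(unclass(pool$rut))
  de <- euclidean_distance(z)
  mean_e <- function(cfg, n = 40) {
    mean(vapply(seq_len(n), function(i) {
      occ <- assemble_communities(pool, env_gen, cfg)
      mean(suppressWarnings(mean_within_plot_distance(occ, de)))
    }, numeric(1)))
  }
  expect_lt(mean_e(cfg_filt), mean_e(cfg))
})

test_that("divergence significance is monotone over the effect grid", {
  grid <- effect_grid()
  rate <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(1:25, function(i) {
      b <- generate_dataset(desk_config(7000 + i,
                                        lambda_div = grid$lambda_div[g]))$bundle
      r <- suppressWarnings(median_difference_test(
        restrict_to_trait_coverage(b, "SM"),
        jaccard_dissimilarity(filter_shared_columns(b$sm)),
        R = 100, alternative = "divergence", seed = 7100 + i))
      r$p <= 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
})

test_that("generated bundles pass validation across a seed sweep", {
  # full sweep at desk size, spot checks at the default design size
  for (s in 1:100) {
    b <- generate_dataset(desk_config(s))$bundle
    expect_s3_class(b, "analysis_bundle")
    expect_true(all(unclass(b$occurrence) %in% c(0L, 1L)))
    expect_true(all(rowSums(unclass(b$occurrence)) >= 2))
  }
  for (s in 1:5) {
    b <- generate_dataset(synthetic_config(seed = s))$bundle
    expect_s3_class(b, "analysis_bundle")
    expect_true(all(colSums(unclass(b$sm)) >= 0))
    expect_equal(nrow(b$occurrence), 19L)
  }
})
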