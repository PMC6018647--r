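make_dist <- function(D) {
  D <- D + t(D); diag(D) <- 0
  distance_matrix(D, "euclidean")
}

test_that("tau_st_pair matches closed cases and the enumeration oracle", {
  sp <- paste0("s", 1:4)
  # all pairwise distances equal -> tau = 0
  D <- matrix(0.7, 4, 4, dimnames = list(sp, sp)); diag(D) <- 0
  d <- distance_matrix(D, "euclidean")
  r <- tau_st_pair(c("s1", "s2"), c("s3", "s4"), d)
  expect_equal(r$tau, 0)
  # within 1 and 1, all cross 2 -> Dw = 1, Da = 2, tau = 0.5
  D2 <- matrix(2, 4, 4, dimnames = list(sp, sp))
  D2["s1", "s2"] <- D2["s2", "s1"] <- 1
  D2["s3", "s4"] <- D2["s4", "s3"] <- 1
  diag(D2) <- 0
  r2 <- tau_st_pair(c("s1", "s2"), c("s3", "s4"), distance_matrix(D2, "euclidean"))
  expect_equal(r2, list(tau = 0.5, Dw = 1, Da = 2))
  # identical species sets: Da over distinct pairs equals Dw -> tau = 0
  r3 <- tau_st_pair(c("s1", "s2", "s3"), c("s1", "s2", "s3"), d)
  expect_equal(r3$tau, 0)
  # random toys vs brute-force oracle
  set.seed(14)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    ids <- paste0("x", seq_len(n))
    M <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    d4 <- make_dist(M)
    si <- sample(ids, sample(2:3, 1))
    sj <- sample(ids, sample(2:3, 1))
    got <- tau_st_pair(si, sj, d4)
    expect_equal(got$tau, oracle_tau(si, sj, as.matrix(d4)),
                 tolerance = 1e-12)
  }
})

test_that("tau_st_pair masks degenerate pairs", {
  sp <- paste0("s", 1:3)
  D <- matrix(0.5, 3, 3, dimnames = list(sp, sp)); diag(D) <- 0
  d <- distance_matrix(D, "euclidean")
  expect_true(is.na(tau_st_pair("s1", c("s2", "s3"), d)$tau))
  # all-zero distances: Da = 0 -> masked
  Z <- matrix(0, 3, 3, dimnames = list(sp, sp))
  expect_true(is.na(tau_st_pair(c("s1", "s2"), c("s1", "s3"),
                                distance_matrix(Z, "euclidean"))$tau))
})

test_that("tau_st_matrix composes pairs with the documented sign convention", {
  sp <- paste0("s", 1:6)
  # clustered world: within-plot distances small, cross distances large
  D <- matrix(2, 6, 6, dimnames = list(sp, sp))
  D[1:3, 1:3] <- 0.5; D[4:6, 4:6] <- 0.5
  diag(D) <- 0
  d <- distance_matrix(D, "euclidean")
  occ <- occurrence_matrix(rbind(pA = c(1, 1, 1, 0, 0, 0),
                                 pB = c(0, 0, 0, 1, 1, 1),
                                 pC = c(1, 1, 0, 1, 0, 0)) |>
                             (\(m) {colnames(m) <- sp; m})())
  tr <- tau_st_matrix(occ, d)
  expect_gt(tr$tau["pA", "pB"], 0)
  # matrix equals independent pairwise calls
  for (pr in list(c("pA", "pB"), c("pA", "pC"), c("pB", "pC"))) {
    spl <- lapply(pr, function(p) sp[unclass(occ)[p, ] == 1])
    expect_equal(tr$tau[pr[1], pr[2]],
                 tau_st_pair(spl[[1]], spl[[2]], d)$tau)
  }
  # overdispersed mirror: within large, cross small
  D2 <- matrix(0.5, 6, 6, dimnames = list(sp, sp))
  D2[1:3, 1:3] <- 2; D2[4:6, 4:6] <- 2
  diag(D2) <- 0
  tr2 <- tau_st_matrix(occurrence_matrix(unclass(occ)[c("pA", "pB"), ]),
                       distance_matrix(D2, "euclidean"))
  expect_lt(tr2$tau["pA", "pB"], 0)
  # TAU_st invariants: 1 - Dw/Da identity and scale invariance
  ut <- upper.tri(tr$tau)
  expect_equal(tr$tau[ut], 1 - tr$Dw[ut] / tr$Da[ut], tolerance = 1e-12)
  tr3 <- tau_st_matrix(occ, distance_matrix(D * 3.7, "euclidean"))
  expect_equal(as.matrix(tr3$tau), as.matrix(tr$tau), tolerance = 1e-12)
})

test_that("mantel_test: maximal statistic, exact enumeration, invariance", {
  set.seed(6)
  # 8 plots: 8! permutations, so no random permutation ties the identity
  ids <- paste0("p", 1:8)
  M1 <- matrix(runif(64), 8, 8, dimnames = list(ids, ids))
  m1 <- make_dist(M1)
  r <- mantel_test(m1, m1, permutations = 199, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 200)
  # exhaustive oracle on 4 plots (24 permutations)
  ids4 <- paste0("q", 1:4)
  A <- matrix(runif(16), 4, 4, dimnames = list(ids4, ids4))
  B <- matrix(runif(16), 4, 4, dimnames = list(ids4, ids4))
  a <- make_dist(A); b <- make_dist(B)
  ex <- oracle_mantel_exact(as.matrix(a), as.matrix(b), upper_tail = TRUE)
  got <- mantel_test(a, b, permutations = 99999, seed = 2,
                     alternative = "greater")
  expect_equal(got$r, ex$r, tolerance = 1e-12)
  expect_lt(abs(got$p - ex$p), 3 * sqrt(ex$p * (1 - ex$p) / 99999) + 1e-4)
  # invariant under common relabeling
  ids <- paste0("p", 1:5)
  M1 <- matrix(runif(25), 5, 5, dimnames = list(ids, ids))
  m1 <- make_dist(M1)
  pm <- sample(5)
  m1p <- distance_matrix(as.matrix(m1)[pm, pm], "euclidean")
  M2 <- matrix(runif(25), 5, 5, dimnames = list(ids, ids))
  m2 <- make_dist(M2)
  m2p <- distance_matrix(as.matrix(m2)[pm, pm], "euclidean")
  expect_equal(mantel_test(m1, m2, permutations = 99, seed = 3)$r,
               mantel_test(m1p, m2p, permutations = 99, seed = 3)$r,
               tolerance = 1e-12)
  expect_error(mantel_test(make_dist(A)[1:3, 1:3] |>
                             (\(x) distance_matrix(x, "euclidean"))(),
                           make_dist(B)[1:3, 1:3] |>
                             (\(x) distance_matrix(x, "euclidean"))()),
               "at least 4")
})

test_that("mantel_test agrees with vegan on r and is close on p", {
  skip_if_not_installed("vegan")
  set.seed(44)
  ids <- paste0("p", 1:12)
  A <- matrix(runif(144), 12, 12, dimnames = list(ids, ids))
  h <- runif(12)
  B <- abs(outer(h, h, "-")) + matrix(runif(144, 0, 0.2), 12, 12)
  dimnames(B) <- list(ids, ids)
  m1 <- make_dist(A); m2 <- make_dist(B + 0.3 * (A + t(A)))
  got <- mantel_test(m1, m2, permutations = 999, seed = 9,
                     alternative = "greater")
  veg <- vegan::mantel(as.dist(as.matrix(m1)), as.dist(as.matrix(m2)),
                       permutations = 999)
  expect_equal(got$r, unname(veg$statistic), tolerance = 1e-12)
  expect_lt(abs(got$p - veg$signif), 0.05)
})

test_that("masked pairs are dropped pairwise-consistently", {
  ids <- paste0("p", 1:5)
  set.seed(10)
  M1 <- matrix(runif(25), 5, 5, dimnames = list(ids, ids))
  m1 <- as.matrix(make_dist(M1))
  m1["p1", "p2"] <- m1["p2", "p1"] <- NA
  M2 <- matrix(runif(25), 5, 5, dimnames = list(ids, ids))
  m2 <- make_dist(M2)
  r <- mantel_test(m1, m2, permutations = 99, seed = 4)
  expect_equal(r$n_pairs, 9)
  ok <- !is.na(m1[upper.tri(m1)])
  expect_equal(r$r, cor(m1[upper.tri(m1)][ok],
                        as.matrix(m2)[upper.tri(m2)][ok]),
               tolerance = 1e-12)
})

test_that("mantel p is near-uniform under a fixed-direction null", {
  set.seed(23)
  n_rep <- 400
  ids <- paste0("p", 1:8)
  ps <- vapply(seq_len(n_rep), function(i) {
    m1 <- make_dist(matrix(runif(64), 8, 8, dimnames = list(ids, ids)))
    m2 <- make_dist(matrix(runif(64), 8, 8, dimnames = list(ids, ids)))
    mantel_test(m1, m2, permutations = 49, seed = 1000 + i,
                alternative = "greater")$p
  }, numeric(1))
  # p takes values k/50; KS-style check on coarse bins
  expect_gt(mean(ps <= 0.2), 0.2 - 3 * sqrt(0.2 * 0.8 / n_rep))
  expect_lt(mean(ps <= 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / n_rep))
  expect_gt(mean(ps <= 0.5), 0.5 - 3 * sqrt(0.25 / n_rep))
  expect_lt(mean(ps <= 0.5), 0.5 + 3 * sqrt(0.25 / n_rep))
})

test_that("run_turnover_suite returns the full assemblage x predictor grid", {
  b <- generate_dataset(synthetic_config(seed = 55))$bundle
  asm <- rut_axis_assemblages(b$rut)
  out <- suppressWarnings(run_turnover_suite(
    b, asm$assemblages, soil_vars = c("CN", "P", "NO3", "K", "Ca"),
    permutations = 99, seed = 21))
  expect_setequal(unique(out$summary$assemblage),
                  c("SM", names(asm$assemblages)))
  expect_setequal(unique(out$summary$predictor),
                  c("spatial", "soil", "soil_residual"))
  expect_true(all(out$summary$r >= -1 & out$summary$r <= 1))
  out2 <- suppressWarnings(run_turnover_suite(
    b, asm$assemblages, soil_vars = c("CN", "P", "NO3", "K", "Ca"),
    permutations = 99, seed = 21))
  expect_equal(out$summary, out2$summary)
})
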