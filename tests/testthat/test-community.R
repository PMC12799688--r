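test_that("assembly sums effects off-diagonal and fixes the diagonal", {
  B <- matrix(0, 2, 2)
  B[1, 2] <- 1
  C <- matrix(0, 2, 2)
  C[1, 2] <- -0.4
  A <- assemble_community(B, C, diagonal = 0)
  expect_equal(A[1, 2], 0.6)
  A2 <- assemble_community(B, matrix(0, 2, 2), diagonal = -2)
  expect_equal(diag(A2), c(-2, -2))
  expect_equal(A2[1, 2], 1)
  expect_error(assemble_community(B, matrix(0, 3, 3)), "dimensions")
})

test_that("a single TIM on a trophic pair reproduces the four-cell sign layout", {
  # consumer 2 eats resource 1; modifier 3 facilitates (c > 0)
  B <- matrix(0, 3, 3)
  B[1, 2] <- -1 # consumer harms resource
  B[2, 1] <- 1 # resource feeds consumer
  tims <- tibble::tibble(i = 1L, j = 2L, k = 3L, c = 0.4)
  A <- assemble_community(B, build_nte_matrix(tims, 3), diagonal = 0)
  expect_lt(A[1, 2], 0) # trophic: effect of consumer on resource
  expect_gt(A[2, 1], 0) # trophic: effect of resource on consumer
  expect_gt(A[2, 3], 0) # NTE: facilitator helps the consumer
  expect_lt(A[1, 3], 0) # NTE: facilitator harms the resource
  expect_equal(sum(A != 0), 4)
})

test_that("assembly is linear in the non-trophic matrix", {
  set.seed(301)
  B <- matrix(rnorm(25), 5, 5)
  C1 <- matrix(rnorm(25), 5, 5)
  C2 <- matrix(rnorm(25), 5, 5)
  lhs <- assemble_community(B, C1 + C2, diagonal = -2)
  rhs <- assemble_community(B, C1, diagonal = -2) + C2
  diag(rhs) <- -2
  expect_equal(lhs, rhs, ignore_attr = TRUE)
})

test_that("matrix connectance counts nonzero off-diagonal cells over S(S-1)", {
  expect_equal(connectance(matrix(0, 4, 4)), 0)
  full <- matrix(1, 4, 4)
  expect_equal(connectance(full), 1) # diagonal excluded from both sides
  set.seed(302)
  web <- generate_niche_web(20, 0.2)
  B <- parameterise_trophic(web)
  # each directed link fills two cells (minus mutual-feeding overlaps)
  n_mutual <- sum(
    paste(web$links[, 1], web$links[, 2]) %in%
      paste(web$links[, 2], web$links[, 1])
  )
  expect_equal(
    connectance(B),
    (2 * nrow(web$links) - n_mutual) / (20 * 19)
  )
})

test_that("off-diagonal variance matches the sparse-fill closed form", {
  expect_equal(offdiag_variance(matrix(0, 3, 3)), 0)
  M <- matrix(0, 2, 2)
  M[1, 2] <- 3
  expect_equal(offdiag_variance(M), 9 / 4) # population var of {3, 0}
  # fill * sd^2 + fill * (1 - fill) * mean^2 for cells that are either 0 or
  # N(mean, sd), against direct computation
  set.seed(303)
  S <- 80
  fill <- 0.3
  cells <- which(upper.tri(matrix(0, S, S)) | lower.tri(matrix(0, S, S)))
  M2 <- matrix(0, S, S)
  on <- sample(cells, round(fill * length(cells)))
  M2[on] <- rnorm(length(on), mean = 2, sd = 0.5)
  direct <- {
    v <- M2[cells]
    mean(v^2) - mean(v)^2
  }
  expect_equal(offdiag_variance(M2), direct)
  f <- length(on) / length(cells)
  expect_equal(direct, f * var(M2[on]) * (length(on) - 1) / length(on) +
    f * (1 - f) * mean(M2[on])^2, tolerance = 1e-10)
})

test_that("degree heterogeneity is zero for regular structures and matches hand values", {
  # cyclic tournament: every species has in-degree = out-degree = 1
  M <- matrix(0, 4, 4)
  M[cbind(1:4, c(2, 3, 4, 1))] <- 1
  expect_equal(degree_heterogeneity(M), 0)
  expect_error(degree_heterogeneity(matrix(0, 3, 3)), "no nonzero")

  # star web hub at S = 4: trophic matrix has hub row/col filled
  B <- parameterise_trophic(star_web(3), strength_params())
  # degrees: hub in 3 / out 3, leaves in 1 / out 1
  # pooled 2S-vector (1,1,1,3,1,1,1,3) has mean 1.5; population variance of
  # the normalised vector: hand computation
  v <- c(1, 1, 1, 3, 1, 1, 1, 3) / 1.5
  hand <- mean(v^2) - mean(v)^2
  set.seed(304)
  expect_equal(degree_heterogeneity(B), hand)
})

test_that("pairwise correlation behaves on symmetric, antisymmetric and trophic matrices", {
  set.seed(305)
  M <- matrix(0, 6, 6)
  vals <- rnorm(5, sd = 2)
  for (p in 1:5) {
    M[p, p + 1] <- vals[p]
    M[p + 1, p] <- -vals[p]
  }
  expect_equal(pairwise_correlation(M), -1)
  Msym <- abs(M) + t(abs(M))
  expect_equal(pairwise_correlation(Msym), 1)

  # trophic baseline: pooling reciprocal cells mixes the two role clusters
  # centred at (mu_RC, mu_CR) and (mu_CR, mu_RC), so the pooled Pearson is
  # (rho * sd^2 + mu_RC * mu_CR) / (sd^2 + (mu_RC^2 + mu_CR^2) / 2) = -0.96,
  # more negative than the role-ordered draw correlation of -0.8
  pooled <- (-0.8 * 0.25 + (-1) * 1) / (0.25 + (1 + 1) / 2)
  expect_equal(pooled, -0.96)
  B <- parameterise_trophic(generate_niche_web(60, 0.2))
  expect_lt(abs(pairwise_correlation(B) - pooled), 0.02)
})

test_that("cov(B, C) matches a brute-force cell sum and signs as expected", {
  B <- matrix(0, 3, 3)
  expect_equal(cov_bc(B, matrix(0, 3, 3)), 0)
  set.seed(306)
  B <- parameterise_trophic(generate_niche_web(15, 0.25))
  mask <- row(B) != col(B)
  expect_equal(cov_bc(B, B), mean(B[mask]^2) - mean(B[mask])^2)

  # mutual interference writes negative NTEs onto positive trophic cells
  covs <- replicate(20, {
    web <- generate_niche_web(20, 0.25)
    Bw <- parameterise_trophic(web)
    tims <- sample_tim_set(web, "mutual_interference", 3, compute_alpha(Bw))
    Cw <- build_nte_matrix(tims)
    brute <- {
      m <- row(Bw) != col(Bw)
      b <- Bw[m]
      cc <- Cw[m]
      sum((b - mean(b)) * (cc - mean(cc))) / length(b)
    }
    expect_equal(cov_bc(Bw, Cw), brute)
    brute
  })
  expect_lt(mean(covs), 0)
})

test_that("metrics are invariant under species relabelling", {
  set.seed(307)
  web <- generate_niche_web(15, 0.25)
  B <- parameterise_trophic(web)
  tims <- sample_tim_set(web, "random", 4, compute_alpha(B))
  C <- build_nte_matrix(tims)
  perm <- sample(15)
  Bp <- B[perm, perm]
  Cp <- C[perm, perm]
  m1 <- structure_metrics(B, C)
  m2 <- structure_metrics(Bp, Cp)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("at lambda = 0 the combined matrix reduces to the trophic baseline", {
  set.seed(308)
  web <- generate_niche_web(60, 0.2)
  B <- parameterise_trophic(web)
  tims <- sample_tim_set(web, "random", 0, compute_alpha(B))
  C <- build_nte_matrix(tims, 60)
  m <- structure_metrics(B, C)
  expect_equal(m$connectance_C, 0)
  expect_equal(m$variance_C, 0)
  expect_equal(m$cov_BC, 0)
  expect_equal(m$connectance_A, connectance(B))
  expect_lt(abs(m$pairwise_correlation - (-0.96)), 0.02)
})

test_that("connectance is subadditive under overlap", {
  set.seed(309)
  web <- generate_niche_web(20, 0.2)
  B <- parameterise_trophic(web)
  tims <- sample_tim_set(web, "nearby_only", 5, compute_alpha(B))
  C <- build_nte_matrix(tims)
  A <- assemble_community(B, C, 0)
  expect_lte(connectance(A), connectance(B) + connectance(C))
})
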