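# Synthetic cohort generator: covariance construction, sampling, toy atlas,
# volume rendering.

test_that("zero-strength covariance is identity plus diagonal load", {
  spec <- build_group_covariance(4, backbone_degree = 2, rewire_prob = 0,
                                 edge_strength = 0, diagonal_load = 0.5)
  expect_equal(spec$matrix, diag(1.5, 4))
})

test_that("unrewired backbone covariance has ring-lattice support", {
  spec <- build_group_covariance(6, backbone_degree = 2, rewire_prob = 0,
                                 edge_strength = 0.3)
  # enumerate the 6-cycle edges independently
  ring <- matrix(0, 6, 6)
  for (i in 1:6) {
    j <- (i %% 6) + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  off <- spec$matrix
  diag(off) <- 0
  expect_equal((off != 0) + 0, ring)
  expect_equal(off[ring == 1], rep(0.3, sum(ring)))
})

test_that("weaken alteration zeroes the region's off-diagonals", {
  spec <- build_group_covariance(
    6, backbone_degree = 2, rewire_prob = 0, edge_strength = 0.3,
    planted_alterations = list(list(region = 3, mode = "weaken")))
  expect_true(all(spec$matrix[3, -3] == 0))
  expect_true(all(spec$matrix[-3, 3] == 0))
  expect_gt(spec$matrix[3, 3], 0)
})

test_that("covariance spec is symmetric positive definite, even after strengthening", {
  spec <- build_group_covariance(
    20, backbone_degree = 4, rewire_prob = 0.1, edge_strength = 0.3,
    planted_alterations = list(list(region = 5, mode = "strengthen",
                                    magnitude = 1.0)),
    seed = 7)
  expect_equal(spec$matrix, t(spec$matrix))
  ev <- eigen(spec$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("odd backbone degree and invalid regions are rejected", {
  expect_error(build_group_covariance(10, backbone_degree = 3), "even")
  expect_error(build_group_covariance(
    10, planted_alterations = list(list(region = 99, mode = "weaken")),
    backbone_degree = 4), "invalid region")
})

test_that("cohort sampling has the contracted shape and is seed-reproducible", {
  spec <- build_group_covariance(90)
  x1 <- sample_region_matrix(spec, 22, seed = 11)
  x2 <- sample_region_matrix(spec, 22, seed = 11)
  x3 <- sample_region_matrix(spec, 22, seed = 12)
  expect_equal(dim(x1$values), c(22, 90))
  expect_identical(x1$values, x2$values)
  expect_false(identical(x1$values, x3$values))
  expect_true(all(x1$values > 0))  # mean 100, sd ~1: SUVR-like positive scale
})

test_that("independent-region spec yields near-zero sample correlations at large n", {
  spec <- build_group_covariance(20, backbone_degree = 4, edge_strength = 0)
  x <- sample_region_matrix(spec, 5000, seed = 42)
  cc <- cor(x$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("toy atlas partitions the ellipsoid mask into the full label set", {
  atlas <- make_toy_atlas(c(24, 24, 24), 90, seed = 3)
  labs <- atlas$labels
  expect_setequal(unique(as.integer(labs[labs > 0])), 1:90)
  expect_true(all(tabulate(labs[labs > 0], 90) >= 1))
  # exhaustive: labelled voxels are exactly the mask voxels
  expect_identical(sum(labs > 0), sum(labs != 0))
  atlas2 <- make_toy_atlas(c(24, 24, 24), 90, seed = 3)
  expect_identical(atlas$labels, atlas2$labels)
  expect_error(make_toy_atlas(c(3, 3, 3), 90), "too small")
})

test_that("noise-free rendering round-trips exactly through extraction", {
  atlas <- make_toy_atlas(c(14, 14, 14), 25, seed = 2)
  spec <- build_group_covariance(25, backbone_degree = 4)
  cohort <- sample_region_matrix(spec, 5, seed = 8)
  vols <- render_subject_volumes(cohort, atlas, noise_sd = 0, seed = 1)
  expect_length(vols, 5)
  expect_equal(dim(vols[[1]]$values), c(14, 14, 14))
  back <- t(vapply(vols, extract_region_means, numeric(25), atlas = atlas))
  expect_equal(back, unname(cohort$values), tolerance = 1e-12)
})

test_that("rendered region means vary at the expected standard error", {
  # one region with >= 100 voxels, unit voxel noise: mean error sd = 1/sqrt(n_vox)
  atlas <- make_toy_atlas(c(12, 12, 12), 4, seed = 5)
  counts <- tabulate(atlas$labels[atlas$labels > 0], 4)
  r <- which.max(counts)
  expect_gte(counts[r], 100)
  cohort <- region_matrix(matrix(100, 1, 4))
  hits <- 0
  n_rep <- 100
  band <- 4 / sqrt(counts[r])  # ~4 standard errors
  for (i in seq_len(n_rep)) {
    v <- render_subject_volumes(cohort, atlas, noise_sd = 1, seed = 100 + i)[[1]]
    m <- extract_region_means(v, atlas)[r]
    if (abs(m - 100) <= band) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("rendering is deterministic under a fixed seed", {
  atlas <- make_toy_atlas(c(10, 10, 10), 6, seed = 4)
  cohort <- sample_region_matrix(build_group_covariance(6, backbone_degree = 2), 4, seed = 1)
  v1 <- render_subject_volumes(cohort, atlas, noise_sd = 1, seed = 9)
  v2 <- render_subject_volumes(cohort, atlas, noise_sd = 1, seed = 9)
  expect_identical(lapply(v1, `[[`, "values"), lapply(v2, `[[`, "values"))
})

test_that("modular covariance has community blocks, bridges, and is PD", {
  spec <- build_modular_covariance(90, seed = 4)
  expect_equal(spec$n_communities, 5)
  expect_equal(spec$matrix, t(spec$matrix))
  ev <- eigen(spec$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  same <- outer(spec$communities, spec$communities, "==")
  off <- spec$matrix
  diag(off) <- 0
  expect_true(all(off[same & off != 0] == spec$within_cov))
  # a few weak bridges between communities, nothing else off-block
  bridges <- off[!same & off != 0]
  expect_length(bridges, 2 * 5 * spec$bridges_per_pair)
  expect_true(all(bridges == spec$bridge_frac * spec$within_cov))
})

test_that("modular alterations weaken, strengthen, and pair-strengthen as documented", {
  wk <- build_modular_covariance(
    36, planted_alterations = list(list(region = 5, mode = "weaken")), seed = 1)
  expect_true(all(wk$matrix[5, -5] == 0))

  st <- build_modular_covariance(
    90, planted_alterations = list(list(region = 17, mode = "strengthen")),
    seed = 2)
  own <- setdiff(which(st$communities == st$communities[17]), 17)
  expect_true(all(st$matrix[17, own] == 0))       # decoupled from own community
  foreign <- which(st$communities != st$communities[17])
  expect_equal(sum(st$matrix[17, foreign] > 1), 6 * 4)  # 6 links per community
  expect_gt(min(eigen(st$matrix, symmetric = TRUE, only.values = TRUE)$values), 0)

  pr <- build_modular_covariance(
    90, planted_alterations = list(list(region = 3, mode = "pair_strengthen",
                                        target_region = 50)), seed = 3)
  expect_equal(pr$matrix[3, 50], 1.45)
  expect_true(all(pr$matrix[3, -c(3, 50)] == 0))
  expect_gt(min(eigen(pr$matrix, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("strengthen-mode alteration raises the planted region's bi rank", {
  # majority direction over 20 seeds
  target <- 17
  wins <- 0
  for (s in 1:20) {
    base <- build_modular_covariance(90, seed = 700 + s)
    alt <- build_modular_covariance(
      90, planted_alterations = list(list(region = target, mode = "strengthen")),
      seed = 700 + s)
    bi_base <- metcovnet:::group_bi(normalize_region_matrix(
      sample_region_matrix(base, 22, seed = 500 + s))$values, 0.21)
    bi_alt <- metcovnet:::group_bi(normalize_region_matrix(
      sample_region_matrix(alt, 22, seed = 500 + s))$values, 0.21)
    if (rank(-bi_alt)[target] < rank(-bi_base)[target]) wins <- wins + 1
  }
  expect_gt(wins, 10)
})
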