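# Partial-correlation network estimation and sparsity binarization.

test_that("trivariate partial correlation matches the closed form at large n", {
  # known correlation structure; closed form computed from the marginals
  r12 <- 0.5; r13 <- 0.4; r23 <- 0.3
  Sigma <- matrix(c(1, r12, r13,
                    r12, 1, r23,
                    r13, r23, 1), 3, 3)
  set.seed(77)
  X <- MASS::mvrnorm(5000, mu = rep(0, 3), Sigma = Sigma)
  net <- partial_correlation_matrix(region_matrix(X, normalized = TRUE),
                                    shrinkage = 0)
  expected <- (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  expect_equal(net$R[1, 2], expected, tolerance = 0.03)
  expect_identical(net$R, t(net$R))
  expect_equal(diag(net$R), rep(1, 3))
})

test_that("independent regions give near-zero partial correlations", {
  spec <- build_group_covariance(20, backbone_degree = 4, edge_strength = 0)
  x <- sample_region_matrix(spec, 8000, seed = 13)
  net <- partial_correlation_matrix(region_matrix(x$values, normalized = TRUE),
                                    shrinkage = 0)
  off <- net$R[upper.tri(net$R)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("raw sample covariance is singular at p >= n without shrinkage", {
  pair <- quick_pair(seed = 1, n_regions = 40, n_subjects = 22)
  co <- normalize_region_matrix(pair$cohort_a)
  expect_error(partial_correlation_matrix(co, shrinkage = 0), "shrinkage")
  # the pseudo-inverse fallback still returns a valid matrix
  net <- partial_correlation_matrix(co, estimator = "pseudoinverse")
  expect_true(all(abs(net$R) <= 1 + 1e-8))
})

test_that("binarization keeps exactly floor(s * M) edges", {
  pair <- quick_pair(seed = 2, n_regions = 90)
  net <- partial_correlation_matrix(normalize_region_matrix(pair$cohort_a))
  b <- binarize_by_sparsity(net, 0.21)
  expect_equal(sum(b$A) / 2, 841)  # floor(0.21 * 4005)
  expect_identical(b$A, t(b$A))
  expect_true(all(diag(b$A) == 0))
})

test_that("binarization keeps the largest |R| pairs (brute-force check)", {
  net <- structure(list(region_ids = 1:4,
                        R = matrix(c(1, .9, -.95, .1,
                                     .9, 1, .2, .3,
                                     -.95, .2, 1, .05,
                                     .1, .3, .05, 1), 4, 4),
                        shrinkage = 0.5, estimator = "shrinkage",
                        A = NULL, sparsity = NA_real_),
                   class = "group_network")
  b <- binarize_by_sparsity(net, 0.5)  # floor(0.5 * 6) = 3 edges
  expect_equal(sum(b$A) / 2, 3)
  # brute force: |R| off-diagonals are .9 (1,2), .95 (1,3), .1 (1,4),
  # .2 (2,3), .3 (2,4), .05 (3,4) -> top 3 are (1,3), (1,2), (2,4)
  expect_equal(b$A[1, 3], 1)
  expect_equal(b$A[1, 2], 1)
  expect_equal(b$A[2, 4], 1)
  expect_equal(b$A[2, 3], 0)
})

test_that("ties are broken toward lexicographically smallest pairs", {
  R <- matrix(0.5, 5, 5); diag(R) <- 1
  net <- structure(list(region_ids = 1:5, R = R, shrinkage = 0.5,
                        estimator = "shrinkage", A = NULL,
                        sparsity = NA_real_),
                   class = "group_network")
  b <- binarize_by_sparsity(net, 0.35)  # floor(0.35 * 10) = 3 edges
  got <- which(b$A == 1 & upper.tri(b$A), arr.ind = TRUE)
  got <- got[order(got[, 1], got[, 2]), ]
  expect_equal(unname(got), cbind(c(1, 1, 1), c(2, 3, 4)))
})

test_that("binarization depends on |R| only through ranks", {
  pair <- quick_pair(seed = 3, n_regions = 30)
  net <- partial_correlation_matrix(normalize_region_matrix(pair$cohort_a))
  b1 <- binarize_by_sparsity(net, 0.2)
  net2 <- net
  net2$R <- sign(net$R) * abs(net$R)^3  # strictly monotone in |R|
  diag(net2$R) <- 1
  b2 <- binarize_by_sparsity(net2, 0.2)
  expect_identical(b1$A, b2$A)
})

test_that("largest component size follows the component structure", {
  two_triangles <- matrix(0, 6, 6)
  two_triangles[1, 2] <- two_triangles[2, 3] <- two_triangles[1, 3] <- 1
  two_triangles[4, 5] <- two_triangles[5, 6] <- two_triangles[4, 6] <- 1
  two_triangles <- two_triangles + t(two_triangles)
  two_triangles[two_triangles > 1] <- 1
  expect_equal(largest_component_size(two_triangles), 3)
  expect_equal(largest_component_size(matrix(0, 3, 3)), 1)
  pair <- quick_pair(seed = 4, n_regions = 90)
  net <- partial_correlation_matrix(normalize_region_matrix(pair$cohort_a))
  expect_equal(largest_component_size(binarize_by_sparsity(net, 0.30)$A), 90)
})

test_that("component size is non-decreasing in sparsity", {
  for (s in 1:3) {
    pair <- quick_pair(seed = 10 + s, n_regions = 50)
    net <- partial_correlation_matrix(normalize_region_matrix(pair$cohort_a))
    sizes <- vapply(sparsity_grid(), function(sp) {
      largest_component_size(binarize_by_sparsity(net, sp)$A)
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("min_connected_sparsity agrees with an exhaustive scan", {
  pair <- quick_pair(seed = 6, n_regions = 40)
  net <- partial_correlation_matrix(normalize_region_matrix(pair$cohort_a))
  grid <- sparsity_grid()
  res <- min_connected_sparsity(net, grid, min_size = 35)
  # brute-force scan oracle
  oracle <- NA_real_
  for (s in grid) {
    if (largest_component_size(binarize_by_sparsity(net, s)$A) > 35) {
      oracle <- s
      break
    }
  }
  expect_equal(res$sparsity, oracle)
  expect_equal(nrow(res$curve), length(grid))
  # min_size = 0: first grid value qualifies
  expect_equal(min_connected_sparsity(net, grid, min_size = 0)$sparsity, grid[1])
  # unreachable requirement is flagged, not an error
  res2 <- min_connected_sparsity(net, grid, min_size = 1000)
  expect_false(res2$reached)
  expect_true(is.na(res2$sparsity))
})
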