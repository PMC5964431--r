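# Small named graphs and quick simulated cohorts used across test files.

graph_triangle <- function() {
  A <- matrix(0, 3, 3); A[upper.tri(A)] <- 1; A + t(A)
}

graph_path3 <- function() {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 3] <- 1; A + t(A)
}

graph_star <- function(leaves = 3) {
  n <- leaves + 1
  A <- matrix(0, n, n); A[1, 2:n] <- 1; A + t(A)
}

graph_complete <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0; A
}

# 4-cycle a-b-c-d plus chord a-c
graph_cycle4_chord <- function() {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[4, 1] <- A[1, 3] <- 1
  A + t(A)
}

# Test-local seed derivation (kept separate from package internals so the
# suite's seeds are stable whatever the implementation does).
derive_seed_acc <- function(a, b) {
  as.integer((a * 10007 + b * 97 + 12345) %% 2147483647)
}

# Small two-cohort simulation for fast integration-style tests.
quick_pair <- function(seed = 1, n_subjects = 22, n_regions = 40, ...) {
  simulate_cohort_pair(n_subjects = n_subjects, n_regions = n_regions,
                       seed = seed, ...)
}
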