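# Nonparametric group-reassignment permutation inference: subjects are
# pooled, relabelled preserving group sizes, and the full network chain
# (normalize -> partial correlation -> binarize -> metric) is recomputed per
# relabelling.

ensure_normalized <- function(cohort) {
  if (!inherits(cohort, "region_matrix")) stopf("expected a region_matrix")
  if (cohort$normalized) cohort else normalize_region_matrix(cohort)
}

# Pooled subject rows in a canonical (content-sorted) order, so the sampled
# relabellings are identical whichever way the two cohorts are passed in:
# with equal group sizes, swapping the cohort arguments then flips every
# observed difference's sign and leaves two-sided p-values unchanged.
canonical_pool <- function(Xa, Xb) {
  pooled <- rbind(Xa, Xb)
  pooled[do.call(order, as.data.frame(pooled)), , drop = FALSE]
}

# Metric value of one group's rows at a fixed sparsity. `rows` is the
# normalized subjects x regions matrix.
group_metric_value <- function(rows, metric, sparsity, shrinkage = 0.7,
                               n_null = 20, seed = 1L) {
  net <- partial_correlation_matrix(
    region_matrix(rows, normalized = TRUE), shrinkage = shrinkage)
  A <- binarize_by_sparsity(net, sparsity)$A
  switch(metric,
         C = clustering_coefficient(A)$C,
         L = characteristic_path_length(A),
         E_glob = global_efficiency(A),
         E_loc = local_efficiency(A),
         gamma = ,
         lambda = ,
         sigma = small_world_indices(A, n_null = n_null, seed = seed)[[metric]],
         stopf("unknown metric '%s'", metric))
}

group_bi <- function(rows, sparsity, shrinkage = 0.7) {
  net <- partial_correlation_matrix(
    region_matrix(rows, normalized = TRUE), shrinkage = shrinkage)
  A <- binarize_by_sparsity(net, sparsity)$A
  betweenness_normalized(A)$bi_node
}

#' Permutation test of a group-difference statistic
#'
#' Pools the two cohorts' subjects, reshuffles group labels preserving the
#' original group sizes, and recomputes `statistic` per relabelling. The
#' add-one permutation p-value is
#' `(1 + #qualifying null samples) / (1 + n_perm)`, so it is never 0:
#' qualifying means `null >= observed` for `tail = "greater"`,
#' `null <= observed` for `"less"`, and `|null| >= |observed|` for
#' `"two_sided"`.
#'
#' @param cohort_a,cohort_b [region_matrix()] cohorts (normalized
#'   automatically if raw).
#' @param statistic Function `(rows_a, rows_b) -> scalar` taking the two
#'   groups' normalized row matrices; see [metric_difference_statistic()].
#' @param n_perm Number of relabellings (>= 100; the headline analyses use
#'   1000 for hub comparisons and 2000 for metric curves).
#' @param tail One of `"greater"`, `"less"`, `"two_sided"`.
#' @param seed Integer RNG seed for the relabellings.
#' @return An object of class `null_distribution`: `statistic_name`,
#'   `observed`, `null_samples`, `n_perm`, `p_value`, `tail`, `seed`.
#' @export
permutation_test_statistic <- function(cohort_a, cohort_b, statistic,
                                       n_perm = 1000,
                                       tail = c("greater", "less", "two_sided"),
                                       seed = 1L) {
  tail <- match.arg(tail)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  cohort_a <- ensure_normalized(cohort_a)
  cohort_b <- ensure_normalized(cohort_b)
  Xa <- cohort_a$values
  Xb <- cohort_b$values
  if (ncol(Xa) != ncol(Xb)) stopf("cohorts must share the region set")
  n_a <- nrow(Xa)
  pooled <- canonical_pool(Xa, Xb)
  n_tot <- nrow(pooled)

  observed <- statistic(Xa, Xb)
  perms <- with_seed(seed, replicate(n_perm, sample.int(n_tot), simplify = FALSE))
  null_samples <- vapply(perms, function(idx) {
    statistic(pooled[idx[seq_len(n_a)], , drop = FALSE],
              pooled[idx[-seq_len(n_a)], , drop = FALSE])
  }, numeric(1))

  bad <- !is.finite(null_samples)
  if (mean(bad) > 0.10) {
    stopf("statistic non-finite in %.0f%% of permutations", 100 * mean(bad))
  }
  finite_null <- null_samples[!bad]
  k <- switch(tail,
              greater = sum(finite_null >= observed),
              less = sum(finite_null <= observed),
              two_sided = sum(abs(finite_null) >= abs(observed)))
  structure(list(statistic_name = attr(statistic, "name") %||% "statistic",
                 observed = observed, null_samples = null_samples,
                 n_perm = n_perm,
                 p_value = (1 + k) / (1 + length(finite_null)),
                 tail = tail, seed = as.integer(seed)),
            class = "null_distribution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: observed %.4g, p = %.4g (%s, %d permutations)\n",
              x$statistic_name, x$observed, x$p_value, x$tail, x$n_perm))
  invisible(x)
}

#' Build a metric-difference statistic for permutation testing
#'
#' Returns a statistic function computing
#' `metric(group A) - metric(group B)` through the full chain (partial
#' correlation at `shrinkage`, binarization at `sparsity`, metric).
#'
#' @param metric One of `"C"`, `"L"`, `"E_glob"`, `"E_loc"`, `"gamma"`,
#'   `"lambda"`, `"sigma"`.
#' @param sparsity Binarization sparsity.
#' @param shrinkage Partial-correlation shrinkage.
#' @param n_null Rewired nulls per network for the small-world metrics.
#' @param seed Seed for those nulls (fixed inside the statistic so the
#'   statistic is a deterministic function of the data).
#' @return Function `(rows_a, rows_b) -> scalar` with a `name` attribute.
#' @export
metric_difference_statistic <- function(metric, sparsity, shrinkage = 0.7,
                                        n_null = 20, seed = 1L) {
  force(metric); force(sparsity); force(shrinkage); force(n_null); force(seed)
  f <- function(rows_a, rows_b) {
    group_metric_value(rows_a, metric, sparsity, shrinkage, n_null, seed) -
      group_metric_value(rows_b, metric, sparsity, shrinkage, n_null, seed)
  }
  attr(f, "name") <- sprintf("%s difference at sparsity %.2f", metric, sparsity)
  f
}

#' Metric curves over the sparsity grid with permutation p-values
#'
#' For every grid sparsity and metric, computes both group values and a
#' permutation p-value. One set of relabellings is drawn per sparsity and
#' shared across metrics (one shuffle, all metrics), matching the joint
#' permutation procedure and saving recomputation.
#'
#' @param cohort_a,cohort_b [region_matrix()] cohorts.
#' @param grid Sparsity grid (default [sparsity_grid()]).
#' @param metrics Metrics to trace (default all seven).
#' @param n_perm Relabellings per sparsity (default 2000).
#' @param n_null Rewired nulls per network for gamma/lambda/sigma (default
#'   20 inside permutations; the observed values use `n_null_observed`).
#' @param n_null_observed Nulls for the observed group values (default 200).
#' @param tail `"auto"` (one-tailed in the observed direction, reported in
#'   the output) or `"two_sided"`.
#' @param shrinkage Partial-correlation shrinkage.
#' @param seed Master integer seed.
#' @param fdr Logical; if `TRUE`, adds a `p_adjusted` column with
#'   Benjamini-Hochberg adjustment across the grid within each metric
#'   (off by default: the headline procedure reports raw p-values).
#' @return Long data.frame: sparsity, metric, value_a, value_b, diff, tail,
#'   p_value (plus p_adjusted when `fdr = TRUE`).
#' @export
metric_sparsity_curves <- function(cohort_a, cohort_b, grid = sparsity_grid(),
                                   metrics = c("C", "L", "E_glob", "E_loc",
                                               "gamma", "lambda", "sigma"),
                                   n_perm = 2000, n_null = 20,
                                   n_null_observed = 200,
                                   tail = c("auto", "two_sided"),
                                   shrinkage = 0.7, seed = 1L, fdr = FALSE) {
  tail <- match.arg(tail)
  if (any(grid <= 0 | grid >= 1)) stopf("grid must lie in (0, 1)")
  cohort_a <- ensure_normalized(cohort_a)
  cohort_b <- ensure_normalized(cohort_b)
  Xa <- cohort_a$values
  Xb <- cohort_b$values
  n_a <- nrow(Xa)
  pooled <- canonical_pool(Xa, Xb)
  n_tot <- nrow(pooled)
  need_null <- any(metrics %in% c("gamma", "lambda", "sigma"))

  rows <- list()
  for (gi in seq_along(grid)) {
    s <- grid[gi]
    vals <- function(rows_, n_null_, seed_) {
      net <- partial_correlation_matrix(region_matrix(rows_, normalized = TRUE),
                                        shrinkage = shrinkage)
      A <- binarize_by_sparsity(net, s)$A
      eg <- global_efficiency(A)
      out <- c(C = clustering_coefficient(A)$C,
               L = if (eg > 0) 1 / eg else Inf,
               E_glob = eg,
               E_loc = local_efficiency(A),
               gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
      if (need_null) {
        sw <- small_world_indices(A, n_null = n_null_, seed = seed_)
        out[c("gamma", "lambda", "sigma")] <-
          c(sw$gamma, sw$lambda, sw$sigma)
      }
      out[metrics]
    }
    obs_a <- vals(Xa, n_null_observed, derive_seed(seed, 1000L + gi))
    obs_b <- vals(Xb, n_null_observed, derive_seed(seed, 2000L + gi))
    obs_diff <- obs_a - obs_b

    perms <- with_seed(derive_seed(seed, gi),
                       replicate(n_perm, sample.int(n_tot), simplify = FALSE))
    null_mat <- vapply(seq_along(perms), function(pi) {
      idx <- perms[[pi]]
      seed_p <- derive_seed(seed, 3000L + pi)
      vals(pooled[idx[seq_len(n_a)], , drop = FALSE], n_null, seed_p) -
        vals(pooled[idx[-seq_len(n_a)], , drop = FALSE], n_null, seed_p)
    }, numeric(length(metrics)))
    null_mat <- matrix(null_mat, nrow = length(metrics))

    for (mi in seq_along(metrics)) {
      nulls <- null_mat[mi, ]
      nulls <- nulls[is.finite(nulls)]
      d <- obs_diff[mi]
      if (tail == "two_sided") {
        this_tail <- "two_sided"
        k <- sum(abs(nulls) >= abs(d))
      } else if (d >= 0) {
        this_tail <- "greater"
        k <- sum(nulls >= d)
      } else {
        this_tail <- "less"
        k <- sum(nulls <= d)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sparsity = s, metric = metrics[mi],
        value_a = unname(obs_a[mi]), value_b = unname(obs_b[mi]),
        diff = unname(d), tail = this_tail,
        p_value = (1 + k) / (1 + length(nulls)))
    }
  }
  out <- do.call(rbind, rows)
  if (fdr) {
    out$p_adjusted <- stats::ave(out$p_value, out$metric,
                                 FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out
}

#' Compare normalized betweenness per region between groups
#'
#' At a fixed sparsity, computes each region's normalized betweenness `bi`
#' in both groups and a two-sided permutation p-value for the difference
#' `bi_A - bi_B` (one pooled set of relabellings for all regions). Regions
#' that are hubs (`bi >` threshold) in either group are flagged; output is
#' sorted by ascending p — the altered-hub screen.
#'
#' @param cohort_a,cohort_b [region_matrix()] cohorts.
#' @param sparsity Binarization sparsity (headline 0.21).
#' @param n_perm Relabellings (default 1000).
#' @param shrinkage Partial-correlation shrinkage.
#' @param hub_threshold Hub rule on `bi` (default 1.5, strict).
#' @param seed Integer RNG seed.
#' @return data.frame: region_id, bi_a, bi_b, diff, p_value, hub_a, hub_b,
#'   sorted by p_value.
#' @export
compare_hub_bi <- function(cohort_a, cohort_b, sparsity = 0.21, n_perm = 1000,
                           shrinkage = 0.7, hub_threshold = 1.5, seed = 1L) {
  cohort_a <- ensure_normalized(cohort_a)
  cohort_b <- ensure_normalized(cohort_b)
  Xa <- cohort_a$values
  Xb <- cohort_b$values
  if (ncol(Xa) != ncol(Xb)) stopf("cohorts must share the region set")
  n_a <- nrow(Xa)
  pooled <- canonical_pool(Xa, Xb)
  n_tot <- nrow(pooled)

  bi_a <- group_bi(Xa, sparsity, shrinkage)
  bi_b <- group_bi(Xb, sparsity, shrinkage)
  obs <- bi_a - bi_b

  perms <- with_seed(seed, replicate(n_perm, sample.int(n_tot), simplify = FALSE))
  exceed <- integer(length(obs))
  for (idx in perms) {
    d <- group_bi(pooled[idx[seq_len(n_a)], , drop = FALSE], sparsity, shrinkage) -
      group_bi(pooled[idx[-seq_len(n_a)], , drop = FALSE], sparsity, shrinkage)
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(region_id = cohort_a$region_ids,
                    bi_a = bi_a, bi_b = bi_b, diff = obs, p_value = p,
                    hub_a = bi_a > hub_threshold, hub_b = bi_b > hub_threshold)
  out[order(out$p_value, out$region_id), ]
}
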