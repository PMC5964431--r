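# End-to-end orchestration: simulate-or-load -> preprocess -> group networks
# -> graph metrics -> permutation statistics -> seed maps, with a JSON
# manifest making the run reproducible from its config and master seed.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the study-layout defaults: two
#' cohorts of 22 subjects, 90 regions, partial-correlation shrinkage 0.7,
#' headline sparsity 0.21 over the 0.06-0.40 grid, 200 rewired nulls,
#' 2000 permutations for metric curves and 1000 for hub comparison, hub
#' threshold bi > 1.5, FDR level q = 0.05. Override any entry via `...`.
#'
#' @param ... Named overrides of default entries.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "simulate",            # "simulate", "tables", or "volumes"
    # simulate mode
    n_subjects = 22, n_regions = 90, grid_shape = c(24, 24, 24),
    noise_sd = 0.5, alterations_a = list(), alterations_b = list(),
    generator = "modular", generator_args = list(),
    render_volumes = TRUE,
    # tables mode
    table_a = NULL, table_b = NULL,
    # volumes mode
    volumes_a = NULL, volumes_b = NULL, atlas_path = NULL,
    # preprocessing
    fwhm_mm = NULL, grayscale = FALSE, reference_region = NULL,
    # network + metrics
    shrinkage = 0.7, sparsity = 0.21, sparsity_grid = sparsity_grid(),
    min_component_size = 50, n_null = 200, swaps_per_edge = 10,
    # permutation inference
    n_perm_curves = 2000, n_perm_hubs = 1000,
    curve_metrics = c("C", "L", "E_glob", "E_loc"),
    n_null_perm = 20, run_curves = TRUE,
    # hubs + seed correlation
    hub_threshold = 1.5, seed_region_id = NULL, q = 0.05,
    # reproducibility
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config entries: %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage in analysis order — data acquisition (simulated or
#' loaded), preprocessing/reduction, group network estimation, graph metrics
#' with small-world indices, permutation group statistics (metric curves and
#' hub comparison), and seed-based voxel correlation comparison — and writes
#' all tables (TSV), maps (NIfTI) and a JSON manifest under `out_dir`.
#' Deterministic for a fixed config and master seed.
#'
#' @param config A [pipeline_config()] list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages_done <- character(0)
  current_stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(paste("failed at stage:", current_stage), conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", current_stage, conditionMessage(e))
  }

  res <- tryCatch({
    seed <- as.integer(config$seed)

    ## stage 1: acquire data ------------------------------------------------
    current_stage <- "acquire"
    atlas <- NULL
    volumes_a <- volumes_b <- NULL
    if (config$mode == "simulate") {
      sim <- do.call(simulate_cohort_pair, c(
        list(n_subjects = config$n_subjects, n_regions = config$n_regions,
             alterations_a = config$alterations_a,
             alterations_b = config$alterations_b, seed = seed,
             generator = config$generator),
        config$generator_args))
      raw_a <- sim$cohort_a
      raw_b <- sim$cohort_b
      if (config$render_volumes) {
        atlas <- make_toy_atlas(config$grid_shape, config$n_regions,
                                seed = derive_seed(seed, 10L))
        volumes_a <- render_subject_volumes(raw_a, atlas, config$noise_sd,
                                            seed = derive_seed(seed, 11L))
        volumes_b <- render_subject_volumes(raw_b, atlas, config$noise_sd,
                                            seed = derive_seed(seed, 12L))
      }
    } else if (config$mode == "tables") {
      raw_a <- read_region_matrix(config$table_a)
      raw_b <- read_region_matrix(config$table_b)
    } else if (config$mode == "volumes") {
      atlas <- read_atlas_nifti(config$atlas_path)
      volumes_a <- lapply(config$volumes_a, read_volume_nifti)
      volumes_b <- lapply(config$volumes_b, read_volume_nifti)
      raw_a <- raw_b <- NULL
    } else stopf("unknown mode '%s'", config$mode)
    stages_done <- c(stages_done, "acquire")

    ## stage 2: preprocess & reduce ----------------------------------------
    current_stage <- "preprocess"
    reduce <- function(vols) {
      volumes_to_region_matrix(vols, atlas, fwhm_mm = config$fwhm_mm,
                               grayscale = config$grayscale,
                               reference_region = config$reference_region)
    }
    if (config$mode == "volumes") {
      cohort_a <- reduce(volumes_a)
      cohort_b <- reduce(volumes_b)
    } else {
      cohort_a <- normalize_region_matrix(raw_a)
      cohort_b <- normalize_region_matrix(raw_b)
    }
    write_region_matrix(cohort_a, file.path(out_dir, "cohort_a_normalized.tsv"))
    write_region_matrix(cohort_b, file.path(out_dir, "cohort_b_normalized.tsv"))
    stages_done <- c(stages_done, "preprocess")

    ## stage 3: group networks ----------------------------------------------
    current_stage <- "networks"
    net_a <- binarize_by_sparsity(
      partial_correlation_matrix(cohort_a, config$shrinkage), config$sparsity)
    net_b <- binarize_by_sparsity(
      partial_correlation_matrix(cohort_b, config$shrinkage), config$sparsity)
    write_group_network(net_a, file.path(out_dir, "network_a_R.tsv"),
                        file.path(out_dir, "network_a_A.tsv"))
    write_group_network(net_b, file.path(out_dir, "network_b_R.tsv"),
                        file.path(out_dir, "network_b_A.tsv"))
    conn_a <- min_connected_sparsity(net_a, config$sparsity_grid,
                                     config$min_component_size)
    conn_b <- min_connected_sparsity(net_b, config$sparsity_grid,
                                     config$min_component_size)
    comp_curve <- rbind(cbind(group = "A", conn_a$curve),
                        cbind(group = "B", conn_b$curve))
    utils::write.table(comp_curve, file.path(out_dir, "component_sizes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages_done <- c(stages_done, "networks")

    ## stage 4: graph metrics -----------------------------------------------
    current_stage <- "metrics"
    met_a <- network_metrics(net_a$A, n_null = config$n_null,
                             seed = derive_seed(seed, 20L),
                             swaps_per_edge = config$swaps_per_edge)
    met_b <- network_metrics(net_b$A, n_null = config$n_null,
                             seed = derive_seed(seed, 21L),
                             swaps_per_edge = config$swaps_per_edge)
    summarize <- function(m, label) {
      data.frame(group = label, C = m$C, L = m$L, E_glob = m$E_glob,
                 E_loc = m$E_loc, gamma = m$gamma, lambda = m$lambda,
                 sigma = m$sigma)
    }
    utils::write.table(rbind(summarize(met_a, "A"), summarize(met_b, "B")),
                       file.path(out_dir, "network_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    node_tbl <- data.frame(region_id = cohort_a$region_ids,
                           B_a = met_a$B_node, bi_a = met_a$bi_node,
                           B_b = met_b$B_node, bi_b = met_b$bi_node)
    utils::write.table(node_tbl, file.path(out_dir, "node_betweenness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages_done <- c(stages_done, "metrics")

    ## stage 5: permutation group statistics --------------------------------
    current_stage <- "group_stats"
    curves <- NULL
    if (isTRUE(config$run_curves)) {
      curves <- metric_sparsity_curves(
        cohort_a, cohort_b, grid = config$sparsity_grid,
        metrics = config$curve_metrics, n_perm = config$n_perm_curves,
        n_null = config$n_null_perm, n_null_observed = config$n_null,
        shrinkage = config$shrinkage, seed = derive_seed(seed, 30L))
      utils::write.table(curves, file.path(out_dir, "metric_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    hubs <- compare_hub_bi(cohort_a, cohort_b, sparsity = config$sparsity,
                           n_perm = config$n_perm_hubs,
                           shrinkage = config$shrinkage,
                           hub_threshold = config$hub_threshold,
                           seed = derive_seed(seed, 31L))
    utils::write.table(hubs, file.path(out_dir, "hub_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages_done <- c(stages_done, "group_stats")

    ## stage 6: seed correlation --------------------------------------------
    current_stage <- "seed_correlation"
    seed_maps <- NULL
    if (!is.null(volumes_a) && !is.null(atlas)) {
      seed_region <- config$seed_region_id
      if (is.null(seed_region)) {
        # default: the most altered hub — the region with the largest
        # |bi| difference among hubs of either group, else the top-bi region
        cand <- hubs[hubs$hub_a | hubs$hub_b, ]
        seed_region <- if (nrow(cand)) {
          cand$region_id[which.max(abs(cand$diff))]
        } else hubs$region_id[which.max(pmax(hubs$bi_a, hubs$bi_b))]
      }
      seed_maps <- seed_group_compare(volumes_a, volumes_b, atlas,
                                      seed_region, q = config$q)
      write_volume_nifti(volume_image(seed_maps$r_map_a, atlas$voxel_size_mm),
                         file.path(out_dir, "seed_rmap_a.nii.gz"))
      write_volume_nifti(volume_image(seed_maps$r_map_b, atlas$voxel_size_mm),
                         file.path(out_dir, "seed_rmap_b.nii.gz"))
      write_volume_nifti(volume_image(seed_maps$z_diff_map, atlas$voxel_size_mm),
                         file.path(out_dir, "seed_zdiff.nii.gz"))
      write_volume_nifti(volume_image(seed_maps$p_map, atlas$voxel_size_mm),
                         file.path(out_dir, "seed_p.nii.gz"))
      write_volume_nifti(volume_image(seed_maps$fdr_mask + 0, atlas$voxel_size_mm),
                         file.path(out_dir, "seed_fdr_mask.nii.gz"))
      utils::write.table(
        mask_cluster_summary(seed_maps$fdr_mask, seed_maps$z_diff_map),
        file.path(out_dir, "seed_clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    stages_done <- c(stages_done, "seed_correlation")

    ## manifest --------------------------------------------------------------
    current_stage <- "manifest"
    cfg_json <- jsonlite::toJSON(config[!vapply(config, is.function, logical(1))],
                                 auto_unbox = TRUE, digits = NA, null = "null")
    cfg_file <- file.path(out_dir, "config.json")
    writeLines(cfg_json, cfg_file)
    manifest <- list(
      package = "metcovnet",
      version = as.character(utils::packageVersion("metcovnet")),
      master_seed = seed,
      stages = stages_done,
      config_md5 = unname(tools::md5sum(cfg_file)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    list(cohort_a = cohort_a, cohort_b = cohort_b, net_a = net_a, net_b = net_b,
         metrics_a = met_a, metrics_b = met_b, component_curves = comp_curve,
         curves = curves, hubs = hubs, seed_maps = seed_maps,
         manifest = manifest)
  }, error = on_fail)
  invisible(res)
}
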