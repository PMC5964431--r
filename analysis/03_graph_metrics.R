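#!/usr/bin/env Rscript
# Stage 3 — network parameters and hubs.
#
# Computes clustering, characteristic path length (harmonic), global and
# local efficiency, the small-world indices gamma/lambda/sigma against 200
# degree-preserving rewired nulls, and normalized-betweenness hubs
# (bi > 1.5) for each group's 21%-sparsity network.

library(metcovnet)

out <- "results/analysis"
read_adj <- function(f) {
  as.matrix(read.table(f, sep = "\t", header = TRUE, row.names = 1,
                       check.names = FALSE))
}
A_a <- unname(read_adj(file.path(out, "network_a_A.tsv")))
A_b <- unname(read_adj(file.path(out, "network_b_A.tsv")))

met_a <- network_metrics(A_a, n_null = 200, seed = 11L)
met_b <- network_metrics(A_b, n_null = 200, seed = 12L)

summary_tbl <- do.call(rbind, lapply(list(A = met_a, B = met_b), function(m) {
  data.frame(C = m$C, L = m$L, E_glob = m$E_glob, E_loc = m$E_loc,
             gamma = m$gamma, lambda = m$lambda, sigma = m$sigma)
}))
summary_tbl <- cbind(group = rownames(summary_tbl), summary_tbl)
write.table(summary_tbl, file.path(out, "network_metrics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

hub_tbl <- data.frame(region_id = seq_len(nrow(A_a)),
                      bi_a = met_a$bi_node, bi_b = met_b$bi_node,
                      hub_a = met_a$bi_node > 1.5, hub_b = met_b$bi_node > 1.5)
write.table(hub_tbl, file.path(out, "hub_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Group A: C =", round(met_a$C, 3), " L =", round(met_a$L, 3),
    " sigma =", round(met_a$sigma, 3), "\n")
cat("Group B: C =", round(met_b$C, 3), " L =", round(met_b$L, 3),
    " sigma =", round(met_b$sigma, 3), "\n")
cat("Both sigma > 1:", met_a$sigma > 1 && met_b$sigma > 1,
    "- small-world topology in both groups.\n")
cat("Hubs (bi > 1.5): A =", paste(detect_hubs(met_a$bi_node), collapse = " "),
    "| B =", paste(detect_hubs(met_b$bi_node), collapse = " "), "\n")
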