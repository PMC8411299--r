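#!/usr/bin/env Rscript

# Stage 3: build the five transfer networks and compute scaled degree
# centralities, centrality ratios, and their natural-log transform.
#
# Reads  results/episodes/transfers.csv
# Writes results/networks/edges_<label>.tsv and centrality_<label>.csv
#        for labels all, ed_ip, ip_ip, op, no_op.

suppressPackageStartupMessages(library(egsnet))

tr <- utils::read.csv(file.path("results", "episodes", "transfers.csv"),
                      stringsAsFactors = FALSE)
out_dir <- file.path("results", "networks")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

networks <- build_all_networks(tr)
for (lbl in network_labels()) {
  nw <- networks[[lbl]]
  cent <- log_transform_ratios(degree_centralities(nw, convention = "weighted"))
  excl <- attr(cent, "exclusions")
  utils::write.table(nw$edges, file.path(out_dir, paste0("edges_", lbl, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cent, file.path(out_dir, paste0("centrality_", lbl, ".csv")),
                   row.names = FALSE)
  cat(sprintf(
    "%-6s %4d nodes, %5d edges, weight %5d; median in/out %.2f / %.2f; log-ratio excluded %d\n",
    lbl, length(nw$nodes), nrow(nw$edges), sum(nw$edges$weight),
    stats::median(cent$in_degree_scaled),
    stats::median(cent$out_degree_scaled), sum(excl)))
}
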