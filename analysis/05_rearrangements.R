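#!/usr/bin/env Rscript

# Stage 5: rearrangement analysis between the ancestral and derived genomes
# from stage 1. Shared single-copy nonmobile genes define signed gene
# orders; maximal colinear runs are the syntenic clusters; the breakpoint
# distance is the desk-scale rearrangement statistic; mobile elements
# within +/-3 kb of cluster boundaries are tallied.

library(endoerode)

fa <- read_feature_table("results/ancestral_features.tsv", "tsv")
fb <- read_feature_table("results/derived_features.tsv", "tsv")
truth_perm <- as.integer(strsplit(readLines(
  "results/truth_permutation.tsv"), "\t")[[1]])

so <- shared_signed_orders(fa, fb)
stopifnot(identical(so$b$order, truth_perm))
message(length(so$a$order), " shared single-copy genes; derived order ",
        "matches the planted permutation")

d <- breakpoint_distance(so$b$order)
message("breakpoint distance: ", d, " (circular framing: ",
        breakpoint_distance(so$b$order, circular = TRUE), ")")
message("greedy reversal upper bound: ",
        greedy_reversal_count(so$b$order), " reversals")

# tally flanks in the derived genome, where the IS scars live
so_rev <- shared_signed_orders(fb, fa)
cl <- synteny_clusters(so_rev)
mean_size <- mean(cl$a_end - cl$a_start)
message(nrow(cl), " syntenic clusters, mean span ",
        format(round(mean_size, 2), big.mark = ","), " bp")
tally <- flanking_element_tally(cl, fb, window = 3000L)
message("clusters flanked within 3 kb by: ",
        paste(names(tally$counts), tally$counts, collapse = ", "))

utils::write.table(cl, "results/synteny_clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(tally$per_cluster, "results/cluster_flanks.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(c(paste("breakpoint_distance", d, sep = "\t"),
             paste("clusters", nrow(cl), sep = "\t"),
             paste("mean_cluster_span_bp", round(mean_size, 2), sep = "\t")),
           "results/rearrangement_stats.tsv")
message("wrote results/{synteny_clusters,cluster_flanks,rearrangement_stats}.tsv")
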