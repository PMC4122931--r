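#!/usr/bin/env Rscript

# Stage 1: build the synthetic study system. One ancestral chromosome is
# generated, a rearranged sister genome is derived from it by inversions
# with insertion-sequence scars at the breakpoints, and the ancestral copy
# is degraded into an N-gapped draft assembly with repeat families planted
# around the gaps -- the assembly state the gap-closure stage starts from.
#
# Outputs under results/: FASTA + feature TSVs for both genomes, the gapped
# draft, and truth tables for gaps, repeats and the inversion permutation.

library(endoerode)

seed <- 20260928L
dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = seed)

g <- generate_genome(cfg)
message("ancestral genome: ", scaffold_lengths(g$scaffolds), " bp, ",
        nrow(g$features), " genes")

inv <- apply_inversions(g$scaffolds, g$features, cfg$n_inversions,
                        seed = seed)
message("derived genome: ", cfg$n_inversions, " inversions, ",
        sum(inv$features$klass == "IS"), " IS scars, truth permutation ",
        paste(inv$truth$perm[1:8], collapse = " "), " ...")

sg <- scaffoldize(g$scaffolds, g$features, cfg$n_gaps, cfg$gap_size_range,
                  seed = seed)
pr <- plant_repeats(sg$scaffolds, g$features, cfg$n_repeat_families,
                    cfg$repeat_copies, cfg$repeat_length, seed = seed,
                    gaps = sg$truth)
message("draft assembly: ", nrow(sg$truth), " gaps, ", nrow(pr$truth),
        " planted repeat copies (", cfg$n_repeat_families, " families)")

write_fasta(g$scaffolds, "results/ancestral.fa")
write_feature_table(g$features, "results/ancestral_features.tsv")
write_fasta(inv$scaffolds, "results/derived.fa")
write_feature_table(inv$features, "results/derived_features.tsv")
write_fasta(pr$scaffolds, "results/draft_assembly.fa")
utils::write.table(sg$truth[, c("scaffold_id", "start", "end")],
                   "results/truth_gaps.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(pr$truth, "results/truth_repeats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(paste(inv$truth$perm, collapse = "\t"),
           "results/truth_permutation.tsv")
message("wrote results/{ancestral,derived,draft_assembly}.fa and truth tables")
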