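#!/usr/bin/env Rscript
# Step 3: library specificity, arm preference and switching, duplicate
# mature grouping, genomic clusters and chromosome densities for the kept
# candidates.
#
# Reads results/simulation + results/filtering, writes results/characterize.

library(sheepmir)

dir.create("results/characterize", showWarnings = FALSE, recursive = TRUE)

precursors <- read_precursor_table("results/simulation/precursors.tsv")
chrom_lengths <- read_chrom_lengths("results/simulation/chrom_lengths.tsv")
report <- utils::read.delim("results/filtering/filter_report.tsv")
kept <- precursors[precursors$id %in% report$id[report$status == "kept"], ]
kept_novel <- kept[!kept$is_known, ]
libs <- library_cols(kept)[1:2]

spec <- classify_specificity(kept_novel, libs)
cat("Novel precursor specificity totals:\n")
print(spec$totals)

arms <- arm_profile(kept_novel, libs)
for (lib in libs) {
  d <- arms[[paste0("dominant_", lib)]]
  cat(sprintf("5p dominant in %s: %d/%d (%.2f%%)\n", lib,
              sum(d == "5p", na.rm = TRUE), sum(!is.na(d)),
              100 * mean(d[!is.na(d)] == "5p")))
}
cat("Arm switches between", paste(libs, collapse = " and "), ":",
    sum(arms$switch_flag), "\n")

dups <- duplicate_mature_groups(kept_novel)
cat("Precursor groups sharing one mature sequence:",
    length(unique(dups$mature_seq)), "\n")

clusters <- detect_clusters(kept, max_gap = 10000)
clusters_novel <- detect_clusters(kept_novel, max_gap = 10000)
cat("Clusters (all kept):", nrow(clusters), "; novel-only:",
    nrow(clusters_novel), "holding",
    sum(clusters_novel$n_members), "precursors\n")
write_bed(clusters, "results/characterize/clusters.bed")

cs <- chromosome_summary(kept, chrom_lengths)
cat(sprintf("Mean novel precursors per chromosome: %.1f; densest: %s (%.2f/Mbp)\n",
            mean(cs$novel), cs$chrom[which.max(cs$density)],
            max(cs$density)))

utils::write.table(spec$precursor_calls,
                   "results/characterize/specificity.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(arms, "results/characterize/arm_profiles.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(dups, "results/characterize/duplicate_matures.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cs, "results/characterize/chromosome_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
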