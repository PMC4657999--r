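#!/usr/bin/env Rscript
# Step 2: pick the detection-score cutoff from the signal-to-noise table,
# apply the retention filters, tier surviving novel candidates by
# conservation and assign deterministic names.
#
# Reads results/simulation (step 1), writes results/filtering.

library(sheepmir)

dir.create("results/filtering", showWarnings = FALSE, recursive = TRUE)

precursors <- read_precursor_table("results/simulation/precursors.tsv")
hits <- read_homology_table("results/simulation/homology_hits.tsv")
snr <- read_snr_table("results/simulation/snr.tsv")
homologs <- read_fasta_seqs("results/simulation/homolog_matures.fa")

cutoff <- select_score_cutoff(snr, min_snr = 10)
cat("Score cutoff:", cutoff, "(lowest cutoff with SNR above 10:1; SNR",
    snr$snr[snr$cutoff == cutoff], ")\n")

report <- apply_candidate_filters(precursors, hits, score_cutoff = cutoff)
write_filter_report(report, "results/filtering/filter_report.tsv")
cat("Kept", length(report$kept), "candidates; dropped",
    length(report$dropped), ":\n")
print(table(report$dropped))

kept_novel <- precursors[precursors$id %in% report$kept &
                           !precursors$is_known, ]
tiers <- assign_tiers(unique(kept_novel$id), hits)
cat("Conservation tiers of the", length(unique(kept_novel$id)),
    "kept novel precursors:\n")
print(table(tiers$tier))

names_df <- assign_names(kept_novel, tiers, homologs)
fams <- group_families(names_df)
cat("Assigned", nrow(names_df), "unique names in",
    length(fams), "families;",
    sum(grepl("^oar-miR-N", names_df$name)),
    "provisional sheep-specific N-names.\n")

utils::write.table(tiers[, c("precursor_id", "tier", "n_species")],
                   "results/filtering/tiers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(names_df, "results/filtering/names.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
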