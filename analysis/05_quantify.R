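#!/usr/bin/env Rscript
# Step 5: median-of-ratios normalization and no-replicate fold change
# between the two libraries, plus qRT-PCR relative quantification of the LV
# validation panels (study input tables shipped with the package).
#
# Reads results/simulation + results/filtering, writes results/quantify.

library(sheepmir)

dir.create("results/quantify", showWarnings = FALSE, recursive = TRUE)

precursors <- read_precursor_table("results/simulation/precursors.tsv")
report <- utils::read.delim("results/filtering/filter_report.tsv")
kept <- precursors[precursors$id %in% report$id[report$status == "kept"], ]
libs <- library_cols(kept)[1:2]

counts <- mature_count_matrix(kept, libs)
sf <- size_factors(counts)
cat(sprintf("Size factors: %s = %.3f, %s = %.3f\n",
            libs[1], sf[[1]], libs[2], sf[[2]]))

fc <- fold_change(counts, sf, libs)
fin <- fc[is.finite(fc$fc) & fc$fc > 0, ]
top <- fin[order(-fin$fc), ][1:5, ]
cat("Top", libs[1], "-enriched matures (normalized fold change):\n")
print(top, digits = 3)
utils::write.table(fc, "results/quantify/fold_changes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (panel in c("novel", "known")) {
  f <- system.file("extdata", sprintf("qpcr_ct_%s_lv.tsv", panel),
                   package = "sheepmir")
  q <- qpcr_quantify(read_ct_table(f), control = "U6", ct_max = 35)
  cat(sprintf("qRT-PCR %s panel: %d/%d assays expressed (Ct < 35)\n",
              panel, sum(q$expressed[q$assay != "U6"]),
              sum(q$assay != "U6")))
  print(q, digits = 4)
  utils::write.table(q, sprintf("results/quantify/qpcr_%s.tsv", panel),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
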