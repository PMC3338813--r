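#!/usr/bin/env Rscript
# delta-delta-Ct quantification of the target transcripts, normalised to
# the ribosomal protein L24 reference, reported with the signed fold
# convention (values below 1 as negative reciprocals).

library(molitoR)

dat <- "results/data"
dir.create("results", showWarnings = FALSE)

records <- read_ct_table(file.path(dat, "qpcr_ct.tsv"))
truth <- read.delim(file.path(dat, "qpcr_truth.tsv"))
reference <- "rpl24"

ft <- qpcr_fold_table(records, reference = reference)
write.table(ft, "results/qpcr_folds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("relative expression (treated vs control, reference", reference, "):\n")
merged <- merge(ft, truth, by = "gene")
print(merged[, c("gene", "fold", "signed_fold", "ddct")],
      row.names = FALSE, digits = 4)
cat("('fold' is estimated, 'signed_fold' is the generator truth)\n")
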