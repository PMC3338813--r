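#!/usr/bin/env Rscript
# Generate the synthetic study dataset every later analysis step reads.
#
# The contig stage mirrors the scale of the real experiment (1,318 control
# and 1,140 Cry3Aa-treated contigs; 134,090 and 124,287 reads; log-normal
# contig lengths around 780 bp) with ten leaf GO terms spiked at fold 5 in
# the treated group. The microarray stage is a 2-condition x {6,12,24} h
# dye-swapped design with two biological replicates per cell; the qPCR
# stage carries the two chitin-binding-domain-3 transcripts of interest
# (true folds 37.9 and -7.2) normalised to ribosomal protein L24.

library(molitoR)

seed <- 42
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed, profile = "study")

ont <- simulate_ontology(cfg)
leaves <- spike_candidates(ont)
set.seed(seed)
spiked <- data.frame(term = sample(leaves, 10), fold = 5)
cfg$contigs$spiked <- spiked

exp <- simulate_contig_experiment(cfg, ont)
write_obo(ont, file.path(out, "ontology.obo"))
write_contig_table(exp$contigs, file.path(out, "contigs.tsv"))
write_annotation_table(exp$annotations, file.path(out, "annotations.tsv"))
write.table(exp$truth, file.path(out, "contig_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

arr <- simulate_microarray(cfg)
write_expression_matrix(arr$em, file.path(out, "array_values.tsv"),
                        file.path(out, "array_samples.tsv"))
write.table(arr$truth, file.path(out, "array_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

qp <- simulate_qpcr(cfg)
write_ct_table(qp$records, file.path(out, "qpcr_ct.tsv"))
write.table(qp$truth, file.path(out, "qpcr_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("ontology:", nrow(ont$terms), "terms;",
    nrow(exp$contigs), "contigs;",
    sum(exp$contigs$reads), "reads;",
    nrow(spiked), "spiked terms\n")
cat("microarray:", nrow(arr$em$values), "probes x", ncol(arr$em$values),
    "samples;", nrow(arr$truth), "DE probes\n")
cat("qPCR:", length(unique(qp$records$gene)), "genes,",
    nrow(qp$records), "Ct measurements\n")
cat("inputs written under", out, "\n")
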