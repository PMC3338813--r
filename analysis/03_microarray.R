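#!/usr/bin/env Rscript
# Temporal microarray stage: mean-scaling normalisation, per-time
# control-vs-treated t tests, all-times ANOVA, Venn overlap of the
# significant sets, PCA of the sample profiles and Manhattan /
# average-linkage clustering.

library(molitoR)

dat <- "results/data"
dir.create("results", showWarnings = FALSE)
alpha <- 0.05

em <- read_expression_matrix(file.path(dat, "array_values.tsv"),
                             file.path(dat, "array_samples.tsv"))
truth <- read.delim(file.path(dat, "array_truth.tsv"))
nem <- normalize_intensities(em)

sig <- list()
for (tm in sort(unique(nem$samples$time_h))) {
  de <- pairwise_de(nem, tm)
  write.table(de, sprintf("results/de_pairwise_%02dh.tsv", tm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  up <- sum(de$p < alpha & de$fold > 0)
  dn <- sum(de$p < alpha & de$fold < 0)
  cat(sprintf("%2d h: %d induced, %d repressed at p < %.2f (of %d probes)\n",
              tm, up, dn, alpha, nrow(de)))
  sig[[sprintf("%dh", tm)]] <- de$probe_id[de$p < alpha]
}

vc <- venn_counts(sig)
write.table(data.frame(region = names(vc), count = as.integer(vc)),
            "results/venn_significant.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Venn regions:", paste(names(vc), vc, sep = "=", collapse = "  "), "\n")

av <- anova_de(nem)
write.table(av, "results/de_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("ANOVA (control vs all times): %d probes at p < %.2f, %d at q <= %.2f\n",
            sum(av$p < alpha), alpha, sum(av$q <= alpha), alpha))
cat(sprintf("  truth probes among top-%d by ANOVA q: %d of %d\n",
            nrow(truth), sum(av$probe_id[order(av$q)][seq_len(nrow(truth))] %in%
                               truth$probe_id), nrow(truth)))

pc <- pca_samples(nem)
write.table(data.frame(sample_id = rownames(pc$scores), pc$scores,
                       check.names = FALSE),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pc$proportion[1], 100 * pc$proportion[2]))

hc <- hcluster_manhattan_average(nem)
writeLines(dendrogram_newick(hc), "results/sample_dendrogram.nwk")
cat("sample dendrogram written (Manhattan distance, average linkage)\n")
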