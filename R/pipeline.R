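#' Reference bookkeeping of the gut 454 dataset the simulator emulates
#'
#' Per-group usable read and assembled contig counts of the T. molitor
#' control and Cry3Aa-fed gut transcriptome (separate-assembly run), the
#' printed total of usable reads, and the number of contigs with a
#' significant BLASTx hit (e < 1e-5) against NCBI nr. These numbers anchor
#' the simulator defaults and support simple arithmetic consistency
#' checks; the raw reads themselves are not redistributed with the
#' package.
#'
#' @return list with `groups` (data.frame: group, reads, contigs,
#'   total_nt), `total_usable_reads`, `nr_hit_contigs`.
#' @export
assembly_reference <- function() {
  list(
    groups = data.frame(
      group = c("control", "treated"),
      reads = c(134090L, 124287L),
      contigs = c(1318L, 1140L),
      total_nt = c(1026138L, 898431L),
      stringsAsFactors = FALSE),
    total_usable_reads = 258377L,
    nr_hit_contigs = 2121L)
}

#' Run the full pipeline on simulated data
#'
#' Generates a tiny-profile (or study-profile) dataset, runs every stage
#' in order -- ontology + contig experiment -> quantitative and
#' qualitative enrichment; microarray -> normalization, per-time t tests,
#' ANOVA, Venn overlaps, PCA, sample clustering; qPCR -> signed fold table
#' -- and writes all inputs, outputs and a checksum manifest under
#' `out_dir`. Rerunning with the same seed reproduces every file
#' byte-identically.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param profile simulation profile, `"tiny"` (default) or `"study"`.
#' @param spiked optional data.frame (`term`, `fold`) of spiked terms for
#'   the contig stage; default spikes 3 terms at fold 5.
#' @param alpha significance cut-off used across stages.
#' @param ... overrides passed to [simulation_config()].
#' @return invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(seed, out_dir, profile = "tiny", spiked = NULL,
                         alpha = 0.05, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- simulation_config(seed, profile, ...)
  paths <- list()
  pth <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  stage("enrichment", {
    ont <- simulate_ontology(cfg)
    if (is.null(spiked)) {
      leaves <- spike_candidates(ont)
      spiked <- data.frame(term = leaves[seq_len(min(3L, length(leaves)))],
                           fold = rep(5, min(3L, length(leaves))))
    }
    cfg$contigs$spiked <- spiked
    exp <- simulate_contig_experiment(cfg, ont)
    paths$obo <- write_obo(ont, pth("ontology.obo"))
    paths$contigs <- write_contig_table(exp$contigs, pth("contigs.tsv"))
    paths$annotations <- write_annotation_table(exp$annotations,
                                                 pth("annotations.tsv"))
    utils::write.table(exp$truth, pth("contig_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$contig_truth <- pth("contig_truth.tsv")
    ann <- propagate_annotations(exp$annotations, ont)
    quant <- run_enrichment(exp$contigs, ann, ont,
                            enrichment_config(mode = "quantitative", alpha = alpha))
    qual <- run_enrichment(exp$contigs, ann, ont,
                           enrichment_config(mode = "qualitative", alpha = alpha))
    paths$enrichment_quantitative <- write_enrichment_table(
      quant, pth("enrichment_quantitative.tsv"))
    paths$enrichment_qualitative <- write_enrichment_table(
      qual, pth("enrichment_qualitative.tsv"))
  })

  stage("arraydiff", {
    sim <- simulate_microarray(cfg)
    paths$array_values <- pth("array_values.tsv")
    paths$array_samples <- pth("array_samples.tsv")
    write_expression_matrix(sim$em, paths$array_values, paths$array_samples)
    utils::write.table(sim$truth, pth("array_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$array_truth <- pth("array_truth.tsv")
    nem <- normalize_intensities(sim$em)
    sig <- list()
    for (tm in cfg$array$times) {
      de <- pairwise_de(nem, tm)
      f <- pth(sprintf("de_pairwise_%02dh.tsv", tm))
      utils::write.table(de, f, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[[sprintf("de_%dh", tm)]] <- f
      sig[[sprintf("%dh", tm)]] <- de$probe_id[de$p < alpha]
    }
    vc <- venn_counts(sig)
    utils::write.table(data.frame(region = names(vc), count = as.integer(vc)),
                       pth("venn_significant.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$venn <- pth("venn_significant.tsv")
    av <- anova_de(nem)
    utils::write.table(av, pth("de_anova.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$anova <- pth("de_anova.tsv")
    pc <- pca_samples(nem)
    sc <- data.frame(sample_id = rownames(pc$scores), pc$scores,
                     check.names = FALSE)
    utils::write.table(sc, pth("pca_scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$pca <- pth("pca_scores.tsv")
    writeLines(dendrogram_newick(hcluster_manhattan_average(nem)),
               pth("sample_dendrogram.nwk"))
    paths$dendrogram <- pth("sample_dendrogram.nwk")
  })

  stage("qpcr", {
    sim <- simulate_qpcr(cfg)
    paths$ct_table <- write_ct_table(sim$records, pth("qpcr_ct.tsv"))
    utils::write.table(sim$truth, pth("qpcr_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$qpcr_truth <- pth("qpcr_truth.tsv")
    ft <- qpcr_fold_table(sim$records, reference = cfg$qpcr$reference)
    utils::write.table(ft, pth("qpcr_folds.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$qpcr_folds <- pth("qpcr_folds.tsv")
  })

  stage("manifest", {
    files <- sort(unlist(paths))
    manifest <- data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE)
    attr_lines <- c(sprintf("# seed: %d", as.integer(seed)),
                    sprintf("# profile: %s", profile),
                    sprintf("# package: molitoR %s",
                            as.character(utils::packageVersion("molitoR"))))
    con <- file(pth("manifest.tsv"), "wt")
    writeLines(attr_lines, con)
    utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths$manifest <- pth("manifest.tsv")
  })

  invisible(paths)
}
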