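# molitoR

Analysis pipeline for the transcriptional response of the *Tenebrio
molitor* (yellow mealworm) larval gut to *Bacillus thuringiensis* Cry3Aa
protoxin. The package is aimed at researchers analysing 454-era RNA-Seq
contig sets, custom two-colour microarrays and qPCR follow-ups in
organisms without a sequenced genome, where per-contig read counts are the
only abundance signal available.

## What it computes

**Read- and length-weighted GO enrichment.** Classical (Blast2GO-style)
enrichment applies Fisher's exact test to contig presence, discarding read
abundance. The core statistic here weights every contig by its reads and
length: for a GO term *t* and contig group *g* (control or Cry3Aa-treated),

    W_t,g = scale * R_t,g / L_t,g

where `R_t,g` is the summed read count and `L_t,g` the summed length (bp)
of the contigs annotated to *t* (true-path propagated), and
`scale = 1000` puts `W` in reads per kilobase. Each term's 2×2 table
contrasts the rounded weight of its contigs with the rounded weight of the
remaining contigs in each group ("function annotated" / "function not
annotated"), and a two-sided Fisher's exact test is applied. The reporting
cascade follows the study design: Benjamini–Hochberg FDR at 0.05, fold
change different from 1 (ratio of within-group relative abundances), at
least 2 supporting contigs, pruning of terms with a significant
descendant, and a score restriction (`max_g W_t,g > 100`). The qualitative
contig-presence test is available through the same interface
(`mode = "qualitative"`).

**Temporal microarray stage.** Mean-scaling normalisation and log2
transform; per-exposure-time (6/12/24 h) control-vs-treated pooled
Student t tests with BH correction and signed folds (values below 1
reported as negative reciprocals, e.g. −5.68); one-way ANOVA of control
against all exposure times; 3-set Venn overlap counts; PCA of sample
profiles; Manhattan-distance/average-linkage sample clustering with
Newick export.

**qPCR stage.** ΔΔCt relative quantification against a reference gene
(ribosomal protein L24 in the study design): fold = 2^(−ΔΔCt), with
technical replicates averaged within biological replicates first and the
same signed reporting convention.

**Synthetic data.** Seeded generators emulate the study scale (1,318 +
1,140 contigs; 134,090 + 124,287 reads; log-normal contig lengths; a
random GO-like DAG; a dye-swapped 2×3 time-course array; Ct tables with a
stable reference), with ground-truth tables so every stage's recovery is
testable without the original raw data.

## Worked example

```r
library(molitoR)

cfg <- simulation_config(11, contigs = list(
  n_contigs = c(control = 300L, treated = 300L),
  total_reads = c(control = 15000L, treated = 15000L),
  n_terms = 40L))
ont <- simulate_ontology(cfg)
cfg$contigs$spiked <- data.frame(term = spike_candidates(ont)[1], fold = 5)
exp <- simulate_contig_experiment(cfg, ont)
ann <- propagate_annotations(exp$annotations, ont)
res <- run_quantitative_enrichment(exp$contigs, ann, ont)
subset(res, reported,
       select = c(term, weight_control, weight_treated, fold, direction, q))
```

```
        term weight_control weight_treated     fold direction            q
1 GO:0000022       65.29592       311.2583 4.982998  enriched 1.077954e-12
```

The one spiked term (fold 5 in the treated group) is the one reported
term; its weights say its contigs carry ~65 reads/kb in the control
contig set and ~311 reads/kb in the treated set, a relative-abundance
fold of ~5.0, q ≪ 0.05.

The full workflow over a study-scale dataset is scripted under
`analysis/` (run from the repository root, in order):

```sh
Rscript analysis/01_simulate.R     # writes results/data/ (inputs + truth)
Rscript analysis/02_enrichment.R   # qualitative + quantitative GO enrichment
Rscript analysis/03_microarray.R   # normalise, t tests, ANOVA, Venn, PCA, clustering
Rscript analysis/04_qpcr.R         # delta-delta-Ct folds
```

At the default seed, `02_enrichment.R` reports exactly the 10 spiked
terms (TPR 1.00, FDR 0.00) from 200 tested, and `04_qpcr.R` recovers
42.7-fold induction / −7.2-fold repression for the two
chitin-binding-domain-3 transcripts whose true folds are 37.9 and −7.2.
`run_pipeline(seed, out_dir)` performs the same end-to-end run
programmatically and writes a checksum manifest; reruns with the same
seed are byte-identical.

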