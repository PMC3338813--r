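---
title: "Methods: weighted GO enrichment, temporal expression and qPCR in the Cry3Aa gut response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted GO enrichment, temporal expression and qPCR in the Cry3Aa gut response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molitoR)
```

# Background and scope

When a transcriptome is sequenced without a reference genome — as for the
*Tenebrio molitor* larval gut exposed to *Bacillus thuringiensis* Cry3Aa
protoxin — the units of analysis are assembled contigs, each carrying a
length and the number of reads that built it. The read count is the only
abundance signal, and a functional enrichment analysis that ignores it
(the classical contig-presence Fisher test) discards most of the
information in the experiment. molitoR implements the quantitative
alternative: a Fisher's exact test over read-abundance weights, together
with the surrounding stages of such a study — true-path GO annotation
handling, a temporal two-colour microarray differential-expression
analysis, and ΔΔCt qPCR verification — plus generators that simulate all
three data types with known ground truth.

Out of scope: sequencing, assembly, BLAST/Blast2GO annotation retrieval,
probe design and image quantification. Contig tables, annotations,
intensities and Ct values are inputs.

# The weighted enrichment statistic

For term $t$ and group $g \in \{\text{control}, \text{treated}\}$, over
the contigs of $g$ whose (propagated) annotation set contains $t$:

$$W_{t,g} = s \cdot \frac{R_{t,g}}{L_{t,g}},$$

with $R$ the summed reads, $L$ the summed length in bp and $s = 1000$ the
`scale`, so $W$ is in reads per kilobase — a length-normalised abundance
comparable across terms. The per-term 2×2 table has rows = groups and
columns "function annotated" / "function not annotated":

$$\begin{pmatrix} [W_{t,T}] & [W_{t,T} + W_{\bar t,T}] - [W_{t,T}] \\
[W_{t,C}] & [W_{t,C} + W_{\bar t,C}] - [W_{t,C}] \end{pmatrix}$$

where $W_{\bar t,g}$ is the weight of the contigs *not* annotated to $t$
and $[\cdot]$ is round-half-even. A two-sided Fisher's exact test (sum of
hypergeometric probabilities not exceeding the observed one, relative
tolerance $10^{-7}$) yields $p$; Benjamini–Hochberg adjustment across the
tested terms yields $q$.

**Why the complement, not the dataset total.** Two constructions of the
"not annotated" cell are defensible: the weight of the complement contigs
(used here), or the whole-group weight $s R_g / L_g$ minus the term
weight. The second is degenerate: $W$ is a coverage, so any term whose
contigs are at least averagely covered has $W_{t,g} \ge s R_g/L_g$ and the
complement cell clamps to zero, destroying the contrast — under a null in
which reads are proportional to length, *every* term sits at the group
coverage and every table degenerates. The complement construction keeps
both margins informative; the dataset-total convention remains available
via `enrichment_config(complement = "dataset")` for comparison.

**Integerisation.** Fisher's test needs integer cells while $W$ is real.
Cells are rounded (round-half-even, the default of R's `round`),
negative complements are clamped to zero with a warning, and `scale`
controls the granularity: at $s = 1000$ the cells are of order
$10$–$10^3$ for the study-scale data. Because the rounded weights
fluctuate less than Poisson counts of the same size, the test is
conservative — its attained type-I rate sits below the nominal level,
which the test suite checks as a one-sided guarantee (an exact discrete
test can never be held to a two-sided band around the nominal level).

**Fold and direction.** The fold is the ratio of within-group relative
abundances $(W_{t,T}/T_T) / (W_{t,C}/T_C)$ with $T_g = s R_g / L_g$ the
whole-group weight; direction is enriched when the treated proportion is
larger, repressed otherwise. A zero control proportion gives the $+\infty$
sentinel; both zero gives `NA` and the term is flagged.

**Reporting cascade.** A term is *reported* when $q \le \alpha$ (default
0.05) and no flag is set:

* `fold_filtered` — fold equal to 1 (no change), quantitative mode;
* `min_contig_filtered` — fewer than 2 supporting contigs across groups;
* `child_pruned` — a significant `is_a` descendant exists ("child" is
  read as *any* descendant, which is stricter than direct children and
  independent of evaluation order; the reported set is therefore an
  antichain);
* `score_filtered` — score $= \max_g W_{t,g} \le 100$. The score
  restriction singles out the most abundant functions; its unit is the
  weight itself (100 ≈ 0.1 reads per base at the default scale). It is
  off in qualitative mode.

The qualitative mode replaces the weight cells by contig counts
(annotated vs not, per group) and applies only the min-contig, FDR and
pruning filters by default.

**Degenerate tables** (all four cells zero) get $p = 1$ and are excluded
from the BH family, which consists of all terms annotated to at least one
contig.

# Ontology handling

The OBO reader ingests the `[Term]` subset (`id`, `name`, `namespace`,
`is_a`, `is_obsolete`); obsolete stanzas and their edges are dropped;
dangling `is_a` targets and cycles are fatal (the cycle is named).
Only `is_a` edges are traversed — `part_of` and other relations are
ignored as the conservative core of the hierarchy. Annotation sets are
propagated to ancestors (true-path rule) by default, since GO-era counts
conventionally include ancestor terms; `propagate = FALSE` switches to
direct-only counting, and both behaviours are exercised in the tests.
Namespaces (BP/CC/MF) are analysed jointly; the result table carries the
namespace for per-namespace reporting.

# Microarray stage

Raw intensities are normalised by the relative intensity of the means:
each sample column is scaled so its mean equals the grand mean of column
means, then log2-transformed. Mean scaling is applied per sample column
(per channel readings are provided as separate columns); zeros are
floored at half the smallest positive intensity with a warning. This is
the appropriate reading of mean-based normalisation for single-intensity
sample columns; loess or print-tip normalisation is out of scope.

Per exposure time, a pooled-variance two-sample Student t test is applied
per probe on the log2 values (Welch's test behind `welch = TRUE`),
two-sided p from $t_{n_1+n_2-2}$, BH-adjusted across probes. Signed folds
follow the field's reporting convention: $2^{\Delta}$ if $\ge 1$, else
$-2^{-\Delta}$, so label swapping maps $x \mapsto -x$. Zero pooled
variance with equal means gives $p = 1$; with unequal means the probe is
flagged (`zero_var_shift`) and assigned the smallest representable p
rather than an undefined statistic. The all-times comparison is a one-way
fixed-effects ANOVA with levels {control, 6 h, 12 h, 24 h} (controls
pooled across times by default; an explicit grouping can be passed);
with two levels it reduces exactly to the squared t test, which the
acceptance tests verify to $10^{-10}$.

The dye-swap design is honoured by the generator (dye labels swap
between successive replicates), but the tests treat arrays as
independent samples — a plain Student t matches the study's analysis;
a paired/ratio analysis is deliberately not implemented. PCA
(`prcomp`, probe-centred, unscaled) and Manhattan/average-linkage
clustering of sample profiles are both provided: the study's figure
captions attach the distance/linkage language to "PCA", which is
contradictory, so both readings are reproducible. Venn overlap counts
use the raw per-time significance sets at $p < 0.05$, matching how the
temporal overlap was summarised.

# qPCR stage

$\Delta Ct_g = Ct_{\text{target},g} - Ct_{\text{ref},g}$,
$\Delta\Delta Ct = \Delta Ct_{T} - \Delta Ct_{C}$, fold
$= 2^{-\Delta\Delta Ct}$, reported signed. Technical replicates are
averaged within each biological replicate first, then biological
replicates are averaged (the aggregation order is stated because designs
with unbalanced technical replication make the pooled mean differ).
Amplification efficiency is fixed at 2 (100%); standard-curve efficiency
estimation is out of scope. Reference normalisation cancels any constant
Ct shift, and label swapping negates the signed fold — both are tested
exactly.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of `(config, seed)`; byte-identical
reruns are an acceptance requirement.

**Contig experiment.** Group sizes and read totals default to the study
scale (1,318/1,140 contigs, 134,090/124,287 reads; the `tiny` profile
uses 100 contigs and 5,000 reads per group for speed). Contig lengths are
log-normal with mean ≈ 780 bp (matching total nucleotides / contigs of
the reference assembly) and sdlog 0.5. Reads are allocated multinomially
with probabilities proportional to length, so under the null the weight
$W$ is flat across terms and the spiked fold is the estimand of the
enrichment statistic. For a spiked term the treated read-probability of
its contigs is set to fold × length-share — i.e. the renormalisation that
keeps the group total fixed is compensated — so the expected
treated/control weight ratio equals the configured fold exactly (the test
suite checks a fold-4 spike is recovered within 10% on average).

Two generator choices matter for calibration and are deliberate:

* *Annotations are dealt, not drawn i.i.d.* Each term receives
  near-equally many contigs in both groups (stratified assignment). With
  i.i.d. uniform draws, rare terms end up present in one group and absent
  in the other; that is a genuine abundance difference in the emitted
  data, the test rightly detects it, and a "null" dataset would not be
  null. Real annotation noise does behave like the i.i.d. variant — which
  is why presence/absence observations on real data (e.g. a function
  found only in treated larvae) belong to the descriptive
  `term_read_summary`, not to the null-calibrated test.
* *One direct term per contig; spikes restricted to leaves.* Direct
  density defaults to 1 (the most specific term; true-path propagation
  supplies the ancestors). Spiking is compositional: with a fixed read
  total, mass given to spiked contigs is taken from everything else, so
  if spiked terms cover too much of the dataset every other term becomes
  significantly "repressed". Leaf terms (via `spike_candidates()`) at
  density 1 keep the spiked mass ≈ 25% of treated reads in the standard
  recovery configuration; the generator refuses configurations where the
  spiked share reaches 90%.

Features of real data *not* emulated: overdispersed per-contig expression
(reads ∝ length is an idealisation; real coverage varies by orders of
magnitude), annotation errors and biases, assembly artefacts, and
correlated annotation structure beyond the DAG. Passing the recovery
tests therefore demonstrates correctness of the statistical machinery on
its own model, not performance on arbitrary real data.

**Microarray.** Per-probe baseline log2 intensities are
$N(10, 1)$; differentially expressed probes are shifted ±2 log2 units in
the treated condition at one exposure time (or all times, configurable);
noise is i.i.d. $N(0, 0.2^2)$; intensities are exponentiated. The default
of 2 biological replicates per (condition, time) cell mirrors the study
design; note that with $n = 2$ per group the pooled t has 2 degrees of
freedom and essentially no ranking power, so power-oriented tests use 4
replicates. Dye swap is realised as label assignment only — no dye bias
is simulated, hence nothing for a ratio analysis to remove.

**qPCR.** Gene-level base Cts are $N(22, 1.5^2)$; treated Cts are shifted
by $-\log_2(\text{fold})$; measurement noise $N(0, 0.2^2)$ per technical
replicate; the reference gene has fold 1 (condition-stable Ct, as a good
reference should). Default true folds 37.9 and 1/7.2 mirror the two
chitin-binding-domain-3 transcripts verified in the study.

# Evaluating recovery

`evaluate_recovery()` scores an enrichment run against the truth table:
a spiked term counts as recovered when $q \le \alpha$ in its true
direction *before* child pruning — pruning intentionally suppresses a
term whenever a more specific significant descendant exists, which is a
reporting choice, not a detection failure. Ancestors and descendants of
spiked terms are genuinely differentially abundant by construction
(their annotation sets share the spiked contigs), so they count neither
as true nor as false positives; the empirical FDR is taken over the
remaining significant terms.

# Numerical choices and degenerate inputs

* Fisher p values sum the hypergeometric mass with a $1+10^{-7}$
  relative guard against floating-point ties (the convention of standard
  implementations, against which the implementation is cross-checked,
  alongside exhaustive enumeration of every table with total ≤ 40).
* BH adjustment delegates to `stats::p.adjust`; ties need no special
  treatment.
* Rounding of weight cells is round-half-even; negative complement cells
  (possible only after rounding) are clamped with a warning.
* All-zero tables: $p = 1$, flagged degenerate, excluded from the BH
  family.
* Zero-variance probes: $p = 1$ when means agree, flagged minimal-p when
  they differ.
* Zero or negative intensities are floored before the log transform.
* Problem sizes used in the checks: the enrichment calibration runs use
  1,000 contigs and 50,000 reads per group with 200 terms (50 null
  simulations; 20 spike-recovery simulations with 10 leaf terms at fold
  5); the microarray calibration uses 2,000 probes × 8 samples over 10
  simulations; the exhaustive Fisher sweep covers all 135,751 tables
  with grand total ≤ 40. These sizes give the Monte Carlo bands stated
  in the tests while keeping a full run to a few minutes.

# Known limitations

* The weighted test treats rounded weights as counts; its conservatism
  grows as `scale` shrinks, and its calibration under extreme coverage
  heterogeneity (not generated here) is unexplored.
* Relative-abundance enrichment is compositional: strong enrichment of
  some functions necessarily depresses the rest. Interpret "repressed"
  terms accordingly.
* Terms covering almost the entire dataset have near-empty complements;
  their tables are close to degenerate and their p values uninformative
  (the root term is always degenerate by construction).
* The microarray stage implements the study's test-per-probe analysis;
  no empirical-Bayes variance moderation is applied, so two-replicate
  designs have very low power.
* qPCR assumes 100% amplification efficiency and a truly stable
  reference gene.
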