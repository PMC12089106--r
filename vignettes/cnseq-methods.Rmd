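---
title: "cnseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cnseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnseq)
```

## Scope and assumptions

`cnseq` analyses gene × sample FPKM matrices from very small cohorts
(the reference design is 5 controls, 6 AD, 3 PD donors over two
sequencing sessions). Three assumptions shape everything downstream:

1. **FPKM, not counts.** Inputs are already length- and
   depth-normalized, non-negative and heavy-tailed. Count-model DE
   (negative-binomial shrinkage) is deliberately out of scope; the
   package performs no normalization beyond an optional
   `log2(v + pseudocount)` transform.
2. **Tiny n.** With 3–6 samples per group, asymptotics are unreliable.
   The Mann-Whitney test therefore enumerates its full exact
   permutation distribution whenever `n_x + n_y ≤ 12` and the data are
   tie-free; sample-label permutation nulls are avoided entirely (see
   *Enrichment* below).
3. **Raw scale for reported effects, log scale for geometry.** Group
   means and fold changes are reported on raw FPKM (matching how such
   values are printed in study reports, e.g. "305 vs. 46 FPKM"), while
   PCA, clustering and the enrichment ranking metric operate on
   `log2(FPKM + 1)`, where Euclidean distances are meaningful and a
   handful of high-abundance loci cannot dominate.

## Group comparisons

For a contrast `"B-vs-A"` (A is the reference, normally `control`),
each gene gets:

* `fold = max(μ_A, μ_B) / min(μ_A, μ_B) ≥ 1`, with the direction of B
  relative to A carried separately. A single zero mean yields an
  *undefined-fold* flag (`NA`) rather than `Inf`; two zero means are an
  error at the scalar interface and an `NA` row in the per-gene driver.
  Means are arithmetic means of raw FPKM — the obvious reading of
  printed group means, exposed in code rather than hidden.
* A two-sided p-value from Welch's *t* (default) or Mann-Whitney *U*.
  The exact Mann-Whitney two-sided p is `min(1, 2 · smaller tail)` over
  the enumerated null; the large-sample branch applies both the tie
  correction and a 0.5 continuity correction. Degenerate genes (zero
  variance within a group for Welch) get `NA` p-values instead of
  aborting a 60,000-gene run.
* A star label: `""` for p ≥ 0.05, `*`, `**`, `***` below 0.05, 0.01,
  0.005 — all strict inequalities, so a p of exactly 0.05 is unstarred
  and 0.005 earns `**`, not `***`.

Ranking is a stable sort by ascending p, then descending fold change,
then gene identifier, making output order a pure function of the table.
"Effect size" in this ranking is the fold change; a standardized effect
would be another defensible choice but is not what printed fold-change
language suggests. No multiple-testing correction is applied by default
(the reference analysis reports raw p-values across all loci);
Benjamini–Hochberg is available behind `p_adjust = "BH"` and is clearly
an extension.

For three groups, `bf_welch_anova()` reports both the Welch ANOVA and
the Brown-Forsythe F\* omnibus p-values and control-referenced pairwise
Welch comparisons. The Dunnett-T3 adjustment properly uses the
studentized maximum modulus (SMM) distribution, which base R lacks; we
approximate the SMM tail under independence, `p_adj = 1 − (1 −
p_pair)^k`, i.e. a Šidák step over the pairwise Welch p-values. This is
mildly conservative for positively correlated comparisons (they share
the control arm) and satisfies `p_adj ≥ p_pair` exactly. Games–Howell
(studentized range via `ptukey`) is the alternative.

## PCA and clustering

PCA treats **genes as observations and samples as variables**, the
orientation in which individual genes are datapoints on a biplot and
each sample contributes a loading. Standardization (correlation PCA) is
the default, mirroring spreadsheet-style PCA tools; covariance PCA is a
flag away. Components are sign-fixed by making the largest-magnitude
sample loading positive, so runs are bit-reproducible. A constant
sample column under standardization is an error naming the sample.
Note that in this orientation PC1 routinely carries > 80% of the
variance: all samples share the per-gene baseline, and that shared
axis *is* PC1. The analysis input is `log2(FPKM + 1)` by default.

Samples are clustered on gene profiles with Euclidean distance and Ward
(D2) linkage by default; the gene-wise tree behind the k-subgroup
cluster profiles uses average linkage. Neither metric nor linkage is
dictated by the source analysis (only the software is named), so both
are parameters. Dendrograms serialize to Newick via `ape`. Gene
subgroups come from a deterministic tree cut (seeded k-means optional);
each cluster's profile is its per-sample mean expression.

## Enrichment

The ranking metric is the difference of group means on `log2(FPKM+1)`,
sorted descending with identifier tie-breaks (signal-to-noise is
offered but is unstable when a group has n = 3). The enrichment score
is the classic weighted running sum: hits step up by `|r_i|^p`
normalized over the set's in-list members, misses step down by
`1/(N − N_hit)`; ES is the signed extremum, always in [−1, 1], and at
`weight_p = 0` it reduces to the two-sample KS deviation (oracle-tested
against direct CDF arithmetic). `weight_p = 1` is the default. The
leading edge is the members at/before a positive extremum or at/after a
negative one.

Significance uses **gene-set resampling**, not sample-label
permutation: with n = 3 per group only `choose(6,3)/2 = 10` distinct
label splits exist, so a label-permutation p cannot resolve below 0.1.
Random same-size member sets drawn from the ranked universe give the
null, with the add-one estimator `p = (1 + #{|ES₀| ≥ |ES|})/(1 +
n_perm)` — strictly positive, reproducible under a fixed seed, and
invariant to positive rescaling of the metric. This is a deliberate
deviation from external GSEA software defaults and is what the tests
certify. Raw ES (not NES) is reported; cross-collection FDR is out of
scope.

## Mutability factors

* **Telomere distance** is to the *nearest* chromosome end,
  `min(start − 1, L − end)/10⁶` Mb; coordinates are 1-based inclusive
  at the interface (GFF3 convention; BED input is converted on import).
  Per-arm distances are available since "its telomere" is ambiguous for
  a gene on a metacentric chromosome.
* **F(i)** is `distance < 50 Mb`, **F(ii)** is `A+T fraction > 0.59`
  (the human chromosomal average); both strict, so boundary values fall
  on the non-matching side. No boundary case is exhibited in the source
  material, so the convention is ours and is pinned by tests.
* **A+T content** is computed over the genomic gene span by default
  (the transcript-sequence route exists); ambiguity codes (N runs,
  assembly gaps) are excluded from the denominator. When both a length
  table and FASTA are supplied their lengths must agree — silent
  disagreement would corrupt every distance.
* **Matching rates** are plain panel percentages, kept both exact and
  rounded to integer percent for reporting. Linkage calls use the
  inclusive 50 cM rule and the coarse 1 cM ≈ 1 Mb equivalence, exposed
  as standalone operations only — no quantitative composition with
  telomere proximity is defined in the source methodology, and none is
  invented here.
* **Size conservation** flags a species' transcript as unusual when it
  falls outside a user-supplied reference range (a stand-in synthetic
  range ships for testing; the real 90-gene AD/PD panel is not public).

## The synthetic cohort

`expression_sim_spec()` defaults *are* the stated world: 5/6/3 samples,
two sessions (the first three samples per group form session 1,
matching a preliminary n = 3-per-group batch), log-normal baseline
(`meanlog = log 15`, `sdlog = 1.6`, giving a median around 15 FPKM and
an upper tail of several hundred — bracketing printed values from tens
to ~300 FPKM), per-cell log-noise `sd = 0.4`, gene-specific session-2
shifts `sd = 0.2`, and a disease-like control (`outlier_control_index =
3`) whose spiked genes follow the AD distribution, emulating a control
donor that clusters with the disease group. Spikes shift a group's
log-mean by `± log(fold)`, so in the zero-noise limit the generator
reproduces exact printed-style means (305 vs 46 at fold 305/46).

Two fixture families intentionally switch the outlier off: fold-change
recovery and Monte-Carlo unbiasedness tests, which score how well the
pipeline recovers *designed* effects — effects the disease-like control
exists to degrade. That is a property of what those tests measure, not
a tuning of the world; the outlier stays on everywhere structure is
tested, and the sample-clustering test asserts it lands in the disease
branch.

What a green synthetic-recovery test does **not** establish: log-normal
noise is a model choice (real FPKM has zero inflation and
gene-correlated technical structure); batch effects here are
mean-shifts only; no postmortem RNA-degradation gradient is modeled;
and genome simulation draws i.i.d. bases, so isochores, repeats and
real telomeric sequence context are absent. Cohort-scale figures from
the motivating study (e.g. a PC1 variance share of 86.6%, per-gene
p-values, per-species matching percentages) depend on the unavailable
raw matrix and assembly versions and are explicitly not reproduction
targets.

`simulate_genome()` places genes to hit target telomere distances
exactly (placement is integral) and draws gene-span bases with an exact
A+T count, `round(target × length)`, so realized fractions are within
half a base of target. `simulate_gene_sets()` designs one enriched set
by spiking its members in both disease groups and records the truth.
All generators are pure functions of spec + seed; sub-seeds derive
deterministically from the single pipeline seed.

## Numerical and interface choices

* The detection filter (`min_samples_nonzero`, default 1) stands in for
  an unspecified upstream rule that reduced ~62.7k loci to ~42k
  analysed points; it is a parameter precisely because the true rule is
  unknown.
* Missing cells are rejected at parse time, never imputed.
* `read_fpkm_table`/`write_fpkm_table` round-trip finite decimal values
  bit-identically (15 significant digits on write).
* Exact Mann-Whitney enumeration is capped at a combined n of 20
  (`choose(20,10) = 184,756` splits) to keep forced-exact calls
  bounded.
* Permutation p-values require `n_perm ≥ 100`; below that the add-one
  estimator's granularity exceeds any usable threshold.
* Errors are classed conditions (`cnseq_argument_error`,
  `cnseq_validation_error`, `cnseq_parse_error`, `cnseq_config_error`,
  `cnseq_stage_error`), so callers and the CLI can map them to distinct
  exit codes (2 for configuration, 3 for stage failures).

## Known limitations

* The Dunnett-T3 independence approximation is conservative; exact SMM
  quantiles would need an external dependency.
* `es_profile` scores one contrast at a time; cross-collection FDR and
  NES normalization are out of scope by design.
* Ortholog mapping is input, not computed: the mutability module trusts
  the caller's gene↔species correspondence.
* The pipeline keeps the expression matrix in memory; at 62,704 × 14
  doubles this is ~7 MB and not a constraint, but single-cell-scale
  matrices are out of scope.
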