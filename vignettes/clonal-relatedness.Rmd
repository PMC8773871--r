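---
title: "Deciding clonal relatedness of paired tumour components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding clonal relatedness of paired tumour components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetpair)
```

## The question

A minority of invasive lobular breast carcinomas show heterogeneous
E-cadherin expression: one macrodissected region of the tumour has lost the
protein entirely (the *Neg* component) while an adjacent region retains
weak or aberrant expression (*Abr*). Two explanations compete. Either both
regions descend from one common ancestor that later diverged, or two
independent tumours collided. The two hypotheses make sharply different
predictions about molecular data: a common ancestor leaves a *truncal* set
of somatic mutations shared by both components, similar mutational-process
activity, and largely concordant copy-number and methylation landscapes; a
collision predicts essentially disjoint mutation sets.

`hetpair` implements the computational pipeline for this decision: build a
high-confidence somatic callset per component from several variant callers,
filter it, quantify sharing, profile the mutational processes, and compare
copy-number and promoter-methylation state between the components. Because
patient-level WGS cannot be shipped with a package, `hetpair` also contains
a paired-tumour simulator with known ground truth; every claim the pipeline
makes is tested against that truth.

## Consensus calling and the filter chain

Each component is assumed to have been called by three somatic callers
(two of which also call indels) against the same matched normal. The
consensus rule is the conventional one:

* an SNV is retained when **at least 2 of the 3** SNV callers report it;
* an indel is retained when **both** indel-capable callers report it.

Cross-caller matching requires one canonical representation per variant, so
all keys are left-aligned and parsimony-trimmed before comparison
(`normalize_variants()`); the simulator deliberately emits right-shifted
indel representations from one caller to keep this step honest. The
consensus VAF follows a caller precedence (first caller that reports an
allele-fraction field; `tumour_alt/tumour_depth` as a fallback), matching
how a single VAF column is usually assembled for downstream deconvolution.

Consensus variants then pass a fixed six-rule filter chain
(`apply_post_hoc_filters()`), applied in a documented order with the first
failing rule recorded per variant:

1. remove multiallelic sites;
2. remove common variants (population allele frequency > 1%);
3. remove variants with tumour allele frequency < 0.01;
4. remove variants insufficiently covered (default: less than 10x in
   either tumour or normal);
5. require at least 5 alternate reads in tumour and at most 2 in normal
   (both bounds inclusive);
6. remove synonymous variants.

Two readings needed a decision. Rule 4's "depth < 10 in both samples" is
ambiguous; the stricter reading (require 10x in *both* samples) matches the
intent of confident somatic sites and is the default, with
`depth_rule = "either"` available for the permissive reading. Rule 6 is
applied to exonic annotations only: promoter and intronic variants are
analytically important here (e.g. regulatory CTNNA1 variants) and must
survive. Missing population AF is treated as "not in the database", i.e.
kept. All thresholds live in `filter_thresholds()`.

## Quantifying relatedness

Sharing is summarised by the **overlap coefficient**
$|A \cap B| / \min(|A|, |B|)$, computed separately for SNVs and indels
(`component_pair()`). It is robust to unequal callset sizes, which matters
because purity and mutation burden differ between components. Overlap on an
empty set is defined as 0 (the collision regime should not produce 0/0).
The final call (`classify_relatedness()`) uses explicit, reported
heuristics: SNV overlap at or above 0.3 is called clonally related, below
0.1 independent, otherwise indeterminate. Related pairs in practice sit
near 0.6 with occasional low outliers; the thresholds are deliberately
conservative and configurable, because the underlying argument is
qualitative.

Mutational processes are profiled two ways. The six-class substitution
spectrum (`substitution_spectrum()`) folds every SNV onto the pyrimidine
strand and reports class fractions. The 96-channel SBS profile
(`build_sbs_profile()`) additionally conditions on the flanking bases,
using the standard channel order (substitution class major, then 5' and 3'
base), and is compared to a reference catalogue by cosine similarity --
scale-invariant, so raw counts are used without normalisation. There is no
signature *fitting* (no NNLS or de novo extraction); cosine similarity
against catalogue columns plus complete-linkage clustering of the
similarity matrix is the whole analysis, by design. The bundled catalogue
is **synthetic**: twelve columns reproducing the qualitative channel
concentrations of the breast-cancer signature set (SBS1's CpG-focused C>T,
SBS2/SBS13's TpC-focused APOBEC activity, flat SBS3/SBS5, and so on), built
deterministically by `synthetic_signature_catalog()`. It exists so the
machinery is exercisable offline; `load_signature_catalog()` accepts a real
COSMIC TSV unmodified and records the file checksum in reports.

Subclonal structure is read out with a deliberately simple model
(`fit_vaf_mixture()`): a k-component binomial mixture on `(alt, depth)`
fitted by EM, k chosen by BIC with `2k - 1` free parameters. Initialisation
is at the k interior quantiles of the raw VAFs, so the fit is fully
deterministic. This is a clonality *readout*, not a full subclonal
deconvolution: there is no neutral-drift power-law tail and no
copy-number-aware CCF transformation, so the means are allele fractions,
not cancer-cell fractions. For the well-separated structures of interest
(a clonal cluster near `purity/2` plus a distinctly lower subclone) BIC
selects the right k in essentially all replicates.

Recurrence across a cohort uses the proportion test: per gene, the number
of samples in each group carrying a qualifying variant (non-genic
annotations excluded), gated on an absolute carrier-count difference of at
least 3 before testing, with chi-squared continuity correction (Fisher's
exact optionally for small counts). A Benjamini-Hochberg FDR is reported
alongside the raw p-values as an extension; the raw values remain primary.

## Copy number and methylation

Copy-number input is a segment table per component (an ASCAT-style caller's
output, assumed purity-corrected upstream). A gene overlapping several
segments takes the one covering the largest number of its bases, ties to
the lower-coordinate segment; measuring overlap in bases rather than
gene-length fraction is a documented choice (`overlap_unit` switches it).
States are interpreted relative to tumour ploidy through the ratio
`r = total_cn / ploidy` with cut-points 0.75 / 1.25 / 2 for
loss / neutral / gain / amplification. No formula for the ploidy
adjustment is standard, so this rule was chosen to satisfy two anchors:
at ploidy 2 it reduces exactly to conventional diploid calls, and total CN
4 at ploidy 4 is *neutral* -- combined with a minor-allele count of zero it
is the copy-neutral-LOH state that distinguishes a tetraploid genome from a
true loss. LOH itself is simply `minor_cn == 0` with `total_cn > 0`.

Methylation input is a beta-value probe table. Probes are removed when the
detection p-value exceeds 0.05 in any sample (strictly greater), when they
lie on the Y chromosome, carry a common SNP at the CpG, or are
cross-reactive; the SNP/cross-reactive designations are input flags because
the published exclusion lists are external data. Status is a hard
threshold: methylated iff beta > 0.3 (0.30 itself is unmethylated). A probe
is differentially methylated between components when it is a promoter
probe, the statuses are opposite, and `|delta| >= 0.1` on the raw betas (no
smoothing). "Promoter" follows the EPIC annotation convention
(TSS1500/TSS200/5'UTR), supplied in the probe map so any definition can be
substituted. The per-gene "promoter methylated" call (more than half of
promoter probes methylated, `promoter_methylation_summary()`) is a package
decision -- gene-level statements are usually made without a printed rule --
and genes without promoter probes are reported as no-data, never as
unmethylated.

## What the simulator emulates, and what it does not

`simulate_mutation_set()` draws the mutation structure the common-ancestor
model predicts: a truncal block shared by both components (the truncal
count is binomial with expectation `trunk_fraction * n_mutations`), private
blocks per component, and optional subclones at lower cellular fraction.
Trinucleotide contexts are drawn from per-component signature mixtures
(truncal mutations from the mean of the two mixtures, as befits a shared
ancestor) and each SNV is placed at a reference position whose folded
context matches its channel, so profile construction can be validated
against the generating mixture. Reads follow the standard sampling model:
per-site depth Poisson around the configured mean, alt reads binomial at
the true VAF, which is `purity * ccf / 2` under the diploid-heterozygous
assumption. Callers see the same read pool but differ in sensitivity,
injected false positives (truth VAF 0, tumour-only alt support), VAF noise
and indel capability; one caller emits right-shifted indel representations
and one reports no allele-fraction field. Contaminant classes (multiallelic
sites, common germline-frequency variants, engineered artifact sites, and
`FILTER=LowQual` records) are injected so that every consensus and filter
rule encounters both passing and failing records.

Default study conditions: 2000 mutations per component at trunk fraction
0.6, purity 0.7 per component (exposed as a free parameter -- per-component
purity is rarely reported), tumour depth 80x and normal 40x, 10% indels,
caller sensitivities 0.95-0.98 with 25 false positives each. The reference
is synthetic (5 x 200 kb contigs by default, i.i.d. bases at 41% GC) --
ample context diversity for tens of thousands of placements while keeping
the context index cheap.

The simulator is deliberately read-free: no FASTQ/BAM level error model, no
germline variation, no mapping artefacts, no trinucleotide abundance bias
matching a real genome, and caller errors are independent across callers
rather than correlated by locus context as real callers' errors are.
Passing tests therefore demonstrate that the *pipeline logic* is correct
under the stated sampling model; they do not certify performance on real
sequencing data, where caller-correlated artefacts and copy-number-driven
VAF distortion are the dominant difficulties.

`simulate_cna_segments()` tiles each contig with baseline segments at the
component's ploidy and carves dedicated segments for planted events
(e.g. single-copy CDH1 loss in Neg only, or total CN 4 / minor 0 at ploidy
4 for the copy-neutral LOH case). `simulate_methylation()` keeps concordant
probes' base betas at least 0.1 away from the 0.3 threshold and plants
discordant probes on opposite sides with a pre-noise delta of at least
0.25, so with the default noise (sd 0.02) the planted set is recoverable
exactly -- which is what makes exact-recovery tests meaningful rather than
flaky.

## Numerical choices and degenerate inputs

* Variant identity is `(chrom, pos, ref, alt)` after left-alignment;
  multiallelic records are expanded at parse time, kept through consensus,
  and removed by filter rule 1, preserving the documented rule order.
* One global RNG stream per simulation, seeded once; rerunning any
  config reproduces every output byte-for-byte (the pipeline report is
  asserted byte-identical across reruns).
* EM convergence: relative log-likelihood change below 1e-8, 500 iteration
  cap, success probabilities clamped to `[1e-4, 1 - 1e-4]`; coincident
  quantile starts are spread by 1e-6 to avoid a degenerate fit. Fewer than
  20 variants, or all-zero alt counts, are refused rather than fitted.
* Cosine similarity of a zero vector is an error, not 0; empty substitution
  spectra are returned all-zero with an `empty` attribute.
* Clustering ties follow `stats::hclust`'s deterministic handling of its
  input order; merge heights are order-invariant, leaf order is reported
  as-is.
* SNVs at contig edges (no flanking base) are skipped with a warning count
  rather than failing profile construction.

## A short run

```{r demo, eval = FALSE}
cfg <- demo_pipeline_config(seed = 7)
report <- run_pipeline(cfg, out_dir = tempfile("hetpair-demo"))
report$overlap$snv
report$relatedness
report$signatures$best_match
```

On the demo configuration (400 mutations per component at trunk fraction
0.6, an APOBEC-skewed Neg component, a 30%-cellularity subclone in Neg, a
planted CDH1 loss and a hypermethylated CTNNA1 promoter) the pipeline
recovers an SNV overlap near 0.6, calls the pair clonally related, selects
k = 2 for the Neg component's VAF mixture, and reports exactly the planted
CNA and methylation events. The problem sizes used by the test suite
(cohorts of 2000 mutations for trunk-fraction recovery, 20000 draws for
signature recovery, 10000 probes for methylation exactness, 100 replicates
for model-selection rates) were chosen as the smallest at which the
statistical tolerances are comfortably stable.

## Known limitations

* The subclone detector reports allele-fraction clusters, not
  copy-number-corrected cancer-cell fractions; a subclone on an aberrant
  copy-number background will be misplaced.
* The relatedness thresholds are heuristics over one statistic; borderline
  pairs (overlap 0.1-0.3) are deliberately left indeterminate.
* The bundled signature catalogue is synthetic; conclusions about real
  samples require a real catalogue file.
* Filters assume annotation fields (population AF, functional class) are
  supplied by an upstream annotator; the package does not annotate.
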