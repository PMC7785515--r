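---
title: "Models and methods: classifying TCR- and CD28-sensitive genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: classifying TCR- and CD28-sensitive genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimgrid)
```

## The experimental design

T-cell activation integrates two signals: the T-cell receptor (TCR,
signal 1) and CD28 costimulation (signal 2). stimgrid analyses a
titration grid in which naive (CD45RA+) and memory (CD45RA-) CD4 T cells
from several donors are stimulated with seven (TCR, CD28) dose
combinations — resting (0,0), lowTCR+lowCD28, lowTCR+highCD28,
highTCR+lowCD28, highTCR+highCD28, highTCR alone and highCD28 alone —
and profiled by bulk RNA-seq. The central question is, per gene and per
cell subset: does expression track the intensity of TCR, of CD28, of
both, or of neither?

## Negative-binomial model

Counts for gene $g$ in sample $j$ are modelled as
$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\mathrm{Var}(y) = \mu + \alpha\mu^2$ and
$\mu_{gj} = s_j \exp(x_j^\top \beta_g)$, where $s_j$ is a per-sample
size factor and $x_j$ the design row. GLMs are fitted by Fisher scoring
(IRLS) with working weights $\mu/(1+\alpha\mu)$, converged when the
largest coefficient update falls below $10^{-6}$ (at most 100
iterations).

**Filtering.** Genes on autosomes or chromosome X with at least 20
counts in at least 3 samples are retained; everything else is dropped
before normalization.

**Size factors.** Median-of-ratios: $s_j$ is the median over genes of
$y_{gj}$ divided by the gene's geometric mean, rescaled to geometric
mean 1. This assumes most genes do not change across samples. T-cell
activation violates that assumption badly — half or more of expressed
genes can be induced, all in the same direction — which drags the
medians upward in stimulated samples and attenuates every estimated
fold-change. `robust_size_factors()` therefore re-estimates the medians
over *condition-stable* genes: each gene's spread of log2 normalized
condition means is studentized by its own sampling noise
(within-condition variance, delta method), genes with a spread above
4.5 noise units are set aside (under no condition effect the spread of
seven condition means is about 2.7 units), and the medians are
recomputed over the remainder. The ratio/median definition itself is
unchanged; only the gene set the medians run over, in the spirit of
normalization against control genes. The classifier uses the robust
variant throughout; when fewer than 10% of genes are stable the plain
estimate is kept.

**Dispersion.** Per gene, $\alpha_g$ maximizes the Cox-Reid adjusted
profile likelihood (the $\tfrac12\log\det X^\top W X$ term corrects the
downward bias of the plain MLE when the design is not small relative to
the sample count), bounded to $[10^{-8}, 10]$, with means refitted once
at the first estimate. Gene-wise estimates are then shrunk toward a
mean-dispersion trend $\alpha_{tr}(\mu) = a_1/\mu + a_0$ (least squares
on the gene-wise estimates) as the posterior mode under a normal prior
in log space. The prior variance is estimated from the data: the
MAD-variance of log gene-wise estimates around the log trend minus the
approximate sampling variance $\psi_1((m-p)/2)$ of a log-dispersion
estimate, floored at 0.05. A configured fallback (0.761, the
`dispersion_prior_var` entry of `default_config()`) is used when fewer
than 10 genes are available. Dispersions are estimated *under each
test's own full design*: sharing estimates from a richer design with a
smaller test's reduced model leaves condition-mean noise uncovered and
inflates the test.

**Wald pairwise differential expression.** One GLM per gene on the full
condition-factor + batch design of one cell type; each stimulated
condition is contrasted against resting via $z = \beta/\mathrm{SE}$ from
the coefficient covariance. Two-sided p-values use a t reference with
$n - p$ degrees of freedom: with four donors per condition the normal
reference is visibly anticonservative for plug-in dispersions, and the t
reference is the standard small-sample correction. BH correction is
applied within each (cell type, contrast) family. A gene is
*upregulated* in a contrast at fold-change $\ge 2$ and BH FDR
$\le 0.05$; the upregulated set of a cell type is the union over the six
stimulated-vs-resting contrasts.

**Likelihood-ratio tests.** $2(\ell_{full} - \ell_{reduced})$ against
$\chi^2$ with degrees of freedom equal to the column difference, both
models fitted at the same dispersion.

## The sensitivity classifier

Only upregulated genes are classified, per cell type and per stimulus:

1. **Dose encoding.** When testing CD28, each sample contributes its
   CD28 dose (0/1/2) regardless of its TCR dose, so highTCR-alone is
   grouped with resting at dose 0 (neither received CD28); symmetrically
   for TCR. The other stimulus is absorbed into the intercept, not
   modelled. All seven conditions enter every test.
2. **Linear model.** LRT of `~ dose + batch` vs `~ batch` with dose as a
   *numeric* covariate, so the coefficient is the per-increment log
   fold-change. Pass: BH $q \le 0.05$ (across tested genes),
   per-increment fold-change $\ge 1.5$, coefficient positive.
3. **Switch model.** Genes failing the linear model are retested with
   the presence indicator (dose > 0) as covariate. Pass: $q \le 0.05$,
   fold-change $\ge 2$, positive. The linear model is prioritised: a
   gene never carries a switch label for a stimulus whose linear test
   passed.
4. **Assignment.** A gene passing exactly one stimulus is TCR- or
   CD28-sensitive; passing both gives `both`, which is reported but
   excluded from the *unique-sensitivity* set (the resolution of
   two-stimulus genes is not dictated by the classification scheme;
   `unique_sensitivity(both_stimuli = "stronger")` keeps them under
   their larger-effect stimulus instead); passing neither gives `none`.

**Switchers** are genes uniquely TCR-sensitive in naive cells and
CD28-sensitive in memory cells (or the converse). The linear-stage FDR
threshold is taken as 5%, matching the pairwise-DE threshold; the dose
is modelled as 0/1/2 because the titration uses two log-spaced doses per
stimulus and the claim under test is monotone intensity tracking, not
the exact dose-response shape.

## Preranked gene-set enrichment

Genes are ranked by the linear-model per-increment log2 fold-change.
For a set $S$, the weighted Kolmogorov-Smirnov running sum gains
$|r_i|/\sum_{S}|r|$ at members and loses $1/(N-|S|)$ elsewhere; the
enrichment score is the extremum and the leading edge the members at or
before it. Significance comes from a gene-label permutation null
(random same-size sets), $p = (1 + \#\{\text{same-sign } |ES_{null}|
\ge |ES|\}) / (1 + \#\text{same-sign nulls})$, NES divides ES by the
mean same-sign $|ES_{null}|$, BH across sets. Sets outside [5, 500]
members are skipped. Ties in the statistic are broken by gene id so the
ranking is deterministic. Note the attainability constraint of
permutation p-values: with $B$ permutations the smallest p is roughly
$2/B$, so a BH-corrected $q$ below a target requires $B$ large relative
to (family size / target).

## GWAS locus enrichment

**Loci.** Index SNPs are filtered to $p < 5\times10^{-8}$ and outside
the MHC interval (default chr6:25-34 Mb; the build and coordinates are
configuration, not biology). Panel SNPs on the same chromosome within
1 Mb with $r^2 > 0.8$ (squared Pearson correlation of 0/1/2 dosages)
are proxies; the locus spans index and proxies, extended 150 kb per
side, clipped at chromosome ends, and merged per trait when
overlapping.

**Matched permutation test.** The statistic is the number of query
genes whose *body* intersects any locus (no extra flank — the loci were
already extended). Null draws resample, within each (gene-length
quintile x mean-expression quintile) bin, as many universe genes as the
query holds there, so the null preserves the query's size and
expression profile exactly. One-sided add-one p over 10,000 draws by
default. Genes (not loci) are counted, and each trait is tested
separately with no cross-trait correction, plus an all-trait pool in
the analysis scripts.

**SNP annotation.** Driver genes are query genes intersecting a locus.
A driver is flagged when a member SNP of its locus falls inside a peak
(half-open: start inclusive, end exclusive) within the gene's 150 kb
window. Allele-specific motif disruption scores every PWM placement
overlapping the SNP on both strands for each allele;
$\Delta = \max_{alt} - \max_{ref}$ bits, "disrupting" when the better
allele reaches 80% of the motif's maximal score and $|\Delta| \ge 1$
bit.

## Chromatin analytics

Gene windows are the gene body flanked by 150 kb per side (the per-side
reading is consistent with the locus-extension convention; a total-width
alternative is available via `window_per_side`). Window coverage is
read mass over library total; enrichment between states is
$\log_2((stim + \varepsilon)/(rest + \varepsilon))$ with pseudo-mass
$\varepsilon = 1$, tested by a one-sample paired t-test across the gene
set. Motif enrichment compares the fraction of foreground peaks (near
sensitive genes) containing at least one PWM hit at 80% of the maximal
score against background peaks (near non-differentially-expressed
genes; foreground takes precedence for peaks in both), with a one-sided
binomial test treating the background rate as known — justified because
the background is much larger in intended use — and a continuity floor
of $1/(2 n_{bg})$ when the background rate is zero. QC reports peak
counts, FRiP and the fraction of peaks with signal above 10.

PWMs are built from counts with a pseudocount of 1 per cell:
$\log_2\{((c+1)/(N+4))/b\}$ against a uniform background by default, so
scores are in bits. Ambiguous bases contribute 0 bits. Scanning covers
both strands and reports forward-strand half-open intervals.

## The synthetic-data generator

The generator emulates the study conditions so that every stage is
testable with known truth; its defaults are fixed once:

- 2 cell types x 7 conditions x 4 donors (two sequencing batches of two
  donors each); per-(batch, gene) multiplicative log-normal batch
  factors (sd 0.3 log2); relative depths uniform in [0.7, 1.4].
- Baseline log2 expression Normal(5, 2); dispersions log-normal around
  0.1 (sdlog 0.5) — typical bulk RNA-seq magnitudes.
- Planted classes: linear genes add 1 log2 unit per dose increment of
  their stimulus; switch genes add 2 log2 units when the stimulus is
  present; `both` responds linearly to both; switcher genes are
  TCR-linear in naive and CD28-linear in memory cells.
- The synthetic genome is four 50 Mb chromosomes; genes occupy evenly
  sized slots with 100 kb spacing where density permits (the spacing
  scales down with the slot when more genes are requested than 100 kb
  spacing can hold, keeping locus-gene overlap unambiguous).
- GWAS panel: diploid dosages from binomial haplotypes (MAF uniform in
  [0.1, 0.5]); LD proxies copy the index haplotypes with per-haplotype
  flip probability $f$, giving expected $r^2 = (1-2f)^2$; index SNPs
  receive genome-wide significant p-values. Locus centres are genes
  sampled so sensitive genes are covered at `enrichment_factor` times
  the non-sensitive rate; factor 1 reduces to proportional sampling, a
  calibrated null.
- Chromatin: 1-3 peaks within 50 kb of each TSS, exponential signal
  scores; window read mass gamma-distributed, multiplied by a configured
  factor for matching (naive-class) genes under matching stimulation;
  motif consensus strings embedded in a configurable fraction of
  foreground peak sequences.

What the generator does *not* emulate: read-level data, realistic
haplotype/recombination structure, chromatin fragment-size effects,
co-location of trait SNPs with peaks (the SNP-in-peak fraction is near
zero by construction on synthetic data, unlike in real data), secondary
structure in expression (cell-cycle, donor-specific response
amplitudes), or down-regulation. Passing tests therefore demonstrate
correctness and calibration of the statistical machinery under the
stated NB model, not performance on any real dataset.

## Numerical choices and degenerate inputs

- Dispersion bounds $[10^{-8}, 10]$; all-zero genes are flagged and set
  to the upper bound; dispersion optimization uses a tolerance of
  $10^{-3}$ on the log scale.
- Optional ridge-type LFC shrinkage (normal prior, variance 0.661 in
  `default_config()`) exists on `fit_nb_glm()` but is off for
  classification, matching the convention of reporting unshrunk LFCs
  from likelihood-ratio analyses.
- Genes with an all-zero contrast group keep a finite reported LFC via
  the +0.5 working pseudo-count in the IRLS start; tests whose
  information matrix becomes singular are flagged NA rather than fatal.
- Coverage t-tests with identical non-zero ratios return p = 0 (the
  degenerate limit); identical zero ratios return NA.
- Interval work is 0-based half-open everywhere internally (BED
  native); gene tables declared 1-based are shifted on read; overlap
  queries are delegated to GenomicRanges with the +1 start conversion.
- Every simulation seeds a single RNG stream once; pipeline stages
  derive sub-seeds by fixed offsets so adding stages does not perturb
  earlier draws, and identical (params, config, seed) give byte-identical
  output tables.

## Problem sizes used in the packaged checks

The shipped test-suite and acceptance script run the calibration checks
at 2,000 genes x 28 samples, classifier recovery at 2,000 genes,
switcher recovery at 1,020 genes x 2 cell types, permutation calibration
at 200 replicates of B = 500 and power at 50 replicates of B = 1,000,
GSEA at 200-1,000 permutations, and the end-to-end determinism run at
250 genes. These sizes were chosen to give the calibration estimates
standard errors well inside the acceptance bands while keeping a full
run in the minutes range on a single core; production analyses would
raise the permutation counts (e.g. `n_perm_gsea = 1e6`) via the
configuration.

## Known limitations

- The NB machinery is a clean-room implementation sharing DESeq2's model
  but not its exact estimator internals (no Cox-Reid *dispersion prior
  iteration*, no independent filtering, no outlier replacement); small
  numeric differences from DESeq2 are expected by design.
- Median-of-ratios — even the robust variant — assumes a core of stable
  genes exists; experiments where essentially every gene responds are
  outside its operating range.
- The permutation GSEA replaces the adaptive multilevel p-value
  algorithm; very small p-values are floored at ~1/B.
- The linear model tests monotone intensity tracking on a 0/1/2 dose
  scale; non-monotone dose-response shapes fall through to the switch
  model or to `none`.
- LD is simulated as noisy copies of one index haplotype per locus;
  multi-block loci and allelic heterogeneity are not represented.
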