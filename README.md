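# stimgrid

T-cell activation needs two signals: antigen recognition through the
T-cell receptor (TCR) and costimulation through CD28. stimgrid
implements the computational side of a stimulation-titration study that
asks, gene by gene and separately in naive and memory CD4 T cells,
*which* of the two signals a gene's expression responds to. It is aimed
at computational immunologists analysing dose-grid bulk RNA-seq designs,
and at anyone who wants a fully synthetic, truth-known testbed for this
class of pipeline.

## The models

Counts follow a negative-binomial GLM, `y ~ NB(mu, alpha)` with
`Var = mu + alpha mu^2` and `mu = s_j exp(X beta)` (median-of-ratios
size factors `s_j`, Cox-Reid-adjusted gene-wise dispersion with trend
shrinkage). Genes upregulated versus resting (Wald test per contrast,
fold-change >= 2, BH FDR <= 0.05) are classified per stimulus with two
nested likelihood-ratio tests over all seven (TCR, CD28) dose
conditions:

- **linear**: `~ dose + batch` vs `~ batch`, dose numeric 0/1/2; pass
  at q <= 0.05 with per-increment fold-change >= 1.5 — expression tracks
  stimulus *intensity*;
- **switch**: presence indicator instead of dose, tested only when the
  linear model fails (linear is prioritised); pass at q <= 0.05 with
  fold-change >= 2 — on/off response to stimulus *presence*.

A gene passing exactly one stimulus is TCR- or CD28-sensitive;
"switcher" genes change stimulus between the naive and memory subsets.
Around the classifier sit a preranked permutation GSEA on the
linear-model fold-change ranking, an LD-based GWAS locus builder
(r^2 > 0.8 proxies, 150 kb extension, MHC exclusion) with a gene-matched
permutation enrichment null, a PWM scanner with allele-specific
disruption scoring, and chromatin window-coverage analytics. A
synthetic-data module generates counts, genotype panels with LD blocks,
and peak sets with planted motifs, all with known ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data: `01_simulate.R` writes a 1,000-gene, 56-sample experiment plus a
GWAS panel and peak calls under `results/data/`, and `02_classify.R`
through `05_chromatin.R` consume them. From the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify.R
```

prints, for the packaged generator settings (20 planted switchers):

```
 cell_type n_upregulated n_tcr n_cd28 n_both n_none frac_unique frac_linear
    memory           358   139    157     55      7   0.8268156   0.9932432
     naive           355   158    140     55      2   0.8394366   0.9932886
switchers: 20 TCR->CD28 called, 20 of 20 planted recovered
```

i.e. ~83% of activation-upregulated genes get a unique single-stimulus
assignment, almost all under the linear (intensity-tracking) model, and
every planted switcher is recovered with no false calls. The later
scripts report, on the same data: the planted TCR-response pathway at
the top of the GSEA ranking (q = 0.002, null sets flat), a pooled
locus-enrichment p = 0.022 for sensitive genes against the matched
permutation null (loci were planted at 3x the background coverage
rate), a mean log2 window-coverage ratio of 0.87 for CD28-sensitive
genes under highCD28 stimulation (planted factor 2 under library
normalization), and the planted AP1-like motif enriched in foreground
peaks at q < 1e-70.

Programmatic entry points mirror the scripts: `simulate_experiment()`,
`classify_experiment()`, `find_switchers()`, `gsea_test()`,
`build_loci()` + `permutation_enrichment()`, `scan_pwm()` /
`tfbs_disruption()`, `coverage_enrichment()` / `motif_enrichment()`,
and `run_pipeline()` for an end-to-end run into one output directory.
`vignettes/stimulus-sensitivity-methods.Rmd` documents every model,
threshold and design choice.

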