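---
title: "Mapping genotype-by-environment interactions in gene expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genotype-by-environment interactions in gene expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ggxe` implements a genetical-genomics workflow for a recombinant inbred
line (RIL) population expression-profiled in two environments: eQTL mapping
with permutation- and FDR-calibrated genome-wide thresholds, local/distant
classification, hotspot detection, signed-profile comparison across
environments ("plasticity" analysis), and the population statistics
(heritability, transgression, enrichment) that accompany such a study. This
vignette explains the statistical model behind each stage, the defaults and
why they were chosen, what the synthetic-data generator does and does not
emulate, and the numerical conventions.

## The mapping model

Every trait is a gene's log-expression, averaged over replicate samples to
one value per line. For a biallelic inbred population we code genotypes
$x \in \{+1, -1\}$ (allele A = parent-1/Ler, allele B = parent-2/Cvi) and
fit, per gene and marker,

$$y_l = \mu + a\,x_l + \varepsilon_l,$$

so the additive effect $a$ is half the difference between the genotype-class
means, positive when the A allele raises expression. The two-sided test of
$a = 0$ is the pooled two-sample t-test; the package reports $p$,
$-\log_{10} p$ and $a$ per gene $\times$ marker (`marker_regression`,
`genome_scan`). A forward-selection cofactor mode (`select_cofactors`, and
`cofactors` in `genome_scan`) conditions the scan on background QTL in the
spirit of multiple-QTL mapping: greedily chosen markers (smallest
conditional p-value below `entry_p`, default `1e-4`, at most
`max_cofactors = 5`) enter the model as covariates and a 10 cM window
around each cofactor is excluded from its own scan. The plain single-marker
scan is the default mode. Interval mapping between markers and epistasis
scans are out of scope.

Degenerate traits follow fixed conventions so that null bookkeeping stays
well defined: a flat trait gives $p = 1, a = 0$; perfect separation with
zero residual variance gives the machine-minimum p-value with
$-\log_{10} p$ capped at 300 (configurable) to avoid infinities.

## Genome-wide significance: two thresholds

**Permutation.** `permutation_threshold` implements the Churchill–Doerge
genome-wide threshold: line labels of the expression values are permuted
with genotypes fixed; each permutation draws one gene from the panel, scans
all markers and records the genome-wide minimum p-value; the threshold is
the empirical $\alpha$-quantile (type-1, i.e. the $\lfloor \alpha B
\rfloor$-th order statistic) of those minima. Defaults $\alpha = 0.05$ and
10,000 permutations; the bundled analyses use 1,000 permutations, which
locates the 5% quantile to within a few percent and keeps the demo fast.

**Pooled FDR.** For a transcriptome-scale study the package also derives a
threshold from Storey q-values on the pooled gene $\times$ marker p-values
(`storey_qvalues`, `pooled_threshold`). $\hat\pi_0$ is estimated by the
smoother (natural cubic spline, df 3, of $\hat\pi_0(\lambda)$ over
$\lambda = 0.05, \dots, 0.90$, evaluated at the largest $\lambda$, clipped
to $(0, 1]$); fixed-$\lambda$ and $\pi_0 = 1$ modes exist for deterministic
testing — with $\pi_0 = 1$ the q-values are exactly Benjamini–Hochberg.
Because neighbouring markers repeat largely the same test, the pool may be
thinned first (`thin_markers`): a greedy left-to-right pass per chromosome
keeps a marker only when its genotype $r^2$ with the last kept marker is at
most `r2_max = 0.95`. Thinning by $r^2$ rather than by plain adjacency
makes the rule data-driven and deterministic. Note that at typical RIL
densities (2.5 cM spacing, $r^2 \approx 0.82$) the default keeps all
markers; thinning bites only on very dense maps.

**Why the FDR target is divided by an integer factor.** Storey's procedure
on the pooled p-values controls the FDR *among gene–marker tests*, but an
eQTL discovery is claimed per gene, and linkage breaks the equivalence:
every truly regulated gene drags a whole block of correlated markers over
the pair-level threshold (loosening it), while every null gene gets roughly
one chance per effectively independent marker to cross it. The realized
gene-level FDR therefore exceeds the nominal pair-level target, and
increasingly so on denser maps. `estimate_fdr_inflation` measures this by
simulation: a mixed panel (default 10% genes with a real additive effect,
$\beta = 1.5$, noise SD 1) is scanned on the actual genotypes, Storey
q-values are computed on the pooled p-values, and the gene-level
false-discovery proportion (null genes declared / genes declared) is
averaged over replicates. On a 120-line population this yields inflation
factors of roughly 2, 4 and 6 at 5, 15 and 35 markers per chromosome, while
with a single marker per chromosome (independent tests) it is close to 1.
An all-null design cannot show this effect: under the global null with
positively correlated tests the any-rejection probability of BH/Storey is
bounded by the nominal level, and we measured it flat in marker density —
the inflation is a property of mixed pools, which is why true effects are
part of the simulation. The pipeline's default correction factor is 5
(ceiling of a ~4.4-fold inflation at the study's density), i.e. the pooled
threshold targets $q \le 0.05 / 5 = 0.01$.

The final mapping threshold is $-\log_{10}$ of the *stricter* of the
permutation and pooled-FDR p-thresholds (`threshold_set`).

## Peaks, locality, hotspots

`call_peaks` turns each gene's profile into eQTL records: per chromosome,
every maximal run of consecutive markers with $-\log_{10} p$ at or above
the threshold becomes one record, peaked at the maximal marker (leftmost on
ties) with the run as its support interval. `classify_local_distant` labels
a record *local* (cis) when the peak lies on the gene's own chromosome
within `window_bp` of its annotated position (inclusive; default 2 Mb — a
deliberately broad window, matching the extensive linkage disequilibrium of
a ~120–160-line RIL cross), otherwise *distant* (trans);
`locality_summary` rolls records up into the only-local / only-distant /
both gene categories.

`hotspot_scan` tests whether some marker carries more eQTL peaks than
expected if the $T$ peaks fell uniformly over the $M$ markers: the
per-marker null is Poisson with $\lambda = T/M$ and the hotspot threshold
is the smallest count $c$ with $P(X \ge c) \le \alpha/M$ (Bonferroni across
markers). The uniform-multinomial null and Bonferroni correction are this
package's choice; the original study does not state how its hotspot
threshold lines were derived. Counting can use all peaks or distant peaks
only.

## Plasticity: comparing two experiments

For each gene and experiment the *signed profile* is
$s_m = (-\log_{10} p_m) \cdot \mathrm{sign}(a_m)$ over markers
(`signed_profiles`), zero where $p = 1$. The Pearson correlation $r$ of a
gene's two profiles summarizes how similarly it is regulated in the two
environments; classes use strict bounds, strong-positive $r > 0.5$ and
strong-negative $r < -0.5$, with $r$ undefined (class *weak*) when either
profile is constant or shorter than 3 markers. Genes are stratified by eQTL
presence (neither / one experiment only / both). `match_eqtls` pairs peak
records across experiments per gene, greedily by genetic distance, calling
a pair *overlapping* when the peaks lie on the same chromosome at most
`max_peak_distance_cM` apart (default 10 cM, inclusive; the source study
never defines "overlapping", and peak-to-peak distance is the simplest
reproducible criterion) and *opposite-effect* when the matched additive
effects have strictly opposite signs. A formal QTL-by-environment
interaction model is deliberately not fitted: profile correlation is the
method under study.

## Population statistics

*Differential expression* between two replicate groups (parents, or NIL vs
recurrent parent) is the pooled-variance two-sample t-test per gene with
Storey q-values over the gene set; this plain linear model stands in for
the moderated (empirical-Bayes) models used on real arrays — moderation
matters for very small replicate numbers but not for the simulated designs
here.

*Broad-sense heritability.* In the parents, a one-way ANOVA decomposition
over replicate samples: $\hat\sigma^2_e$ = pooled within-line variance,
$\hat\sigma^2_g = (\mathrm{MS}_B - \mathrm{MS}_W)/r$ floored at zero, and
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$. In the RILs, the among-line
variance of line means is the total and the parental error variance is
plugged in: $H^2 = \max(0, \mathrm{total} - \sigma^2_e)/\mathrm{total}$.
The RIL decomposition is a reconstruction — the original procedure is not
published in detail.

*Transgression.* Per gene, parental means and SDs define the bounds
$\mu_{\max} + 2\,\mathrm{SD}_{\max}$ and $\mu_{\min} - 2\,\mathrm{SD}_{\min}$;
the statistic is the number of RILs outside them. The calling threshold
`n_min` deserves a note: by noise alone each line exceeds the bounds with
probability ~4.6%, so with 120–160 lines requiring only 2 extreme lines
flags almost every gene — a degenerate criterion. Requiring 20 extreme
lines (the reading we adopt of the ambiguous "n = 20" in the source study's
methods) is essentially unreachable by noise ($P(X \ge 20)$ for
$X \sim \mathrm{Bin}(160, 0.046)$ is ~$10^{-5}$) and yields transgression
rates of the observed order; the pipeline defaults to `n_min = 20` while
the bare function keeps `n_min = 2` as a conservative floor for small
populations.

*Enrichment.* `hypergeom_enrichment` computes exact hypergeometric tails in
log space (log-binomial coefficients combined by log-sum-exp; no normal
approximation). The default tail is strict, $P(X > k)$, which is the
convention of common over-representation software and is numerically
consistent with the printed bounds it reproduces; the inclusive tail
$P(X \ge k)$ is available and always reported alongside its mode.
`interval_membership` (closed intervals, 1-based bp) and `binned_counts`
(midpoint-to-midpoint marker loci) provide the NIL-introgression and
density bookkeeping, and `distribution_correlation` the Pearson-$r$ t-test
$t = r\sqrt{(n-2)/(1-r^2)}$ used to compare per-marker distributions.

## The synthetic-data generator

`generate_map` builds an equally spaced map (default 5 chromosomes; the
bundled analyses use 20 markers per 95 cM chromosome, and the FDR
simulations up to 35 per chromosome, the densest case in the emulated
design). `simulate_ril_genotypes` draws each line as a chromosome-wise
Markov chain over markers: first allele fair, then a switch between
adjacent markers at distance $d$ cM with the selfing-RIL probability
$R = 2r/(1+2r)$, $r = (1 - e^{-2d/100})/2$ (Haldane, no interference —
interference is not discussed in the emulated design, and only marker-level
correlation matters downstream; whole-chromosome crossover simulation would
add nothing the statistics can see). The population is treated as fully
inbred (infinite-selfing limit, no heterozygotes), and parents enter as
pseudo-lines of constant genotype so all downstream code treats parents and
RILs uniformly.

`build_architecture` + `simulate_expression` generate expression as
baseline + $\beta_{env} x$ + Gaussian noise per gene, with per-environment
betas expressing the three genotype-by-environment patterns: shared
($\beta_1 = \beta_2$), environment-specific ($\beta = 0$ in one
environment: constant in one parent, plastic in the other), and sign-flip
($\beta_1 \beta_2 < 0$: both parents plastic, with the stronger activation
switching between environments). Cis genes are annotated at (up to a small
jitter) their source marker; trans and null genes get uniform positions.
Default desk-scale conditions: 160 lines, 100 markers, ~2000 genes,
baseline 8 (a typical log2 microarray intensity), noise SD 1, effect sizes
1.5–2; one pooled sample per RIL and replicated parents (9 in the demo),
matching the emulated design's "three plants pooled per RIL, nine per
parent".

What the generator does *not* emulate, and hence what passing tests do not
certify about real data: two-colour array intensities, dye effects and
normalization (values are already normalized log-expression); polygenic
background variance (null genes have *no* genetic variance, so simulated
heritability medians sit far below values seen on real transcriptomes, and
parent-mode $H^2$ is exactly 0 for most genes); correlated expression
noise across genes; missing values; segregation distortion. Parameter
recovery and calibration results transfer to real data only to the extent
that single-locus additive effects with Gaussian noise describe it.

## Numerical conventions and problem sizes

- p-values are floored at the double machine minimum; $-\log_{10} p$ capped
  at 300. Peak ties break leftmost; cofactor ties break by (chromosome,
  position); all greedy procedures are deterministic.
- Every stochastic function takes an explicit integer seed, and the
  pipeline fans a single config seed out to its stages, so a config + seed
  pair reproduces every output file byte-identically.
- TSV is the single file dialect (header, tab, `NA`, floats at 6
  significant digits); truth tables and configs serialize to YAML.
- The bundled analyses and checks run at desk scale — 160 lines, 100
  markers, 500–2000 genes, 1,000 permutations, 120–300 simulation
  replicates — sizes chosen so the whole workflow re-runs in minutes on one
  CPU while keeping Monte-Carlo error well inside the asserted margins. The
  emulated study's full scale (120 lines, up to 35 markers per chromosome,
  ~24,000 transcripts, 10,000 permutations) is reachable through the same
  configuration knobs.

## Known limitations

- The cofactor forward selection is a stand-in for the original
  multiple-QTL-mapping procedure, whose exact cofactor rules are not
  published; conclusions about conditional scans are specific to this
  implementation.
- The pooled-FDR machinery assumes the pool mixes null and true tests in
  realistic proportion; `estimate_fdr_inflation`'s default 10% true-gene
  fraction is a design choice, and the resulting integer correction factor
  is conservative by construction (`ceiling`).
- Whether pooled q-values should use all gene-marker p-values or only peak
  p-values after thinning is ambiguous in the emulated design; both are
  possible here (pass any pool to `pooled_threshold`), and the bundled
  analyses pool all thinned gene-marker p-values.
- Support intervals are maximal supra-threshold marker runs, not LOD-drop
  or confidence intervals; they are bookkeeping, not coverage statements.
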