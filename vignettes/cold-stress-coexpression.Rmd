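---
title: "Methods: coexpression network analysis of cold-stress bark transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression network analysis of cold-stress bark transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frostnet)
```

# The study design frostnet models

frostnet analyses bulk RNA-seq experiments in which dormant woody tissue —
the motivating system is bark from 1-year-old apple branches of a
cold-sensitive cultivar ("G") and a cold-hardy one ("H") — is exposed to a
stepped low-temperature schedule: successive 24 h stages at 4, −4, −9, −14,
−19, −24 and −29 °C. Transcriptomes are taken per cultivar × temperature
(two replicates; 28 samples in all), and three sample traits accompany
them:

* **LT** — the treatment temperature (°C);
* **Ac_LT** — accumulated low temperature, the product of stage temperature
  and stage duration summed over the stages a sample has completed (°C·h;
  `compute_ac_lt()`); a sample held through the full schedule has
  Ac_LT = (4 − 4 − 9 − 14 − 19 − 24 − 29) × 24 = −2280 °C·h;
* **ELR** — electrolyte leakage rate, the initial conductivity of shaken
  stem sections as a percentage of the post-boil maximal conductivity
  (`elr()`), a proxy for membrane damage.

The six freezing temperatures are grouped into an early phase
(Phase I: −4/−9/−14 °C), where leakage stays flat and tissue tolerates the
stress, and a late phase (Phase II: −19/−24/−29 °C), where leakage rises in
the sensitive cultivar.

# Pipeline stages and their models

## Quantification and filtering

Counts are converted to FPKM,
$\mathrm{FPKM}_{gs} = 10^9 \, c_{gs} / (L_g N_s)$, with gene length $L_g$
in bp and library size $N_s$ defaulting to the column sum of counts — the
only computable proxy for total mapped reads when alignments are not
retained. A gene is *expressed* when its FPKM reaches 0.01 (inclusive) in
at least one sample of the chosen scope; the maximum-over-scope reading is
the most permissive literal interpretation of an "FPKM ≥ 0.01" filter, and
a mean-over-scope alternative is exposed (`filter_expressed(stat =)`).
Sample PCA (`pca_samples()`) operates on log2(FPKM + 1), gene-centred and
unscaled — the standard treatment for FPKM, exposed as flags — and reports
per-sample cos² values (squared coordinate shares) as representation
quality.

## Differential expression

DEGs between the chilling treatment (4 °C) and each freezing treatment are
called with a conditional negative-binomial exact test authored in the
package. The count model is NB with variance $\mu + \phi\mu^2$; the same
$\phi$ symbol parameterises the simulator, so the test is evaluated
against data from exactly the model it assumes.

* **Normalization.** Median-of-ratios factors (`normalize_library_sizes()`):
  the per-sample median, over genes with all-positive counts, of the count
  divided by the gene's geometric mean, rescaled to geometric mean 1.
* **Dispersion.** Per gene, a method-of-moments estimate
  $\hat\phi_g = \max\{0, (s^2 - m)/m^2\}$ within replicate groups on
  normalized counts, combined across groups with df weights, then pooled
  across genes **by the mean**. With two replicates per group the per-gene
  statistic is driven by a 1-df variance estimate, approximately
  $\phi\,\chi^2_1$-distributed at large counts; a median pool would
  converge to roughly $0.455\,\phi$ and make the exact test
  anti-conservative, while the mean pool is moment-consistent. This is the
  one place the package deliberately departs from the more obvious robust
  pool, and it is why the null calibration test holds at two replicates.
* **The test.** Counts are scaled to a common effective size and summed
  within groups. Because an NB sum of i.i.d. NB variables with a shared
  mean is again NB (shape $n/\phi$), the conditional distribution of the
  group-A sum given the total is computed exactly by enumeration, and the
  two-sided p-value adds up all splits as or less likely than the observed
  one. At $\phi = 0$ this reduces to the conditional binomial: for group
  sums (10, 0) with equal group sizes, $p = 2/1024$. Thresholds are
  inclusive as printed: chilling-vs-freezing calls require $p \le 0.05$
  **and** BH FDR $\le 0.001$; the within-freezing comparisons against
  −4 °C require fold change $\ge 2$ and $p \le 0.05$ with no FDR step (the
  threshold pair is stated without one). Fold changes use normalized group
  means with a 0.5 pseudo-count.
* **Phase classes.** Per direction of change, a DEG is *PhaseI_II* when
  called at ≥ 1 early and ≥ 1 late temperature, *PhaseII_only* when called
  only at late temperatures, *PhaseI_only* otherwise. Requiring all six
  temperatures for PhaseI_II is a defensible stricter reading; it is
  available as `classify_deg_phases(mode = "all")`, with the ≥ 1-per-phase
  reading as the default.

## Network construction

The coexpression network is built on the cross-cultivar DEG union, by
default on log2(FPKM + 1) (raw-FPKM mode is a flag). Unsigned adjacency
$a_{ij} = |\mathrm{cor}_{ij}|^\beta$; the signed variant is exposed but not
default, matching common practice when only the three headline parameters
of a run are known. The soft threshold $\beta$ is the lowest power whose
scale-free fit index — the signed $R^2$ of log10 bin frequency against
log10 bin mean connectivity over 10 equal-width connectivity bins —
reaches 0.8. When no candidate reaches the cut (typical for data dominated
by a few planted or real modules, where the index climbs slowly with
power), the pipeline falls back to the sample-count rule of thumb used in
coexpression practice: $\beta = 8$ for 20–30 samples in an unsigned
network. Choosing the maximal-$R^2$ power instead would drive $\beta$ to
the top of the candidate range and collapse within-module adjacency.

Topological overlap is
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
with $\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$ and
$k_i = \sum_{u \ne i} a_{iu}$; genes are clustered by average linkage on
$1 - \mathrm{TOM}$.

**Module detection** is a documented two-stage procedure rather than a
re-implementation of dynamic tree cutting: a static cut of the dendrogram,
dissolution of clusters below `min_module_size = 30` into grey, and an
optional rescue pass that reassigns a grey gene to its nearest module when
the average dissimilarity is below 0.6 (between the within-module and
between-module regimes of the TOM dissimilarity). The default cut is a
*fixed height of 0.95*: on TOM dissimilarities, unconnected genes sit in a
dense band just below 1, so a cut placed at a high quantile of the merge
heights lands inside that band, above the heights at which distinct
modules join, and fuses everything; 0.95 is the static-cut convention in
coexpression practice. A `cut_quantile` argument provides the
quantile-of-heights behaviour for callers who want it. Ties are broken
deterministically (lowest label / first index).

Modules whose eigengenes correlate above 0.75 (dissimilarity < 0.25) are
merged iteratively, recomputing eigengenes after each merge until a
fixpoint; labels are then reassigned by decreasing size, with grey (label
0) never counted as a module.

## Eigengenes, gene scores and hub genes

A module eigengene is the first principal component of the module's
standardized expression across samples, rescaled to unit variance and
sign-aligned with the module's mean standardized profile. kME (module
membership / intramodular connectivity) is the correlation of a gene with
its own module's eigengene; gene significance (GS) is the correlation of a
gene with a sample trait; module–trait correlations carry two-sided
p-values from the $t$ distribution with $n - 2$ df.

The hub screen ranks a module's members by |kME|, |GS_LT| and |GS_ELR|,
takes the top 20% by each (ceiling of 0.2 × module size; boundary ties
included so the result is deterministic), and returns the union of the
three pairwise intersections. Absolute values are used because
chilling-responsive modules carry strongly *negative* connectivity–GS
relationships; a signed mode is exposed. GS_Ac_LT is computed and reported
but not screened on, since the screening rule is stated only for the
kME/GS_LT/GS_ELR pairs.

## Enrichment and reporting

`hypergeometric_enrichment()` performs an upper-tail hypergeometric test of
term over-representation with BH correction across terms; the background
universe is a required explicit argument because whole-genome and
expressed-gene backgrounds answer different questions and neither is a
safe default. `run_pipeline()` chains the stages, writes per-stage TSVs, a
JSON summary and a run log, and aborts with the failing stage's name. The
package is driven from R; `run_pipeline()` plus the exported stage
functions are the orchestration surface.

# The synthetic-data generator

`generate_dataset()` emulates the study so every stage can be validated
against planted ground truth without any external data. Its defaults *are*
the package's reference study conditions; they were chosen once, as
follows, and the test suite and acceptance script run against them.

* **Design**: 2 cultivars × 7 temperatures × 2 replicates, as above. ELR
  follows a configurable per-cultivar profile; the default is flat near
  24% with G rising below −19 °C and H rising only at −29 °C — the shape
  of the motivating phenotype, with no figure values claimed. Replicate
  ELR variance is a free parameter (default sd 1.5%, three assay
  replicates averaged); the treatment-level mean is assigned to both
  transcriptome replicates, the only consistent alignment of a 3-replicate
  leakage assay with a 2-replicate transcriptome.
* **Modules**: 5 modules × 100 genes in a 1000-gene transcriptome subset.
  Latents are treatment-level responses built as
  $r\,t + \sqrt{1 - r^2}\,o$ on standardized vectors, with each module's
  random component orthogonalized against all traits and the other
  modules' components, so planted trait couplings are exact and
  cross-module correlation flows only through the traits. Default
  couplings: +0.9 (LT), −0.9 (ELR), +0.6 (LT), −0.6 (Ac_LT), +0.45 (ELR).
  Two strong couplings are deliberately not placed on the same trait: an
  unsigned network cannot distinguish $r = +0.9$ from $r = -0.9$ couplings
  to one trait (their latents correlate −0.81). Loadings are uniform on
  [0.8, 1.2]; gene-level noise sd is 0.3 log2 units, giving within-module
  correlations around 0.9 — a strong but realistic module.
* **Planted DEGs**: 10 genes per phase class per direction per cultivar
  (120 in all), shifted by 2 log2 units. Keeping each class below the
  30-gene module floor ensures planted DEG clusters do not masquerade as
  coexpression modules in the recovery experiment.
* **Counts**: NB draws with $\phi = 0.05$ on means obtained by inverting
  the FPKM formula; baseline log2 FPKM uniform on [2, 8]; lengths 0.5–3 kb;
  library sizes 15–25 million mapped reads. The simulated genes are a
  1000-gene subset of a larger transcriptome, so column sums are smaller
  than the nominal library sizes — the library size is the FPKM
  denominator, not the column sum.
* **Seed**: 20160201 by default; every random draw flows from the single
  seeded generator, so fixtures are byte-identical across runs.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level artifacts (GC and length bias within
a gene, mapping ambiguity), batch effects, count–count correlation beyond
the planted latents, heavy-tailed per-gene dispersion, unbalanced designs,
and any real genome annotation. Recovery results on this generator
demonstrate the correctness and calibration of the algorithms under their
stated model, not performance on arbitrary real experiments.

# Numerical choices and degenerate inputs

* Exact-test enumeration is done in log space and renormalized; observed
  probabilities are compared with a `1 + 1e-10` relative guard so ties at
  the observed split are always included. A zero total gives p = 1.
* Zero-variance genes are dropped (with a warning) from correlation and
  kME computations; a constant trait is an error for GS.
* `scale_free_fit_index()` returns NA when fewer than two connectivity
  bins are occupied, and 0 for an exactly flat bin-frequency profile.
* Eigengene sign ties (zero correlation with the module mean) keep the
  SVD's sign; single-gene modules return the standardized profile with a
  warning.
* Half-up rounding is used for printed percentages
  (`deg_genome_fraction()`), matching how such tables are typeset.
* Welch's form of the t-test is used for two-group phenotype comparisons
  ("t-test" alone underdetermines the variant; unequal variances are the
  robust default). Two zero-variance groups with equal means give p = 1.

# Problem sizes used in validation

The shipped tests and the acceptance script run the full pipeline on the
1000-gene, 28-sample default fixture (a few minutes end to end on one
core), the null-calibration experiment on 2000 genes × 4 samples, and the
oracle comparisons (TOM, BH, hub screen, UPGMA) on small random instances
where brute-force enumeration is exact. These sizes were chosen so that
every validation is an exact or well-powered check while the whole suite
remains quick to run; the algorithms themselves are plain matrix code and
scale to DEG unions of a few tens of thousands of genes, though the dense
TOM matrix (O(n²) memory) is the practical ceiling, and block-wise
decomposition is out of scope.

# Known limitations

* The module detector is a static-cut procedure; it will not reproduce
  WGCNA's dynamic hybrid tree cut label-for-label on real data, and nested
  or close modules separated only by branch-shape criteria will merge or
  dissolve. Module recovery on planted structure is the supported
  contract.
* The exact test uses a common dispersion; per-gene empirical-Bayes
  shrinkage (tagwise dispersion) and GLM-based designs with covariates are
  out of scope.
* With two replicates per group, genes whose chilling replicates draw an
  extreme baseline can fail the FDR ≤ 0.001 bar at every freezing
  temperature; sensitivity for 4-fold planted shifts is about 0.9–1.0 at
  the default conditions, and that is a property of the replication level,
  not of the implementation.
* ELR enters the pipeline at treatment level; replicate-level leakage
  variation is not propagated into module–trait p-values.
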