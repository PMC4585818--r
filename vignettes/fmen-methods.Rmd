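---
title: "Methods: from spot signals to RMT ecological networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spot signals to RMT ecological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmen)
library(dplyr)
```

This vignette documents the models and procedures behind `fmen`, the
assumptions they make, the tunable parameters that matter, and the design
choices taken where the underlying methodology leaves the details open.

## The measurement model

A functional gene array experiment produces, per hybridized slide, one
fluorescence signal per spotted probe. The signal observed for probe $p$ of
gene $g$ on slide $t$ of sample $j$ is modelled (and simulated) as

$$
y_{gpjt} = \underbrace{e^{\mu_g + \sigma_b z_{gj}}}_{\text{biology}}
  \cdot \underbrace{\alpha_p}_{\text{probe affinity}}
  \cdot \underbrace{\beta_{t,\text{grid}} \, \gamma_t \, \delta_j}_{\text{technical biases}}
  \cdot \underbrace{(1 + \varepsilon)}_{\text{noise}},
$$

where gene base intensities $e^{\mu_g}$ are log-normal, per-sample
biological variation $z_{gj}$ is Gaussian on the log scale with SD
`bio_sd`, and $\beta, \gamma, \delta$ are multiplicative sub-grid,
technical-replicate and sample biases — exactly the three levels the
normalization stage removes. Every sub-grid also carries a
reference-standard spot of constant true intensity, so each bias level has
an observable anchor. Genes absent from a sample produce only background
signal with a sub-threshold signal-to-noise ratio, which is how absence
manifests at the spot level.

## Preprocessing

The stage order is fixed: QC → normalization → outlier loop → collapse of
technical replicates → detection call → replicate-consistency filter →
abundance transform.

* **QC** removes spots flagged with codes 1 or 3 and spots with SNR below
  2.0. Boundaries are inclusive on the keep side (SNR = 2.0 is kept): the
  removal rules are phrased as "less than" and "more than", so equality
  survives. SNR is taken as a given input column; its pixel-level
  definition belongs to the image-quantification software, not to this
  pipeline.
* **Normalization** rescales multiplicatively with mean-ratio factors on
  the reference-standard spots, at sub-grid, technical-replicate and
  whole-data-set level in that order. The estimator (ratio of means) is a
  design choice; the methodology names the three levels but not the
  statistic. All scalings are checked strictly positive.
* **Outlier loop**: among the repeated (technical-replicate) measurements
  of a probe, any value deviating from the current mean by more than
  $k = 2$ sample standard deviations is removed, iterating until stable.
  With the $n-1$ denominator the maximum standardized deviation is
  $(n-1)/\sqrt n < 2$ for $n \le 5$, so the rule is provably inert for up
  to five replicates. We document and test this consequence rather than
  "fix" it: with triplicate hybridizations the loop only bites when
  probes are pooled more widely.
* **Detection**: a gene is called present when its positive probes reach
  $\max(\texttt{min\_spots}, \lceil \texttt{fraction} \cdot
  \text{probes} \rceil)$ with defaults 2 and 0.34. "A minimum of two
  spots" is read as a floor, and the fraction is applied per gene (not per
  gene family); both knobs are exposed.
* **Replicate consistency**: detection must be supported by at least 2 of
  the 3 biological replicates of a site × treatment group, otherwise the
  gene is zeroed *in that group only*. Zeroing study-wide would make
  site-level presence (and hence the three-site Venn partitions)
  meaningless, so per-group zeroing is the only interpretation consistent
  with site-resolved core sets.
* **Abundance transform**: $a_{ij} = \ln(s_{ij} / \sum_i s_{ij} \cdot
  \overline{T} + 1)$ with $\overline{T}$ the mean of the per-sample signal
  totals. Zeros map exactly to zero, so detection status survives the
  transform; pre-log scaled abundances per sample sum to $\overline{T}$
  by construction (a conservation identity the tests check to 1e-9).

## Diversity and core-gene algebra

Diversity is intensity-weighted: $p_i$ is gene $i$'s share of the sample's
summed abundance, $H' = -\sum p_i \ln p_i$ (nats) and $1/D = 1/\sum
p_i^2$. By default the proportions are computed from the ln-transformed
abundances — the matrix every downstream stage consumes — with
`use_pre_ln = TRUE` available since the methodology does not state which
scale fed the indices.

Core genes of a treatment are the intersection of its per-site detected
sets; the *increased core* is the planting core minus the non-planting
core. Venn partitions are exact seven-region set partitions (counts sum to
the union; regions are disjoint — both tested properties).

## Mantel machinery

Community dissimilarity uses Bray–Curtis on the abundance matrix
(delegated to `vegan::vegdist`); environmental distances are Euclidean on
(by default z-scored) variables. The Mantel statistic is the Pearson
correlation of upper-triangle vectors; significance comes from jointly
permuting rows/columns of one matrix. Three conventions are fixed here
and exposed as flags:

* **one-tailed (greater)** by default, matching the convention of
  reporting positive associations as significant (strong negative r then
  shows $p \approx 1$);
* the **first matrix is permuted** in the partial test (raw permutation,
  not residual permutation), recomputing the first-order partial
  correlation each round;
* $p = (1 + \#\{r^* \ge r\})/(1 + n_\text{perm})$ with $n_\text{perm} =
  999$ by default, so $p \ge 1/(n_\text{perm}+1)$ and zero p-values are
  impossible.

Under the null (independent distance matrices) the empirical type-I error
at $\alpha = 0.05$ sits in $[0.03, 0.07]$ over 1000 simulated datasets —
recomputed by the test suite and the acceptance script.

## RMT threshold selection

The similarity between genes is the absolute Pearson correlation of their
abundance profiles. For a candidate threshold $S_t$, off-diagonal entries
below $S_t$ are zeroed, retained entries keep their similarity value (unit
diagonal), and rows with no retained neighbour are dropped. The
eigenvalues of this matrix are *unfolded* — mapped through a smoothed
empirical cumulative spectral function (cubic smoothing spline, default
10 effective degrees of freedom, forced monotone) — so that their mean
spacing is 1 regardless of the local density of states. Exactly degenerate
eigenvalues (gap < 1e-10) collapse to one level first.

The nearest-neighbour spacing distribution of the unfolded levels is then
tested against the Poisson form $P(d) = e^{-d}$ with a chi-square
goodness-of-fit on equal-probability exponential bins (default 20 bins,
reduced automatically so expected counts stay ≥ 5; spacings rescaled to
mean exactly 1 first — the raw mean is separately required to be within
5% of 1, so a poor unfolding cannot hide behind the rescale). A matrix
whose spacings *reject* Poisson at $\alpha = 0.05$ behaves like a random
(GOE) matrix with delocalized eigenvectors; acceptance indicates
uncorrelated levels, i.e. the matrix has decomposed into
system-specific, modular structure. The test reproduces both limits:
independent levels (diagonal random matrices) are accepted and GOE
matrices of order 500 rejected, each in ≥ 90% of seeds.

**Threshold rule.** The scan walks $S_t$ over a grid (default 0.30–0.99,
step 0.01; matrices below `min_order = 50` retained nodes are marked
untestable rather than decided) and selects the *lowest Poisson-like
threshold confirmed by the next testable grid point*. An earlier design
required Poisson-like decisions at *every* higher threshold, but the NNSD
decision is demonstrably non-monotone on realistic data: as the threshold
erodes dense similarity blocks, their remnants drift back toward GOE
behaviour before fragmenting, so a strict all-higher rule frequently
rejects every candidate. The one-point confirmation keeps the intended
protection — deep in the GOE regime p-values are ~1e-20, so an isolated
false acceptance cannot recruit a confirming neighbour — while remaining
well-defined on non-monotone traces. `stability_window = Inf` restores
the strict rule.

Networks are then built *unweighted* at the chosen $S_t$ (edge iff
$s_{ij} \ge S_t$), isolated nodes removed; the eigenvalue stage alone uses
the weighted matrix. Topology is summarised by size $n$, links $L$, and
avgK $= 2L/n$ (an exact identity, tested as such). Modules come from
deterministic Newman-type greedy modularity agglomeration
(`igraph::cluster_fast_greedy`), with the cut along the merge tree chosen
by recomputed modularity and ties resolved toward fewer modules, so module
counts are reproducible; counts are reported both with and without
singleton modules since either convention appears in published tables.

## The synthetic generator: what it does and does not emulate

Defaults describe the emulated study: 3 sites × 2 treatments (maize
planting vs bare fallow) × 3 biological replicates, triplicate
hybridizations per sample, 500 genes × 4 probes, 4 sub-grids per slide.
Treatment affects *richness* through per-group Bernoulli presence masks —
not intensity shifts — so detection-call behaviour is genuinely
exercised: a quarter of genes form the non-planting core (2.5% of which
drop one planted site, emulating the small observed core dropout),
another quarter become core only under planting, 15% are confined to one
site, and the rest are scattered with per-site presence probabilities
0.35 (unplanted) vs 0.55 (planted). Scattered presence uses *nested*
uniform draws shared across treatments, so every unplanted occurrence
persists under planting and the core-superset relation holds
structurally. Correlated modules are induced by a shared latent Gaussian
factor per module on the log-intensity scale
($z = \sqrt\rho F_m + \sqrt{1-\rho}\,\epsilon$), drawn from the
planting-only core so they survive core filtering. Environmental
variables are baseline + treatment effect + site effect + noise, with the
plant variables (AGB, SPAD) zero under fallow and the climate variables
(AR, RH) purely site-determined.

With 9 planted samples the *sample* correlation between genes of
different modules is inflated by chance correlation of the 9-sample
latent factors ($E|r| \approx 0.28$ under independence at $n=9$); the
generator's mechanism is therefore validated at larger replicate counts
(36 planted samples: mean within-module $|r| \ge 0.7$, between-module
$\le 0.3$), while under study conditions the tested property is
separation (within > between) rather than an absolute between-module
bound.

What the generator does **not** emulate: probe sequences and
hybridization thermodynamics, spatial slide artefacts, dye bias,
cross-hybridization, and non-log-normal signal tails. Passing tests
therefore demonstrate that the *pipeline logic* is correct under a
realistic factorial noise model, not that any particular biological
dataset would yield identical numbers.

## Problem sizes and numerical choices

The validation suites use sizes chosen to make the statistical properties
sharp yet quick to recompute: NNSD discrimination on order-500 matrices
over 20 seeds; module recovery on the default 500-gene design (3 modules
× 30 genes, $\rho = 0.9$, 18 samples) over 10 seeds, scored by normalized
mutual information against ground truth with success defined as
NMI ≥ 0.8; Mantel type-I error over 1000 null datasets × 999 permutations
(500 in the acceptance script). Degenerate inputs fail loudly and
specifically: empty QC output, missing reference spots, all-zero sample
columns, constant distance vectors, collinear conditioning matrices,
edgeless networks and exhausted threshold scans each carry their own
error class or message, and the scan failure transports its full
per-threshold trace for audit.

## Known limitations

* The NNSD chi-square needs ≳ 50 retained nodes; below that the scan
  marks thresholds untestable, and very small studies may yield no
  admissible threshold at all.
* Similarity from 9 samples per treatment is noisy; spurious edges at
  high thresholds are expected and module recovery is statistical, not
  exact.
* The one-point confirmation rule can still, in principle, select inside
  a transient Poisson window on pathological spectra; inspect
  `autoplot()` of the scan trace when in doubt.
* Mantel conditioning sets must be chosen by the analyst; the package
  does not infer which environmental variables to partial out.
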