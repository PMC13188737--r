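---
title: "Models and methods behind qsipcge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qsipcge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsipcge)
```

# The experiment this package models

A dry Mediterranean grassland soil is rewetted with ^18^O-enriched water.
Microbes that grow after the wet-up synthesize DNA using oxygen from that
water, so their DNA becomes denser. Separating each sample's DNA on a CsCl
density gradient, quantifying 16S rRNA gene copies per density fraction by
qPCR, and sequencing the fractions lets one attribute density shifts to
individual taxa (quantitative stable isotope probing, qSIP). Together with
headspace CO~2~, this yields taxon-specific growth and mortality rates and a
community growth efficiency (CGE) metric; FTICR-MS peak lists describe the
organic-matter substrate pool; and a gene-by-sample expression matrix lets a
partial least squares regression (PLSR) rank transcripts by their
association with CGE.

The package implements that inference chain end to end, plus a forward
simulator with known ground truth so every stage is testable without any
external data.

# Excess atom fraction from density shifts

For a taxon with unlabeled weighted mean buoyant density $W_{light}$ and
labeled density $W_{lab}$, the standard qSIP chain is

$$G = \frac{W_{light} - 1.646057}{0.083506}, \qquad
  M_{light} = 0.496\,G + 307.691,$$
$$M_{lab} = M_{light}\frac{W_{lab}}{W_{light}}, \qquad
  EAF = \frac{M_{lab} - M_{light}}{(M_{light} + 12.07747) - M_{light}}
        \,(1 - 0.002000429).$$

$W$ is the abundance-weighted mean of fraction densities, with per-fraction
abundance = (ASV relative abundance in the fraction) x (total 16S copies in
the fraction). All calibration constants live in `qsip_config()` and can be
recalibrated; they follow the standard qSIP formulation. Negative EAF values
are retained rather than truncated so that classifying taxa as growing via
the confidence interval stays unbiased.

Control (natural-abundance) samples carry no labeling signal, so control
densities are pooled across the five post-rewetting harvests: 3 plots x 5
timepoints gives up to 15 control replicates per taxon. A taxon must occur
in at least 3 of those 15 and in all labeled replicates of a
treatment-timepoint to be estimated — the same rare-taxon guard the study
design uses.

## Bootstrap confidence intervals and their calibration

EAF intervals come from a percentile bootstrap (1000 iterations): replicate
densities are resampled with replacement, the EAF recomputed from the
resampled means, and the 2.5/97.5 percentiles reported; the point estimate
is the bootstrap median (robust to the skew the nonlinear density-to-EAF map
induces).

The resampling unit is genuinely ambiguous, so the package implements three
schemes and quantifies their calibration on simulated data (the acceptance
suite recomputes this): resampling replicate plots (`resample = "plot"`, the
default, mirroring a bootstrap over replicate tubes) is anti-conservative
with only 3 labeled replicates — simulated coverage of the nominal 95%
interval is near 80–85%, the familiar small-sample behaviour of the
percentile bootstrap, not a data defect. Resampling gradient fractions
within replicates (`"fraction"`), or both (`"hierarchical"`), widens the
intervals into over-coverage (essentially 100%), because fraction
resampling counts the band's intrinsic density spread as sampling noise.
We keep plot-level resampling as the default because it matches the
experimental replication structure, and document that its 95% intervals
should be read as roughly 80–85% intervals at this replicate count.

## The resolution limit of pooled density bins

The study sequenced 5 pooled density bins rather than all 36 fractions.
A taxon's band (spread ~0.006 g/mL) usually sits inside one bin
(widths 0.013–0.064 g/mL), and the bin's density is a bulk copy-weighted
average, so the binned weighted mean cannot localize the band: per-taxon
EAF estimates from pooled bins carry a deterministic resolution bias (a
dedicated test measures its magnitude, roughly 0.03–0.10 in EAF units for a
mixed community). Community-level contrasts — treatment ratios of growth,
the direction of CGE differences — are robust to it. Estimator-calibration
checks (exact round-trips, noise-only recovery, CI coverage) therefore run
on the unpooled 36-fraction tables (`simulate_gradient(pool = FALSE)`),
which are unbiased; the pooled route remains the pipeline default because
it is what the experimental design produces.

# Growth, mortality, and community growth efficiency

Population growth is modeled as linear over each interval $[0, t]$
(t in days, from the 3/24/48/72/168 h harvests). The fraction of a taxon's
DNA that is new follows from its EAF:

$$a_t = \frac{EAF}{0.60\,(x_w - 0.002000429)},$$

where 0.60 is the fraction of DNA oxygen drawn from water and $x_w$ the
^18^O atom fraction of soil water (default 0.85: 98-atom% water diluted by
residual soil moisture; the true value is configurable because it is not
directly measured). Then

$$g = \frac{N_t\,a_t}{t}, \qquad m = \frac{N_0 - N_t(1 - a_t)}{t},$$

which satisfy the bookkeeping identity $gt - mt = N_t - N_0$ exactly.
Negative mortality estimates (possible under noise) are floored at zero and
flagged; the raw value is kept. Absolute abundances $N_t$ are qPCR totals
times composite relative abundances, averaged over replicate jars, with the
0 h harvest supplying $N_0$.

Community rates are sums of taxon rates. Cumulative new biomass is
$B(t) = \sum_i N_{it} a_{it}$ — equivalent to (community growth rate) x
(time) under the linear model, but computed from one estimate rather than
two. With cumulative respiration $R(t)$ (each jar is destructively
harvested, so its headspace total is its cumulative CO~2~),

$$CGE_{raw} = B / R, \qquad CGE = CGE_{raw} / \max(CGE_{raw}),$$

so exactly one record scores 1. CGE~raw~ has units of copies per µmol and is
a relative metric; no copies-to-carbon conversion is attempted. Records with
$R = 0$ (the 0 h baseline) are flagged and excluded from the maximum.

# Composite community profiles

Fraction-level sequencing is turned into a bulk-equivalent profile by
weighting each fraction by its share of the sample's 16S copies, adjusting
read counts by those weights, and summing DNA-weighted ASV counts across
fractions. Taxa below 0.01% relative abundance are then removed (strict
less-than, judged on the across-sample mean by default, per-sample by flag)
and abundances renormalized so downstream summaries total 1. Compositing is
done before filtering; both orderings are defensible and the filter is
idempotent either way.

# FTICR-MS chemistry

Peak lists are aligned by greedy single-linkage on sorted m/z with a 0.5 ppm
gap threshold; clusters spanning more than twice the tolerance are split at
their largest internal gap, deterministically. Features present in any
extraction blank are removed, then features seen in fewer than two samples.
The method is presence/absence; intensities are carried but never used for
inference.

Formula assignment is an exhaustive CHNO search (C >= 1, H >= 1, O >= 0,
N <= 2, S = P = 0) against the neutral mass m/z + 1.00727646688, under
chemical validity (H <= 2C + N + 2, integer non-negative ring-double-bond
equivalents, even-electron parity) and a 0.5 ppm error ceiling. The smallest
absolute error wins; two candidates within 0.05 ppm of each other leave the
peak unassigned with an ambiguity flag — below 800 Da such collisions are
rare and recovery of simulated formulas is essentially complete.

Classes come from rectangular O:C / H:C regions on the van Krevelen plane
(`vk_boundaries()`, MetaboDirect convention, applied in a fixed precedence
order so every point maps to at most one class). Thermodynamics:
NOSC = 4 − (4C + H − 3N − 2O + 5P − 2S)/C and GFE = 60.3 − 28.5 NOSC
(kJ per mol C); both coefficients are arguments.

A compound is detected in a treatment when present in at least 2 of its 3
plots (pooled across timepoints; a per-timepoint mode is a flag away), and
unique when detected in exactly one treatment. Class enrichment among
unique compounds uses the log-likelihood-ratio G-test: one overall test on
the class x treatment table, then one 2x2 test per class (class versus all
others) with Benjamini–Hochberg correction across classes, and a log2 fold
change of class proportions (proportions, not counts, so unequal totals do
not masquerade as enrichment).

# Associating transcripts with CGE

The PLSR of log CGE on the gene-by-sample matrix uses NIPALS after
mean-centering and unit-variance scaling (autoscaling; center-only is a
flag). Samples from the 0 h harvest are excluded — no labeled samples exist
there, so CGE is undefined — and any sample with non-positive CGE is
dropped with a message. The number of components is chosen by leave-one-out
prediction error up to 10 unless fixed. Variable importance in projection is

$$VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\lVert w_a \rVert)^2 \big/ \sum_a SS_a},$$

which satisfies $\sum_j VIP_j^2 = p$; genes in the top decile are selected
(ties at the threshold all included) with direction from the sign of the
regression coefficient. Pathway-level checks sum the normalized abundances
of selected genes within curated pathway lists and report Pearson
correlations with log CGE, BH-corrected across pathways; a ratio variant
(e.g. biosynthesis over energy production) drops samples with a zero
denominator. A synthetic default pathway list matching the simulated gene
ids ships in `inst/extdata/pathways_synthetic.tsv`; real analyses should
supply their own curated list.

# The synthetic experiment

`sim_config()` fixes the study conditions: 2 treatments (100% and 50% of
mean annual precipitation) x 3 plots x harvests at 0/3/24/48/72/168 h; 36
gradient fractions over 1.64–1.78 g/mL pooled into the 5 sequencing bins;
lognormal initial abundances; per-taxon GC in 0.35–0.70 mapping to density
through the same calibration the estimator inverts (forward/inverse
symmetry makes parameter recovery a clean test).

Forward dynamics are linear birth-death mirroring the estimator's
bookkeeping: new copies $g t$, deaths drawn from the pre-existing pool
$m t$, so new + surviving old = total exactly. Per-capita mortality draws
are capped at 0.95 of the feasibility bound so no taxon exhausts its old
DNA within the week (configs that would do so anyway are rejected). An
exponential mode exists for robustness experiments only.

Noise models and their defaults are chosen from the stated experimental
conditions: qPCR copies carry lognormal noise with CV 0.1 (assays run in
triplicate and averaged; a single-assay CV near 0.2 divided by sqrt(3));
reads are multinomial at 30,000 per bin library (one MiSeq v2 300-cycle run
shared across 330 bin libraries is ~45,000 reads each; 30,000 is
conservative); CO~2~ has 10% lognormal measurement noise; expression counts
are negative binomial (size 10) around means whose logs track log CGE with
slope ±1 for the 50 planted genes. FTICR mass error is Gaussian with 0.2 ppm
sd truncated at 2.5 sd — internal recalibration bounds residual errors, and
an unbounded error model would place ~1% of peaks outside the 0.5 ppm
assignment window by construction, which contradicts the acquisition
conditions being emulated.

What the generator does **not** emulate: plot-to-plot biological
heterogeneity (replicate variation is purely measurement noise), taxon
interactions, time-varying rates within the week, 16S copy-number variation
between taxa, chimeras and sequencing artifacts, fungi, and intensity
information in FTICR spectra. Passing tests therefore demonstrate the
correctness and calibration of the inference chain under the stated noise
processes — not robustness to every failure mode of real soil data.

# Numerical choices and problem sizes

All randomness flows from one root seed split per stage, so a repeated run
is byte-identical. Gradient masses are exact Gaussian integrals over
fraction ranges, renormalized to conserve each taxon's total mass to
machine precision; fraction densities are interval midpoints (for a band
spread well above the fraction width the midpoint discretization error in
the weighted mean is below 1e-12 g/mL, which is what makes 1e-6 EAF
round-trips attainable). Zero-abundance taxa are dropped rather than
returned as NaN densities; empty bins keep their geometric midpoint as
density. The G-test adds nothing for zero observed cells and rejects only
truly empty tables; quantiles everywhere are R's default type 7.

Validation runs use deliberately modest sizes — 200 taxa for recovery
checks, 500 simulation repeats for CI calibration, 100 repeats for the CGE
direction check, 1000 formulas for assignment recovery, 1000 genes x 30
samples for the PLSR checks — chosen so the full suite stays comfortably
within a coffee break on a single core while keeping Monte-Carlo error
well below the decision margins.

# Known limitations

* Pooled-bin EAF estimates carry the resolution bias described above; use
  unpooled fraction tables when per-taxon EAF accuracy matters.
* Percentile bootstrap intervals under-cover at 3 labeled replicates;
  treat them as ~80–85% intervals, or increase replication.
* CGE is relative (normalized to the experiment-wide maximum) and its raw
  units (copies per µmol) are not a carbon-use efficiency.
* Formula assignment is CHNO-only by design; S/P-containing chemistry is
  out of scope.
* The PLSR component count from leave-one-out selection can be unstable for
  near-null signals; fix `ncomp` for strict reproducibility across subsets.
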