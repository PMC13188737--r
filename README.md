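# qsipcge

Quantitative inference for soil rewetting experiments that label growing
microbes with ¹⁸O-enriched water (H₂¹⁸O qSIP). The package is aimed at
microbial ecologists who have fraction-level CsCl-gradient data (per-fraction
densities, 16S qPCR copies, and ASV read counts), headspace CO₂
measurements, FTICR-MS peak lists, and/or normalized transcript matrices,
and want to go from those tables to taxon-specific growth and mortality
rates, a community growth efficiency metric, organic-matter chemistry, and
gene–CGE associations — with every step testable against a built-in
forward simulator with known ground truth.

## What it computes

**Excess atom fraction (EAF).** A taxon's weighted mean buoyant density is
W = Σ x_f·ab_f / Σ ab_f over gradient fractions, with ab_f = (relative ASV
abundance in fraction f) × (16S copies in f). With control density W_light
and labeled density W_lab:

    G        = (W_light − 1.646057) / 0.083506
    M_light  = 0.496·G + 307.691
    M_lab    = M_light · W_lab / W_light
    EAF      = (M_lab − M_light) / 12.07747 · (1 − 0.002000429)

Controls are pooled across post-rewetting harvests (3 plots × 5 timepoints
= 15 replicates); taxa present in ≥3 control and all labeled replicates are
bootstrapped (1000 iterations, percentile 95% CIs).

**Growth, mortality, CGE.** Under linear population growth, a_t =
EAF / (0.60·(x_water − x_natural)) is the fraction of new DNA, and

    g = N_t·a_t / t        m = (N_0 − N_t·(1 − a_t)) / t
    B = Σ_i N_it·a_it      CGE_raw = B / R      CGE = CGE_raw / max(CGE_raw)

with R the cumulative CO₂ efflux (µmol per g dry soil).

**FTICR-MS chemistry.** Peak alignment (0.5 ppm), blank subtraction,
≥2-sample presence filter, exhaustive CHNO formula assignment (N ≤ 2,
S = P = 0, <0.5 ppm), van Krevelen compound classes, NOSC and Gibbs free
energy (GFE = 60.3 − 28.5·NOSC kJ/mol C), treatment-unique compounds
(present in ≥2 of 3 plots of exactly one treatment), and G-tests of class
enrichment with FDR correction.

**Transcript associations.** NIPALS partial least squares regression of
log CGE on a gene-by-sample matrix, VIP scores (Σ VIP² = p), top-decile
selection with coefficient signs, and pathway-sum Pearson correlations.

## Worked example

Simulate a study-shaped experiment (2 precipitation treatments × 3 plots ×
6 harvests, 36 fractions pooled into 5 bins) and run the chain:

```r
library(qsipcge)

cfg       <- sim_config(n_taxa = 20, seed = 42)
truth     <- simulate_dynamics(cfg)
fractions <- simulate_gradient(truth)
eaf       <- eaf_estimate(fractions, seed = 42)
head(eaf[, c("taxon","treatment","timepoint_h","eaf","ci_low","ci_high","growing")], 4)
#>   taxon treatment timepoint_h    eaf ci_low ci_high growing
#> 1 t001  100                 3 0.0262 0.0206  0.0326 TRUE
#> 2 t002  100                 3 0.0256 0.0248  0.0263 TRUE
#> 3 t003  100                 3 0.0548 0.0511  0.0581 TRUE
#> 4 t004  100                 3 0.0327 0.0319  0.0335 TRUE
```

Each row is a taxon×treatment×timepoint EAF with its bootstrap interval;
`growing` marks intervals excluding zero. Rates and the CGE metric:

```r
rates <- qsip_rates(eaf, taxon_abundances(fractions))
cge   <- cge_table(rates, cumulative_co2(simulate_co2(truth)))
cge[cge$timepoint_h == 24, c("treatment","b_copies_g","r_umol_g","cge_raw","cge")]
#>   treatment b_copies_g r_umol_g  cge_raw   cge
#> 1 100       240350939.     59.5 4039939. 1
#> 2 50         26316847.     21.5 1224863. 0.303
```

At 24 h the normal-precipitation community has built ~240 million new 16S
copies per gram against 59.5 µmol CO₂; the reduced-precipitation community
is about 3× less efficient on the normalized scale (here the 100% MAP
record at 24 h happens to be the experiment-wide maximum, CGE = 1).
Formula assignment works peak by peak — deprotonated glucose:

```r
assign_formula(179.05611)[, c("C","H","N","O","error_ppm")]
#>   C  H N O error_ppm
#> 1 6 12 0 6   0.00916
```

`run_pipeline(sim_config(seed = 1))` executes every stage in order
(simulation → EAF → rates → CGE → composite community → FTICR → PLSR) and
returns all stage tables; `plot_cge()`, `plot_community_rates()`,
`plot_van_krevelen()` and `autoplot()` on the PLSR fit give the standard
figures.

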