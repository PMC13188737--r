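#' qSIP calibration constants and filtering rules
#'
#' Bundles the constants of the standard H2-18O qSIP calculation: the linear
#' map from DNA buoyant density to GC content, the linear map from GC content
#' to the molecular weight of a DNA base pair, the maximum mass gain of a base
#' pair when every oxygen atom is replaced by 18O, the natural abundance of
#' 18O, and the replicate-presence filters and bootstrap settings used when
#' estimating excess atom fraction (EAF).
#'
#' All constants are exposed so the calculation can be recalibrated; the
#' defaults are the values used throughout the package.
#'
#' @param o_fraction_from_water Fraction of oxygen atoms in new DNA sourced
#'   from soil water (rather than organic precursors). Default 0.60.
#' @param natural_18o_abundance Natural atom fraction of 18O. Default
#'   0.002000429.
#' @param density_intercept,density_slope Linear calibration of unlabeled DNA
#'   buoyant density (g/mL) against GC content:
#'   `density = intercept + slope * GC`.
#' @param mw_slope,mw_intercept Linear calibration of average base-pair
#'   molecular weight (g/mol) against GC content:
#'   `MW = mw_slope * GC + mw_intercept`.
#' @param delta_m_max_18o Maximum molecular-weight gain (g/mol) of a base pair
#'   at full 18O substitution. Default 12.07747.
#' @param n_boot Bootstrap iterations for EAF confidence intervals.
#' @param min_control_reps Minimum control (natural-abundance) replicates a
#'   taxon must appear in (out of the pooled control set) to be retained.
#' @param min_label_reps Minimum labeled replicates a taxon must appear in
#'   (out of all labeled replicates at a treatment-timepoint) to be retained.
#' @param water_18o_atom_fraction Atom fraction of 18O in soil water after
#'   adding the label (98-atom% water diluted by residual soil moisture).
#'
#' @return A list of class `qsip_config`.
#' @examples
#' cfg <- qsip_config()
#' cfg$o_fraction_from_water
#' @export
qsip_config <- function(o_fraction_from_water = 0.60,
                        natural_18o_abundance = 0.002000429,
                        density_intercept = 1.646057,
                        density_slope = 0.083506,
                        mw_slope = 0.496,
                        mw_intercept = 307.691,
                        delta_m_max_18o = 12.07747,
                        n_boot = 1000,
                        min_control_reps = 3,
                        min_label_reps = 3,
                        water_18o_atom_fraction = 0.85) {
  cfg <- list(
    o_fraction_from_water = o_fraction_from_water,
    natural_18o_abundance = natural_18o_abundance,
    density_intercept = density_intercept,
    density_slope = density_slope,
    mw_slope = mw_slope,
    mw_intercept = mw_intercept,
    delta_m_max_18o = delta_m_max_18o,
    n_boot = as.integer(n_boot),
    min_control_reps = as.integer(min_control_reps),
    min_label_reps = as.integer(min_label_reps),
    water_18o_atom_fraction = water_18o_atom_fraction
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) abort("all qsip_config fields must be numeric")
  if (any(vapply(cfg[c(
    "o_fraction_from_water", "natural_18o_abundance", "density_intercept",
    "density_slope", "mw_slope", "mw_intercept", "delta_m_max_18o"
  )], function(x) x <= 0, logical(1)))) {
    abort("qSIP calibration constants must be positive")
  }
  for (f in c("o_fraction_from_water", "natural_18o_abundance",
              "water_18o_atom_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste(f, "must lie in [0, 1]"))
  }
  structure(cfg, class = "qsip_config")
}

#' Van Krevelen compound-class boundary table
#'
#' Rectangular O:C / H:C regions used to assign a biochemical compound class
#' to each molecular formula, following the MetaboDirect convention. Regions
#' overlap; classification applies them in the row order given here
#' (first match wins), so the table's order is part of the definition.
#'
#' @return A tibble with columns `class`, `oc_min`, `oc_max`, `hc_min`,
#'   `hc_max`, `oc_min_open`, `hc_max_open` describing each region.
#'   `oc_min_open = TRUE` means the lower O:C bound is strict (`>`), and
#'   `hc_max_open = TRUE` means the upper H:C bound is strict (`<`).
#' @examples
#' vk_boundaries()
#' @export
vk_boundaries <- function() {
  tribble(
    ~class,                    ~oc_min, ~oc_max, ~hc_min, ~hc_max, ~oc_min_open, ~hc_max_open,
    "lipid",                     0,       0.3,     1.5,     2.5,    TRUE,         FALSE,
    "unsaturated-hydrocarbon",   0,       0.125,   0.8,     2.5,    FALSE,        TRUE,
    "protein",                   0.3,     0.55,    1.5,     2.3,    TRUE,         FALSE,
    "amino-sugar",               0.55,    0.7,     1.5,     2.2,    TRUE,         FALSE,
    "carbohydrate",              0.7,     1.5,     1.5,     2.5,    TRUE,         FALSE,
    "lignin",                    0.125,   0.65,    0.8,     1.5,    TRUE,         TRUE,
    "tannin",                    0.65,    1.1,     0.8,     1.5,    TRUE,         TRUE,
    "condensed-hydrocarbon",     0,       0.95,    0.2,     0.8,    FALSE,        TRUE
  )
}

# monoisotopic masses (u); proton mass for [M-H]- conversion
.masses <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  proton = 1.00727646688
)

#' Experiment simulation configuration
#'
#' Parameters of the forward simulator that emulates a rewetting 18O-water
#' labeling experiment: taxon abundance dynamics under linear birth and death,
#' CsCl gradient fractionation and pooled-bin sequencing, headspace CO2
#' accumulation, FTICR-MS peak lists, and a gene expression matrix with genes
#' whose expression tracks community growth efficiency.
#'
#' Defaults mirror the design of the emulated field study: two legacy
#' precipitation treatments (`"100"` = normal, `"50"` = reduced mean annual
#' precipitation), 3 plots per treatment, harvests at 0/3/24/48/72/168 h,
#' 36 gradient fractions pooled into 5 density bins.
#'
#' @param n_taxa Number of simulated taxa.
#' @param n_plots_per_treatment Replicate plots per treatment.
#' @param timepoints_h Harvest times in hours; must start at 0.
#' @param growth_per_capita Named list (by treatment) of mean per-capita
#'   growth rate (per day, relative to initial abundance).
#' @param mortality_per_capita Named list (by treatment) of mean per-capita
#'   mortality rate (per day).
#' @param rate_cv Lognormal coefficient of variation of per-taxon rates
#'   around the treatment means.
#' @param n0_meanlog,n0_sdlog Lognormal parameters of initial taxon
#'   abundances (16S copies per g soil).
#' @param gc_range Range of per-taxon GC content (fractions).
#' @param water_18o_atom_fraction Atom fraction of 18O in soil water after
#'   labeling.
#' @param o_fraction_from_water Fraction of DNA oxygen drawn from water.
#' @param gradient_sigma Within-gradient density spread per taxon (g/mL).
#' @param n_fractions Number of gradient fractions.
#' @param density_range Density range spanned by the fractions (g/mL).
#' @param bin_edges Boundaries of the pooled density bins (g/mL); must be
#'   strictly increasing and cover `density_range`.
#' @param seq_depth Reads per sample-bin for the multinomial read simulator
#'   (default 30000, the order implied by one MiSeq v2 300-cycle run shared
#'   across 330 bin libraries).
#' @param qpcr_cv Lognormal coefficient of variation of the qPCR copy totals
#'   as used downstream, i.e. of triplicate-averaged assays (default 0.1).
#' @param true_cge_by_treatment Named list (by treatment) of true community
#'   growth efficiency used to generate CO2.
#' @param co2_scale Copies of 16S per micromole CO2-C at CGE = 1; converts
#'   biomass units to respiration units.
#' @param co2_noise_cv Multiplicative lognormal noise on CO2 measurements.
#' @param n_genes,n_planted_genes Total genes and genes with a planted
#'   CGE-linked expression slope.
#' @param planted_effect Slope of mean log expression against log CGE for
#'   planted genes (half positive, half negative).
#' @param nb_dispersion Negative-binomial size parameter for expression
#'   counts (larger = less overdispersed).
#' @param expr_baseline_log Mean log baseline expression.
#' @param n_compounds,n_unique_per_treatment FTICR features simulated and
#'   features planted as unique to each treatment.
#' @param mz_ppm_sd Gaussian mass-error standard deviation (ppm) added to
#'   theoretical m/z values.
#' @param detect_prob Per-sample detection probability for shared FTICR
#'   features.
#' @param exponential_growth If `TRUE`, abundances follow exponential birth
#'   and death instead of the default linear model (for robustness
#'   experiments; the estimator assumes the linear model).
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_taxa = 10, seed = 1)
#' cfg$timepoints_h
#' @export
sim_config <- function(n_taxa = 60,
                       n_plots_per_treatment = 3,
                       timepoints_h = c(0, 3, 24, 48, 72, 168),
                       growth_per_capita = list("100" = 0.5, "50" = 0.05),
                       mortality_per_capita = list("100" = 0.08, "50" = 0.03),
                       rate_cv = 0.6,
                       n0_meanlog = log(1e7),
                       n0_sdlog = 1.0,
                       gc_range = c(0.35, 0.70),
                       water_18o_atom_fraction = 0.85,
                       o_fraction_from_water = 0.60,
                       gradient_sigma = 0.006,
                       n_fractions = 36,
                       density_range = c(1.64, 1.78),
                       bin_edges = c(1.6400, 1.70395, 1.71695, 1.72995,
                                     1.74495, 1.7800),
                       seq_depth = 30000,
                       qpcr_cv = 0.1,
                       true_cge_by_treatment = list("100" = 0.4, "50" = 0.1),
                       co2_scale = 1e7,
                       co2_noise_cv = 0.1,
                       n_genes = 1000,
                       n_planted_genes = 50,
                       planted_effect = 1.0,
                       nb_dispersion = 10,
                       expr_baseline_log = log(500),
                       n_compounds = 1200,
                       n_unique_per_treatment = 60,
                       mz_ppm_sd = 0.2,
                       detect_prob = 0.9,
                       exponential_growth = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (length(cfg$timepoints_h) < 2 || cfg$timepoints_h[1] != 0 ||
      is.unsorted(cfg$timepoints_h, strictly = TRUE)) {
    abort("timepoints_h must start at 0 and increase strictly")
  }
  if (is.unsorted(cfg$bin_edges, strictly = TRUE)) {
    abort("bin_edges must be strictly increasing")
  }
  if (min(cfg$bin_edges) > cfg$density_range[1] + 1e-9 ||
      max(cfg$bin_edges) < cfg$density_range[2] - 1e-9) {
    abort("bin_edges must cover the full density range")
  }
  for (f in c("water_18o_atom_fraction", "o_fraction_from_water",
              "detect_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste(f, "must lie in [0, 1]"))
  }
  if (any(unlist(cfg$growth_per_capita) < 0) ||
      any(unlist(cfg$mortality_per_capita) < 0)) {
    abort("per-capita rates must be non-negative")
  }
  if (any(unlist(cfg$true_cge_by_treatment) <= 0)) {
    abort("true_cge_by_treatment must be positive")
  }
  if (!identical(sort(names(cfg$growth_per_capita)),
                 sort(names(cfg$true_cge_by_treatment)))) {
    abort("treatment names must agree across rate and CGE lists")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_taxa, "taxa,",
      length(x$growth_per_capita), "treatments x",
      x$n_plots_per_treatment, "plots x",
      length(x$timepoints_h), "timepoints; seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.qsip_config <- function(x, ...) {
  cat("<qsip_config> o_water =", x$o_fraction_from_water,
      "| n_boot =", x$n_boot,
      "| filters:", x$min_control_reps, "control /",
      x$min_label_reps, "label reps\n")
  invisible(x)
}
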