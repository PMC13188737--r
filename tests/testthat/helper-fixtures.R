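# Shared fixtures built in code.

# minimal two-bin fraction table for hand-computable weighted means
tiny_fraction_table <- function() {
  tibble::tibble(
    sample_id = "s1", plot = 1L, treatment = "100", timepoint_h = 24,
    label = "18O", bin_id = 1:2, density_g_ml = c(1.70, 1.72),
    copies_16s = c(1, 3), asv_a = c(100L, 100L)
  )
}

# small community with a single treatment, deterministic rates
small_sim_config <- function(seed, n_taxa = 5, ...) {
  args <- utils::modifyList(
    list(
      n_taxa = n_taxa, seed = seed,
      growth_per_capita = list("100" = 0.5),
      mortality_per_capita = list("100" = 0.08),
      true_cge_by_treatment = list("100" = 0.4)
    ),
    list(...)
  )
  do.call(sim_config, args)
}

# plant an exact fraction-new-DNA value a* at the final timepoint: with
# zero mortality and no rate jitter, a(t) = g*t / (1 + g*t) so
# g = a / (t * (1 - a))
config_with_planted_a <- function(a_target, seed = 1) {
  t_final <- 7 # days
  g <- if (a_target >= 1) stop("a must be < 1") else {
    a_target / (t_final * (1 - a_target))
  }
  sim_config(
    n_taxa = 1, seed = seed, rate_cv = 0,
    growth_per_capita = list("100" = g),
    mortality_per_capita = list("100" = 0),
    true_cge_by_treatment = list("100" = 0.4),
    gc_range = c(0.5, 0.5)
  )
}

planted_eaf_lookup <- function(truth, est) {
  tr <- truth$abundance
  tr$eaf[match(paste(est$taxon, est$treatment, est$timepoint_h),
               paste(tr$taxon, tr$treatment, tr$timepoint_h))]
}
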