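# Growth/mortality rates and the community growth efficiency (CGE) metric.
#
# Under the linear population model, over an interval of t days a taxon's
# new copies are N_t * a_t (a_t = fraction of its DNA that is newly
# synthesized, from EAF) and the old copies that died are
# N_0 - N_t * (1 - a_t), giving interval-averaged absolute rates
#   g = N_t * a_t / t,   m = (N_0 - N_t * (1 - a_t)) / t
# with the bookkeeping identity g*t - m*t = N_t - N_0.

#' Fraction of new DNA from excess atom fraction
#'
#' Converts 18O excess atom fraction into the fraction of a taxon's DNA that
#' was newly synthesized during the incubation, given the atom fraction of
#' 18O in soil water and the fraction of DNA oxygen sourced from water.
#' Values are clamped to `[0, 1]`.
#'
#' @param eaf Excess atom fraction (vectorized).
#' @param config A [qsip_config()]; uses `o_fraction_from_water`,
#'   `water_18o_atom_fraction` and `natural_18o_abundance`.
#' @return Numeric vector of fractions of new DNA in `[0, 1]`.
#' @examples
#' fraction_new_dna(c(0, 0.25), qsip_config())
#' @export
fraction_new_dna <- function(eaf, config = qsip_config()) {
  denom <- config$o_fraction_from_water *
    (config$water_18o_atom_fraction - config$natural_18o_abundance)
  if (denom <= 0) {
    abort("water 18O atom fraction must exceed natural abundance")
  }
  pmin(pmax(eaf / denom, 0), 1)
}

#' Interval-averaged absolute growth and mortality rates
#'
#' @param n_0,n_t Taxon abundance (16S copies per g soil) at the start and
#'   end of the interval.
#' @param a_t Fraction of DNA at `n_t` that is newly synthesized.
#' @param t_days Interval length in days; must be positive.
#' @param floor_mortality Floor negative mortality estimates at zero (the
#'   raw value is kept in `m_raw` and flagged)?
#' @return A tibble with `g`, `m`, `m_raw` and `m_floored` (was the raw
#'   mortality negative?). Rates are copies per g soil per day.
#' @examples
#' growth_mortality(100, 150, 0.5, 1) # g = 75, m = 25
#' @export
growth_mortality <- function(n_0, n_t, a_t, t_days, floor_mortality = TRUE) {
  if (any(t_days <= 0)) abort("t_days must be positive")
  if (any(n_0 < 0 | n_t < 0)) abort("abundances must be non-negative")
  g <- n_t * a_t / t_days
  m_raw <- (n_0 - n_t * (1 - a_t)) / t_days
  floored <- m_raw < 0
  if (floor_mortality && any(floored)) {
    inform(sprintf("%d negative mortality estimate(s) floored at 0",
                   sum(floored)))
  }
  tibble(
    g = g,
    m = if (floor_mortality) pmax(m_raw, 0) else m_raw,
    m_raw = m_raw,
    m_floored = floored
  )
}

#' Per-taxon absolute abundances from fraction tables
#'
#' Total 16S copies per sample (summed over bins) multiplied by each taxon's
#' composite (DNA-weighted) relative abundance gives absolute taxon
#' abundances, which are then averaged across the replicate samples of each
#' treatment-timepoint.
#'
#' @inheritParams taxon_weighted_density
#' @return A tibble `treatment`, `timepoint_h`, `taxon`, `n` (copies per g
#'   soil, averaged over plots and labels).
#' @export
taxon_abundances <- function(fractions) {
  comp <- composite_counts(fractions)
  totals <- fractions |>
    group_by(.data$sample_id) |>
    summarise(total_copies = sum(.data$copies_16s), .groups = "drop")
  comp |>
    left_join(totals, by = "sample_id") |>
    mutate(n = .data$rel_abund * .data$total_copies) |>
    group_by(.data$treatment, .data$timepoint_h, .data$taxon) |>
    summarise(n = mean(.data$n), .groups = "drop")
}

#' Taxon growth and mortality rates from EAF estimates
#'
#' Joins EAF estimates (per taxon x treatment x timepoint) with absolute
#' abundances, converts EAF to fraction-new-DNA, and computes
#' interval-averaged growth and mortality rates over each interval from 0 h
#' to the labeled timepoint. Rate confidence bounds are propagated from the
#' EAF confidence interval (the rates are monotone in EAF at fixed
#' abundances); when `eaf_tbl` carries bootstrap draw list-columns these are
#' propagated as rate draws for community-level resampling.
#'
#' @param eaf_tbl Output of [eaf_estimate()].
#' @param abundances Output of [taxon_abundances()] (or a tibble with
#'   `treatment`, `timepoint_h`, `taxon`, `n`); must include the 0 h
#'   baseline.
#' @param config A [qsip_config()].
#' @param floor_mortality Passed to [growth_mortality()].
#' @return A tibble with one row per taxon x treatment x interval: `n_0`,
#'   `n_t`, `a`, `g`, `m`, `m_raw`, `m_floored`, `g_low`, `g_high`,
#'   `m_low`, `m_high` (copies per g soil per day), plus `g_draws`/`m_draws`
#'   list-columns when draws were kept.
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 4, seed = 11))
#' fr <- simulate_gradient(truth)
#' rates <- qsip_rates(eaf_estimate(fr, seed = 1), taxon_abundances(fr))
#' @export
qsip_rates <- function(eaf_tbl, abundances, config = qsip_config(),
                       floor_mortality = TRUE) {
  n0 <- abundances |>
    filter(.data$timepoint_h == 0) |>
    select("treatment", "taxon", n_0 = "n")
  if (nrow(n0) == 0) abort("abundances lack the 0 h baseline")
  has_draws <- "draws" %in% names(eaf_tbl)

  out <- eaf_tbl |>
    filter(.data$timepoint_h > 0) |>
    left_join(n0, by = c("treatment", "taxon")) |>
    left_join(abundances |> rename(n_t = "n"),
              by = c("treatment", "timepoint_h", "taxon")) |>
    filter(!is.na(.data$n_0), !is.na(.data$n_t)) |>
    mutate(
      t_days = .data$timepoint_h / 24,
      a = fraction_new_dna(.data$eaf, config),
      a_low = fraction_new_dna(.data$ci_low, config),
      a_high = fraction_new_dna(.data$ci_high, config)
    )
  gm <- growth_mortality(out$n_0, out$n_t, out$a, out$t_days,
                         floor_mortality)
  lo <- growth_mortality(out$n_0, out$n_t, out$a_low, out$t_days,
                         floor_mortality = FALSE)
  hi <- growth_mortality(out$n_0, out$n_t, out$a_high, out$t_days,
                         floor_mortality = FALSE)
  out <- out |>
    mutate(
      g = gm$g, m = gm$m, m_raw = gm$m_raw, m_floored = gm$m_floored,
      g_low = lo$g, g_high = hi$g,
      # mortality rises with a at fixed N_t, so the EAF CI maps directly
      m_low = pmax(lo$m_raw, 0), m_high = pmax(hi$m_raw, 0)
    )
  if (has_draws) {
    out <- out |>
      mutate(
        g_draws = pmap(list(.data$draws, .data$n_t, .data$t_days),
                       function(d, nt, t) {
                         nt * fraction_new_dna(d, config) / t
                       }),
        m_draws = pmap(list(.data$draws, .data$n_0, .data$n_t, .data$t_days),
                       function(d, n0_, nt, t) {
                         pmax((n0_ - nt * (1 - fraction_new_dna(d, config))) / t,
                              0)
                       })
      )
  }
  out |> select(-any_of(c("draws", "a_low", "a_high")))
}

#' Community growth and mortality rates
#'
#' Sums taxon-level absolute rates within each treatment-timepoint. When the
#' rate table carries bootstrap draw list-columns, community confidence
#' intervals are computed by summing the taxon-level draws iteration-wise;
#' otherwise the per-taxon CI bounds are summed (a conservative bound).
#'
#' @param rates Output of [qsip_rates()].
#' @return A tibble per treatment x timepoint: `n_taxa`, `growth`,
#'   `mortality` (copies per g soil per day), `growth_low`, `growth_high`,
#'   `mortality_low`, `mortality_high`.
#' @export
community_rates <- function(rates) {
  has_draws <- all(c("g_draws", "m_draws") %in% names(rates))
  base <- rates |>
    group_by(.data$treatment, .data$timepoint_h) |>
    summarise(
      n_taxa = n(),
      growth = sum(.data$g),
      mortality = sum(.data$m),
      growth_low = sum(.data$g_low), growth_high = sum(.data$g_high),
      mortality_low = sum(.data$m_low), mortality_high = sum(.data$m_high),
      .groups = "drop"
    )
  if (has_draws) {
    ci <- rates |>
      group_by(.data$treatment, .data$timepoint_h) |>
      summarise(
        g_ci = list(quantile(Reduce(`+`, .data$g_draws), c(0.025, 0.975))),
        m_ci = list(quantile(Reduce(`+`, .data$m_draws), c(0.025, 0.975))),
        .groups = "drop"
      )
    base <- base |>
      left_join(ci, by = c("treatment", "timepoint_h")) |>
      mutate(
        growth_low = map_dbl(.data$g_ci, 1),
        growth_high = map_dbl(.data$g_ci, 2),
        mortality_low = map_dbl(.data$m_ci, 1),
        mortality_high = map_dbl(.data$m_ci, 2)
      ) |>
      select(-"g_ci", -"m_ci")
  }
  base
}

#' Cumulative CO2 efflux per gram dry soil
#'
#' Each jar is destructively harvested, so its headspace total at harvest is
#' the cumulative respiration to that timepoint. Converts per-jar headspace
#' amounts to micromoles CO2 per gram dry soil and averages replicate jars
#' per treatment-timepoint.
#'
#' @param co2 A tibble with `treatment`, `plot`, `timepoint_h`,
#'   `soil_mass_g`, `co2_umol` (as from [simulate_co2()]).
#' @return A tibble `treatment`, `timepoint_h`, `r_umol_g` (mean over
#'   plots), `n_jars`.
#' @examples
#' co2 <- tibble::tibble(treatment = "100", plot = 1, timepoint_h = 24,
#'                       soil_mass_g = 5, co2_umol = 10)
#' cumulative_co2(co2)
#' @export
cumulative_co2 <- function(co2) {
  if (any(co2$co2_umol < 0)) abort("negative headspace CO2 amounts")
  if (any(co2$soil_mass_g <= 0)) abort("soil mass must be positive")
  co2 |>
    group_by(.data$treatment, .data$timepoint_h) |>
    summarise(
      r_umol_g = mean(.data$co2_umol / .data$soil_mass_g),
      n_jars = n(),
      .groups = "drop"
    )
}

#' Community growth efficiency from biomass and respiration
#'
#' Cumulative new biomass `B` at each timepoint is the sum of
#' `N_t * a_t` over taxa (equivalently the community growth rate times
#' time under the linear model). `CGE_raw = B / R` with `R` the cumulative
#' CO2 efflux, and `CGE = CGE_raw / max(CGE_raw)` so the sample with the
#' highest raw efficiency scores exactly 1. Both scales are reported;
#' records with `R = 0` are flagged and excluded from the maximum.
#'
#' @param rates Output of [qsip_rates()].
#' @param co2 Output of [cumulative_co2()].
#' @return A tibble per treatment x timepoint: `b_copies_g` (cumulative new
#'   biomass), `g_copies_g_d` (community growth rate `B / t`), `r_umol_g`,
#'   `cge_raw` (copies per umol), `cge` (unitless, max = 1), `flagged`.
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 4, seed = 11))
#' fr <- simulate_gradient(truth)
#' rates <- qsip_rates(eaf_estimate(fr, seed = 1), taxon_abundances(fr))
#' cge_table(rates, cumulative_co2(simulate_co2(truth)))
#' @export
cge_table <- function(rates, co2) {
  b <- rates |>
    group_by(.data$treatment, .data$timepoint_h) |>
    summarise(
      b_copies_g = sum(.data$n_t * .data$a),
      g_copies_g_d = sum(.data$g),
      .groups = "drop"
    )
  out <- b |>
    left_join(co2, by = c("treatment", "timepoint_h")) |>
    mutate(
      flagged = is.na(.data$r_umol_g) | .data$r_umol_g <= 0,
      cge_raw = if_else(.data$flagged, NA_real_,
                        .data$b_copies_g / .data$r_umol_g)
    )
  cge_max <- max(out$cge_raw, na.rm = TRUE)
  if (!is.finite(cge_max) || cge_max <= 0) {
    abort("no record with positive respiration and biomass")
  }
  out |>
    mutate(cge = .data$cge_raw / cge_max) |>
    select("treatment", "timepoint_h", "b_copies_g", "g_copies_g_d",
           "r_umol_g", "cge_raw", "cge", "flagged")
}
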