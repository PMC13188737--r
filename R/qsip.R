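# Excess atom fraction estimation from fraction-level qPCR + ASV data.
#
# A taxon's buoyant density in a sample is the abundance-weighted mean of the
# bin densities, with per-bin abundance = (ASV relative abundance in bin) x
# (16S copies in bin). The shift between labeled and control densities is
# converted to 18O excess atom fraction through the GC <-> density <->
# molecular-weight calibrations in qsip_config().

.fraction_long <- function(fractions) {
  asv_cols <- grep("^asv_", names(fractions), value = TRUE)
  if (length(asv_cols) == 0) abort("no asv_* read-count columns found")
  fractions |>
    mutate(total_reads = rowSums(across(all_of(asv_cols)))) |>
    pivot_longer(all_of(asv_cols), names_to = "taxon", values_to = "reads") |>
    mutate(
      taxon = sub("^asv_", "", .data$taxon),
      rel_abund = if_else(.data$total_reads > 0,
                          .data$reads / .data$total_reads, 0),
      abund = .data$rel_abund * .data$copies_16s
    )
}

#' Taxon-specific weighted mean buoyant density
#'
#' For every sample and taxon, computes the weighted mean density
#' `sum(x_f * ab_f) / sum(ab_f)` across gradient bins, where the per-bin
#' taxon abundance `ab_f` is its relative read abundance in the bin times the
#' bin's total 16S copy number.
#'
#' @param fractions A fraction-level tibble as produced by
#'   [simulate_gradient()]: one row per sample x bin with `sample_id`,
#'   `plot`, `treatment`, `timepoint_h`, `label`, `density_g_ml`,
#'   `copies_16s` and `asv_*` read-count columns.
#' @param taxon Optional taxon id(s) (without the `asv_` prefix) to restrict
#'   the result to.
#' @return A tibble with one row per sample x taxon that has non-zero
#'   abundance: sample metadata, `taxon`, and `weighted_density` (g/mL).
#'   Taxa with zero total abundance in a sample are dropped (their weighted
#'   density is undefined).
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 3, seed = 2))
#' fr <- simulate_gradient(truth, noise = FALSE)
#' taxon_weighted_density(fr)
#' @export
taxon_weighted_density <- function(fractions, taxon = NULL) {
  long <- .fraction_long(fractions)
  if (!is.null(taxon)) long <- long |> filter(.data$taxon %in% !!taxon)
  long |>
    group_by(.data$sample_id, .data$plot, .data$treatment,
             .data$timepoint_h, .data$label, .data$taxon) |>
    summarise(
      abund_total = sum(.data$abund),
      weighted_density = sum(.data$density_g_ml * .data$abund) /
        sum(.data$abund),
      .groups = "drop"
    ) |>
    filter(.data$abund_total > 0) |>
    select(-"abund_total")
}

#' Convert weighted densities to 18O excess atom fraction
#'
#' Implements the standard qSIP chain: GC content from the unlabeled density,
#' base-pair molecular weight from GC, labeled molecular weight from the
#' density ratio, and excess atom fraction from the mass gain relative to the
#' maximum possible 18O mass gain, discounted by natural 18O abundance.
#'
#' @param w_light,w_lab Unlabeled (control) and labeled weighted mean
#'   densities (g/mL); vectorized.
#' @param config A [qsip_config()].
#' @return A tibble with `gc_est`, `m_light`, `m_lab`, `m_heavymax` (g/mol)
#'   and `eaf`. Negative EAF values are retained so downstream
#'   classification by confidence interval stays unbiased.
#' @examples
#' eaf_from_density(1.70, 1.71)
#' @export
eaf_from_density <- function(w_light, w_lab, config = qsip_config()) {
  gc <- (w_light - config$density_intercept) / config$density_slope
  if (any(gc < -0.2 | gc > 1.2, na.rm = TRUE)) {
    warn("GC estimate outside [-0.2, 1.2]: check density calibration")
  }
  m_light <- config$mw_slope * gc + config$mw_intercept
  m_lab <- m_light * (w_lab / w_light)
  m_heavymax <- m_light + config$delta_m_max_18o
  eaf <- (m_lab - m_light) / (m_heavymax - m_light) *
    (1 - config$natural_18o_abundance)
  tibble(gc_est = gc, m_light = m_light, m_lab = m_lab,
         m_heavymax = m_heavymax, eaf = eaf)
}

#' Pool natural-abundance control replicates across timepoints
#'
#' Control (natural-abundance) densities carry no labeling signal, so the
#' per-taxon control replicate set pools every post-rewetting control sample
#' of a treatment: with 3 plots and 5 timepoints this yields up to 15
#' control replicates per taxon.
#'
#' @param wdens Output of [taxon_weighted_density()].
#' @param control_label Label value marking natural-abundance samples.
#' @return A tibble of control replicates: `treatment`, `taxon`,
#'   `sample_id`, `plot`, `timepoint_h`, `w_light`.
#' @export
pool_control_timepoints <- function(wdens, control_label = "natural") {
  wdens |>
    filter(.data$label == control_label, .data$timepoint_h > 0) |>
    select("treatment", "taxon", "sample_id", "plot", "timepoint_h",
           w_light = "weighted_density")
}

#' Bootstrap an EAF estimate from replicate densities
#'
#' Resamples the replicate-level data with replacement, recomputes the EAF
#' from the resampled means each iteration, and reports the bootstrap median
#' as the point estimate with a 2.5/97.5 percentile confidence interval.
#'
#' Three resampling schemes are available. `"plot"` (the default) resamples
#' the replicate-level weighted densities, mirroring a bootstrap over
#' replicate plots; with only 3 labeled replicates its percentile intervals
#' are anti-conservative (simulated coverage of a nominal 95% interval is
#' near 83%), which is a known small-sample property of the percentile
#' bootstrap, not a defect of the data. `"fraction"` keeps the replicates
#' fixed and resamples the gradient fractions within each, and
#' `"hierarchical"` does both; both widen the intervals into
#' over-coverage because the band's intrinsic density spread is then
#' counted as sampling noise. The calibration of all three is quantified in
#' the package vignette.
#'
#' @param control_w Numeric vector of control replicate densities (g/mL).
#' @param label_w Numeric vector of labeled replicate densities (g/mL).
#' @param config A [qsip_config()]; `config$n_boot` sets the iteration count.
#' @param seed Optional integer seed (set once before resampling).
#' @param keep_draws Keep the vector of bootstrap EAF draws (for downstream
#'   uncertainty propagation)?
#' @param control_fractions,label_fractions Optional lists (one element per
#'   replicate, aligned with `control_w` / `label_w`) of two-column matrices
#'   `cbind(density, abundance)` giving the taxon's per-fraction data, used
#'   by the hierarchical scheme.
#' @param resample `"plot"`, `"fraction"`, or `"hierarchical"`.
#' @return A one-row tibble: `w_light`, `w_lab`, `gc_est`, `eaf`, `ci_low`,
#'   `ci_high`, `growing` (is `ci_low > 0`), `n_control_reps`,
#'   `n_label_reps`, and (if requested) a `draws` list-column.
#' @examples
#' bootstrap_eaf(rnorm(15, 1.70, 0.002), rnorm(3, 1.71, 0.002), seed = 1)
#' @export
bootstrap_eaf <- function(control_w, label_w, config = qsip_config(),
                          seed = NULL, keep_draws = FALSE,
                          control_fractions = NULL, label_fractions = NULL,
                          resample = c("plot", "fraction", "hierarchical")) {
  resample <- match.arg(resample)
  if (!is.null(seed)) set.seed(seed)
  n_c <- length(control_w)
  n_l <- length(label_w)
  if (n_c == 0 || n_l == 0) abort("empty replicate set")
  if (is.null(control_fractions) || is.null(label_fractions)) {
    resample <- "plot"
  }
  b <- config$n_boot

  rep_means <- function(w, fr) {
    n_r <- length(w)
    if (resample == "plot") {
      wstar <- matrix(rep(w, each = b), b) # replicate j's W, constant in i
    } else {
      # per-iteration fraction-resampled W for each replicate
      wstar <- vapply(fr, function(m) {
        n_f <- nrow(m)
        idx <- matrix(sample.int(n_f, b * n_f, TRUE), b)
        num <- rowSums(matrix(m[idx, 1] * m[idx, 2], b))
        den <- rowSums(matrix(m[idx, 2], b))
        ifelse(den > 0, num / den, NA_real_)
      }, numeric(b))
    }
    if (resample == "fraction") {
      return(rowMeans(wstar, na.rm = TRUE))
    }
    idx_r <- matrix(sample.int(n_r, b * n_r, TRUE), b)
    picked <- matrix(wstar[cbind(rep(seq_len(b), n_r), as.vector(idx_r))], b)
    rowMeans(picked, na.rm = TRUE)
  }

  mean_c <- rep_means(control_w, control_fractions)
  mean_l <- rep_means(label_w, label_fractions)
  draws <- eaf_from_density(mean_c, mean_l, config)$eaf
  point <- eaf_from_density(mean(control_w), mean(label_w), config)
  ci <- unname(quantile(draws, c(0.025, 0.975), type = 7, na.rm = TRUE))
  out <- tibble(
    w_light = mean(control_w), w_lab = mean(label_w),
    gc_est = point$gc_est,
    eaf = median(draws, na.rm = TRUE), ci_low = ci[1], ci_high = ci[2],
    growing = ci[1] > 0,
    n_control_reps = n_c, n_label_reps = n_l
  )
  if (keep_draws) out$draws <- list(draws)
  out
}

#' Estimate per-taxon EAF with replicate filters and bootstrap CIs
#'
#' The full estimation flow: weighted densities per sample and taxon, control
#' replicates pooled across post-rewetting timepoints, the replicate-presence
#' filter (a taxon must occur in at least `min_control_reps` pooled control
#' replicates and in at least `min_label_reps` labeled replicates of the
#' treatment-timepoint), and a bootstrap over replicate-level densities.
#' Taxa whose confidence interval excludes zero from below are flagged as
#' growing; excluded taxa are reported separately with the reason.
#'
#' @inheritParams taxon_weighted_density
#' @param config A [qsip_config()].
#' @param seed Integer seed for the bootstrap.
#' @param keep_draws Keep per-taxon bootstrap draw vectors (list-column) for
#'   propagating uncertainty into community rates?
#' @param resample Bootstrap scheme, see [bootstrap_eaf()]: `"plot"`
#'   (replicate plots, the default), `"fraction"`, or `"hierarchical"`.
#' @return A tibble with one row per taxon x treatment x labeled timepoint
#'   passing the filters (columns of [bootstrap_eaf()] plus ids), with the
#'   excluded combinations in `attr(, "excluded")`.
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 4, seed = 11))
#' fr <- simulate_gradient(truth)
#' eaf_estimate(fr, seed = 1)
#' @export
eaf_estimate <- function(fractions, config = qsip_config(), seed = 1L,
                         keep_draws = FALSE,
                         resample = c("plot", "fraction", "hierarchical")) {
  resample <- match.arg(resample)
  long <- .fraction_long(fractions)
  per <- long |>
    group_by(.data$sample_id, .data$plot, .data$treatment,
             .data$timepoint_h, .data$label, .data$taxon) |>
    summarise(
      abund_total = sum(.data$abund),
      weighted_density = sum(.data$density_g_ml * .data$abund) /
        sum(.data$abund),
      fr = list(cbind(.data$density_g_ml, .data$abund)),
      .groups = "drop"
    ) |>
    filter(.data$abund_total > 0)

  controls <- per |>
    filter(.data$label == "natural", .data$timepoint_h > 0)
  labeled <- per |>
    filter(.data$label == "18O")
  n_label_samples <- labeled |>
    distinct(.data$treatment, .data$timepoint_h, .data$plot) |>
    count(.data$treatment, .data$timepoint_h, name = "n_label_samples")

  cand <- labeled |>
    group_by(.data$treatment, .data$timepoint_h, .data$taxon) |>
    summarise(label_w = list(.data$weighted_density),
              label_fr = list(.data$fr),
              n_label = n(), .groups = "drop") |>
    left_join(
      controls |>
        group_by(.data$treatment, .data$taxon) |>
        summarise(control_w = list(.data$weighted_density),
                  control_fr = list(.data$fr),
                  n_control = n(), .groups = "drop"),
      by = c("treatment", "taxon")
    ) |>
    mutate(n_control = replace_na(.data$n_control, 0L)) |>
    left_join(n_label_samples, by = c("treatment", "timepoint_h"))

  keep <- cand$n_control >= config$min_control_reps &
    cand$n_label >= pmin(config$min_label_reps, cand$n_label_samples) &
    cand$n_label == cand$n_label_samples
  excluded <- cand[!keep, ] |>
    mutate(reason = if_else(
      .data$n_control < config$min_control_reps,
      sprintf("in %d control replicates (need >= %d)",
              .data$n_control, config$min_control_reps),
      sprintf("in %d of %d labeled replicates (need all)",
              .data$n_label, .data$n_label_samples)
    )) |>
    select("treatment", "timepoint_h", "taxon", "n_control", "n_label",
           "reason")
  cand <- cand[keep, ] |>
    arrange(.data$treatment, .data$timepoint_h, .data$taxon)

  set.seed(seed)
  res <- cand |>
    mutate(fit = pmap(
      list(.data$control_w, .data$label_w, .data$control_fr,
           .data$label_fr),
      function(cw, lw, cf, lf) {
        bootstrap_eaf(cw, lw, config, keep_draws = keep_draws,
                      control_fractions = cf, label_fractions = lf,
                      resample = resample)
      }
    )) |>
    select("treatment", "timepoint_h", "taxon", "fit") |>
    unnest("fit")
  attr(res, "excluded") <- excluded
  res
}
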