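# Forward simulator for the rewetting 18O-water labeling experiment.
# Each generator consumes the shared sim_config and a stage-specific seed
# derived from the root seed, so a fixed root seed reproduces every table.

.stage_seed <- function(config, stage) {
  offsets <- c(dynamics = 101L, gradient = 211L, co2 = 307L,
               fticr = 401L, expression = 503L)
  (config$seed %% 2000000000L) + offsets[[stage]]
}

.treatments <- function(config) names(config$growth_per_capita)

#' Simulate taxon abundance dynamics with known ground truth
#'
#' Forward-simulates per-taxon abundance trajectories under a linear
#' birth-death model that mirrors the downstream rate estimator's bookkeeping:
#' over an interval of length `t` days a taxon produces `g * t` new 16S copies
#' and loses `m * t` of its pre-existing (unlabeled) copies, so
#' `new + surviving_old = N_t` holds exactly. The fraction of new DNA `a_it`
#' and the implied excess atom fraction of 18O are stored per
#' taxon-treatment-timepoint.
#'
#' @param config A [sim_config()].
#' @param qsip A [qsip_config()] supplying the natural 18O abundance used to
#'   convert fraction-new-DNA into excess atom fraction.
#' @return An object of class `qsip_truth`: a list with `taxa` (per-taxon GC
#'   content, initial abundance, absolute rates by treatment), `abundance`
#'   (taxon x treatment x timepoint trajectories with `n_t`, `new`,
#'   `surviving_old`, `a`, `eaf`), `community` (per treatment-timepoint
#'   cumulative new biomass, true CGE, expected cumulative CO2), and the
#'   config.
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 5, seed = 42))
#' head(truth$abundance)
#' @export
simulate_dynamics <- function(config, qsip = qsip_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "dynamics"))
  trts <- .treatments(config)

  sdlog <- sqrt(log(1 + config$rate_cv^2))
  taxa <- tibble(
    taxon = sprintf("t%03d", seq_len(config$n_taxa)),
    gc = runif(config$n_taxa, config$gc_range[1], config$gc_range[2]),
    n0 = rlnorm(config$n_taxa, config$n0_meanlog, config$n0_sdlog)
  )
  rates <- crossing(taxon = taxa$taxon, treatment = trts) |>
    left_join(taxa, by = "taxon") |>
    mutate(
      g_percap = map_dbl(.data$treatment, ~ config$growth_per_capita[[.x]]) *
        rlnorm(n(), -sdlog^2 / 2, sdlog),
      m_percap = map_dbl(.data$treatment, ~ config$mortality_per_capita[[.x]]) *
        rlnorm(n(), -sdlog^2 / 2, sdlog),
      g_abs = .data$g_percap * .data$n0,
      m_abs = .data$m_percap * .data$n0
    )

  t_days <- config$timepoints_h / 24
  max_t <- max(t_days)
  if (!config$exponential_growth) {
    # linear deaths draw on the finite pre-existing DNA pool: cap per-capita
    # mortality draws so no taxon exhausts it within the incubation
    rates <- rates |>
      mutate(m_percap = pmin(.data$m_percap, 0.95 / max_t),
             m_abs = .data$m_percap * .data$n0)
    if (any(rates$m_abs * max_t > rates$n0)) {
      abort(paste(
        "mortality too high: a taxon's pre-existing DNA is exhausted before",
        "the final timepoint; lower mortality_per_capita or shorten the",
        "incubation"
      ))
    }
  }

  abundance <- crossing(
    rates |> select("taxon", "treatment", "gc", "n0", "g_abs", "m_abs",
                    "g_percap", "m_percap"),
    timepoint_h = config$timepoints_h
  ) |>
    mutate(t_days = .data$timepoint_h / 24)

  if (config$exponential_growth) {
    abundance <- abundance |>
      mutate(
        n_t = .data$n0 * exp((.data$g_percap - .data$m_percap) * .data$t_days),
        surviving_old = .data$n0 * exp(-.data$m_percap * .data$t_days),
        new = .data$n_t - .data$surviving_old
      )
  } else {
    abundance <- abundance |>
      mutate(
        new = .data$g_abs * .data$t_days,
        surviving_old = .data$n0 - .data$m_abs * .data$t_days,
        n_t = .data$new + .data$surviving_old
      )
  }
  abundance <- abundance |>
    mutate(
      a = if_else(.data$n_t > 0, .data$new / .data$n_t, 0),
      eaf = .data$a * config$o_fraction_from_water *
        (config$water_18o_atom_fraction - qsip$natural_18o_abundance)
    )

  community <- abundance |>
    group_by(.data$treatment, .data$timepoint_h) |>
    summarise(
      biomass_new = sum(.data$new),
      n_total = sum(.data$n_t),
      growth_abs = sum(.data$g_abs),
      mortality_abs = sum(.data$m_abs),
      .groups = "drop"
    ) |>
    mutate(
      true_cge = map_dbl(.data$treatment, ~ config$true_cge_by_treatment[[.x]]),
      co2_umol_g = .data$biomass_new / (.data$true_cge * config$co2_scale)
    )

  structure(
    list(taxa = taxa, rates = rates, abundance = abundance,
         community = community, config = config, qsip = qsip),
    class = "qsip_truth"
  )
}

#' @export
print.qsip_truth <- function(x, ...) {
  cat("<qsip_truth>", nrow(x$taxa), "taxa,",
      length(unique(x$abundance$treatment)), "treatments,",
      length(unique(x$abundance$timepoint_h)), "timepoints\n")
  invisible(x)
}

# unlabeled mean buoyant density and the labeled mean implied by an EAF,
# via the inverse of the estimator's density<->molecular-weight maps
.density_unlabeled <- function(gc, qsip) {
  qsip$density_intercept + qsip$density_slope * gc
}

.density_labeled <- function(gc, eaf, qsip) {
  w_light <- .density_unlabeled(gc, qsip)
  m_light <- qsip$mw_slope * gc + qsip$mw_intercept
  m_lab <- m_light + eaf / (1 - qsip$natural_18o_abundance) *
    qsip$delta_m_max_18o
  w_light * m_lab / m_light
}

#' Simulate CsCl gradient fractionation and pooled-bin sequencing
#'
#' Spreads each taxon's DNA over the gradient as a Gaussian centred on its
#' (GC-dependent) unlabeled buoyant density, or on the density implied by its
#' planted excess atom fraction in labeled samples, integrates the mixture
#' over fraction density ranges, optionally pools the fractions into the
#' 5 sequencing bins, and layers on qPCR (lognormal) and sequencing
#' (multinomial) noise.
#'
#' One labeled and one natural-abundance control sample is generated per
#' plot at every post-rewetting timepoint; the 0 h harvest (before labeling)
#' is emitted as a natural-abundance sample.
#'
#' @param truth A `qsip_truth` from [simulate_dynamics()].
#' @param config The [sim_config()] used to build `truth`.
#' @param pool Pool the fractions into the density bins given by
#'   `config$bin_edges` (the default, matching the sequencing design)?
#'   `FALSE` emits all unpooled fractions.
#' @param noise Apply qPCR and multinomial read noise? `FALSE` emits exact
#'   copy totals and expected read counts (useful for round-trip checks).
#' @return A fraction-level tibble with one row per sample x bin (or
#'   fraction): `sample_id`, `plot`, `treatment`, `timepoint_h`, `label`
#'   (`"18O"` or `"natural"`), `bin_id`, `density_g_ml`, `copies_16s`, and
#'   one `asv_*` read-count column per taxon.
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 4, seed = 7))
#' fr <- simulate_gradient(truth, truth$config)
#' dplyr::count(fr, label)
#' @export
simulate_gradient <- function(truth, config = truth$config,
                              pool = TRUE, noise = TRUE) {
  stopifnot(inherits(truth, "qsip_truth"))
  set.seed(.stage_seed(config, "gradient"))
  qsip <- truth$qsip

  edges <- seq(config$density_range[1], config$density_range[2],
               length.out = config$n_fractions + 1)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  bin_of <- findInterval(mids, config$bin_edges, rightmost.closed = TRUE)

  tps <- config$timepoints_h
  samples <- bind_rows(
    crossing(treatment = .treatments(config),
             plot = seq_len(config$n_plots_per_treatment),
             timepoint_h = 0, label = "natural"),
    crossing(treatment = .treatments(config),
             plot = seq_len(config$n_plots_per_treatment),
             timepoint_h = tps[tps > 0], label = c("18O", "natural"))
  ) |>
    mutate(sample_id = sprintf("P%d_x%s_t%g_%s", .data$plot, .data$treatment,
                               .data$timepoint_h, .data$label))

  ab <- truth$abundance
  taxa_ids <- truth$taxa$taxon

  one_sample <- function(treatment, plot, timepoint_h, label, sample_id) {
    st <- ab[ab$treatment == treatment & ab$timepoint_h == timepoint_h, ]
    st <- st[match(taxa_ids, st$taxon), ]
    mu <- if (label == "18O") {
      .density_labeled(st$gc, st$eaf, qsip)
    } else {
      .density_unlabeled(st$gc, qsip)
    }
    # fraction masses: Gaussian integrated over fraction ranges, renormalized
    # to the in-range probability so per-taxon mass is conserved exactly
    cdf <- outer(edges, mu, function(e, m) pnorm(e, m, config$gradient_sigma))
    probs <- cdf[-1, , drop = FALSE] - cdf[-nrow(cdf), , drop = FALSE]
    probs <- sweep(probs, 2, colSums(probs), "/")
    mass <- sweep(probs, 2, st$n_t, "*") # fractions x taxa

    if (pool) {
      grp <- rowsum(mass, bin_of)
      dens <- as.vector(rowsum(rowSums(mass) * mids, bin_of) /
                          rowSums(grp))
      # a bin holding no DNA still has a gradient position: use its
      # unweighted member-fraction midpoint
      mid_fallback <- as.vector(rowsum(mids, bin_of)) /
        as.vector(table(bin_of))
      dens <- ifelse(is.finite(dens), dens, mid_fallback)
      mass <- grp
      ids <- as.integer(rownames(grp))
    } else {
      dens <- mids
      ids <- seq_along(mids)
    }

    totals <- rowSums(mass)
    copies <- if (noise) {
      totals * rlnorm(length(totals),
                      -log(1 + config$qpcr_cv^2) / 2,
                      sqrt(log(1 + config$qpcr_cv^2)))
    } else {
      totals
    }
    rel <- sweep(mass, 1, ifelse(totals > 0, totals, 1), "/")
    reads <- if (noise) {
      t(apply(rel, 1, function(p) {
        if (sum(p) <= 0) rep(0L, length(p))
        else as.integer(rmultinom(1, config$seq_depth, p))
      }))
    } else {
      rel * config$seq_depth
    }
    colnames(reads) <- paste0("asv_", taxa_ids)
    bind_cols(
      tibble(sample_id = sample_id, plot = plot, treatment = treatment,
             timepoint_h = timepoint_h, label = label,
             bin_id = ids, density_g_ml = dens, copies_16s = copies),
      as_tibble(reads)
    )
  }

  pmap(samples[c("treatment", "plot", "timepoint_h", "label", "sample_id")],
       one_sample) |>
    list_rbind()
}

#' Simulate cumulative headspace CO2 per jar
#'
#' Cumulative respiration at each destructive harvest is the community's
#' cumulative new biomass divided by the treatment's true community growth
#' efficiency (scaled from copies to micromoles), with multiplicative
#' lognormal measurement noise.
#'
#' @inheritParams simulate_gradient
#' @param soil_mass_g Dry soil per jar (g).
#' @param noise Apply lognormal measurement noise?
#' @return A tibble with one row per treatment x plot x timepoint:
#'   `co2_umol` (headspace total per jar) and `soil_mass_g`.
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 4, seed = 7))
#' simulate_co2(truth)
#' @export
simulate_co2 <- function(truth, config = truth$config, soil_mass_g = 5,
                         noise = TRUE) {
  stopifnot(inherits(truth, "qsip_truth"))
  set.seed(.stage_seed(config, "co2"))
  out <- crossing(
    truth$community |> select("treatment", "timepoint_h", "co2_umol_g"),
    plot = seq_len(config$n_plots_per_treatment)
  ) |>
    mutate(
      soil_mass_g = soil_mass_g,
      co2_umol = .data$co2_umol_g * soil_mass_g
    )
  if (noise) {
    cv <- config$co2_noise_cv
    if (cv > 0) {
      out$co2_umol <- out$co2_umol *
        rlnorm(nrow(out), -log(1 + cv^2) / 2, sqrt(log(1 + cv^2)))
    }
  }
  out |>
    select("treatment", "plot", "timepoint_h", "soil_mass_g", "co2_umol")
}
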