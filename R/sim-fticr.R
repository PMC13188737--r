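# FTICR-MS peak-list simulator: draws CHNO molecular formulas inside van
# Krevelen class regions, converts them to [M-H]- m/z with ppm-scale mass
# error, and plants compounds unique to one treatment.

.formula_mass <- function(C, H, N, O) {
  C * .masses[["C"]] + H * .masses[["H"]] + N * .masses[["N"]] +
    O * .masses[["O"]]
}

# H + N must be even for an integer ring-double-bond count (even-electron
# CHNO neutral); degree of unsaturation must be a non-negative integer
.formula_valid <- function(C, H, N, O) {
  dbe <- C - H / 2 + N / 2 + 1
  C >= 1 & H >= 1 & O >= 0 & N >= 0 &
    H <= 2 * C + N + 2 & (H + N) %% 2 == 0 & dbe >= 0
}

#' Simulate FTICR-MS peak lists with known formulas and classes
#'
#' Draws molecular formulas uniformly inside the van Krevelen class regions
#' of [vk_boundaries()], computes theoretical negative-mode `[M-H]-` m/z
#' values, adds Gaussian ppm-scale mass error, and distributes compounds
#' across per-plot samples of a two-treatment design. A configurable number
#' of compounds is planted as unique to each treatment (present in at least
#' 2 of its 3 plots, absent from the other treatment); the rest are shared.
#' Blank samples carry contaminant peaks that also bleed into real samples.
#'
#' @param config A [sim_config()].
#' @param class_weights Named sampling weights over compound classes;
#'   defaults to a soil-organic-matter-like mix dominated by lignin-like
#'   formulas.
#' @param unique_class_weights Optional named list (by treatment) of class
#'   weights for the planted treatment-unique compounds, to plant a
#'   compound-class enrichment between treatments; `NULL` draws unique
#'   compounds from `class_weights`.
#' @param n_blank_peaks Contaminant compounds present in the extraction
#'   blanks.
#' @param mass_range Neutral monoisotopic mass window for simulated
#'   compounds (Da).
#' @return A list: `peaks` (tibble `sample_id`, `mz`, `intensity`), `design`
#'   (tibble `sample_id`, `treatment`, `plot`, `is_blank`), and `truth`
#'   (tibble of compound id, elemental counts, neutral mass, realized class,
#'   and `unique_to` treatment or `NA` for shared compounds).
#' @examples
#' fs <- simulate_fticr(sim_config(n_compounds = 50, seed = 3))
#' head(fs$truth)
#' @export
simulate_fticr <- function(config,
                           class_weights = c(
                             lignin = 0.35, tannin = 0.12, protein = 0.12,
                             lipid = 0.10, carbohydrate = 0.08,
                             "amino-sugar" = 0.05,
                             "condensed-hydrocarbon" = 0.10,
                             "unsaturated-hydrocarbon" = 0.08
                           ),
                           unique_class_weights = NULL,
                           n_blank_peaks = 30,
                           mass_range = c(210, 800)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "fticr"))
  vk <- vk_boundaries()
  vk <- vk[match(names(class_weights), vk$class), ]

  draw_formulas <- function(n, weights = class_weights) {
    empty <- tibble(C = integer(), H = integer(), N = integer(),
                    O = integer(), neutral_mass = double())
    if (n == 0) return(empty)
    out <- list(empty)
    got <- 0
    while (got < n) {
      k <- sample(nrow(vk), 2 * n, replace = TRUE, prob = weights)
      oc <- runif(length(k), vk$oc_min[k], vk$oc_max[k])
      hc <- runif(length(k), vk$hc_min[k], vk$hc_max[k])
      C <- sample(8:30, length(k), replace = TRUE)
      O <- round(oc * C)
      H <- round(hc * C)
      N <- sample(0:2, length(k), replace = TRUE, prob = c(0.6, 0.3, 0.1))
      H <- H + (H + N) %% 2  # enforce even-electron parity
      ok <- .formula_valid(C, H, N, O)
      mass <- .formula_mass(C, H, N, O)
      ok <- ok & mass >= mass_range[1] & mass <= mass_range[2]
      cand <- tibble(C = C[ok], H = H[ok], N = N[ok], O = O[ok],
                     neutral_mass = mass[ok])
      out <- c(out, list(cand))
      got <- got + nrow(cand)
    }
    distinct(list_rbind(out), .data$C, .data$H, .data$N, .data$O,
             .keep_all = TRUE)
  }

  trts <- .treatments(config)
  n_unique <- min(config$n_unique_per_treatment,
                  floor((config$n_compounds - 1) / 2))
  n_shared <- config$n_compounds - 2 * n_unique
  uw <- function(trt) {
    if (is.null(unique_class_weights)) class_weights
    else unique_class_weights[[trt]]
  }
  formulas <- bind_rows(
    draw_formulas(n_unique, uw(trts[1])) |>
      slice_head(n = n_unique) |> mutate(unique_to = trts[1]),
    draw_formulas(n_unique, uw(trts[2])) |>
      slice_head(n = n_unique) |> mutate(unique_to = trts[2]),
    draw_formulas(n_shared + n_blank_peaks) |>
      slice_head(n = n_shared + n_blank_peaks) |>
      mutate(unique_to = NA_character_)
  ) |>
    distinct(.data$C, .data$H, .data$N, .data$O, .keep_all = TRUE) |>
    mutate(
      compound = sprintf("cmp%05d", row_number()),
      class = classify_formula(.data$C, .data$H, .data$N, .data$O)$class,
      is_blank_compound = is.na(.data$unique_to) &
        cumsum(is.na(.data$unique_to)) > pmax(
          sum(is.na(.data$unique_to)) - n_blank_peaks, 0
        )
    )

  real <- formulas |> filter(!.data$is_blank_compound)

  design <- crossing(treatment = trts,
                     plot = seq_len(config$n_plots_per_treatment)) |>
    mutate(sample_id = sprintf("P%d_x%s", .data$plot, .data$treatment),
           is_blank = FALSE) |>
    bind_rows(tibble(treatment = NA_character_, plot = NA_integer_,
                     sample_id = c("blank_1", "blank_2"), is_blank = TRUE))

  n_plots <- config$n_plots_per_treatment
  presence_for <- function(cmp_unique_to) {
    # returns logical vector over non-blank samples, ordered as in design
    smp <- design |> filter(!.data$is_blank)
    if (is.na(cmp_unique_to)) {
      pres <- rbinom(nrow(smp), 1, config$detect_prob) == 1
      if (sum(pres) < 2) pres[sample(nrow(smp), 2)] <- TRUE
    } else {
      pres <- rep(FALSE, nrow(smp))
      in_trt <- which(smp$treatment == cmp_unique_to)
      k <- sample(2:n_plots, 1)
      pres[sample(in_trt, k)] <- TRUE
    }
    pres
  }

  smp <- design |> filter(!.data$is_blank)
  peaks_real <- real |>
    mutate(presence = map(.data$unique_to, presence_for)) |>
    unnest_presence(smp)

  blanks <- formulas |> filter(.data$is_blank_compound)
  blank_rows <- crossing(blanks |> select("compound", "neutral_mass"),
                         sample_id = design$sample_id) |>
    filter(grepl("^blank", .data$sample_id) | rbinom(n(), 1, 0.5) == 1)

  all_rows <- bind_rows(
    peaks_real |> select("compound", "neutral_mass", "sample_id"),
    blank_rows
  ) |>
    mutate(
      # residual mass error after internal recalibration: Gaussian, bounded
      # (truncated at 2.5 sd) as for a recalibrated spectrum
      mz = (.data$neutral_mass - .masses[["proton"]]) *
        (1 + .rtruncnorm(n(), config$mz_ppm_sd) * 1e-6),
      intensity = rlnorm(n(), log(1e6), 0.8)
    )

  list(
    peaks = all_rows |> select("sample_id", "mz", "intensity"),
    design = design,
    truth = bind_rows(
      real |> select("compound", "C", "H", "N", "O", "neutral_mass",
                     "class", "unique_to"),
      blanks |> select("compound", "C", "H", "N", "O", "neutral_mass",
                       "class") |>
        mutate(unique_to = "blank")
    )
  )
}

# zero-centred Gaussian truncated at +/- 2.5 sd
.rtruncnorm <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  lim <- pnorm(2.5)
  stats::qnorm(runif(n, 1 - lim, lim)) * sd
}

# helper: expand a list-column of presence vectors into per-sample rows
unnest_presence <- function(df, smp) {
  df |>
    mutate(sample_id = rep(list(smp$sample_id), dplyr::n())) |>
    unnest(c("presence", "sample_id")) |>
    filter(.data$presence)
}

#' Simulate a gene-by-sample expression matrix with CGE-linked genes
#'
#' Generates negative-binomial expression counts for post-rewetting samples.
#' A planted subset of genes has mean log expression that tracks the
#' sample-level log community growth efficiency with slope
#' `planted_effect` (half the planted genes positively, half negatively);
#' the remaining genes are noise around a common baseline.
#'
#' @param truth A `qsip_truth` from [simulate_dynamics()] (supplies the true
#'   CGE per treatment).
#' @inheritParams simulate_gradient
#' @param cge_jitter_sdlog Lognormal sd of per-sample CGE around the
#'   treatment truth.
#' @return A list: `counts` (tibble, one `gene` column plus one column per
#'   sample), `log_norm` (same shape, `log2(count + 1)` normalized values for
#'   regression), `samples` (tibble `sample_id`, `treatment`, `plot`,
#'   `timepoint_h`, `cge`), `planted` (tibble `gene`, `sign`).
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 4, n_genes = 20,
#'                                       n_planted_genes = 4, seed = 5))
#' ex <- simulate_expression(truth)
#' ex$planted
#' @export
simulate_expression <- function(truth, config = truth$config,
                                cge_jitter_sdlog = 0.3) {
  stopifnot(inherits(truth, "qsip_truth"))
  set.seed(.stage_seed(config, "expression"))
  tps <- config$timepoints_h
  samples <- crossing(
    treatment = .treatments(config),
    plot = seq_len(config$n_plots_per_treatment),
    timepoint_h = tps[tps > 0]
  ) |>
    mutate(
      sample_id = sprintf("P%d_x%s_t%g", .data$plot, .data$treatment,
                          .data$timepoint_h),
      cge = map_dbl(.data$treatment,
                    ~ config$true_cge_by_treatment[[.x]]) *
        rlnorm(n(), 0, cge_jitter_sdlog)
    )

  genes <- sprintf("K%05d", seq_len(config$n_genes))
  n_pl <- min(config$n_planted_genes, config$n_genes)
  planted <- tibble(
    gene = genes[seq_len(n_pl)],
    sign = rep_len(c(1, -1), n_pl)
  )

  x <- log(samples$cge) - mean(log(samples$cge))
  slope <- numeric(config$n_genes)
  slope[seq_len(n_pl)] <- planted$sign * config$planted_effect
  mu_log <- outer(slope, x) + config$expr_baseline_log
  mu <- exp(mu_log)
  counts <- matrix(
    rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
    nrow = config$n_genes,
    dimnames = list(genes, samples$sample_id)
  )

  list(
    counts = as_tibble(counts, rownames = "gene"),
    log_norm = as_tibble(log2(counts + 1), rownames = "gene"),
    samples = samples,
    planted = planted
  )
}
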