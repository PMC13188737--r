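# End-to-end orchestration over the synthetic experiment, input validation,
# and TSV interchange.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-separated stage table
#'
#' @param path Path to a TSV written by [run_pipeline()] or external tooling.
#' @return A tibble.
#' @export
read_stage_tsv <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Validate pipeline input tables
#'
#' Schema and range checks on the fraction table, CO2 table, and design
#' grid: required columns, densities within the plausible gradient window,
#' non-negative copy numbers and CO2 amounts, duplicated sample-bin rows,
#' and (when a design is derivable) completeness of the
#' treatment x plot x timepoint x label grid.
#'
#' @param fractions Optional fraction-level tibble.
#' @param co2 Optional per-jar CO2 tibble.
#' @return A diagnostics tibble (`table`, `check`, `detail`); zero rows
#'   means no problems found.
#' @examples
#' truth <- simulate_dynamics(sim_config(n_taxa = 3, seed = 1))
#' validate_inputs(simulate_gradient(truth), simulate_co2(truth))
#' @export
validate_inputs <- function(fractions = NULL, co2 = NULL) {
  diag <- list()
  note <- function(table, check, detail) {
    diag[[length(diag) + 1]] <<- tibble(table = table, check = check,
                                        detail = detail)
  }
  if (!is.null(fractions)) {
    need <- c("sample_id", "plot", "treatment", "timepoint_h", "label",
              "bin_id", "density_g_ml", "copies_16s")
    missing <- setdiff(need, names(fractions))
    if (length(missing) > 0) {
      note("fractions", "missing columns", paste(missing, collapse = ", "))
    } else {
      bad <- fractions$density_g_ml < 1.60 | fractions$density_g_ml > 1.80
      if (any(bad)) {
        note("fractions", "density outside [1.60, 1.80]",
             paste(unique(fractions$sample_id[bad]), collapse = ", "))
      }
      if (any(fractions$copies_16s < 0)) {
        note("fractions", "negative 16S copies", "")
      }
      dup <- fractions |>
        count(.data$sample_id, .data$bin_id) |>
        filter(.data$n > 1)
      if (nrow(dup) > 0) {
        note("fractions", "duplicated sample x bin rows",
             paste(unique(dup$sample_id), collapse = ", "))
      }
      reads_ok <- fractions |>
        group_by(.data$sample_id) |>
        summarise(
          n_bins = sum(rowSums(across(starts_with("asv_"))) > 0),
          .groups = "drop"
        )
      if (any(reads_ok$n_bins < 2)) {
        note("fractions", "fewer than 2 bins with reads",
             paste(reads_ok$sample_id[reads_ok$n_bins < 2], collapse = ", "))
      }
      grid <- fractions |>
        filter(.data$timepoint_h > 0) |>
        distinct(.data$treatment, .data$plot, .data$timepoint_h, .data$label)
      full <- crossing(
        distinct(grid, .data$treatment, .data$plot),
        distinct(grid, .data$timepoint_h),
        label = c("18O", "natural")
      )
      gap <- anti_join(
        full, grid, by = c("treatment", "plot", "timepoint_h", "label")
      )
      if (nrow(gap) > 0) {
        note("fractions", "incomplete design grid",
             sprintf("%d missing sample(s)", nrow(gap)))
      }
    }
  }
  if (!is.null(co2)) {
    need <- c("treatment", "plot", "timepoint_h", "soil_mass_g", "co2_umol")
    missing <- setdiff(need, names(co2))
    if (length(missing) > 0) {
      note("co2", "missing columns", paste(missing, collapse = ", "))
    } else {
      if (any(co2$co2_umol < 0)) note("co2", "negative CO2 amounts", "")
      if (any(co2$soil_mass_g <= 0)) note("co2", "non-positive soil mass", "")
    }
  }
  if (length(diag) == 0) {
    tibble(table = character(), check = character(), detail = character())
  } else {
    list_rbind(diag)
  }
}

#' Run the full synthetic-experiment pipeline
#'
#' Simulates the experiment (dynamics, gradient, CO2, FTICR peak lists,
#' expression), then runs every analysis stage in dependency order: EAF
#' estimation, growth/mortality rates, community rates, the CGE metric, the
#' DNA-weighted composite community profile, the FTICR chemistry chain
#' (align, blank-subtract, presence-filter, formula assignment,
#' classification, thermodynamics, uniqueness, G-tests), and the PLSR/VIP
#' association of gene expression with the estimated CGE. All randomness
#' flows from `config$seed`, so a repeated run is byte-identical.
#'
#' @param config A [sim_config()].
#' @param qsip A [qsip_config()].
#' @param dir Optional output directory; when given, every stage table is
#'   written as TSV along with a `provenance.json` recording the seed,
#'   package version and parameter digest.
#' @return A named list of stage outputs: `truth`, `fractions`, `co2`,
#'   `eaf`, `rates`, `community`, `cge`, `composite`, `fticr` (aligned,
#'   assignments, unique, enrichment), `association`, `pathway_cor`, and
#'   `diagnostics` from [validate_inputs()].
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(n_taxa = 8, n_genes = 50,
#'                                n_compounds = 80, seed = 1))
#' res$cge
#' }
#' @export
run_pipeline <- function(config = sim_config(), qsip = qsip_config(),
                         dir = NULL) {
  truth <- simulate_dynamics(config, qsip)
  fractions <- simulate_gradient(truth, config)
  co2 <- simulate_co2(truth, config)
  fticr_sim <- simulate_fticr(config)
  expr_sim <- simulate_expression(truth, config)

  diagnostics <- validate_inputs(fractions, co2)
  if (nrow(diagnostics) > 0) {
    warn("input diagnostics non-empty; see $diagnostics")
  }

  eaf <- eaf_estimate(fractions, qsip, seed = config$seed)
  abund <- taxon_abundances(fractions)
  rates <- qsip_rates(eaf, abund, qsip)
  community <- community_rates(rates)
  cge <- cge_table(rates, cumulative_co2(co2))
  composite <- filter_rare(composite_counts(fractions))

  aligned <- align_peaks(fticr_sim$peaks) |>
    subtract_blanks(fticr_sim$design$sample_id[fticr_sim$design$is_blank]) |>
    min_presence_filter(k = 2)
  features <- distinct(aligned, .data$feature_id, .data$mz_feature)
  assignments <- bind_cols(
    features,
    assign_formula(features$mz_feature)[-1]
  )
  ok <- assignments$assigned
  assignments <- assignments |>
    mutate(
      class = NA_character_, oc = NA_real_, hc = NA_real_,
      nosc = NA_real_, gfe = NA_real_
    )
  if (any(ok)) {
    cls <- classify_formula(assignments$C[ok], assignments$H[ok],
                            assignments$N[ok], assignments$O[ok])
    th <- nosc_gfe(assignments$C[ok], assignments$H[ok],
                   assignments$N[ok], assignments$O[ok])
    assignments$class[ok] <- cls$class
    assignments$oc[ok] <- cls$oc
    assignments$hc[ok] <- cls$hc
    assignments$nosc[ok] <- th$nosc
    assignments$gfe[ok] <- th$gfe
  }
  uniq <- unique_compounds(aligned, fticr_sim$design) |>
    left_join(assignments |> select("feature_id", "class"),
              by = "feature_id")
  enrichment <- class_enrichment(uniq |> filter(!is.na(.data$class)))

  # map the estimated CGE metric onto expression samples by
  # treatment-timepoint (0 h is excluded: no labeled samples exist there)
  expr_cge <- expr_sim$samples |>
    select(-any_of("cge")) |>
    left_join(cge |> select("treatment", "timepoint_h", "cge"),
              by = c("treatment", "timepoint_h")) |>
    filter(!is.na(.data$cge)) |>
    select("sample_id", "cge")
  association <- cge_association(expr_sim$log_norm, expr_cge)
  pathways <- read_stage_tsv(system.file("extdata", "pathways_synthetic.tsv",
                                         package = "qsipcge"))
  selected <- association$associations |>
    filter(.data$selected) |>
    pull(.data$gene)
  pathway_cor <- tryCatch(
    pathway_correlations(expr_sim$log_norm, expr_cge, pathways,
                         genes = selected),
    error = function(e) tibble()
  )

  out <- list(
    truth = truth, fractions = fractions, co2 = co2,
    eaf = eaf, rates = rates, community = community, cge = cge,
    composite = composite,
    fticr = list(aligned = aligned, assignments = assignments,
                 unique = uniq, enrichment = enrichment,
                 design = fticr_sim$design, truth = fticr_sim$truth),
    expression = expr_sim,
    association = association, pathway_cor = pathway_cor,
    diagnostics = diagnostics
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(fractions, file.path(dir, "fractions.tsv"))
    .write_tsv(co2, file.path(dir, "co2.tsv"))
    .write_tsv(eaf |> select(-any_of("draws")), file.path(dir, "eaf.tsv"))
    .write_tsv(rates |> select(-any_of(c("g_draws", "m_draws"))),
               file.path(dir, "rates.tsv"))
    .write_tsv(community, file.path(dir, "community_rates.tsv"))
    .write_tsv(cge, file.path(dir, "cge.tsv"))
    .write_tsv(composite, file.path(dir, "composite.tsv"))
    .write_tsv(fticr_sim$peaks, file.path(dir, "fticr_peaks.tsv"))
    .write_tsv(assignments, file.path(dir, "fticr_assignments.tsv"))
    .write_tsv(enrichment$per_class, file.path(dir, "fticr_enrichment.tsv"))
    .write_tsv(association$associations, file.path(dir, "associations.tsv"))
    if (nrow(pathway_cor) > 0) {
      .write_tsv(pathway_cor, file.path(dir, "pathway_correlations.tsv"))
    }
    provenance <- list(
      package = "qsipcge",
      version = as.character(utils::packageVersion("qsipcge")),
      r_version = R.version.string,
      seed = config$seed,
      param_digest = sum(utf8ToInt(paste(
        deparse(config[order(names(config))]), collapse = ""
      )))
    )
    jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
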