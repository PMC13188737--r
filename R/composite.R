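# DNA-weighted composite (bulk-equivalent) community profiles from
# fraction-level sequencing.

#' Per-fraction DNA weights within a sample
#'
#' Divides each fraction's 16S copy number by the sum across all fractions
#' of the sample, giving the proportion of the sample's DNA each fraction
#' represents.
#'
#' @inheritParams taxon_weighted_density
#' @return A tibble `sample_id`, `bin_id`, `weight`; weights are
#'   non-negative and sum to 1 within each sample.
#' @examples
#' fr <- tibble::tibble(sample_id = "s1", bin_id = 1:2,
#'                      copies_16s = c(100, 300), asv_a = c(1, 1))
#' fraction_weights(fr)
#' @export
fraction_weights <- function(fractions) {
  out <- fractions |>
    group_by(.data$sample_id) |>
    mutate(weight = .data$copies_16s / sum(.data$copies_16s)) |>
    ungroup()
  if (any(!is.finite(out$weight))) {
    abort("a sample has zero total 16S copies; weights undefined")
  }
  out |> select("sample_id", "bin_id", "weight")
}

#' Composite DNA-weighted ASV counts per sample
#'
#' Each fraction's adjusted read count is its sequencing depth multiplied by
#' its DNA weight; each ASV's composite count is the sum over fractions of
#' its relative read abundance times the adjusted read count. Summing across
#' fractions yields one bulk-equivalent count table per sample.
#'
#' @inheritParams taxon_weighted_density
#' @param depth Sequencing depth per fraction used for the adjusted read
#'   counts: a scalar, or `NULL` (default) to use each fraction's observed
#'   total read count.
#' @return A long tibble `sample_id`, `treatment`, `timepoint_h`, `label`
#'   (when present in the input), `taxon`, `count` (DNA-weighted),
#'   `rel_abund` (per-sample relative abundance).
#' @examples
#' fr <- tibble::tibble(sample_id = "s1", bin_id = 1:2,
#'                      copies_16s = c(100, 300), density_g_ml = c(1.7, 1.72),
#'                      asv_a = c(10, 5), asv_b = c(0, 5))
#' composite_counts(fr, depth = 1)
#' @export
composite_counts <- function(fractions, depth = NULL) {
  long <- .fraction_long(fractions)
  w <- fraction_weights(fractions)
  long <- long |>
    left_join(w, by = c("sample_id", "bin_id")) |>
    mutate(adjusted = (if (is.null(depth)) .data$total_reads else depth) *
             .data$weight)
  meta <- intersect(c("treatment", "plot", "timepoint_h", "label"),
                    names(fractions))
  long |>
    group_by(across(all_of(c("sample_id", meta, "taxon")))) |>
    summarise(count = sum(.data$rel_abund * .data$adjusted),
              .groups = "drop") |>
    group_by(.data$sample_id) |>
    mutate(rel_abund = .data$count / sum(.data$count)) |>
    ungroup()
}

#' Filter rare taxa from a composite table
#'
#' Removes ASVs whose relative abundance is strictly below `threshold`
#' (default 0.01%); abundance is judged on the mean relative abundance
#' across samples (`by = "mean"`) or within each sample
#' (`by = "per_sample"`). Surviving abundances are renormalized per sample
#' by default so downstream summaries still total 1.
#'
#' @param composite Output of [composite_counts()].
#' @param threshold Relative-abundance cutoff (strict less-than removal).
#' @param by Apply the threshold to the across-sample mean or per sample?
#' @param renormalize Renormalize relative abundances after filtering?
#' @return The filtered composite tibble.
#' @examples
#' fr <- tibble::tibble(sample_id = "s1", bin_id = 1,
#'                      copies_16s = 100, density_g_ml = 1.7,
#'                      asv_a = 9999, asv_b = 1)
#' filter_rare(composite_counts(fr), threshold = 0.001)
#' @export
filter_rare <- function(composite, threshold = 1e-4,
                        by = c("mean", "per_sample"), renormalize = TRUE) {
  by <- match.arg(by)
  if (by == "mean") {
    keep_taxa <- composite |>
      group_by(.data$taxon) |>
      summarise(mean_rel = mean(.data$rel_abund), .groups = "drop") |>
      filter(.data$mean_rel >= threshold) |>
      pull(.data$taxon)
    out <- composite |> filter(.data$taxon %in% keep_taxa)
  } else {
    out <- composite |> filter(.data$rel_abund >= threshold)
  }
  if (nrow(out) == 0) abort("filter removed every taxon")
  if (renormalize) {
    out <- out |>
      group_by(.data$sample_id) |>
      mutate(rel_abund = .data$count / sum(.data$count)) |>
      ungroup()
  }
  out
}
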