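# FTICR-MS workflow: peak alignment, blank subtraction, presence filtering,
# exhaustive CHNO formula assignment, van Krevelen classification,
# carbon-oxidation thermodynamics, treatment uniqueness, and G-tests.

#' Align peaks across samples into features
#'
#' Greedy single-linkage clustering on the pooled, sorted m/z values: a new
#' feature starts wherever the gap to the previous peak exceeds the ppm
#' tolerance. Clusters that end up spanning more than twice the tolerance
#' are split deterministically at their largest internal gap. Peak detection
#' is treated as presence/absence; intensities are carried along but not
#' used for grouping.
#'
#' @param peaks A tibble `sample_id`, `mz`, `intensity` (one row per
#'   detected peak).
#' @param tol_ppm Alignment tolerance in parts per million.
#' @return A tibble of aligned peaks: `feature_id`, `mz_feature` (mean m/z
#'   of the cluster), `sample_id`, `mz`, `intensity`.
#' @examples
#' p <- tibble::tibble(sample_id = c("a", "b"), mz = c(300.0000, 300.00003),
#'                     intensity = 1)
#' align_peaks(p)
#' @export
align_peaks <- function(peaks, tol_ppm = 0.5) {
  if (length(unique(peaks$sample_id)) < 2) {
    abort("alignment needs peaks from at least 2 samples")
  }
  ord <- order(peaks$mz)
  mz <- peaks$mz[ord]
  gap <- diff(mz) / mz[-length(mz)] * 1e6
  grp <- cumsum(c(1, gap > tol_ppm))

  # split clusters spanning > 2x tolerance at their largest gap, repeatedly
  repeat {
    span <- tapply(mz, grp, function(x) (max(x) - min(x)) / min(x) * 1e6)
    wide <- as.integer(names(span)[span > 2 * tol_ppm])
    if (length(wide) == 0) break
    next_id <- max(grp) + 1L
    for (g in wide) {
      idx <- which(grp == g)
      gaps <- diff(mz[idx])
      cut <- which.max(gaps)
      grp[idx[(cut + 1):length(idx)]] <- next_id
      next_id <- next_id + 1L
    }
  }

  grp <- match(grp, unique(grp))
  out <- peaks[ord, ] |>
    mutate(feature_id = sprintf("f%05d", grp)) |>
    group_by(.data$feature_id) |>
    mutate(mz_feature = mean(.data$mz)) |>
    ungroup() |>
    select("feature_id", "mz_feature", "sample_id", "mz", "intensity") |>
    arrange(.data$mz_feature, .data$sample_id)
  out
}

#' Remove features detected in extraction blanks
#'
#' @param aligned Output of [align_peaks()].
#' @param blank_samples Character vector of blank sample ids.
#' @return The aligned table with blank-contaminated features and all blank
#'   rows removed.
#' @export
subtract_blanks <- function(aligned, blank_samples) {
  blank_features <- aligned |>
    filter(.data$sample_id %in% blank_samples) |>
    pull(.data$feature_id) |>
    unique()
  out <- aligned |>
    filter(!.data$feature_id %in% blank_features,
           !.data$sample_id %in% blank_samples)
  if (nrow(out) == 0) warn("all features were present in blanks")
  out
}

#' Drop features detected in fewer than k samples
#'
#' @param aligned Output of [align_peaks()] (after blank subtraction).
#' @param k Minimum number of distinct samples a feature must appear in.
#' @return The filtered aligned table.
#' @export
min_presence_filter <- function(aligned, k = 2) {
  keep <- aligned |>
    group_by(.data$feature_id) |>
    summarise(n_samples = n_distinct(.data$sample_id), .groups = "drop") |>
    filter(.data$n_samples >= k) |>
    pull(.data$feature_id)
  aligned |> filter(.data$feature_id %in% keep)
}

# candidate grid over C, N, O for exhaustive CHNO search (H solved per mass)
.chno_grid <- function(max_mass) {
  grid <- expand.grid(
    C = seq_len(floor(max_mass / .masses[["C"]])),
    N = 0:2,
    O = 0:floor(max_mass / .masses[["O"]])
  )
  grid$base <- grid$C * .masses[["C"]] + grid$N * .masses[["N"]] +
    grid$O * .masses[["O"]]
  grid[grid$base <= max_mass, ]
}

#' Assign CHNO molecular formulas to negative-mode m/z values
#'
#' Exhaustive search over C >= 1, H >= 1, O >= 0, N in 0..2 (S = 0, P = 0)
#' for the formula whose neutral monoisotopic mass matches
#' `mz + m(proton)` within the ppm tolerance, subject to chemical validity:
#' `H <= 2C + N + 2`, integer non-negative ring-double-bond equivalents, and
#' even-electron neutral parity (H + N even). The candidate with the
#' smallest absolute ppm error wins; if a second candidate lies within
#' `ambiguity_ppm` of the best, the peak is left unassigned and flagged
#' ambiguous.
#'
#' @param mz Numeric vector of negative-mode `[M-H]-` m/z values.
#' @param tol_ppm Maximum |mass error| for an assignment (ppm).
#' @param ambiguity_ppm Two candidates closer than this (in ppm of the
#'   measured mass) are considered indistinguishable.
#' @return A tibble, one row per input m/z: `mz`, `neutral_mass`, `C`, `H`,
#'   `N`, `O`, `error_ppm`, `assigned`, `ambiguous`. Unassigned rows carry
#'   `NA` counts.
#' @examples
#' assign_formula(179.05611) # glucose, C6H12O6
#' @export
assign_formula <- function(mz, tol_ppm = 0.5, ambiguity_ppm = 0.05) {
  neutral <- mz + .masses[["proton"]]
  grid <- .chno_grid(max(neutral) + 1)
  mh <- .masses[["H"]]

  one <- function(m) {
    rem <- m - grid$base
    H <- round(rem / mh)
    err <- (grid$base + H * mh - m) / m * 1e6
    ok <- H >= 1 & abs(err) < tol_ppm &
      .formula_valid(grid$C, H, grid$N, grid$O)
    if (!any(ok)) {
      return(tibble(C = NA_integer_, H = NA_integer_, N = NA_integer_,
                    O = NA_integer_, error_ppm = NA_real_,
                    assigned = FALSE, ambiguous = FALSE))
    }
    cand <- tibble(C = grid$C[ok], H = H[ok], N = grid$N[ok], O = grid$O[ok],
                   error_ppm = err[ok]) |>
      arrange(abs(.data$error_ppm))
    if (nrow(cand) > 1 &&
        abs(cand$error_ppm[2]) - abs(cand$error_ppm[1]) < ambiguity_ppm) {
      return(tibble(C = NA_integer_, H = NA_integer_, N = NA_integer_,
                    O = NA_integer_, error_ppm = NA_real_,
                    assigned = FALSE, ambiguous = TRUE))
    }
    cand[1, ] |> mutate(assigned = TRUE, ambiguous = FALSE)
  }

  map(neutral, one) |>
    list_rbind() |>
    mutate(mz = mz, neutral_mass = neutral, .before = 1)
}

#' Van Krevelen compound classification
#'
#' Maps molecular formulas to biochemical compound classes by their O:C and
#' H:C ratios using the rectangular regions of [vk_boundaries()], applied in
#' precedence order (first match wins). Formulas outside every region are
#' `"unassigned"`.
#'
#' @param C,H,N,O Elemental counts (vectorized; `N` is accepted for
#'   interface symmetry but classification uses C, H, O only).
#' @param boundaries A boundary table shaped like [vk_boundaries()].
#' @return A tibble `oc`, `hc`, `class`.
#' @examples
#' classify_formula(6, 12, 0, 6) # carbohydrate
#' @export
classify_formula <- function(C, H, N = 0, O, boundaries = vk_boundaries()) {
  oc <- O / C
  hc <- H / C
  class <- rep("unassigned", length(oc))
  unset <- rep(TRUE, length(oc))
  for (i in seq_len(nrow(boundaries))) {
    b <- boundaries[i, ]
    in_oc <- (if (b$oc_min_open) oc > b$oc_min else oc >= b$oc_min) &
      oc <= b$oc_max
    in_hc <- hc >= b$hc_min &
      (if (b$hc_max_open) hc < b$hc_max else hc <= b$hc_max)
    hit <- unset & in_oc & in_hc & !is.na(oc) & !is.na(hc)
    class[hit] <- b$class
    unset <- unset & !hit
  }
  class[is.na(oc) | is.na(hc)] <- NA_character_
  tibble(oc = oc, hc = hc, class = class)
}

#' Nominal oxidation state of carbon and Gibbs free energy
#'
#' `NOSC = 4 - (4C + H - 3N - 2O + 5P - 2S) / C`; the Gibbs free energy of
#' the carbon oxidation half reaction is the linear relation
#' `GFE = 60.3 - 28.5 * NOSC` (kJ per mol C). Higher NOSC means more
#' oxidized carbon and energetically cheaper oxidation.
#'
#' @param C,H,N,O,S,P Elemental counts (vectorized).
#' @param gfe_intercept,gfe_slope Coefficients of the GFE relation,
#'   config-exposed for recalibration.
#' @return A tibble `nosc`, `gfe`.
#' @examples
#' nosc_gfe(6, 12, 0, 6) # glucose: NOSC 0, GFE 60.3
#' @export
nosc_gfe <- function(C, H, N = 0, O, S = 0, P = 0,
                     gfe_intercept = 60.3, gfe_slope = -28.5) {
  nosc <- 4 - (4 * C + H - 3 * N - 2 * O + 5 * P - 2 * S) / C
  tibble(nosc = nosc, gfe = gfe_intercept + gfe_slope * nosc)
}

#' Treatment-unique and shared compounds
#'
#' A compound counts as detected in a treatment when it is present in at
#' least `min_plots` of that treatment's plots (pooled across timepoints).
#' Compounds detected in exactly one treatment are unique to it; compounds
#' detected in both are shared; compounds detected in neither are excluded.
#'
#' @param aligned Aligned peak table (`feature_id`, `sample_id`, ...).
#' @param design Sample design tibble with `sample_id`, `treatment`, `plot`.
#' @param min_plots Plots a compound must appear in to count as detected.
#' @return A tibble `feature_id`, one `detected_*` logical column per
#'   treatment, and `status` (`"unique-to-<treatment>"`, `"shared"`; only
#'   detected compounds are returned).
#' @export
unique_compounds <- function(aligned, design, min_plots = 2) {
  trts <- sort(unique(design$treatment[!is.na(design$treatment)]))
  det <- aligned |>
    distinct(.data$feature_id, .data$sample_id) |>
    inner_join(design, by = "sample_id") |>
    filter(!is.na(.data$treatment)) |>
    group_by(.data$feature_id, .data$treatment) |>
    summarise(n_plots = n_distinct(.data$plot), .groups = "drop") |>
    mutate(detected = .data$n_plots >= min_plots) |>
    select("feature_id", "treatment", "detected") |>
    pivot_wider(names_from = "treatment", values_from = "detected",
                names_prefix = "detected_", values_fill = FALSE)
  for (trt in trts) {
    col <- paste0("detected_", trt)
    if (!col %in% names(det)) det[[col]] <- FALSE
  }
  det_mat <- as.matrix(det[paste0("detected_", trts)])
  n_det <- rowSums(det_mat)
  status <- rep(NA_character_, nrow(det))
  status[n_det == 2] <- "shared"
  for (i in seq_along(trts)) {
    status[n_det == 1 & det_mat[, i]] <- paste0("unique-to-", trts[i])
  }
  det |>
    mutate(status = status) |>
    filter(!is.na(status))
}

#' Log-likelihood ratio (G-) test of independence
#'
#' `G = 2 * sum(O * ln(O / E))` over the cells of a contingency table, with
#' expected counts from the row and column marginals and
#' `df = (nrow - 1) * (ncol - 1)`. Cells with zero observed count contribute
#' nothing; a zero expected count with a positive observed count is an
#' invalid table.
#'
#' @param x A contingency table (matrix of non-negative counts).
#' @return A one-row tibble `g`, `df`, `p_value`.
#' @examples
#' g_test(matrix(c(10, 20, 20, 10), 2)) # G = 6.796, df = 1
#' @export
g_test <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) abort("counts must be non-negative")
  n <- sum(x)
  if (n == 0) abort("empty table")
  expected <- outer(rowSums(x), colSums(x)) / n
  if (any(expected == 0 & x > 0)) abort("zero expected count with observed > 0")
  terms <- ifelse(x > 0, x * log(x / expected), 0)
  g <- 2 * sum(terms)
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  tibble(g = g, df = df, p_value = pchisq(g, df, lower.tail = FALSE))
}

#' Compound-class enrichment among treatment-unique compounds
#'
#' Builds the class-by-treatment count table of unique compounds, runs the
#' overall G-test of independence across it, then a per-class 2x2 G-test
#' (that class versus all other compounds) with Benjamini-Hochberg FDR
#' correction across classes, and reports the log2 fold change of class
#' proportions between treatments.
#'
#' @param unique_tbl Output of [unique_compounds()] joined to a `class`
#'   column (one row per compound, `status` of the form
#'   `"unique-to-<treatment>"`; shared compounds are ignored).
#' @return A list: `overall` (one-row G-test tibble plus table dimensions)
#'   and `per_class` (tibble `class`, per-treatment counts, `g`, `df`,
#'   `p_value`, `p_fdr`, `log2fc`).
#' @export
class_enrichment <- function(unique_tbl) {
  uniq <- unique_tbl |>
    filter(grepl("^unique-to-", .data$status)) |>
    mutate(treatment = sub("^unique-to-", "", .data$status))
  if (nrow(uniq) == 0) abort("no treatment-unique compounds")
  tab <- table(uniq$class, uniq$treatment)
  overall <- g_test(tab) |>
    mutate(n_classes = nrow(tab), n_treatments = ncol(tab))

  trts <- colnames(tab)
  per_class <- map(rownames(tab), function(cl) {
    two <- rbind(tab[cl, ], colSums(tab) - tab[cl, ])
    res <- g_test(two)
    prop <- tab[cl, ] / colSums(tab)
    tibble(
      class = cl,
      !!paste0("n_", trts[1]) := tab[cl, 1],
      !!paste0("n_", trts[2]) := tab[cl, 2],
      g = res$g, df = res$df, p_value = res$p_value,
      log2fc = log2(prop[2] / prop[1])
    )
  }) |>
    list_rbind() |>
    mutate(p_fdr = p.adjust(.data$p_value, "BH"))
  list(overall = overall, per_class = per_class)
}
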