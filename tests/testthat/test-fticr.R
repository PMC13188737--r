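test_that("peak alignment merges within tolerance and splits beyond it", {
  close_pair <- tibble::tibble(sample_id = c("a", "b"),
                               mz = 300 * c(1, 1 + 0.1e-6), intensity = 1)
  expect_equal(dplyr::n_distinct(align_peaks(close_pair)$feature_id), 1)

  far_pair <- tibble::tibble(sample_id = c("a", "b"),
                             mz = 300 * c(1, 1 + 5e-6), intensity = 1)
  expect_equal(dplyr::n_distinct(align_peaks(far_pair)$feature_id), 2)

  # a chain of peaks each 0.4 ppm apart spans > 2x tolerance and is split
  chain <- tibble::tibble(sample_id = letters[1:5],
                          mz = 400 * cumprod(c(1, rep(1 + 0.4e-6, 4))),
                          intensity = 1)
  al <- align_peaks(chain)
  expect_gt(dplyr::n_distinct(al$feature_id), 1)
  spans <- al |>
    dplyr::group_by(feature_id) |>
    dplyr::summarise(span = (max(mz) - min(mz)) / min(mz) * 1e6)
  expect_true(all(spans$span <= 1.0))

  expect_error(align_peaks(close_pair[1, ]), "at least 2 samples")
})

test_that("alignment groups jittered replicates of the same compound", {
  cfg <- sim_config(n_compounds = 300, n_unique_per_treatment = 0, seed = 12)
  fs <- simulate_fticr(cfg, n_blank_peaks = 0)
  set.seed(12)
  # 6 replicate samples (the 2 treatment x 3 plot design) of every
  # compound, each with 0.2 ppm mass error
  # (bounded, as for a recalibrated spectrum -- the generator's error model)
  jitter <- function(s) tibble::tibble(
    sample_id = s,
    mz = (fs$truth$neutral_mass - 1.00727646688) *
      (1 + qsipcge:::.rtruncnorm(nrow(fs$truth), 0.2) * 1e-6),
    intensity = 1,
    compound = fs$truth$compound
  )
  peaks <- dplyr::bind_rows(lapply(paste0("s", 1:6), jitter))
  al <- align_peaks(peaks |> dplyr::select(sample_id, mz, intensity))
  al$compound <- peaks$compound[match(paste(al$sample_id, al$mz),
                                      paste(peaks$sample_id, peaks$mz))]
  purity <- al |>
    dplyr::group_by(compound) |>
    dplyr::summarise(one_feature = dplyr::n_distinct(feature_id) == 1)
  expect_gte(mean(purity$one_feature), 0.99)
})

test_that("blank subtraction and the 2-sample presence filter compose", {
  al <- tibble::tibble(
    feature_id = c("f1", "f1", "f2", "f2", "f3", "f4", "f4"),
    mz_feature = 1, intensity = 1,
    mz = 1,
    sample_id = c("s1", "blank", "s1", "s2", "s1", "s1", "s2")
  )
  noblank <- subtract_blanks(al, "blank")
  expect_false("f1" %in% noblank$feature_id) # seen in a blank
  expect_false("blank" %in% noblank$sample_id)
  expect_identical(subtract_blanks(al, "no_such_sample"), al)
  filtered <- min_presence_filter(noblank, k = 2)
  expect_setequal(unique(filtered$feature_id), c("f2", "f4"))
  expect_identical(min_presence_filter(filtered, 2), filtered)
  expect_warning(subtract_blanks(al, c("blank", "s1", "s2")), "all features")
})

test_that("formula assignment finds glucose and rejects off-grid masses", {
  glu <- assign_formula(179.05611)
  expect_true(glu$assigned)
  expect_equal(unlist(glu[c("C", "H", "N", "O")]),
               c(C = 6, H = 12, N = 0, O = 6))
  expect_lt(abs(glu$error_ppm), 0.1)
  # a mass midway between formula grid points has no candidate
  off <- assign_formula(180.5011111)
  expect_false(off$assigned)
})

test_that("formula search equals an independent brute-force enumeration", {
  # independent oracle: nested loops over N and O with H solved per C
  oracle <- function(mz, tol_ppm = 0.5) {
    m <- mz + 1.00727646688
    best <- NULL
    for (N in 0:2) for (C in 1:floor(m / 12)) {
      for (O in 0:floor((m - 12 * C - N * 14.0030740052) / 15.9949146221)) {
        rem <- m - 12 * C - N * 14.0030740052 - O * 15.9949146221
        H <- round(rem / 1.0078250319)
        if (H < 1 || H > 2 * C + N + 2) next
        if ((H + N) %% 2 != 0) next
        if (C - H / 2 + N / 2 + 1 < 0) next
        err <- (12 * C + H * 1.0078250319 + N * 14.0030740052 +
                  O * 15.9949146221 - m) / m * 1e6
        if (abs(err) < tol_ppm &&
            (is.null(best) || abs(err) < abs(best$err))) {
          best <- list(C = C, H = H, N = N, O = O, err = err)
        }
      }
    }
    best
  }
  set.seed(44)
  masses <- runif(30, 150, 500)
  got <- assign_formula(masses)
  for (i in seq_along(masses)) {
    ref <- oracle(masses[i])
    if (is.null(ref)) {
      expect_false(got$assigned[i] && !got$ambiguous[i])
    } else if (got$assigned[i]) {
      expect_equal(unlist(got[i, c("C", "H", "N", "O")]),
                   c(C = ref$C, H = ref$H, N = ref$N, O = ref$O))
    }
  }
})

test_that("van Krevelen classes match the boundary table and are unique", {
  expect_equal(classify_formula(6, 12, 0, 6)$class, "carbohydrate")
  expect_equal(classify_formula(16, 10, 0, 0)$class,
               "condensed-hydrocarbon")
  expect_equal(classify_formula(8, 8, 0, 3)$class, "lignin")
  # every grid point maps to exactly one label (precedence is total)
  grid <- expand.grid(oc = seq(0, 1.5, 0.01), hc = seq(0, 2.5, 0.01))
  cls <- classify_formula(C = 100, H = grid$hc * 100, O = grid$oc * 100)
  expect_equal(length(cls$class), nrow(grid))
  expect_false(any(is.na(cls$class)))
  expect_true(all(cls$class %in% c(vk_boundaries()$class, "unassigned")))
})

test_that("NOSC and Gibbs free energy follow the carbon-oxidation relation", {
  glu <- nosc_gfe(6, 12, 0, 6)
  expect_equal(glu$nosc, 0)
  expect_equal(glu$gfe, 60.3)
  expect_equal(nosc_gfe(1, 4, 0, 0)$nosc, -4) # methane
  expect_equal(nosc_gfe(1, 0, 0, 2)$nosc, 4)  # CO2
  # intensive: doubling the formula leaves NOSC unchanged
  expect_equal(nosc_gfe(12, 24, 0, 12)$nosc, 0)
  # more oxygen at fixed C and H raises NOSC
  expect_true(all(diff(nosc_gfe(6, 12, 0, 1:6)$nosc) > 0))
})

test_that("uniqueness rule is exact over all plot-presence patterns", {
  design <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    treatment = rep(c("A", "B"), each = 3),
    plot = rep(1:3, 2)
  )
  # all 2^6 presence patterns, one feature per pattern
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  rows <- lapply(seq_len(nrow(patterns)), function(i) {
    pres <- unlist(patterns[i, ])
    if (!any(pres)) return(NULL)
    tibble::tibble(feature_id = sprintf("p%02d", i),
                   sample_id = design$sample_id[pres])
  })
  aligned <- dplyr::bind_rows(rows)
  u <- unique_compounds(aligned, design, min_plots = 2)
  for (i in seq_len(nrow(patterns))) {
    pres <- unlist(patterns[i, ])
    in_a <- sum(pres[1:3]) >= 2
    in_b <- sum(pres[4:6]) >= 2
    id <- sprintf("p%02d", i)
    row <- u[u$feature_id == id, ]
    if (in_a && in_b) {
      expect_equal(row$status, "shared")
    } else if (in_a) {
      expect_equal(row$status, "unique-to-A")
    } else if (in_b) {
      expect_equal(row$status, "unique-to-B")
    } else {
      expect_equal(nrow(row), 0) # below detection everywhere: excluded
    }
  }
})

test_that("G-test matches its closed form and chi-square asymptotics", {
  res <- g_test(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$g, 6.796, tolerance = 1e-3 / 6.796)
  expect_equal(res$df, 1)

  # identical class distributions carry no information
  flat <- g_test(matrix(c(30, 30, 15, 15), 2, byrow = TRUE))
  expect_equal(flat$g, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)

  # 9 categories x 2 treatments gives df = 8
  set.seed(3)
  big <- matrix(rpois(18, 50) + 20, nrow = 9)
  res9 <- g_test(big)
  expect_equal(res9$df, 8)
  # G tracks the Pearson chi-square when all expected counts are large
  chi <- suppressWarnings(chisq.test(big, correct = FALSE))$statistic
  expect_lt(abs(res9$g - chi) / chi, 0.10)

  # a margin that is entirely zero carries no observations either, so the
  # zero-expected cells contribute nothing rather than erroring
  zero_col <- g_test(matrix(c(0, 0, 5, 5), 2))
  expect_equal(zero_col$g, 0)
  expect_error(g_test(matrix(0, 2, 2)), "empty")
})

test_that("planted class enrichment is detected with the right sign", {
  tannin_rich <- c(lignin = 0.2, tannin = 0.55, protein = 0.05,
                   lipid = 0.05, carbohydrate = 0.02, "amino-sugar" = 0.02,
                   "condensed-hydrocarbon" = 0.06,
                   "unsaturated-hydrocarbon" = 0.05)
  base <- c(lignin = 0.45, tannin = 0.06, protein = 0.12, lipid = 0.1,
            carbohydrate = 0.08, "amino-sugar" = 0.05,
            "condensed-hydrocarbon" = 0.09,
            "unsaturated-hydrocarbon" = 0.05)
  cfg <- sim_config(n_compounds = 2000, n_unique_per_treatment = 150,
                    seed = 14)
  fs <- simulate_fticr(cfg, unique_class_weights =
                         list("100" = tannin_rich, "50" = base))
  aligned <- align_peaks(fs$peaks) |>
    subtract_blanks(fs$design$sample_id[fs$design$is_blank]) |>
    min_presence_filter()
  # map features back to truth classes via m/z
  feat <- dplyr::distinct(aligned, feature_id, mz_feature)
  feat$class <- fs$truth$class[
    vapply(feat$mz_feature, function(m) {
      which.min(abs(fs$truth$neutral_mass - 1.00727646688 - m))
    }, integer(1))
  ]
  uniq2 <- unique_compounds(aligned, fs$design) |>
    dplyr::left_join(feat |> dplyr::select(feature_id, class),
                     by = "feature_id")
  enr <- class_enrichment(uniq2)
  expect_lt(enr$overall$p_value, 0.001)
  tan <- enr$per_class[enr$per_class$class == "tannin", ]
  expect_lt(tan$p_fdr, 0.05)
  # treatments sort as "100" then "50": tannins enriched in "100" means the
  # proportion ratio 50/100 is below one
  expect_lt(tan$log2fc, 0)
})
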