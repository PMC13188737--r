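test_that("linear dynamics keep exact new/surviving bookkeeping", {
  truth <- simulate_dynamics(sim_config(n_taxa = 20, seed = 5))
  ab <- truth$abundance
  expect_equal(ab$new + ab$surviving_old, ab$n_t)
  expect_true(all(ab$surviving_old >= 0))
  expect_true(all(ab$a >= 0 & ab$a <= 1))
  expect_equal(ab$a[ab$timepoint_h == 0], rep(0, sum(ab$timepoint_h == 0)))
  # EAF never exceeds the labeling ceiling
  qs <- qsip_config()
  ceiling_eaf <- qs$o_fraction_from_water *
    (truth$config$water_18o_atom_fraction - qs$natural_18o_abundance)
  expect_true(all(ab$eaf <= ceiling_eaf + 1e-12))
})

test_that("zero turnover means constant abundance and no new DNA", {
  cfg <- sim_config(n_taxa = 4, seed = 2, rate_cv = 0,
                    growth_per_capita = list("100" = 0),
                    mortality_per_capita = list("100" = 0),
                    true_cge_by_treatment = list("100" = 0.4))
  truth <- simulate_dynamics(cfg)
  ab <- truth$abundance
  expect_equal(ab$n_t, rep(truth$taxa$n0, each = length(cfg$timepoints_h)))
  expect_equal(ab$a, rep(0, nrow(ab)))
})

test_that("generators are byte-identical under a repeated seed", {
  cfg <- sim_config(n_taxa = 6, n_genes = 30, n_compounds = 40,
                    n_unique_per_treatment = 5, seed = 77)
  t1 <- simulate_dynamics(cfg)
  t2 <- simulate_dynamics(cfg)
  expect_identical(t1$abundance, t2$abundance)
  expect_identical(simulate_gradient(t1, cfg), simulate_gradient(t2, cfg))
  expect_identical(simulate_co2(t1, cfg), simulate_co2(t2, cfg))
  f1 <- simulate_fticr(cfg)
  f2 <- simulate_fticr(cfg)
  expect_identical(f1$peaks, f2$peaks)
  expect_identical(simulate_expression(t1, cfg)$counts,
                   simulate_expression(t2, cfg)$counts)
})

test_that("gradient conserves taxon mass and partitions fractions into bins", {
  cfg <- sim_config(n_taxa = 8, seed = 13)
  truth <- simulate_dynamics(cfg)
  unpooled <- simulate_gradient(truth, cfg, pool = FALSE, noise = FALSE)
  pooled <- simulate_gradient(truth, cfg, pool = TRUE, noise = FALSE)

  # per-sample total copies equal the community total (mass conservation)
  totals <- truth$abundance |>
    dplyr::group_by(treatment, timepoint_h) |>
    dplyr::summarise(n = sum(n_t), .groups = "drop")
  for (tbl in list(unpooled, pooled)) {
    got <- tbl |>
      dplyr::group_by(sample_id, treatment, timepoint_h) |>
      dplyr::summarise(n = sum(copies_16s), .groups = "drop") |>
      dplyr::left_join(totals, by = c("treatment", "timepoint_h"))
    expect_equal(got$n.x, got$n.y, tolerance = 1e-9)
  }
  # 36 fractions per sample; the 5 bins partition them (no fraction lost)
  expect_equal(unique(table(unpooled$sample_id)), 36L)
  expect_setequal(unique(pooled$bin_id), 1:5)
  expect_equal(sum(pooled$copies_16s), sum(unpooled$copies_16s),
               tolerance = 1e-9)
})

test_that("without labeling the 18O and control profiles coincide", {
  cfg <- sim_config(n_taxa = 4, seed = 3, rate_cv = 0,
                    growth_per_capita = list("100" = 0),
                    mortality_per_capita = list("100" = 0),
                    true_cge_by_treatment = list("100" = 0.4))
  truth <- simulate_dynamics(cfg)
  fr <- simulate_gradient(truth, cfg, noise = FALSE)
  lab <- fr[fr$label == "18O" & fr$timepoint_h == 72, ]
  ctl <- fr[fr$label == "natural" & fr$timepoint_h == 72, ]
  expect_equal(lab$copies_16s, ctl$copies_16s, tolerance = 1e-12)
  expect_equal(lab$density_g_ml, ctl$density_g_ml, tolerance = 1e-12)
})

test_that("a narrow band at GC 0.5 lands in the bin containing 1.68781 g/mL", {
  cfg <- sim_config(n_taxa = 1, seed = 1, gc_range = c(0.5, 0.5),
                    gradient_sigma = 1e-4,
                    growth_per_capita = list("100" = 0),
                    mortality_per_capita = list("100" = 0),
                    true_cge_by_treatment = list("100" = 0.4))
  truth <- simulate_dynamics(cfg)
  fr <- simulate_gradient(truth, cfg, pool = TRUE, noise = FALSE)
  s1 <- fr[fr$sample_id == fr$sample_id[1], ]
  target_bin <- findInterval(1.646057 + 0.083506 * 0.5, cfg$bin_edges)
  expect_gt(s1$copies_16s[s1$bin_id == target_bin] / sum(s1$copies_16s),
            0.999)
})

test_that("expected CO2 halves when true CGE doubles", {
  base <- small_sim_config(seed = 4)
  dbl <- small_sim_config(seed = 4,
                          true_cge_by_treatment = list("100" = 0.8))
  co2_base <- simulate_co2(simulate_dynamics(base), base, noise = FALSE)
  co2_dbl <- simulate_co2(simulate_dynamics(dbl), dbl, noise = FALSE)
  expect_equal(co2_base$co2_umol, 2 * co2_dbl$co2_umol, tolerance = 1e-12)
})

test_that("simulated FTICR peaks sit at [M-H]- within the ppm error budget", {
  cfg <- sim_config(n_compounds = 60, n_unique_per_treatment = 5, seed = 8)
  fs <- simulate_fticr(cfg)
  # every peak matches one truth compound within 0.5 ppm of neutral - proton
  expected_mz <- fs$truth$neutral_mass - 1.00727646688
  nearest <- vapply(fs$peaks$mz, function(m) min(abs(m - expected_mz) / m),
                    numeric(1))
  expect_lt(max(nearest) * 1e6, 0.5)
  # planted formulas are chemically valid CHNO even-electron neutrals
  tr <- fs$truth
  expect_true(all((tr$H + tr$N) %% 2 == 0))
  expect_true(all(tr$H <= 2 * tr$C + tr$N + 2))
  expect_true(all(tr$N <= 2))
})

test_that("with full detection and no planted uniques nothing is unique", {
  cfg <- sim_config(n_compounds = 50, n_unique_per_treatment = 0,
                    detect_prob = 1, seed = 6)
  fs <- simulate_fticr(cfg)
  aligned <- align_peaks(fs$peaks) |>
    subtract_blanks(fs$design$sample_id[fs$design$is_blank])
  u <- unique_compounds(aligned, fs$design)
  expect_true(all(u$status == "shared"))
})

test_that("expression generator plants the requested number of signed genes", {
  cfg <- sim_config(n_taxa = 4, n_genes = 40, n_planted_genes = 6, seed = 9)
  ex <- simulate_expression(simulate_dynamics(cfg), cfg)
  expect_equal(nrow(ex$planted), 6)
  expect_setequal(unique(ex$planted$sign), c(1, -1))
  expect_equal(dim(as.matrix(ex$counts[-1])),
               c(40, 2 * 3 * 5)) # genes x (trt x plot x post-0h timepoints)
  expect_true(all(ex$samples$timepoint_h > 0))
})
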