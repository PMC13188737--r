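test_that("VIP scores satisfy their normalization identity", {
  set.seed(51)
  x <- matrix(rnorm(40 * 25), 40, 25)
  y <- x %*% rnorm(25) + rnorm(40)
  for (a in c(1, 3, 5)) {
    v <- vip(plsr_fit(x, y, ncomp = a))
    expect_equal(sum(v^2), 25, tolerance = 1e-8)
  }
  # a single predictor has VIP exactly 1
  v1 <- vip(plsr_fit(cbind(x[, 1]), y, ncomp = 1))
  expect_equal(unname(v1), 1, tolerance = 1e-12)
})

test_that("univariate one-component PLSR reproduces least squares", {
  set.seed(52)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 + 3 * x[, 1] + rnorm(30, sd = 0.2)
  fit <- plsr_fit(x, y, ncomp = 1)
  ols <- lm(y ~ x[, 1])
  expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), unname(coef(ols)[2]),
               tolerance = 1e-8)
})

test_that("fit rejects degenerate inputs and ignores sample order", {
  set.seed(53)
  x <- matrix(rnorm(60), 20, 3)
  expect_error(plsr_fit(x, rep(1, 20)), "constant")
  expect_error(plsr_fit(x[1:2, ], rnorm(2), ncomp = 3))
  y <- x[, 1] + rnorm(20, sd = 0.1)
  fit <- plsr_fit(x, y, ncomp = 2)
  perm <- sample(20)
  fit_p <- plsr_fit(x[perm, ], y[perm], ncomp = 2)
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-10)
})

test_that("NIPALS agrees with an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(54)
  x <- matrix(rnorm(25 * 12), 25, 12,
              dimnames = list(NULL, paste0("g", 1:12)))
  y <- x %*% c(2, -1.5, rep(0, 10)) + rnorm(25, sd = 0.3)
  fit <- plsr_fit(x, y, ncomp = 3)
  ref <- mixOmics::pls(x, y, ncomp = 3, mode = "regression", scale = TRUE)
  pred_ref <- predict(ref, x)$predict[, 1, 3]
  expect_equal(unname(fit$fitted), unname(pred_ref), tolerance = 1e-6)
})

test_that("top-decile selection counts and tie handling are correct", {
  set.seed(55)
  x <- matrix(rnorm(30 * 100), 30, 100,
              dimnames = list(NULL, sprintf("g%03d", 1:100)))
  y <- x[, 1:5] %*% rep(1, 5) + rnorm(30, sd = 0.5)
  fit <- plsr_fit(x, y, ncomp = 2)
  sel <- select_top(fit, fraction = 0.10)
  expect_equal(sum(sel$selected), 10) # 100 genes, no ties
  expect_equal(nrow(sel), 100)
  expect_true(all(sel$vip[sel$selected] >= max(sel$vip[!sel$selected])))
  # signs come from the coefficients
  expect_equal(sel$sign, sign(sel$coefficient))
})

test_that("planted genes dominate the top decile; null planting does not", {
  cfg <- sim_config(n_taxa = 10, n_genes = 1000, n_planted_genes = 50,
                    planted_effect = 1, seed = 56)
  truth <- simulate_dynamics(cfg)
  ex <- simulate_expression(truth, cfg)
  assoc <- cge_association(
    ex$log_norm,
    ex$samples |> dplyr::select(sample_id, cge),
    ncomp = 2
  )
  sel <- assoc$associations
  hit <- mean(ex$planted$gene %in% sel$gene[sel$selected])
  expect_gte(hit, 0.8)
  # signs of strongly planted genes match their planted direction
  strong <- sel[sel$gene %in% ex$planted$gene & sel$selected, ]
  planted_sign <- ex$planted$sign[match(strong$gene, ex$planted$gene)]
  expect_gt(mean(strong$sign == planted_sign), 0.9)

  # with no planted effect the planted set is not enriched among selected
  cfg0 <- sim_config(n_taxa = 10, n_genes = 1000, n_planted_genes = 50,
                     planted_effect = 0, seed = 57)
  truth0 <- simulate_dynamics(cfg0)
  ex0 <- simulate_expression(truth0, cfg0)
  assoc0 <- cge_association(
    ex0$log_norm, ex0$samples |> dplyr::select(sample_id, cge), ncomp = 2
  )
  sel0 <- assoc0$associations
  tab <- table(planted = sel0$gene %in% ex0$planted$gene,
               selected = sel0$selected)
  expect_gt(fisher.test(tab)$p.value, 0.05)
})

test_that("pathway correlations recover hand-computable relationships", {
  expr <- tibble::tibble(
    gene = c("g1", "g2"),
    s1 = c(1, 0), s2 = c(2, 0), s3 = c(3, 0)
  )
  # log CGE perfectly linear in the pathway sum with slope 2
  cge <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                        cge = exp(c(2, 4, 6)))
  paths <- tibble::tibble(gene = c("g1", "g2"),
                          pathway = c("biosynthesis", "degradation"))
  res <- suppressWarnings(pathway_correlations(expr, cge, paths))
  bio <- res[res$pathway == "biosynthesis", ]
  expect_equal(bio$r, 1, tolerance = 1e-12)
  expect_equal(bio$slope, 2, tolerance = 1e-12)
  # flipping the response flips the correlation sign
  flip <- suppressWarnings(
    pathway_correlations(expr, dplyr::mutate(cge, cge = exp(-log(cge))),
                         paths)
  )
  expect_equal(flip$r[flip$pathway == "biosynthesis"], -1,
               tolerance = 1e-12)
  # the constant-sum pathway is skipped with a warning
  expect_warning(pathway_correlations(expr, cge, paths), "degradation")
})

test_that("ratio correlation reduces to the numerator when denominator is flat", {
  set.seed(58)
  expr <- tibble::tibble(
    gene = c("num1", "num2", "den"),
    s1 = c(1, 2, 5), s2 = c(2, 3, 5), s3 = c(4, 2, 5), s4 = c(5, 6, 5)
  )
  cge <- tibble::tibble(sample_id = paste0("s", 1:4),
                        cge = c(0.1, 0.2, 0.5, 0.9))
  r_ratio <- ratio_correlation(expr, cge, c("num1", "num2"), "den")
  r_path <- suppressWarnings(pathway_correlations(
    expr, cge, tibble::tibble(gene = c("num1", "num2"), pathway = "p")
  ))
  expect_equal(r_ratio$r, r_path$r, tolerance = 1e-12)
  # zero denominator drops the sample with a warning
  expr0 <- dplyr::mutate(expr, s1 = c(1, 2, 0))
  expect_warning(
    out <- ratio_correlation(expr0, cge, c("num1", "num2"), "den"),
    "zero denominator"
  )
  expect_equal(out$n_samples, 3)
})
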