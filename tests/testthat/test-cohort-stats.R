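test_that("compare_groups is a two-tailed t-test with a flag", {
  same <- compare_groups(c(10, 10, 10, 10), c(10, 10, 10, 10))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$flag)

  set.seed(6)
  sep <- compare_groups(c(10, 10, 10, 10) + stats::rnorm(4, 0, 1e-3),
                        c(20, 20, 20, 20) + stats::rnorm(4, 0, 1e-3))
  expect_lt(sep$p, 1e-6)
  expect_true(sep$flag)
  expect_error(compare_groups(5, c(1, 2)), ">= 2")
})

test_that("summary_stat_ttest reproduces catalog-row inferences", {
  eq <- summary_stat_ttest(10, 1, 7, 10, 1, 6)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  # complement C3 row: strongly significant under Student pooling
  c3 <- summary_stat_ttest(12.77, 0.81, 7, 9.98, 1.20, 6)
  expect_lt(c3$p, 0.005)

  # serotransferrin row: not reproducible as significant from summaries
  st_w <- summary_stat_ttest(37.62, 1.74, 7, 33.12, 6.63, 6,
                             variant = "welch")
  expect_gt(st_w$p, 0.05)

  expect_error(summary_stat_ttest(1, 0, 7, 2, 1, 6), "SD")
  expect_error(summary_stat_ttest(1, 1, 1, 2, 1, 6), "sizes")
})

test_that("per-animal and summary-stat t-tests agree to 1e-12", {
  set.seed(31)
  for (i in 1:10) {
    a <- stats::rnorm(7, 20, 3)
    b <- stats::rnorm(6, 16, 3)
    full <- compare_groups(a, b, var_equal = TRUE)
    summ <- summary_stat_ttest(mean(a), stats::sd(a), 7,
                               mean(b), stats::sd(b), 6)
    expect_equal(full$p, summ$p, tolerance = 1e-12)
    expect_equal(full$t, summ$t, tolerance = 1e-12)
  }
})

test_that("halflife_regression is through-origin and scale-equivariant", {
  x <- c(10, 20, 30, 40)
  same <- halflife_regression(x, x)
  expect_equal(same$slope, 1)
  expect_equal(same$r2, 1)
  halfed <- halflife_regression(x, 0.5 * x)
  expect_equal(halfed$slope, 0.5)
  expect_equal(halfed$r2, 1)

  set.seed(14)
  y <- x * 0.8 + stats::rnorm(4, 0, 1)
  base <- halflife_regression(x, y)
  for (cc in c(0.3, 2, 7)) {
    expect_equal(halflife_regression(x, cc * y)$slope, cc * base$slope,
                 tolerance = 1e-12)
  }
  expect_error(halflife_regression(c(1, 2), c(1, 2)), ">= 3")
  expect_error(halflife_regression(c(1, 2, -3), c(1, 2, 3)), "> 0")
})

test_that("cohort_summary in summary-stat mode reanalyzes the catalog", {
  res <- cohort_summary(hdl_halflife_catalog())
  s <- res$summary
  expect_equal(res$mode, "summary-stat")
  expect_equal(s$n_proteins, 34)
  expect_equal(s$pct_reduction, 17.35, tolerance = 0.01)
  expect_equal(s$slope, 0.838, tolerance = 1e-3)
  expect_equal(s$r2, 0.946, tolerance = 1e-3)
  # printed flags kept verbatim next to recomputed ones, never reconciled
  disc <- res$proteins$accession[res$proteins$flag_discrepant]
  expect_setequal(disc, c("Q3UEG8", "Q3TJ94", "Q921I1"))
})

test_that("cohort_summary handles identical groups and per-animal mode", {
  cat <- hdl_halflife_catalog()[1:5, ]
  flat <- data.frame(accession = cat$accession,
                     control_thalf = cat$control_thalf, control_sd = 1,
                     hfd_thalf = cat$control_thalf, hfd_sd = 1)
  res <- cohort_summary(flat)
  expect_equal(res$summary$pct_reduction, 0)
  expect_equal(res$summary$pct_significant_reduced, 0)

  # per-animal mode on a constructed two-group table with a known k ratio
  set.seed(9)
  grid <- expand.grid(animal = 1:4, accession = c("P1", "P2", "P3", "P4"),
                      group = c("control", "HFD"))
  k <- ifelse(grid$group == "control", 0.04, 0.05) *
    (1 + stats::rnorm(nrow(grid), 0, 0.01))
  tab <- data.frame(group = as.character(grid$group),
                    animal_id = paste0(substr(grid$group, 1, 1), grid$animal),
                    accession = as.character(grid$accession),
                    mean_k = k, t_half = log(2) / k)
  res2 <- cohort_summary(tab)
  expect_equal(res2$mode, "per-animal")
  expect_equal(res2$summary$n_proteins, 4)
  expect_equal(res2$summary$slope, 0.8, tolerance = 0.02)
  expect_equal(res2$summary$pct_significant_reduced, 100)
  expect_lt(res2$summary$mean_halflife_p, 0.05)
})

test_that("optional BH adjustment only tightens flags", {
  res_raw <- cohort_summary(hdl_halflife_catalog())
  res_bh <- cohort_summary(hdl_halflife_catalog(), p_adjust = "BH")
  expect_true(all(res_bh$proteins$flag <= res_raw$proteins$flag))
})
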