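test_that("body_water_timecourse follows the protocol mass balance", {
  # bolus mass balance: 0.999 * 30 / (600 + 30)
  p <- labeling_protocol(mode = "exponential", equil_rate_per_h = 1e-9)
  e <- body_water_timecourse(p, c(0, 1e-6))
  expect_equal(e[1], 0)
  expect_equal(e[2], 0.999 * 30 / 630, tolerance = 1e-6)

  inst <- labeling_protocol(plateau = 0.05)
  expect_equal(body_water_timecourse(inst, c(0, 8, 24, 168)),
               c(0, 0.05, 0.05, 0.05))
  off <- labeling_protocol(dose_ul_per_g = 0, drinking_water = 0)
  expect_equal(body_water_timecourse(off, c(0, 8, 168)), c(0, 0, 0))
  expect_error(labeling_protocol(body_water_ml_per_g = 0.9), "0.4, 0.8")
})

test_that("body-water calibration inverts exactly and flags extrapolation", {
  e <- c(0, 0.01, 0.02, 0.03, 0.04, 0.05)
  cal <- calibrate_body_water(e, 2 * e + 1)
  expect_equal(invert_calibration(cal, 1.06)$enrichment, 0.03,
               tolerance = 1e-12)
  expect_false(invert_calibration(cal, 1.06)$extrapolated)
  expect_true(invert_calibration(cal, 1.2)$extrapolated)
  expect_error(calibrate_body_water(c(0, 0.05), c(1, 1.1)), "3")
  expect_error(calibrate_body_water(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("sample_peptides is seeded, bounded and unique", {
  a <- sample_peptides("P1", 5, seed = 99)
  b <- sample_peptides("P1", 5, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(sample_peptides("P1", 3, seed = 1)), 3)
  expect_false(anyDuplicated(a$peptide) > 0)
  expect_true(all(grepl("[KR]$", a$peptide)))  # tryptic termini
  expect_error(sample_peptides("P1", 2, seed = 1), "\\[3, 20\\]")
  expect_error(sample_peptides("P1", 4, length_range = c(9, 5), seed = 1),
               "infeasible")
})

test_that("cohort_config validates its fields by name", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(n_control = 1, seed = 1), "n_control")
  expect_error(cohort_config(times = c(0, 8, 24), seed = 1), "times")
  expect_error(cohort_config(peptides_per_protein = c(1, 5), seed = 1),
               "peptides_per_protein")
  bad <- hdl_halflife_catalog()
  bad$control_thalf[1] <- -1
  expect_error(cohort_config(catalog = bad, seed = 1), "catalog")
})

test_that("generate_cohort is bit-reproducible for a fixed seed", {
  cfg <- cohort_config(catalog = hdl_halflife_catalog()[1:3, ],
                       n_control = 2, n_hfd = 2,
                       peptides_per_protein = c(3, 4), seed = 123)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$timecourse, s2$timecourse)
  expect_identical(s1$truth, s2$truth)
})

test_that("noiseless cohorts lie exactly on the labeling curve and are identifiable", {
  cfg <- cohort_config(catalog = hdl_halflife_catalog()[c(4, 8), ],
                       n_control = 2, n_hfd = 2,
                       peptides_per_protein = c(3, 3),
                       intensity_cv = 0, proportion_noise = 0,
                       animal_cv = 0, seed = 77)
  sim <- generate_cohort(cfg)
  tc <- sim$timecourse
  key <- paste(tc$animal_id, tc$peptide)
  for (kk in unique(key)[1:6]) {
    d <- tc[key == kk, ]
    ser <- enrichment_series(d)
    pep <- sim$peptides[sim$peptides$peptide == d$peptide[1], ]
    tru <- sim$truth[sim$truth$animal_id == d$animal_id[1] &
                       sim$truth$accession == d$accession[1], ]
    curve <- pep$I0_theory + (pep$Iplateau_theory - pep$I0_theory) *
      (1 - exp(-tru$k_true * ser$time_h))
    expect_equal(ser$I, curve, tolerance = 1e-12)
    fit <- fit_peptide(ser)
    expect_lt(abs(fit$k / tru$k_true - 1), 1e-4)
  }
})

test_that("ground-truth ledger means track the catalog half-lives", {
  cfg <- cohort_config(seed = 2024)
  sim <- generate_cohort(cfg)
  agg <- stats::aggregate(thalf_true ~ group + accession, data = sim$truth,
                          FUN = mean)
  cat <- hdl_halflife_catalog()
  agg$expected <- ifelse(agg$group == "control",
                         cat$control_thalf[match(agg$accession, cat$accession)],
                         cat$hfd_thalf[match(agg$accession, cat$accession)])
  ratio <- agg$thalf_true / agg$expected
  # animal CV 8%, n = 6-7: SE of a group mean ratio is ~3%
  expect_lt(abs(mean(ratio) - 1), 0.015)
  expect_lt(max(abs(ratio - 1)), 0.15)
})

test_that("generated isotopomer proportions are non-negative and normalized", {
  cfg <- cohort_config(catalog = hdl_halflife_catalog()[1:2, ],
                       n_control = 2, n_hfd = 2,
                       peptides_per_protein = c(3, 3),
                       intensity_cv = 0, proportion_noise = 0, seed = 5)
  tc <- generate_cohort(cfg)$timecourse
  mm <- as.matrix(tc[, grep("^m[0-9]+$", names(tc))])
  expect_true(all(mm >= 0))
  props <- mm / tc$total_intensity
  expect_equal(rowSums(props), rep(1, nrow(tc)), tolerance = 1e-12)
})

test_that("the packaged half-life catalog is complete and positive", {
  cat <- hdl_halflife_catalog()
  expect_equal(nrow(cat), 34)
  expect_true(all(cat$control_thalf > 0 & cat$hfd_thalf > 0))
  c3 <- cat[cat$accession == "P01027", ]
  expect_equal(c(c3$control_thalf, c3$hfd_thalf), c(12.77, 9.98))
  apoa1 <- cat[cat$accession == "Q3V2G1", ]
  expect_equal(c(apoa1$control_thalf, apoa1$hfd_thalf), c(24.33, 20.51))
})
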