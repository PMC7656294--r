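test_that("fit_exponential recovers exact parameters from noiseless data", {
  ser <- make_series(0.05, 0.0132, 0.30)
  fit <- fit_exponential(ser)
  expect_true(fit$converged)
  expect_lt(abs(fit$k / 0.05 - 1), 1e-4)
  expect_equal(fit$I0, 0.0132, tolerance = 1e-6)
  expect_equal(fit$Iplateau, 0.30, tolerance = 1e-6)
  expect_equal(fit$t_half * fit$k, log(2))
})

test_that("fit_exponential enforces its preconditions", {
  ser <- make_series(0.05, 0.0132, 0.30)
  expect_error(fit_exponential(ser[1:3, ]), "at least 4")
  expect_error(fit_exponential(ser[-1, ]), "baseline")
  short <- make_series(0.05, 0.0132, 0.30, times = c(0, 4, 8, 24))
  expect_error(fit_exponential(short), "48")
})

test_that("median recovered k from noisy replicates is within 5%", {
  comp <- composition_from_sequence("LVNEVTEFAK")
  n_eh <- exchangeable_hydrogens("LVNEVTEFAK")
  nat <- natural_distribution(comp); nat <- nat / sum(nat)
  lab <- labeled_distribution(comp, n_eh, 0.05); lab <- lab / sum(lab)
  tm <- c(0, 8, 24, 48, 96, 168)
  f <- 1 - exp(-0.05 * tm)
  expec <- outer(1 - f, nat) + outer(f, lab)
  set.seed(4242)
  ks <- replicate(100, {
    noisy <- expec * matrix(stats::rlnorm(length(expec),
                                          -log(1.0009) / 2,
                                          sqrt(log(1.0009))),
                            nrow(expec))
    I <- apply(noisy, 1, total_labeling)
    fit_peptide(data.frame(time_h = tm, I = I))$k
  })
  expect_lt(abs(stats::median(ks) / 0.05 - 1), 0.05)
})

test_that("remove_outliers drops only genuinely displaced points", {
  ser <- make_series(0.05, 0.0132, 0.30)
  fit <- fit_exponential(ser)
  clean <- remove_outliers(ser, fit)
  expect_length(attr(clean, "removed"), 0)  # noiseless: zero removals

  set.seed(21)
  noisy <- ser
  noisy$I <- noisy$I + stats::rnorm(6, 0, 0.002)
  noisy$I[4] <- noisy$I[4] + 10 * 0.002  # +10 SD displacement
  fit1 <- fit_peptide(noisy)
  expect_equal(fit1$removed, 4L)
  expect_lt(abs(fit1$k - 0.05), 1e-3)

  # more flagged outliers than max_removals: one removal, flag raised
  set.seed(77)
  many <- make_series(0.05, 0.0132, 0.30,
                      times = c(0, 4, 8, 16, 24, 48, 72, 96, 120, 168))
  many$I <- many$I + stats::rnorm(10, 0, 0.004)
  f2 <- fit_exponential(many)
  pruned <- remove_outliers(many, f2, threshold = 1, max_removals = 1)
  expect_length(attr(pruned, "removed"), 1)
  expect_true(attr(pruned, "flagged"))

  # removal that would drop below the point floor is blocked and flagged
  fit6 <- fit_peptide(noisy, max_removals = 0)
  blocked <- remove_outliers(noisy, fit6, min_points = 6)
  expect_length(attr(blocked, "removed"), 0)
  expect_true(attr(blocked, "flagged"))
})

test_that("half_life is ln2 over k", {
  expect_equal(half_life(0.0693147), 10, tolerance = 1e-5)
  # printed control ApoA-I rate 2.86 %/h vs catalog half-life 24.33 +/- 1.76
  expect_lt(abs(half_life(0.0286) - 24.33), 1.76)
  expect_error(half_life(0), "> 0")
  expect_error(half_life(-1), "> 0")
})

test_that("fitting is invariant to time-unit rescaling", {
  set.seed(12)
  I <- make_series(0.05, 0.0132, 0.30)$I + stats::rnorm(6, 0, 0.003)
  tm <- c(0, 8, 24, 48, 96, 168)
  fit_h <- fit_exponential(data.frame(time_h = tm, I = I))
  fit_d <- fit_exponential(data.frame(time_h = tm / 24, I = I),
                           k_bounds = c(1e-5, 2) * 24, min_span_h = 2)
  expect_equal(fit_d$k / 24, fit_h$k, tolerance = 1e-6)
  expect_equal(fit_d$I0, fit_h$I0, tolerance = 1e-6)
})

test_that("aggregate_protein averages converged peptide fits", {
  mk <- function(k, conv = TRUE) {
    structure(list(k = k, converged = conv), class = "kinetic_fit")
  }
  agg <- aggregate_protein(list(mk(0.05), mk(0.06), mk(0.07)))
  expect_equal(agg$mean_k, 0.06)
  expect_equal(agg$sd_k, 0.01)
  expect_equal(agg$t_half, log(2) / 0.06, tolerance = 1e-12)
  expect_equal(agg$t_half, 11.55, tolerance = 1e-3)

  two <- aggregate_protein(list(mk(0.05), mk(0.06)))
  expect_true(two$excluded)
  expect_match(two$reason, "2 converged")

  four <- aggregate_protein(list(mk(0.05), mk(0.06), mk(0.07),
                                 mk(0.2, conv = FALSE)))
  expect_false(four$excluded)
  expect_equal(four$mean_k, 0.06)
  expect_equal(four$n_peptides, 3)
  expect_error(aggregate_protein(list()), "no peptide fits")
})
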