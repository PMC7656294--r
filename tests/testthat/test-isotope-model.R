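test_that("composition_from_sequence follows peptide condensation", {
  expect_equal(composition_from_sequence("G"),
               c(C = 2, H = 5, N = 1, O = 2, S = 0))
  expect_equal(composition_from_sequence("GG"),
               c(C = 4, H = 8, N = 2, O = 3, S = 0))
  expect_equal(composition_from_sequence("AG"),
               c(C = 5, H = 10, N = 2, O = 3, S = 0))
  expect_error(composition_from_sequence("GXG"), "position 2")
  expect_error(composition_from_sequence(""), "empty")
})

test_that("natural_distribution matches single-element closed forms", {
  ab <- natural_abundances()
  d <- natural_distribution("C1")
  expect_equal(unname(d[1:2]), c(0.9893, 0.0107), tolerance = 1e-15)
  expect_equal(unname(d[3:6]), rep(0, 4))
  a_d <- ab$H[2]
  h2 <- natural_distribution("H2")
  expect_equal(unname(h2[1]), (1 - a_d)^2, tolerance = 1e-15)
  expect_equal(unname(h2[2]), 2 * a_d * (1 - a_d), tolerance = 1e-15)
  expect_error(natural_distribution("C1", n_iso = 1), "n_iso")
})

test_that("natural_distribution matches the enumeration oracle", {
  for (seqs in c("GG", "AG", "C", "CM", "WR")) {
    comp <- composition_from_sequence(seqs)
    got <- natural_distribution(comp, n_iso = 6)
    want <- oracle_natural(comp)[1:6]
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
    expect_lt(abs(attr(got, "truncation") - max(0, 1 - sum(want))), 1e-12)
  }
})

test_that("distributions are proper within the reported truncation", {
  set.seed(11)
  res <- residue_table()
  for (i in 1:20) {
    pep <- paste(sample(res$residue, sample(3:20, 1), replace = TRUE),
                 collapse = "")
    comp <- composition_from_sequence(pep, res)
    d <- natural_distribution(comp)
    expect_true(all(d >= 0))
    expect_gt(d[1], 0)
    expect_equal(sum(d) + attr(d, "truncation"), 1, tolerance = 1e-12)
    l <- labeled_distribution(comp, exchangeable_hydrogens(pep, res), 0.05)
    expect_true(all(l >= 0))
    expect_equal(sum(l) + attr(l, "truncation"), 1, tolerance = 1e-12)
  }
})

test_that("exchangeable_hydrogens sums the residue table", {
  expect_equal(exchangeable_hydrogens("GG"), 4.12)
  expect_equal(exchangeable_hydrogens("A"), 4.00)
  zero_tab <- residue_table()
  zero_tab$exchangeable_H <- 0
  expect_equal(exchangeable_hydrogens("ACDEFGHIK", zero_tab), 0)
  expect_error(exchangeable_hydrogens("GXG"), "position 2")
})

test_that("labeled_distribution reduces to natural when unlabeled", {
  comp <- composition_from_sequence("GG")
  nat <- natural_distribution(comp)
  expect_equal(labeled_distribution(comp, 4.12, 0), nat)
  expect_equal(labeled_distribution(comp, 0, 0.05), nat)
  expect_error(labeled_distribution(comp, 4.12, 0.5), "p_w")
  expect_error(labeled_distribution(comp, 4.12, -0.01), "p_w")
})

test_that("labeled_distribution matches the enumeration oracle", {
  for (pep in c("GG", "CM", "AR")) {
    comp <- composition_from_sequence(pep)
    n_eh <- exchangeable_hydrogens(pep)
    got <- labeled_distribution(comp, n_eh, 0.05)
    want <- oracle_labeled(comp, n_eh, 0.05)[1:6]
    expect_equal(as.numeric(got), want, tolerance = 1e-10)
  }
})

test_that("labeling is a monotone probability mixture", {
  comp <- composition_from_sequence("AGLVR")
  n_eh <- exchangeable_hydrogens("AGLVR")
  pws <- c(0, 0.01, 0.02, 0.035, 0.05, 0.1)
  m0 <- vapply(pws, function(p) labeled_distribution(comp, n_eh, p)[[1]],
               numeric(1))
  expect_true(all(diff(m0) < 0))  # M0 non-increasing in p_w
  itot <- vapply(pws, function(p) asymptotic_labeling(comp, n_eh, p),
                 numeric(1))
  expect_true(all(diff(itot) > 0))  # labeling non-decreasing in p_w
  iesc <- vapply(c(0, 2, 5, 9, 14), function(n)
    asymptotic_labeling(comp, n, 0.05), numeric(1))
  expect_true(all(diff(iesc) > 0))  # and in N_EH
})

test_that("asymptotic_labeling agrees with Eq.-1 on the oracle pattern", {
  comp <- composition_from_sequence("GG")
  n_eh <- exchangeable_hydrogens("GG")
  expect_equal(asymptotic_labeling(comp, n_eh, 0),
               total_labeling(natural_distribution(comp)))
  lab <- oracle_labeled(comp, n_eh, 0.05)[1:6]
  expect_equal(asymptotic_labeling(comp, n_eh, 0.05),
               1 - lab[1] / sum(lab), tolerance = 1e-10)
  expect_gt(asymptotic_labeling(comp, n_eh, 0.05),
            asymptotic_labeling(comp, n_eh, 0.02))
})
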