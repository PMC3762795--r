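test_that("asymptotic HWE test matches hand-computed chi-squared values", {
  r <- hwe_asymptotic(25, 50, 25)  # exactly p^2 : 2pq : q^2
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_false(r$monomorphic)

  # Benes controls: borderline case where asymptotic and exact disagree
  r <- hwe_asymptotic(86, 106, 17)
  expect_equal(r$chi2, 4.0, tolerance = 0.01)
  expect_lt(r$p, 0.05)

  r <- hwe_asymptotic(63, 31, 20)  # Sun controls: gross violation
  expect_lt(r$p, 0.001)

  r <- hwe_asymptotic(50, 0, 0)
  expect_true(r$monomorphic)
  expect_equal(r$p, 1)
})

test_that("exact HWE test reproduces reference values and handles edge cases", {
  expect_equal(hwe_exact(14, 73, 37), 0.025, tolerance = 0.02)  # Mei controls
  expect_equal(hwe_exact(49, 26, 13), 0.009, tolerance = 0.06)  # Raza controls
  expect_lt(hwe_exact(63, 31, 20), 0.001)                       # Sun controls
  expect_equal(hwe_exact(100, 0, 0), 1)                         # monomorphic
  expect_equal(hwe_exact(0, 0, 7), 1)
})

test_that("exact test agrees with brute-force enumeration on tiny samples", {
  cases <- list(c(3, 4, 3), c(5, 2, 0), c(2, 0, 2), c(0, 5, 0), c(4, 4, 1))
  for (g in cases) {
    expect_equal(hwe_exact(g[1], g[2], g[3]),
                 oracle_hwe_exact(g[1], g[2], g[3]), tolerance = 1e-10)
  }
})

test_that("exact test is symmetric under allele relabelling", {
  set.seed(7)
  for (i in 1:25) {
    g <- as.integer(rmultinom(1, sample(20:200, 1), c(0.4, 0.4, 0.2)))
    expect_equal(hwe_exact(g[1], g[2], g[3]), hwe_exact(g[3], g[2], g[1]),
                 tolerance = 1e-12)
  }
})

test_that("asymptotic and exact tests disagree only near the threshold", {
  corp <- mthfr_corpus()
  rep_ <- hwe_report(corp)
  bounds <- snpmeta:::parse_printed_p(rep_$printed_p)
  # where the source prints a clear verdict (p < 0.01 or p > 0.3) the two
  # tests agree on rejection at 0.05
  clear <- !is.na(bounds[, 2]) & (bounds[, 2] < 0.01 | bounds[, 1] > 0.3)
  expect_true(any(clear))
  expect_equal(rep_$p_exact[clear] < 0.05, rep_$p_asymptotic[clear] < 0.05)

  # the documented borderline discrepancies: asymptotic rejects, exact keeps
  for (id in c("Benes 2001", "Mackawy 2011")) {
    row <- rep_[rep_$study_id == id, ]
    expect_lt(row$p_asymptotic, 0.05)
    expect_gte(row$p_exact, 0.05)
  }
})

test_that("HWE partition of the bundled corpus isolates the four violations", {
  corp <- mthfr_corpus()
  parts <- partition_by_hwe(corp)
  expect_setequal(parts$out_of_hwe$study_id,
                  c("Mei 2012", "Raza 2012", "Sun 2006", "Mtiraoui 2007"))
  out_tot <- corpus_totals(parts$out_of_hwe)
  expect_equal(out_tot$total_cases, 574L)
  expect_equal(out_tot$total_controls, 726L)
  in_tot <- corpus_totals(parts$in_hwe)
  expect_equal(in_tot$total_cases, 4281L)
  expect_equal(in_tot$total_controls, 4516L)

  # a corpus at perfect HWE proportions has no out-of-HWE stratum
  perfect <- study_corpus(data.frame(
    study_id = c("p1", "p2"), ethnicity = "Asian",
    complications = "explicitly_absent",
    case_cc = 25L, case_ct = 50L, case_tt = 25L,
    ctrl_cc = 25L, ctrl_ct = 50L, ctrl_tt = 25L))
  expect_null(partition_by_hwe(perfect)$out_of_hwe)

  # the printed classifier reproduces the same split on this corpus
  parts_pr <- partition_by_hwe(corp, classifier = "printed")
  expect_identical(parts_pr$out_of_hwe$study_id, parts$out_of_hwe$study_id)
})
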