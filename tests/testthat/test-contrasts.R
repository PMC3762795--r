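corp <- mthfr_corpus()
one <- function(id) corp[corp$study_id == id, ]

test_that("contrast tables map genotype counts to the documented 2x2 cells", {
  # allele counting: 2*CC + CT C alleles, 2*TT + CT T alleles, per arm
  tb <- build_contrast(one("Mackawy 2011"), "allele")
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(58, 22, 70, 10))
  expect_false(tb$corrected)
  expect_false(tb$excluded)

  # recessive with no TT in either arm: no information, excluded
  tb <- build_contrast(one("Movva 2011"), "recessive")
  expect_true(tb$excluded)
  tb <- build_contrast(one("Movva 2011"), "homozygote")
  expect_true(tb$excluded)
  expect_false(build_contrast(one("Movva 2011"), "allele")$excluded)
  expect_false(build_contrast(one("Movva 2011"), "dominant")$excluded)

  # single zero cell: 0.5 added to all four cells
  tb <- build_contrast(one("Soares 2008"), "homozygote")
  expect_true(tb$corrected)
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(5.5, 0.5, 9.5, 2.5))
})

test_that("per-study effects follow the Woolf log odds ratio machinery", {
  sym <- list(study_id = "sym", contrast = "allele", a = 10, b = 10,
              c = 10, d = 10, corrected = FALSE, excluded = FALSE,
              reason = "")
  class(sym) <- "contrast_table"
  ef <- study_effect(sym)
  expect_equal(ef$log_or, 0)
  expect_equal(ef$se, sqrt(0.4))

  ef <- study_effect(build_contrast(one("Mackawy 2011"), "allele"))
  expect_equal(ef$or, 580 / 1540, tolerance = 1e-12)
  expect_equal(ef$se, sqrt(1/58 + 1/22 + 1/70 + 1/10), tolerance = 1e-12)
  expect_equal(round(ef$or, 4), 0.3766)
  expect_equal(round(ef$se, 4), 0.4207)

  ef <- study_effect(build_contrast(one("Soares 2008"), "homozygote"))
  expect_equal(ef$or, 13.75 / 4.75, tolerance = 1e-12)

  expect_error(study_effect(build_contrast(one("Movva 2011"), "recessive")),
               "excluded")
})

test_that("odds ratios obey the case-control and exposure swap symmetries", {
  ids <- c("Mackawy 2011", "Chauhan 2012", "Soares 2008", "Zhou 2004")
  for (id in ids) for (ct in contrast_names()) {
    tb <- build_contrast(one(id), ct)
    if (tb$excluded) next
    ef <- study_effect(tb)

    # swap case and control arms
    rec <- as.data.frame(one(id))
    swapped <- rec
    swapped[c("case_cc", "case_ct", "case_tt")] <-
      rec[c("ctrl_cc", "ctrl_ct", "ctrl_tt")]
    swapped[c("ctrl_cc", "ctrl_ct", "ctrl_tt")] <-
      rec[c("case_cc", "case_ct", "case_tt")]
    ef_sw <- study_effect(build_contrast(study_corpus(swapped)[1, ], ct))
    expect_equal(ef_sw$log_or, -ef$log_or, tolerance = 1e-12)
    expect_equal(ef_sw$se, ef$se, tolerance = 1e-12)
  }

  # relabelling the alleles (CC<->TT in both arms) inverts the allele and
  # homozygote ORs
  for (id in ids) for (ct in c("allele", "homozygote")) {
    tb <- build_contrast(one(id), ct)
    if (tb$excluded) next
    rec <- as.data.frame(one(id))
    flip <- rec
    flip[c("case_cc", "case_tt")] <- rec[c("case_tt", "case_cc")]
    flip[c("ctrl_cc", "ctrl_tt")] <- rec[c("ctrl_tt", "ctrl_cc")]
    ef <- study_effect(tb)
    ef_fl <- study_effect(build_contrast(study_corpus(flip)[1, ], ct))
    expect_equal(ef_fl$log_or, -ef$log_or, tolerance = 1e-12)
  }
})

test_that("fixture-wide table invariants hold", {
  n_case <- corp$case_cc + corp$case_ct + corp$case_tt
  n_ctrl <- corp$ctrl_cc + corp$ctrl_ct + corp$ctrl_tt
  tabs <- contrast_tables(corp, "allele")
  for (i in seq_along(tabs)) {
    expect_equal(tabs[[i]]$a + tabs[[i]]$b, 2 * n_case[i])
    expect_equal(tabs[[i]]$c + tabs[[i]]$d, 2 * n_ctrl[i])
  }

  n_excl <- vapply(contrast_names(), function(ct)
    sum(vapply(contrast_tables(corp, ct), `[[`, logical(1), "excluded")),
    integer(1))
  expect_equal(unname(n_excl), c(0L, 0L, 1L, 1L))
  excl_h <- contrast_effects(corp, "homozygote")
  expect_equal(excl_h$study_id[excl_h$excluded], "Movva 2011")
})
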