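fx <- mthfr_corpus()

eff_df <- function(log_or, se) {
  data.frame(study_id = sprintf("s%d", seq_along(log_or)),
             log_or = log_or, se = se,
             excluded = rep(FALSE, length(log_or)))
}

test_that("a single study pools to itself with zero heterogeneity", {
  corp <- toy_corpus()[1, ]
  res <- meta_analyse(corp, "allele")
  ef <- study_effect(build_contrast(corp[1, ], "allele"))
  expect_equal(res$or, ef$or, tolerance = 1e-10)
  expect_equal(res$q, 0)
  expect_equal(res$i2, 0)
  expect_equal(res$tau2, 0)
  expect_equal(res$k, 1L)
  expect_match(res$model, "fixed")
})

test_that("heterogeneity and DL pooling match the two-study closed form", {
  ef <- eff_df(c(0, 1), c(0.1, 0.1))
  het <- heterogeneity(ef)
  expect_equal(het$q, 50)
  expect_equal(het$tau2, 0.49)
  re <- pool_random(ef, het$tau2)
  expect_equal(re$se, 0.5)
  expect_equal(re$log_or, 0.5)
})

test_that("DL random pooling with tau2 = 0 is the IV fixed estimate", {
  ef <- eff_df(c(-0.2, 0.1, 0.4), c(0.2, 0.3, 0.25))
  expect_equal(pool_random(ef, 0)$log_or, pool_fixed(ef, "IV")$log_or,
               tolerance = 1e-12)
  expect_equal(pool_random(ef, 0)$se, pool_fixed(ef, "IV")$se,
               tolerance = 1e-12)
})

test_that("DL pooling agrees with an independent brute-force oracle (k <= 3)", {
  set.seed(42)
  for (k in 2:3) for (rep in 1:20) {
    theta <- rnorm(k, 0, 0.8)
    se <- runif(k, 0.05, 0.6)
    ef <- eff_df(theta, se)
    het <- heterogeneity(ef)
    re <- pool_random(ef, het$tau2)
    orc <- oracle_dl(theta, se)
    expect_equal(het$q, orc$q, tolerance = 1e-10)
    expect_equal(het$tau2, orc$tau2, tolerance = 1e-10)
    expect_equal(het$i2, orc$i2, tolerance = 1e-10)
    expect_equal(re$log_or, orc$mu, tolerance = 1e-10)
    expect_equal(re$se, orc$se, tolerance = 1e-10)
  }
})

test_that("MH and IV fixed estimates agree on large homogeneous corpora", {
  cfg <- simulation_config(k = 10L, n_case_range = c(3000L, 4000L),
                           n_ctrl_range = c(3000L, 4000L),
                           true_log_or = log(1.3), tau = 0, seed = 9L)
  corp <- simulate_corpus(cfg)
  ef <- contrast_effects(corp, "allele")
  mh <- pool_fixed(ef, "MH")
  iv <- pool_fixed(ef, "IV")
  expect_lt(abs(mh$or / iv$or - 1), 0.001)
})

test_that("the model-selection rule is a strict P > 0.10 cut", {
  expect_equal(select_model(0.54), "fixed")
  expect_equal(select_model(0.11), "fixed")
  expect_equal(select_model(0.10), "random")   # boundary is random
  expect_equal(select_model(0.099), "random")
  expect_equal(select_model(1e-6), "random")
  expect_error(select_model(1.2))
})

test_that("pooled estimates stay inside the per-study hull, random CI covers fixed CI", {
  for (ct in contrast_names()) {
    ef <- contrast_effects(fx, ct)
    inc <- ef[!ef$excluded, ]
    het <- heterogeneity(ef)
    for (pooled in list(pool_fixed(ef, "IV"), pool_fixed(ef, "MH"),
                        pool_random(ef, het$tau2))) {
      expect_gte(pooled$log_or, min(inc$log_or))
      expect_lte(pooled$log_or, max(inc$log_or))
    }
    fixed <- pool_fixed(ef, "IV")
    random <- pool_random(ef, het$tau2)
    expect_gte(random$se, fixed$se)
    if (het$tau2 == 0) expect_equal(random$se, fixed$se, tolerance = 1e-12)

    res <- meta_analyse(fx, ct)
    expect_gte(res$i2, 0); expect_lte(res$i2, 100)
    expect_gt(res$p_z, 0); expect_lte(res$p_z, 1)
    expect_gt(res$p_q, 0); expect_lte(res$p_q, 1)
    expect_lte(res$ci_low, res$or); expect_lte(res$or, res$ci_high)
  }
})

test_that("pooling cross-checks against metafor on the bundled corpus", {
  skip_if_not_installed("metafor")
  ef <- contrast_effects(fx, "allele")
  het <- heterogeneity(ef)
  re <- pool_random(ef, het$tau2)
  m <- metafor::rma(yi = ef$log_or, vi = ef$se^2, method = "DL")
  expect_equal(re$log_or, as.numeric(m$beta), tolerance = 1e-8)
  expect_equal(re$se, m$se, tolerance = 1e-8)
  expect_equal(het$q, m$QE, tolerance = 1e-8)
  expect_equal(het$tau2, m$tau2, tolerance = 1e-8)

  ef_h <- contrast_effects(fx, "homozygote")
  mh <- pool_fixed(ef_h, "MH")
  inc <- ef_h[!ef_h$excluded, ]
  m2 <- metafor::rma.mh(ai = inc$a, bi = inc$b, ci = inc$c, di = inc$d,
                        measure = "OR", correct = FALSE)
  expect_equal(mh$log_or, as.numeric(m2$beta), tolerance = 1e-8)
  expect_equal(mh$se, m2$se, tolerance = 1e-8)
})

test_that("degenerate pooling inputs raise errors", {
  ef <- eff_df(numeric(0), numeric(0))
  expect_error(pool_fixed(ef), "no studies")
  all_excl <- data.frame(study_id = "x", log_or = NA_real_, se = NA_real_,
                         excluded = TRUE)
  expect_error(pool_fixed(all_excl), "no studies")
})
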