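#' Fixed-effect pooling of per-study odds ratios
#'
#' Pools the non-excluded studies of `effects` under a common-effect
#' assumption. Two estimators are available:
#'
#' * `"MH"` (default): Mantel-Haenszel pooled odds ratio
#'   `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`, with the
#'   Robins-Breslow-Greenland variance for its logarithm — the standard
#'   estimator for sparse 2x2 data;
#' * `"IV"`: inverse-variance weighted mean of the per-study log odds
#'   ratios, weights `1/se_i^2`.
#'
#' The 95% CI is `exp(log OR +/- 1.96 SE)` and the Z statistic is
#' `log OR / SE` with a two-sided normal p-value.
#'
#' @param effects data.frame as returned by [contrast_effects()] (columns
#'   `log_or`, `se`, and for MH also `a`, `b`, `c`, `d`; excluded rows are
#'   dropped).
#' @param method `"MH"` or `"IV"`.
#' @return Object of class `pooled_result`; see [meta_analyse()] for the
#'   fields.
#' @export
pool_fixed <- function(effects, method = c("MH", "IV")) {
  method <- match.arg(method)
  ef <- included_effects(effects)
  k <- nrow(ef)
  if (method == "IV") {
    w <- 1 / ef$se^2
    log_or <- sum(w * ef$log_or) / sum(w)
    se <- sqrt(1 / sum(w))
  } else {
    n <- ef$a + ef$b + ef$c + ef$d
    R <- sum(ef$a * ef$d / n)
    S <- sum(ef$b * ef$c / n)
    P <- (ef$a + ef$d) / n
    Q <- (ef$b + ef$c) / n
    Ri <- ef$a * ef$d / n
    Si <- ef$b * ef$c / n
    log_or <- log(R / S)
    se <- sqrt(sum(P * Ri) / (2 * R^2) +
               sum(P * Si + Q * Ri) / (2 * R * S) +
               sum(Q * Si) / (2 * S^2))
  }
  new_pooled(effects, log_or, se,
             model = if (method == "MH") "fixed_MH" else "fixed_IV",
             tau2 = 0)
}

#' Cochran's Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-study log odds ratios about the inverse-variance fixed-effect
#' pooled estimate (the classic Cochran form); its null distribution is
#' chi-squared with `k - 1` degrees of freedom. `i2 = max(0, 100 (Q - df)/Q)`
#' expresses the share of total variation attributable to between-study
#' heterogeneity, and the DerSimonian-Laird moment estimator of the
#' between-study variance is
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`.
#'
#' `centre = "MH"` instead measures dispersion about the Mantel-Haenszel
#' pooled estimate (the convention of some meta-analysis software); the
#' two differ negligibly in practice.
#'
#' For a single study Q = 0, `p_q` = 1, `i2` = 0, `tau2` = 0.
#'
#' @param effects data.frame with `log_or` and `se` (and the 2x2 cells if
#'   `centre = "MH"`); excluded rows are dropped.
#' @param centre `"IV"` (default) or `"MH"`.
#' @return List with `q`, `df`, `p_q`, `i2`, `tau2`.
#' @export
heterogeneity <- function(effects, centre = c("IV", "MH")) {
  centre <- match.arg(centre)
  ef <- included_effects(effects)
  k <- nrow(ef)
  df <- k - 1L
  if (k < 2L)
    return(list(q = 0, df = df, p_q = 1, i2 = 0, tau2 = 0))
  w <- 1 / ef$se^2
  mid <- if (centre == "IV") {
    sum(w * ef$log_or) / sum(w)
  } else {
    pool_fixed(ef, method = "MH")$log_or
  }
  q <- sum(w * (ef$log_or - mid)^2)
  p_q <- stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, 100 * (q - df) / q) else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(q = q, df = df, p_q = p_q, i2 = i2, tau2 = tau2)
}

#' Random-effects (DerSimonian-Laird) pooling
#'
#' Inverse-variance pooling with the between-study variance added to each
#' study's sampling variance: weights `1/(se_i^2 + tau2)`. With
#' `tau2 = 0` this reduces exactly to the inverse-variance fixed-effect
#' estimate.
#'
#' @param effects data.frame with `log_or` and `se`.
#' @param tau2 non-negative between-study variance, usually from
#'   [heterogeneity()].
#' @return Object of class `pooled_result`.
#' @export
pool_random <- function(effects, tau2) {
  stopifnot(is.numeric(tau2), length(tau2) == 1L, tau2 >= 0)
  ef <- included_effects(effects)
  w <- 1 / (ef$se^2 + tau2)
  log_or <- sum(w * ef$log_or) / sum(w)
  se <- sqrt(1 / sum(w))
  new_pooled(effects, log_or, se, model = "random_DL", tau2 = tau2)
}

#' Model selection by the heterogeneity Q-test
#'
#' The fixed-effect model is retained when the Q-test gives no evidence
#' of heterogeneity (`p_q > threshold`, default 0.10, strict inequality);
#' otherwise the random-effects model is selected. `p_q` exactly at the
#' threshold selects the random-effects model.
#'
#' @param p_q p-value of Cochran's Q.
#' @param threshold selection threshold, default 0.10.
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(p_q, threshold = 0.10) {
  stopifnot(is.numeric(p_q), p_q >= 0, p_q <= 1)
  if (p_q > threshold) "fixed" else "random"
}

#' Full meta-analysis of one genetic contrast
#'
#' Composes the pipeline for a corpus and contrast: build the 2x2 tables
#' (with continuity correction and exclusion flags), estimate per-study
#' log odds ratios, compute heterogeneity, select the model by the Q-test
#' rule, and pool — Mantel-Haenszel (or inverse-variance) under the fixed
#' model, DerSimonian-Laird under the random model.
#'
#' @param corpus a [study_corpus].
#' @param contrast one of [contrast_names()].
#' @param fixed_method fixed-effect estimator, `"MH"` (default) or `"IV"`.
#' @param q_centre how Cochran's Q is centred, see [heterogeneity()].
#' @param model_rule_threshold Q-test p-value threshold of the selection
#'   rule, default 0.10.
#' @return Object of class `pooled_result` with fields `contrast`, `model`
#'   (`fixed_MH`, `fixed_IV` or `random_DL`), `k`, `df`, `or`, `ci_low`,
#'   `ci_high`, `z`, `p_z`, `q`, `p_q`, `i2`, `tau2`, `n_cases`,
#'   `n_controls`, `excluded_studies`, plus `log_or` and `se` on the log
#'   scale.
#' @examples
#' meta_analyse(mthfr_corpus(), "recessive")
#' @export
meta_analyse <- function(corpus, contrast,
                         fixed_method = c("MH", "IV"),
                         q_centre = c("IV", "MH"),
                         model_rule_threshold = 0.10) {
  fixed_method <- match.arg(fixed_method)
  q_centre <- match.arg(q_centre)
  contrast <- match_contrast(contrast)
  effects <- contrast_effects(corpus, contrast)
  if (all(effects$excluded))
    stop("all studies are excluded from the ", contrast, " contrast",
         call. = FALSE)
  het <- heterogeneity(effects, centre = q_centre)
  model <- select_model(het$p_q, model_rule_threshold)
  pooled <- if (model == "fixed") {
    pool_fixed(effects, method = fixed_method)
  } else {
    pool_random(effects, tau2 = het$tau2)
  }
  pooled$contrast <- contrast
  pooled$q <- het$q
  pooled$p_q <- het$p_q
  pooled$i2 <- het$i2
  pooled$tau2 <- if (model == "fixed") 0 else het$tau2
  inc <- corpus[!effects$excluded, ]
  tot <- corpus_totals(inc)
  pooled$n_cases <- tot$total_cases
  pooled$n_controls <- tot$total_controls
  pooled$excluded_studies <- effects$study_id[effects$excluded]
  pooled
}

#' Forest-plot data for one contrast
#'
#' Per-study odds ratios, 95% CIs and percentage weights under the model
#' actually selected for the pooled analysis, followed by the pooled row,
#' in corpus order.
#'
#' @inheritParams meta_analyse
#' @return data.frame with columns `study_id`, `or`, `ci_low`, `ci_high`,
#'   `weight_pct` (NA for excluded studies); the final row (`study_id ==
#'   "POOLED"`) holds the pooled estimate.
#' @export
forest_data <- function(corpus, contrast, fixed_method = c("MH", "IV"),
                        model_rule_threshold = 0.10) {
  fixed_method <- match.arg(fixed_method)
  pooled <- meta_analyse(corpus, contrast, fixed_method = fixed_method,
                         model_rule_threshold = model_rule_threshold)
  effects <- contrast_effects(corpus, contrast)
  inc <- !effects$excluded
  w <- rep(NA_real_, nrow(effects))
  w[inc] <- if (pooled$model == "random_DL") {
    1 / (effects$se[inc]^2 + pooled$tau2)
  } else if (pooled$model == "fixed_MH") {
    n <- effects$a + effects$b + effects$c + effects$d
    (effects$b[inc] * effects$c[inc] / n[inc])
  } else {
    1 / effects$se[inc]^2
  }
  w[inc] <- 100 * w[inc] / sum(w[inc])
  out <- data.frame(study_id = effects$study_id, or = effects$or,
                    ci_low = effects$ci_low, ci_high = effects$ci_high,
                    weight_pct = w)
  rbind(out, data.frame(study_id = "POOLED", or = pooled$or,
                        ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                        weight_pct = 100))
}

#' @export
print.pooled_result <- function(x, ...) {
  model_lab <- c(fixed_MH = "Fixed (Mantel-Haenszel)",
                 fixed_IV = "Fixed (inverse variance)",
                 random_DL = "Random (DerSimonian-Laird)")[x$model]
  cat(sprintf("Pooled %s contrast: OR %.2f [%.2f, %.2f], Z = %.2f (P = %.3g)\n",
              if (is.null(x$contrast)) "?" else x$contrast,
              x$or, x$ci_low, x$ci_high, abs(x$z), x$p_z))
  if (!is.null(x$q))
    cat(sprintf("Heterogeneity: Q = %.2f, df = %d (P = %.3g), I2 = %.0f%%, tau2 = %.4f\n",
                x$q, x$df, x$p_q, x$i2, x$tau2))
  cat(sprintf("Model: %s; k = %d studies (%d cases, %d controls)\n",
              model_lab, x$k,
              if (is.null(x$n_cases)) NA_integer_ else x$n_cases,
              if (is.null(x$n_controls)) NA_integer_ else x$n_controls))
  if (length(x$excluded_studies))
    cat("Excluded:", paste(x$excluded_studies, collapse = ", "), "\n")
  invisible(x)
}

# -- internal helpers --------------------------------------------------------

included_effects <- function(effects) {
  if (is.data.frame(effects)) {
    if ("excluded" %in% names(effects)) effects <- effects[!effects$excluded, ]
    if (nrow(effects) == 0L)
      stop("no studies to pool", call. = FALSE)
    return(effects)
  }
  stop("`effects` must be a data.frame of per-study estimates", call. = FALSE)
}

new_pooled <- function(effects, log_or, se, model, tau2) {
  ef <- included_effects(effects)
  k <- nrow(ef)
  z <- log_or / se
  structure(list(model = model, k = k, df = k - 1L,
                 log_or = log_or, se = se, or = exp(log_or),
                 ci_low = exp(log_or - 1.96 * se),
                 ci_high = exp(log_or + 1.96 * se),
                 z = z, p_z = 2 * stats::pnorm(-abs(z)),
                 tau2 = tau2),
            class = "pooled_result")
}
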