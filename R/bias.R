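#' Funnel-plot coordinates
#'
#' Per-study (log odds ratio, standard error) pairs for a contrast, in
#' corpus order — the raw material of a Begg-style funnel plot. Excluded
#' studies (no exposure variation in either arm) are omitted.
#'
#' @inheritParams meta_analyse
#' @return data.frame with columns `study_id`, `log_or`, `se`.
#' @export
funnel_data <- function(corpus, contrast) {
  effects <- contrast_effects(corpus, contrast)
  out <- effects[!effects$excluded, c("study_id", "log_or", "se")]
  rownames(out) <- NULL
  out
}

#' Harbord's modified test for small-study bias
#'
#' Score-based regression test for funnel asymmetry in 2x2 data. Each
#' study contributes its efficient score for the log odds ratio,
#' `Z = a - (a+b)(a+c)/n`, and Fisher information
#' `V = (a+b)(c+d)(a+c)(b+d) / (n^2 (n-1))`, both computed on the
#' *uncorrected* integer tables (the score is well defined with zero
#' cells, so no continuity correction is applied). The standardized score
#' `Z/sqrt(V)` is regressed on `sqrt(V)` by ordinary least squares; the
#' intercept estimates the small-study bias and is tested against zero
#' with a two-sided t-test on `k - 2` degrees of freedom.
#'
#' Studies excluded from the contrast (double-empty margins) are dropped,
#' as are studies with `V = 0` (with a message).
#'
#' @param corpus a [study_corpus], or a list of `contrast_table`s.
#' @param contrast one of [contrast_names()] (ignored when `corpus` is
#'   already a list of tables).
#' @return Object of class `harbord_result`: list with `intercept`,
#'   `intercept_se`, `slope`, `t`, `df`, `p`, `k`.
#' @examples
#' harbord_test(mthfr_corpus(), "allele")
#' @export
harbord_test <- function(corpus, contrast = "allele") {
  tabs <- if (inherits(corpus, "study_corpus")) {
    contrast_tables(corpus, contrast)
  } else {
    corpus
  }
  # uncorrected cells: remove the 0.5 the builder added
  cells <- lapply(tabs, function(tb) {
    if (tb$excluded) return(NULL)
    x <- c(tb$a, tb$b, tb$c, tb$d)
    if (tb$corrected) x <- x - 0.5
    x
  })
  cells <- cells[!vapply(cells, is.null, logical(1L))]
  Z <- V <- numeric(length(cells))
  for (i in seq_along(cells)) {
    x <- cells[[i]]
    n <- sum(x)
    Z[i] <- x[1] - (x[1] + x[2]) * (x[1] + x[3]) / n
    V[i] <- (x[1] + x[2]) * (x[3] + x[4]) * (x[1] + x[3]) * (x[2] + x[4]) /
      (n^2 * (n - 1))
  }
  drop <- V <= 0
  if (any(drop)) {
    message("dropping ", sum(drop), " study(ies) with zero information")
    Z <- Z[!drop]; V <- V[!drop]
  }
  k <- length(Z)
  if (k < 3L)
    stop("Harbord's test needs at least 3 informative studies", call. = FALSE)
  y <- Z / sqrt(V)
  x <- sqrt(V)
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  df <- k - 2L
  t_stat <- cf["(Intercept)", "t value"]
  # a perfectly symmetric corpus has zero residual variance: report no bias
  if (!is.finite(t_stat))
    t_stat <- if (abs(cf["(Intercept)", "Estimate"]) < 1e-12) 0 else
      sign(cf["(Intercept)", "Estimate"]) * Inf
  structure(list(intercept = cf["(Intercept)", "Estimate"],
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 slope = cf["x", "Estimate"],
                 t = t_stat, df = df,
                 p = 2 * stats::pt(-abs(t_stat), df = df),
                 k = k),
            class = "harbord_result")
}

#' @export
print.harbord_result <- function(x, ...) {
  cat(sprintf(paste0("Harbord's modified test for small-study bias\n",
                     "  intercept = %.4f (SE %.4f), t = %.3f, df = %d, ",
                     "P = %.3f  (k = %d studies)\n"),
              x$intercept, x$intercept_se, x$t, x$df, x$p, x$k))
  invisible(x)
}
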