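#' Stratified meta-analysis
#'
#' Runs the full [meta_analyse()] pipeline for every contrast within each
#' stratum of the requested stratification. The fixed/random model-
#' selection rule is re-applied independently inside every stratum, so
#' different strata may legitimately use different models for the same
#' contrast. Strata with zero studies are omitted with a message.
#'
#' Stratifications: `"overall"` (one stratum), `"ethnicity"` and
#' `"complications"` (from the corpus labels), `"hwe"` (control-arm
#' Hardy-Weinberg status, classified by `hwe_classifier` at
#' `hwe_threshold`).
#'
#' @param corpus a [study_corpus].
#' @param stratification one of `"overall"`, `"ethnicity"`,
#'   `"complications"`, `"hwe"`.
#' @param contrasts contrasts to run, default all four.
#' @param hwe_classifier,hwe_threshold passed to [partition_by_hwe()]
#'   when `stratification = "hwe"`.
#' @inheritParams meta_analyse
#' @return Object of class `stratified_report`: list with `stratification`
#'   and `strata`, a named list where each stratum holds `label`,
#'   `n_studies`, `n_cases`, `n_controls` and `results` (one
#'   `pooled_result` per contrast).
#' @examples
#' rep <- stratified_meta(mthfr_corpus(), "ethnicity")
#' as.data.frame(rep)
#' @export
stratified_meta <- function(corpus,
                            stratification = c("overall", "ethnicity",
                                               "complications", "hwe"),
                            contrasts = contrast_names(),
                            fixed_method = c("MH", "IV"),
                            model_rule_threshold = 0.10,
                            hwe_classifier = "exact",
                            hwe_threshold = 0.05) {
  stopifnot(inherits(corpus, "study_corpus"))
  stratification <- match.arg(stratification)
  fixed_method <- match.arg(fixed_method)
  contrasts <- vapply(contrasts, match_contrast, character(1L),
                      USE.NAMES = FALSE)

  parts <- switch(stratification,
    overall = list(all = corpus),
    ethnicity = {
      lv <- c("Asian", "Caucasian", "African")
      stats::setNames(lapply(lv, function(e) {
        sub <- corpus$ethnicity == e
        if (any(sub)) corpus[sub, ] else NULL
      }), lv)
    },
    complications = {
      lv <- c("present_or_unreported", "explicitly_absent")
      stats::setNames(lapply(lv, function(e) {
        sub <- corpus$complications == e
        if (any(sub)) corpus[sub, ] else NULL
      }), lv)
    },
    hwe = partition_by_hwe(corpus, classifier = hwe_classifier,
                           threshold = hwe_threshold))

  empty <- vapply(parts, is.null, logical(1L))
  if (any(empty))
    message("omitting empty stratum(s): ",
            paste(names(parts)[empty], collapse = ", "))
  parts <- parts[!empty]

  strata <- lapply(names(parts), function(lab) {
    sub <- parts[[lab]]
    tot <- corpus_totals(sub)
    results <- stats::setNames(lapply(contrasts, function(ct)
      meta_analyse(sub, ct, fixed_method = fixed_method,
                   model_rule_threshold = model_rule_threshold)), contrasts)
    list(label = lab, n_studies = tot$n_studies, n_cases = tot$total_cases,
         n_controls = tot$total_controls, results = results)
  })
  names(strata) <- names(parts)
  structure(list(stratification = stratification, strata = strata),
            class = "stratified_report")
}

#' @export
as.data.frame.stratified_report <- function(x, ...) {
  rows <- list()
  for (st in x$strata) {
    for (ct in names(st$results)) {
      r <- st$results[[ct]]
      rows[[length(rows) + 1L]] <- data.frame(
        stratification = x$stratification, stratum = st$label,
        n_studies = st$n_studies, n_cases = st$n_cases,
        n_controls = st$n_controls, contrast = ct,
        k = r$k, df = r$df, or = r$or, ci_low = r$ci_low,
        ci_high = r$ci_high, z = abs(r$z), p_z = r$p_z, q = r$q,
        p_q = r$p_q, i2 = r$i2, tau2 = r$tau2,
        model = if (r$model == "random_DL") "Random" else "Fixed",
        estimator = r$model)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.stratified_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("stratified_report (%s): %d strata x %d contrasts\n",
              x$stratification, length(x$strata),
              length(x$strata[[1L]]$results)))
  fmt <- data.frame(stratum = df$stratum, contrast = df$contrast,
                    `OR [95% CI]` = sprintf("%.2f [%.2f, %.2f]", df$or,
                                            df$ci_low, df$ci_high),
                    `Z (P)` = sprintf("%.2f (%.3g)", df$z, df$p_z),
                    Q = sprintf("%.2f", df$q),
                    `df (P)` = sprintf("%d (%.3g)", df$df, df$p_q),
                    I2 = sprintf("%.0f%%", df$i2), model = df$model,
                    check.names = FALSE)
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the full meta-analysis of one contrast with each study omitted
#' in turn. The fixed/random selection rule is re-applied in every
#' iteration. Only studies included in the full analysis of the contrast
#' are omitted (one row each); each re-pooled analysis therefore has
#' `k - 1` of the originally included studies.
#'
#' @inheritParams meta_analyse
#' @return data.frame with one row per omitted study: `omitted`, `k`,
#'   `or`, `ci_low`, `ci_high`, `z`, `p_z`, `q`, `p_q`, `i2`, `tau2`,
#'   `model`.
#' @export
leave_one_out <- function(corpus, contrast, fixed_method = c("MH", "IV"),
                          model_rule_threshold = 0.10) {
  fixed_method <- match.arg(fixed_method)
  contrast <- match_contrast(contrast)
  effects <- contrast_effects(corpus, contrast)
  ids <- effects$study_id[!effects$excluded]
  if (length(ids) < 2L)
    stop("leave-one-out needs at least 2 included studies", call. = FALSE)
  rows <- lapply(ids, function(id) {
    sub <- corpus[corpus$study_id != id, ]
    r <- meta_analyse(sub, contrast, fixed_method = fixed_method,
                      model_rule_threshold = model_rule_threshold)
    data.frame(omitted = id, k = r$k, or = r$or, ci_low = r$ci_low,
               ci_high = r$ci_high, z = abs(r$z), p_z = r$p_z, q = r$q,
               p_q = r$p_q, i2 = r$i2, tau2 = r$tau2,
               model = if (r$model == "random_DL") "Random" else "Fixed")
  })
  out <- do.call(rbind, rows)
  attr(out, "contrast") <- contrast
  out
}
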