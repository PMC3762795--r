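#' The four genetic contrasts
#'
#' A biallelic SNP with genotypes CC/CT/TT supports four standard 2x2
#' codings of the case-control comparison. Throughout the package the
#' first-named group of a contrast is the exposure (the numerator odds):
#'
#' * `allele`: C alleles vs T alleles (each subject contributes 2 alleles);
#' * `dominant`: CC carriers vs CT+TT carriers;
#' * `homozygote`: CC vs TT (heterozygotes are dropped entirely);
#' * `recessive`: TT vs CC+CT.
#'
#' @return Character vector of the four contrast names.
#' @export
contrast_names <- function() c("allele", "dominant", "homozygote", "recessive")

match_contrast <- function(contrast) {
  match.arg(contrast, contrast_names())
}

#' Build the 2x2 table for one study under a genetic contrast
#'
#' Maps a study's six genotype counts to the 2x2 table
#' (`a` = exposed cases, `b` = unexposed cases, `c` = exposed controls,
#' `d` = unexposed controls) of the requested contrast. Zero cells are
#' handled with the usual continuity rule: if any single cell is zero,
#' 0.5 is added to all four cells and the table is flagged `corrected`;
#' if an entire exposure column is empty in both arms (`a + c = 0` or
#' `b + d = 0`), the study carries no information about that contrast and
#' the table is flagged `excluded` instead.
#'
#' @param record one-row [study_corpus] (or list with the count fields).
#' @param contrast one of [contrast_names()].
#' @return An object of class `contrast_table`: list with `study_id`,
#'   `contrast`, cells `a`, `b`, `c`, `d`, and flags `corrected`,
#'   `excluded`, `reason`.
#' @examples
#' corp <- mthfr_corpus()
#' build_contrast(corp[corp$study_id == "Mackawy 2011", ], "allele")
#' @export
build_contrast <- function(record, contrast) {
  contrast <- match_contrast(contrast)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  cells <- with(record, switch(contrast,
    allele = c(2 * case_cc + case_ct, 2 * case_tt + case_ct,
               2 * ctrl_cc + ctrl_ct, 2 * ctrl_tt + ctrl_ct),
    dominant = c(case_cc, case_ct + case_tt, ctrl_cc, ctrl_ct + ctrl_tt),
    homozygote = c(case_cc, case_tt, ctrl_cc, ctrl_tt),
    recessive = c(case_tt, case_cc + case_ct, ctrl_tt, ctrl_cc + ctrl_ct)))
  cells <- as.numeric(cells)
  excluded <- (cells[1] + cells[3] == 0) || (cells[2] + cells[4] == 0)
  reason <- if (excluded) "no variation in exposure in either arm" else ""
  corrected <- !excluded && any(cells == 0)
  if (corrected) cells <- cells + 0.5
  structure(list(study_id = as.character(record$study_id),
                 contrast = contrast,
                 a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 corrected = corrected, excluded = excluded, reason = reason),
            class = "contrast_table")
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("contrast_table [%s, %s]%s%s\n", x$study_id, x$contrast,
              if (x$corrected) " (0.5-corrected)" else "",
              if (x$excluded) paste0(" EXCLUDED: ", x$reason) else ""))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2L, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Contrast tables for every study in a corpus
#'
#' @param corpus a [study_corpus].
#' @param contrast one of [contrast_names()].
#' @return List of [build_contrast()] results, in corpus order.
#' @export
contrast_tables <- function(corpus, contrast) {
  stopifnot(inherits(corpus, "study_corpus"))
  contrast <- match_contrast(contrast)
  lapply(seq_len(nrow(corpus)),
         function(i) build_contrast(corpus[i, ], contrast))
}

#' Per-study odds ratio from a 2x2 contrast table
#'
#' Woolf log odds ratio and its standard error on the (possibly
#' continuity-corrected) table: `log_or = log(ad/(bc))`,
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param table a `contrast_table` from [build_contrast()].
#' @return An object of class `effect_estimate`: list with `study_id`,
#'   `log_or`, `se` and `or`.
#' @export
study_effect <- function(table) {
  stopifnot(inherits(table, "contrast_table"))
  if (table$excluded)
    stop("study ", table$study_id, " is excluded from the ", table$contrast,
         " contrast (", table$reason, ")", call. = FALSE)
  log_or <- log(table$a * table$d / (table$b * table$c))
  se <- sqrt(1 / table$a + 1 / table$b + 1 / table$c + 1 / table$d)
  structure(list(study_id = table$study_id, log_or = log_or, se = se,
                 or = exp(log_or)),
            class = "effect_estimate")
}

#' Per-study effect estimates for a whole corpus
#'
#' Builds the contrast tables for every study and computes the per-study
#' log odds ratios. Excluded studies are kept as rows (with `NA`
#' estimates) so bookkeeping against the corpus stays transparent.
#'
#' @param corpus a [study_corpus].
#' @param contrast one of [contrast_names()].
#' @return data.frame in corpus order with columns `study_id`, `a`, `b`,
#'   `c`, `d`, `corrected`, `excluded`, `log_or`, `se`, `or`, `ci_low`,
#'   `ci_high` (95% per-study Wald limits).
#' @export
contrast_effects <- function(corpus, contrast) {
  tabs <- contrast_tables(corpus, contrast)
  rows <- lapply(tabs, function(tb) {
    if (tb$excluded) {
      data.frame(study_id = tb$study_id, a = tb$a, b = tb$b, c = tb$c,
                 d = tb$d, corrected = tb$corrected, excluded = TRUE,
                 log_or = NA_real_, se = NA_real_, or = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_)
    } else {
      ef <- study_effect(tb)
      data.frame(study_id = tb$study_id, a = tb$a, b = tb$b, c = tb$c,
                 d = tb$d, corrected = tb$corrected, excluded = FALSE,
                 log_or = ef$log_or, se = ef$se, or = ef$or,
                 ci_low = exp(ef$log_or - 1.96 * ef$se),
                 ci_high = exp(ef$log_or + 1.96 * ef$se))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "contrast") <- match_contrast(contrast)
  out
}
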