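#' Run the complete meta-analytic report
#'
#' Orchestrates the whole pipeline on one corpus: the stratified pooled-
#' results grid (overall, ethnicity, complications, Hardy-Weinberg
#' status, by default), per-study effect/forest data for every contrast,
#' the per-study HWE report, leave-one-out sensitivity tables, funnel
#' coordinates and Harbord's small-study bias test. When `out_dir` is
#' given, every piece is also written to disk (TSV/JSON, fixed column
#' order, no timestamps in the data files, so identical inputs and
#' configuration give byte-identical outputs) together with a run log
#' echoing the configuration, package version and input checksum.
#'
#' @param corpus a [study_corpus], or a file path readable by
#'   [read_corpus()].
#' @param out_dir optional output directory (created if needed).
#' @param contrasts contrasts to run, default all four.
#' @param stratifications stratifications for the results grid.
#' @param hwe_classifier,hwe_threshold see [partition_by_hwe()].
#' @param fixed_method,model_rule_threshold see [meta_analyse()].
#' @param verbose emit progress messages.
#' @return Invisibly, a list with `grid` (data.frame of all pooled
#'   results), `forest` (named list of per-contrast forest data), `hwe`
#'   (the [hwe_report()]), `leave_one_out` (named list of per-contrast
#'   tables), `funnel` (named list), `harbord` (named list of
#'   `harbord_result`), and `config`.
#' @examples
#' bundle <- run_full_analysis(mthfr_corpus())
#' subset(bundle$grid, stratum == "all", c(contrast, or, model))
#' @export
run_full_analysis <- function(corpus, out_dir = NULL,
                              contrasts = contrast_names(),
                              stratifications = c("overall", "ethnicity",
                                                  "complications", "hwe"),
                              hwe_classifier = "exact",
                              hwe_threshold = 0.05,
                              fixed_method = "MH",
                              model_rule_threshold = 0.10,
                              verbose = FALSE) {
  input_path <- NULL
  if (is.character(corpus)) {
    input_path <- corpus
    corpus <- read_corpus(corpus)
  }
  stopifnot(inherits(corpus, "study_corpus"))
  contrasts <- vapply(contrasts, match_contrast, character(1L),
                      USE.NAMES = FALSE)
  stratifications <- match.arg(stratifications,
                               c("overall", "ethnicity", "complications",
                                 "hwe"), several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("pooled-results grid over %d stratifications", length(stratifications))
  grid <- do.call(rbind, lapply(stratifications, function(s)
    as.data.frame(stratified_meta(
      corpus, s, contrasts = contrasts, fixed_method = fixed_method,
      model_rule_threshold = model_rule_threshold,
      hwe_classifier = hwe_classifier, hwe_threshold = hwe_threshold))))
  rownames(grid) <- NULL

  say("per-study forest data")
  forest <- stats::setNames(lapply(contrasts, function(ct)
    forest_data(corpus, ct, fixed_method = fixed_method,
                model_rule_threshold = model_rule_threshold)), contrasts)

  say("Hardy-Weinberg report")
  hwe <- hwe_report(corpus, classifier = hwe_classifier,
                    threshold = hwe_threshold)

  say("leave-one-out sensitivity")
  loo <- stats::setNames(lapply(contrasts, function(ct)
    leave_one_out(corpus, ct, fixed_method = fixed_method,
                  model_rule_threshold = model_rule_threshold)), contrasts)

  say("funnel data and Harbord test")
  funnel <- stats::setNames(lapply(contrasts, function(ct)
    funnel_data(corpus, ct)), contrasts)
  harbord <- stats::setNames(lapply(contrasts, function(ct)
    harbord_test(corpus, ct)), contrasts)

  config <- list(contrasts = contrasts, stratifications = stratifications,
                 hwe_classifier = hwe_classifier,
                 hwe_threshold = hwe_threshold, fixed_method = fixed_method,
                 model_rule_threshold = model_rule_threshold,
                 ci_level = 0.95)
  bundle <- list(grid = grid, forest = forest, hwe = hwe,
                 leave_one_out = loo, funnel = funnel, harbord = harbord,
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wtsv(format_grid(grid), "pooled_results.tsv")
    jsonlite::write_json(grid, file.path(out_dir, "pooled_results.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    for (ct in contrasts) {
      wtsv(forest[[ct]], sprintf("forest_%s.tsv", ct))
      wtsv(loo[[ct]], sprintf("leave_one_out_%s.tsv", ct))
      wtsv(funnel[[ct]], sprintf("funnel_%s.tsv", ct))
    }
    wtsv(hwe, "hwe_report.tsv")
    jsonlite::write_json(lapply(harbord, unclass),
                         file.path(out_dir, "harbord.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tot <- corpus_totals(corpus)
    log_lines <- c(
      sprintf("snpmeta %s", as.character(utils::packageVersion("snpmeta"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("input: %s",
              if (is.null(input_path)) attr(corpus, "provenance") else input_path),
      sprintf("input md5: %s", corpus_checksum(corpus)),
      sprintf("studies: %d (%d cases, %d controls)", tot$n_studies,
              tot$total_cases, tot$total_controls),
      sprintf("config: %s",
              jsonlite::toJSON(config, auto_unbox = TRUE)))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(bundle)
}

# Table-2-like fixed-precision rendering: OR/CI and Q to 2 decimals,
# I2 to whole percent.
format_grid <- function(grid) {
  data.frame(stratification = grid$stratification, stratum = grid$stratum,
             n_cases = grid$n_cases, n_controls = grid$n_controls,
             contrast = grid$contrast, k = grid$k,
             or_ci = sprintf("%.2f [%.2f, %.2f]", grid$or, grid$ci_low,
                             grid$ci_high),
             z = sprintf("%.2f", grid$z), p_z = signif(grid$p_z, 2L),
             q = sprintf("%.2f", grid$q), df = grid$df,
             p_q = signif(grid$p_q, 2L),
             i2 = sprintf("%.0f%%", grid$i2),
             tau2 = sprintf("%.4f", grid$tau2), model = grid$model)
}

corpus_checksum <- function(corpus) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_corpus(corpus, tmp)
  unname(tools::md5sum(tmp))
}
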