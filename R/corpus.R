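#' Study corpora for case-control SNP meta-analysis
#'
#' A study corpus holds one row per case-control study of a biallelic SNP:
#' a study label, an ethnicity stratum, a complications stratum, and the six
#' genotype counts (CC/CT/TT among cases and among controls). The optional
#' `reported_hwe_p` column carries the Hardy-Weinberg p-value as printed in
#' the source publication, which may be a bound such as `"<0.001"`; it is
#' stored as text and parsed on demand (see [hwe_report()]).
#'
#' @param records data.frame with columns `study_id`, `ethnicity`,
#'   `complications`, `case_cc`, `case_ct`, `case_tt`, `ctrl_cc`, `ctrl_ct`,
#'   `ctrl_tt` and optionally `reported_hwe_p`.
#' @param provenance free-text tag recording where the records came from.
#' @return An object of class `study_corpus`: the validated data.frame with
#'   a `provenance` attribute. Row order is preserved throughout the
#'   package (forest-plot and report order follow corpus order).
#' @seealso [read_corpus()], [corpus_totals()], [mthfr_corpus()]
#' @export
study_corpus <- function(records, provenance = "unspecified") {
  if (!is.data.frame(records))
    stop("`records` must be a data.frame", call. = FALSE)
  required <- c("study_id", "ethnicity", "complications",
                "case_cc", "case_ct", "case_tt",
                "ctrl_cc", "ctrl_ct", "ctrl_tt")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L)
    stop("corpus contains no study records", call. = FALSE)

  records$study_id <- as.character(records$study_id)
  if (anyDuplicated(records$study_id))
    stop("duplicate study_id: ",
         paste(unique(records$study_id[duplicated(records$study_id)]),
               collapse = ", "), call. = FALSE)

  eth_levels <- c("Asian", "Caucasian", "African")
  bad <- !records$ethnicity %in% eth_levels
  if (any(bad))
    stop("invalid ethnicity for ", records$study_id[bad][1L],
         ": '", records$ethnicity[bad][1L], "' (expected one of ",
         paste(eth_levels, collapse = ", "), ")", call. = FALSE)
  comp_levels <- c("explicitly_absent", "present_or_unreported")
  bad <- !records$complications %in% comp_levels
  if (any(bad))
    stop("invalid complications label for ", records$study_id[bad][1L],
         ": '", records$complications[bad][1L], "'", call. = FALSE)

  count_cols <- required[4:9]
  for (cl in count_cols) {
    x <- records[[cl]]
    if (!is.numeric(x) || any(is.na(x)) || any(x != trunc(x)))
      stop("non-integer count in field ", cl, " for study ",
           records$study_id[which(!is.finite(x) | x != trunc(x))[1L]],
           call. = FALSE)
    if (any(x < 0))
      stop("negative count in field ", cl, " for study ",
           records$study_id[which(x < 0)[1L]], call. = FALSE)
    records[[cl]] <- as.integer(x)
  }
  n_case <- records$case_cc + records$case_ct + records$case_tt
  n_ctrl <- records$ctrl_cc + records$ctrl_ct + records$ctrl_tt
  if (any(n_case < 1L))
    stop("study ", records$study_id[which(n_case < 1L)[1L]],
         " has an empty case arm", call. = FALSE)
  if (any(n_ctrl < 1L))
    stop("study ", records$study_id[which(n_ctrl < 1L)[1L]],
         " has an empty control arm", call. = FALSE)

  if (!"reported_hwe_p" %in% names(records))
    records$reported_hwe_p <- NA_character_
  records$reported_hwe_p <- as.character(records$reported_hwe_p)

  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("study_corpus", "data.frame"))
}

#' Read a study corpus from a delimited file
#'
#' Reads a UTF-8 CSV or TSV file with a header row and one study per data
#' row, and validates it into a [study_corpus].
#'
#' @param path path to the file.
#' @param dialect `"auto"` (by file extension, default), `"csv"` or `"tsv"`.
#' @return A [study_corpus] with `provenance` set to the file path.
#' @examples
#' corp <- read_corpus(system.file("extdata", "mthfr_t2dm_studies.csv",
#'                                 package = "snpmeta"))
#' corpus_totals(corp)
#' @export
read_corpus <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  count_cols <- c("case_cc", "case_ct", "case_tt",
                  "ctrl_cc", "ctrl_ct", "ctrl_tt")
  for (cl in intersect(count_cols, names(raw))) {
    x <- suppressWarnings(as.numeric(raw[[cl]]))
    if (any(is.na(x)))
      stop("non-integer count in field ", cl, " for study ",
           raw$study_id[which(is.na(x))[1L]], call. = FALSE)
    raw[[cl]] <- x
  }
  study_corpus(raw, provenance = path)
}

#' Write a study corpus to a delimited file
#'
#' Inverse of [read_corpus()]: round-tripping a corpus through
#' `write_corpus()`/`read_corpus()` reproduces every count and label.
#'
#' @param corpus a [study_corpus].
#' @param path output file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(corpus, "study_corpus"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- as.data.frame(corpus)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Corpus bookkeeping totals
#'
#' @param corpus a [study_corpus].
#' @return A list with `n_studies`, `total_cases` and `total_controls`.
#'   Totals are additive over any partition of the corpus.
#' @export
corpus_totals <- function(corpus) {
  stopifnot(inherits(corpus, "study_corpus"))
  list(n_studies = nrow(corpus),
       total_cases = sum(corpus$case_cc + corpus$case_ct + corpus$case_tt),
       total_controls = sum(corpus$ctrl_cc + corpus$ctrl_ct + corpus$ctrl_tt))
}

#' The bundled MTHFR 677C>T / type 2 diabetes corpus
#'
#' Loads the packaged corpus of 39 case-control studies of the MTHFR
#' rs1801133 (677C>T) polymorphism and type 2 diabetes mellitus
#' (4855 cases, 5242 controls; 26 Asian, 9 Caucasian and 4 African study
#' populations), the worked example used throughout the documentation.
#' The `complications` column partitions the studies into 25 whose authors
#' explicitly reported the absence of serious diabetes-related
#' complications among cases and 14 that reported their presence or did
#' not report on them; `reported_hwe_p` carries the control-arm
#' Hardy-Weinberg p-values as printed in the source table.
#'
#' @return A [study_corpus] of 39 records.
#' @export
mthfr_corpus <- function() {
  read_corpus(system.file("extdata", "mthfr_t2dm_studies.csv",
                          package = "snpmeta", mustWork = TRUE))
}

#' Subset a study corpus
#'
#' `[` keeps the `study_corpus` class and provenance when whole rows are
#' selected, so stratified analyses can index corpora directly.
#'
#' @param x a [study_corpus].
#' @param i,j,... passed to the data.frame method.
#' @param drop passed to the data.frame method.
#' @return A [study_corpus] when the result still has all corpus columns,
#'   otherwise a plain data.frame.
#' @export
`[.study_corpus` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("study_id", "case_cc", "ctrl_tt") %in% names(out)) &&
      nrow(out) > 0L) {
    return(study_corpus(out, provenance = attr(x, "provenance")))
  }
  out
}

#' @export
as.data.frame.study_corpus <- function(x, ...) {
  out <- x
  attr(out, "provenance") <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.study_corpus <- function(x, ...) {
  tot <- corpus_totals(x)
  cat(sprintf("study_corpus: %d studies, %d cases, %d controls\n",
              tot$n_studies, tot$total_cases, tot$total_controls))
  cat(sprintf("provenance: %s\n", attr(x, "provenance")))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... and %d more studies\n", nrow(x) - 5L))
  invisible(x)
}

# Parse a printed HWE p-value ("0.439", "1.000", "<0.001") into numeric
# lower/upper bounds; NA text parses to c(NA, NA).
parse_printed_p <- function(txt) {
  t(vapply(txt, function(s) {
    if (is.na(s) || !nzchar(s)) return(c(NA_real_, NA_real_))
    s <- trimws(s)
    if (startsWith(s, "<")) {
      u <- as.numeric(substring(s, 2L))
      c(0, u)
    } else {
      v <- as.numeric(s)
      c(v, v)
    }
  }, numeric(2L), USE.NAMES = FALSE))
}
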