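#' Asymptotic (chi-squared) test of Hardy-Weinberg equilibrium
#'
#' Pearson goodness-of-fit test of observed genotype counts against the
#' Hardy-Weinberg proportions at the estimated allele frequency: with
#' `n = cc + ct + tt` subjects and major-allele frequency
#' `p = (2 cc + ct) / 2n`, the expected counts are `n p^2`, `2 n p (1-p)`
#' and `n (1-p)^2`, and the statistic is chi-squared with 1 df. A
#' monomorphic sample (one allele absent) carries no information and
#' returns `chi2 = 0`, `p = 1` with `monomorphic = TRUE`.
#'
#' @param cc,ct,tt genotype counts (one arm of one study).
#' @return List with `chi2`, `p` and `monomorphic`.
#' @export
hwe_asymptotic <- function(cc, ct, tt) {
  stopifnot(cc >= 0, ct >= 0, tt >= 0)
  n <- cc + ct + tt
  if (n < 1L) stop("empty genotype sample", call. = FALSE)
  p <- (2 * cc + ct) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0)
    return(list(chi2 = 0, p = 1, monomorphic = TRUE))
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(cc, ct, tt) - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, every
#' heterozygote count of the same parity is an attainable genotype
#' configuration, with null probability proportional to
#' `2^ct * n! / (cc! ct! tt!)` (a hypergeometric-type law). The p-value
#' sums the probabilities of all configurations no more probable than the
#' observed one (the standard convention; not mid-p). Computations are in
#' log space, so large arms are handled exactly.
#'
#' The test is symmetric in the two alleles (`cc` and `tt` can be
#' swapped) and returns 1 for monomorphic samples.
#'
#' @param cc,ct,tt genotype counts (one arm of one study).
#' @return The exact p-value, in (0, 1].
#' @examples
#' hwe_exact(14, 73, 37)  # 0.025
#' @export
hwe_exact <- function(cc, ct, tt) {
  stopifnot(cc >= 0, ct >= 0, tt >= 0)
  n <- cc + ct + tt
  if (n < 1L) stop("empty genotype sample", call. = FALSE)
  n_minor <- min(2 * cc + ct, 2 * tt + ct)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  log_prob <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    h * log(2) + lfactorial(n) -
      lfactorial(hom_minor) - lfactorial(h) - lfactorial(hom_major)
  }, numeric(1L))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  p_obs <- prob[hets == ct]
  sum(prob[prob <= p_obs * (1 + 1e-10)])
}

#' Per-study Hardy-Weinberg report for a corpus
#'
#' Runs both HWE tests on every control arm and classifies each study at
#' the given threshold. The `printed_p` column echoes the source
#' publication's value (text, possibly a bound) when the corpus carries
#' one, so discrepancies between test variants and the published column
#' are visible side by side.
#'
#' @param corpus a [study_corpus].
#' @param classifier which p-value drives the `in_hwe` flag: `"exact"`
#'   (default), `"asymptotic"`, or `"printed"` (the upper bound of the
#'   parsed `reported_hwe_p`).
#' @param threshold significance threshold, default 0.05; `p >= threshold`
#'   counts as in equilibrium (strict inequality for violation).
#' @return data.frame with columns `study_id`, `chi2`, `p_asymptotic`,
#'   `p_exact`, `printed_p`, `monomorphic`, `in_hwe`.
#' @export
hwe_report <- function(corpus, classifier = c("exact", "asymptotic", "printed"),
                       threshold = 0.05) {
  stopifnot(inherits(corpus, "study_corpus"))
  classifier <- match.arg(classifier)
  asym <- lapply(seq_len(nrow(corpus)), function(i)
    hwe_asymptotic(corpus$ctrl_cc[i], corpus$ctrl_ct[i], corpus$ctrl_tt[i]))
  p_exact <- vapply(seq_len(nrow(corpus)), function(i)
    hwe_exact(corpus$ctrl_cc[i], corpus$ctrl_ct[i], corpus$ctrl_tt[i]),
    numeric(1L))
  out <- data.frame(study_id = corpus$study_id,
                    chi2 = vapply(asym, `[[`, numeric(1L), "chi2"),
                    p_asymptotic = vapply(asym, `[[`, numeric(1L), "p"),
                    p_exact = p_exact,
                    printed_p = corpus$reported_hwe_p,
                    monomorphic = vapply(asym, `[[`, logical(1L), "monomorphic"))
  p_class <- switch(classifier,
    exact = out$p_exact,
    asymptotic = out$p_asymptotic,
    printed = {
      bounds <- parse_printed_p(out$printed_p)
      if (anyNA(bounds[, 2L]))
        stop("classifier 'printed' needs a reported_hwe_p for every study",
             call. = FALSE)
      bounds[, 2L]
    })
  out$in_hwe <- p_class >= threshold
  out
}

#' Split a corpus by Hardy-Weinberg status of the control arms
#'
#' @inheritParams hwe_report
#' @return List of two [study_corpus] objects, `in_hwe` and `out_of_hwe`
#'   (either may be NULL when empty), both preserving corpus order.
#' @examples
#' parts <- partition_by_hwe(mthfr_corpus())
#' parts$out_of_hwe$study_id
#' @export
partition_by_hwe <- function(corpus, classifier = c("exact", "asymptotic", "printed"),
                             threshold = 0.05) {
  rep_ <- hwe_report(corpus, classifier = classifier, threshold = threshold)
  list(in_hwe = if (any(rep_$in_hwe)) corpus[rep_$in_hwe, ] else NULL,
       out_of_hwe = if (any(!rep_$in_hwe)) corpus[!rep_$in_hwe, ] else NULL)
}
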