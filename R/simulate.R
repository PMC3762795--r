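#' Configuration for synthetic study corpora
#'
#' Bundles the generative parameters of [simulate_corpus()]. The defaults
#' emulate a corpus like the bundled MTHFR/T2DM one: 39 studies, arm
#' sizes between 40 and 300 subjects, control minor (T) allele
#' frequencies drawn uniformly on [0.10, 0.55] (the span seen across
#' ethnic groups for this locus), no true allele effect, no between-study
#' heterogeneity and Hardy-Weinberg-conformant controls.
#'
#' @param k number of studies.
#' @param n_case_range,n_ctrl_range integer ranges (length-2) for
#'   per-study arm sizes, drawn uniformly.
#' @param maf_range range of the control T-allele frequency, drawn
#'   uniformly per study (use equal endpoints for a fixed frequency).
#' @param true_log_or mean allele-level log odds ratio (cases vs
#'   controls, C as exposure).
#' @param tau between-study standard deviation of the study-level log
#'   odds ratio (0 for a common effect).
#' @param inbreeding_f inbreeding coefficient in [0, 1) distorting the
#'   *control* genotype law away from Hardy-Weinberg proportions:
#'   P(TT) = q^2 + f q(1-q), P(CT) = 2 q (1-q)(1-f),
#'   P(CC) = (1-q)^2 + f q(1-q).
#' @param seed master seed; per-study substreams are derived from it so
#'   corpora are reproducible.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(k = 39L,
                              n_case_range = c(40L, 300L),
                              n_ctrl_range = c(40L, 300L),
                              maf_range = c(0.10, 0.55),
                              true_log_or = 0,
                              tau = 0,
                              inbreeding_f = 0,
                              seed = 1L) {
  stopifnot(k >= 1L,
            length(n_case_range) == 2L, n_case_range[1] >= 1L,
            n_case_range[2] >= n_case_range[1],
            length(n_ctrl_range) == 2L, n_ctrl_range[1] >= 1L,
            n_ctrl_range[2] >= n_ctrl_range[1],
            length(maf_range) == 2L, maf_range[2] >= maf_range[1],
            is.finite(true_log_or), tau >= 0,
            inbreeding_f >= 0, inbreeding_f < 1,
            is.finite(seed))
  if (maf_range[1] <= 0 || maf_range[2] >= 1)
    stop("maf_range must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(k = as.integer(k),
                 n_case_range = as.integer(n_case_range),
                 n_ctrl_range = as.integer(n_ctrl_range),
                 maf_range = as.numeric(maf_range),
                 true_log_or = true_log_or, tau = tau,
                 inbreeding_f = inbreeding_f, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a case-control SNP study corpus
#'
#' Generates `k` studies under a controlled truth. Per study: a control
#' T-allele frequency `q` is drawn from `maf_range`; control genotype
#' probabilities follow the inbreeding-distorted Hardy-Weinberg law of
#' [simulation_config()]; a study-level allele log odds ratio
#' `theta ~ Normal(true_log_or, tau^2)` multiplies the control *C-allele*
#' odds to give the case allele frequency, and case genotypes are
#' composed under Hardy-Weinberg proportions at that induced frequency.
#' Genotype counts are multinomial draws. Genotype-level effects for the
#' dominant/recessive/homozygote contrasts are therefore emergent from
#' the allele-level truth rather than separately controlled.
#'
#' The generator is deterministic for a given config: per-study random
#' substreams are derived from the master seed, so the i-th study is
#' reproducible even in isolation.
#'
#' @param config a [simulation_config()].
#' @return A [study_corpus] of `k` simulated records (ethnicity and
#'   complications labels are assigned round-robin so stratified code
#'   paths are exercisable; they carry no effect).
#' @examples
#' simulate_corpus(simulation_config(k = 5, seed = 42))
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, config$k)
  eth <- rep_len(c("Asian", "Caucasian", "African"), config$k)
  comp <- rep_len(c("explicitly_absent", "present_or_unreported"), config$k)
  rows <- lapply(seq_len(config$k), function(i) {
    set.seed(study_seeds[i])
    n_case <- sample_range(config$n_case_range)
    n_ctrl <- sample_range(config$n_ctrl_range)
    q <- stats::runif(1L, config$maf_range[1], config$maf_range[2])
    f <- config$inbreeding_f
    p_ctrl <- c(cc = (1 - q)^2 + f * q * (1 - q),
                ct = 2 * q * (1 - q) * (1 - f),
                tt = q^2 + f * q * (1 - q))
    theta <- stats::rnorm(1L, config$true_log_or, config$tau)
    # theta is the log OR of the C allele; case C odds = control C odds * e^theta
    odds_c_case <- (1 - q) / q * exp(theta)
    q_case <- 1 / (1 + odds_c_case)        # case T-allele frequency
    p_case <- c(cc = (1 - q_case)^2, ct = 2 * q_case * (1 - q_case),
                tt = q_case^2)
    if (any(!is.finite(p_case)) || any(p_case < 0) || any(p_ctrl < 0))
      stop("config produces degenerate genotype probabilities", call. = FALSE)
    gc_case <- stats::rmultinom(1L, n_case, p_case)[, 1L]
    gc_ctrl <- stats::rmultinom(1L, n_ctrl, p_ctrl)[, 1L]
    data.frame(study_id = sprintf("sim%03d", i), ethnicity = eth[i],
               complications = comp[i],
               case_cc = gc_case[1L], case_ct = gc_case[2L],
               case_tt = gc_case[3L],
               ctrl_cc = gc_ctrl[1L], ctrl_ct = gc_ctrl[2L],
               ctrl_tt = gc_ctrl[3L],
               reported_hwe_p = NA_character_)
  })
  study_corpus(do.call(rbind, rows),
               provenance = sprintf("simulated (seed %d)", config$seed))
}

#' Operating characteristics of the pooling pipeline
#'
#' Repeatedly simulates corpora from `config` and meta-analyses the
#' allele contrast (with the usual model-selection rule), summarising how
#' the pipeline behaves under the known truth: 95% CI coverage of the
#' true allele odds ratio, the Z-test rejection rate at 0.05 (the type-I
#' error rate when `true_log_or = 0`), and the mean estimated
#' `tau2` and pooled OR.
#'
#' @param config a [simulation_config()]; its own `seed` is ignored here.
#' @param reps number of replicate corpora.
#' @param seed master seed for the experiment.
#' @return List with `coverage`, `type1_rate`, `mean_tau2`, `mean_or`,
#'   `reps`.
#' @export
operating_characteristics <- function(config, reps = 1000L, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"), reps >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  true_or <- exp(config$true_log_or)
  cover <- reject <- logical(reps)
  tau2 <- or <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    corp <- simulate_corpus(cfg)
    res <- meta_analyse(corp, "allele")
    cover[r] <- res$ci_low <= true_or && true_or <= res$ci_high
    reject[r] <- res$p_z < 0.05
    tau2[r] <- res$tau2
    or[r] <- res$or
  }
  list(coverage = mean(cover), type1_rate = mean(reject),
       mean_tau2 = mean(tau2), mean_or = mean(or), reps = reps)
}

# Uniform integer draw from a closed range; safe for degenerate ranges
# (sample(10:10, 1) would draw from 1:10).
sample_range <- function(range) {
  range[1L] + sample.int(range[2L] - range[1L] + 1L, 1L) - 1L
}

# Save/restore .Random.seed so simulation helpers do not clobber the
# caller's RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
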