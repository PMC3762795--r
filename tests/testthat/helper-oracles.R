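# Independent oracles, deliberately written as direct transcriptions of the
# closed-form definitions with no code shared with the package internals.

# DerSimonian-Laird pooling from scratch for a handful of (log OR, SE) pairs.
oracle_dl <- function(theta, se) {
  w <- se^-2
  mu_fe <- sum(theta * w) / sum(w)
  Q <- sum(w * (theta - mu_fe)^2)
  df <- length(theta) - 1
  tau2 <- (Q - df) / (sum(w) - sum(w^2) / sum(w))
  if (tau2 < 0) tau2 <- 0
  wstar <- 1 / (se^2 + tau2)
  mu <- sum(theta * wstar) / sum(wstar)
  list(q = Q, tau2 = tau2, mu = mu, se = sqrt(1 / sum(wstar)),
       i2 = if (Q > 0) max(0, 100 * (Q - df) / Q) else 0)
}

# Exact HWE p-value by brute-force enumeration of every genotype triple
# (not just heterozygote counts) compatible with the allele margins, with
# probabilities from first-principles factorials. Feasible for tiny n.
oracle_hwe_exact <- function(cc, ct, tt) {
  n <- cc + ct + tt
  na <- 2 * cc + ct       # count of one allele
  configs <- list()
  for (x_cc in 0:n) for (x_ct in 0:(n - x_cc)) {
    x_tt <- n - x_cc - x_ct
    if (2 * x_cc + x_ct == na)
      configs[[length(configs) + 1L]] <- c(x_cc, x_ct, x_tt)
  }
  prob <- vapply(configs, function(g) {
    factorial(n) / (factorial(g[1]) * factorial(g[2]) * factorial(g[3])) *
      2^g[2] * factorial(na) * factorial(2 * n - na) / factorial(2 * n)
  }, numeric(1L))
  obs <- which(vapply(configs, function(g)
    all(g == c(cc, ct, tt)), logical(1L)))
  sum(prob[prob <= prob[obs] * (1 + 1e-10)])
}

# A tiny three-study corpus with hand-checkable counts, used across files.
toy_corpus <- function() {
  study_corpus(data.frame(
    study_id = c("alpha", "beta", "gamma"),
    ethnicity = c("Asian", "Caucasian", "African"),
    complications = c("explicitly_absent", "present_or_unreported",
                      "explicitly_absent"),
    case_cc = c(30L, 12L, 25L), case_ct = c(40L, 30L, 20L),
    case_tt = c(10L, 18L, 5L),
    ctrl_cc = c(35L, 20L, 20L), ctrl_ct = c(35L, 28L, 25L),
    ctrl_tt = c(10L, 12L, 5L),
    reported_hwe_p = c("0.5", "0.5", "0.5")), provenance = "toy")
}
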