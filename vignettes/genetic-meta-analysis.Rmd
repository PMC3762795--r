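---
title: "Pooling case-control SNP association studies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling case-control SNP association studies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem

A case-control genetic association study of a biallelic SNP reports six
numbers: the CC/CT/TT genotype counts among cases and among controls. A
single such study is rarely decisive — arm sizes are modest, allele
frequencies differ strongly between populations, and genotyping or
sampling artefacts are common. Meta-analysis pools many such studies into
one odds ratio (OR) per *genetic contrast*, with the between-study
heterogeneity quantified rather than ignored.

snpmeta implements that pipeline end to end for the four standard
contrasts of a C/T polymorphism, taking the **first-named group as the
exposure** (the numerator odds) in every case:

| contrast     | exposed        | unexposed      |
|--------------|----------------|----------------|
| `allele`     | C alleles      | T alleles      |
| `dominant`   | CC carriers    | CT + TT        |
| `homozygote` | CC             | TT (CT dropped)|
| `recessive`  | TT             | CC + CT        |

The allele contrast treats each subject as two independent alleles — an
approximation that is exact only under Hardy-Weinberg equilibrium (HWE)
in both arms, which is one reason control-arm HWE screening is part of
the pipeline. The homozygote contrast discards heterozygotes entirely:
"CC vs TT" is a comparison of homozygotes, and pooling CT into either
side would change the estimand.

The worked corpus shipped with the package
(`mthfr_corpus()`) contains 39 published case-control studies of the
MTHFR 677C→T polymorphism (rs1801133) and type 2 diabetes — 4855 cases
and 5242 controls across Asian, Caucasian and African populations — with
study-level genotype counts, ethnicity and complications strata, and the
control-arm HWE p-values as printed by the source publications.

## Per-study estimates

Each study × contrast gives a 2×2 table \((a, b, c, d)\) (exposed/unexposed
× case/control), the Woolf log odds ratio and its standard error:

\[
\hat\theta_i = \log\frac{a_i d_i}{b_i c_i},\qquad
\mathrm{SE}_i = \sqrt{\tfrac1{a_i}+\tfrac1{b_i}+\tfrac1{c_i}+\tfrac1{d_i}}.
\]

**Zero cells.** If any single cell is zero, 0.5 is added to *all four*
cells of that study's table (`corrected` flag) — the convention of the
RevMan software family, which keeps the estimate finite without
re-weighting the other studies. If an entire exposure column is empty in
*both* arms (\(a+c=0\) or \(b+d=0\)), the study carries no information
about the contrast and is excluded from it (`excluded` flag); no amount
of continuity correction makes such a table informative, and a corrected
all-cells table would inject a spurious null estimate with non-trivial
weight. In the bundled corpus exactly one study (no TT genotypes in
either arm) is excluded from the homozygote and recessive contrasts,
which is why those contrasts pool 38 studies (df = 37) while the allele
and dominant contrasts pool all 39.

## Pooling models

Two fixed-effect estimators are provided:

* **Mantel-Haenszel** (default):
  \(\mathrm{OR}_{MH} = \sum_i (a_i d_i/n_i) \big/ \sum_i (b_i c_i/n_i)\),
  with the Robins-Breslow-Greenland variance for \(\log \mathrm{OR}_{MH}\).
  MH is robust with sparse tables and is the field's default for
  dichotomous outcomes.
* **Inverse-variance**: \(\hat\theta = \sum w_i\hat\theta_i/\sum w_i\)
  with \(w_i = 1/\mathrm{SE}_i^2\); retained both as a user-facing option
  and because Q and \(\tau^2\) are defined through these weights.

Heterogeneity is quantified by Cochran's Q about the inverse-variance
fixed estimate,

\[
Q = \sum_i w_i (\hat\theta_i - \hat\theta_{IV})^2 \sim \chi^2_{k-1}
\text{ under homogeneity},\qquad
I^2 = \max\!\left(0, 100\,\tfrac{Q - (k-1)}{Q}\right),
\]

and the DerSimonian-Laird moment estimator
\(\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}\).
A variant centring Q on the MH estimate is available
(`heterogeneity(..., centre = "MH")`); the two differ only in the third
decimal on realistic corpora. \(\tau^2\) is estimated once by the moment
formula — no REML or Paule-Mandel iteration — matching the behaviour of
the era's standard tools and keeping every result a closed form.

**Model selection.** The pipeline applies the conventional rule: if the
Q-test p-value exceeds 0.10 the fixed-effect model is used, otherwise
DerSimonian-Laird random effects with weights \(1/(\mathrm{SE}_i^2 +
\hat\tau^2)\). The threshold is deliberately lenient (the Q-test is
underpowered at typical study counts); the boundary case \(p = 0.10\)
selects the random model, since only \(p > 0.10\) is evidence of
homogeneity. The rule is re-applied *independently* inside every
subgroup and every leave-one-out iteration — heterogeneity is a property
of the study set actually pooled, not of the full corpus.

All intervals are 95% Wald intervals on the log-OR scale
(\(\pm 1.96\,\mathrm{SE}\)); the pooled effect is tested with a two-sided
normal Z-test. No t-quantile small-sample adjustment (Hartung-Knapp or
otherwise) is applied, by design: the package reproduces the classical
pipeline, and mixing adjustments would silently change every interval.

## Hardy-Weinberg screening

Control-arm genotypes are screened two ways:

* `hwe_asymptotic()`: 1-df Pearson chi-squared against the \(p^2 : 2pq :
  q^2\) proportions at the estimated allele frequency;
* `hwe_exact()`: the conditional exact test — given the allele counts,
  the heterozygote count follows a hypergeometric-type law, and the
  p-value sums the probabilities of all configurations no more probable
  than the one observed (standard convention, not mid-p). Computation is
  in log space, so control arms of any realistic size are exact.

The **exact test is the default classifier** for the HWE subgroup split,
at threshold 0.05 with \(p \ge 0.05\) counting as "in HWE". The
asymptotic chi-squared is anticonservative for moderate arms with an
uncommon allele: in the bundled corpus two borderline control arms sit at
asymptotic \(p \approx 0.045\)–0.047 but exact \(p \approx 0.06\)–0.09,
and only the exact classification reproduces the per-study HWE column
that the source publications report (`hwe_report()` shows all three side
by side). A `printed` classifier is also available, which drives the
split from the corpus's `reported_hwe_p` column alone — useful for
separating "which studies violate HWE" from "which test was used".
Monomorphic arms are defined as in equilibrium (\(\chi^2 = 0, p = 1\),
flagged) rather than an error.

## Small-study bias

`harbord_test()` implements the modified score-based regression test for
2×2 outcomes: per study the efficient score of the log OR and its
information under the margins,

\[
Z_i = a_i - \frac{(a_i+b_i)(a_i+c_i)}{n_i},\qquad
V_i = \frac{(a_i+b_i)(c_i+d_i)(a_i+c_i)(b_i+d_i)}{n_i^2(n_i-1)},
\]

then ordinary least squares of \(Z_i/\sqrt{V_i}\) on \(\sqrt{V_i}\); the
intercept estimates the small-study (funnel-asymmetry) bias and is
tested with a two-sided t on \(k-2\) df. Unlike the Egger regression on
\(\hat\theta_i/\mathrm{SE}_i\), the score formulation does not inherit
the correlation between the log OR and its variance estimate, so its
size is close to nominal for binary data. Scores are computed on the
**uncorrected integer tables** — \(Z_i\) and \(V_i\) are well defined
with zero cells, and a continuity correction would distort the score
statistic; studies excluded from the contrast, or with \(V_i = 0\), are
dropped. `funnel_data()` exports the per-study \((\hat\theta_i,
\mathrm{SE}_i)\) coordinates for visual funnel inspection; no rank-based
funnel statistic is computed.

## The synthetic-data generator

`simulate_corpus()` generates corpora with a controlled truth so every
pipeline stage can be validated against known parameters:

* per study, a control T-allele frequency \(q_i\) is drawn uniformly
  from `maf_range` (default \([0.10, 0.55]\), spanning the frequency
  variation this locus shows across ethnic groups);
* control genotypes follow an inbreeding-distorted HWE law with
  coefficient \(f\): \(P(TT) = q^2 + f q(1-q)\),
  \(P(CT) = 2q(1-q)(1-f)\), \(P(CC) = (1-q)^2 + f q(1-q)\) —
  \(f = 0\) is exact HWE, larger \(f\) depletes heterozygotes the way
  genotyping error or population stratification does;
* a study-level allele log OR \(\theta_i \sim N(\mu, \tau^2)\)
  multiplies the control C-allele odds, and case genotypes are composed
  under HWE at the induced case frequency. Effects are therefore induced
  at the **allele level**: the dominant/recessive/homozygote ORs are
  emergent consequences, not separately dialled knobs — the simplest
  generative model consistent with the allele-contrast estimand;
* counts are multinomial; per-study random substreams are derived from
  the master seed, so corpora are bit-reproducible.

The defaults (`k = 39` studies, arm sizes 40–300) mirror the scale of
the bundled corpus. What the generator deliberately does **not** emulate:
publication selection (funnel asymmetry arises only through sampling
noise), covariate-adjusted ORs, linkage with other loci, and case-arm
HWE violation. Passing operating-characteristic tests therefore
demonstrate calibration of the estimators under the stated generative
model, not robustness to those real-data phenomena.

`operating_characteristics()` wraps the simulate → pool loop and reports
CI coverage, Z-test rejection rate, and mean \(\hat\tau^2\) and OR. The
shipped test suite exercises it at desk scale: 1000 replicates of
39-study null corpora for the Harbord test's size, 1000 replicates of
20-study corpora (arms of 400–600) for the Z-test's size, 1000
replicates with \(\mu = \log 1.2, \tau = 0.2\) (arms 200–500) for
random-effects coverage, and 2000 simulated control arms (n = 200,
MAF 0.3) for the exact HWE test's size — a few minutes in total, with
every band checked in `tests/testthat/` under fixed seeds.

## Numerical and degenerate-input choices

* A single study pools to itself (\(Q = 0, I^2 = 0, \tau^2 = 0\), fixed
  model); an empty study set is an error, as is a contrast from which
  every study is excluded.
* The exact-test tie rule includes configurations with probability equal
  to the observed one (up to a \(1 + 10^{-10}\) relative guard against
  floating-point ties).
* A perfectly symmetric corpus gives the Harbord regression zero
  residual variance; the test then reports no bias (\(t = 0, p = 1\))
  rather than 0/0.
* Corpus I/O is plain UTF-8 CSV/TSV with a header and unquoted numerics;
  reading is strict (missing columns, non-integer or negative counts,
  duplicate study ids, and empty arms are named errors, not warnings).
* `run_full_analysis()` output is deterministic: fixed column order,
  fixed precision in the rendered grid (ORs/CIs and Q to 2 decimals,
  I² to whole percent), no timestamps in data files — two runs on the
  same input diff empty.

## Known limitations

* Only unadjusted ORs from genotype counts are supported — no
  covariate-adjusted effects, genotype trend tests, or meta-regression.
* \(\tau^2\) uncertainty is ignored in the random-effects interval, as
  in the classical pipeline; prediction intervals are not produced.
* The HWE machinery is biallelic and autosomal only.
* The complications and ethnicity strata are taken from the corpus
  labels as data; the package never re-derives them from country or
  population names.
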