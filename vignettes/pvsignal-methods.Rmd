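---
title: "Signal detection for FAERS-style spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection for FAERS-style spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(dplyr)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) accumulate millions of voluntary reports, each naming one or more
suspect drugs and one or more adverse-event preferred terms (PTs). Because
there is no denominator of exposed patients, risk cannot be estimated
directly; instead, *disproportionality analysis* asks whether a drug–event
pair is reported more often than the rest of the database would predict.
pvsignal implements that analysis end to end for FAERS-dialect quarterly
tables — deduplication, cohort extraction, four disproportionality
statistics with a confidence-interval signal rule, Weibull time-to-onset
modelling, and logistic risk-factor regression — together with a synthetic
report generator so that every stage can be validated against known ground
truth. The worked setting throughout is dermatologic adverse events under
the third-generation aromatase inhibitors (anastrozole, exemestane,
letrozole), but nothing in the machinery is specific to that cohort.

## Data model and deduplication

A FAERS case (`caseid`) may be reported several times as amended versions
(`primaryid`). All counting must happen on deduplicated cases, otherwise a
heavily amended case inflates its own signal. `dedup_reports()` applies the
FDA-recommended rule: within a case, keep the report with the most recent
FDA receipt date (`fda_dt`); break ties by the highest `primaryid`.

Two situations the rule does not address required decisions:

* **Undated duplicates.** A report with missing `fda_dt` always loses to
  any dated report of the same case. Keeping an undated version over a
  dated one is indefensible, so missing dates sort as minus infinity.
* **Partial dates.** FAERS dates arrive as `YYYYMMDD`, `YYYYMM` or `YYYY`
  integers. For *ordering* (deduplication) a partial date is padded with
  `01`; for *day-level arithmetic* (time to onset) a partial date counts
  as missing. `pad_ymd()` and `ymd_to_date()` implement the two views, so
  the same raw column serves both purposes without double bookkeeping.

## Cohort extraction

Drug matching is exact on normalized strings — lowercase, trimmed, with
trailing punctuation stripped — against a lexicon of generic plus brand
spellings (`ai_lexicon()`). Substring matching is deliberately avoided: it
captures combination products and look-alike names, and the package's
validation data controls its own spellings. By default only suspect roles
(`PS`, `SS`) count as drug mentions; the `roles` argument relaxes this.

PTs are mapped to a system organ class (SOC) through a two-column stub
dictionary (`derm_meddra()`, dermatologic SOC 10040785). Real MedDRA is
licensed, so the stub covers exactly the simulated vocabulary; unknown PTs
are logged and ignored rather than failing the run.

The characteristics table (`characteristics()`) reproduces the layout of a
typical descriptive Table 1: counts with percentages computed on the
stratum total and rounded **half-up** to two decimals (base R's
round-half-even would print 96.75 as 96.74 in some cells), and medians
with min–max for age and weight. Band boundaries partition without
overlap: weight `<80` is `[0, 80)`, `80–100` is `[80, 100]`, `>100` is
`(100, Inf)`; age `<18`, `18–44` is `[18, 45)`, `45–65` is `[45, 65]`,
`>65` is `(65, Inf)`. A report can carry several outcome codes but a Table
1 outcome block must sum to the stratum total, so one code is chosen per
case by severity precedence DE > LT > HO > DS > RI > OT (death dominates,
then life-threatening, and so on); cases with no outcome row count as
Unknown.

Unit conversion: ages in months or days divide by 12 or 365.25; weights in
pounds multiply by 0.453592. A missing unit code with a present value is
taken as years/kilograms (the dominant FAERS convention); an unrecognized
code makes the value missing rather than guessing.

## Disproportionality statistics

For a drug $D$ and event $E$ in a universe of $N$ deduplicated reports,
the 2×2 table is $a$ (both), $b$ (drug only), $c$ (event only), $d$
(neither), with $E_{\mathrm{ind}} = (a+b)(a+c)/N$ the count expected under
independence. Four statistics are computed per pair
(`signal_stats()`, `pt_scan()`):

* **ROR** $= ad/bc$ with the Wald interval
  $\exp(\ln \mathrm{ROR} \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})$.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with Pearson's $\chi^2$ on the raw
  table (Yates continuity correction off by default, available via
  `yates = TRUE`).
* **IC** (BCPNN information component), the closed-form shrinkage
  approximation $\mathrm{IC} = \log_2 \frac{a + 0.5}{E_{\mathrm{ind}} + 0.5}$ with
  $\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} - 2(a+0.5)^{-3/2}$.
  It is defined at $a = 0$ and needs no sampling.
* **EBGM** (MGPS): under a two-component gamma mixture prior on the
  relative reporting rate $\lambda$, the posterior given $a$ is a mixture
  of $\Gamma(\alpha_j + a,\ \beta_j + E_{\mathrm{ind}})$ with updated weights;
  $\mathrm{EBGM} = \exp(\mathbb{E}[\ln \lambda])$ via the digamma function and
  EBGM05 is the 5th posterior percentile, root-found from the mixture CDF.
  The default prior is the canonical
  $\tfrac13\,\Gamma(0.2, 0.1) + \tfrac23\,\Gamma(2, 4)$;
  `fit_mgps_prior()` re-estimates it from the observed $(a, E)$ pairs by a
  generalized EM whose marginal log-likelihood is provably non-decreasing
  (the M-step maximizes each component's weighted negative-binomial
  likelihood from the current point), falling back to the default prior
  with a warning if it fails to converge.

These four formulations are the standard published forms; where a source
reports the statistics without spelling out its exact variants, this
package's choices (Wald ROR interval, Pearson $\chi^2$ without Yates,
closed-form IC, DuMouchel EBGM with the canonical prior) are the de-facto
defaults of the field. The normal quantile is `qnorm(0.975) = 1.959964`,
not the rounded 1.96, which moves interval bounds in the fifth significant
digit.

**Zero cells.** The Haldane–Anscombe correction (+0.5 on all four cells)
is applied *only* when some cell is zero, and the row is flagged
`corrected`; clean tables keep exact arithmetic. With `correction =
FALSE` a zero-cell table yields `NA`, flagged rather than dropped.

**Signal rule.** A pair is a positive signal when the lower 95% bound of
the ROR exceeds 1 and $a \ge$ `min_count` (default 3). The PT-level scan
orders by ROR descending with ties broken by ($a$ descending, PT name
ascending), so output is invariant to input record order.

**Counting unit.** Report-level: one deduplicated report contributes once
to a PT's count however often the PT repeats within it. Published
drug-level and case-level counts are not always reconcilable (report
versus report×PT denominators); report-level counting is the
unambiguous choice and the one the contingency identity $a+b+c+d=N$
requires.

## Time to onset

Onset is `event_dt − start_dt` in whole days, the therapy start taken
from the THER row(s) linked to the matched drug's sequence number —
earliest valid full-precision start when several exist ("treatment
initiation"). Only strictly positive onsets are analysed; dropped rows are
partitioned by reason: `missing_date` (either date absent or
partial-precision), `erroneous_date` (start after event), `zero_onset`.
Medians and quartiles use linear interpolation, so an even group yields
half-day medians (e.g. {241, 242} → 241.5).

`fit_weibull()` maximizes the Weibull likelihood on $(\log k, \log
\lambda)$ (BFGS, relative tolerance $10^{-14}$, gradient checked at the
optimum), starting from the coefficient-of-variation method-of-moments
values $k_0 = (s/\bar t\,)^{-1.086}$, $\lambda_0 = \bar t / \Gamma(1 +
1/k_0)$. Wald intervals come from the observed information on the log
scale, guaranteeing positive bounds. The hazard is classified from the
shape CI: entirely below 1 → early-failure (decreasing hazard), covering
1 → random (the exponential special case), entirely above 1 →
late-failure. Fits with fewer than 10 onsets are refused rather than
reported with meaningless intervals. No censoring model is used: the data
are observed onsets, not a time-to-event cohort.

## Risk-factor regression

`build_design()` frames a case/non-case logistic regression *within one
drug's deduplicated report universe*: outcome 1 if the report is a
dermatologic case, 0 otherwise, with binary covariates hospitalization
(HO outcome code), age ≥ 65 years, and extreme weight (< 50 or > 100 kg;
reference 50–100 kg). Reports missing age or weight are incomplete and
excluded (logged). The drug-wide universe — not just the dermatologic
cases — is the only denominator that makes "hospitalization as a risk
factor for dermatologic AEs" a well-posed contrast.

`fit_logistic()` is maximum likelihood by IRLS with step-halving (the
deviance never increases), convergence at score norm $< 10^{-8}$, Wald
intervals $\exp(\beta \pm z\,\mathrm{SE})$ and two-sided Wald p-values. A
singular design names the collinear covariate; separation (any fitted
$|\eta| > 20$) raises an explicit error instead of returning divergent
estimates. On a single binary covariate the fit reproduces the analytic
2×2 odds ratio and its Woolf standard error to $10^{-8}$, which the test
suite asserts.

## The synthetic world

`default_ai_config()` states one fixed simulated world, chosen to mirror
the published dermatologic-AE cohorts for aromatase inhibitors:

* three AI generics with brand spellings (Arimidex, Aromasin, Femara)
  plus six background drugs; drug mentions written under a random
  generic/brand spelling with randomized case, targets in role PS,
  co-medications C;
* 19 dermatologic PTs (alopecia, nail disorder, onychoclasis, night
  sweats, urticaria, rash, pruritus, dry skin, erythema, hyperhidrosis,
  skin ulcer, bullous dermatitis, maculopapular rash, angioedema,
  pruritic rash, abnormal hair growth, anhidrosis, pseudo cellulitis,
  nail toxicity) under SOC 10040785, plus ten non-dermatologic
  background PTs;
* ~96.7% female, ages from a normal mixture centred at 66 years,
  log-normal weight with median 68 kg; outcome-code frequencies matching
  a published all-stratum outcome margin (~22.5% hospitalization, ~5.2%
  death);
* one planted association — anastrozole × alopecia at odds ratio 5 —
  with a Weibull(shape 1.5, scale 60 days) onset clock;
* duplicate rate 0.05 (re-emission of a case under a new `primaryid`
  with later `fda_dt`), erroneous-date rate 0.02 (therapy start shifted
  after the event), partial-date rate 0.01, and per-field missingness
  (age 30%, weight 32%, therapy start 25%, event date 15%) in the range
  real FAERS quarters exhibit.

The planting mechanism is exact, not approximate: for marginals $p_D$,
$p_E$ and target odds ratio $\psi$, the joint cell $p_{11}$ solves
Plackett's quadratic (`solve_joint_or()`), and presence of the planted
drug and PT is drawn jointly from the resulting 2×2 distribution. The
generator therefore returns a `truth` table whose expected contingency
counts are closed-form, and recovery tests compare the pipeline's
estimate against that planted table's CI, not against another simulation.
Reports that would otherwise carry no drug or no PT fall back to a
*background* catalog entry so the planted margins stay exact.

What the generator does **not** emulate — and what a green test therefore
does not establish: correlated co-prescription structure, reporting-rate
drift across quarters, country-specific reporting cultures, free-text
drug-name noise beyond case/brand variation, multiple outcome codes per
report, and the real MedDRA hierarchy above PT level. Headline quantities
of any specific published FAERS analysis (particular RORs, counts of
positive PTs) require the full multi-million-report download and are
deliberately not asserted anywhere; the tests validate arithmetic
fidelity and statistical calibration instead.

## Numerical and degenerate-input policy

* Dates compared as integers after padding; invalid calendar values
  become missing with a warning at read time.
* Empty strata produce all-zero rows with 0.00 percentages rather than
  errors; empty onset groups are omitted.
* `ebgm_mgps()` brackets the 5th-percentile root inside
  $[\min_j q_j(10^{-4}), \max_j q_j(0.5)]$ of the component gammas and
  reports a diagnostic error if the root-find fails.
* All Monte-Carlo tests fix their seeds; the generator is bit-reproducible
  for a fixed seed and config.

## Known limitations

Single-quarter bundles only (no cross-quarter accumulation); no
multiple-comparison correction across PTs (matching common practice in
published scans — the CI-based rule is itself the filter); no
interval-censored onset imputation; the MedDRA stub covers only the
simulated vocabulary; IC uses the closed-form approximation rather than
Monte-Carlo credible intervals; the EM prior fit assumes the two-component
family and can be slow on very large scans (fit once, reuse).
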