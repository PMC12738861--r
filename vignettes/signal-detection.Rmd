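---
title: "Disproportionality signal detection: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistics it implements, the
conventions it fixes where the field leaves room, and what its synthetic
data can and cannot establish about behaviour on real spontaneous reports.

## The counting model

A spontaneous reporting database is a collection of case reports; each
deduplicated case carries one or more suspected drugs with roles and one or
more adverse events coded as preferred terms (PTs). `pvsignal` counts
**drug–event pairs**: a case contributes one pair per distinct PT for its
primary-suspect drug. The 2×2 table for target drug \(D\) and event \(e\)
has \(a\) = pairs \((D, e)\), \(b\) = other pairs of \(D\), \(c\) = pairs
\((\text{other}, e)\), \(d\) = the rest, \(N = a+b+c+d\), and expected
count \(E = (a+b)(a+c)/N\). The pair-level convention — report counts, not
patient counts, in the margins — is the one under which the standard
printed relationships between ROR, PRR and the observed-to-expected ratio
hold, and it reproduces the situation where a database's "reports" exceed
its "patients" (a patient with three distinct PTs is three pairs).

At the system-organ-class (SOC) level a case counts **at most once per
SOC** however many of its PTs map there, so a case with three bleeding PTs
is one vascular-disorders count. An aggregate-count source (a
VigiAccess-style export of per-PT totals) carries no within-case
information, so its SOC rollup sums PT counts; that is an upper bound on
the deduplicated count and is documented at the call site.

Deduplication keeps, per case identifier, the version with the latest
version date, breaking ties by the larger report identifier, then removes
cases on the deleted list. Only latest-version retention and deleted-case
removal are implemented as the cleaning rule; both steps are logged so the
rule applied is auditable. The operation is idempotent by construction.

## The four statistics and the joint criterion

With cells as above:

* **ROR** \(= ad/bc\), Woolf CI
  \(\exp(\ln \mathrm{ROR} \pm z\sqrt{1/a+1/b+1/c+1/d})\). Undefined when
  any cell is zero; the optional Haldane–Anscombe 0.5 correction is off by
  default so that zero-cell tables *fail closed* in the signal rules.
* **PRR** \(= [a/(a+b)]/[c/(c+d)]\) with the uncorrected Pearson χ² on the
  2×2 (Yates by flag). Undefined when \(c = 0\) or a margin is empty.
* **BCPNN IC**. Two standard formulations: the Norén closed form
  \(\mathrm{IC} = \log_2\frac{a+0.5}{E+0.5}\) with
  \(\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} - 2(a+0.5)^{-3/2}\)
  (default: reproducible, no approximation error), and the Bate Gaussian
  approximation under the original Beta/Dirichlet priors. Both converge to
  \(\log_2(a/E)\) as counts grow with \(a/E\) fixed. Note that at a large
  count over a *small* expected (e.g. \(a = 370\), \(E \approx 5.8\)) the
  +0.5 shrinkage still shifts the Norén IC visibly (≈0.12 bits) below
  \(\log_2(a/E)\); published tables that print exactly \(\log_2(a/E)\) are
  matched by that raw ratio, not by the shrunk variant.
* **MGPS EBGM**. DuMouchel's empirical-Bayes model: counts are
  Poisson\((\lambda E)\) with
  \(\lambda \sim w\,\Gamma(\alpha_1,\beta_1) + (1-w)\,\Gamma(\alpha_2,\beta_2)\).
  The five hyperparameters are fitted by maximizing the marginal
  (negative-binomial mixture) likelihood over all events of a table set.
  The posterior is again a two-gamma mixture;
  \(\mathrm{EBGM} = e^{\mathbb E[\ln\lambda\,|\,a,E]}\) via
  \(\mathbb E[\ln\Gamma(s,r)] = \psi(s) - \ln r\), and EBGM05 is the
  posterior 5th percentile by bracketed root-finding on the mixture CDF.
  "Lower limit of the 95% interval" is read as the one-sided EB05
  convention; `percentile = 0.025` gives the two-sided variant.

Default thresholds are the standard published criteria — ROR: \(a \ge 3\)
and CI lower > 1; PRR: PRR ≥ 2, χ² ≥ 4, \(a \ge 3\); BCPNN:
IC025 > 0; MGPS: EBGM05 > 2 — all configurable. The joint verdict is the
AND of the four; any undefined statistic fails its rule. Being an AND, the
joint criterion can never flag more events than any single method, which is
also what makes it conservative under the null.

## Numerical choices

* **MGPS optimizer**: Nelder–Mead on \(\log\)-transformed gamma parameters
  and logit weight, started from the canonical values
  \((0.2, 0.1, 2, 4, 1/3)\) plus four fixed multiplicative perturbations
  (deterministic restarts, no RNG), relative tolerance \(10^{-8}\), best
  converged solution kept. On small table sets the ML solution may place a
  near-degenerate spike on a component; the posterior quantities remain
  well-behaved.
* **Posterior percentile**: bracketed `uniroot` between the two component
  quantiles, tolerance \(10^{-10}\); degenerate weights fall back to the
  single-gamma quantile.
* **Weibull MLE**: the shape solves the profile score
  \(1/k + \overline{\ln x} - \sum x^k \ln x / \sum x^k = 0\) by bracketed
  root-finding (the inner ratio computed as a log-weighted mean so large
  shapes do not overflow); the scale then has the closed form
  \((\overline{x^k})^{1/k}\). CIs come from the observed information on
  \((\log \alpha, \log \beta)\), exponentiated — bounds stay positive and
  intervals are asymmetric, matching how onset-time fits are reported. An
  independent MLE (`fitdistrplus`) is the cross-check oracle in the tests.
* **Zero onsets**: dates have day resolution, so a same-day event is
  represented as half a day (0 → 0.5) by default — Weibull support is
  positive and the half-day convention matches "median onset 0.5 days
  (12 h)" style reporting. `zero_policy = "exclude"` is available; the
  choice is logged with the fit's n.
* **Failure typing**: early if the shape CI's upper bound < 1, wear-out if
  its lower bound > 1, random if the CI spans 1; fewer than 10 usable
  onsets → no fit, type `undetermined` (the "too few cases to analyze"
  footnote convention).
* **Percentiles and bins**: summaries use type-7 (linear interpolation)
  quantiles; onset bins are `[0, 30], (30, 60], …` days, so day 30 belongs
  to the first bin.
* **Kaplan–Meier**: `survival::survfit` product-limit; with no censoring
  the cumulative incidence equals the empirical CDF exactly (asserted in
  the tests).
* **Subgroup tests**: the Cochran cascade on the minimum expected cell
  (≥ 5 Pearson, [1, 5) Yates, < 1 Fisher). A zero *observed* cell forces
  Fisher's exact test regardless of the cascade, since the between-group
  ROR is then undefined and an exact p is the defensible report. Fisher's
  two-sided p is the probability-ordering convention of
  `stats::fisher.test`, verified against full hypergeometric enumeration
  for every table with \(N \le 30\).
* **Determinism**: signal tables sort by count then EBGM descending (with
  the event name as final tie-break), exports are plain TSV, and re-running
  a pipeline configuration is byte-identical.

## The synthetic generator

`synth_config()` / `generate_reports()` emulate a mid-sized reporting
database so every stage is testable with known ground truth. Each case
draws one primary-suspect drug from exposure probabilities; each PT enters
independently with probability `background × rho(drug, pt)` clipped at 1
(`rho = 1` is the null), with a redraw guaranteeing at least one PT per
case. Onset is day 0 with probability `p0`, else Weibull, rounded to whole
days and realized as `event_date − therapy_start`; demographics and
per-field missingness are sampled independently; duplicates get an extra
earlier-dated version and deleted cases a list entry, so
`deduplicate_cases(inject_artifacts(x))` recovers `x` minus deletions
exactly. All randomness derives from one master seed through fixed
per-stage sub-seeds, so stages can be regenerated independently.

Defaults describe the conditions the package is exercised under: five
drugs with equal exposure; fifty PTs with background probabilities
log-spaced from 0.2% to 8% per case; demographics with male predominance
(60/40), an elderly-skewed age distribution, healthcare-professional
reporters ~94%, and heavy missingness (30% sex and age, 50% onset dates) —
the shape typical of cardiovascular-drug report series; onset law scale
4.193 days, shape 0.597 with a 40% same-day mass, matching the published
thrombocytopenia fit and the abundance of day-0 onsets in onset tables;
duplicate rate 5%, deletion rate 2%.

Two honest caveats about what the generator shows:

* The at-least-one-PT redraw inflates marginal pair rates whenever the
  background probabilities sum well below 1 (with ~0.5 expected PTs per
  case, over half of cases are redrawn and realized frequencies roughly
  double). Marginal-rate recovery is therefore asserted under
  configurations with ≈8 expected PTs per case, where the redraw
  probability is ~e⁻⁸; disproportionality contrasts are unaffected either
  way because the inflation is shared by target and comparator.
* PT draws are independent given the drug (no PT–PT correlation), there is
  one suspect drug per case, and reporting rates are time-constant. Passing
  tests therefore establish correctness of the estimators and plumbing, not
  robustness to co-reporting clusters, polypharmacy, or notoriety-driven
  reporting waves in real data.

## Problem sizes used by the test suite

The suite runs on one CPU in a few minutes: null false-positive monitoring
uses 20 generator seeds at 50,000 cases × 200 events; signal recovery uses
50,000 cases with a planted relative reporting ratio of 20; Weibull CI
coverage uses 500 fits at n = 117; mixture-prior recovery averages 5
replicates of 2,000 events (a single replicate's rare-component mean is
weakly identified — the fitted optimum is the global ML, but at 10% weight
~200 events carry its information — so recovery is judged on the replicate
mean, the same averaging design as the shape-recovery check); Fisher
enumeration sweeps all ~46,000 tables with N ≤ 30.

## Known limitations

* The BCPNN IC025 printed by published analyses depends on prior and
  credibility conventions that vary between implementations; both standard
  variants are provided, and neither is claimed to reproduce any particular
  table's IC025 exactly.
* The MGPS prior fit needs ≥ 10 events with positive expected count;
  smaller strata return per-method results with EBGM marked unavailable,
  and no event can then pass the joint criterion in that stratum.
* Aggregate-count sources cannot support within-case SOC deduplication or
  onset analysis (no dates); the pipeline simply skips what the source
  cannot provide.
* No multiple-testing adjustment is applied anywhere — deliberate, since
  the joint four-method, two-database criterion is itself the false-positive
  control in this design.
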