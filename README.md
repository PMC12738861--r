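# pvsignal

Signal detection for spontaneous adverse-event reporting databases.

Post-marketing drug safety relies on spontaneous reporting systems (FAERS,
VigiBase): large collections of case reports in which a suspected drug is
linked to one or more adverse events coded as MedDRA preferred terms (PTs).
Because these databases have no denominator of exposed patients, safety
signals are found by **disproportionality analysis**: for a target drug and
each event, the 2×2 table

|                | event         | no event |
|----------------|---------------|----------|
| target drug    | a             | b        |
| all other drugs| c             | d        |

is summarized by measures of how far `a` exceeds its expectation
`E = (a+b)(a+c)/N`. `pvsignal` implements the four standard statistics and
the joint criterion used in dual-database pharmacovigilance studies:

- **ROR** `= ad/bc` with the Woolf interval
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; rule: `a ≥ 3`, CI lower > 1.
- **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Pearson χ² on the 2×2;
  rule: PRR ≥ 2, χ² ≥ 4, `a ≥ 3`.
- **BCPNN information component**, a shrunk `log2(a/E)` (Norén closed form
  `IC = log2((a+0.5)/(E+0.5))` with its closed-form credibility bound, and
  the Bate Gaussian approximation); rule: IC025 > 0.
- **MGPS EBGM**: DuMouchel's empirical-Bayes gamma–Poisson shrinker. A
  two-component gamma mixture prior on the relative reporting rate λ is
  fitted by marginal maximum likelihood across all events; the posterior
  geometric mean `EBGM = 2^E[log2 λ | a, E]` and its 5th percentile EBGM05
  give the shrunk estimate; rule: EBGM05 > 2.

An event is a **signal** when it passes all four rules, optionally in two
databases at once (cross-database intersection). Around this core the
package provides FAERS-style quarterly ASCII ingestion with latest-version
deduplication and deleted-case removal, VigiAccess-style aggregate-count
ingestion, PT- and SOC-level table construction, Weibull time-to-onset
modelling with failure-type classification (early / random / wear-out from
the shape parameter's CI against 1), Kaplan–Meier cumulative incidence,
sex-/age-/reporter-stratified sensitivity analyses, a configuration-driven
pipeline, and a synthetic report generator with known ground truth so the
whole chain is testable without external data.

## Worked example

Generate a synthetic database with one planted drug–event association
(relative reporting ratio 20), build the 2×2 tables, and detect signals:

```r
library(pvsignal)

cfg <- synth_config(
  n_cases = 20000, seed = 42,
  signal_matrix = tibble::tibble(drug = "drug01", pt = "pt010", rho = 20)
)
g <- generate_reports(cfg)
tables <- build_pt_tables(g$reports, "drug01")
signals <- detect_signals(tables)
dplyr::select(signals, event, a, ror, prr, chi2, ic025, ebgm, ebgm05)
#> # A tibble: 1 × 8
#>   event     a   ror   prr  chi2 ic025  ebgm ebgm05
#>   <chr> <int> <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl>
#> 1 pt010   383  16.4  15.4 1070.  1.80  3.93   3.92
```

Only the planted pair is flagged: 383 reports against an expected 97, so
the observed-to-expected ratio (and hence EBGM) is ≈3.9, while the ROR —
which contrasts odds against all *other* drugs — is ≈16. All four rules
pass, so the joint verdict is positive; the 49 null events are not flagged.

The same estimators reproduce a published FAERS haemorrhage row when the
2×2 is rebuilt from its printed margins
(`a = 370, b = 3117, c = 92235, d = 55261741`):

```r
t <- tibble::tibble(a = 370, b = 3117, c = 92235, d = 55261741)
round(dplyr::bind_cols(compute_ror(t), compute_prr(t), compute_ic(t)), 2)
#> # A tibble: 1 × 7
#>     ror ror_lo ror_hi   prr   chi2    ic ic025
#>   <dbl>  <dbl>  <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1  71.1   63.8   79.2  63.7 22774.  5.87   5.7
```

(The Norén IC sits slightly below the raw `log2(a/E) = 5.99` because the
+0.5 shrinkage is material at `E ≈ 5.8`.)

Time-to-onset on the synthetic reports:

```r
os <- compute_onset(g$reports)
os
#> <onset_sample> 'all events': 9997 onsets kept of 20000 reports
#>   (10003 missing, 0 negative, 0 outlier)
fit_weibull(os)
#> <weibull_fit> n = 9997
#>   scale 2.713 (2.628, 2.801) days
#>   shape 0.653 (0.644, 0.662)
#>   failure type: early
```

The shape below 1 with CI entirely under 1 classifies the hazard as an
early-failure pattern: risk concentrated right after therapy start. (The
fitted shape is pulled above the generating 0.597 by day-rounding and the
half-day convention for same-day onsets; see the vignette.)

The full pipeline — ingestion, deduplication, demographics, PT/SOC signal
tables, cross-database overlap, onset analysis, stratified reruns, and a
JSON manifest — runs from one configuration:

```r
cfg <- pipeline_config(drug = "tirofiban", faers_dir = "faers_ascii/",
                       aggregate_paths = c(who = "vigiaccess_counts.csv"),
                       soc_map_path = "pt_soc.csv", out_dir = "out")
run_pipeline(cfg)
```

A thin command-line wrapper with `simulate` and `run` subcommands is at
`inst/scripts/pvsignal.R`.

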