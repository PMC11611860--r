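---
title: "Disproportionality signal detection on FAERS-style report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect millions of unverified reports, each
naming one or more drugs (with a role code: primary suspect, secondary
suspect, interacting, concomitant) and one or more adverse events coded as
MedDRA preferred terms (PTs), which roll up into system organ classes
(SOCs). There is no denominator of exposed patients, so drug safety
screening works by *disproportionality*: for a drug–event pair, compare
how often the event is reported with the drug against how often it is
reported with everything else. faersignal implements that workflow end to
end for a single target drug: ingesting the quarterly ASCII tables,
collapsing re-submitted case versions, extracting the primary-suspect
cohort, building per-event 2×2 tables, and computing four screening
statistics with their conventional flagging thresholds.

## The data model and its cleaning rules

A case travels through FAERS as successive versions under one CASEID.
`deduplicate_reports()` keeps, per CASEID, the version with the latest FDA
receipt date (FDA_DT), breaking date ties by the numerically largest
PRIMARYID. Numeric comparison matters: lexicographically "9" > "10". The
rule is idempotent and order-free, which the test suite checks as a
property.

`join_case()` then aggregates the DRUG, REAC and OUTC rows of each
retained version. Within a report, repeated PTs collapse to one — the
counting unit everywhere downstream is the *report*, never the reaction
row. Demographics are normalised at this point:

* **Age.** AGE plus AGE_COD converts to years (MON/12, DY/365.25,
  WK/52.18, DEC×10, HR/8766). A unitless age is accepted as years only
  when ≤ 120; beyond that it is treated as missing rather than guessed.
* **Gender.** F → Female, M → Male, anything else (UNK, NS, empty) →
  Unknown, matching the three-way split used in published summaries.
* **Country.** The reporter country, falling back to the occurrence
  country when absent; empty → Unknown.
* **Report year.** The year of the retained version's FDA receipt date.
  Published tables bin by "report year" without defining the source
  column; the receipt date of the surviving version is the one date the
  dedup rule guarantees to exist.

Age groups use the strata ≤17, 18–64, 65–85, >85, Unknown. The published
strata are gapped ("<17", "18~64"); a total partition needs a decision,
and fractional ages below 18 go to "<17". A ">85" stratum is carried even
though summary tables rarely show it — silently merging it into 65–85
would misstate that bin.

Percentages round half away from zero to one decimal, the convention
under which published count/percent pairs recompute exactly. Outcome
percentages are computed over outcome *entries* (a report can carry
several outcomes; reports with none contribute a Missing entry), because
report-level denominators cannot reproduce published outcome percents
that sum beyond 100.

## The 2×2 table and the four statistics

For an event at PT or SOC level, with `a` case reports carrying the
event, `b` cases without it, `c` background reports with it and `d`
without, `N = a+b+c+d`:

| Statistic | Estimate | Interval | Flag |
|---|---|---|---|
| ROR | $ad/bc$ | $\exp(\ln ROR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$ | $a \ge 3$ and lower bound $> 1$ |
| PRR | $\frac{a/(a+b)}{c/(c+d)}$ | $\exp(\ln PRR \pm 1.96\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)})$ | $a \ge 3$, $PRR \ge 2$, $\chi^2 \ge 4$ |
| BCPNN | $IC = \log_2 \frac{aN}{(a+b)(a+c)}$ | posterior $E(IC)$, $V(IC)$ | $IC_{025} = E(IC) - 2\sqrt{V(IC)} > 0$ |
| EBGM | $\frac{aN}{(a+c)(a+b)}$ | $\exp(\ln EBGM \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$ | $EBGM_{05} > 2$ |

Numerical and interpretive choices worth stating:

* **χ² form.** Pearson without continuity correction,
  $N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))$ — the PRR literature's default.
  Yates' correction is available via `correction = "yates"` for users who
  want the conservative variant.
* **BCPNN priors.** Beta margins with $\alpha = \beta = 2$,
  $\alpha_i = \beta_j = 1$ and joint Dirichlet component
  $\gamma_{ij} = 1$, with the Dirichlet total derived per table as
  $\gamma = \gamma_{ij}(N+\alpha)(N+\beta) / ((a+b+\alpha_i)(a+c+\beta_j))$
  so the posterior IC centres on zero under independence. These are the
  method's standard defaults and are configurable through
  `bcpnn_hyperparameters()`. $IC_{025}$ is the normal-approximation lower
  bound $E(IC) - 2\,SD(IC)$.
* **EBGM without shrinkage.** The EBGM computed here is the observed-to-
  expected reporting ratio $aN/((a+c)(a+b))$ with a log-normal interval —
  algebraically $2^{IC}$, a fact the tests assert to machine precision.
  The full multi-item gamma-Poisson shrinker, which fits an empirical-
  Bayes mixture across *all* drug–event pairs in a corpus, is out of
  scope; at single-drug desk scale there is no corpus to estimate the
  mixture from. EBGM05 rankings from this package are therefore more
  anti-conservative for small `a` than a shrunken implementation would
  be.
* **Degenerate cells.** Tables with a zero in a denominator-relevant cell
  yield an explicit `NA` (undefined) and can never flag. No silent 0.5
  correction is applied, because that would quietly change threshold
  semantics; the Haldane–Anscombe correction is available explicitly via
  `zero_correction = TRUE`.
* **Thresholds.** Inclusive for PRR ≥ 2 and χ² ≥ 4, strict for the three
  lower bounds (> 1, > 0, > 2), exactly as conventionally printed. No
  multiple-testing adjustment is made — the procedure is a screen, not a
  test battery — and this is a known limitation: with ~100 PTs evaluated,
  a few null events will flag on any single algorithm by chance, which is
  one reason the four-algorithm intersection is reported.
* **Ranking.** `rank_by_ebgm05()` orders by the most stringent lower
  bound, EBGM05, descending; undefined values sort last; ties break by
  descending `a`, then label, making output order total and reproducible.

ROR and PRR nearly coincide only in the rare-event limit: their ratio is
$(1+a/b)/(1+c/d)$, so an event common within the cohort (large $a/b$) can
show a 10–15% gap even in an enormous background. The tests assert
near-equality only where the limit applies.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws reports whose demographic blocks follow the
marginals of a published 508-report disulfiram cohort (58.7% male, 72.6%
aged 18–64, physician-led reporting, US-led country mix, a 2004–2023 year
span), a ~100-term PT vocabulary across 18 SOCs with Zipf-decaying
frequencies (the scale at which a single-drug FAERS query typically
expresses its events), multi-PT reports (count ~ 1 + Poisson, mean 2,
de-duplicated within report), multi-drug reports with role codes, and
planted drug–event signals: a PT's background probability is multiplied
by λ inside target-PS reports and the PT distribution renormalises.
Because of renormalisation and within-report de-duplication, λ is *not*
the true odds ratio; the truth record stores the realised per-report
presence probabilities $q = 1-(1-p)e^{-(m-1)p}$ and the odds ratio they
imply, and parameter-recovery tests compare against that, not against λ.
`inject_duplicates()` re-emits a configurable fraction of cases 1–3 extra
times with strictly later dates and larger PRIMARYIDs, tagging the
expected survivor.

Default scale is 10,000 reports with a 1% target fraction;
parameter-recovery and null-calibration experiments in the tests and the
acceptance script use 50,000 reports and 20 seeded replicates, which one
CPU completes in about a minute each.

The generator deliberately does **not** emulate: correlated
co-prescription structure, reporting waves and secular trends within a
year, PT co-occurrence syndromes (PTs are drawn independently within a
report), country-specific reporting cultures, or the deeper MedDRA
hierarchy (HLT/HLGT). Passing tests therefore demonstrate that the
pipeline's arithmetic, rules and rankings are correct under a clean
generative model — not that real FAERS confounding (channeling bias,
stimulated reporting, duplicate clusters that differ in content) is
handled, which no disproportionality method does.

## Known limitations

* Only the post-2012 FAERS ASCII layout ('$'-delimited, named header) is
  read; the legacy LAERS dialect is not.
* Drug identification is by exact name match against a synonym list —
  no RxNorm/ATC normalisation.
* Background reports that name the target drug in a non-PS role remain
  in the background, per the primary-suspect extraction rule; this
  slightly dilutes contrasts for drugs commonly reported as concomitant.
* Signal magnitudes from a corpus of tens of millions of reports are not
  reproducible from desk-scale fixtures; what transfers is the rule set,
  the rankings and the internal consistency of the statistics, and those
  are what the tests pin down.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_cohort_config(
  n_reports = 20000,
  planted_signals = c("Alcohol intolerance" = 10),
  seed = 421
)
res <- run_pipeline(run_config(synthetic = cfg, synonyms = "DISULFIRAM",
                               out_dir = tempfile()))
rank_by_ebgm05(res$pt, top_n = 5) |>
  select(event, a, ror, prr, chi2, ic025, ebgm05, n_algorithms_flagged)
autoplot(res$pt)
```
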