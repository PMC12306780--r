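---
title: "Methods: charting rules, intention analysis, and life-table estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charting rules, intention analysis, and life-table estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmslife)
```

# The problem

Fertility-awareness methods identify the days of a menstrual cycle on
which intercourse can lead to conception.  Whether a pregnancy occurs
during use of such a method depends jointly on the biology (day-specific
fecundability concentrated in a roughly six-day window ending shortly
after ovulation), on the charting system's ability to flag those days,
and on the couple's behavior given their stated intention.  `crmslife`
implements the analysis chain for prospective cohorts of Creighton Model
FertilityCare System (CrMS) users: daily charts are classified day by
day, partner intentions are reconciled per cycle, behavior is
cross-tabulated against intention, "correct use" is identified under
progressively strict evidence filters, and pregnancy probabilities are
estimated by cycle-based single-decrement and month-based
multiple-decrement life tables.

# Day classification

Each charted day carries a bleeding code (H, M, L, VL, B, none), a
discharge code (dry, non-peak mucus, peak-type mucus, unobserved), an
observation-frequency code, and intercourse flags.  The classifier maps
each day to `FERTILE`, `NON_FERTILE`, or `UNKNOWN` under an explicit,
versioned rule table (`default_rule_table()`), shipped as data
(`inst/extdata/crms_rules_default.conf`) so an alternative published
rule set can be substituted without code changes.  The default rules are
a reconstruction of standard CrMS instruction:

* days without a usable observation (discharge unobserved and no
  menses-grade bleeding) are `UNKNOWN` — missing information, never
  silently imputed;
* menses-grade bleeding (H, M, L) is fertile;
* any mucus day is fertile, and the three days following a pre-peak
  non-peak-mucus patch are fertile (the count of three);
* the peak day (last peak-type mucus day) through Peak+3 is fertile;
* pre-peak dry days and Peak+4 are non-fertile **only from the end of
  the day** (`end_of_day_only` in the output), so any act earlier in the
  day is potentially fertile;
* dry days from Peak+5 onward are non-fertile without restriction.

The count of three is applied pre-peak only: post-peak dry days beyond
Peak+4 are non-fertile by instruction, and post-peak mucus days are
fertile in their own right, so extending a count across the peak would
contradict both rules.  Double peaks (two separated peak-type runs) are
annotated by `identify_peak_day()` but do not extend the fertile window
by default: the charting convention observed in evaluation records notes
unrecognized double peaks as a use error rather than a window rule.

Three properties are enforced by tests: the statuses partition the
cycle's days; classification is a pure function of chart and rules; and
adding an observation to an `UNKNOWN` day never yields `UNKNOWN` again.
An independently written straight-line classifier re-derives the status
of every day on 1000 random cycles as an oracle.

# Intentions and reconciliation

The 6-level intention scale is totally ordered by "achieving": abstain <
trying hard to avoid < avoid < undecided < conceive < trying hard to
conceive.  Couple reconciliation is the maximum (join) of the two
partners under this order, which makes it commutative, associative and
idempotent; a single responding partner's answer is used as is.  Placing
*abstain* below *trying hard to avoid* is a design choice: complete
abstention is the least conception-oriented stance.  Prospectivity is
enforced by retaining only questionnaires completed within the first 11
days of the cycle (day 11 generally precedes ovulation); the
all-questionnaires arm (`window_days = Inf`) is the stated sensitivity
analysis.  Duplicate responses resolve to the earliest completion, again
for prospectivity.

Concordance collapses both partners to four groups (Achieving, Neutral,
Avoiding, Abstaining) and reports the diagonal share of the 4×4 table.
Cycles missing either partner are excluded and counted, never imputed.

# Life tables

**Single-decrement (cycles).** For stratum ordinal *i*, the conditional
pregnancy probability is `q_i = e_i / n_i` over the cycles at risk, and
`CP(k) = 1 − Π_{i≤k}(1 − q_i)`.  Each cycle joins the stratum of *its
own* reconciled intention, with the ordinal being the couple's study
cycle number — couples move between strata as intentions change, so
reported "couples" counts both couples ever contributing
(`couples`) and couples at ordinal 1 (`couples_at_first`), since either
convention can be wanted.  Withdrawals are reported as
`n_i − e_i − n_{i+1}` and can be negative in stratified tables (net
entries).  Censored couples exit at the end of their last complete
ordinal unit; no half-unit exposure correction is applied, matching the
discrete product-limit estimator that the Kaplan-Meier oracle in the
test suite reproduces exactly.

**Multiple-decrement (ordinal months).** Following historical CrMS
methodology, months are fixed 30.44-day bins from the analytic entry
(the later of the consent cycle's start and the first-intercourse
cycle's start), all causes share the single all-use denominator `n_m`,
and the net rate per 100 couples for cause *c* is
`NR_c = 100 Σ_m q_{c,m} Π_{j<m} p_j` with `p_j = 1 − Σ_c q_{c,j}`.
The accounting identity `Σ_c NR_c/100 + Π_m p_m = 1` holds exactly by
telescoping and is asserted to 1e−9.  Couples whose pregnancy involved
condoms or withdrawal on fertile days are excluded from this table
entirely.  These net rates are **not** comparable to correct-use
("perfect use") rates: the denominator includes achieving-oriented
months, which deflates the method-related rate.

# Correct use

Level 1 requires an eligible couple (at least one partner reported
recording all or nearly all intercourse), a completely charted cycle (no
`UNKNOWN` day from missing observations), and at least one act of
intercourse.  Level 2 additionally requires the teacher's follow-up
assessment (assigned to the cycle by nearest visit date, ties to the
earlier visit) to certify consistent observations, correct peak
identification, and accurate charting.  Level 3 further excludes cycles
with condom/withdrawal use or nonstandard chart formats.  The five
categories follow intercourse placement against the day statuses.

One deliberate deviation from a literal reading of the strict
end-of-day flag: acts with unrecorded time of day on end-of-day-only
non-fertile days exclude a cycle from `AVOID_STRICT` and
`AVOID_POSTPEAK_ONLY` (the charts of the study era could not record
timing, so the act may have been potentially fertile), but the
*defining* day of `AVOID_LAST_DRY_PREPEAK` is exempt from its own
ambiguity — that category exists precisely to probe conception risk from
the last pre-window day, and excluding every unrecorded act would make
it empty by construction.  Ambiguity on any *other* day still blocks it.

# Pregnancy classification

The classifier encodes the published category logic as a fixed
precedence: barrier involvement on fertile days (or barrier use whose
fertile-day involvement cannot be excluded) → non-CrMS; insufficient
information → unresolved; known fertile-day intercourse or documented
achieving behaviors → achieving; end-of-day-ambiguous conception without
achieving behaviors → unresolved (it could be method-, achieving- or
using-related depending on the unknown timing); interpretation/charting
errors → using; contributory teaching deficiencies → teaching (co-assigned
with using as using/teaching); otherwise, with all instructions
followed, → method.  The original study used an expert panel; this
module is a reconstruction of that panel's published outcome logic, and
every rule carries a reason code drawn from the published review
vocabulary.  A using/teaching pregnancy is echoed once in each reason
family in summaries.

# The synthetic cohort

The generator states one "paper-like" world and is not re-tuned:

* 296 couples (default), one-year censoring, 13-cycle cap, monthly
  dropout hazard 0.02;
* cycle length ~ round N(29, 3) truncated to 21–42 days, luteal phase ~
  round N(13, 1.5), a 5-day pre-peak mucus build-up;
* day-specific fecundability (0.03, 0.07, 0.12, 0.20, 0.26, 0.30, 0.10)
  on days ovulation−5 … ovulation+1, indexed to the *true* ovulation day
  with the charted peak at ovulation ± 1 day — chart-based
  classification is deliberately an imperfect proxy of the truth, which
  is the real mechanism behind correct-use failures;
* an intention mix dominated by avoiders (the enrolment criterion), with
  85% per-cycle persistence; per-day intercourse probabilities by
  intention and charted day status, where the fertile-day entries of the
  avoid intentions are the "leakage" probabilities (0.030–0.035/day,
  producing roughly the observed one-third of avoid cycles with
  fertile-day exposure);
* missing observations as a cycle-level mixture: 30% of cycles carry
  missing days at three times the 10% marginal rate.  Independent
  per-day missingness at the same marginal rate would make fully charted
  cycles vanishingly rare (~5%), contradicting the observed volume of
  complete-chart correct-use cycles; clustered missingness preserves the
  ~8–9% unknown-day share while leaving a realistic fraction of
  complete charts;
* condom/withdrawal cycles (5%) multiply day-specific fecundability by
  0.2 rather than zeroing it, so non-CrMS pregnancies occur;
* partner-specific SOC nonresponse (12% female, 18% male, giving ~72%
  of cycles with both sources), completion day 1 + Geometric(0.3), 8%
  one-level partner disagreement noise;
* 5% of cycles never return a chart (SOC-only cycles), and the
  exit-questionnaire fidelity mix leaves about 62% of couples eligible
  for correct-use analyses.

What a green test establishes — and what it does not.  The generator
reproduces the statistical *structure* the analysis assumes (streams,
missingness, intention-behavior coupling, competing exits), so passing
tests establish that the estimators recover known truth under that
structure.  Real charts contain features the generator does not emulate:
continuous-mucus patterns and yellow-stamp protocols, double peaks,
intention drift within a cycle, correlated partner nonresponse, and
center-level heterogeneity.  No attempt is made to fit the generator to
the original study's unpublished raw data, and published rate tables are
not reproduced numerically — only their estimators and structure.

# Numerical choices

* Display percentages are rounded half-up to one decimal
  (`round_half_up()`), matching the convention of the printed tables;
  raw counts are always emitted alongside.
* Cycle-length imputation uses the woman's median observed length,
  rounded half-up to an integer.
* The post-peak pregnancy-surveillance threshold defaults to 17 days and
  the menses-delay threshold to 7 days; both are configurable, as no
  published value exists.
* Ordinal month length defaults to 30.44 days (365.25/12).
* Empty risk sets at an ordinal are skipped (q undefined) and reported,
  never smoothed.
* Ties in teacher-assessment assignment break toward the earlier visit.

# Known limitations

* The exact published supplementary day-classification rules and
  condom/withdrawal ascertainment hierarchy were not available; the rule
  table and the union rule (either partner's questionnaire, shifted one
  cycle back, or a chart annotation) are documented reconstructions.
* The historical CrMS net-rate formula may treat censoring differently
  from the discrete product-limit convention implemented here; the
  convention is surfaced, not guessed, and the half-unit correction is
  intentionally absent.
* No confidence intervals are produced, and no regression modelling is
  included; the cohort generator carries the baseline covariates so
  users can fit hazard models externally.
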