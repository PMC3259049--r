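---
title: "Combination stopping rules on response rate and time to progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combination stopping rules on response rate and time to progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrdesign)
```

## The design problem

Single-arm phase II oncology trials screen new agents for activity. The
conventional endpoint is the objective response rate (RR), but a drug that
stabilises disease without shrinking tumours — a cytostatic agent — can
look inactive on RR while delivering a clinically meaningful time to
progression (TTP). A design that tests only RR discards such drugs; a
design that tests only TTP is slow (the whole first-stage cohort must be
followed to progression before the trial can stop for futility) and can
miss drugs whose activity shows up as responses.

The combination stopping rule (CSR) implemented here hedges both bets. The
investigator specifies four clinical quantities:

* $r_{nul}$, $ttp_{nul}$ — the response rate and median TTP (months) that
  make a drug *uninteresting*;
* $r_{alt}$, $ttp_{alt}$ — the values that make it *interesting*.

The hypotheses are composite and asymmetric:

$$H_{nul}: r \le r_{nul} \text{ and } ttp \le ttp_{nul}
\qquad
H_{alt}: r \ge r_{alt} \text{ or } ttp \ge ttp_{alt}.$$

Inactivity means failing on *both* endpoints; activity means succeeding on
*either*. At the end of stage II (cumulative sample $n_1 + n_2$) the rule
rejects $H_{nul}$ if the cumulative response count reaches $r_{2a}$ **or**
the Kaplan–Meier median TTP reaches $ttp_{2a}$ months.

### Early progressive disease as the stage-I surrogate for TTP

Waiting for a median TTP estimate at stage I would defeat the purpose of a
futility look. Instead the stage-I rule uses early progressive disease
(EPD): progression already present at the first post-baseline tumour
measurement, taken $t_{first}$ months into treatment. Under the design's
exponential progression model with median $m$,

$$P(\mathrm{EPD}) \;=\; 1 - 2^{-t_{first}/m},$$

so the TTP hypotheses translate directly into EPD rates
(`epd_probability()`), and a high EPD count is the earliest observable
signal of a short TTP. The trial stops after stage I, accepting $H_{nul}$,
only when responses are few **and** EPD is common:
$r_1 \le r_{1nul}$ and $epd \ge epd_{1nul}$. Early *rejection* of
$H_{nul}$ at stage I is never permitted.

## The patient-level simulation model

`simulate_trials()` draws each patient as:

* response ~ Bernoulli(true RR), independent of the progression time. The
  model deliberately does not couple an individual's response to that
  individual's TTP: responses are assessed in aggregate, and coupling them
  would require assumptions about how a response moves a patient along the
  growth curve.
* latent TTP ~ Exponential with median equal to the true median TTP
  (rate $\log 2 / m$ per month). Exponential tumour progression is the
  standard minimal model; other growth laws (e.g. Gompertz) are out of
  scope.
* censoring: with probability `censor_prob` (default 0.05) the patient is
  censored for the TTP endpoint, at a time drawn uniformly between 0 and
  the latent progression time. The per-patient censoring *rate* is the
  design parameter; the uniform-before-progression *law* is this
  package's choice of the simplest mechanism achieving that rate while
  guaranteeing the censoring event precedes progression.
* replacement: a patient censored before the first scan (off study from
  toxicity or death before $t_{first}$, not from progression) is replaced
  by a fresh draw, mirroring the usual handling of unevaluable patients.
  Replacements are counted separately and excluded from expected-sample
  -size arithmetic.
* EPD: progression observed at or before $t_{first}$ in a non-responder.
  Response and EPD are mutually exclusive readings of the same first scan
  (a patient cannot simultaneously meet shrinkage and growth criteria),
  which also guarantees $r_1 + epd \le n_1$. A responder's latent
  progression time still enters the Kaplan–Meier estimate unchanged.

### The Kaplan–Meier median convention

The median TTP of a simulated trial is the smallest observed event time at
which the product-limit estimate falls **strictly below** 0.5. A step that
lands exactly on $S(t) = 0.5$ leaves half the cohort progression-free, so
it does not yet define the median: for an uncensored even sample of size
$n$ the median is the $(n/2+1)$-th order statistic. This differs from the
`survival::survfit()` rule (first time with $S(t) \le 0.5$, the
$n/2$-th order statistic); the two agree whenever the estimate does not
step exactly onto 0.5. The distinction is far from cosmetic at these
sample sizes: with $n = 30$ and a true median of 6 months, the probability
that the estimated median reaches 5.25 months is about 0.75 under the
strict rule and about 0.69 under the $\le$ rule, and only the strict rule
reproduces the operating characteristics and selected thresholds of the
reference design table this engine was validated against. A median never
reached (heavy censoring) is returned as `Inf` and therefore counts as
exceeding any TTP threshold — a median beyond follow-up is evidence of
long TTP, not of inactivity.

## Operating characteristics

For fixed rules, `operating_characteristics()` estimates:

* **alpha** — rejection probability at the null scenario
  (RR $= r_{nul}$, median TTP $= ttp_{nul}$);
* **power** — rejection probability under a 50/50 *mixture* alternative:
  half the trials have RR $= r_{alt}$ with median TTP drawn uniformly
  between `min_median_ttp` (the absolute floor on a plausible median,
  default 1 month) and $ttp_{alt}$; the other half have median TTP
  $= ttp_{alt}$ with RR drawn uniformly between 0 and $r_{alt}$. The
  mixture encodes "the drug is good on one endpoint, agnostic on the
  other"; uniform is the minimal-assumption law for the undetermined
  endpoint, and the pooled rejection fraction is the reported power;
* **PES / EN** — the stage-I stop probability and the expected enrolment
  through the exact identity $EN = n_1 + (1 - PES)\,n_2$ (replaced
  patients are excluded here and reported separately).

Every estimate carries its binomial Monte-Carlo standard error.

## Threshold search

`design_csr()` derives the four thresholds in the order the decision rule
uses them, from one pair of simulation banks (null and mixture). Because
thresholds are pure functions of per-trial summaries — stage-I response
and EPD counts, cumulative responses, KM median — the banks are simulated
once and re-thresholded across the whole candidate grid, which makes the
search hundreds of times cheaper than re-simulating per candidate and
keeps all comparisons internally consistent.

* **Stage II.** Candidate response thresholds run over
  $1 \ldots n_1+n_2$ in single patients; candidate TTP thresholds over
  $[ttp_{nul},\, ttp_{alt}+2]$ months in quarter-month steps (values above
  $ttp_{alt}$ are allowed but flagged). For each response threshold the
  paired TTP threshold is placed at the *power boundary* — the largest
  grid value whose estimated power still meets the floor — which is also
  the minimum-alpha choice among power-admissible values. The selected
  pair is the largest response threshold whose boundary pair also meets
  the alpha limit; preferring the higher response threshold pushes the
  required response rate toward $r_{alt}$, with the TTP threshold
  compensating to maintain power.
* **Stage I.** Given the stage-II pair, all reachable
  $(r_{1nul}, epd_{1nul})$ pairs are enumerated and the one maximising the
  null early-stopping probability is selected, subject to the overall
  power (now including what stage-I stopping costs) staying at the floor.
  Ties prefer the smaller EPD threshold, then the larger response
  threshold: stop decisions should be driven by the progression signal,
  which is the module's purpose. Stage-I stopping can only lower both
  alpha and power, so the reported final alpha is at most the stage-II
  search value.
* **Power admissibility within Monte-Carlo error.** Both searches accept a
  candidate when its estimated power is within two Monte-Carlo standard
  errors of the floor. A hard cut on a noisy estimate would bias
  selection toward candidates that got lucky in the bank and make the
  selected stage-I rule flip between adjacent pairs from seed to seed;
  the two-standard-error allowance makes the selection stable while
  keeping the true power of selected designs at the floor to within
  sampling error (the reported estimate always carries its SE).
* **Infeasible alpha.** If no stage-II pair meets the alpha limit at the
  required power, the minimum-alpha pair among power-admissible ones is
  returned with a warning, and the stage-I search is skipped in favour of
  the never-stop sentinel $(r_{1nul}, epd_{1nul}) = (-1, n_1+1)$: with
  the type I error already above its limit the design has no error budget
  left to trade, and early stopping would only sacrifice power. This is
  the regime in which small trials print sentinel stage-I rows and
  inflated alphas.
* **Relaxation.** If stage II met both limits but no stage-I pair with
  positive stopping probability survives the power constraint, one
  relaxation round loosens stage II by a single grid step (TTP down a
  quarter month, or the response threshold down one patient) and repeats
  the stage-I search — buying early stopping at the price of a higher
  type I error. One round only; if it fails the sentinel stands.

## Defaults and the conditions they encode

| parameter | default | why |
|---|---|---|
| `t_first` | 1.5 mo | a standard six-week restaging interval; at the null of the reference small-trial design it gives a stage-I stop probability of ~0.2, consistent with the closed-form binomial check $P(\mathrm{Bin}(15,.05)\le 0)\,P(\mathrm{Bin}(15,.95\times.293)\ge 5)\approx 0.19$ |
| `censor_prob` | 0.05 | typical phase II TTP censoring; operating characteristics move little up to 0.10 |
| `min_median_ttp` | 1 mo | a median TTP below one month is not a plausible drug effect; lower bound of the mixture draw |
| `alpha_max`, `power_min` | 0.05, 0.80 | conventional one-sided phase II error limits |
| `n_sim` | 100&nbsp;000 | binomial SE $\approx 0.0013$ on power near 0.8 |
| `ttp_grid_step` | 0.25 mo | the resolution at which TTP thresholds are clinically meaningful |

## Worked example

The reference small-trial design ($r_{nul}=0.05$, $r_{alt}=0.2$,
$ttp_{nul}=3$, $ttp_{alt}=6$, $n_1=n_2=15$):

```{r design, eval = FALSE}
hyp <- csr_hypotheses(0.05, 0.2, 3, 6)
cfg <- csr_config(n1 = 15, n2 = 15, n_sim = 20000, seed = 1)
design_csr(hyp, cfg)
#> stage I : accept H_nul if responses <= 0 and EPD >= 5
#> stage II: reject H_nul if responses >= 5 or KM median TTP >= 5.25 mo
#> power 0.802, alpha 0.030, null EN 27.0 / PES 0.203
```

Against the classical single-endpoint comparators at the same response
hypotheses — `simon_optimal(0.05, 0.20)` (stop after 10 patients with
probability 0.599 under the null) and `fleming_two_stage(0.05, 0.20, 15, 15)`
(stop probability 0.463, exact alpha 0.058) — the CSR stops early far less
often (PES ≈ 0.2). That is the price of testing two endpoints at once: a
trial must look inactive on *both* RR and EPD before stopping.

## What the simulations do and do not show

The generator reproduces the study conditions the design is defined under:
Bernoulli response independent of exponential progression, a fixed scan
time, uniform-before-progression censoring at a fixed rate with pre-scan
replacement, and no accrual calendar. Real trials differ in ways the model
does not capture: progression is detected at discrete restaging visits
(observed TTP is interval-censored upward), hazards are rarely constant,
censoring is seldom independent of prognosis, response and progression are
correlated within patients, and accrual may pause between stages. Passing
the package's tests therefore validates the engine's arithmetic and its
agreement with the reference design table under the stated model — not the
clinical adequacy of the exponential-progression assumption for any
particular disease. Problem sizes used in the test suite (banks of
20 000–100 000 trials, full-scale evaluations at 100 000) were chosen so
that Monte-Carlo standard errors are an order of magnitude below every
tolerance asserted.

## Known limitations

* TTP only; progression-free survival (death as an event) would need a
  survival hazard on top of the progression model and is not implemented.
* Stage sizes $n_1, n_2$ are inputs, not optimised; there is no
  minimax/optimal search over sample size as in single-endpoint designs.
* The mixture alternative weights "good RR" and "good TTP" drugs equally;
  other priors would change the reported power.
* Thresholds far from the reference table's conditions (very small
  hypothesis gaps, alpha limits that cannot be met) are reported with
  warnings rather than refused, matching how such rows appear in the
  reference table.
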