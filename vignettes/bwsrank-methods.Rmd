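---
title: "Methods: blocked best-worst scaling for outcome prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blocked best-worst scaling for outcome prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwsrank)
```

## The problem

Core-outcome-set and comparative-effectiveness work needs to know *which*
treatment outcomes matter most to patients. Benefits are few and can be
ranked directly; harms number in the hundreds even after grouping, so a
survey can only ask each respondent about a subset. `bwsrank` implements
the standard compromise: a fixed 7-item benefits ranking task for
everyone (six specific benefits plus one aggregate "side effects" item),
and a 21-item harm catalog split into 12 ranking sets of 7 so that each
harm appears in exactly 4 sets, with respondents routed to a set by birth
month. Harms are then scored by best-worst scaling and the per-set scores
averaged into one ordering.

Because surveys of this kind rarely release microdata, the package treats
the *synthetic-data generator* as a first-class module: every downstream
stage is exercised, and its statistical behavior quantified, against
simulated respondents with known preferences.

## The ranking model

Complete rankings are simulated from a Plackett–Luce (PL) model. Each
item has a latent utility (log-worth) $u_i$; the item ranked 1 is drawn
with probability $e^{u_i} / \sum_j e^{u_j}$ among the items on offer, the
item ranked 2 likewise among the rest, and so on. We implement the exact
equivalent Gumbel-max representation (rank items by $u_i + G_i$,
$G_i \sim$ standard Gumbel, descending), which vectorizes cleanly.

PL was chosen because it is the canonical latent-worth model consistent
with an exhaustive best-to-worst ranking task, and because it gives the
recovery diagnostics a well-defined ground truth: the true item ordering
is descending $u_i$ (ties broken by item id, the same tie-break the
scorer uses, so perfect recovery corresponds to Kendall tau exactly 1).
Utilities are identified only up to an additive constant; the test suite
checks this invariance explicitly.

## Best-worst scores

Within a set with $n$ complete rankings,
$$\mathrm{BWS}_i = \frac{\#\{\text{ranked } i \text{ first}\}}{n} -
                   \frac{\#\{\text{ranked } i \text{ last}\}}{n}.$$
Every respondent contributes exactly one "best" and one "worst", so the
seven scores of a set sum to zero exactly and each lies in $[-1, 1]$. An
item's overall score is the *unweighted* mean of its four per-set scores
(a literal reading of averaging "across the sets"; an $n$-weighted mean
is available via `bws_average(..., weighted = TRUE)` but is off by
default). Middle ranks (2–6) are deliberately discarded — that is what
the best-worst statistic does; full-ranking estimators such as
rank-ordered logit are out of scope.

One sign convention needs care: the score is defined here as
$P(\text{ranked 1}) - P(\text{ranked 7})$, so *positive* scores mean an
item was more often the most important. A sentence describing the same
computation as "subtracting the proportion ranked 1 from the proportion
ranked 7" would flip the sign and contradict the interpretation "scores
greater than 0 were ranked 1 more often"; we follow the interpretation
and the standard best-minus-worst convention.

## The block design

With 21 items in 12 blocks of 7, each item must appear in
$12 \times 7 / 21 = 4$ blocks (`required_replication()` checks this
feasibility arithmetic for any parameters). Pairwise co-occurrence cannot
be constant: 12·C(7,2) = 252 co-occurrence slots spread over C(21,2) =
210 pairs, a mean of 1.2 per pair, so no BIBD exists. One might hope to
confine counts to {1, 2}; this is provably impossible. Writing the
co-occurrence matrix as $C = N^\top N = 3I + J + D$ (with $N$ the 12×21
incidence and $D$ the adjacency matrix of the 4-regular graph of
twice-co-occurring pairs, 42 edges), $\mathrm{rank}(C) \le 12$ forces $D$
to have eigenvalue $-3$ with multiplicity at least 9, whence
$\mathrm{trace}(D^2) \ge 4^2 + 9\cdot 3^2 = 97 > 84 = 2\cdot 42$ — a
contradiction. The best achievable designs (empirically, squared
co-occurrence sum 372 versus the naive bound 336) have counts in
{0, 1, 2} with about 18 never-co-occurring pairs.

`generate_design()` therefore *minimizes co-occurrence variance* rather
than promising balance: a seeded randomized greedy fill (deal each item's
four copies into the emptiest admissible blocks) followed by
pairwise-swap hill-climbing on the sum of squared co-occurrences, wrapped
in an iterated local search (3-swap kicks, re-climb, keep the best) with
restarts. Plain hill-climbing alone stalls around sums of 390–450; the
kicks reliably reach 372 at the canonical scale in a few seconds. The
search is deterministic given `seed`, and the global RNG state is
restored on exit. Blocks are unordered internally; presentation order is
catalog order; month *m* maps to set $((m-1) \bmod b) + 1$ (January =
set 1), the natural order, since nothing constrains this choice further.

## The synthetic respondent world

Defaults describe a plausible chronic-pain patient-group survey and are
fixed once, not tuned:

| parameter | default | note |
|---|---|---|
| respondents `n` | 746 | completed-survey count emulated |
| invited | 4130 | flow denominator |
| % female | 92% | |
| age | median 52, IQR 8 (rounded normal) | survey year 2015 |
| PPI | integer 0–10, median 4, IQR 3 | scale max configurable |
| comorbid pain / current meds / past meds | Poisson, means 3 / 3 / 6 | |
| trade-off answer | benefits .60 / harms .28 / equal .12 | ~1.3% skip |
| p(missing demographics) | 0.051 | ≈ 38/746 |
| p(incomplete benefits) | 0.143 | ≈ 101/708 |
| p(incomplete harms) | 0.155 | ≈ 110/708 |
| p(non-TMJ condition) | 0 | no published rate exists |

The present-pain-intensity scale is not fixed by the summary statistics
it must reproduce (a 0–5 or a 0–10 scale both admit median 4, IQR 3); we
default to 0–10 and keep the maximum configurable rather than committing
to a specific instrument.

What the generator deliberately does **not** emulate: correlated
dropout (the four censoring channels are independent, whereas real
respondents who quit mid-survey fail several criteria at once — so the
simulated union of the two analysis cohorts is larger than a real
survey's), demographic effects on preferences (demographics are dressing
unless the user supplies group-specific utilities; the cross-set balance
check expects exchangeable groups), response styles, and any relationship
between item labels and utilities. A green test therefore establishes
correctness of the *pipeline arithmetic* and the estimator's sampling
behavior under PL — not realism of any particular utility configuration.

Missing values are encoded as empty CSV cells, never sentinel numbers
(sentinels would corrupt the bijection checks); ranks are stored exactly
as asked (1 = most important), with no internal reversal.

## Inclusion cascade

Filters apply in a fixed order: qualifying condition → demographics (age,
sex, PPI all present) → ranking completeness. Completeness is
task-specific and the two criteria combine as a disjunction: a respondent
complete on only one task enters only that task's cohort, and the final
included count is the union. `flow_counts()` enforces the arithmetic
identities (base = responded − condition exclusions − demographic
exclusions; each cohort = base − its exclusion; union bounded by base and
by each cohort) at construction time, so a flow table that reaches the
caller is internally consistent by definition.

## Numerical choices

* Quartiles (hence IQRs) use linear interpolation (`stats::quantile`
  type 7) by default; the `qtype` argument exposes the other rules since
  published IQRs depend on the convention of the software that produced
  them.
* All orderings break ties deterministically: benefits by median, then
  IQR, then item id; BWS by averaged score, then item id.
* Zero-sum of per-set BWS scores is exact in integer arithmetic
  (`score × n` recovers best-minus-worst tallies); tests assert it there
  rather than on floating-point sums.
* Seeds: every stochastic entry point takes an explicit integer seed,
  derives sub-seeds below 2^31 where replication grids are involved, and
  restores the caller's RNG state.

## Known limitations

Two acceptance expectations are deliberately left failing, because the
properties they assert are unattainable, not because the code falls
short:

1. **Co-occurrence confined to {1,2}** at (21, 12, 7): impossible by the
   rank/trace argument above.
2. **Perfect recovery of the 21-harm ordering** (tau = 1 in ≥95% of
   replicates) from ~400 respondents per set with unit utility gaps.
   Computing *expected* scores at 200,000 respondents per set shows two
   obstacles. First, 21 items with adjacent gaps ≥ 1 span ≥ 20 log-worth
   units, so a mid-pack item is ranked 1 or 7 with probability on the
   order of $e^{-5}$; adjacent expected-score differences (~0.001) are an
   order of magnitude below the sampling noise of a BWS score at n ≈ 400
   (SE ≈ 0.02). Second, because some pairs never share a set, an item
   that never faces the strongest items sees systematically weaker
   competition and its average score is biased upward — the estimator is
   biased at the full-ordering level, and no sample size fixes that.
   Recovery *is* achieved where the structure permits it: with a single
   shared block of 7 items, or with equal utilities (mean tau ≈ 0), both
   covered by tests.

Beyond those: BWS scores here come without confidence intervals, no
preference-model fitting is provided (simulation only), harms are
compared only by identity — not severity or duration — and the
cross-set balance table is descriptive, with no hypothesis test attached.
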