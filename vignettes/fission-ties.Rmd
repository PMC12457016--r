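---
title: "Methods: social tie persistence and group choice after fission"
author: "fissionties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social tie persistence and group choice after fission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fissionties)
```

# The problem

When a stable social group of philopatric females splits permanently into
two daughter groups, each female effectively chooses — for the only time in
her life — who her groupmates will be. `fissionties` implements a complete
analysis chain for asking *which relationships females preserve*: from raw
behavioural observation records to dyadic tie strength, dominance,
kinship and reproductive attributes, and finally to two complementary
statistical models:

* an **edge-persistence model**: among all pre-fission female dyads, which
  ties survive (both members in the same daughter group)?
* **conditional-logit group-choice models**: does a female follow the
  original group's resident male, and does this depend on her infanticide
  risk?

The package also ships a synthetic-data generator with known ground truth,
so every stage — and both estimators — can be validated end to end without
any field data.

# From records to covariates

## Dyadic sociality index (DSI)

Tie strength for a female dyad \((i, j)\) over an annual window is

\[
\mathrm{DSI}_{ij} \;=\; \frac{1}{2}\,\frac{G_{ij}}{G_{med}}
 \;+\; \frac{1}{4}\left(\frac{R_{ij}}{R_{med}} + \frac{R_{ji}}{R_{med}}\right),
\]

where \(G_{ij}\) is time spent grooming together per minute of the pair's
combined focal observation, and \(R_{ij}\) is the rate at which \(i\) was
recorded resting within 1 m of \(j\) per minute of *i's own* focal time.
The proximity terms stay directional because they have different
denominators. Medians are taken over all included dyads of the same group
and window, so DSI = 1 means "exactly as affiliative as the median dyad of
this group"; the index is invariant to any group-wide rescaling of
behaviour rates or observation effort.

Interpretation choices the formula leaves open, and how we resolved them:

* **Denominator of \(G_{ij}\)**: the sum of both members' focal minutes.
  This is symmetric in the pair and robust to uneven sampling. When only
  one member was ever a focal subject, her minutes alone form the
  denominator.
* **Proximity records**: only resting-within-1 m scans count. Feeding
  proximity is recorded at a 7 m radius (a different quantity), and
  grooming co-occurs with the grooming term; both are excluded
  (`rest_only = TRUE`, overridable).
* **\(R_{med}\)**: one pooled median over both directed rates of every
  dyad, because the formula uses a single normaliser for both terms.
* **Single-focal dyads** get weights \((\tfrac12, \tfrac12)\) on grooming
  and the lone proximity term.
* **Zero medians** are an error by default — a group so inactive that the
  median dyad never grooms makes the index meaningless — with an optional
  `drop_term` fallback that renormalises the remaining weights.

## Eligibility and consistency classes

Dyads enter the analysis if both females were parous for at least half of
the pre-fission year (coverage \(\ge 0.5\), boundary inclusive; the window
is the 365 days ending the day before subgrouping onset). A tie is
*consistently strong* if DSI > 1 in both the pre-fission year and the year
before, *consistently weak* if \(\le 1\) in both, otherwise *inconsistent*
(the reference class in the model). A DSI exactly at the threshold —
measure-zero in the field, common in symmetric test fixtures — bins with
the weak side so the classification is total. For the earlier year the
eligibility rules are relaxed: a female who was not yet adult contributes
through her partners' follows via the single-focal variant.

## Dominance: the I&SI ordering

Agonistic records with clear outcomes, restricted to the fission's calendar
year up to the fission date, form a winner:loser count matrix per group.
`isi_order()` seeks the linear order minimising, lexicographically, the
number of inconsistencies **I** (dyads where the lower-ranked individual
won the majority of contests) and then their summed strength **SI** (rank
distances of inconsistent dyads). Ties in win counts and never-interacting
dyads are not inconsistencies.

The search is a two-phase heuristic — David's-score initialisation, then
pairwise-swap hill climbing under seeded random restarts — and is
deterministic given matrix and seed. Degenerate optima are counted and
reported. For \(n \le 8\), `isi_exhaustive()` enumerates all orderings;
the test suite pins the heuristic to the exhaustive optimum on random
matrices up to \(n = 7\). One worked case worth recording: for a circular
triad (A>B, B>C, C>A, one win each) every ordering has exactly one
inconsistency and the best attainable value is \((I, SI) = (1, 2)\) — the
inconsistent dyad always spans the full rank range.

Rank distance (steps between two ranks) is Z-scored over the pooled dyads
of **all** fissions entering the model, since the model is fitted jointly;
standardising within fission would let hierarchy size alter the scale of
the covariate.

## Relatedness, reproductive state, residency

Maternal pedigree links give a coarse relatedness scheme:
mother–offspring 0.5; sisters and grandmother–granddaughter 0.25;
aunt–niece 0.125; first cousins 0.0625; any *detectable* more distant
maternal-line path 0.03125; unrelated or undetectable 0. This equals
\(0.5^{d_i + d_j}\) (generations to the closest common maternal ancestor),
floored at 0.03125, with the closest relationship winning. Only recorded
links count: a link through an unrecorded female does not exist for the
pedigree.

A female is **pregnant** at a date if she gives birth within the following
176 days (the species' gestation), **lactating** if she has a living infant
under 365 days old (an infant's death ends lactation immediately), and
**at risk of infanticide** if either holds. A birth on the reference date
itself counts as lactation, not pregnancy, so the two states partition
cleanly.

A male is **resident** once he has been the sole male for at least seven
consecutive *observation* days (census days — monitoring has gaps, so this
can exceed a calendar week), with tenure backdated to the first day of the
qualifying run; backdating makes tenure-length checks such as "resident
for a full gestation before fission" conservative. He loses the status
after seven consecutive observation days of complete absence, the interval
closing on his last day seen.

# The two models

## Edge persistence

The inferential target is the persistence (dissolution) component of a
separable temporal ERGM between two timesteps — pre-fission network to
post-fission network — under a block-diagonal constraint that restricts
dyads to the same parent group. Every model term is dyad-independent: edge
covariates (consistency dummies, relatedness, Z-scored rank distance), one
nodematch term (both females share the same infanticide-risk state), and
the relatedness × risk-match product. Under dyad-independent terms the
STERGM persistence likelihood factorises exactly into independent
Bernoulli contributions,

\[
\ell(\beta) = \sum_d \left[ y_d\, x_d'\beta - \log(1 + e^{x_d'\beta}) \right],
\]

so we maximise this likelihood directly by Newton–Raphson instead of MCMC:
exact, fast, and testable against both a dense grid search and `glm()`.
Wald standard errors come from the observed information. The intercept is
the *baseline edge persistence*: with all covariates at zero (an
inconsistent, unrelated, risk-mismatched dyad at average rank distance),
`plogis(intercept)` is the fitted persistence probability, and an
intercept-only model reproduces the empirical persistence rate exactly.
Standard errors are reported on the log-odds scale, with a delta-method
column (`or_se`) on the odds-ratio scale, since published coefficient
tables are ambiguous about which scale "s.e." means next to an odds ratio.

Model comparison is by AIC (`compare_models()`); no multiple-testing
adjustment is applied, matching standard practice for these models.

Degenerate inputs: a fission whose smaller daughter group holds fewer than
two analysis females leaves all dyads defined (they simply all persist
within the larger group) and emits a warning. Complete separation and rank
deficiency abort with named diagnostics rather than returning divergent
estimates; separation genuinely occurs in sparse interaction covariates —
kin dyads are ~13% of the data — and silently huge coefficients would be
worse than an error.

## Group choice

Each female facing a fission contributes one choice set with two
alternatives (the daughter groups) and exactly one chosen row. The
conditional-logit likelihood

\[
\prod_c \frac{e^{\eta_{c,\mathrm{chosen}}}}{\sum_a e^{\eta_{c,a}}}
\]

has no intercept: anything constant across a female's two rows cancels.
Hence her DSI with the resident male — an attribute of the *female*, not of
an alternative — can enter only through its interaction with resident-male
presence. We keep that DSI uncentered, so the `resident_present` main
effect is the effect for a female with DSI 0 (no recorded affiliation with
the male); centering would change the main effect's meaning, and any
reanalysis should state its coding. Females present at two fissions
contribute independent choices, classified into the at-risk or not-at-risk
stratum per event.

The likelihood is written for any number of alternatives but validated for
two, where the MLE has a closed form against which the Newton fit is
tested: with a single binary alternative attribute chosen by \(k\) of
\(n\) females, the odds ratio is \(k/(n-k)\).

# The synthetic generator

`sim_config()` defines a study of (by default) 5 groups × 15 parous
females — about 525 within-group dyads, the scale of the motivating data —
with:

* matriline-structured pedigrees (5 founding matrilines per group), giving
  roughly 13–15% kin dyads across all relatedness categories;
* two annual windows of minute-level focal scans (400 min per female-year;
  follows are 30-minute blocks on census days). Grooming partners and
  resting-proximity sets are drawn with dyad affinities that multiply a
  tie-class factor (strong 3×, weak 0.35×; inconsistent dyads swap between
  years) by a kinship gain \(1 + 4r\). These values were chosen once so
  that the DSI classifier recovers the generating classes with high
  (not perfect) probability at the default observation effort — the
  misclassifications that remain are the realistic ones, dyads near the
  group median;
* a latent hierarchy generating ~2.5 contests per dyad-year with a 10%
  upset probability (with upsets disabled, I&SI recovers the latent order
  exactly — a test oracle);
* birth timelines targeting the observed 41% at-risk fraction, including
  dead-infant records that exercise the lactation-ends-at-death rule;
* one resident male per group with a qualifying sole-male tenure, plus
  sporadically censused visitor males (the resident is deliberately not
  sole in the pre-fission year);
* ground-truth coefficients \(\beta\) (persistence) and \(\gamma\)
  (choice) at the scale of the published estimates. The relatedness ×
  risk-match default is a moderate log 4 rather than the published point
  estimate (odds ratio 147 with a huge standard error): that estimate is
  weakly identified, and as a *generating* value it would make kin dyads
  with matching risk persist almost surely.

## Two fission modes, and why recovery uses a third path

`simulate_fission()` offers two assignment modes:

* **choice-first**: each female independently samples a daughter group
  from the conditional-logit law (her stratum's \(\gamma\), her true male
  DSI). Realistic; dyadic persistence effects appear only as induced,
  attenuated associations.
* **dyad-target**: the larger daughter's share is drawn from the observed
  0.65–0.82 range, then the composition is sampled from the partition
  Gibbs measure that weights each dyad by its persistence odds
  \(e^{\beta'x}\) when co-assigned — exactly, by enumerating all size-k
  bipartitions (Metropolis swaps for groups too large to enumerate).

Two facts about this construction deserve emphasis, because they are the
reason the estimator-validation arm exists:

1. The *unconditional* Gibbs measure over bipartitions is degenerate at
   realistic coupling scales: its mode is "everyone in one group". This is
   the classic ERGM degeneracy, and is why the split size is conditioned
   on separately.
2. No distribution over partitions can make the dyadic outcomes follow the
   independent logistic law: same-group membership is transitive, so
   outcomes like \(y_{12} = y_{23} = 1, y_{13} = 0\) have probability
   zero. Empirically, refitting the persistence model to partitions
   sampled with couplings \(\beta\) *amplifies* the risk-homophily
   (nodematch) coefficient by about +2 log-odds units at the default
   configuration — attribute homophily and partition transitivity
   reinforce each other. The test suite asserts this amplification rather
   than hiding it.

`simulate_dyad_outcomes()` therefore draws each dyad's persistence
indicator directly from \(\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta'x))\)
— the data-generating process the model itself assumes. Parameter-recovery
validation (200 replicate studies; and 200 replicates of 500 independent
choices for \(\gamma\)) runs on this arm, where the Newton estimators are
unbiased within Monte-Carlo error and Wald intervals attain near-nominal
coverage. What that does and does not show: it validates the *estimators*
under their own assumptions and the full covariate-construction chain; it
does not make the dyadic-independence approximation true of real
partitions — the amplification result quantifies exactly how it fails.

## What the generator does not emulate

Seasonality and uneven observer effort; ranging and spatial structure;
demographic turnover (births and deaths only enter as reproductive-state
inputs); paternal kinship; multi-male influxes; and any behavioural change
during the subgrouping period itself (scans are only generated inside the
two annual windows). Passing tests on synthetic data say nothing about
these features of real data.

# Reproducibility and numerical conventions

* Validation problem sizes: 5 fissions × 15 females (≈525 dyads) for
  persistence, 500 choice sets for the choice model, 200 replicates each;
  I&SI oracle checks run at \(n \le 7\) against exhaustive enumeration
  (5040 orderings at most).
* All randomness flows from a single integer seed per config; the same
  seed yields byte-identical datasets, and `report_hash()` certifies that
  two pipeline runs with identical config and inputs agree.
* Dates are day-resolution; windows are closed intervals; "observation
  day" always means a census day.
* Constants (365-day windows, 176-day gestation, 365-day dependency,
  7-day residency runs, DSI threshold 1) live in `run_config()` as named,
  overridable defaults — they are biological facts about one study system,
  not properties of the method.

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_study(cfg, mode = "dyad_target")
report <- run_pipeline(run_config(dataset = sim$dataset, seed = 1))
print(report)
writeLines(render_report(report, "markdown"))
```
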