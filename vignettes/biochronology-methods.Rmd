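---
title: "Quantitative biochronology with pampachron: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative biochronology with pampachron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pampachron)
```

## The problem

Fossil vertebrate assemblages ("faunas") from a region rarely come with
radioisotopic dates. Their relative and absolute ages must instead be
inferred from faunal content: which taxa co-occur, which appear or
disappear between levels, and how assemblage composition resembles that of
the few independently dated faunas. `pampachron` packages this workflow
for presence/absence occurrence matrices (taxa by faunas), together with
the downstream dynamics one wants once a temporal order exists — richness,
per-capita origination and extinction, community-structure change — and a
40Ar/39Ar step-heating reduction for the volcanic-glass dates that anchor
the chronology.

Everything operates on three tables: a binary occurrence matrix, fauna
metadata (coordinates, age bounds, stratigraphic section), and per-taxon
trait labels (taxonomic group, diet, body-size class). Ages are in Ma
before present throughout; larger values are older, and `age_max` always
denotes the older bound of a range.

## Seriation by ordination

Faunal resemblance is measured on presence/absence data only. Two binary
coefficients are provided:

* the **corrected Forbes similarity**
  \(F' = a(n+\sqrt n) \,/\, (a(n+\sqrt n) + \tfrac32 bc)\), with \(a\)
  shared taxa, \(b\) and \(c\) exclusive taxa and \(n=a+b+c\); the
  joint-absence cell is ignored so that shared sampling gaps do not fake
  similarity. The \(3/2\) constant is defined in exactly one place in the
  source so the formula can be amended if the literature is re-read
  differently.
* the **binary Bray–Curtis** (Sørensen) dissimilarity
  \(d=(b+c)/(2a+b+c)\).

Distance matrices feed three ordinations: non-metric multidimensional
scaling (Kruskal stress-1 via `vegan::monoMDS`, 2 axes, 50 starts — the
first from classical scaling, the rest random, best stress kept),
principal coordinates (classical scaling; negative eigenvalues are
reported but never corrected, axis scores use positive eigenvalues only),
and correspondence analysis of the raw matrix (`vegan::cca`). Because
ordination axes are sign-arbitrary, every axis is flipped, when known ages
exist, so that its Spearman correlation with age is nonnegative; this
keeps downstream regression signs stable across runs.

## Appearance event ordination

The AEO module seriates faunas on a composite sequence of first- and
last-appearance events. The evidential atom is the *conjunction*: two taxa
demonstrably coexisted if they share at least one fauna. A candidate
temporal order of the faunas implies, for every taxon, a range (first to
last occupied fauna); two overlapping ranges assert a coexistence. Orders
are penalised for coexistences they assert but that were never observed:
with \(\hat r_t\) the fraction of its span a taxon actually occupies, each
fauna in an implied-but-unobserved overlap of taxa \(t\) and \(u\) costs
\(-\ln(1-\hat r_t \hat r_u)\), the log-probability of jointly failing to
sample the pair. Minimising this total is a maximum-likelihood-flavoured
seriation criterion that is fully explicit and testable; recovering the
exact internals of legacy desktop software is deliberately out of scope,
and acceptance is defined as ordering recovery on synthetic successions.

Searching at the level of fauna permutations (rather than raw event
sequences) makes the hard constraints free: observed conjunctions and
F-before-L hold automatically, and stratigraphic superposition within a
section is enforced as precedence constraints on the permutation
(infeasible constraint sets are reported with a violating cycle). The
search is hill climbing over single-fauna relocations from 20 restarts
(the first seeded by CA axis 1, the rest by random shuffles repaired to
feasibility). Fauna scores are the midpoints of each fauna's admissible
event-rank interval, normalised to [0, 1] and oriented to grow toward
younger faunas (anchored by known ages where present, else by the section
chains). Uncertainty comes from bootstrapping taxa with replacement (100
replicates by default), each replicate re-optimised from the point
estimate.

## Parsimony analysis of endemicity

PAE treats faunas as terminals and taxa as binary characters. Tree length
is a two-state Sankoff dynamic programme vectorised over characters, under
either the standard symmetric cost (Fitch) or an irreversible cost where
losses are forbidden, state 0 is ancestral and even an all-present
character pays its single origin on the root edge — so only shared
presences can group faunas. The search uses random stepwise addition
followed by branch swapping on a package-internal unrooted tree structure;
tree bisection-reconnection is the default neighbourhood, with SPR
available. All distinct topologies at the best length are retained
(canonical split hashing), and a plateau sweep collects tied optima
reachable through equal-length rearrangements. Strict (optionally reduced)
consensus and symmetric resampling — each character up- or down-weighted
with probability 0.33, support reported as recovery frequency and
frequency difference (GC) — complete the module. The 0.33 perturbation
probability is the common default; the source material names the method
but not the probability.

## Age calibration by quantile regression

Ordination and AEO scores of the dated faunas are regressed on their ages.
The calibration deliberately uses quantile regression: the median line
(τ = 0.5) gives point ages while outer quantile lines (τ = 0.05/0.95 by
default; the levels are a package choice, as only per-fauna maxima and
minima are conventionally reported) give age bounds. Because a linear
two-parameter τ-fit always admits an optimum interpolating two data
points, the fit is computed exactly by enumerating point pairs and
minimising the check loss — no iterative solver, deterministic to the last
bit, with ties broken toward the flattest line.

Equations are screened by **prediction percentage error**,
\(\mathrm{PPE} = 100 \cdot \mathrm{mean}\,|y-\hat y|/\hat y\) on the
calibration faunas (predicted-value denominator, the %PE convention; an
observed-denominator and a leave-one-out variant are flags). Equations
under 10% are used; each contributes point and bound predictions, and the
per-fauna medians across equations are reported. PPE is computed in-sample
by default — the source procedure does not state otherwise — with LOO
exposed. Scores can also be correlated with latitude/longitude (Spearman,
with ρ² as percent variation explained) to diagnose geographic rather
than temporal gradients.

## Diversity and turnover

Given a temporal order, each taxon's range is closed ("range-through") and
classified against every bin by the four boundary-crosser classes:
range-through both boundaries (`Nbt`), bottom crossers ending in the bin
(`NbL`), originations crossing the top (`NFt`) and bin-confined taxa
(`NFL`). Foote's per-capita rates follow as \(q=-\ln(N_{bt}/N_b)\) and
\(p=-\ln(N_{bt}/N_t)\); they are per bin, not per Ma, because several
faunas lack duration estimates (a duration argument exists). Bins with no
two-boundary crossers yield `NA`, flagged, never infinities. Approach 1
reports observed richness, approach 2 range-through richness; pseudo-fauna
composites appended at the sequence ends let edge faunas have boundary
counts while staying out of richness reporting.

Classical rarefaction draws 40% of each fauna's occurrence records
without replacement, 1000 times, and recomputes everything; on binary
data the per-fauna subsampled richness equals the quota by construction,
so the analytic check of the machinery is the pooled hypergeometric
rarefaction curve \(E[S_n]=\sum_t 1-\binom{N-m_t}{n}/\binom{N}{n}\),
which the Monte-Carlo mean must match.

Community structure uses counts of member taxa by taxonomic group, diet
or body-size class, compared between successive faunas with a multinomial
log-likelihood statistic: \(\Delta LL\) is the gap between the next
fauna's log likelihood under its own proportions and under the previous
fauna's proportions (nonnegative by Gibbs' inequality), with 0.5 added to
every reference category so unobserved categories stay finite without
dominating small samples. Change is called significant above 2
log-likelihood units, the conventional cutoff; the raw statistic is
reported (no per-taxon normalisation) with the vocabulary fixed: eleven
mammalian groups, five diet classes, seven body-size classes (I: <100 g
… VII: >1000 kg).

## 40Ar/39Ar step heating

The age equation \(t=\lambda^{-1}\ln(1+JR)\) converts radiogenic
40Ar*/39Ar ratios to ages, with first-order error propagation over R and
J; J is solved from a Fish Canyon sanidine monitor at 28.201 ± 0.046 Ma
with λ = 5.463×10⁻¹⁰ /yr (both printed into every result and overridable).
A **plateau** is a contiguous run of ≥3 steps releasing >50% of the 39Ar
whose ages pairwise overlap at 2σ (the strictest reading of the
concordance rule; a weighted-mean-overlap variant sits behind a flag),
aged by the inverse-variance weighted mean with its error inflated by
√MSWD when scatter exceeds the analytical errors — the usual lab
convention. The **inverse isochron** (36Ar/40Ar vs 39Ar/40Ar) is fitted
by York's errors-in-both-variables regression with optional error
correlation; its y-intercept reciprocal is the trapped 40Ar/36Ar and its
x-intercept the radiogenic ratio. The preferred interpretation recomputes
per-step 40Ar* with the isochron's trapped composition and re-detects the
plateau; the trapped-ratio uncertainty is a systematic shared by all
steps, so it is added to the plateau error as an age shift at ±1σ rather
than folded into per-step errors (which govern concordance). The
atmospheric 40Ar/36Ar defaults to 298.56 with the legacy 295.5 available.

## Synthetic data: what it emulates and what it does not

`simulate_succession()` draws taxon ranges from a discrete birth–death
process: survival across a bin boundary with probability \(e^{-q^*}\),
new taxa per bin Poisson with mean \(N(e^{p^*}-1)\) over the
bottom-crossing cohort, so complete sampling recovers the true rates in
expectation; detection is Bernoulli per occupied bin. Defaults — 10
faunas spanning 9.5–2 Ma, per-bin rates 0.35, detection 0.8, about 60
taxa, 60% of faunas dated, faunas paired into sections — describe a
moderately turned-over, well-sampled succession of the kind the package
targets. The generator assigns trait labels independently of ranges (an
optional coupling knob exists for power studies), has no geographic
structure, no taphonomic covariance between taxa, and no
abundance information; passing tests therefore demonstrate correctness of
the algorithms under the stated sampling model, not robustness to every
bias of real fossil data.

`simulate_spectrum()` builds step-heating spectra from a single trapped
component of configurable 40Ar/36Ar plus a per-step trapped-amount
profile. The default concentrates trapped argon in the early steps with
composition 1200 — well above atmospheric — so the default spectrum shows
the classic excess-argon signature: inflated early apparent ages under an
atmospheric reduction, a tail plateau near the true age, and an inverse
isochron that recovers both the true age and the trapped composition.
Because all steps share one trapped component, every simulated spectrum
lies on an exact isochron; multi-component trapped argon is not emulated.

## Numerical choices and degenerate inputs

Single-fauna matrices score 0.5 in AEO by convention. All-singleton
matrices, empty faunas, constant predictors, non-binary cells, duplicate
identifiers, contradictory section constraints and sub-three-step spectra
are rejected with specific errors; absence of a plateau is a `NULL`
result, not an error. Quantile-fit ties break toward the smallest
absolute slope then intercept; plateau ties break toward the largest gas
fraction then lowest MSWD; equally parsimonious trees are deduplicated by
canonical split hash. Whether Lazarus filling runs before or after
singleton removal is left to the caller (both orders are valid
compositions of the two exported functions); analyses here drop
singletons first.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: ordering recovery on
the default 10-fauna succession; Foote-rate recovery over 100 replicates
of 200-taxon, 12-bin successions at complete sampling; exhaustive
parsimony enumeration up to 7 faunas against the heuristic search;
500-replicate spectrum recovery at 2σ; and 1000-iteration rarefaction.
These sizes were chosen as the smallest at which the statistical
assertions have useful power. The 2σ recovery assertion deserves a note:
for perfectly calibrated Gaussian errors the true coverage of a 2σ
interval is 95.45%, and plateau-step selection costs a few tenths more,
so the realised rate of a finite replicate set fluctuates around ~95%; a
run landing just below that line indicates binomial fluctuation, not
method error — the z-scores of the recovered ages are unit-normal.

## Known limitations

The AEO objective is a principled surrogate, not a reimplementation of
any legacy program's likelihood; bit-exact agreement with PAST or TNT is
a non-goal. Parsimony searches are heuristic (guarantees only come from
the exhaustive oracle sizes). Calibration is linear in the score;
strongly arched gradients (a known correspondence-analysis artefact) can
degrade it, which the PPE screen is there to catch. The Ar–Ar module
starts from background- and discrimination-corrected ratios: reactor
interference corrections and irradiation geometry are upstream of its
inputs.
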