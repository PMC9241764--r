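---
title: "Methods: profile-group dynamics in longitudinal nasopharyngeal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-group dynamics in longitudinal nasopharyngeal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmdyn)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter and their defaults, what the
simulator does and does not emulate, the numerical choices, and the known
limitations.

## The analysis problem

A longitudinal asthma cohort yields a samples-by-genera count table and
per-sample metadata: subject, collection order, scheduled time point, asthma
group (AE = at least one exacerbation during follow-up, AS = stable), and
sample type (baseline, nonexacerbation, exacerbation, control). The pipeline
asks four questions. Which dominant-genus community states persist within
subjects over time? Does community diversity drift, and differently between
AE and AS children? Are any genera preferentially "stable colonizers" of one
group? And how does the community move through an exacerbation — does it
return?

## MPG assignment and transitions

A sample's microbiome profile group (MPG) is the genus with the largest
relative abundance in that sample. Exact ties are broken toward the genus
with the higher cohort-wide mean abundance, then lexicographically; tie
events are logged because they indicate the label is fragile for that
sample. Argmax labelling is scale-invariant, so MPGs can be assigned on
counts or fractions interchangeably.

For every non-control subject with at least two samples, each adjacent pair
in collection order contributes one transition record. Extra illness visits
participate at their fractional collection positions. A record is *stable*
when both ends carry the same MPG. Exacerbation samples are included by
default (`scope = "all"`); `scope = "nonexacerbation"` removes them before
pairing, the sensitivity analysis for readers worried that event samples
drive the transitions.

## The stability test and its null

For MPG $g$, let $N$ be the total number of transition records and $p_g$ the
fraction of records whose starting (T1) endpoint is in $g$ — a sample
interior to a series appears as both a T1 and a T2 endpoint, which is the
intended bookkeeping. Under random transitions at constant state
frequencies, a record lands in $g$ at T1 *and* at T2 with probability
$p_g^2$. The observed statistic is

$$\hat{o}_g = \frac{\#\{g \to g\}}{N},$$

the share of **all** transitions that are stable for $g$. This denominator
is forced by the null: the frequency of $g\to g$ pairs conditioned on
starting in $g$ would have expectation $p_g$, not $p_g^2$, and pairing the
conditional statistic with the squared expectation would bias every MPG
toward "more stable". A 95% percentile bootstrap interval for $\hat{o}_g$ is
computed by resampling the $N$ transition records with replacement
($B = 1000$ by default); the verdict is `more_stable` if $\hat p_g^2$ lies
below the interval, `less_stable` if above, `compatible` otherwise.

Two properties of this construction are worth knowing. First, the expected
frequency is a *plug-in* estimate $\hat p_g^2$ computed from the same
records as $\hat o_g$, and the two are positively correlated; under a true
random-transition regime the `more_stable` false-positive rate is therefore
*below* the nominal one-sided 2.5% of the percentile interval, which the
test suite verifies by simulation (rates of 0–1% per MPG over 200 null
cohorts). The verdict is conservative, not anti-conservative, which is the
acceptable direction for a screening call. Second, when an MPG has no
observed stable transition at all, the bootstrap interval degenerates to
$[0, 0]$ and any positive $\hat p_g^2$ yields `less_stable`; for rare MPGs
this is the rule faithfully applied rather than evidence of active
instability, and the reported CI makes the situation visible.

The bootstrap resamples individual transition records because they are the
units whose proportion is being estimated. Records from one subject are not
independent in principle; a subject-block bootstrap
(`resample = "subject"`) is provided for sensitivity, at the price of a
random denominator.

## Stable colonization

A subject is stably colonized by a genus when **strictly more than** half of
its longitudinal samples (baseline included) carry that genus's MPG: 3 of 6
reads as exactly 50% and does not qualify, 4 of 6 does. Per genus, the
AE/AS × colonized/not table is tested with the two-sided Fisher exact test
using the point-probability rule (sum of hypergeometric probabilities of all
tables no more probable than the observed one) — the convention of
`stats::fisher.test`, and the one that reproduces the worked contingency
example (4/13 vs 0/11 giving $p = 0.098$) in the acceptance suite.

## Diversity and ordination

Alpha diversity uses Shannon entropy in base 2 (bits) with Pielou's evenness
$J = H/\log_2 S$ (undefined and reported missing for single-taxon samples)
and the observed-taxon count; the logarithm base is configurable and affects
no comparison, only the unit. Beta diversity uses Bray-Curtis on rarefied
counts (equivalent to relative abundances at equal depth) and Jaccard on
presence/absence. PCoA is classical metric scaling: double-centre
$-\tfrac12 D^2$, eigendecompose, scale eigenvectors by the square roots of
positive eigenvalues. Negative eigenvalues are reported raw by default;
a Cailliez correction is available by flag but off, so that the printed
eigenvalue spectrum shows how non-Euclidean the input was.

Counts are first rarefied to an even depth by a single seeded multivariate
hypergeometric draw (sampling reads without replacement); the default depth
is the minimum sample total so no sample is lost. One draw rather than an
average of draws keeps the downstream table an honest integer count table;
the seed is a required argument and is recorded in the run manifest. Taxa
with total frequency below 2 are removed beforehand.

## PERMANOVA conventions

`permanova()` delegates the distance-based ANOVA to `vegan::adonis2` with
sequential (order-of-entry) term decomposition, so "the group effect after
adjustment for age" is expressed by listing age before group. Permutation
p-values use the $+1$ correction, $(1 + \#\{F^* \ge F\})/(1 + n_{perm})$,
and therefore never return zero. An explicit permutation matrix can be
passed for exhaustive enumeration; the acceptance suite verifies exact
agreement with a hand-rolled Gower-centring oracle at $n = 4$.

## Mixed-effects trend models

Every longitudinal response — alpha metrics, consecutive-pair distances, and
the relative abundances of the top genera (at most 8 with cohort mean
> 1%) — is modelled as

$$y \sim \text{time} \times \text{group} + (1 + \text{time} \mid \text{subject})$$

by REML, with p-values from the sequential (type-1) ANOVA using Satterthwaite
denominator degrees of freedom. Time is the scheduled visit index 0–5; extra
illness visits, which have no scheduled index, are excluded from these
series by default. Eligibility requires at least 3 longitudinal samples per
subject. Consecutive-pair distances are assigned the later sample's time
(the transition "arrives" there); a midpoint convention is available by
flag. Abundance responses are untransformed by default, with an
arcsine-square-root option as a variance-stabilising sensitivity analysis.
When the random-slope fit fails the model falls back to random intercepts
only, then to a fixed-effects linear model, and a constant response is
returned as a flagged degenerate row; the `model` field always records which
fit produced the row. Calibration is checked by simulation: with a true
interaction of zero the rejection rate at $\alpha = 0.05$ over 500 Gaussian
cohorts (12 subjects per group, 6 visits) stays within binomial bounds, and
an interaction of 0.25 SD-units per visit is detected with $\ge 90\%$ power.

## Three-phase exacerbation analysis

Each exacerbation sample defines an event; PreE and PostE are the nearest
non-exacerbation samples of the same subject by collection order (optionally
within a maximum gap). Events with neither neighbour are excluded and
logged. Subjects contributing several events contribute several triplets,
and paired tests use one observation per event — the event, not the subject,
is the unit of analysis, which slightly understates between-subject
variability and is documented for that reason. Alpha contrasts use the
Wilcoxon signed-rank test (exact for $n \le 25$; enumeration over sign
patterns handles tied ranks up to $n = 14$, beyond which the tie-corrected
normal approximation is used). Phase summaries report per-genus means over
each phase's sample set and fold changes where the denominator is positive;
MPG switches are counted separately for the pre→exacerbation and
exacerbation→post stages.

## The simulator

`simulate_cohort()` generates the kind of data the analyses assume, with
ground truth for every recovered quantity:

* **Cohort design.** Defaults: 11 AE + 13 AS subjects × 6 visits plus 9
  one-off controls — the scale of a single-season surveillance cohort.
* **Latent states.** Each subject follows a first-order Markov chain over
  the six profile-defining genera. Off-diagonal mass is distributed
  proportionally to the base frequencies, so setting a state's
  self-probability equal to its base frequency makes consecutive states
  independent draws — the $p^2$ null holds *exactly* in that regime, which
  is what makes the calibration simulations meaningful. Defaults keep
  Moraxella and Dolosigranulum at self-probability 0.9 (persistent
  colonizers) and the rest at their base frequencies.
* **Compositions.** Given a state, the sample composition is Dirichlet
  around a template in which the dominant genus holds 65%, a residual
  "Other" pool 10%, and the remaining genera split the rest proportionally
  to base frequency; the Dirichlet precision (default 30) sets within-state
  noise. Per-genus temporal trends act multiplicatively on the template
  (additively on the log scale) before renormalisation, so compositions stay
  on the simplex; defaults give Moraxella +0.15/visit and
  Corynebacterium 1 and Anoxybacillus −0.10/visit.
* **Exacerbations.** AE subjects receive events at interior scheduled visits
  (probability 0.25 per visit, at least one forced), guaranteeing PreE and
  PostE neighbours exist by design. At an event the pathogen-analog genus
  (Moraxella) is multiplied by the bloom factor (default 3, which after
  renormalisation roughly doubles a 20–30% baseline share) and the sample is
  flagged `exacerbation`. With `recovery = TRUE` (default) the latent chain
  is untouched and the bloom is transient; with `recovery = FALSE` the
  state switches to the bloom genus.
* **Depths.** Sequencing depth is negative-binomial (mean 60,000,
  dispersion 10) floored at 22,201 reads, so rarefaction at that
  conventional depth never drops a sample.

Within-subject dispersion, trend sizes and the bloom factor are free
parameters of the generator, documented here as design choices — no
quantitative claim about any real cohort is attached to them. The simulator
does **not** emulate sequence-level artefacts (PCR bias, chimeras,
contamination), taxonomic misassignment, viral co-infection dynamics,
subject dropout, or seasonal covariates; passing tests demonstrate that the
statistical machinery recovers known structure under the stated generative
model, not that any particular real cohort satisfies that model.

## Numerical and design choices

* Seeds are explicit everywhere randomness occurs; pipeline stages derive
  their seeds from the master seed by hashing the stage name, so adding a
  stage never perturbs existing ones.
* The degenerate bootstrap interval $[v, v]$ for a constant statistic is
  reported as-is rather than widened.
* Thresholds that define the analysis (rare-taxon total < 2, colonization
  > 0.5, $B = 1000$, top-8 genera at > 1% mean, $\alpha = 0.05$) are
  configuration defaults, not hard-coded constants.
* Problem sizes in the validation suites — 200 null cohorts and 100 power
  cohorts of 24 subjects × 6 visits for the stability verdict, 500 null and
  100 powered mixed-model fits, 50 resilience cohorts — were chosen to put
  Monte-Carlo error well inside the tolerances being asserted while keeping
  the whole suite runnable in minutes on a laptop.

## Known limitations

* The MPG reduction discards within-sample structure below the dominant
  genus; a sample at 35% vs 34% is as firmly labelled as one at 90%.
  The logged `dominant_fraction` lets users audit label strength.
* The $p^2$ null assumes constant state frequencies; a strong secular trend
  (as injected for Moraxella) shifts both observed and expected frequencies
  and the verdict then mixes persistence with drift.
* The transition bootstrap ignores within-subject dependence by default
  (see above for the block option).
* Phylogeny-dependent metrics (UniFrac, Faith PD) are out of scope — the
  pipeline starts from a count table with no tree.
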