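---
title: "Ecologically informed body-site biomarkers: models and methods"
author: "siteMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecologically informed body-site biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteMarkers)
```

## Scope

`siteMarkers` bundles the computational machinery for attributing microbiome
samples to human body sites: preprocessing of OTU count tables, local causal
biomarker discovery, two-source mixture simulation with detection-limit
evaluation, calibrated Random-Forest classification, and trait enrichment.
Everything operates downstream of an OTU table; read mapping, OTU picking
and taxonomy assignment are out of scope.

## Preprocessing

Samples detecting fewer than 20 distinct OTUs are removed
(`filterLowRichness`); such ultra-shallow samples are dominated by
stochastic detection noise. Counts are normalized per sample to relative
abundances for classification, and binarized (count ≥ 1) for independence
testing — presence/absence is far less sensitive to sequencing-depth
differences between studies than abundance is.

Near-duplicate OTU profiles are indistinguishable to conditional
independence tests (each can "explain away" the other), so OTUs are
collapsed before discovery: pairs with normalized mutual information above
0.9 are grouped (`redundancyGroups`) and a seeded random representative is
kept. The default clusters on the dissimilarity `d = 1 − NMI` with
complete linkage and cuts at `d = 0.1`; complete linkage makes the
threshold exact (every within-group pair satisfies NMI ≥ 0.9). A literal
alternative — Euclidean distances between rows of the NMI matrix — is kept
as `metric = "euclidean"`, where the tree is cut at the largest height that
still satisfies the all-pairs NMI bound. Which of the two variants (and
which NMI normalization: geometric mean by default, arithmetic mean and
minimum selectable) best matches practice is genuinely open; the defaults
were chosen because they make the 0.9 threshold a testable guarantee.

## Biomarker discovery

For each site, a one-vs-rest binary indicator is tested against every OTU
with an unconditional G-test (`G = 2·N·MI`, natural logs); p-values are
Benjamini–Hochberg adjusted across OTUs and candidates with adjusted
p ≤ α = 0.05 enter in order of decreasing G (ties by OTU id — the ordering
must be total for reproducibility). FDR is applied only at this screening
stage; the conditioning stage uses raw α, since each conditional test is a
targeted elimination attempt rather than a mass screen.

Semi-interleaved HITON-PC (`hitonPC`) then admits candidates one at a time
into a tentative parents-and-children set (TPC), discarding a candidate
permanently as soon as *some* conditioning subset **Z** of current TPC
members (|**Z**| ≤ max-k = 3) renders it independent of the site
(conditional G-test, p > α). A backward pass re-tests every member against
the rest until stable. Subset enumeration is capped: only subsets of the
`h_ps = 5` most relevant TPC members are tried.

Two design choices deserve emphasis:

* **Pool ranking.** `h_ps` is an efficiency cap whose exact published
  semantics are unclear. We rank the pool by association with the
  *candidate under test* (default `pool_rank = "candidate"`), not with the
  target. The variable most likely to explain a candidate away is its own
  strongest ecological associate — for an indirectly associated OTU, its
  parent. Ranking by target association (selectable as
  `pool_rank = "target"`) can exclude the parent from the pool in
  one-vs-rest runs for *other* sites, letting indirect OTUs leak into those
  sites' marker sets; candidate ranking closes that leak.
* **Symmetry correction.** The plain forward/backward scheme can retain a
  false member whose separating set lies partly outside the target's
  neighbourhood (the classic case: T→C, S→C, S→X, C→X; separating X from T
  requires S, which is marginally independent of T and never screened in).
  `hitonPCSymmetric` applies the GLL-family correction — keep X only if T
  is recovered in X's own neighbourhood — which restores exactness under a
  faithful independence oracle. Data-driven discovery
  (`discoverMarkers`) uses the plain variant; the corrected one backs the
  oracle-equivalence validation on random DAGs, where `max_k = 3` suffices
  because in/out-degrees are bounded by 3 and the pool is left uncapped.

Surviving markers get a sign from the 2×2 determinant ad−bc (equivalently
the Spearman sign between two binary vectors): +1 marks presence-associated
(PA) OTUs, −1 absence-associated (NA) OTUs. An exactly zero determinant is
reported indeterminate and such markers are excluded from PA/NA-only
classifier subsets. Strength is the NMI with the site indicator; when a
trained forest is supplied, markers also carry the percentile of their
impurity importance among the site's markers.

The G-test itself: the statistic accumulates over conditioning strata
(empty strata skipped, zero cells contribute nothing), with
df = (levels(X)−1)(levels(Y)−1)·(#non-empty strata) and the p-value from
the upper χ² tail; df = 0 yields p = 1. Statistics below 1e−8 are treated
as exact zeros: a truly independent finite table accumulates G at machine
epsilon, and the χ² tail is square-root sensitive at the origin, so
roundoff would otherwise surface in the p-value at ~1e−7.

## Classification

Forests are probability forests (ranger) trained on relative abundances.
Hyperparameters — trees ∈ {500, 1000, 2000} and
mtry = round(m·√p), m ∈ {½, 1, 2}, floored at 1 — are selected by
stratified 4-fold inner cross-validation with macro-F1 (unweighted mean of
per-class F1) as objective; macro-F1 is also the headline report because it
is insensitive to class imbalance. Class weights are inversely proportional
to class frequency. Whether the published inner objective was macro or
sample-weighted F1 is open; macro matches reporting per-site F1 plus their
mean, and the weighted variant remains available through `f1Report`'s
`sample_weights`.

Per-class isotonic calibrators are fitted on *out-of-fold* scores of the
selected grid point (never on training-fold scores, which are optimistic).
`stats::isoreg` supplies the monotone fit; fitted values are averaged over
tied scores and linearly interpolated, and a vanishing linear term (1e−6·s)
keeps the map strictly increasing — so per-class sample rankings, and hence
every AUC, are provably unchanged by calibration. Renormalizing the
calibrated probabilities across classes *can* change rankings, so
mixture AUCs and thresholds always use the un-renormalized target-class
score.

Study effects are handled at evaluation time: `studyWeights` weights each
sample by the inverse of its study's size, so the weighted F1 rewards
models that generalize to small studies instead of overfitting the dominant
one. `learningCurveByStudy` orders studies largest-first (then seeded
random) and retrains on cumulative sets against a fixed stratified
held-out split.

## Mixtures

`mixPair` draws a mixed sample from
p = (1−F)·p_target + F·p_background with depth
n = round((1−F)·n_target + F·n_background), floored at 1 (the rounding rule
is ours; only "weighted average" is specified). F is the fraction
contributed by the background source, so F = 0 and F = 1 reproduce the
parent compositions exactly. Evaluation sets mix every target-site
validation sample with a background partner drawn uniformly with
replacement; the negative class is the unmixed background-site validation
samples — a choice (the published negative set is not stated) that makes
the F→0 limit coincide with the unmixed-sample baseline. Decision
thresholds are fitted per (target, background, fraction) cell on mixed
*training* samples only — the forest and calibrators never see mixtures —
by maximizing binary F1 over observed score cut points (rule:
score ≥ threshold; intermediate cut points yield identical confusion
counts, and ties break toward the higher threshold). With 5 sites and a
10-step fraction grid this yields the full 5 × 4 × 10 = 200-entry table.
`contaminateTraining` additionally supports the robustness regime where
half the training samples are mixed with 30% of an environmental
background before training.

## Trait enrichment

Physiological traits (aerobicity, gram stain, shape, sporulation, motility)
recorded per genus are extrapolated to member OTUs. For each (site,
association type, sub-category), a one-tailed (greater) Fisher test
compares the focal markers against markers of the same type at other
sites; OTUs with unknown status are excluded from both margins, and
multi-valued traits count once per alternative. BH adjustment is applied
jointly across all records (the adjustment family is not delimited in the
literature we follow; per-site adjustment would be the alternative), and an
OTU already in the focal set is not re-counted in the background. Flagged
means adjusted p ≤ 0.05.

## The synthetic generator

The generator defines the package's reference study conditions and is the
ground-truth oracle for every downstream test. Per sample: a site, a
uniformly assigned study, and a log-normal depth (meanlog = log 5000,
sdlog = 0.7, rounded up to ≥ 1). Per OTU, Bernoulli presence:

* direct PA markers: 0.9 in their own site, 0.25 elsewhere;
* direct NA markers: 0.05 in their own site, 0.25 elsewhere — the NA
  mechanism is modelled as depressed presence, a modelling choice, not a
  claim about the real mechanism;
* noise OTUs: 0.25 everywhere;
* indirect OTUs: 0.8 given their parent (a direct PA marker) is present,
  0.05 otherwise — conditional on the parent's realized state, presence is
  site-independent by construction, which is exactly the conditional
  independence the discovery stage must exploit.

Every (study, OTU) pair draws an extra nondetection probability uniformly
from [0, 0.2], and presence is thinned accordingly — a one-parameter stand-in
for primer/amplification detection bias; abundance shifts between studies
are deliberately not modelled. Counts are allocated multinomially across
present OTUs with log-normal weights (meanlog 0, sdlog 1), so column sums
equal drawn depths exactly. Defaults: 5 sites × 300 samples, 8 studies,
5 PA + 3 NA markers per site, 25 indirect, 200 noise OTUs. A master seed
deterministically derives one sub-seed per stage, so outputs are
byte-identical per seed.

What the generator does *not* emulate: compositional correlations beyond
single parent–child edges, phylogenetic structure, abundance-level study
effects, chimeras or any read-level artefacts. Passing recovery tests shows
the algorithms find the structure they are designed for — it does not
certify performance on real data, where effect sizes are smaller and
dependency networks denser.

## Problem sizes and numerical choices

Tests and the acceptance script run the reference dataset (1500 samples,
265 OTUs) for discovery and classification, a 5 × 40-sample dataset for the
200-entry threshold table, 1000 random tables for G-test/oracle
equivalence, 12 random DAGs (≤ 8 nodes, degree ≤ 3) for oracle exactness,
and 20 + 50 null replicates for false-positive control — sizes chosen so
the full battery completes in minutes on one CPU while every check retains
clear statistical margin. Tolerances: G within 1e−9 of brute force, p
within 1e−10, NMI symmetric to 1e−12; Monte-Carlo checks use 99%
family-corrected normal intervals. Tie-breaking is total everywhere
(candidate order by G then id; threshold ties toward the higher cut; grid
ties toward the first point) so all outputs are deterministic given a seed.

## Known limitations

* Marker discovery is presence/absence only; abundance-modulated
  associations that never change detection status are invisible.
* The plain HITON-PC variant can admit spouse-of-child false positives
  (see above); at α = 0.05, indirect OTUs also retain a ~5% per-site chance
  of slipping through a conditioning test. Expect a small number of false
  markers rather than none.
* Isotonic calibration on modest out-of-fold samples is step-like;
  probabilities are honest in rank but coarse in value.
* One forest family only (Random Forests); no alternative learners or
  calibrators are implemented.
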