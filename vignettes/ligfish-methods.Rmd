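---
title: "ligfish: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ligfish: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ligand-based target fishing inverts the usual virtual-screening question:
instead of ranking many compounds against one target, a fixed compound
series (say, a couple dozen natural products from one plant family) is
scored against many bioassay models at once, and the *biological
activities* are ranked by how strongly the series hits them. `ligfish`
implements the full chain: 3D structure → pharmacophore fingerprint →
per-assay ensemble classifier → calibrated activity probability →
aggregated activity-class ranking.

## Descriptors: modal 3-point pharmacophore fingerprints

Each conformer's heavy atoms are mapped to potential pharmacophore points
(PPPs) of six types: hydrogen-bond donor, acceptor, positively charged,
negatively charged, aromatic (placed at ring centroids) and lipophilic.
An atom may carry several types at once — a protonated primary amine is
both donor and positive. All `choose(n, 3)` point triples are converted
into triplet keys: the three types plus the three pairwise distances,
each distance binned and paired with the *opposite* vertex. A key is
canonicalized as the lexicographically least of the six
rotations/reflections of its cyclic (type, opposite-edge-bin) sequence,
which makes it invariant to point relabelling without hashing. Per-
conformer key sets are unioned into the compound's *modal* fingerprint
(capped at 10 conformers, first in file order), so the descriptor is
invariant to conformer order and can only grow as conformers are added.

Design choices made here, since no canonical rule table or bin-edge
convention exists for this descriptor family:

* **PPP rule table** (`default_ppp_rules()`): conventional definitions —
  donor = N/O with an H; acceptor = any O, plus N that is neither amide
  nor positively charged/quaternary; positive = formal charge > 0,
  aliphatic amines, amidine/guanidine sp2 N; negative = formal charge
  < 0 plus ionizable acid hydroxyls on C/S/P centres bearing a
  double-bonded O; aromatic = 5/6-rings that are either explicitly
  aromatic (order-4 bonds) or alternating Kekulé; lipophilic = uncharged
  carbon with no N/O/S or charged neighbour. The table is a plain list
  and is serialized into run manifests. Tetrazole acidity and
  pyrrole-type NH subtleties are beyond this table — an explicit,
  documented approximation.
* **Distance binning** (`distance_binning()`): half-open 1.0 Å bins on
  [0, 20) Å; triples with any edge ≥ 20 Å are discarded. 1 Å is the
  customary granularity for triplet fingerprints and bounds the key
  space; both width and cutoff are configurable.
* **Exact sparse keys**: no folding into fixed-width vectors internally
  (collisions would make tests nondeterministic); `fold_fingerprint()`
  exists for interoperability only.
* **Degenerate geometry**: collinear/coincident points are kept — a
  triplet is defined by its distances, not its area; coincident points
  produce bin-0 edges.
* **Hydrogen counting**: explicit H atoms plus implicit H from standard
  valences (aromatic bonds counted 1.5). Kekulé or explicit-aromatic
  input is assumed; perception is deliberately minimal rather than a
  full aromaticity model.

## Ensemble models

Each bioassay dataset (labels "active"/"inactive") is modeled by an
ensemble built from a *recurrent stratified partition*: 30 repeats
(configurable, never fewer) of a 70/30 split, stratified per class with
round-half-up counts, repeat `r` seeded `master + r`. Every repeat fits
one member model on its training stratum:

* **Linear SVM** — L2-regularized L1-loss, solved by deterministic dual
  coordinate descent (no libsvm binding exists in the target
  environment; the solver is compiled and uses a fixed sweep order so
  ensembles are bit-reproducible). The cost C is selected per member
  over the 19-value grid 2^-12 … 2^6 (step ×2) by stratified 5-fold CV,
  maximizing the **Power Metric** TPR/(TPR+FPR) at the operating quota
  χ = TPR+FPR = 0.5, linearly interpolated between ROC points; ties go
  to the smaller cost. Scores are signed decision values, not
  probabilities — calibration happens downstream.
* **Bernoulli naive Bayes** — present/absent likelihoods per triplet key
  restricted to training-seen keys, Laplace α = 1, score = log posterior
  odds (additive over keys).

Member scores of validation compounds are pooled per compound into its
out-of-sample (OOF) list; the OOF means are the ensemble's reference
score distribution and give the internal validation AUC. If some
compound never lands in a validation set, the whole plan is redrawn
(incremented master seed, ≤ 5 attempts) because calibration needs an OOF
score for every reference compound; the coverage requirement is only
enforced when the repeat count makes it combinatorially possible.

## Calibration: Pa, Pi and the applicability-domain filter

A query's raw score `s` (mean over members) is converted to
`Pa` = fraction of reference actives scoring *worse* than `s`, and
`Pi` = fraction of reference inactives scoring *better*; ties count ½,
consistent with the AUC's midrank convention (weak vs strict inequality
is a genuine convention choice; ½-ties is our declared reading). The
prediction score is Pa−Pi. The member-score spread gives a 95%
t-interval on the mean score (`mean ± t(0.975, N−1)·SD/√N`); evaluating
Pa/Pi at the interval ends yields the Pa−Pi upper limit (highest Pa −
lowest Pi) and lower limit (lowest Pa − highest Pi). The call rule is:

> active ⇔ Pa−Pi mean ≥ threshold (inclusive) **and** Pa−Pi lower
> limit > 0.

The second clause is the applicability-domain filter: an outlier
fingerprint makes members disagree, the interval widens, the lower limit
dips below zero, and the compound cannot be called active regardless of
its mean. The default prediction threshold is 0.15; class-level scoring
uses the MCC-selected operating points 0.25 (SVM) and 0.30 (naive
Bayes), all on the 0.05 threshold grid. The "Both" combination calls a
compound active if either method does. The reference distribution is the
per-compound OOF means (pooling all raw fold scores is a documented
alternative, not the default).

## Validation statistics

* `auc_rank_sum()` — Mann-Whitney AUC from midranks; ties between
  classes contribute ½ per pair.
* `auc_se()` — Hanley-style smooth-ROC approximation
  `sqrt(w²(1−w)/((1+w)Na) + w(1−w)²/((2−w)²Ni))`.
* `auc_dof()` — Welch–Satterthwaite combination of the two variance
  addends above, pairing the active component with Na−1 and the inactive
  with Ni−1 — the standard Welch–Satterthwaite pairing, which reduces to
  2(Na−1) in the symmetric limit and to Na−1 when the inactive component
  vanishes.
* `contingency_metrics()` — F-score, MCC, enrichment factor. EF uses the
  table's own prevalence unless `prevalence_override` supplies the
  prevalence of the full collection the table was drawn from — the
  convention needed to reproduce published validation rows.
  Zero-denominator metrics are `NA`, never 0.
* `filter_models()` — strictly AUC > 0.5; a model at exactly 0.5 carries
  no ranking information.

## Activity classes

Assay models are grouped (many-to-many) into activity classes. The class
score is `hits / (n_compounds · sqrt(M))` where a hit is one (compound,
model) active call among the class's M models — a compound active in 3
models contributes 3. The √M divisor is the middle ground between
penalizing large classes (divide by M) and privileging them (no
divisor); duplicating every model k-fold scales the score by exactly √k.
Classes are labelled by strict majority of experimental outcomes
(probable_active / probable_inactive, equal counts excluded) and the
ranking is validated by a class-level rank-sum AUC. SVM and NB rankings
merge with the sort key (best rank, mean rank, class_id) — a total
order, hence a reproducible final list.

## Synthetic data: what it emulates, what it does not

`gen_fingerprint_dataset()` draws sparse binary fingerprints with
planted signal keys (defaults: 50+50 compounds, 200 keys, 20 signal keys
at 0.9 in actives vs 0.1 in inactives, 5% background — a strongly
separable assay of realistic size). `gen_class_collection()` builds a
whole collection (20 classes, 1–4 models each, 25% planted-active, 27
query compounds — the size of a typical natural-product series) in which
planted classes share their signal keys with the queries and null
classes use disjoint per-class signals. Generators bypass the
pharmacophore module deliberately, isolating machine-learning failures
from chemistry-perception failures; `gen_point_cloud_molecule()` covers
the geometric path instead. All generators take explicit seeds and
restore global RNG state.

A green synthetic test therefore establishes protocol correctness —
stratification, OOF bookkeeping, calibration arithmetic, ranking — under
an idealized independence structure. It does not establish chemical
realism: real fingerprints have correlated keys, scaffold clustering and
activity cliffs, and real collections have heterogeneous assay quality.
AUC figures of the kind reported for thousand-dataset bioassay
collections require such a collection and are out of reach at desk
scale; the test suite substitutes the property checks above.

## Numerical and degenerate-input choices

* Round-half-up for the 70/30 class counts (R's `round()` is banker's).
* SVM solver: tolerance 1e-4 on the projected gradient, ≤ 300 passes,
  warm-started along the ascending cost grid during CV; deterministic
  sweep order, no RNG.
* `select_cost` ties break to the smaller (more regularized) cost.
* Single-member score samples have undefined limits → the compound is
  low-confidence and never called active.
* Degenerate references (e.g. one active) are allowed; Pa granularity is
  then 1/Na by construction.
* Empty fingerprints are scored (bias/prior only) and flagged.
* Empty AUC-filter survivor sets propagate as explicit empty tables with
  a warning.

## Limitations

* The minimal V2000 reader covers atoms/bonds/charges only (no isotopes,
  stereo parity, or V3000); conformer generation is delegated to
  external tools.
* Chemistry perception is rule-table driven, not a full aromaticity/
  tautomer model.
* Config files are JSON (no YAML parser in the supported dependency
  set).
* No nonlinear kernels, instance weighting, or Platt scaling — the
  Pa/Pi construction replaces probability scaling by design.
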