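---
title: "Methods: ligand-based virtual screening with lbvscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based virtual screening with lbvscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lbvscreen` implements a complete ligand-based virtual-screening workflow
of the kind used to discover new inhibitors of aromatase (CYP19A1), the
cytochrome P450 that converts androgens to estrogens and the principal
drug target in hormone-receptor-positive breast cancer. The canonical
inhibition mode is coordination of an aromatic azole or pyridine nitrogen
to the heme iron, which is why ring motifs play a central role in the
screening funnel. This vignette explains the statistical machinery, the
tunable parameters, and the design decisions behind each stage.

## 1. Curation and labeling

Raw bioactivity tables carry one of two labeling semantics:

* **Potency sources** report a pChEMBL-style value, the negative decadic
  logarithm of a molar potency endpoint. A compound is *active* when the
  value is at least 6 (potency of 1 uM or better), *inactive* otherwise.
* **Score sources** report an integer activity score from 0 to 100.
  Score 0 is *inactive*, scores 40-100 are *active*, and everything in
  the ambiguous 1-39 band is *excluded* from modeling. We exclude the
  whole complement of the two stated intervals — a superset of the
  narrower "5-30" exclusion sometimes quoted for such assays — because an
  ambiguous record is worthless either way.

Structures are standardized in a fixed order: salt/solvent stripping
(largest organic fragment), charge neutralization, annular-azole tautomer
normalization, stereo removal, canonicalization. The order matters: it
prevents the tautomer choice from depending on counter-ions that are about
to be discarded. Standardization is idempotent — a property the test suite
asserts on generated corpora — so curated SMILES are stable join keys.

Two implementation notes. Charge neutralization uses OpenBabel's
`neutralize` operation, which protonates simple anions and deprotonates
ammonium nitrogens while leaving charge-separated groups (nitro,
N-oxides, quaternary ammonium) intact. Tautomer normalization is scoped
to annular azole N-H tautomers: all placements of an aromatic N-H over
the aromatic nitrogens are enumerated (formula-preserving, parseable
candidates only) and the lexicographically smallest canonical SMILES is
taken, to a fixpoint. This covers the tautomerism that actually matters
for azole-rich CYP-inhibitor chemistry; keto-enol and other prototropic
tautomers are out of scope and users with exotic chemistry should
pre-standardize with a dedicated tool.

Admission requires only the common organic elements (H, B, C, N, O, F,
Si, P, S, Cl, Se, Br, I) and an average parent molecular weight between
250 and 900 Da inclusive. Duplicates collapse on canonical SMILES: groups
that agree on the label keep their first record by identifier order;
groups with conflicting labels are removed outright, because neither
label can be trusted. Conflicts *across* sources are only reported
(`cross_source_overlap()`), never auto-resolved — the one documented
real-world case of this kind was a units transcription error that only a
human could adjudicate.

## 2. Features

* `ecfp4()` — extended-connectivity fingerprints of radius 2. OpenBabel
  produces a 4096-bit ECFP4; we fold it to the conventional 2048 bits by
  OR-ing the halves. Fingerprints feed the models, every similarity
  computation, and the clustering.
* `physchem_panel()` — a 208-feature two-dimensional physicochemical
  panel pinned by a manifest shipped with the package (OpenBabel
  descriptors such as logP, TPSA and H-bond counts; molecular-graph
  counts; and a SMARTS census of functional groups, atom environments
  and ring systems). Descriptor panels of this kind are toolkit-specific,
  so the manifest — not a literal count — is the contract; tests assert
  manifest consistency. Non-finite values are median-imputed.
* `pca_panel_13()` — the compact 13-property panel used for
  chemical-space maps: N and O counts, candidate stereocenters, molecular
  weight, heavy atoms, H-bond acceptors and donors, logP, TPSA, aromatic
  atoms, net formal charge, ring count, and fraction of sp3 carbons.
  Because standardization removes stereo annotations, stereocenters are
  *candidate* centers: sp3 carbons whose four branches are distinct under
  two rounds of Morgan-style neighborhood refinement.

`pca_project()` z-scores columns before the decomposition; mixing atom
counts with logP on raw scales would let molecular weight dominate every
component. Zero-variance columns are dropped rather than divided by zero.

Tanimoto similarity uses the standard bit-set definition with one
convention: two all-zero fingerprints have similarity 1, and an all-zero
fingerprint has similarity 0 to anything else.

## 3. Similarity-constrained cross-validation

Random k-fold CV flatters fingerprint models, because analogs of one
series land on both sides of every split. The package instead clusters
the training set with Butina sphere exclusion at a Tanimoto floor of 0.3
(every member at least 0.3-similar to its cluster centroid; centroids
chosen by descending neighbor count, ties by input order) and assigns
whole clusters to folds. The assignment is greedy: clusters are visited
in descending size order (a seeded shuffle breaks ties) and each goes to
the currently smallest fold. Descending-size order keeps fold totals as
even as possible — the spread is provably bounded by the largest cluster
size — and makes small worked examples deterministic.

Inside each CV iteration the training folds are rebalanced with SMOTE:
synthetic minority points interpolate between a minority compound and one
of its five nearest minority neighbors. Held-out folds are never touched
(asserted byte-for-byte in the tests). On binary fingerprints plain
interpolation produces fractional bits; these are fed to the tree
ensemble as-is — trees are indifferent to monotone feature
transformations — and a SMOTENC-style `nominal` mode (majority vote over
the neighbor set) is available when strict binarity matters.

The classifier is a 1000-tree random forest (`ranger` backend,
single-threaded, fully grown trees, fixed seed 42). The probability of
activity is the fraction of trees voting active. One hyperparameter is
tuned: `max_features`, the number of candidate features per split, over
the grid {all, sqrt, 0.2, 0.4, 0.8 of the panel}. The selection metric is
**BEDROC** (Boltzmann-enhanced discrimination of ROC), an exponentially
rank-weighted enrichment score: with `alpha = 20` roughly 80% of the
weight falls on the top ~8% of the ranked list, which matches what a
screening campaign actually consumes. The literature quotes BEDROC with
several normalizations; here it is the min-max rescaled robust initial
enhancement, so 1 always means "all actives first" and 0 "all actives
last". Ranking ties break by stable input order — BEDROC is
tie-sensitive, so the tie policy is part of the definition, and the
implementation is checked against a literal direct-summation oracle.
`alpha` is exposed as a parameter; 20 is the default early-recognition
setting. One fold plan is shared across the whole grid (lower variance
between settings than re-clustering per setting).

Two engine-level optimizations are worth documenting. Constant feature
columns (fingerprint bits never set in a training set) are dropped before
fitting, and `mtry` is rescaled as `round(m * d_kept / d_total)` so that
the expected number of informative split candidates matches full-panel
semantics; for `max_features = all` the two are exactly equivalent.
`roc_auc()` is the Mann-Whitney midrank statistic (ties count 1/2),
verified against exhaustive pair counting.

After selection, the training and test sets are recombined and the final
model is retrained on the oversampled full dataset (`train_final()`); the
returned `screen_model` carries a manifest (panel, hyperparameters,
seeds, dataset hash) sufficient to retrain it identically.

## 4. The triage funnel

`run_funnel()` applies, in order, with full per-compound audit trail:

1. **Rule of five** — at most one violation of MW <= 500, logP <= 5,
   HBD <= 5, HBA <= 10 (the original formulation allows one).
2. **CYP motif** — an aromatic imidazole, 1,2,3- or 1,2,4-triazole, or
   pyridine ring must be present (the heme-coordinating motifs).
3. **Ensemble gate** — keep a compound if it ranks in the top
   `top_n = 10000` of *any* of the four models (the union reading) *and*
   its maximum probability strictly exceeds `p_min = 0.7`. Rank ties
   break on compound id.
4. **Novelty** — maximum Tanimoto similarity to every known active must
   be strictly below 0.7. Behavior at exactly 0.7 is ambiguous in common
   usage ("below 0.7" vs "greater than 0.7 removed"); strict exclusion
   is chosen, so a 0.7-similar compound is rejected.
5. **Liabilities** — PAINS alerts plus structural exclusions: net
   positive charge, bromine or iodine, nitro groups, basic aliphatic
   amines, unbranched chains of 7+ sp3 carbons ("long alkanes" — the
   source procedure names no number; 7 is the package's quantification),
   and more than 8 rotatable bonds. The basic-amine SMARTS deliberately
   exempts amides, anilines and aromatic azole nitrogens so the mandatory
   motif from stage 2 can never self-trip the filter. The shipped PAINS
   set is a curated collection of alerts covering the canonical PAINS
   chemotype families (quinones, catechols, rhodanines, hydrazones,
   alkylidene barbiturates, isothiazolones, azo compounds, Mannich
   phenols and related enamine/enone classes), documented as
   representative rather than exhaustive; a full published list can be
   supplied through `funnel_config(pains_smarts = ...)`.
6. **Diversity** — Butina clustering of the survivors at similarity 0.6,
   one representative per cluster (highest ensemble probability, ties to
   the smallest id).

Survivor sets are nested and each removed compound records its first
failing stage. The funnel deliberately ends with an exported ranked
shortlist: the downstream steps of a real campaign — docking, visual
inspection, steric-hindrance judgment — are human-in-the-loop and are
not automated here.

## 5. The synthetic data generator

Every stage above is testable offline because the generator produces
data with the statistical structure the analysis assumes:

* **Two source profiles** mirror curated reality: `balanced_potency`
  (about 1.24 actives per inactive, continuous potencies) and
  `imbalanced_score` (about 1:11, discrete scores). Potencies are drawn
  consistently with the observed label — actives from N(7.0, 0.7)
  truncated at >= 6, inactives from N(5.0, 0.6) truncated below 6 — so
  curation relabels nothing.
* **A planted structure-activity rule**: a molecule is truly active iff
  it matches a SMARTS pattern, by default the chromen-2-one (coumarin)
  lactone. Observed labels flip with probability `label_noise`
  (default 0.1), emulating database mislabeling: the activity *value* of
  a flipped record is drawn from the wrong side, exactly as a wrongly
  curated entry would appear.
* **Clustered scaffold structure**: molecules are composed from a
  scaffold-by-decoration grammar. Active series share the coumarin
  lactone but differ in core substitution pattern, linker chemistry and
  head ring system, and each scaffold family draws decorations from its
  own fragment subpool — so analog series form distinct Butina clusters
  at the 0.3 floor while all series share the substructure that carries
  the signal, the same tension that makes scaffold-split validation
  meaningful on real data.
* **Non-trivial funnels**: screening-library decoys never match the rule,
  a fraction carries the CYP motif (so the motif gate removes some but
  not all), a fraction carries planted liabilities (halogens, nitro,
  basic amines, long alkanes), and a fraction carries a polyether tail
  that breaks two rule-of-five criteria at once. Library molecules and
  the cross-source "foreign" variant are built from the complementary
  half of the scaffold templates and a shifted decoration pool, which
  keeps planted library actives below the 0.7 novelty threshold against
  a training set.

What the generator does **not** emulate: real chemical-space geometry,
assay noise structure beyond symmetric label flips, activity cliffs
within a series, or the scale of purchasable libraries (millions of
compounds). Passing tests demonstrate that the machinery — curation,
cluster-split CV, BEDROC selection, the funnel bookkeeping — behaves
correctly and recovers a planted signal under realistic class imbalance
and noise; they do not certify predictive performance on any real
target.

## 6. Problem sizes and numerical choices

The documented desk scale, used by the test suite and the acceptance
script, is: n = 600 per source (480 train / 120 held out at the 4:1
split), five folds, the full five-point `max_features` grid on the
potency source, four final bundles (two sources times two panels), and a
screening library of 5,000 decoys plus 50 planted actives. At this scale
the whole acceptance run takes a few minutes on one CPU; all sizes are
parameters, and nothing in the code depends on them.

Other numerical decisions: test-set size is `floor(0.2 n)` with the
remainder to training; BEDROC is clamped to [0, 1] against floating-point
spill; single-member minority classes fall back to replication in SMOTE
(interpolation needs two points); degenerate all-zero fingerprints
cluster together by the similarity-1 convention; string orderings
(deduplication, tie-breaks, tautomer choice) use C-locale radix sorting
so results do not depend on the session locale.

## 7. Known limitations

* OpenBabel's ECFP implementation sets sparser bit patterns than other
  toolkits; absolute Tanimoto values are not comparable across toolkits,
  only within one. All thresholds here are applied consistently within
  the OpenBabel fingerprint space.
* The tautomer normalizer is scoped to annular azole N-H tautomers.
* The PAINS set is representative, not the full published catalog.
* The candidate-stereocenter count is a refinement-based approximation.
* Butina clustering materializes the full similarity matrix; it is meant
  for datasets of up to a few thousand compounds, not for clustering a
  whole purchasable library (the funnel only ever clusters survivors).
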