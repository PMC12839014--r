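---
title: "Methods: ligand-based virtual screening with chemsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based virtual screening with chemsieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Kinase inhibitor discovery routinely starts from public bioactivity
databases: thousands of heterogeneous potency measurements (IC50, EC50,
Ki, Kd), reported against one target in different assays, units and salt
forms, some only as censored bounds ("> 10 uM"). `chemsieve` implements a
complete ligand-based virtual-screening workflow over such data, developed
around CDK9 (cyclin-dependent kinase 9, a transcription-elongation kinase
and anticancer target) as the motivating system: curate the measurements
into defensible active/inactive training data, learn probability-scoring
classifiers over several molecular representations, pick the best model by
Matthews correlation coefficient (MCC), and use it to prioritize a
diverse, high-confidence subset of a large purchasable library.

Every stage is exercised offline through a synthetic-data module that
emulates the relevant pathologies of the real inputs, so the statistical
behaviour of the pipeline (signal recovery, calibration of the
probability-score threshold, diversity selection) is testable without any
database download.

# Curation model

**pActivity.** All potencies are converted to pActivity = -log10(molar
concentration); 1 uM corresponds to 6.0.

**Exact vs censored records.** Only relation "=" records enter the
potency pools. Records with relation ">" certify only a lower bound on
the concentration needed for effect; they are held aside and used later
as confident inactives when the reported bound is at or beyond a scheme's
inactivity cutoff. Records with missing SMILES, unparseable structures,
unknown activity types or units are rejected with reason codes; the
funnel report makes every input record accountable to exactly one fate
(conservation is property-tested).

**Standardization.** Every structure (training, test, decoy, screening)
passes the same protocol: salt stripping to the parent fragment (largest
heavy-atom count, ties by molecular weight then lexicographically smallest
canonical SMILES), ionization at pH 7.4, and canonicalization into a
deduplication key. The ionization rule table is: deprotonate carboxylic,
sulfonic and phosphonic acids and tetrazoles; protonate aliphatic
primary/secondary/tertiary amines, amidines and guanidines; leave
anilines, amides and aromatic N-heterocycles neutral. These are the
dominant pH-7.4 species for drug-like chemistry; the transformation is
applied with OpenBabel's pH model and asserted rule-by-rule in the test
suite. Stereochemistry is retained through standardization: two records
differing only in stereo descriptors are treated as different compounds,
because potency against a kinase can be strongly enantiospecific.

**Train/test partition.** IC50 measurements (the large majority in the
emulated extracts) form the training pool; EC50/Ki/Kd measurements form
the test pool. When a compound has both, the IC50 record wins, and any
remaining same-structure collisions resolve in favour of the training
set. Duplicate exact measurements for one structure collapse to the
median pActivity (order-independent, robust to outliers).

**Labeling schemes.** Two threshold pairs are built in:

| scheme | active | inactive | exclusion window |
|---|---|---|---|
| lead-oriented (LO) | pActivity >= 6.0 (<= 1 uM) | pActivity <= 5.30 (>= 5 uM) | 5.30-6.0 |
| potency-oriented (PO) | pActivity >= 7.5 (<= 31.6 nM) | pActivity <= 5.5 (>= 3.2 uM) | 5.5-7.5 |

Both boundaries are inclusive. Compounds inside the window are dropped to
avoid training on boundary noise where assay variability can flip the
class.

**Balancing.** Public kinase extracts are strongly active-skewed, so the
inactive class is augmented twice: first with the censored records that
certify inactivity under the scheme's cutoff (derived from the inactive
threshold: 10^(9 - inactive_max_p) nM, i.e. ~5 uM for LO and ~3.2 uM for
PO, inclusive), then with uniformly sampled drug-like decoys until the
classes are exactly equal. Decoy draws for train and test are disjoint,
and a final control removes any residual key overlap between train and
test.

# Molecular representations

Seven encodings, all computed from the standardized (ionized) structure:

1. **Path fingerprint** (1024 bits): hashed linear atom-bond paths up to
   seven atoms (OpenBabel FP2).
2. **Circular fingerprint** (1024 bits): extended-connectivity
   environments to radius 2 (ECFP4), folded from 4096 to 1024 bits by
   OR-ing aligned 1024-bit blocks. Folding preserves the subset relation
   between radius-0 and radius-2 environment sets, which is tested.
3. **Substructure-key fingerprint** (881 bits): a versioned dictionary
   ("cs-dict-1") of graph-derived structural keys - element-count
   thresholds, ring-size and aromaticity keys, element-degree and
   formal-charge environments, bonded element-pair keys by bond order,
   path-2 class triples, and heteroatom topological-distance keys - in a
   fixed order, truncated to exactly 881 entries. The original
   881-key database convention is not a published artifact, so the
   dictionary here is defined by the package and pinned; its order and
   cardinality must never change silently.
4. **Descriptors** (208 values): a pinned manifest combining 8 bulk
   physicochemical properties (MW, logP, TPSA, H-bond donors and
   acceptors, molar refractivity, fluorine count) with 200 graph-derived
   attributes: element/bond/degree/ring counts, distance-based indices
   (Wiener, Harary, eccentricities), connectivity indices (Zagreb,
   Randic, Platt), spectral descriptors (adjacency and Laplacian
   eigenvalue summaries, spectral moments), Moreau-Broto and Moran
   autocorrelations of atomic number, electronegativity, covalent
   radius, degree and heteroatom indicator over topological lags 1-8,
   and shape/composition ratios. Descriptors are min-max scaled to
   [0, 1] with a scaler **fitted on the training split only** and frozen
   for test and screening compounds; out-of-range values are clipped,
   constant training features map to 0, and non-finite values fall back
   to the training median (logged).
5-7. **Hybrids**: fingerprint-first concatenation of each fingerprint
   with the scaled descriptors - hybridRR (path, 1232), hybridMR
   (circular, 1232), hybridPR (keys, 1089). The hybrids feed the
   continuous generalization of the Tanimoto kernel, so scaled (not raw)
   descriptors are used throughout.

**Tanimoto similarity.** For binary fingerprints T = s/(a + b - s); the
kernel form `<x,y> / (<x,x> + <y,y> - <x,y>)` reduces to T on binary rows
and extends it to hybrid rows. T = 0 is defined when both fingerprints
are empty, and zero rows give kernel value 0.

# The model zoo

Five algorithms, each with the declared hyperparameter grid (grids are
ordered by increasing complexity; exact ties in tuning resolve to the
earlier, simpler grid point):

| algorithm | grid | points |
|---|---|---|
| random forest | trees {100, 500} x features-per-split {all, sqrt, log2} | 6 |
| SVM | kernel {linear, poly, rbf, sigmoid, Tanimoto} | 5 |
| k-nearest neighbours | k {3..15 odd} x weights {uniform, distance} | 14 |
| Gaussian process | kernel {dot-product, rational-quadratic, Matern, white-noise, RBF} | 5 |
| multi-layer perceptron | layers {2, 3} x width {100, 200, 1000} x batch {100, 200} | 12 |

The MLP grid reads "(2, 3) layers x (100, 200, 1000) neurons" as a
uniform width per network, the smallest grid consistent with that
phrasing; per-layer width mixtures are out of scope.

Implementation notes, in the order they matter:

* **Probability scores.** Every model emits PS in [0, 1], the estimated
  probability that the compound is an active inhibitor; the label rule is
  PS > 0.5. The SVM gets Platt-style sigmoid calibration fitted on
  internal cross-validated decision values within the training data (with
  a fallback calibration on training decision values when the internal
  3-fold calibration is degenerate, e.g. perfectly separable folds). The
  Gaussian process emits its posterior class probability.
* **Kernels.** The Tanimoto, Matern (nu = 3/2), rational-quadratic and
  white-noise kernels are implemented as kernlab-compatible kernel
  classes with vectorized Gram-matrix methods; the test suite checks the
  vectorized forms against the element-wise definitions. On 1024-bit
  fingerprints a fixed unit length scale would push stationary kernels'
  off-diagonal entries to zero, so the GP kernels use a median-heuristic
  length scale (median pairwise training distance, subsampled at 200
  rows); the SVM's rbf/poly/sigmoid kernels use the 1/(p * var(X))
  scaling convention.
* **KNN** uses Euclidean distances; with distance weighting, weights are
  1/d and zero-distance neighbours take all the weight.
* **MLP** is a seeded ReLU network (He initialization, sigmoid output,
  binary cross-entropy, Adam at learning rate 1e-3) trained for a fixed
  epoch budget (40 by default; the reduced pipeline configuration uses
  20). There is no early stopping; the epoch cap is an explicit artifact
  choice.
* **Determinism.** Every stochastic component (forest bootstrap, fold
  assignment, MLP initialization and batch order, decoy draws, library
  generation) consumes a named seed, and `predict_ps()` is deterministic
  given the fitted state.

**Tuning and assessment.** Grid search evaluates every grid point by
stratified cross-validation on the training set only (the tuning CV uses
the same stratified 5-fold scheme as model assessment, with its own
seed), maximizing mean MCC. The selected configuration is refit on the
complete training set and evaluated once on the held-out test set; models
are ranked by test MCC with ties broken by precision, then recall, then
model name. Grid search and cross-validation never receive the test
split, by interface.

# Evaluation conventions

MCC, precision and recall are computed from the confusion counts; MCC is
0 when any denominator factor vanishes, precision and recall are 0 on
0/0 (both logged conventions keep threshold sweeps total). Model
evaluation thresholds are **strict** (predicted active iff PS > t), while
the screening hit filter is **inclusive** (hit iff PS >= ps_min); both
comparators are explicit configuration, mirroring the two conventions
used at the evaluation and hit-selection stages. The threshold sweep runs
0.50 to 0.90 in 0.05 steps by default (the granularity between the
endpoints is an artifact choice) and reports the smallest threshold with
perfect precision, the criterion used to set the screening cutoff.

# Screening and diversity selection

The library is standardized with the training protocol (unparseable
entries go to a reject log and never abort a run), scored in batches
(output is batch-size invariant), and filtered at PS >= 0.8. Hits are
clustered by hierarchical agglomerative clustering under average linkage
on distance 1 - T between path fingerprints, with the dendrogram cut at
distance 0.30: every merge inside a surviving cluster happened at
distance <= 0.30. A distance cut (not a fixed cluster count) is the
implemented rule. From each cluster the available member with maximal PS
is selected (ties by lexicographic compound id); clusters with no
available member contribute no representative and are logged - the
mechanism by which a 21-cluster outcome can yield a shorter purchase
list. Clustering was checked against an exhaustive agglomerator on all
small instances with distinct pairwise distances, where tie conventions
cannot differ.

# The synthetic-data generator

The generator stands in for three real inputs: the bioactivity extract,
the decoy database, and the purchasable screening catalogue. It composes
molecules from a fixed grammar - 8 two-slot ring scaffolds (biphenyl,
diphenylmethane, bibenzyl, diphenyl ether, benzanilide, diphenyl sulfone,
phenylpyridine, pyridyl benzamide), 4 linkers and 18 plain substituents -
and plants one of 4 pharmacophore fragments (morpholinosulfonyl,
benzothiazole amide, tetrazole, indole carboxamide) in a configurable
fraction of compounds. Pharmacophore-bearing compounds draw their true
pActivity from Normal(mu_active, sigma), plain compounds from
Normal(mu_inactive, sigma). A grammar was chosen over random graph
sampling because it makes pharmacophore presence exactly controllable and
substructure-checkable, which is what the signal-recovery checks require.

Default study conditions, chosen once:

* `frac_ic50 = 0.8` - IC50 records dominate the emulated extracts.
* `mu_active = 7.8`, `mu_inactive = 4.5`, `sigma = 0.6` - a separation of
  5.5 sigma. The active mean sits in the potent nanomolar range typical
  of kinase actives (so both labeling schemes, with active thresholds at
  6.0 and 7.5, produce populated active classes), the inactive mean sits
  at tens of micromolar, and sigma emulates inter-assay potency spread of
  about half a log unit.
* `frac_pharmacophore = 0.7` - public kinase extracts are strongly
  active-skewed (that skew is the reason the decoy-balancing stage
  exists), and the curation funnel's balancing step presupposes
  more actives than inactives; 0.7 reproduces that regime at every
  library size.
* `frac_gt_relation = 0.10` of records are censored ">" rows, emitted for
  the weakest compounds at a reported bound of 10 uM - by construction
  the bound certifies inactivity under both schemes, mirroring how
  censored records are used downstream.
* `frac_salted = 0.15` and `frac_duplicates = 0.10` exercise salt
  stripping and duplicate collapsing; values are reported in mixed nM /
  uM / M units to exercise unit handling.
* Decoys come from the same grammar with the pharmacophore fraction
  forced to zero (pharmacophore-free by construction) and are filtered
  for drug-likeness (MW 200-500, <= 5 donors, <= 10 acceptors).
  Screening libraries use a 5% planted-active rate.

What the generator does **not** emulate: real structure-activity
relationships (potency is a pure function of one planted fragment plus
noise), the actual chemical space and scaffold frequency of public
databases, correlated assay artifacts, activity cliffs, or
stereochemistry-dependent potency. Passing signal-recovery checks on this
data therefore demonstrates that the pipeline's machinery - curation
correctness, leakage-free featurization and tuning, calibration and
selection logic - works end to end; it does not certify any particular
MCC on real kinase data.

# Numerical choices and degenerate inputs

* Parent selection ties: heavy atoms, then molecular weight, then
  lexicographic canonical SMILES.
* Circular-fingerprint folding: OR over 1024-bit blocks of the 4096-bit
  vector.
* Agglomeration ties: for exactly equal merge distances the
  lowest-index pair merges first.
* Bond-free molecules (single heavy atoms) get empty fingerprints and
  zero-valued graph descriptors rather than errors; Tanimoto between two
  empty fingerprints is 0.
* Degenerate CV folds (a single class in train or validation) are
  refused with a message rather than silently scored.
* Grid-search ties resolve to the simplest configuration via the
  declared grid order.

# Problem sizes

The test suite validates signal recovery on a 2000-compound synthetic
extract (about 2150 curated LO training compounds after balancing) with
full RF and GP grid searches, label-shuffled controls over ten seeds, and
an end-to-end campaign - both schemes, the full 5 x 7 zoo on reduced
one-point grids, a 10,000-compound screening library, clustering and
representative selection. The analysis scripts default to a 500-compound
extract and the same 10,000-compound library. These sizes are package
choices that keep a complete run on a single CPU comfortable while
leaving the statistical checks well-powered.

# Known limitations

* The substructure-key dictionary and descriptor manifest are package
  conventions, versioned here, not byte-compatible reimplementations of
  any database's key set; models trained on them are not transferable to
  feature matrices produced by other toolkits.
* The pH-7.4 rule table covers the dominant drug-like ionizable groups
  only; full pKa prediction and tautomer canonicalization are out of
  scope.
* SVM probability calibration on near-separable data relies on the
  documented fallback and yields saturated scores; threshold sweeps on
  such models are step-like.
* The Gaussian process uses fixed median-heuristic length scales rather
  than marginal-likelihood optimization.
* Screening scale was validated to 10^4 compounds; the streaming/batched
  design extends to larger libraries, but wall-clock cost grows linearly
  with the descriptor-bearing representations.
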