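---
title: "Discovering lectin-binding motifs from glycan microarray data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering lectin-binding motifs from glycan microarray data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycanmotifs)
```

## The problem

A glycan microarray experiment exposes a glycan-binding protein (a lectin,
an antibody, a viral haemagglutinin) to hundreds of immobilised glycans and
reports a relative fluorescence unit (RFU) per spot. The scientific question
is *which structural feature — which motif — the protein recognises*, and,
once that is known, whether binding can be predicted for glycans that were
not on the array.

Glycans are branched, so motifs are subtrees of a rooted labelled tree, not
substrings: residues are nodes (root = the reducing-end residue, the one
coupled to the slide), and each edge carries the glycosidic linkage — an
anomeric configuration (α/β) plus the child and parent carbon positions,
e.g. `β1-3`.

Plain subtree mining misses one crucial aspect of recognition: many motifs
bind only when they are *terminal*. The classic example is peanut
agglutinin, which binds the T antigen (Gal β1-3GalNAc) but not its
sialylated form (Neu5Ac α2-3Gal β1-3GalNAc) — yet every subtree of the T
antigen is also a subtree of sialyl-T. This package resolves that with
**restricted-linkage nodes**: for each residue, any backbone position that
is *chemically capable* of carrying a linkage (some glycan in the dataset
occupies that position on that residue type) but is *unoccupied here* is
marked by a pseudo-node whose edge label lists those positions. A terminal
galactose free at positions 3 and 6 becomes `(*3,6)Gal`, and the pattern
`(*3,6)Gal β1-3GalNAc` matches the T antigen but not sialyl-T.

## The pipeline

`run_pipeline()` executes the stages below; every stage is also exported on
its own.

### 1. Calling positive binders (`assign_binding_classes`)

Background RFUs on these arrays are approximately log-normal and binders
are a small minority, so location and spread are estimated robustly:

* transform: $x_i = \log_{10}(\mathrm{RFU}_i - \min(\mathrm{RFU}) + 1)$;
* $\mathrm{MAD} = \mathrm{median}_i\,|x_i - \tilde{x}|$ with $\tilde x$ the
  median of the $x_i$;
* modified z-score: $M_i = 0.6745\,(x_i - \tilde{x})/\mathrm{MAD}$, where
  0.6745 is the standard-normal quantile at the 75th percentile, so $M$ is
  calibrated against an ordinary z-score when the background is roughly
  normal.

Spots with $M_i > 3.5$ are positive binders and $1.5 < M_i \le 3.5$ are
intermediate. The printed inequalities leave $M = 3.5$ unassigned; we close
that boundary downward into the intermediate class, the conservative choice.
Intermediate spots are discarded before mining and training so that neither
class is contaminated. Because the median and MAD ignore the upper tail,
the rule tolerates a substantial binder fraction; it degenerates only when
roughly half the array binds, in which case MAD may be 0 and the package
raises a `degenerate_distribution_error` recommending manually chosen
thresholds rather than guessing.

### 2. Restricted-linkage augmentation (`build_capability_map`, `add_restricted_linkages`)

The capability map records, per residue label, every parent position
occupied anywhere on the array. It is built from *all* structures on the
array, including held-out spots: it uses structures only, never labels or
RFUs, so no information about the response leaks into training. Unknown
positions (`?`) never certify capability. Each residue's capable-but-empty
positions are merged into a single restricted node (edge label
`*p1,p2,...`, sorted), mirroring how such motifs are written, e.g.
`(*3,4,6)GlcNAc α`. Restricted edge labels are matched by **set equality**
everywhere (mining, features, prediction): one consistent semantics, and the
printed motif means exactly what it matches. Augmentation is idempotent,
and the capability map is frozen into a trained model so that new glycans
are augmented consistently at prediction time.

### 3. Frequent subtree mining (`mine_frequent_subtrees`)

Candidate motifs are connected rooted subtree patterns of the augmented
trees. Support is per-glycan (a glycan counts once however many embeddings
it has) and a pattern is frequent at fraction $s$ if contained in at least
$\lceil s\,n\rceil$ glycans. The miner grows patterns one edge at a time
from exact embedding sets, deduplicating by a canonical code — a
child-order-invariant serialisation with the property that two patterns get
equal codes iff they are isomorphic. Because support is anti-monotone,
pruning at every growth step is exact: the miner visits only frequent
patterns and one-edge extensions of them, and its output order
(canonical-code lexicographic) is deterministic. The test suite checks it
against a brute-force enumerator that generates every sub-pattern of every
glycan by subset expansion and counts containment with an independent
backtracking matcher.

Two collections are mined and their results merged by canonical code:
the whole training set at 5% support, and the positive binders alone at
40% — binders resemble one another, and motifs shared by nearly half of
them can still sit below 5% of the full array. Restricted nodes
participate as ordinary nodes but never stand alone and never root a
pattern (a bare restricted node names no residue).

`mine_frequent_subtrees()` itself places no cap on pattern size; the
pipeline's default configuration caps patterns at 12 nodes (residues plus
restricted nodes). Published motif tables for common lectins top out around
11 nodes in this representation, so the cap does not bind in practice while
bounding the worst case on highly branched arrays.

### 4. Motif selection (`mrmr_select`, `augment_with_parent_anomer`, `l1_select`, `vif_prune`)

Mining yields hundreds to thousands of candidates; selection proceeds in
four steps.

**mRMR.** Greedy minimum-redundancy maximum-relevance over the binary
occurrence matrix: the first pick maximises mutual information with the
class labels; each later pick maximises relevance minus the mean MI with
the already-selected features (the difference form). MI is the plug-in
estimate of the empirical 2×2 joint, in bits — the base only scales scores,
never reorders them. Ten features are selected (enough to describe a
binding specificity; the classic choice for this method). Ties within
$10^{-12}$ resolve to the lowest column index, making selection
deterministic; the suite checks the greedy against an exhaustive oracle.

**Anomeric augmentation.** Some specificities depend on the anomeric
configuration at the motif's reducing end (ABA recognises
Gal β1-3GalNAc α). Each selected motif spawns up to three variants —
parent edge α, β, or merely present (α/β) — keeping only variants realised
by at least one training glycan, and a second mRMR round runs on the pooled
set (round-1 motifs plus their variants; the narrower reading of "the
original set of motifs", chosen for parsimony — re-entering the full mined
pool would mostly re-select what round 1 already rejected). An unknown `?`
parent anomer satisfies only the α/β variant.

**L1 logistic selection.** A weighted L1-regularised logistic regression
with cost
$-C\sum_n \{\alpha_1 t_n \ln y_n + \alpha_0 (1-t_n)\ln(1-y_n)\} + \lVert w\rVert_1$,
targets $t_n \in \{0,1\}$, predictions $y_n = \sigma(w^\top x_n + b)$, and
class weights $\alpha_c = N/(2N_c)$ (inverse to class size, normalised so
the weights sum to $N$; binding data are heavily imbalanced). The
unpenalised intercept is estimated alongside. $C$ is tuned over 100
log-spaced values in $[10^{-4}, 10^4]$ by stratified 5-fold
cross-validation, scoring mean Matthews correlation at the 0.5 probability
cut-off (the natural cut-off for a probability; the MCC is the balanced
choice under imbalance, with the zero-marginal convention MCC = 0); ties go
to the smallest $C$, i.e. the strongest regularisation. Features with
$|w| > 10^{-8}$ survive. Fits go through glmnet with
$\lambda = 1/(NC)$, which maps the cost above exactly onto glmnet's
objective; because $\sum_i \alpha_{t_i} = N$, glmnet's internal weight
rescaling is a no-op.

**VIF pruning.** Perfectly collinear survivors (e.g. a motif and a
super-motif that co-occur exactly) make coefficients unidentifiable.
$\mathrm{VIF}_j = 1/(1-R^2_j)$ from the least-squares regression of feature
$j$ on the rest plus an intercept; while any $R^2_j \ge 1 - 10^{-10}$, the
offending feature with the lowest mRMR relevance is removed and VIFs are
recomputed. The last feature is never removed.

### 5. The final classifier (`train_final_model`, `predict_binding`)

The final model is the same weighted logistic regression with a small L2
penalty ($C = 100$, i.e. $\lambda = 1/(100N)$ — nearly unregularised, just
enough to keep separable problems finite) on the surviving motifs.
Logistic regression is deliberate: the coefficient of a motif is the
change in log-odds of binding when the motif is present, so the model *is*
the motif table. Coefficients of highly correlated motifs should still be
read with care; the reported VIFs flag them. Prediction augments incoming
glycans with the model's frozen capability map, evaluates motif
containment, and applies the logistic function.

### 6. Evaluation (`roc_auc`, `cross_validate_pipeline`)

ROC curves and AUC (threshold sweep; ties contribute half, so the AUC
equals the normalised Mann–Whitney statistic) on a held-out stratified 20%
test split, and stratified 5-fold cross-validation in which *the entire
cascade — mining, both mRMR rounds, L1, VIF, final fit — is re-run inside
each fold on that fold's training data only*. Only the capability map is
shared across folds, and it never sees labels. This is the leak-free
reading of pipeline cross-validation; reusing globally mined subtrees
across folds would let validation glycans influence candidate generation.

## The synthetic-data generator

`simulate_array()` emulates exactly the features of real arrays that the
method's assumptions rest on, so that every stage is testable without
downloads:

* a log-normal background — log10-RFU $\sim N(2,\,0.3)$, i.e. spots around
  100 RFU spanning roughly 25–400, typical of a quiet array;
* a binder minority (default 10% of 600 spots, a realistic array size)
  whose log10-RFUs are shifted by +2 (a strong, cleanly separated signal);
* random glycan libraries over a 7-residue alphabet (Gal, Glc, Man, GlcNAc,
  GalNAc, Fuc, Neu5Ac) with chemically plausible attachable positions,
  grown to depth ≤ 3 with branching probability 0.25, giving the 2–12
  residue range typical of array libraries;
* a planted terminal motif — by default the T antigen, Gal β1-3GalNAc —
  grafted onto binders at a terminal position with the galactose left
  unsubstituted, so exactly `round(fraction * n)` structural binders exist
  by construction;
* decoys: half of the non-binders (configurable) carry the same motif
  capped by Neu5Ac α2-3 on the galactose — the sialyl-T mechanism. The
  decoys are the point: with them present, the *unrestricted* motif occurs
  in both classes and only its restricted-linkage form separates binders,
  which is the phenomenon restricted nodes exist to capture (the test suite
  verifies the restricted form carries strictly more mutual information
  with the class than the plain form).

What the generator does **not** emulate: replicate spots and spot-level
technical noise, concentration series, linker/surface effects, steric
hindrance from neighbouring branches, biosynthetically realistic residue
frequencies, and secondary (weaker) motifs. Passing the recovery tests
therefore shows the machinery is correct and sensitive under the model's
own assumptions — not that any particular real lectin will be modelled
well, where binding is messier and motifs overlap.

## Numerical choices and degenerate inputs

* Medians of even-length vectors: mean of the two central order statistics.
* MAD = 0 is an error, never a silent fallback.
* Boundary $M = 3.5$: intermediate; $M = 1.5$: negative.
* glmnet convergence threshold $10^{-10}$; C-grid ties → smallest C;
  non-zero tolerance $10^{-8}$; optimisation is deterministic, and all
  sampling (splits, folds, simulations) flows from explicit seeds, with
  stage seeds derived from one root seed.
* Single-feature fits pad glmnet's two-column minimum with an all-zero
  dummy column, which receives coefficient 0 by construction.
* Zero selected motifs → intercept-only model (with a warning), predicting
  one constant probability.
* Exact duplication of the training data is *not* exactly neutral: the cost
  is a sum, so doubling the data halves the effective penalty. At $C = 100$
  the penalty is already negligible and predictions move by well under 1%
  on non-separable data; the suite asserts that, not exact invariance.
* Unknown anomers/positions (`?`) are ordinary label values that match only
  themselves; they never enter capability maps or restricted sets.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script use: 50 random collections of
5–20 glycans (≤ 8 residues) for the miner–oracle comparison at supports
0.05–1.0; 100 random 30×10 binary matrices for the mRMR–oracle comparison;
and 10 simulated arrays (n = 600, 10% binders, shift 2.0, decoy fraction
0.5) for recovery, each with a full pipeline run and 5-fold pipeline
cross-validation, plus permuted-label and zero-shift null runs of the same
size. These sizes give stable pass/fail behaviour while keeping a full run
in a few minutes on one core.

## Known limitations

* Restricted sets match by equality; a motif mined from one array can fail
  on an array whose capability map differs. Score new glycans with the
  model that carries the matching capability map.
* The miner is exact but exponential in the worst case; the pipeline's
  12-node cap bounds it. Raise `max_nodes` for arrays with very large
  shared cores.
* Only the constructs of CFG linear nomenclature used on the arrays are
  parsed (residues with inline modifications, `a`/`b`/`?` anomers, digit or
  `?` positions, parenthesised branches, `-Sp<n>` spacers); GlycoCT, WURCS
  and IUPAC-extended are out of scope.
* Motifs are purely topological: no steric accessibility, no linker or
  surface effects, no concentration dependence.
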