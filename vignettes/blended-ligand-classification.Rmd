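---
title: "Methods: blended ensemble classification of ligand functional activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blended ensemble classification of ligand functional activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A ligand binding a G protein-coupled receptor can act as an **antagonist**
(blocks activation without signalling), an **agonist** (drives a signalling
response, including partial, inverse and biased agonism) or an **allosteric
modulator** (binds outside the orthosteric site and tunes the response).
`ligandblend` predicts this three-way functional class for a
receptor–ligand pair from two feature blocks: a wide table of ligand
descriptors computed from the molecule's SMILES and a wide table of
receptor embeddings computed from the protein sequence. The package treats
both as externally supplied inputs — the pipeline's contribution is
everything around and after them.

The classifier is a **blending ensemble**. Three tuned base learners are
fitted on the training split; their predicted class probabilities on a
disjoint internal-validation split form nine meta-feature columns
(three models × three classes, model-major order). The metamodel is then
trained on the internal-validation rows only, seeing the original features
plus the nine meta-features. This is single-holdout blending, not k-fold
stacking: the metamodel never sees the base models' training rows, and the
package enforces that disjointness with a hard error rather than a warning.

Assumptions worth stating explicitly:

* class labels are mutually exclusive and exhaustive at the
  (ligand, receptor) level after curation;
* descriptor and embedding tables are complete for every key in the
  interaction table (missing keys are an error, not an imputation);
* Ki values are in nM and comparable across sources once replicate sets
  are deduplicated;
* standardization parameters must come from the training split alone. A
  flag exists to fit on all rows for strict replication of pipelines that
  standardize before splitting, but the default avoids the leak.

## Curation rules

**Replicate-Ki deduplication.** For a replicate set the z-score
`z_i = (Ki_i − μ)/σ` uses the **population** standard deviation
(denominator N): the plain z-score formula makes no N−1 correction, and a
sample-σ variant stays available behind a flag. The cut `|z| > 1` is
strict, so a two-value set — whose z-scores are exactly ±1 — never loses a
value; among survivors the value with `|z|` closest to zero is retained.
Two numerical choices are deliberate: `|z|` comparisons carry a 1e-9
epsilon so floating-point noise cannot delete a value that is
mathematically on the boundary, and `|z|` ties break toward the smaller Ki
(then first occurrence), making the output deterministic and invariant to
input order and to unit rescaling. z-scores are computed once per set;
survivors are not re-scored iteratively.

**Label conflicts.** Databases disagree; resolving a conflict correctly
needs literature review, which a tool cannot automate. The default policy
is therefore `error` (list the conflicting keys and stop); `majority`
(ties toward the lowest class code) and `priority_source` (caller-supplied
source ranking) are available for automated runs.

**Zero-variance filtering** runs on the full curated dataset before
splitting, with tolerance exactly 0: a column must be truly constant to be
dropped. Scope defaults to descriptor columns only — embeddings are
retained wholesale, mirroring the common situation where protein-language
embeddings contain no constant dimensions.

## Split protocol

One rounding rule — round-half-up of `fraction × n`, clamped to
`[1, n−1]` — reproduces every published partition size this protocol is
known by: 6,919 pairs → 692 independent + 6,227, which split 80/10/10 into
4,981/623/623; and 4,274 Ki-bearing pairs → 427 + 3,847 →
3,077/385/385.

The independent holdout is **ligand-disjoint**: whole ligand groups
(every pair sharing a ligand, across all receptors) are allocated by
greedy accumulation over a seeded random ligand order, followed by a
single swap pass that exchanges one held group for one free group whenever
that moves the holdout closer to the target count. The achieved deviation
is recorded in the split manifest. The remaining rows are split with
largest-remainder stratified apportionment, keeping per-class counts
within one record of exact proportionality in every part.

## Scaffold audit

Bemis–Murcko scaffolds are computed on the bond graph: ring atoms (atoms
with a non-bridge incident edge) are protected, non-ring atoms are pruned
from the terminals inward, and atoms attached to the retained core by a
double or triple bond (exocyclic carbonyls on linkers, for instance) are
restored. Acyclic molecules share one empty-scaffold class — the standard
convention. The implementation was cross-checked against an independent
cheminformatics toolkit's Murcko implementation on a panel of probe
molecules, comparing canonical forms through a single canonicalizer.

Diversity is summarised by Shannon entropy `H = −Σ p_i log2 p_i` over
scaffold frequencies and its normalized form `H / log2 M` (defined as 0
when M = 1), the unique/total ratio, novelty (fraction of a query set's
scaffolds absent from a reference set) and a scaffold-overlap score. The
overlap score is defined here as the Pearson correlation of
relative-frequency vectors over the union of scaffolds (absent scaffold →
frequency 0), reported as `NA` when a frequency vector is constant. Under
this convention strongly negative values require nearly anti-correlated
frequency profiles; other definitions of "scaffold correlation" exist, and
this one is simply the package's documented choice.

## Learners and tuning

Six families are registered. The two gradient-boosting families are both
backed by xgboost but differ in growth strategy: `gbdt_a` grows trees
depth-wise under a `max_depth` cap, `gbdt_b` grows leaf-wise (lossguide)
under a `max_leaves` cap — the leaf-wise strategy that distinguishes
LightGBM-style boosting. The random forest is `ranger` with impurity
importances; k-NN (vote-fraction probabilities) and multinomial logistic
regression (softmax network with no hidden layer) round out the core; a
single-hidden-layer MLP is an optional plug-in, not part of the blending
core. Every fit is seeded and single-threaded, so identical
(spec, data, seed) gives bit-identical probability matrices.

Hyperparameter search is seeded random search over ranges declared once in
`inst/config/search_spaces.yaml`. The objective is mean **macro F1** over
stratified 3-fold cross-validation on the training split; macro averaging
weights the minority modulator class equally with the dominant antagonist
class, which plain accuracy would not. An alternative mode scores each
trial on the internal-validation split instead; cross-validation is the
default because it leaves the internal-validation split untouched for the
blending stage — tuning on the very rows that later train the metamodel
would couple model selection to the metamodel's training data. The trial
budget defaults small (the CLI default is 8, the acceptance runs use 6);
an 800-trial budget is a published-scale setting, not a desk-scale one,
and the budget is a plain argument.

Metamodel hyperparameters reuse the tuned specification of the chosen
family rather than being re-searched. Meta-probability columns are not
re-standardized: they are already bounded in [0, 1], and rescaling them
against training statistics would distort the very probabilities the
metamodel is meant to read. Predicted labels are the probability argmax
with ties broken toward the lowest class code — a fixed, documented rule
(it can only favour the majority class on exact ties, which are rare and
otherwise arbitrary).

## Evaluation

Counts are one-vs-rest per class: recall `TP/(TP+FN)`, precision
`TP/(TP+FP)`, `F1 = 2PR/(P+R)`, specificity `TN/(TN+FP)` and FPR
`FP/(FP+TN)`, with `0/0` defined as 0 and warned — degenerate splits
produce deterministic reports instead of NaNs. Macro values are unweighted
class means. AUC is one-vs-rest per class by the Mann–Whitney rank
statistic with average ranks for ties, macro-averaged; multi-class
specificity and AUC have no single canonical definition, and one-vs-rest
macro matches the binary formulas applied per class.

## Baselines

The **frequency baseline** answers "what does receptor identity alone
buy?": each test pair's label is drawn from its receptor's training class
frequencies (global prior for unseen receptors). Its closed-form expected
accuracy is `Σ_c p_c q_c` per receptor (test distribution p, training
frequencies q), aggregated by test support — the sampled mode is checked
against this closed form to three standard errors in the tests. The
**similarity baseline** answers "what does nearest-neighbour chemistry
buy?": the label of the most Tanimoto-similar training ligand of the same
receptor, k = 1, with ties resolved by majority then lowest class code.
Fingerprints are hashed circular (Morgan-style) identifier sets of radius
2 computed on the bond graph from iteratively re-hashed atom invariants
(element, heavy degree, summed bond orders, ring membership); radius and
k are arguments. These concrete choices — k = 1, radius 2, the tie rules —
are this package's interpretation of the baseline designs.

## The synthetic generator

`synth_generate()` produces the statistical structure the pipeline
assumes, with every planted parameter recorded in a truth object:

* **Interactions**: `n_pairs` pairs sampled from the ligand × receptor
  grid; a configurable fraction carries replicate Ki rows from multiple
  sources, and a small fraction is duplicated with a conflicting label.
* **Ki values**: lognormal around class-dependent medians (20 / 100 /
  400 nM for antagonists / agonists / modulators), log-scale SD 0.6 —
  affinities spanning orders of magnitude make the z-score machinery
  meaningful. Replicate sets **without** a planted outlier have exactly
  two values: their z-scores are ±1 and a strict `|z| > 1` cut keeps both,
  so they exercise the keep path. Planted-outlier sets have 3–4 values,
  one multiplied by 10. This structure is what makes the curation report's
  removed-value count auditable: for arbitrary set sizes the population
  z-scores satisfy `Σ z² = n`, so any 3-value set has `max |z| ≥ 1.41` and
  natural sets would always lose a value, divorcing the removal count from
  the planted-outlier count.
* **Features**: receptor embeddings and ligand descriptors are standard
  normal; the last `n_constant_descriptors` descriptor columns are
  constant, planting exact targets for the zero-variance filter.
* **Class signal**: two latent axes `z1 = d1·sign(e1)` and
  `z2 = d2·sign(e2)` — a ligand descriptor whose effective sign is flipped
  by a receptor embedding dimension, so the optimal class depends jointly
  on ligand and receptor and one ligand can genuinely carry different
  labels on different receptors. Gaussian-quantile thresholds carve the
  axes into three regions whose masses equal the configured class mix
  (default 53/27/20, the antagonist/agonist/modulator proportion of a
  6,919-pair corpus). The sampled label follows a softmax that adds
  `signal_strength` logit to the region's class plus a bias vector
  calibrated by fixed-point iteration so the marginal class mix matches
  the target at any signal. `signal_strength = 0` therefore gives labels
  exactly independent of the features (the null-safety tripwire);
  the default 4 gives a Bayes-optimal accuracy near 0.96, a deliberately
  strong signal so end-to-end recovery is a meaningful bar.
* **SMILES** come from a bank of 16 valid template prefixes in about ten
  Bemis–Murcko families, extended with CH2 tails to make molecules
  distinct. The chemistry is **decorative**: parseable enough to exercise
  canonicalization, scaffold and fingerprint code paths, but unrelated to
  the descriptor values.

What passing tests on this generator do **not** show about real data: the
descriptor blocks are isotropic Gaussians rather than correlated
Mold2-like blocks; embeddings carry no evolutionary structure; the
scaffold vocabulary is tiny, so scaffold novelty of a ligand-disjoint
holdout is near zero here whereas real independent sets are reported with
substantial novel-scaffold fractions; and the planted signal is
low-dimensional and axis-aligned, far easier than real structure–activity
relationships. The synthetic suite validates the machinery — leakage
guards, bookkeeping, calibration, metric arithmetic — not chemical
generalisation.

## Problem sizes and runtime choices

The packaged study-shape preset is a deliberate scale-down that preserves
shape: 21 receptors, 400 ligands, 800 pairs, 60 descriptors (8 constant),
64 embedding dimensions, and the 53/27/20 class mix of the full corpus.
The test suite and the acceptance script run the full pipeline on this
preset with a 6-trial budget per family; at these sizes the end-to-end run
completes in about a minute on one CPU. Evaluation splits of 72–80 pairs
make test-split metrics visibly seed-dependent (a few points of macro F1);
the acceptance machinery fixes the preset seed where a deterministic bar
is asserted and otherwise reports the honest, seed-varying number.

## Known limitations

* Descriptor and embedding computation is out of scope; the bundled toy
  featurizers are labelled non-scientific and exist only so pipeline code
  paths can run without external tools.
* The scaffold-overlap convention cannot be compared numerically against
  overlap statistics computed under other, undocumented definitions.
* The deep-learning base family is intentionally absent from the blending
  core; the MLP plug-in is a shallow stand-in.
* OpenBabel and a different canonicalizer may disagree on canonical SMILES
  strings; all within-package comparisons therefore pass through the one
  bundled canonicalizer.
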