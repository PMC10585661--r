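---
title: "Methods: structural comparison of lipids and lipidomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural comparison of lipids and lipidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidstruct)
```

This vignette documents the models and procedures implemented in
`lipidstruct`, the assumptions behind them, the tunable parameters, and
the numerical and design choices a maintainer should know about.

## Nomenclature model

Lipid names are parsed from a curated subset of shorthand nomenclature
covering `r length(lipid_classes())` classes across glycerophospholipids
(diacyl, lyso, ether `O-` and plasmalogen `P-` variants, cardiolipin),
glycerolipids (MG/DG/TG), sphingolipids (Cer, HexCer, Hex2Cer, SM, LSM,
SPB), cholesteryl esters and free fatty acids. Four information levels
form a ladder:

* **species** — one summed chain, e.g. `PC 34:2`;
* **molecular species** — chain compositions known, sn positions not
  (`_` separator);
* **sn-position** — chains assigned to glycerol positions (`/` separator);
* **structure-defined** — additionally all double-bond positions stated,
  e.g. `FA 18:2(9,12)`.

E/Z stereo-descriptors on double-bond positions are parsed and discarded:
the comparison engine uses position integers only, so stereochemistry
cannot influence a distance. Hydroxyl suffixes (`;O2`, `;OH`, positioned
`;3OH`) map to hydroxyl functional-group entries; `oxo`, `COOH`, `OOH`
and `NH2` are handled the same way. The long-chain base of a sphingolipid
carries its hydroxyl/amino groups as chain functional groups, which keeps
backbone graphs connected and lets an sn-resolved ceramide compare
cleanly against a species-level one. Canonical rendering is a parse
fixed point: `format(parse_lipid(x))` re-parses to an equal object.

## Lipid-to-lipid distance

Two lipids are compared at the **lower** of their information levels;
the higher-resolved one is projected down (summing chains, dropping
positions) first. The distance is `1 - J`, with `J` the Jaccard index
over aligned **components** — heavy atoms and bonds:

* The fixed part of each class (backbone + headgroup) is stored as an
  explicit hydrogen-suppressed graph in the class registry. For a class
  pair, an exact branch-and-bound search computes the maximum common
  *connected* subgraph (element labels and bond orders must match); the
  result is cached per unordered pair. A double bond is **one**
  component whose order attribute must match — not two components. A
  bond present in both graphs with differing order therefore counts once
  in the union and never in the intersection.
* Carbon chains are aligned positionally from the carbonyl/linkage
  carbon (the "forward" counting direction). Chain graph sizes follow
  the linkage context: a free fatty acid of C carbons counts `2C + 3`
  components (39 for C18), an esterified acyl `2C` (its ester oxygen
  belongs to the headgroup), ether chains and long-chain bases `2C - 1`.
  The union of two aligned chains is the skeleton of the longer plus all
  unmatched functional-group components; the intersection is the
  skeleton of the shorter plus matched functional groups minus
  double-bond mismatches.
* **Double-bond mismatch rule.** When both chains carry complete
  position sets, mismatches are the positions present in exactly one
  chain within the aligned region. When either chain lacks positions,
  *every* double bond of both chains is a mismatch. Treating unknown
  positions pessimistically is deliberate: across structure-resolved
  reference data most chain pairs share no double-bond positions, so
  assuming a match would systematically overestimate similarity.
* **Identity guard.** Two chains identical at their information level
  count zero mismatches even without positions. Without this guard the
  all-mismatch rule would give a lipid a nonzero distance to itself,
  breaking the equivalence-relation property that the downstream
  Hausdorff comparison and clustering rely on.
* Chains are paired either in sn order (`sn_strict`) or by the
  permutation maximizing the total intersection (`best_permutation`,
  the default — the safer choice for molecular-species data where sn
  positions are unknown). Ties on the intersection prefer the smaller
  union, which makes the choice independent of argument order. With
  unequal chain counts (e.g. TG vs DG), unpaired chains contribute their
  full component count to the union only; this is our reading of how a
  maximum-common-subgraph framework should price a missing chain, and it
  keeps all class pairs comparable. Likewise, chains of different kinds
  (acyl vs ether vs long-chain base) remain alignable, with the linkage
  difference absorbed into the per-kind skeleton size.

The engine's calibration points: `FA 18:2` vs `FA 18:1` → 36/39 shared
components; `FA 18:2(9,12)` vs `FA 18:1(9)` → 38/39; both recomputed in
the test suite and by `scripts/acceptance.R`.

## Structural spaces

`build_global_space()` computes the n × n distance matrix, treats each
lipid's distance profile (matrix row) as an observation, column-centres,
and extracts principal components by deterministic SVD (`prcomp`). The
default of **7 components** balances geometric fidelity against the
noise in trailing components; it is user-settable, and with
`n_components = n` the embedding reproduces the centred row geometry to
numerical precision (asserted at 1e-8 in the tests). Each component's
sign is fixed so its largest-magnitude loading is positive, making runs
bit-reproducible. Degenerate input (all lipids identical) errors rather
than returning an arbitrary embedding.

A lipidome's subspace is the row subset of its observed lipids. With
quantities enabled (the default), one extra coordinate per lipid is
appended: log10 abundance, standardized, then rescaled to the standard
deviation of the subspace's own first-component scores. The log10
transform reflects that lipid abundances span orders of magnitude and
would otherwise let a single abundant lipid dominate; the rescaling makes
the quantity axis commensurate with the structural axes — this exact
normalization is one consistent reading of tying quantities to the
first-component variance, and it is isolated in one function
(`lipidome_subspace`) should a different convention be preferred.
Zero-variance guards: constant abundance vectors and single-lipid
lipidomes get a zero quantity coordinate.

**A property worth knowing:** in a space built from a *homologous
series alone* (e.g. PC 12:0/12:0 through PC 12:0/26:0), the first
component orders the series strictly by chain length. Embedded among a
few hundred heterogeneous lipids, the first components instead capture
class and category separation, and the series appears as an arc that can
fold back — sequential positioning survives (each member's nearest
series neighbour remains a chain-length neighbour, asserted in the
tests), but strict monotonicity along any single global component does
not. Analyses that need within-series ordering should look at the
series' own subspace.

## Lipidome distances and clustering

Lipidomes are compared with the Hausdorff distance between their
subspace point sets, computed in the **global** space coordinates (the
alternative — a per-pair union subspace — would make distances depend on
the pair, breaking the metric structure of the m × m matrix). Both
members of a pair use the same augmented dimension count: quantities on
for both or off for both. The implementation uses the early-break scan
(a point whose nearest neighbour is already below the running maximum is
abandoned) but is required by the tests to equal the naive double loop
exactly — the break changes work, not arithmetic.

Clustering is hand-stepped agglomeration with three linkages; the
default, unweighted average linkage, defines cluster distance as the
arithmetic mean over all cross pairs. Ties in the minimal entry break
deterministically by the smallest index pair, so dendrograms are
reproducible. Heights are merge distances, untransformed; for all three
linkages they are monotone, so the Newick serialization (branch length =
parent height − child height) round-trips heights exactly.
`subtree_reanalysis()` restricts the table to a branch's samples,
shrinks the lipid universe to their union, and recomputes everything —
distances in the smaller universe legitimately differ from the original.

## Feature analysis

Internal dendrogram nodes are annotated per numerical study variable
with the two-sample Kolmogorov–Smirnov statistic between the branch leaf
values; the **best separation value** is the smallest data value
attaining the maximal CDF difference. Categorical variables get
per-branch frequency tables instead of a KS split.

`sfs_select()` performs sequential forward selection over ordinary
least-squares regressions of the study variable on log10-transformed
abundances (half-minimum pseudo-count per lipid; unobserved abundances
enter as zero before the pseudo-count — heavy-tailed raw abundances
would otherwise dominate the fit). The AIC convention is
`N·ln(RSS/N) + 2(k+1)` with `k` = features + intercept; constant terms
of the Gaussian likelihood are omitted since only differences between
models on the same response matter, and the RSS is floored at 1e-12 so
perfect fits stay finite. Round r evaluates all `n − r + 1`
one-lipid extensions of the previous selection; the search stops after
`⌈√n⌉` rounds — a quadratic cap that also limits overfitting — and the
reported best step is the global AIC minimum across rounds, ties going
to the smaller model and, within a round, to the lower lipid index.
Binary categorical targets are coded 0/1 and fitted by OLS (not
logistic regression — a deliberate simplicity choice; the AIC ranking,
not the link function, drives the selection). Variables with more than
two categories are encoded one-vs-rest per category and the
best-scoring encoding is kept; this was an open design point and the
one-vs-rest choice keeps every category's contrast available at the
cost of running the selection once per category. Missing variable
values drop the affected samples; nothing is imputed.

One caveat is documented rather than "fixed": under a null (variable
independent of all lipids) greedy forward selection still drives the
AIC down, because the best of `n` candidate lipids per round gains more
fit than the +2 parameter penalty costs. The `⌈√n⌉` cap bounds the
damage, but the best step under the null is typically *not* the
smallest model — AIC does not account for selection. Users should treat
the selected set as a ranking heuristic, not an inference.

## Statistics and quality control

Group comparisons use Welch's unequal-variance t-test for two groups
(the robust default when group variances are unknown) and one-way ANOVA
beyond two. Volcano analysis computes log2 fold changes on raw group
means but p-values on log10-transformed abundances — conventional
volcano semantics — with Benjamini–Hochberg adjustment; significance
requires both |log2 FC| ≥ log2(threshold) (default threshold 2) and
adjusted p ≤ 0.05. ROC/AUC uses the trapezoid over all thresholds and
equals the Mann–Whitney identity `U/(n₁n₂)` to 1e-12 (asserted). CVs are
sd/mean on raw abundances per lipid and group, with zero-mean lipids
flagged rather than divided.

The Benford check extracts leading decimal digits scale-invariantly
(exactly invariant under powers of ten) and tests observed frequencies
against `log10(1 + 1/d)` with a chi-square goodness-of-fit on 8 degrees
of freedom. Conformance means p ≥ 0.01; the threshold is exposed as an
argument. The chi-square test is the simplest standard choice here; with
fewer than 50 usable values conformance is reported as indeterminate
(`NA`) rather than guessed. Multi-decade positive data (like healthy
abundance tables) conform; narrow-range or poorly imputed data do not.

## Synthetic data: what it emulates, what it does not

`generate_lipidomes()` draws a lipid universe per class (default: 42
lipids over 11 classes spanning all five categories), per-lipid
baselines log-uniform over six decades (`10^U(2, 8)` — matching the
dynamic range of real data and making the pooled abundances conform to
Benford's law by construction), and per-sample lognormal noise with
σ = 0.5 on the natural-log scale (CV ≈ 53%, a realistic combined
technical + biological variability). Planted effects either scale a
lipid or class by a fold change in one group or make it **exclusive** to
a group — a compositional difference, which is the natural way to plant
lipidome clusters for a method whose premise is that lipidomes are
different lipid *sets*. Generation is seeded and bit-reproducible, and
restores the caller's RNG state.

The generator does **not** emulate instrument artifacts (isotope
overlap, in-source fragmentation), correlated lipid co-regulation,
batch effects, or censoring at the detection limit (missingness is
uniform, not abundance-dependent). Passing tests on synthetic data
therefore demonstrate correctness of the algorithms under controlled
conditions, not robustness to real-data pathologies.

Problem sizes used in the test suite were chosen as the smallest that
exercise each property convincingly: 1,000 random pairs for the
symmetry property, 200 point-set pairs (20 points, 7-D) for the
Hausdorff oracle, 50 seeded simulations for planted-cluster recovery
(15 samples, 3 groups, 42 lipids each), 100 for forward-selection
recovery (25 lipids, 20 samples), and 1,000 replicates for the type-I
error calibration.

## Known limitations

* The class registry covers ~28 common classes, not the full shorthand
  grammar: no adducts, glycan headgroup trees beyond two hexoses,
  isotope labels, or ring/stereo detail.
* Headgroup graphs are topological; three-dimensional geometry is
  ignored, as the subgraph matching operates on connectivity.
* The exact connected-MCS search is exponential in the worst case; it is
  fast on the small, label-diverse registry graphs (all 406 class pairs
  compute in seconds, cached thereafter) but is not a general-purpose
  MCS engine.
* Categorical targets in the feature selection use 0/1 OLS; for strongly
  unbalanced groups a likelihood-based classifier would rank differently.
* The statistics module covers the standard univariate battery; mixed
  models, longitudinal designs and batch correction are out of scope.
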