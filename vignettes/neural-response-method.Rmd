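---
title: "Predicting protein function with neural-response kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein function with neural-response kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrprof)
```

## The problem and the model

Sequence-similarity annotation transfer fails for remote homologues: two
proteins can share a molecular function while their sequences no longer
align. `nrprof` attacks this with a two-layer representation built on motif
templates (PROSITE patterns, Pfam domains) rather than raw sequence.

**Layer 1 — the initial kernel.** An ordered library of $m$ templates
$q_1,\dots,q_m$ carries a similarity matrix $S$ with entries $s(q_i, q_j)$,
in practice profile–profile alignment scores exported from an external
aligner. A valid $S$ must be symmetric, self-dominant
($s(q_i,q_j) \le s(q_i,q_i)$ — a motif is most similar to itself) and
positive definite, so that it is a legitimate reproducing kernel.
`validate_similarity()` checks all three; `repair_psd()` projects an
offending matrix into the valid class (see *Numerical choices*).

**Layer 2 — neural responses.** A protein $p$ with template hits
$q_{p1},\dots,q_{pk}$ is encoded as the $m$-vector
$$N(p) = \big(N(p,q_1), \dots, N(p,q_m)\big),$$
where each component is a maximum over the protein's hits. Two readings of
that maximum coexist and both are implemented:

* `hit_score` (default): $N(p,q)$ is the largest scan score of $q$ itself
  among $p$'s hits (0 if $q$ never hits), repeats of one template resolved
  by the maximum score.
* `kernel_propagated`: $N(p,q) = \max_t s(q_{pt}, q)$, propagating
  evidence through the initial kernel so templates similar to a hit
  template also respond.

Both readings are defensible; `hit_score` is the default because it is
the one the CHD1 fixture shipped with the package pins down end to end,
and the other stays selectable.

**Pair encoding and derived kernels.** A protein pair is encoded as the
difference $N_{(i,j)} = N(p_i) - N(p_j)$; concatenating the two responses
is a conceivable alternative encoding, but the difference is the method's
canonical choice and the only one implemented. On these
encodings two derived kernels are available: linear
$\langle N_{(i,j)}, N_{(i'',j'')}\rangle$ and Gaussian
$\exp(-\lVert N_{(i,j)} - N_{(i'',j'')}\rVert^2 / \sigma^2)$.

**Mapping engine.** A kernel classifier $f$ is trained on pairs labeled
$Y = 1$ (the two proteins share a GO term) or $Y = 0$ (they share none),
and outputs a similarity in $[0,1]$. A pair is called positive when
$f \ge 0.5$ (boundary inclusive). Query proteins are then either assigned
the terms of all base proteins exceeding the threshold, or — the
threshold-free mode — the base set is ranked by $f$ and the query inherits
up to five distinct GO terms walking down the ranking, preferring leaf
terms (the most specific annotation level) and, among non-leaf candidates,
the term with the least sequence diversity.

**GO–motif association.** As a by-product, the motifs mapped to a GO term
are ranked by $s_i = NM_i \times AS_i$, where $NM_i$ counts the
(non-redundant) proteins of the term hit by motif $i$ and $AS_i$ is the
motif's alignment strength.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `mode` | `"hit_score"` | neural-response component definition (above) |
| kernel `family` | `"gaussian"` | derived kernel on pair encodings |
| `sigma` | median heuristic | Gaussian scale; median pairwise distance of the training difference vectors, reported at fit time |
| `linear_variant` | `"difference"` | see *Design choices* |
| `engine` | `"least_squares"` | loss of the mapping engine (`"svm"` = hinge) |
| `reg` | `1e-3 * n` | ridge constant (least squares) or `1/C` (SVM box constraint) |
| `threshold` | 0.5 | decision cut on $f$; a sweep shows a flat high-accuracy region around 0.5–0.6, `threshold_sweep()` reproduces this on fixtures |
| `min_proteins` | 5 | GO terms with fewer distinct proteins are screened out |
| `identity_threshold` | 0.80 | redundancy filter cut (sequences above it collapse) |
| `k` (top terms) | 5 | ranked-assignment budget |

All scores are dimensionless alignment bit-score-like quantities; GO edge
distance is counted in `is_a` edges.

The least-squares engine is the default: it solves a single dense linear
system, is markedly faster than the SVM at near-identical accuracy in this
setting, and its solution can be checked against an independent solve
(which the test suite does to $10^{-8}$).

## Design choices made where the design was open

* **GO "tree" distance.** GO is a DAG; the hierarchy is traversed over
  `is_a` edges only, and the edge distance is the undirected shortest path
  within one namespace — the minimal consistent reading of an "edge
  distance". Terms in different namespaces, or in disconnected components,
  are reported unreachable (`Inf`).
* **Linear kernel form.** Two forms of the linear kernel coexist: the
  inner product $\langle N_{(i,j)}, N_{(i'',j'')}\rangle$ of the two
  difference vectors, and an expanded component-sum over the four
  component responses — and the two are not algebraically equal. The
  difference form is the default (it is the one consistent with the pair
  encoding); the expansion is available as `linear_variant = "expanded"`.
* **Gaussian exponent.** Implemented as
  $\exp(-\lVert d \rVert^2/\sigma^2)$ — $\sigma^2$ in the denominator,
  no factor 2.
* **Squashing.** The mapping function must land in $[0,1]$, which the raw
  dual expansion does not guarantee. Least-squares scores are clipped to
  $[0,1]$; SVM decision values pass through a logistic map calibrated on
  the training scores (Platt-style). Both are recorded in the model
  archive.
* **PSD enforcement.** Raw profile–profile alignment scores need not form
  a positive definite matrix — aligners make no such guarantee.
  `repair_psd()` clips eigenvalues at a floor of $10^{-8}$ and then raises
  each diagonal entry to its largest off-diagonal; both moves preserve
  symmetry and positive semidefiniteness, the combination is idempotent,
  and the result always validates. Directional score matrices are
  symmetrized as $(S + S^\top)/2$ on load, with the maximum asymmetry
  reported.
* **Multiple leaf terms.** When a rank-1 protein carries several leaf
  terms, all of them are assigned within the top-$k$ budget; the
  confidence of a term supported by several ranked proteins is the
  maximum contributing $f$.
* **domtblout score.** The per-domain bit score (column 14) is parsed, not
  the sequence-level score, because the response maximizes over individual
  hits.
* **AS definition.** The alignment strength $AS_i$ of a motif is the mean
  over proteins of the per-protein maximal hit score; since other
  aggregates are equally defensible it is configurable (median, max).

## Numerical choices

* Gram matrices are explicitly symmetrized before solving; the
  least-squares system `(G + reg I) alpha = Y` errors with advice when
  singular (`reg = 0` with duplicate pairs).
* Ranking ties are broken lexically by protein id, making predictions
  deterministic; note that least-squares score clipping can produce
  genuine ties at 1.0.
* Degenerate inputs: proteins with no hits encode as all-zero vectors with
  a warning (not an error); empty distance levels are omitted with a
  warning; one-class training sets are errors.
* All randomness (sampling, folds, generators) flows from explicit integer
  seeds.

## What the synthetic generator emulates

`fixture_config()` / `write_fixture()` generate, from one seed, the full
input set: a template library with a valid random Gram initial kernel
(`S = A^\top A + \varepsilon I`, diagonal raised where needed), a complete
toy GO tree, per-leaf-term protein sets, and hit tables in which each
term's proteins share a *signature* template subset. Signature blocks are
allocated per tree node and a leaf's signature is the union of blocks
along its root path, so the number of shared signature templates between
two terms decreases linearly with their edge distance — this is what makes
classification specificity decay with GO distance on fixtures, the
qualitative behaviour expected of a function-specific classifier on real
data.

Scores are gamma-distributed (shape 16, standard deviation a quarter of
the mean), resembling positive, right-skewed bit scores. `signal` is the
mean signature score; `noise` sets both the background hit probability per
non-signature template (`min(1, noise/signal)`) and the background score
scale. At `signal == noise` every response coordinate is an independent
draw from one distribution, so the class structure vanishes by
exchangeability and accuracy is chance-level by construction.

Two presets fix the study conditions used throughout the tests:

* `easy`: 40 templates, 4 leaf terms × 8 proteins (depth-2 binary tree),
  signal 10, noise 1. Pair datasets drawn from it use 100 positive and 100
  negative pairs (the positive universe of this fixture is 112 pairs);
  5-fold cross-validation at these sizes recovers the structure almost
  perfectly (accuracy ≥ 0.95, AUC ≥ 0.98).
* `hard`: 60 templates, 8 leaf terms × 18 proteins (depth-3 tree),
  signal = noise = 5. The larger protein pool matters: cross-validation
  partitions *pairs*, not proteins, and with a small pool the
  co-membership structure of the training pairs alone can reconstruct
  held-out labels even when the responses carry no signal (we measured
  ~0.82 accuracy on provably exchangeable responses over 32 proteins).
  Spreading 200 pairs over 144 proteins keeps each protein in only a few
  pairs, the regime in which the pair-level protocol is honest and the
  chance-level expectation holds.

What passing these tests does *not* show about real data: the generator
draws independent hit scores per template (real motif hits are correlated
along domains), its GO tree is balanced and single-namespace, annotations
are single-term, and sequences are not simulated at all — the redundancy
filter is exercised on ad-hoc strings. Corpus-scale accuracy figures are
therefore not reproduced here, only the method's qualitative and
algebraic properties.

## A worked example that is checked exactly

The package ships the seven template hits of the human chromodomain
helicase DNA-binding protein CHD1 as a fixture
(`inst/extdata/chd1_hits.tsv`):

```{r chd1}
lib <- read_library(system.file("extdata", "chd1_library.tsv", package = "nrprof"))
hits <- parse_hit_table(system.file("extdata", "chd1_hits.tsv", package = "nrprof"))
compute_response("CHD1", hits, lib)
```

The response has exactly seven nonzero components, the largest being
25.932 on PS51192; the acceptance script and test suite assert this
end-to-end.

## End-to-end on a synthetic preset

```{r pipeline}
cfg <- fixture_preset("easy", seed = 1)
lm <- gen_library_and_matrix(cfg)
toy <- gen_go_toy(cfg$depth, cfg$branching)
gh <- gen_hits(cfg, toy$graph)
R <- compute_responses(gh$hits, lm$library)
ds <- make_pair_dataset(gh$annotations, n_pos = 100, n_neg = 100, seed = 1)
cross_validate(ds, R, seed = 1)
```

## Known limitations

* Profile–profile alignment, motif scanning (HMMER/PrositeScan) and
  CD-HIT are external: this package parses and emulates their outputs,
  it does not run or replicate them. The redundancy filter is a greedy
  shared-k-mer stand-in, adequate for fixtures only.
* Only `is_a` edges participate in leaf detection and distance; `part_of`
  and regulatory relations are ignored.
* Assigned terms are not propagated up the DAG (no true-path closure).
* Cross-validation partitions pairs, not proteins; see the `hard` preset
  discussion above for when that leaks.
* One mapping engine serves all GO terms; per-term classifier designs are
  deliberately out of scope.
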