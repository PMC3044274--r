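---
title: "Score regularization on the peptide affinity graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score regularization on the peptide affinity graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmreg)
```

## The problem and the assumption

A shotgun-proteomics search engine assigns each MS/MS spectrum a candidate
peptide and a score (or E-value), judging every peptide-spectrum match (PSM)
in isolation. But peptides are not independent: a protein that is truly
present in the sample tends to contribute several confidently matched
peptides, whereas a random (incorrect) match usually sits in a protein with
no other support. `psmreg` encodes this as a *consistency assumption*:
**PSMs whose peptides co-occur in proteins should receive similar scores.**

The assumption is deliberately soft. Peptides of one protein genuinely differ
in ionization and fragmentation behavior, so their search scores differ too;
the method therefore never forces equality, it only penalizes inconsistency
and balances that penalty against fidelity to the original scores.

## Graph construction

For PSM `i`, let `U_i` be the set of proteins containing its peptide. The
affinity between PSMs `i != j` is the Jaccard index

$$w_{ij} = \frac{|U_i \cap U_j|}{|U_i \cup U_j|},$$

a probability-like quantity in [0, 1]: 1 when the two peptides occur in
exactly the same proteins, 0 when they share none. The diagonal is zero (no
self-loops). Two PSMs of the same peptide — the same peptide identified from
different spectra — are distinct nodes with identical protein sets, hence
joined with weight 1; no special-casing is applied. Because the form of the
affinity is a genuinely open design choice, two alternatives are selectable
via `kernel=`: `overlap_product` ($|U_i \cap U_j| / (|U_i||U_j|)$) and
`overlap_min` ($|U_i \cap U_j| / \min(|U_i|, |U_j|)$). All results in this
package use Jaccard unless stated.

With degrees $d_{ii} = \sum_j w_{ij}$ the normalized operator is
$S = D^{-1/2} W D^{-1/2}$, and $I - S$ is the normalized graph Laplacian. The
normalization matters: peptide neighbor counts vary enormously (a peptide in
a large, well-covered protein has many neighbors; a one-hit wonder has none),
and the unnormalized Laplacian would penalize well-connected peptides in
proportion to their degree.

**Isolated nodes.** A PSM sharing no protein with any other PSM has zero
degree, which makes $D^{-1/2}$ singular. Each isolated node receives a
*dummy neighbor* joined only to it with weight `dummy_weight = 1e-8`. Dummy
nodes enter the solve with initial score 0 and are stripped from every
output. One consequence deserves emphasis: after degree normalization the
dummy edge weight cancels ($S$ restricted to the pair is the 2x2 exchange
matrix regardless of the weight), so an isolated PSM's score is *not*
approximately preserved — it is shrunk to $\lambda x / (1-(1-\lambda)^2) =
x/(2-\lambda)$, e.g. $2x/3$ at $\lambda = 0.5$. This is an inherent property
of the dummy-node strategy, it applies uniformly to all isolated PSMs (a
monotone rescaling within that group), and the test suite asserts it
exactly.

**Sparse representation.** `W` and `S` are stored as symmetric sparse
matrices (`Matrix` package); pairwise intersections come from a single
sparse cross-product of the PSM-by-protein incidence matrix, so construction
and matrix-vector products scale with the number of overlapping pairs, not
$n^2$.

## The objective and its solvers

Given initial scores $X$ (for E-values, $x_i = -\log_{10} E_i$; the base
is a convention — any base rescales $X$, and because the objective is not
scale-invariant the base is part of the method's configuration), the new
scores minimize

$$Q(Y) = (1-\lambda) \sum_{i<j} w_{ij}
\left(\frac{y_i}{\sqrt{d_{ii}}} - \frac{y_j}{\sqrt{d_{jj}}}\right)^2
+ \lambda \sum_i (y_i - x_i)^2, \qquad \lambda \in (0,1).$$

The pairwise sum (each unordered pair once) equals the quadratic form
$Y'(I-S)Y$ exactly — this identity is asserted to 1e-10 in the tests, and it
pins down the constant conventions: with this normalization, setting
$\nabla Q = 0$ gives

$$Y^{*} = \lambda\, (I - (1-\lambda) S)^{-1} X.$$

The unit tests verify this three ways: a hand-inverted 2-node system
($X = (1,0)$, $\lambda = 0.5$, $Y^* = (2/3, 1/3)$), a vanishing
central-difference gradient at $Y^*$, and the minimizer property
$Q(Y^*) \le Q(Y^* + \epsilon V)$ under random perturbations.

Because the eigenvalues of $S$ lie in $[-1, 1]$ (checked numerically on
hundreds of random graphs), every eigenvalue $1 - (1-\lambda)e$ of the
system matrix is positive: the system is symmetric positive definite and
always solvable, and the fixed-point iteration

$$Y(t+1) = \lambda X + (1-\lambda) S\, Y(t)$$

is a contraction converging to $Y^*$ for every $\lambda \in (0,1)$.

Numerical choices, all configurable:

* **Solver switch** — `solver = "auto"` uses the sparse direct solve up to
  5000 nodes and the iteration beyond, where forming/factorizing
  $(I-(1-\lambda)S)$ may be too dense; the iteration needs only sparse
  matrix-vector products.
* **Iteration start** — $Y(0) = X$, the best available guess. The fixed
  point is unique, so the start affects only the sweep count (tested: warm
  and cold starts agree).
* **Tolerances** — the iteration stops when the max-norm change drops below
  `tol = 1e-9` (then the stationarity residual is below about
  $(1-\lambda)\,$`tol`); `max_iter = 10000` is a safety net that is
  unreachable in practice for $\lambda$ bounded away from 0.
* **Stationarity reporting** — both solvers report
  $\max_i |[(I-(1-\lambda)S)Y - \lambda X]_i|$ so a caller can audit the
  solve.

**Choosing lambda.** $\lambda$ trades smoothing (small $\lambda$) against
fidelity (large $\lambda$); at $\lambda \to 1$ the scores revert to $X$
(asserted at $\lambda = 0.999$ to within 1% of the score range). There is no
automatic selection; 0.5 is the default as an equal weighting that performs
well across simulated conditions, and `lambda_sweep()` exposes the
sensitivity. Note the solution is linear in $X$ (doubling $X$ doubles
$Y^*$) but not translation-invariant — adding a constant to all scores does
not add a constant to the output — so scores should be on a meaningful
additive scale (log E-values qualify).

The mechanism by which this helps identification: within each group of
protein-sharing PSMs, scores shrink toward the group mean. Correct PSMs
cluster in truly present proteins with high-scoring company, so their means
stay high; an isolated high-scoring random match is pulled down by its
unsupported neighbors. Both directions reduce the overlap between the
correct and incorrect score distributions.

## Target-decoy evaluation

A PSM is labeled a false positive when its peptide belongs to a decoy
protein — under the default `any_decoy` rule, membership in *any* decoy
protein suffices, which is the literal reading of the labeling rule this
package implements; `target_wins` is available for users who follow the more
common convention that a shared target/decoy peptide counts as target. With
score threshold $\delta$ (inclusive: $x_i \ge \delta$, ties pass together),

$$\mathrm{TPR}(\delta) = \frac{|\{\text{target PSMs with } x_i \ge \delta\}|}{|\{\text{target PSMs}\}|},
\qquad
\mathrm{FPR}(\delta) = \frac{|\{\text{decoy PSMs with } x_i \ge \delta\}|}{|\{\text{decoy PSMs}\}|}.$$

Counting is at the PSM (peptide-spectrum pair) level, not unique peptides.
The ROC curve sweeps the descending unique scores, is anchored at (0,0), and
the AUC is the trapezoidal integral — verified to 1e-12 against a
quadratic-time pairwise-comparison oracle (ties counted 1/2) and against
`pROC`. Min-max normalization (`minmax_normalize()`) places score
distributions on [0,1] for visual comparison; a constant vector maps to the
midpoint 0.5, a degenerate case real data never hits. q-values, FDR
estimation, and protein inference are out of scope.

## What the simulator emulates — and what it does not

`simulate_search()` generates the structure the method exploits, so the full
pipeline is testable without any real MS data:

* a target database in which only a fraction of proteins is present, plus a
  decoy database (`DECOY_`-prefixed accessions);
* per-protein peptide sets (`1 + Poisson(mean-1)` peptides, length-10
  random residue strings — collisions are negligible at $20^{10}$), with a
  `sharing_prob` chance that a peptide also occurs in a second protein of
  the same class, creating shared (degenerate) peptides;
* protein sequences as peptide concatenations with random 5-residue
  linkers, so substring mapping recovers membership exactly;
* correct PSMs drawn from present-protein peptides with scores
  $N(\mu_c, \sigma_c^2)$; incorrect PSMs from absent-target and decoy
  peptides in equal proportion — so the decoy count estimates the
  incorrect-PSM rate, mirroring target-decoy logic — with scores
  $N(\mu_i, \sigma_i^2)$; E-values are reported as $10^{-\text{score}}$;
* a truth table (`is_correct`) distinct from the target/decoy label,
  enabling oracle evaluation.

The defaults (20 target proteins, half present; 20 decoys; mean 8
peptides/protein; sharing 0.1; 400 PSMs, half correct; $N(3,1)$ vs
$N(1,1)$) describe a small benchmark with a two-sigma score separation —
enough overlap that re-ranking has room to help. A single integer seed
drives all sampling through one restored-on-exit RNG scope; identical
config + seed reproduces files byte for byte.

What the simulator does **not** capture: spectrum-level effects (peak
quality, fragmentation bias, precursor errors), realistic E-value tails,
peptide length/composition biases, homologous proteins with near-identical
sequences, and enzymatic-digest structure. Passing benchmarks on simulated
data therefore demonstrates that the machinery works and that the method
improves ranking *when its structural assumption holds*; it does not predict
effect sizes on real searches, where score distributions and sharing
patterns are messier.

## Problem sizes in the test suite

The suite exercises random graphs up to 200 nodes for dense
eigendecomposition checks (200 graphs), solver-agreement instances up to 500
nodes (100 instances), and the improvement-direction benchmark at the
default simulator scale over 50 seeds — sizes chosen so the whole suite
completes in well under a minute on one core while covering the regimes
(isolated nodes, shared peptides, tied scores) where the implementation has
branches.

## Known limitations

* The affinity uses protein co-membership only; spectra-derived similarity
  (peak offsets, sequence composition) is out of scope.
* The objective works on scores, not ranks; rank-based variants are not
  implemented.
* No automatic $\lambda$ selection.
* Isolated PSMs are uniformly shrunk by $1/(2-\lambda)$ (see above), which
  reorders them relative to connected PSMs of similar initial score.
* The `any_decoy` labeling deliberately follows the strict rule; with heavy
  target/decoy peptide sharing it can overcount false positives, which is
  why `target_wins` exists.
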