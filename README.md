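# psmreg

Consistency-based re-ranking of peptide-spectrum matches (PSMs) for shotgun
proteomics.

Search engines score each PSM from its spectrum alone, yet peptides from the
same protein tend to be present or absent together. `psmreg` exploits that
coupling as a post-processing step: it connects PSMs whose peptides co-occur
in proteins into a sparse affinity graph and replaces the initial scores with
ones that are smooth over the graph while staying close to the originals. No
training data, spectra, or retention times are needed — only the search
result and the protein database. The package is aimed at anyone
post-processing target-decoy search results (e.g. X!Tandem, Mascot, or
simulated searches) who wants better separation of correct from incorrect
identifications before FDR filtering.

## The model

Let `X = (x_1, ..., x_n)'` be initial ranking scores (for E-values,
`x_i = -log10 E_i`) and `U_i` the set of proteins containing peptide `p_i`.
The affinity graph has one node per PSM and edge weights

    w_ij = |U_i ∩ U_j| / |U_i ∪ U_j|        (i ≠ j, no self-loops)

With degrees `d_ii = Σ_j w_ij` and the normalized operator
`S = D^{-1/2} W D^{-1/2}`, the new scores minimize

    Q(Y) = (1 − λ) Σ_{i<j} w_ij (y_i/√d_ii − y_j/√d_jj)²  +  λ Σ_i (y_i − x_i)²

for a regularization parameter `λ ∈ (0, 1)` (default 0.5). The first term is
the quadratic form of the normalized graph Laplacian `I − S`; the unique
minimizer has the closed form

    Y* = λ (I − (1 − λ) S)^{-1} X

which the package solves sparsely, or — for large graphs — by the
score-diffusion iteration `Y(t+1) = λX + (1 − λ) S Y(t)`, a contraction for
every `λ ∈ (0, 1)` because the eigenvalues of `S` lie in [−1, 1]. Isolated
PSMs are kept solvable by attaching a dummy neighbor with weight 1e-8.
Performance is evaluated by target-decoy ROC curves (TPR over target PSMs,
FPR over decoy PSMs, inclusive `score ≥ δ` thresholds) and trapezoidal AUC.

## Worked example

Five PSMs over three proteins, with memberships U1={A}, U2={A,C}, U3={B},
U4={B,C}, U5={A}:

```r
library(psmreg)

psms <- tibble::tibble(
  psm_id = 1:5,
  spectrum_id = paste0("spec_", 1:5),
  peptide = c("AAAAK", "CCCCK", "DDDDK", "EEEEK", "FFFFK"),
  score = c(3, 1, 2, 0.5, 2.5),
  proteins = list("A", c("A", "C"), "B", c("B", "C"), "A")
)
fit <- rerank_psms(psms, lambda = 0.6)
tidy(fit)
#> # A tibble: 5 × 4
#>   psm_id initial_score regularized_score   delta
#>    <int>         <dbl>             <dbl>   <dbl>
#> 1      1           3               2.64  -0.355
#> 2      2           1               1.43   0.434
#> 3      3           2               1.49  -0.508
#> 4      4           0.5             0.944  0.444
#> 5      5           2.5             2.41  -0.0919
glance(fit)
#> # A tibble: 1 × 7
#>   n_psms n_edges n_dummy lambda method      iterations final_residual
#>    <int>   <int>   <int>  <dbl> <chr>            <int>          <dbl>
#> 1      5       5       0    0.6 closed_form          0       3.33e-16
```

The graph has exactly 5 edges; the sharing structure pulls each score toward
the scores of its protein neighbors (PSM 1 drops from 3 to 2.64, its
neighbor PSM 2 rises from 1 to 1.43), while `final_residual` confirms the
stationarity of the solution.

On a simulated target-decoy search (400 PSMs, 20 target + 20 decoy proteins,
correct/incorrect scores from N(3,1) vs N(1,1)) the re-ranking improves the
target-decoy AUC:

```r
sim <- simulate_search(psm_sim_config(seed = 42))
labeled <- label_psms(sim$psms)
roc_and_auc(sim$psms$score, labeled$is_target)
#> <psm_roc> AUC = 0.7877 (300 targets, 100 decoys)
fit2 <- rerank_psms(sim$psms, lambda = 0.5)
roc_and_auc(fit2$psms$regularized_score, labeled$is_target)
#> <psm_roc> AUC = 0.8653 (300 targets, 100 decoys)
```

`autoplot()` draws the ROC curve or the score change; `lambda_sweep()` and
`plot_lambda_sweep()` show sensitivity to `λ`; `plot_score_distributions()`
compares min-max-normalized score densities before and after.

A command-line wrapper with `rerank`, `evaluate`, `simulate`, and `sweep`
subcommands is installed at `system.file("cli", "psmreg.R", package = "psmreg")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","psmreg.R",package="psmreg"))')" \
  rerank --psms psms.tsv --out reranked.tsv --lambda 0.5
```

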