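# Shared fixtures and independent oracles.

# Five PSMs with the protein memberships of the worked toy example:
# U1={A}, U2={A,C}, U3={B}, U4={B,C}, U5={A}.
toy_psms <- function(scores = c(3, 1, 2, 0.5, 2.5)) {
  tibble::tibble(
    psm_id = 1:5,
    spectrum_id = paste0("spec_", 1:5),
    peptide = c("AAAAK", "CCCCK", "DDDDK", "EEEEK", "FFFFK"),
    score = scores,
    proteins = list("A", c("A", "C"), "B", c("B", "C"), "A")
  )
}

# Random PSM tibble with random protein memberships (set sizes 1..max_set).
random_psms <- function(n, n_proteins = max(3L, ceiling(n / 3)), max_set = 3L) {
  accs <- sprintf("P%03d", seq_len(n_proteins))
  tibble::tibble(
    psm_id = seq_len(n),
    spectrum_id = sprintf("s%05d", seq_len(n)),
    peptide = paste0("PEP", chartr("0123456789", "ABCDEFGHIJ",
                                   sprintf("%05d", seq_len(n))), "K"),
    score = stats::rnorm(n),
    proteins = lapply(seq_len(n), function(i) {
      sample(accs, sample.int(max_set, 1))
    })
  )
}

# Dense eigenvalues of the normalized operator.
s_eigenvalues <- function(graph) {
  eigen(as.matrix(graph$S), symmetric = TRUE, only.values = TRUE)$values
}

# Dense-linear-algebra oracle for the closed-form solution, independent of
# the sparse solver path.
oracle_closed_form <- function(X, graph, lambda) {
  n <- graph$n_total
  Xf <- c(X, rep(0, n - length(X)))
  A <- diag(n) - (1 - lambda) * as.matrix(graph$S)
  drop(base::solve(A, lambda * Xf))[seq_len(graph$n_real)]
}

# Brute-force pairwise smoothing cost by explicit double loop over pairs.
oracle_smoothing_cost <- function(Y, graph) {
  W <- as.matrix(graph$W)
  d <- graph$d
  total <- 0
  n <- nrow(W)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (W[i, j] > 0) {
        total <- total + W[i, j] * (Y[i] / sqrt(d[i]) - Y[j] / sqrt(d[j]))^2
      }
    }
  }
  total
}

# Quadratic-time pairwise-comparison AUC (ties counted 1/2): the probability
# that a random target outscores a random decoy.
oracle_auc <- function(scores, is_target) {
  ts <- scores[is_target]
  ds <- scores[!is_target]
  cmp <- outer(ts, ds, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
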