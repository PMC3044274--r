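#' Smoothing (inter-peptide inconsistency) cost
#'
#' The pairwise cost `L(Y) = sum over edges w_ij (y_i/sqrt(d_ii) -
#' y_j/sqrt(d_jj))^2`, each unordered pair counted once. By a standard
#' spectral-graph identity this equals the quadratic form `Y' (I - S) Y` of
#' the normalized Laplacian, which is what the solvers exploit; the pairwise
#' evaluation here serves as the independent route. Degree normalization
#' keeps highly connected peptides from dominating the penalty.
#'
#' @param Y Numeric vector over all nodes of the graph (length `n_total`,
#'   dummy entries included).
#' @param graph An [build_affinity_graph()] result.
#' @return A nonnegative scalar.
#' @export
smoothing_cost <- function(Y, graph) {
  stopifnot(inherits(graph, "affinity_graph"))
  if (length(Y) != graph$n_total) {
    abort(paste0("length(Y) [", length(Y), "] must equal n_total [",
                 graph$n_total, "]"))
  }
  Wt <- as(as(graph$W, "generalMatrix"), "TsparseMatrix")
  i <- Wt@i + 1L
  j <- Wt@j + 1L
  keep <- i < j
  z <- Y / sqrt(graph$d)
  sum(Wt@x[keep] * (z[i[keep]] - z[j[keep]])^2)
}

#' Fitting (score-fidelity) cost
#'
#' `F(Y) = sum_i (y_i - x_i)^2`: the squared deviation of the new scores
#' from the initial search-engine scores.
#'
#' @param Y,X Numeric vectors of equal length.
#' @return A nonnegative scalar.
#' @export
fitting_cost <- function(Y, X) {
  if (length(Y) != length(X)) {
    abort(paste0("length(Y) [", length(Y), "] must equal length(X) [",
                 length(X), "]"))
  }
  sum((Y - X)^2)
}

#' Regularized objective
#'
#' `Q(Y) = (1 - lambda) * L(Y) + lambda * F(Y)`: a convex combination of the
#' smoothing cost over the affinity graph and the fidelity cost to the
#' initial scores. Setting the gradient to zero gives the closed-form
#' minimizer `Y* = lambda (I - (1 - lambda) S)^-1 X` (see
#' [solve_closed_form()]); this weighting convention is the one whose
#' stationary point is exactly that expression.
#'
#' @param Y Candidate score vector over all nodes (length `n_total`).
#' @param X Initial score vector over all nodes (dummy entries 0).
#' @param graph An `affinity_graph`.
#' @param lambda Regularization parameter in the open interval (0, 1).
#' @return A nonnegative scalar.
#' @export
reg_objective <- function(Y, X, graph, lambda) {
  check_lambda(lambda)
  (1 - lambda) * smoothing_cost(Y, graph) + lambda * fitting_cost(Y, X)
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0 || lambda >= 1) {
    abort("'lambda' must lie strictly inside the open interval (0, 1)")
  }
  invisible(lambda)
}

# extend a real-node score vector with zeros for the dummy nodes
extend_scores <- function(X, graph) {
  if (length(X) == graph$n_total) return(X)
  if (length(X) != graph$n_real) {
    abort(paste0("length(X) [", length(X), "] must equal n_real [",
                 graph$n_real, "] or n_total [", graph$n_total, "]"))
  }
  c(X, rep.int(0, graph$n_total - graph$n_real))
}

new_reg_result <- function(Y_full, graph, lambda, method, iterations, residual) {
  structure(
    list(
      Y = Y_full[seq_len(graph$n_real)],
      Y_full = Y_full,
      lambda = lambda,
      alpha = 1 - lambda,
      method = method,
      iterations = iterations,
      final_residual = residual
    ),
    class = "reg_result"
  )
}

#' Closed-form score regularization
#'
#' Solves the sparse symmetric positive-definite linear system
#' `(I - (1 - lambda) S) Y = lambda X` whose solution is the unique
#' minimizer of [reg_objective()]. The system is always solvable for
#' `lambda` in (0, 1) because the eigenvalues of `S` lie in \[-1, 1\], so
#' every eigenvalue `1 - (1 - lambda) e` of the system matrix is positive.
#'
#' @param X Initial scores over real nodes (dummy entries are appended as 0)
#'   or over all nodes.
#' @param graph An `affinity_graph`.
#' @param lambda Regularization parameter in (0, 1).
#' @return A `reg_result`: regularized scores `Y` over real nodes, plus
#'   solver diagnostics (`method`, `iterations`, `final_residual` = max-norm
#'   stationarity residual).
#' @export
solve_closed_form <- function(X, graph, lambda) {
  stopifnot(inherits(graph, "affinity_graph"))
  check_lambda(lambda)
  Xf <- extend_scores(X, graph)
  A <- Diagonal(graph$n_total) - (1 - lambda) * graph$S
  Yf <- as.numeric(Matrix::solve(A, lambda * Xf))
  res <- max(abs(as.numeric(A %*% Yf) - lambda * Xf))
  new_reg_result(Yf, graph, lambda, "closed_form", 0L, res)
}

#' Iterative (score-diffusion) regularization
#'
#' Fixed-point iteration `Y(t+1) = lambda X + (1 - lambda) S Y(t)`, started
#' from `Y(0) = X`. Each sweep mixes every node's score with its neighbors'
#' — an information-diffusion view of the closed-form solution. The map is a
#' contraction with factor at most `(1 - lambda)` on the spectral radius of
#' `S` (itself at most 1), so the iteration converges to the closed-form
#' minimizer for every `lambda` in (0, 1); only sparse matrix-vector
#' products are needed, which is what makes large problems tractable.
#'
#' @inheritParams solve_closed_form
#' @param tol Max-norm change between sweeps at which to stop (default 1e-9).
#' @param max_iter Sweep limit (default 10000).
#' @return A `reg_result` (see [solve_closed_form()]); `iterations` is the
#'   number of sweeps, `final_residual` the last max-norm change.
#' @export
solve_iterative <- function(X, graph, lambda, tol = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(graph, "affinity_graph"))
  check_lambda(lambda)
  Xf <- extend_scores(X, graph)
  lX <- lambda * Xf
  beta <- 1 - lambda
  Y <- Xf
  delta <- Inf
  iter <- 0L
  while (iter < max_iter) {
    Y_new <- lX + beta * as.numeric(graph$S %*% Y)
    delta <- max(abs(Y_new - Y))
    Y <- Y_new
    iter <- iter + 1L
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(paste0("score diffusion did not converge within ", max_iter,
                 " sweeps (last max-norm change ", format(delta), ")"))
  }
  new_reg_result(Y, graph, lambda, "iterative", iter, delta)
}

#' Re-rank PSMs by graph-regularized scores
#'
#' The end-to-end method: build the peptide affinity graph from protein
#' membership, then replace each initial score by the minimizer of the
#' smoothing-vs-fitting objective. With the default `lambda = 0.5` the two
#' consistency terms are weighted equally — a robust rule-of-thumb setting;
#' as `lambda -> 1` the regularized scores revert to the initial ones.
#'
#' @param psms A PSM tibble with `score` and a non-empty `proteins`
#'   list-column (see [read_psm_table()], [map_peptides_to_proteins()]).
#' @param lambda Regularization parameter in (0, 1), default 0.5.
#' @param solver `"auto"` (closed form up to `auto_threshold` nodes, then
#'   iterative), `"closed_form"`, or `"iterative"`.
#' @param kernel,dummy_weight Passed to [build_affinity_graph()].
#' @param tol,max_iter Passed to [solve_iterative()].
#' @param auto_threshold Node count above which `"auto"` switches to the
#'   iterative solver (default 5000).
#' @return An object of class `psm_rerank` holding the input tibble with an
#'   added `regularized_score` column (`$psms`), the graph (`$graph`) and
#'   the solver result (`$result`). Use [augment()] for the tibble,
#'   [glance()] for one-row diagnostics.
#' @examples
#' psms <- tibble::tibble(
#'   psm_id = 1:5, spectrum_id = paste0("s", 1:5),
#'   peptide = c("AAK", "ACK", "ADK", "AEK", "AFK"),
#'   score = c(3, 1, 2, 0.5, 2.5),
#'   proteins = list("A", c("A", "C"), "B", c("B", "C"), "A")
#' )
#' fit <- rerank_psms(psms, lambda = 0.6)
#' augment(fit)
#' glance(fit)
#' @export
rerank_psms <- function(psms, lambda = 0.5,
                        solver = c("auto", "closed_form", "iterative"),
                        kernel = c("jaccard", "overlap_product", "overlap_min"),
                        dummy_weight = 1e-8, tol = 1e-9, max_iter = 10000L,
                        auto_threshold = 5000L) {
  solver <- match.arg(solver)
  check_lambda(lambda)
  if (!"score" %in% names(psms)) {
    abort("psms must carry a 'score' column (initial ranking scores)")
  }
  graph <- build_affinity_graph(psms, kernel = kernel, dummy_weight = dummy_weight)
  X <- psms$score
  method <- if (solver == "auto") {
    if (graph$n_total <= auto_threshold) "closed_form" else "iterative"
  } else solver
  result <- if (method == "closed_form") {
    solve_closed_form(X, graph, lambda)
  } else {
    solve_iterative(X, graph, lambda, tol = tol, max_iter = max_iter)
  }
  psms$regularized_score <- result$Y
  structure(
    list(psms = psms, graph = graph, result = result,
         score_transform = "as supplied (use transform_score() for E-values)"),
    class = "psm_rerank"
  )
}

#' @export
print.psm_rerank <- function(x, ...) {
  g <- glance(x)
  cat("<psm_rerank>\n")
  cat("  PSMs:      ", g$n_psms, "\n", sep = "")
  cat("  edges:     ", g$n_edges, " (+", g$n_dummy, " dummy nodes)\n", sep = "")
  cat("  lambda:    ", g$lambda, "\n", sep = "")
  cat("  solver:    ", g$method, " (iterations: ", g$iterations,
      ", residual: ", format(g$final_residual, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Tidy a re-ranking fit
#'
#' @param x A `psm_rerank` object.
#' @param ... Unused.
#' @return A tibble with `psm_id`, `initial_score`, `regularized_score`, and
#'   the score change `delta`.
#' @method tidy psm_rerank
#' @export
tidy.psm_rerank <- function(x, ...) {
  tibble(
    psm_id = x$psms$psm_id,
    initial_score = x$psms$score,
    regularized_score = x$psms$regularized_score,
    delta = x$psms$regularized_score - x$psms$score
  )
}

#' Augment the PSM table with regularized scores
#'
#' @param x A `psm_rerank` object.
#' @param ... Unused.
#' @return The input PSM tibble with a `regularized_score` column.
#' @method augment psm_rerank
#' @export
augment.psm_rerank <- function(x, ...) {
  as_tibble(x$psms)
}

#' One-row summary of a re-ranking fit
#'
#' @param x A `psm_rerank` object.
#' @param ... Unused.
#' @return A one-row tibble: problem size, graph size, `lambda`, solver
#'   method, iterations, and stationarity residual.
#' @method glance psm_rerank
#' @export
glance.psm_rerank <- function(x, ...) {
  tibble(
    n_psms = x$graph$n_real,
    n_edges = nrow(graph_edges(x$graph)),
    n_dummy = x$graph$n_total - x$graph$n_real,
    lambda = x$result$lambda,
    method = x$result$method,
    iterations = x$result$iterations,
    final_residual = x$result$final_residual
  )
}
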