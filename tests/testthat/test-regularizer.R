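two_node_graph <- function() {
  build_affinity_graph(tibble::tibble(
    psm_id = 1:2, spectrum_id = c("a", "b"), peptide = c("AK", "CK"),
    score = c(1, 0), proteins = list("P", "P")
  ))
}

test_that("pairwise smoothing cost equals the normalized-Laplacian quadratic form", {
  g2 <- two_node_graph()
  expect_equal(smoothing_cost(c(1, 1), g2), 0)
  expect_equal(smoothing_cost(c(1, 0), g2), 1)   # 1 * (1/1 - 0)^2
  expect_error(smoothing_cost(c(1, 0, 0), g2), "length")

  withr::local_seed(23)
  for (rep in 1:10) {
    g <- build_affinity_graph(random_psms(sample(2:40, 1)))
    Y <- rnorm(g$n_total)
    L <- smoothing_cost(Y, g)
    quad <- drop(t(Y) %*% (diag(g$n_total) - as.matrix(g$S)) %*% Y)
    expect_gte(L, 0)
    expect_equal(L, quad, tolerance = 1e-10)
    expect_equal(L, oracle_smoothing_cost(Y, g), tolerance = 1e-10)
  }
})

test_that("fitting cost is the summed squared deviation from the initial scores", {
  expect_equal(fitting_cost(c(1, 2), c(1, 2)), 0)
  expect_equal(fitting_cost(c(1, 1, 1), c(0, 0, 0)), 3)
  expect_error(fitting_cost(1:3, 1:2), "length")
  withr::local_seed(3)
  Y <- rnorm(20); X <- rnorm(20)
  brute <- 0
  for (i in 1:20) brute <- brute + (Y[i] - X[i])^2
  expect_equal(fitting_cost(Y, X), brute)
})

test_that("the objective blends the two costs and rejects lambda outside (0,1)", {
  g2 <- two_node_graph()
  X <- c(1, 1)
  expect_equal(reg_objective(X, X, g2, 0.5), 0)   # L(X)=0 on equal scores, F=0
  Y <- c(2, 0)
  expect_equal(reg_objective(Y, X, g2, 0.999),
               0.001 * smoothing_cost(Y, g2) + 0.999 * fitting_cost(Y, X))
  for (bad in c(0, 1, -0.5, 1.5)) {
    expect_error(reg_objective(Y, X, g2, bad), "\\(0, 1\\)")
  }
})

test_that("differentiating the objective reproduces the closed-form solution", {
  # analytic check on a hand-solvable instance ...
  g2 <- two_node_graph()
  fit <- solve_closed_form(c(1, 0), g2, 0.5)
  expect_equal(fit$Y, c(2/3, 1/3), tolerance = 1e-12)
  # ... and a central-difference gradient vanishing at Y* on a random instance
  withr::local_seed(31)
  g <- build_affinity_graph(random_psms(12))
  X <- rnorm(g$n_real)
  Yst <- solve_closed_form(X, g, 0.3)$Y_full
  Xf <- c(X, rep(0, g$n_total - g$n_real))
  h <- 1e-6
  grad <- vapply(seq_len(g$n_total), function(k) {
    e <- rep(0, g$n_total); e[k] <- h
    (reg_objective(Yst + e, Xf, g, 0.3) -
       reg_objective(Yst - e, Xf, g, 0.3)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("closed-form solutions satisfy stationarity and known special cases", {
  g2 <- two_node_graph()
  # constant scores are a fixed point on a degree-regular component
  expect_equal(solve_closed_form(c(1, 1), g2, 0.5)$Y, c(1, 1), tolerance = 1e-12)
  expect_error(solve_closed_form(c(1, 0), g2, 1), "\\(0, 1\\)")
  expect_error(solve_closed_form(c(1, 0), g2, 0), "\\(0, 1\\)")

  withr::local_seed(7)
  for (rep in 1:10) {
    g <- build_affinity_graph(random_psms(sample(2:80, 1)))
    X <- rnorm(g$n_real)
    lambda <- runif(1, 0.05, 0.95)
    fit <- solve_closed_form(X, g, lambda)
    expect_lt(fit$final_residual, 1e-8)
    expect_true(all(is.finite(fit$Y)))
    expect_equal(fit$Y, oracle_closed_form(X, g, lambda), tolerance = 1e-9)
  }
})

test_that("a lone PSM follows the two-node dummy system exactly", {
  one <- toy_psms()[1, ]
  g1 <- build_affinity_graph(one)
  for (lambda in c(0.2, 0.5, 0.9)) {
    fit <- solve_closed_form(one$score, g1, lambda)
    # 2x2 system with S = [[0,1],[1,0]] after degree normalization:
    # y = lambda * x / (1 - (1-lambda)^2)
    expect_equal(fit$Y, lambda * one$score / (1 - (1 - lambda)^2),
                 tolerance = 1e-12)
  }
})

test_that("score diffusion converges to the closed-form fixed point", {
  g2 <- two_node_graph()
  it <- solve_iterative(c(1, 0), g2, 0.5)
  expect_equal(it$Y, c(2/3, 1/3), tolerance = 1e-7)
  expect_gt(it$iterations, 0)

  # larger lambda contracts faster
  g <- build_affinity_graph(toy_psms())
  X <- toy_psms()$score
  it_low <- solve_iterative(X, g, 0.1)
  it_high <- solve_iterative(X, g, 0.9)
  expect_lt(it_high$iterations, it_low$iterations)

  expect_error(solve_iterative(X, g, 0.5, max_iter = 2), "converge")
})

test_that("warm and cold starts agree on the unique fixed point", {
  withr::local_seed(13)
  g <- build_affinity_graph(random_psms(40))
  X <- rnorm(g$n_real)
  tol <- 1e-10
  warm <- solve_iterative(X, g, 0.5, tol = tol)
  # cold start: all zeros (pass a full-length vector so Y(0) = 0)
  cold_res <- {
    Xf <- c(X, rep(0, g$n_total - g$n_real))
    Y <- rep(0, g$n_total)
    for (t in 1:10000) {
      Yn <- 0.5 * Xf + 0.5 * as.numeric(g$S %*% Y)
      if (max(abs(Yn - Y)) < tol) { Y <- Yn; break }
      Y <- Yn
    }
    Y[seq_len(g$n_real)]
  }
  expect_equal(warm$Y, cold_res, tolerance = 10 * tol)
})

test_that("rerank_psms wires graph, solver and tibble together", {
  toy <- toy_psms()
  fit <- rerank_psms(toy, lambda = 0.6)
  expect_s3_class(fit, "psm_rerank")
  expect_equal(fit$psms$regularized_score,
               oracle_closed_form(toy$score, fit$graph, 0.6), tolerance = 1e-9)
  g <- glance(fit)
  expect_equal(g$n_edges, 5)
  expect_equal(g$method, "closed_form")
  td <- tidy(fit)
  expect_equal(td$delta, td$regularized_score - td$initial_score)
  expect_equal(augment(fit)$regularized_score, fit$psms$regularized_score)

  # solver auto-switch honors the node-count threshold
  fit_it <- rerank_psms(toy, lambda = 0.6, auto_threshold = 2L)
  expect_equal(fit_it$result$method, "iterative")
  expect_equal(fit_it$psms$regularized_score, fit$psms$regularized_score,
               tolerance = 1e-7)
  expect_error(rerank_psms(toy, lambda = 1.5), "\\(0, 1\\)")
  expect_error(rerank_psms(toy[, setdiff(names(toy), "score")]), "score")
})

test_that("the minimizer is linear in the initial scores, not translation-invariant", {
  withr::local_seed(19)
  g <- build_affinity_graph(random_psms(25))
  X1 <- rnorm(g$n_real)
  X2 <- rnorm(g$n_real)
  a <- 0.7; b <- -1.3
  Y1 <- solve_closed_form(X1, g, 0.5)$Y
  Y2 <- solve_closed_form(X2, g, 0.5)$Y
  Ymix <- solve_closed_form(a * X1 + b * X2, g, 0.5)$Y
  expect_equal(Ymix, a * Y1 + b * Y2, tolerance = 1e-10)
  # doubling X doubles Y
  expect_equal(solve_closed_form(2 * X1, g, 0.5)$Y, 2 * Y1, tolerance = 1e-10)
})

test_that("a uniform clique shrinks the score spread towards the mean", {
  # five PSMs all in the same single protein: a weight-1 clique
  clique <- tibble::tibble(
    psm_id = 1:5, spectrum_id = paste0("s", 1:5),
    peptide = paste0("PEP", 1:5, "K"),
    score = c(5, 1, 3, 2.5, 0),
    proteins = rep(list("P"), 5)
  )
  fit <- rerank_psms(clique, lambda = 0.5)
  Y <- fit$psms$regularized_score
  X <- clique$score
  expect_true(all(Y >= min(X) & Y <= max(X)))
  expect_lt(max(Y) - min(Y), max(X) - min(X))
})
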