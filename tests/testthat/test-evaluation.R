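test_that("decoy membership labels PSMs, with both tie-break conventions", {
  psms <- tibble::tibble(
    psm_id = 1:3, spectrum_id = paste0("s", 1:3),
    peptide = c("AK", "CK", "DK"), score = c(1, 2, 3),
    proteins = list("P1", "DECOY_P1", c("P1", "DECOY_P2"))
  )
  expect_equal(label_psms(psms)$is_target, c(TRUE, FALSE, FALSE))
  expect_equal(label_psms(psms, mode = "target_wins")$is_target,
               c(TRUE, FALSE, TRUE))
  expect_error(label_psms(psms[, 1:4]), "proteins")
})

test_that("TPR and FPR honor the inclusive threshold on hand-built cases", {
  scores <- c(3, 2, 1, 0)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(tpr(scores, lab, 1.5), 1)
  expect_equal(fpr(scores, lab, 1.5), 0)
  expect_equal(tpr(scores, lab, -Inf), 1)
  expect_equal(fpr(scores, lab, -Inf), 1)
  expect_equal(tpr(scores, lab, 3 + 1e-9), 0)
  expect_equal(fpr(scores, lab, 0), 1)     # ties included via >=
  expect_equal(tpr(scores, lab, 2), 1)     # boundary score counts
  expect_error(tpr(scores, rep(FALSE, 4), 1), "no target")
  expect_error(fpr(scores, rep(TRUE, 4), 1), "no decoy")
  # monotone non-increasing in the threshold
  deltas <- seq(-1, 4, by = 0.25)
  expect_true(all(diff(vapply(deltas, tpr, numeric(1),
                              scores = scores, is_target = lab)) <= 0))
  expect_true(all(diff(vapply(deltas, fpr, numeric(1),
                              scores = scores, is_target = lab)) <= 0))
})

test_that("the ROC curve has proper endpoints and the AUC matches hand values", {
  scores <- c(3, 2, 1, 0)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  res <- roc_and_auc(scores, lab)
  expect_equal(res$auc, 1)                         # perfect separation
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(res$roc$tpr[1], 0)
  expect_equal(utils::tail(res$roc$fpr, 1), 1)
  expect_equal(utils::tail(res$roc$tpr, 1), 1)
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_true(all(diff(res$roc$tpr) >= 0))
  expect_equal(glance(res)$auc, 1)
  expect_equal(tidy(res), res$roc)
  expect_error(roc_and_auc(scores, rep(TRUE, 4)), "both")

  # label-independent scores give chance-level AUC
  withr::local_seed(101)
  n <- 1e4
  res_null <- roc_and_auc(rnorm(n), sample(c(TRUE, FALSE), n, replace = TRUE))
  expect_equal(res_null$auc, 0.5, tolerance = 0.04)
})

test_that("trapezoidal AUC agrees with pairwise and pROC oracles, with invariances", {
  withr::local_seed(55)
  for (rep in 1:20) {
    n <- sample(10:300, 1)
    scores <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    lab <- runif(n) < 0.6
    if (!any(lab) || all(lab)) next
    auc <- roc_and_auc(scores, lab)$auc
    expect_equal(auc, oracle_auc(scores, lab), tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(roc_and_auc(exp(scores / 3), lab)$auc, auc, tolerance = 1e-12)
  }
  # independent library cross-check on one instance
  skip_if_not_installed("pROC")
  scores <- rnorm(500)
  lab <- runif(500) < 0.5
  expect_equal(roc_and_auc(scores, lab)$auc,
               as.numeric(pROC::auc(pROC::roc(response = lab,
                                              predictor = scores,
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
  # score negation flips the ranking on tie-free data
  tie_free <- rank(rnorm(200)) / 7
  lab2 <- runif(200) < 0.5
  expect_equal(roc_and_auc(tie_free, lab2)$auc +
                 roc_and_auc(-tie_free, lab2)$auc, 1, tolerance = 1e-12)
})

test_that("the lambda sweep approaches the initial-score AUC as lambda -> 1", {
  sim <- simulate_search(psm_sim_config(n_psms = 200, seed = 9))
  sweep <- lambda_sweep(sim$psms, lambdas = c(0.3, 0.999))
  expect_equal(nrow(sweep), 2)
  auc0 <- attr(sweep, "auc_initial")
  expect_equal(sweep$auc[sweep$lambda == 0.999], auc0, tolerance = 0.01)
  expect_equal(nrow(lambda_sweep(sim$psms, lambdas = 0.5)), 1)
  expect_error(lambda_sweep(sim$psms, lambdas = c(0.5, 1)), "\\(0, 1\\)")
  # deterministic under a fixed simulation seed
  sweep2 <- lambda_sweep(simulate_search(psm_sim_config(n_psms = 200, seed = 9))$psms,
                         lambdas = c(0.3, 0.999))
  expect_equal(sweep$auc, sweep2$auc)
})

test_that("min-max normalization maps onto [0,1] with a midpoint fallback", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x), x)
  expect_equal(minmax_normalize(c(5, 5)), c(0.5, 0.5))
  expect_error(minmax_normalize(numeric(0)), "non-empty")
})

test_that("the evaluation report round-trips the curve and the AUC", {
  scores <- c(3, 2, 1, 0.5)
  res <- roc_and_auc(scores, c(TRUE, TRUE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(res, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# auc\t1$|^# auc\t1\\.0*$|^# auc\t1(\\.0+)?")
  curve <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_equal(curve$tpr, res$roc$tpr)
})
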