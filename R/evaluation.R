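#' Label PSMs as target or decoy
#'
#' Target-decoy evaluation treats a PSM as a false positive when its peptide
#' belongs to a decoy protein. Under the default `"any_decoy"` rule a PSM
#' whose protein set contains *any* decoy accession is labeled decoy;
#' `"target_wins"` labels it target as soon as one target protein contains
#' the peptide (the convention common in FDR tooling, offered for users who
#' prefer it).
#'
#' @param psms A PSM tibble with a `proteins` list-column.
#' @param decoy_pattern Regular expression matched against accessions
#'   (default `"^DECOY_"`).
#' @param mode `"any_decoy"` (default) or `"target_wins"`.
#' @return The tibble with an added logical column `is_target` (`TRUE` =
#'   counted as a true positive).
#' @export
label_psms <- function(psms, decoy_pattern = "^DECOY_",
                       mode = c("any_decoy", "target_wins")) {
  mode <- match.arg(mode)
  if (!"proteins" %in% names(psms)) {
    abort("psms must carry a 'proteins' list-column")
  }
  any_decoy <- vapply(psms$proteins, function(u) any(grepl(decoy_pattern, u)),
                      logical(1))
  all_decoy <- vapply(psms$proteins, function(u) all(grepl(decoy_pattern, u)),
                      logical(1))
  psms$is_target <- if (mode == "any_decoy") !any_decoy else !all_decoy
  psms
}

#' True positive rate at a score threshold
#'
#' Fraction of target PSMs scoring at or above the threshold:
#' `|{targets with score >= delta}| / |{targets}|`. The comparison is
#' inclusive (`>=`), so tied scores pass or fail together.
#'
#' @param scores Numeric score vector.
#' @param is_target Logical vector, `TRUE` for target PSMs.
#' @param delta Score threshold.
#' @return A value in \[0, 1\].
#' @export
tpr <- function(scores, is_target, delta) {
  stopifnot(length(scores) == length(is_target))
  if (!any(is_target)) {
    abort("TPR is undefined: no target PSMs")
  }
  sum(scores[is_target] >= delta) / sum(is_target)
}

#' False positive rate at a score threshold
#'
#' Fraction of decoy PSMs scoring at or above the threshold:
#' `|{decoys with score >= delta}| / |{decoys}|`.
#'
#' @inheritParams tpr
#' @return A value in \[0, 1\].
#' @export
fpr <- function(scores, is_target, delta) {
  stopifnot(length(scores) == length(is_target))
  if (all(is_target)) {
    abort("FPR is undefined: no decoy PSMs")
  }
  sum(scores[!is_target] >= delta) / sum(!is_target)
}

#' ROC curve and AUC for target-decoy scores
#'
#' Sweeps the threshold over the descending unique scores (ties collapse to
#' a single threshold, consistent with the inclusive `>=` comparison),
#' records (FPR, TPR) at each, prepends the (0, 0) endpoint, and integrates
#' by the trapezoidal rule. Perfectly separated classes give AUC 1;
#' label-independent scores give AUC about 0.5.
#'
#' @inheritParams tpr
#' @return An object of class `psm_roc`: `$roc` (tibble `threshold`, `fpr`,
#'   `tpr`), `$auc`, `$n_target`, `$n_decoy`. `tidy()` returns the curve,
#'   `glance()` the summary row, `autoplot()` a ggplot.
#' @export
roc_and_auc <- function(scores, is_target) {
  stopifnot(length(scores) == length(is_target))
  if (!any(is_target) || all(is_target)) {
    abort("ROC requires both target and decoy PSMs")
  }
  n_t <- sum(is_target)
  n_d <- sum(!is_target)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  targ <- is_target[ord]
  # last index of each tied block = cumulative counts at that threshold
  # (score >= delta semantics: ties pass together)
  block_end <- cumsum(rle(s)$lengths)
  thresholds <- s[block_end]
  tpr_v <- cumsum(targ)[block_end] / n_t
  fpr_v <- cumsum(!targ)[block_end] / n_d
  roc <- tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr_v),
    tpr = c(0, tpr_v)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  structure(
    list(roc = roc, auc = auc, n_target = n_t, n_decoy = n_d),
    class = "psm_roc"
  )
}

#' @export
print.psm_roc <- function(x, ...) {
  cat("<psm_roc> AUC = ", format(x$auc, digits = 4),
      " (", x$n_target, " targets, ", x$n_decoy, " decoys)\n", sep = "")
  invisible(x)
}

#' @rdname roc_and_auc
#' @param x A `psm_roc` object.
#' @param ... Unused.
#' @method tidy psm_roc
#' @export
tidy.psm_roc <- function(x, ...) {
  x$roc
}

#' @rdname roc_and_auc
#' @method glance psm_roc
#' @export
glance.psm_roc <- function(x, ...) {
  tibble(auc = x$auc, n_target = x$n_target, n_decoy = x$n_decoy)
}

#' Sensitivity of the re-ranking to the regularization parameter
#'
#' Re-solves the regularization at each value of `lambda` on a fixed graph
#' and reports the target-decoy AUC of the regularized scores. As `lambda`
#' approaches 1 the AUC approaches that of the initial scores.
#'
#' @param psms A labeled-ready PSM tibble (`score` + `proteins`).
#' @param lambdas Values in (0, 1); default `seq(0.1, 0.9, by = 0.1)`.
#' @param decoy_pattern,mode Passed to [label_psms()].
#' @param ... Passed to [build_affinity_graph()] (`kernel`, `dummy_weight`).
#' @return A tibble with columns `lambda` and `auc`, plus an
#'   `auc_initial` attribute holding the AUC of the unregularized scores.
#' @export
lambda_sweep <- function(psms, lambdas = seq(0.1, 0.9, by = 0.1),
                         decoy_pattern = "^DECOY_",
                         mode = c("any_decoy", "target_wins"), ...) {
  mode <- match.arg(mode)
  if (any(lambdas <= 0 | lambdas >= 1)) {
    abort("all 'lambdas' must lie strictly inside (0, 1)")
  }
  labeled <- label_psms(psms, decoy_pattern = decoy_pattern, mode = mode)
  graph <- build_affinity_graph(psms, ...)
  aucs <- vapply(lambdas, function(l) {
    fit <- solve_closed_form(psms$score, graph, l)
    roc_and_auc(fit$Y, labeled$is_target)$auc
  }, numeric(1))
  out <- tibble(lambda = lambdas, auc = aucs)
  attr(out, "auc_initial") <- roc_and_auc(psms$score, labeled$is_target)$auc
  out
}

#' Min-max normalize scores to \[0, 1\]
#'
#' `(x - min) / (max - min)`; used to place initial and regularized score
#' distributions on a common scale for comparison. A constant vector has no
#' range and maps to the midpoint 0.5.
#'
#' @param scores Non-empty numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(scores) {
  if (length(scores) == 0) {
    abort("'scores' must be non-empty")
  }
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    return(rep.int(0.5, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Write an evaluation report
#'
#' TSV of the ROC curve (threshold, FPR, TPR) preceded by commented summary
#' lines (AUC, class sizes).
#'
#' @param roc A `psm_roc` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(roc, path) {
  stopifnot(inherits(roc, "psm_roc"))
  header <- c(
    paste0("# auc\t", format(roc$auc, digits = 15)),
    paste0("# n_target\t", roc$n_target),
    paste0("# n_decoy\t", roc$n_decoy)
  )
  writeLines(header, path)
  readr::write_tsv(roc$roc, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
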