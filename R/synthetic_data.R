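#' Configuration for the synthetic target-decoy simulator
#'
#' The simulator emulates the statistical structure a consistency-based
#' re-ranker exploits: a target database of which only a fraction of
#' proteins is actually present in the sample, a decoy database of equal
#' standing, peptides optionally shared between proteins of the same class,
#' and PSM scores drawn from separate normal distributions for correct
#' matches (peptides of present proteins) and incorrect matches (peptides of
#' absent or decoy proteins).
#'
#' The defaults describe a small benchmark: 20 target proteins of which half
#' are present, 20 decoys, about 8 peptides per protein, 10% peptide
#' sharing, 400 PSMs split evenly between correct and incorrect, and
#' correct/incorrect score distributions N(3, 1) and N(1, 1) — a two-sigma
#' separation that leaves substantial overlap for the re-ranker to resolve.
#'
#' @param n_target_proteins Number of target proteins.
#' @param fraction_present Fraction of target proteins present in the sample
#'   (in (0, 1]).
#' @param n_decoy_proteins Number of decoy proteins (accessions prefixed
#'   `DECOY_`).
#' @param peptides_per_protein Mean peptide count per protein (Poisson,
#'   truncated at 1).
#' @param sharing_prob Probability that a peptide is also inserted into a
#'   second random protein of the same class (target/decoy), in \[0, 1).
#' @param n_psms Number of PSMs to simulate.
#' @param frac_correct Fraction of PSMs that are correct matches, in (0, 1).
#' @param mu_correct,sigma_correct Normal score parameters for correct PSMs.
#' @param mu_incorrect,sigma_incorrect Normal score parameters for incorrect
#'   PSMs.
#' @param peptide_length Residue length of simulated peptides (default 10:
#'   random collisions are negligible at 20^10 possibilities).
#' @param seed Integer seed; identical config + seed reproduces the dataset
#'   byte for byte.
#' @return A `psm_sim_config` list.
#' @export
psm_sim_config <- function(n_target_proteins = 20,
                           fraction_present = 0.5,
                           n_decoy_proteins = 20,
                           peptides_per_protein = 8,
                           sharing_prob = 0.1,
                           n_psms = 400,
                           frac_correct = 0.5,
                           mu_correct = 3, sigma_correct = 1,
                           mu_incorrect = 1, sigma_incorrect = 1,
                           peptide_length = 10,
                           seed = 1L) {
  cfg <- list(
    n_target_proteins = as.integer(n_target_proteins),
    fraction_present = fraction_present,
    n_decoy_proteins = as.integer(n_decoy_proteins),
    peptides_per_protein = peptides_per_protein,
    sharing_prob = sharing_prob,
    n_psms = as.integer(n_psms),
    frac_correct = frac_correct,
    mu_correct = mu_correct, sigma_correct = sigma_correct,
    mu_incorrect = mu_incorrect, sigma_incorrect = sigma_incorrect,
    peptide_length = as.integer(peptide_length),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_target_proteins < 1 || n_decoy_proteins < 1 || n_psms < 1 ||
        peptides_per_protein < 1 || peptide_length < 1) {
      abort("all counts in the simulator config must be positive")
    }
    if (fraction_present <= 0 || fraction_present > 1) {
      abort("'fraction_present' must lie in (0, 1]")
    }
    if (round(n_target_proteins * fraction_present) < 1) {
      abort("config yields zero present proteins; increase 'fraction_present'")
    }
    if (sharing_prob < 0 || sharing_prob >= 1) {
      abort("'sharing_prob' must lie in [0, 1)")
    }
    if (frac_correct <= 0 || frac_correct >= 1) {
      abort("'frac_correct' must lie in (0, 1)")
    }
    if (sigma_correct <= 0 || sigma_incorrect <= 0) {
      abort("score standard deviations must be positive")
    }
    if (mu_correct <= mu_incorrect) {
      warn("mu_correct <= mu_incorrect: correct PSMs will not outscore incorrect ones")
    }
  })
  structure(cfg, class = "psm_sim_config")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptides <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a target-decoy search result
#'
#' Generates proteins, peptides and PSMs under a [psm_sim_config()]. Target
#' proteins split into present and absent; decoys are never present. Each
#' protein receives `1 + Poisson(mean - 1)` private peptides; with
#' probability `sharing_prob` a peptide is additionally inserted into a
#' second random protein of the same class, creating the shared-peptide
#' edges the affinity graph is built from. Protein sequences are the
#' concatenation of their peptides with random 5-residue linkers, so
#' substring mapping recovers membership exactly. Correct PSMs draw a
#' peptide uniformly from present proteins and a score from the correct
#' distribution; incorrect PSMs draw from absent-target and decoy peptides
#' in equal proportion (so decoy counts estimate the incorrect rate) and
#' score from the incorrect distribution. Reported E-values are `10^-score`,
#' inverting [transform_score()].
#'
#' @param config A `psm_sim_config`.
#' @return An object of class `psm_sim`: `$proteins` (accession, sequence,
#'   is_decoy, is_present), `$psms` (canonical PSM tibble, shuffled order),
#'   `$truth` (psm_id, is_correct — note this is distinct from the
#'   target/decoy label), and `$config`.
#' @export
simulate_search <- function(config = psm_sim_config()) {
  stopifnot(inherits(config, "psm_sim_config"))
  withr::local_seed(config$seed)

  n_tar <- config$n_target_proteins
  n_dec <- config$n_decoy_proteins
  acc <- c(sprintf("PROT_%04d", seq_len(n_tar)),
           sprintf("DECOY_PROT_%04d", seq_len(n_dec)))
  is_decoy <- c(rep(FALSE, n_tar), rep(TRUE, n_dec))
  n_present <- round(n_tar * config$fraction_present)
  present_idx <- sort(sample.int(n_tar, n_present))
  is_present <- rep(FALSE, n_tar + n_dec)
  is_present[present_idx] <- TRUE

  # private peptides per protein, then same-class sharing
  n_pep <- pmax(1L, 1L + rpois(n_tar + n_dec, config$peptides_per_protein - 1))
  pep_seq <- random_peptides(sum(n_pep), config$peptide_length)
  pep_owner <- rep.int(seq_len(n_tar + n_dec), n_pep)
  membership <- data.frame(peptide = pep_seq, protein = pep_owner)
  shared <- runif(length(pep_seq)) < config$sharing_prob
  if (any(shared)) {
    second <- vapply(pep_owner[shared], function(p) {
      pool <- if (p <= n_tar) setdiff(seq_len(n_tar), p) else
        setdiff(seq_len(n_dec) + n_tar, p)
      if (length(pool) == 0) NA_integer_ else pool[sample.int(length(pool), 1)]
    }, integer(1))
    extra <- data.frame(peptide = pep_seq[shared], protein = second)
    membership <- rbind(membership, extra[!is.na(extra$protein), ])
  }

  sequences <- vapply(seq_len(n_tar + n_dec), function(p) {
    peps <- membership$peptide[membership$protein == p]
    linkers <- random_peptides(length(peps), 5)
    paste0(paste0(peps, linkers, collapse = ""), collapse = "")
  }, character(1))

  proteins <- tibble(accession = acc, sequence = sequences,
                     is_decoy = is_decoy, is_present = is_present)

  # peptide -> full protein accession set (including sharing)
  u_sets <- split(acc[membership$protein], membership$peptide)
  pep_class <- vapply(split(membership$protein, membership$peptide),
                      function(p) p[1], numeric(1))
  all_peps <- names(u_sets)
  correct_pool <- all_peps[vapply(u_sets, function(u) any(u %in% acc[present_idx]),
                                  logical(1))]
  absent_pool <- all_peps[pep_class <= n_tar &
                            !vapply(u_sets, function(u) any(u %in% acc[present_idx]),
                                    logical(1))]
  decoy_pool <- all_peps[pep_class > n_tar]
  if (length(correct_pool) == 0 || (length(absent_pool) + length(decoy_pool)) == 0) {
    abort("infeasible config: empty correct or incorrect peptide pool")
  }

  n_correct <- round(config$n_psms * config$frac_correct)
  n_incorrect <- config$n_psms - n_correct
  n_from_decoy <- if (length(absent_pool) == 0) n_incorrect else n_incorrect %/% 2
  n_from_absent <- n_incorrect - n_from_decoy

  pick <- function(pool, k) pool[sample.int(length(pool), k, replace = TRUE)]
  peptides <- c(
    pick(correct_pool, n_correct),
    pick(absent_pool, n_from_absent),
    pick(decoy_pool, n_from_decoy)
  )
  is_correct <- c(rep(TRUE, n_correct), rep(FALSE, n_incorrect))
  scores <- c(
    rnorm(n_correct, config$mu_correct, config$sigma_correct),
    rnorm(n_incorrect, config$mu_incorrect, config$sigma_incorrect)
  )

  ord <- sample.int(config$n_psms)   # shuffle so class is not encoded in order
  peptides <- peptides[ord]
  is_correct <- is_correct[ord]
  scores <- scores[ord]

  psms <- tibble(
    psm_id = seq_len(config$n_psms),
    spectrum_id = sprintf("spec_%05d", seq_len(config$n_psms)),
    peptide = peptides,
    evalue = 10^(-scores),
    score = scores,
    proteins = unname(u_sets[peptides])
  )
  truth <- tibble(psm_id = psms$psm_id, is_correct = is_correct)

  structure(list(proteins = proteins, psms = psms, truth = truth,
                 config = config),
            class = "psm_sim")
}

#' @export
print.psm_sim <- function(x, ...) {
  cat("<psm_sim> ", nrow(x$psms), " PSMs over ",
      sum(!x$proteins$is_decoy), " target + ", sum(x$proteins$is_decoy),
      " decoy proteins (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `proteins.fasta` (target + decoy entries), `psms.tsv` (canonical
#' PSM dialect) and `truth.tsv` (psm_id, is_correct) into a directory.
#'
#' @param sim A `psm_sim` object.
#' @param dir Output directory, created if needed.
#' @param force Overwrite into a non-empty directory (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, force = FALSE) {
  stopifnot(inherits(sim, "psm_sim"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(paste0("output directory is not empty: ", dir,
                 " (use force = TRUE to overwrite)"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::AAStringSet(sim$proteins$sequence)
  names(seqs) <- sim$proteins$accession
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.fasta"))
  write_psm_table(sim$psms, file.path(dir, "psms.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Benchmark the re-ranking against the initial scores
#'
#' Runs the full pipeline on one simulated dataset: simulate, label by decoy
#' membership, compute the target-decoy AUC of the initial scores and of the
#' regularized scores at each requested `lambda`.
#'
#' @param config A [psm_sim_config()].
#' @param lambdas Regularization parameters to evaluate (default 0.5).
#' @param ... Passed to [build_affinity_graph()].
#' @return A tibble with columns `lambda`, `auc_initial`, `auc_regularized`.
#' @export
benchmark_improvement <- function(config = psm_sim_config(), lambdas = 0.5, ...) {
  sim <- simulate_search(config)
  labeled <- label_psms(sim$psms)
  graph <- build_affinity_graph(sim$psms, ...)
  auc0 <- roc_and_auc(sim$psms$score, labeled$is_target)$auc
  aucs <- vapply(lambdas, function(l) {
    fit <- solve_closed_form(sim$psms$score, graph, l)
    roc_and_auc(fit$Y, labeled$is_target)$auc
  }, numeric(1))
  tibble(lambda = lambdas, auc_initial = auc0, auc_regularized = aucs)
}
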