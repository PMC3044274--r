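#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches (PSMs) in the
#' canonical dialect: UTF-8 TSV with columns `spectrum_id`, `peptide`, and at
#' least one of `score` / `evalue`; an optional `proteins` column holds
#' semicolon-separated protein accessions. When `score` is absent it is
#' derived from `evalue` via [transform_score()] (negative base-10 log), the
#' usual "higher is better" orientation for E-value-based rankings.
#'
#' Duplicate (spectrum_id, peptide) rows are kept as distinct PSMs: the same
#' peptide is routinely matched by several spectra and each match is a
#' separate node downstream.
#'
#' @param path Path to a TSV file.
#' @param strip_mods Strip modification annotations from peptides, keeping
#'   only uppercase residue letters (default `TRUE`). Protein mapping and
#'   graph construction key on the plain residue string.
#' @return A tibble with columns `psm_id` (row index), `spectrum_id`,
#'   `peptide`, `evalue` (if present), `score`, and `proteins` (a list-column
#'   of character vectors; empty vectors where the file had no accessions).
#' @seealso [write_psm_table()], [map_peptides_to_proteins()]
#' @export
read_psm_table <- function(path, strip_mods = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("PSM table not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("spectrum_id", "peptide")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("PSM table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!any(c("score", "evalue") %in% names(raw))) {
    abort("PSM table must have at least one of the columns 'score' or 'evalue'")
  }

  n <- nrow(raw)
  out <- tibble(
    psm_id      = seq_len(n),
    spectrum_id = raw$spectrum_id,
    peptide     = if (strip_mods) strip_peptide(raw$peptide) else raw$peptide
  )
  bad_pep <- which(!grepl("^[A-Z]+$", out$peptide))
  if (length(bad_pep) > 0) {
    abort(paste0("Invalid peptide sequence at row(s): ",
                 paste(head(bad_pep, 5), collapse = ", ")))
  }
  if ("evalue" %in% names(raw)) {
    out$evalue <- parse_numeric_column(raw$evalue, "evalue")
  }
  if ("score" %in% names(raw)) {
    out$score <- parse_numeric_column(raw$score, "score")
  } else {
    out$score <- transform_score(out$evalue)
  }
  if (any(!is.finite(out$score))) {
    abort(paste0("Non-finite score at row(s): ",
                 paste(head(which(!is.finite(out$score)), 5), collapse = ", ")))
  }
  out$proteins <- if ("proteins" %in% names(raw)) {
    parse_protein_lists(raw$proteins)
  } else {
    rep(list(character(0)), n)
  }
  out
}

# keep only uppercase residue letters (drops mass tags, brackets, lowercase)
strip_peptide <- function(x) {
  gsub("[^A-Z]", "", toupper(gsub("\\[[^]]*\\]|\\([^)]*\\)", "", x)))
}

parse_numeric_column <- function(x, name) {
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(val))
  if (length(bad) > 0) {
    abort(paste0("Unparsable numeric in column '", name, "' at data row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  val
}

parse_protein_lists <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "") return(character(0))
    unique(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Transform an E-value into a ranking score
#'
#' Returns `-log10(evalue)`, the conventional "higher is better" orientation
#' for E-value-based rankings (an E-value of 0.1 maps to 1, 1e-5 to 5). The
#' transform is strictly decreasing in the E-value, so it preserves the
#' search engine's ranking while placing scores on an additive scale suitable
#' for the quadratic regularizer.
#'
#' @param evalue Numeric vector of positive E-values.
#' @return Numeric vector of scores, same length.
#' @export
transform_score <- function(evalue) {
  if (!is.numeric(evalue) || any(!is.finite(evalue)) || any(evalue <= 0)) {
    abort("'evalue' must be finite and strictly positive")
  }
  -log10(evalue)
}

#' Filter PSMs by E-value cutoff
#'
#' Keeps the rows with `evalue <= cutoff` (boundary inclusive), preserving
#' order. The default cutoff of 0.1 is the customary pre-filter applied to
#' search-engine output before re-ranking.
#'
#' @param psms A PSM tibble carrying an `evalue` column.
#' @param cutoff Maximum E-value to retain (default 0.1).
#' @return The filtered tibble, a subsequence of the input rows.
#' @export
filter_by_evalue <- function(psms, cutoff = 0.1) {
  if (!"evalue" %in% names(psms)) {
    abort("filter_by_evalue() requires an 'evalue' column")
  }
  if (any(is.na(psms$evalue))) {
    abort("filter_by_evalue(): 'evalue' contains missing values")
  }
  psms[psms$evalue <= cutoff, , drop = FALSE]
}

#' Read a target-decoy protein FASTA
#'
#' Parses a protein FASTA (multi-line sequences allowed) into a tibble and
#' flags decoy entries by matching accessions against a regular expression.
#' The accession is the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param decoy_pattern Regular expression identifying decoy accessions
#'   (default `"^DECOY_"`).
#' @return A tibble with columns `accession`, `sequence`, `is_decoy`.
#' @export
read_fasta <- function(path, decoy_pattern = "^DECOY_") {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  if (file.size(path) == 0) {
    return(tibble(accession = character(0), sequence = character(0),
                  is_decoy = logical(0)))
  }
  seqs <- Biostrings::readAAStringSet(path)
  accession <- sub("\\s.*$", "", names(seqs))
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate accession(s) in FASTA: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  tibble(
    accession = accession,
    sequence  = unname(as.character(seqs)),
    is_decoy  = grepl(decoy_pattern, accession)
  )
}

#' Map peptides to proteins by substring scan
#'
#' Fills the `proteins` list-column of a PSM tibble with the accessions of
#' every protein whose sequence contains the peptide as an exact substring
#' (leucine and isoleucine are not equated). PSMs whose peptide occurs in no
#' protein are dropped with a warning: downstream graph construction requires
#' a non-empty protein set per node.
#'
#' @param psms A PSM tibble (peptides already stripped to residue strings).
#' @param proteins A protein tibble as returned by [read_fasta()].
#' @return The PSM tibble with `proteins` replaced by the mapped accession
#'   sets; unmappable rows removed.
#' @export
map_peptides_to_proteins <- function(psms, proteins) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  peps <- unique(psms$peptide)
  hits <- lapply(peps, function(p) {
    proteins$accession[stringr::str_detect(proteins$sequence, stringr::fixed(p))]
  })
  names(hits) <- peps
  psms$proteins <- unname(hits[psms$peptide])
  empty <- lengths(psms$proteins) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " PSM(s) matched no protein and were dropped (psm_id: ",
                paste(head(psms$psm_id[empty], 5), collapse = ", "), ")"))
    psms <- psms[!empty, , drop = FALSE]
  }
  psms
}

#' Write a PSM table
#'
#' Writes the canonical TSV dialect: `proteins` serialized as
#' semicolon-separated accessions, numeric columns at full double precision
#' so a read/write round trip is lossless to at least 12 significant digits.
#' An optional vector of regularized scores is attached as a
#' `regularized_score` column.
#'
#' @param psms A PSM tibble.
#' @param path Output file path.
#' @param new_scores Optional numeric vector, one value per row, written as
#'   `regularized_score`.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path, new_scores = NULL) {
  if (!is.null(new_scores)) {
    if (length(new_scores) != nrow(psms)) {
      abort(paste0("length(new_scores) [", length(new_scores),
                   "] must equal nrow(psms) [", nrow(psms), "]"))
    }
    psms$regularized_score <- new_scores
  }
  out <- psms
  if ("proteins" %in% names(out)) {
    out$proteins <- vapply(out$proteins, paste, character(1), collapse = ";")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
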