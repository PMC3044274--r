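#' Similarity between two protein membership sets
#'
#' Edge weights of the affinity graph quantify the probability that two
#' peptides belong to the same protein, computed from their protein
#' membership sets. The default `"jaccard"` kernel returns
#' `|U_i n U_j| / |U_i u U_j|`: a value in \[0, 1\], equal to 1 when the two
#' peptides occur in exactly the same proteins and 0 when they share none.
#' Alternative kernels normalize the intersection by the product or the
#' minimum of the set sizes instead.
#'
#' @param u_i,u_j Character vectors of protein accessions (non-empty).
#' @param kernel One of `"jaccard"`, `"overlap_product"`, `"overlap_min"`.
#' @return A similarity in \[0, 1\], symmetric in its arguments.
#' @export
pairwise_similarity <- function(u_i, u_j,
                                kernel = c("jaccard", "overlap_product", "overlap_min")) {
  kernel <- match.arg(kernel)
  if (length(u_i) == 0 || length(u_j) == 0) {
    abort("protein sets must be non-empty")
  }
  u_i <- unique(u_i)
  u_j <- unique(u_j)
  inter <- length(intersect(u_i, u_j))
  switch(kernel,
    jaccard         = inter / (length(u_i) + length(u_j) - inter),
    overlap_product = inter / (length(u_i) * length(u_j)),
    overlap_min     = inter / min(length(u_i), length(u_j))
  )
}

#' Build the peptide affinity graph
#'
#' One node per PSM; an undirected edge joins nodes `i != j` whenever their
#' protein sets overlap, weighted by [pairwise_similarity()]. The diagonal is
#' zero (no self-loops). Two PSMs of the same peptide have identical protein
#' sets and are joined with weight 1 under the Jaccard kernel.
#'
#' A node whose protein set overlaps no other node would have zero degree,
#' making the degree normalization singular. Each such isolated node
#' receives a dummy neighbor connected only to it with a tiny weight
#' (`dummy_weight`, default 1e-8). Dummy nodes are appended after the real
#' nodes, carry initial score 0 during regularization, and are stripped from
#' all outputs.
#'
#' Internally the pairwise intersections are obtained in one sparse
#' cross-product of the PSM-by-protein incidence matrix, so construction
#' scales with the number of overlapping pairs rather than `n^2`.
#'
#' @param psms A PSM tibble whose `proteins` list-column is non-empty for
#'   every row.
#' @param kernel Similarity kernel, see [pairwise_similarity()].
#' @param dummy_weight Edge weight attached to isolated nodes (default 1e-8).
#' @return An object of class `affinity_graph`: a list with `n_real`,
#'   `n_total`, sparse symmetric `W` (weights), degree vector `d`, normalized
#'   operator `S` (`D^-1/2 W D^-1/2`), `dummy_of` (named integer vector
#'   mapping isolated real nodes to their dummy index), and `psm_id`.
#' @export
build_affinity_graph <- function(psms,
                                 kernel = c("jaccard", "overlap_product", "overlap_min"),
                                 dummy_weight = 1e-8) {
  kernel <- match.arg(kernel)
  if (!"proteins" %in% names(psms)) {
    abort("psms must carry a 'proteins' list-column (see map_peptides_to_proteins())")
  }
  if (dummy_weight <= 0) {
    abort("'dummy_weight' must be positive")
  }
  sets <- lapply(psms$proteins, unique)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    abort(paste0("PSM(s) with empty protein set (psm_id: ",
                 paste(head(psms$psm_id[empty], 5), collapse = ", "),
                 "); map or drop them before graph construction"))
  }
  n <- length(sets)
  accs <- unique(unlist(sets))
  sizes <- lengths(sets)

  # PSM-by-protein incidence; intersections via one sparse cross-product
  B <- sparseMatrix(
    i = rep.int(seq_len(n), sizes),
    j = match(unlist(sets), accs),
    x = 1,
    dims = c(n, length(accs))
  )
  M <- as(as(tcrossprod(B), "generalMatrix"), "TsparseMatrix")
  keep <- M@i < M@j   # strict upper triangle: one entry per unordered pair
  ei <- M@i[keep] + 1L
  ej <- M@j[keep] + 1L
  inter <- M@x[keep]
  w <- switch(kernel,
    jaccard         = inter / (sizes[ei] + sizes[ej] - inter),
    overlap_product = inter / (sizes[ei] * sizes[ej]),
    overlap_min     = inter / pmin(sizes[ei], sizes[ej])
  )

  # attach a dummy neighbor to every zero-degree node
  isolated <- setdiff(seq_len(n), unique(c(ei, ej)))
  n_dummy <- length(isolated)
  n_total <- n + n_dummy
  dummy_of <- structure(seq_len(n_dummy) + n, names = as.character(isolated))
  ei <- c(ei, isolated)
  ej <- c(ej, seq_len(n_dummy) + n)
  w <- c(w, rep.int(dummy_weight, n_dummy))

  W <- sparseMatrix(i = ei, j = ej, x = w, dims = c(n_total, n_total),
                    symmetric = TRUE)
  d <- Matrix::rowSums(W)
  a <- 1 / sqrt(d)
  # same triplet order on both triangles keeps S bit-exactly symmetric
  S <- sparseMatrix(i = ei, j = ej, x = w * a[ei] * a[ej],
                    dims = c(n_total, n_total), symmetric = TRUE)

  structure(
    list(n_real = n, n_total = n_total, W = W, d = d, S = S,
         dummy_of = dummy_of, dummy_weight = dummy_weight, kernel = kernel,
         psm_id = psms$psm_id %||% seq_len(n)),
    class = "affinity_graph"
  )
}

#' Degree matrix of a weight matrix
#'
#' The diagonal matrix of row sums `d_ii = sum_j w_ij`. Every row sum must be
#' positive: dummy-node insertion (see [build_affinity_graph()]) guarantees
#' this for graphs built by the package.
#'
#' @param W Sparse symmetric nonnegative weight matrix.
#' @return A sparse diagonal matrix.
#' @export
degree_matrix <- function(W) {
  d <- Matrix::rowSums(W)
  if (any(d <= 0)) {
    abort("zero row sum in W; attach dummy nodes before computing degrees")
  }
  Diagonal(x = d)
}

#' Degree-normalized similarity operator
#'
#' Computes `S = D^-1/2 W D^-1/2`, i.e. `S_ij = w_ij / sqrt(d_ii d_jj)`.
#' `I - S` is the normalized graph Laplacian; all eigenvalues of `S` lie in
#' \[-1, 1\], which underpins both the invertibility of the closed-form
#' system and the convergence of the fixed-point iteration.
#'
#' @param W Sparse symmetric weight matrix.
#' @param D Diagonal degree matrix with positive diagonal (defaults to
#'   [degree_matrix()] of `W`).
#' @return Sparse symmetric matrix with the sparsity pattern of `W`.
#' @export
normalize_graph <- function(W, D = degree_matrix(W)) {
  d <- Matrix::diag(D)
  if (any(d <= 0)) {
    abort("degree matrix must have strictly positive diagonal")
  }
  A <- Diagonal(x = 1 / sqrt(d))
  Matrix::forceSymmetric(A %*% W %*% A)
}

#' Edge list of an affinity graph
#'
#' Returns the undirected edges among real (non-dummy) nodes, one row per
#' unordered pair, suitable for TSV export or inspection.
#'
#' @param graph An `affinity_graph`.
#' @return A tibble with columns `node_i`, `node_j` (1-based real-node
#'   indices, `node_i < node_j`) and `weight`.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "affinity_graph"))
  Wt <- as(as(graph$W, "generalMatrix"), "TsparseMatrix")
  i <- Wt@i + 1L
  j <- Wt@j + 1L
  keep <- i < j & j <= graph$n_real
  tibble(node_i = i[keep], node_j = j[keep], weight = Wt@x[keep]) |>
    dplyr::arrange(.data$node_i, .data$node_j)
}

#' @export
print.affinity_graph <- function(x, ...) {
  n_edges <- nrow(graph_edges(x))
  cat("<affinity_graph>\n")
  cat("  nodes:  ", x$n_real, " real + ", x$n_total - x$n_real, " dummy\n", sep = "")
  cat("  edges:  ", n_edges, " (kernel: ", x$kernel, ")\n", sep = "")
  invisible(x)
}
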