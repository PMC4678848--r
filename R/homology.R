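#' Pairwise local-alignment similarity between two protein sequences
#'
#' Aligns two sequences locally (Smith-Waterman) under a substitution matrix
#' with affine gap penalties and reports percent identity over alignment
#' columns and the aligned coverage of each sequence. These are the
#' quantities the homology-reduction thresholds are applied to.
#'
#' @param seq_a,seq_b Amino-acid sequence strings (or single-row protein
#'   record data frames).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_ext Affine gap open/extension penalties (defaults 11
#'   and 1, the familiar protein-BLAST settings).
#' @return A list with elements `percent_identity` (0-100; 100 x identical
#'   columns / alignment columns), `coverage_a`, `coverage_b` (aligned span
#'   of each sequence divided by its length) and `score`.
#' @export
pairwise_similarity <- function(seq_a, seq_b, matrix = "BLOSUM62",
                                gap_open = 11, gap_ext = 1) {
  if (is.data.frame(seq_a)) seq_a <- seq_a$sequence[1]
  if (is.data.frame(seq_b)) seq_b <- seq_b$sequence[1]
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  submat <- get_submatrix(matrix)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_ext)
  ncols <- Biostrings::nchar(al)
  pid <- if (ncols == 0) 0 else 100 * Biostrings::nmatch(al) / ncols
  list(percent_identity = pid,
       coverage_a = Biostrings::width(Biostrings::pattern(al)) /
         nchar(seq_a),
       coverage_b = Biostrings::width(Biostrings::subject(al)) /
         nchar(seq_b),
       score = Biostrings::score(al))
}

get_submatrix <- function(matrix) {
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Homology-reduce a set of protein sequences
#'
#' BLASTclust-style redundancy removal: sequences are connected by an edge
#' when their local alignment reaches at least `id_threshold` percent
#' identity and covers at least `coverage_threshold` of *both* sequences;
#' clusters are the connected components (single linkage); one
#' representative per cluster is drawn uniformly at random under `seed`.
#' Requiring coverage on both sequences is deliberately conservative: it
#' reduces train/test leakage through partial-length homologs.
#'
#' @param records Protein record data frame.
#' @param id_threshold Minimum percent identity for an edge (default 35).
#' @param coverage_threshold Minimum alignment coverage of each sequence
#'   (default 0.9).
#' @param seed Integer seed for representative selection.
#' @param matrix,gap_open,gap_ext Alignment scoring, see
#'   [pairwise_similarity()].
#' @return A list with `representatives` (record data frame, input order)
#'   and `clusters` (data frame `cluster_id`, `protein_id`,
#'   `representative`, one row per input record).
#' @export
homology_reduce <- function(records, id_threshold = 35,
                            coverage_threshold = 0.9, seed = 1,
                            matrix = "BLOSUM62", gap_open = 11,
                            gap_ext = 1) {
  n <- nrow(records)
  stopifnot(n >= 1)
  validate_records(records)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    hit <- logical(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      sim <- pairwise_similarity(records$sequence[i], records$sequence[j],
                                 matrix = matrix, gap_open = gap_open,
                                 gap_ext = gap_ext)
      hit[k] <- sim$percent_identity >= id_threshold &&
        min(sim$coverage_a, sim$coverage_b) >= coverage_threshold
    }
    edges <- t(pairs[, hit, drop = FALSE])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel clusters in input order of first member, for determinism
  first <- match(unique(comp), comp)
  cluster_id <- match(comp, comp[sort(first)])
  rep_idx <- local_seed(seed, {
    vapply(sort(unique(cluster_id)), function(cid) {
      members <- which(cluster_id == cid)
      if (length(members) == 1) members else sample(members, 1)
    }, integer(1))
  })
  is_rep <- seq_len(n) %in% rep_idx
  reps <- records[sort(rep_idx), , drop = FALSE]
  rownames(reps) <- NULL
  list(representatives = reps,
       clusters = data.frame(cluster_id = cluster_id,
                             protein_id = records$id,
                             representative = is_rep,
                             stringsAsFactors = FALSE))
}

#' Remove candidates homologous to a reference set
#'
#' Drops every candidate record whose local alignment against any reference
#' record reaches the identity and (both-sided) coverage thresholds. Used to
#' keep an independent test pool free of homologs of the training pool.
#'
#' @param candidates,reference Protein record data frames.
#' @param id_threshold,coverage_threshold,matrix,gap_open,gap_ext As in
#'   [homology_reduce()].
#' @return The retained candidate records, input order preserved.
#' @export
exclude_cross_homologs <- function(candidates, reference,
                                   id_threshold = 35,
                                   coverage_threshold = 0.9,
                                   matrix = "BLOSUM62", gap_open = 11,
                                   gap_ext = 1) {
  if (nrow(reference) == 0 || nrow(candidates) == 0) return(candidates)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    for (j in seq_len(nrow(reference))) {
      sim <- pairwise_similarity(candidates$sequence[i],
                                 reference$sequence[j],
                                 matrix = matrix, gap_open = gap_open,
                                 gap_ext = gap_ext)
      if (sim$percent_identity >= id_threshold &&
          min(sim$coverage_a, sim$coverage_b) >= coverage_threshold)
        return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
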