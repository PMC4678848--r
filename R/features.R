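#' Amino-acid composition feature vectors
#'
#' Computes the single feature type used by the classifier: the fraction of
#' each of the 20 canonical amino acids in a sequence. Tolerated
#' noncanonical residues (X, B, Z, J, U, O) are excluded from both the
#' numerator and the denominator, so every vector sums to exactly one over
#' the canonical alphabet.
#'
#' @param records A protein record data frame (see [read_fasta()]), or a
#'   character vector of sequences (optionally named with ids).
#' @param max_noncanonical Maximum tolerated fraction of noncanonical
#'   residues per sequence (default 0.10); records above it are rejected.
#' @return A numeric matrix with one row per record (rownames = ids) and 20
#'   columns named by [AA_CANONICAL], in that fixed order.
#' @examples
#' aa_composition(c(p1 = "ACDEFGHIKLMNPQRSTVWY"))["p1", "A"]  # 0.05
#' @export
aa_composition <- function(records, max_noncanonical = 0.10) {
  if (is.data.frame(records)) {
    seqs <- records$sequence
    ids <- records$id
  } else {
    seqs <- as.character(records)
    ids <- if (!is.null(names(records))) names(records)
           else paste0("seq", seq_along(seqs))
  }
  out <- matrix(0, nrow = length(seqs), ncol = length(AA_CANONICAL),
                dimnames = list(ids, AA_CANONICAL))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    is_canon <- chars %in% AA_CANONICAL
    is_known <- is_canon | chars %in% AA_NONCANONICAL
    if (any(!is_known))
      stop("invalid residue '", chars[which(!is_known)[1]], "' in record ",
           ids[i])
    n_canon <- sum(is_canon)
    if (n_canon == 0)
      stop("record ", ids[i], " has no canonical residues")
    frac_noncanon <- 1 - n_canon / length(chars)
    if (frac_noncanon > max_noncanonical)
      stop("record ", ids[i], " has ", round(100 * frac_noncanon, 1),
           "% noncanonical residues (limit ",
           round(100 * max_noncanonical, 1), "%)")
    counts <- table(factor(chars[is_canon], levels = AA_CANONICAL))
    out[i, ] <- as.numeric(counts) / n_canon
  }
  out
}

#' Write a feature matrix as a TSV artifact
#'
#' @param features A matrix from [aa_composition()].
#' @param path Output path.
#' @param metadata Optional metadata for the comment header.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, metadata = NULL) {
  df <- data.frame(protein_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, metadata = c(feature_order =
    paste(colnames(features), collapse = ","), metadata))
}
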