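#' Read and validate a protein FASTA file
#'
#' Reads a (possibly line-wrapped) protein FASTA file into a data frame of
#' protein records. Sequences are uppercased and trailing stop characters
#' (`*`) are stripped before validation. The record id is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @param species Optional species label attached to every record.
#' @return A data frame with columns `id`, `sequence`, `description` and
#'   `species`, one row per FASTA entry in file order.
#' @details Residues must come from the 20 canonical amino acids
#'   ([AA_CANONICAL]) plus the tolerated noncanonical set
#'   ([AA_NONCANONICAL]). A duplicate id or an invalid character is an
#'   error naming the offending record (and position). An empty file yields
#'   an empty record set with a warning.
#' @seealso [write_fasta()], [filter_by_length()]
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  records <- data.frame(id = ids, sequence = seqs, description = desc,
                        species = rep(species, length(ids)),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  if (nrow(records) == 0) {
    warning("FASTA file is empty: ", path)
    return(records)
  }
  validate_records(records)
  records
}

# Shared record validation: non-empty unique ids, allowed residue alphabet.
validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (any(!nzchar(records$id))) stop("empty protein id")
  dup <- records$id[duplicated(records$id)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(records$sequence)))
    stop("empty sequence for record(s): ",
         paste(records$id[!nzchar(records$sequence)], collapse = ", "))
  allowed <- c(AA_CANONICAL, AA_NONCANONICAL)
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$sequence[i], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad))
      stop("invalid residue '", chars[bad[1]], "' at position ", bad[1],
           " of record ", records$id[i])
  }
  invisible(records)
}

#' Write protein records to FASTA
#'
#' @param records A protein record data frame (see [read_fasta()]).
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- records$id[i]
    if (!is.null(records$description) && nzchar(records$description[i]))
      header <- paste(header, records$description[i])
    seq <- records$sequence[i]
    starts <- seq(1, nchar(seq), by = width)
    lines <- substring(seq, starts, pmin(starts + width - 1, nchar(seq)))
    writeLines(c(paste0(">", header), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Remove short protein sequences
#'
#' Drops records shorter than `min_length` residues. Short entries in
#' proteome FASTA files are usually fragments rather than full-length
#' proteins, so they are excluded before model training (default cutoff 40
#' residues).
#'
#' @param records A protein record data frame.
#' @param min_length Minimum retained length in residues (default 40).
#' @return The retained records, original order preserved. The number of
#'   removed records is reported via `message()`.
#' @export
filter_by_length <- function(records, min_length = 40) {
  stopifnot(min_length >= 1)
  keep <- nchar(records$sequence) >= min_length
  removed <- sum(!keep)
  if (removed > 0)
    message("filter_by_length: removed ", removed, " of ", nrow(records),
            " record(s) shorter than ", min_length, " residues")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a data frame as a commented TSV artifact
#'
#' All tabular artifacts of the package are tab-separated with a header line
#' and optional `#`-prefixed metadata lines (tool version, seed, parameters)
#' before it.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param metadata Named character/numeric vector written as `# name: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, metadata = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  meta <- c(plantDBP = as.character(utils::packageVersion("plantDBP")),
            metadata)
  writeLines(paste0("# ", names(meta), ": ", as.character(meta)), con,
             sep = "\n")
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV artifact
#'
#' @param path Path to a file written by [write_tsv()] (or any TSV whose
#'   comment lines start with `#`).
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
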