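# Independent oracles used by the tests. These share no code with the
# package implementation paths they check.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive affine-gap Smith-Waterman with full co-optimal traceback.
# Gap of length L costs open + L * ext (the Biostrings convention).
# Returns the optimal local score plus the set of (identity, coverage)
# statistics over ALL co-optimal alignments, so a test can assert that the
# implementation's choice is one of the optima.
sw_oracle <- function(a, b, open = 11, ext = 1, submat = blosum62) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- submat[av[i], bv[j]]
    M[i + 1, j + 1] <- s + max(0, M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  best <- max(0, M)
  if (best == 0)
    return(list(score = 0, stats = list(list(pid = 0, cov_a = 0,
                                             cov_b = 0))))
  stats <- list()
  # DFS over all co-optimal paths ending at each maximal M cell
  walk <- function(i, j, state, ncol, nid, imin, jmin, imax, jmax) {
    if (state == "M") {
      s <- submat[av[i - 1], bv[j - 1]]
      ncol <- ncol + 1; nid <- nid + (av[i - 1] == bv[j - 1])
      imin <- min(imin, i - 1); jmin <- min(jmin, j - 1)
      prev <- M[i, j] - s
      if (prev <= 1e-9) {
        # fresh local start: this cell opens the alignment
        stats[[length(stats) + 1]] <<-
          list(pid = 100 * nid / ncol,
               cov_a = (imax - imin + 1) / n,
               cov_b = (jmax - jmin + 1) / m)
      }
      # co-optimal continuations (including through zero-score columns)
      for (st in c("M", "X", "Y")) {
        val <- switch(st, M = M[i - 1, j - 1], X = X[i - 1, j - 1],
                      Y = Y[i - 1, j - 1])
        if (abs(val - prev) < 1e-9 && val > -1e8)
          walk(i - 1, j - 1, st, ncol, nid, imin, jmin, imax, jmax)
      }
    } else if (state == "X") {
      ncol <- ncol + 1
      imin <- min(imin, i - 1)
      if (abs(M[i - 1, j] - open - ext - X[i, j]) < 1e-9)
        walk(i - 1, j, "M", ncol, nid, imin, jmin, imax, jmax)
      if (abs(X[i - 1, j] - ext - X[i, j]) < 1e-9)
        walk(i - 1, j, "X", ncol, nid, imin, jmin, imax, jmax)
    } else {
      ncol <- ncol + 1
      jmin <- min(jmin, j - 1)
      if (abs(M[i, j - 1] - open - ext - Y[i, j]) < 1e-9)
        walk(i, j - 1, "M", ncol, nid, imin, jmin, imax, jmax)
      if (abs(Y[i, j - 1] - ext - Y[i, j]) < 1e-9)
        walk(i, j - 1, "Y", ncol, nid, imin, jmin, imax, jmax)
    }
  }
  for (i in 2:(n + 1)) for (j in 2:(m + 1))
    if (abs(M[i, j] - best) < 1e-9)
      walk(i, j, "M", 0, 0, i - 1, j - 1, i - 1, j - 1)
  list(score = best, stats = stats)
}

# Brute-force connected components by repeated merging of edge endpoints.
components_oracle <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    if (nrow(edges)) for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      if (comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# All-pairs homology edge list at the package's default thresholds,
# recomputed directly from pairwise_similarity.
all_pairs_edges <- function(records, id_threshold = 35,
                            coverage_threshold = 0.9) {
  n <- nrow(records)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sim <- pairwise_similarity(records$sequence[i], records$sequence[j])
    if (sim$percent_identity >= id_threshold &&
        min(sim$coverage_a, sim$coverage_b) >= coverage_threshold)
      out <- rbind(out, c(i, j))
  }
  out
}

# Random valid protein records for round-trip and filtering tests.
random_records <- function(n, len_range = c(30, 130), seed = 1) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  data.frame(
    id = sprintf("prot%03d", seq_len(n)),
    sequence = vapply(lens, function(L)
      paste(sample(AA_CANONICAL, L, replace = TRUE), collapse = ""),
      character(1)),
    description = "",
    species = NA_character_,
    stringsAsFactors = FALSE)
}

write_fasta_text <- function(text) {
  path <- tempfile(fileext = ".fasta")
  writeLines(text, path)
  path
}
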