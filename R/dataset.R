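#' Labeled dataset construction
#'
#' A labeled dataset is a data frame of protein records with a binary
#' `label` column (`"DNA_BP"` / `"NON_DNA_BP"`), plus `provenance` and
#' `seed` attributes recording how it was assembled.
#'
#' @param records Protein record data frame.
#' @param labels Character vector, one of `"DNA_BP"`/`"NON_DNA_BP"` per
#'   record.
#' @param provenance Free-text tag, e.g. `"arabidopsis_equal_train"`.
#' @param seed Seed used in assembly (for the audit trail only).
#' @return A `dbp_dataset` data frame.
#' @export
labeled_dataset <- function(records, labels, provenance = "", seed = NA) {
  stopifnot(nrow(records) == length(labels),
            all(labels %in% c("DNA_BP", "NON_DNA_BP")))
  if (anyDuplicated(records$id))
    stop("duplicate protein ids in labeled dataset")
  out <- records
  out$label <- factor(labels, levels = c("DNA_BP", "NON_DNA_BP"))
  attr(out, "provenance") <- provenance
  attr(out, "seed") <- seed
  class(out) <- c("dbp_dataset", class(out))
  out
}

sample_ids <- function(pool, n, what) {
  if (n > nrow(pool))
    stop("requested ", n, " ", what, " but pool has only ", nrow(pool))
  pool[sample.int(nrow(pool), n), , drop = FALSE]
}

#' Balanced (equal-class) train/test split
#'
#' Samples the requested numbers of positive (DNA-binding) and negative
#' proteins for the training and test sets uniformly without replacement,
#' under one seed. Train and test are disjoint by construction.
#'
#' @param pos_pool,neg_pool Protein record data frames; the pools must not
#'   share ids.
#' @param n_train_pos,n_train_neg,n_test_pos,n_test_neg Class counts.
#' @param seed Integer seed.
#' @param provenance Tag prefix for the two datasets.
#' @return A list with `train` and `test` [labeled_dataset()]s.
#' @export
balanced_split <- function(pos_pool, neg_pool, n_train_pos, n_train_neg,
                           n_test_pos, n_test_neg, seed = 1,
                           provenance = "equal") {
  if (length(intersect(pos_pool$id, neg_pool$id)))
    stop("positive and negative pools share protein ids")
  if (n_train_pos + n_test_pos > nrow(pos_pool))
    stop("positive pool too small: need ", n_train_pos + n_test_pos,
         ", have ", nrow(pos_pool))
  if (n_train_neg + n_test_neg > nrow(neg_pool))
    stop("negative pool too small: need ", n_train_neg + n_test_neg,
         ", have ", nrow(neg_pool))
  local_seed(seed, {
    pos <- sample_ids(pos_pool, n_train_pos + n_test_pos, "positives")
    neg <- sample_ids(neg_pool, n_train_neg + n_test_neg, "negatives")
    train <- rbind(pos[seq_len(n_train_pos), , drop = FALSE],
                   neg[seq_len(n_train_neg), , drop = FALSE])
    test <- rbind(pos[n_train_pos + seq_len(n_test_pos), , drop = FALSE],
                  neg[n_train_neg + seq_len(n_test_neg), , drop = FALSE])
    list(train = labeled_dataset(train,
           rep(c("DNA_BP", "NON_DNA_BP"), c(n_train_pos, n_train_neg)),
           paste0(provenance, "_train"), seed),
         test = labeled_dataset(test,
           rep(c("DNA_BP", "NON_DNA_BP"), c(n_test_pos, n_test_neg)),
           paste0(provenance, "_test"), seed))
  })
}

#' Realistic (class-imbalanced) train/test split
#'
#' Emulates the class balance expected in a proteome, where non-DNA-binding
#' proteins outnumber DNA-binding ones roughly 10:1. The negative pool is
#' split in two (training gets the larger half when odd); each side gets
#' `floor(negatives_per_side / ratio)` positives, capped by the positive
#' pool.
#'
#' @param pos_pool,neg_pool Protein record data frames.
#' @param ratio Negative:positive ratio (default 10).
#' @param seed Integer seed.
#' @param provenance Tag prefix.
#' @return A list with `train` and `test` [labeled_dataset()]s.
#' @export
realistic_split <- function(pos_pool, neg_pool, ratio = 10, seed = 1,
                            provenance = "realistic") {
  if (length(intersect(pos_pool$id, neg_pool$id)))
    stop("positive and negative pools share protein ids")
  n_neg <- nrow(neg_pool)
  n_train_neg <- ceiling(n_neg / 2)
  n_test_neg <- n_neg - n_train_neg
  n_pos_side <- min(floor(n_train_neg / ratio), floor(n_test_neg / ratio))
  n_pos_side <- min(n_pos_side, floor(nrow(pos_pool) / 2))
  if (n_pos_side < 1)
    stop("pools too small for ratio ", ratio, ": ", n_neg, " negatives, ",
         nrow(pos_pool), " positives")
  balanced_split(pos_pool, neg_pool,
                 n_train_pos = n_pos_side, n_train_neg = n_train_neg,
                 n_test_pos = n_pos_side, n_test_neg = n_test_neg,
                 seed = seed, provenance = provenance)
}

#' Combine positive sources and sample per-source negatives
#'
#' Builds a lineage-level training pool: the positives are the union of the
#' per-source positive sets (e.g. Arabidopsis plus other-plant DNA-binding
#' proteins), and the negatives are sampled from each source's negative
#' pool in the stated per-source counts under one seed.
#'
#' @param pos_sets List of protein record data frames (all used in full).
#' @param neg_pools List of protein record data frames, parallel to
#'   `neg_counts`.
#' @param neg_counts Integer vector: how many negatives to draw from each
#'   pool. Their sum must equal the total number of positives.
#' @param seed Integer seed.
#' @param provenance Tag.
#' @return A [labeled_dataset()] with equal class counts.
#' @export
combine_plant_pool <- function(pos_sets, neg_pools, neg_counts, seed = 1,
                               provenance = "plant") {
  pos <- do.call(rbind, pos_sets)
  if (anyDuplicated(pos$id)) stop("positive sources share protein ids")
  stopifnot(length(neg_pools) == length(neg_counts))
  if (sum(neg_counts) != nrow(pos))
    stop("negative counts sum to ", sum(neg_counts), " but there are ",
         nrow(pos), " positives")
  neg <- local_seed(seed, {
    do.call(rbind, lapply(seq_along(neg_pools), function(i)
      sample_ids(neg_pools[[i]], neg_counts[i], "negatives")))
  })
  all <- rbind(pos, neg)
  rownames(all) <- NULL
  labeled_dataset(all, rep(c("DNA_BP", "NON_DNA_BP"),
                           c(nrow(pos), nrow(neg))),
                  provenance, seed)
}

#' Write a labeled dataset and its companion FASTA
#'
#' @param dataset A [labeled_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.fasta`.
#' @param split Split tag recorded in the table (e.g. "train").
#' @return The TSV path, invisibly.
#' @export
write_dataset <- function(dataset, prefix, split = "") {
  tsv <- data.frame(protein_id = dataset$id,
                    label = as.character(dataset$label),
                    split = split,
                    provenance = attr(dataset, "provenance"),
                    stringsAsFactors = FALSE)
  write_fasta(dataset, paste0(prefix, ".fasta"))
  write_tsv(tsv, paste0(prefix, ".tsv"),
            metadata = c(seed = attr(dataset, "seed")))
}
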