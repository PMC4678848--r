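#' Default domain-keyword list for DNA-binding evidence
#'
#' Regular expressions matched (case-insensitively) against Interpro/Pfam
#' domain descriptions to count a domain as evidence of DNA binding. The
#' list is a configurable operating definition, not a reconstruction of any
#' curator's judgment.
#' @format Character vector of regular expressions.
#' @export
DNA_BINDING_DOMAIN_KEYWORDS <- c("DNA[- ]binding", "transcription factor",
                                 "histone", "helix-turn-helix",
                                 "zinc finger.*DNA")

#' Assign annotation-comparison classes (GOA-DB / GOA-Other / GOA-Unknown)
#'
#' Classifies each protein by its existing annotation: `GOA_DB` when it has
#' evidence of DNA binding (a GO term in the DNA-binding closure, or a
#' domain description matching the DNA-binding keyword list); `GOA_UNKNOWN`
#' when it has neither a GO term nor an informative domain; `GOA_OTHER`
#' otherwise (annotated, but with alternative functions). The three classes
#' partition any protein list.
#'
#' @param protein_ids Character vector of proteins to classify.
#' @param go_terms Named list mapping protein id to its GO term ids (or an
#'   annotation data frame with `protein_id` and `go_term` columns).
#' @param domain_labels Named list mapping protein id to domain description
#'   strings (or a data frame with `protein_id` and `domain` columns).
#' @param dna_binding_terms Character vector of term ids counting as
#'   DNA-binding evidence (typically a [term_closure()]).
#' @param dna_keywords Regular expressions for DNA-binding domains
#'   (default [DNA_BINDING_DOMAIN_KEYWORDS]).
#' @return A character vector of classes named by protein id.
#' @export
classify_goa <- function(protein_ids, go_terms = list(),
                         domain_labels = list(), dna_binding_terms,
                         dna_keywords = DNA_BINDING_DOMAIN_KEYWORDS) {
  if (is.data.frame(go_terms))
    go_terms <- split(go_terms$go_term, go_terms$protein_id)
  if (is.data.frame(domain_labels))
    domain_labels <- split(domain_labels$domain, domain_labels$protein_id)
  pattern <- paste0("(", paste(dna_keywords, collapse = ")|("), ")")
  out <- vapply(protein_ids, function(id) {
    terms <- go_terms[[id]]
    domains <- domain_labels[[id]]
    db_term <- length(terms) && any(terms %in% dna_binding_terms)
    db_domain <- length(domains) &&
      any(grepl(pattern, domains, ignore.case = TRUE))
    if (db_term || db_domain) return("GOA_DB")
    if (!length(terms) && !length(domains)) return("GOA_UNKNOWN")
    "GOA_OTHER"
  }, character(1))
  names(out) <- protein_ids
  out
}

#' Nuclear-localisation fold enrichment
#'
#' Fold over-representation of predicted-nuclear proteins in the predicted
#' DNA-BP set relative to the whole proteome:
#' \deqn{(nNL_{DNA\mbox{-}BP} / nDNA\mbox{-}BP) / (nNL_{TProt} / nTProt)}
#'
#' @param n_nl_dbp Predicted-nuclear proteins among predicted DNA-BPs.
#' @param n_dbp Number of predicted DNA-BPs.
#' @param n_nl_proteome Predicted-nuclear proteins in the whole proteome.
#' @param n_proteome Proteome size.
#' @return The fold enrichment (a non-negative real; scale-invariant in the
#'   counts).
#' @export
nl_enrichment <- function(n_nl_dbp, n_dbp, n_nl_proteome, n_proteome) {
  stopifnot(n_nl_dbp >= 0, n_nl_proteome >= 0,
            n_nl_dbp <= n_dbp, n_nl_proteome <= n_proteome)
  if (n_dbp <= 0 || n_proteome <= 0 || n_nl_proteome <= 0)
    stop("zero denominator in enrichment calculation")
  (n_nl_dbp / n_dbp) / (n_nl_proteome / n_proteome)
}

#' Read nuclear-localisation flags
#'
#' Consumes a subcellular-localisation ranking table (protein_id,
#' nuclear_rank); proteins ranked 1 — the highest confidence for nuclear
#' localisation — are counted as predicted-nuclear.
#'
#' @param path TSV with columns `protein_id` and `nuclear_rank`.
#' @return Character vector of predicted-nuclear protein ids.
#' @export
read_nuclear_flags <- function(path) {
  tab <- read_tsv(path)
  stopifnot(all(c("protein_id", "nuclear_rank") %in% names(tab)))
  unique(tab$protein_id[tab$nuclear_rank == 1])
}

#' GO term over-representation analysis
#'
#' Singular enrichment analysis of a study set against a reference: for each
#' GO term annotated to the study set, a one-sided Fisher's exact test for
#' over-representation of term-carrying proteins in the set relative to the
#' rest of the reference, with Benjamini-Hochberg false-discovery-rate
#' correction. Proteins without any GO term are removed from both sides
#' before testing. Study-set proteins present in the reference are excluded
#' from the comparison side, so the 2x2 table is set vs reference-only.
#'
#' @param set_annotations Data frame (`protein_id`, `go_term`) for the study
#'   set.
#' @param reference_annotations Data frame (`protein_id`, `go_term`) for the
#'   reference (e.g. the whole proteome).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return A data frame sorted by `q_value`: `go_term`, `set_with_term`,
#'   `set_total`, `ref_with_term`, `ref_total`, `p_value`, `q_value`,
#'   `significant`.
#' @export
term_enrichment <- function(set_annotations, reference_annotations,
                            alpha = 0.05) {
  set_ann <- unique(set_annotations)
  set_terms <- split(set_ann$go_term, set_ann$protein_id)
  ref_ann <- unique(reference_annotations)
  ref_ann <- ref_ann[!(ref_ann$protein_id %in% names(set_terms)), ,
                     drop = FALSE]
  ref_terms <- split(ref_ann$go_term, ref_ann$protein_id)
  n_set <- length(set_terms)
  n_ref <- length(ref_terms)
  if (n_set == 0) stop("study set is empty after removing proteins ",
                       "without GO terms")
  terms <- sort(unique(unlist(set_terms, use.names = FALSE)))
  set_count <- vapply(terms, function(t)
    sum(vapply(set_terms, function(ts) t %in% ts, logical(1))), integer(1))
  ref_count <- vapply(terms, function(t)
    sum(vapply(ref_terms, function(ts) t %in% ts, logical(1))), integer(1))
  p <- vapply(seq_along(terms), function(i) {
    tab <- matrix(c(set_count[i], n_set - set_count[i],
                    ref_count[i], n_ref - ref_count[i]), nrow = 2,
                  byrow = TRUE)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(go_term = terms, set_with_term = set_count,
                    set_total = n_set, ref_with_term = ref_count,
                    ref_total = n_ref, p_value = p, q_value = q,
                    significant = q < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$go_term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-set overlap report (Venn regions)
#'
#' Counts the seven regions of a three-set Venn diagram, e.g. predicted
#' DNA-BPs vs externally annotated DNA-BPs vs chromatin-associated
#' proteins. Region counts sum to the size of the union.
#'
#' @param set_a,set_b,set_c Character vectors of ids.
#' @param names Labels for the three sets.
#' @return A named list of the seven region counts
#'   (`a_only`, `b_only`, `c_only`, `ab_only`, `ac_only`, `bc_only`,
#'   `abc`), plus `union` and the input set sizes.
#' @export
overlap_report <- function(set_a, set_b, set_c,
                           names = c("a", "b", "c")) {
  a <- unique(set_a); b <- unique(set_b); c <- unique(set_c)
  u <- unique(c(a, b, c))
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  out <- list(
    a_only = sum(in_a & !in_b & !in_c),
    b_only = sum(!in_a & in_b & !in_c),
    c_only = sum(!in_a & !in_b & in_c),
    ab_only = sum(in_a & in_b & !in_c),
    ac_only = sum(in_a & !in_b & in_c),
    bc_only = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c),
    union = length(u),
    sizes = stats::setNames(c(length(a), length(b), length(c)), names))
  stopifnot(sum(unlist(out[1:7])) == out$union)
  out
}
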