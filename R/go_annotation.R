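#' Construct a Gene Ontology DAG from term/parent lists
#'
#' Only `is_a` parentage is represented: the molecular-function hierarchy is
#' essentially `is_a`, and class assignment here uses molecular-function
#' terms only.
#'
#' @param terms Character vector of term ids.
#' @param parents Named list mapping a term id to a character vector of its
#'   `is_a` parent term ids. Terms absent from the list have no parents.
#' @return An object of class `go_dag` with elements `terms` (character) and
#'   `parents` (named list). Construction fails if a parent id is not a
#'   member of `terms` or if the graph is cyclic.
#' @export
go_dag <- function(terms, parents = list()) {
  terms <- unique(as.character(terms))
  parents <- parents[intersect(names(parents), terms)]
  all_parents <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(all_parents, terms)
  if (length(unknown))
    stop("parent term(s) not in term set: ", paste(unknown, collapse = ", "))
  dag <- structure(list(terms = terms, parents = parents), class = "go_dag")
  # cycle check: DFS from every node must never revisit the active path
  check_acyclic(dag)
  dag
}

check_acyclic <- function(dag) {
  state <- new.env(parent = emptyenv())
  visit <- function(t) {
    s <- state[[t]]
    if (identical(s, "active")) stop("cycle detected at term ", t)
    if (identical(s, "done")) return(invisible())
    state[[t]] <- "active"
    for (p in dag$parents[[t]]) visit(p)
    state[[t]] <- "done"
  }
  for (t in dag$terms) visit(t)
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", length(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a edges\n")
  invisible(x)
}

#' Parse a minimal OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas and extracts only `id:` and `is_a:` lines, which
#' is all that descendant-closure computation needs. Obsolete terms are
#' skipped. Other tags, typedefs and relationship types (e.g. `part_of`)
#' are ignored.
#'
#' @param path Path to an OBO flat file.
#' @return A [go_dag()] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur_id <- NULL; cur_parents <- character(); obsolete <- FALSE
  terms <- character(); parents <- list()
  flush <- function() {
    if (in_term && !is.null(cur_id) && !obsolete) {
      terms[[length(terms) + 1L]] <<- cur_id
      if (length(cur_parents)) parents[[cur_id]] <<- unique(cur_parents)
    }
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE; cur_id <- NULL; cur_parents <- character()
      obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE
    } else if (in_term) {
      if (grepl("^id:", ln)) {
        cur_id <- sub("^id:\\s*", "", ln)
      } else if (grepl("^is_a:", ln)) {
        p <- sub("^is_a:\\s*", "", ln)
        p <- sub("\\s*[!{].*$", "", p)  # strip comment / trailing modifiers
        cur_parents <- c(cur_parents, sub("\\s+$", "", p))
      } else if (grepl("^is_obsolete:\\s*true", ln)) {
        obsolete <- TRUE
      }
    }
  }
  flush()
  go_dag(unique(c(terms, unlist(parents, use.names = FALSE))), parents)
}

#' Descendant closure of a set of GO terms
#'
#' Returns the roots together with every term from which a root is reachable
#' by following `is_a` parent edges, i.e. the roots plus all their
#' descendants. Used to expand the DNA-binding roots (GO:0003677,
#' GO:0003700) to "and their child terms".
#'
#' @param dag A [go_dag()] object.
#' @param roots Character vector of term ids; all must be present in `dag`.
#' @return A character vector of term ids (a set; sorted for determinism).
#' @export
term_closure <- function(dag, roots) {
  roots <- as.character(roots)
  missing <- setdiff(roots, dag$terms)
  if (length(missing))
    stop("unknown root term(s): ", paste(missing, collapse = ", "))
  # invert parent edges once: parent -> children
  children <- list()
  for (child in names(dag$parents))
    for (p in dag$parents[[child]])
      children[[p]] <- c(children[[p]], child)
  seen <- new.env(parent = emptyenv())
  queue <- roots
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    if (!is.null(seen[[t]])) next
    seen[[t]] <- TRUE
    queue <- c(queue, children[[t]])
  }
  sort(ls(seen))
}

#' Evidence-code policies for annotation filtering
#'
#' Returns the set of GO evidence codes admitted by a named preset:
#' `"experimental_direct"` is IDA only (function inferred from direct
#' assay); `"manual"` is the manually-curated code set
#' EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC.
#'
#' @param preset `"experimental_direct"` or `"manual"`, or a character
#'   vector of codes to pass through unchanged.
#' @return A character vector of evidence codes.
#' @export
evidence_policy <- function(preset = "experimental_direct") {
  if (length(preset) == 1 && preset %in% c("experimental_direct", "manual"))
    return(switch(preset,
      experimental_direct = "IDA",
      manual = c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")))
  codes <- as.character(preset)
  if (!length(codes)) stop("evidence policy must be non-empty")
  codes
}

#' Read a GO annotation table
#'
#' Reads a tab-separated annotation table with one row per (protein, GO
#' term) pair. The default column names are `protein_id`, `go_term`,
#' `evidence_code`, `aspect`; a GAF-style file can be adapted by supplying
#' `columns` as a named mapping from these canonical names to the file's
#' column names or indices.
#'
#' @param path Path to the TSV (comment lines starting with `!` or `#` are
#'   skipped; a header is expected unless `columns` is numeric).
#' @param columns Named character or integer vector mapping canonical names
#'   (`protein_id`, `go_term`, `evidence_code`, `aspect`) to the file's
#'   columns.
#' @return A data frame with the four canonical columns. `aspect` values
#'   `F`/`P`/`C` are normalised to `molecular_function` /
#'   `biological_process` / `cellular_component`.
#' @export
read_go_annotations <- function(path,
                                columns = c(protein_id = "protein_id",
                                            go_term = "go_term",
                                            evidence_code = "evidence_code",
                                            aspect = "aspect")) {
  header <- !is.numeric(columns)
  raw <- utils::read.delim(path, sep = "\t", header = header,
                           comment.char = "#", stringsAsFactors = FALSE)
  raw <- raw[!grepl("^!", raw[[1]]), , drop = FALSE]
  need <- c("protein_id", "go_term", "evidence_code", "aspect")
  if (!all(need %in% names(columns)))
    stop("columns mapping must name: ", paste(need, collapse = ", "))
  out <- data.frame(lapply(columns[need], function(col) raw[[col]]),
                    stringsAsFactors = FALSE)
  names(out) <- need
  long <- c(F = "molecular_function", P = "biological_process",
            C = "cellular_component")
  short <- out$aspect %in% names(long)
  out$aspect[short] <- long[out$aspect[short]]
  out
}

#' Select proteins by GO term membership under an evidence policy
#'
#' Restricts annotations to the molecular-function aspect and the allowed
#' evidence codes, then selects proteins positively or negatively with
#' respect to a term set.
#'
#' @param annotations Annotation data frame (see [read_go_annotations()]).
#' @param term_set Character vector of GO term ids, typically a
#'   [term_closure()] of the DNA-binding roots.
#' @param policy Character vector of allowed evidence codes (see
#'   [evidence_policy()]).
#' @param positive If `TRUE`, return proteins with at least one
#'   allowed-evidence annotation inside `term_set`. If `FALSE`, return
#'   proteins with at least one allowed-evidence molecular-function
#'   annotation, none of which is in `term_set` (a protein carrying both a
#'   term-set and an outside annotation is excluded from the negative set to
#'   avoid label noise).
#' @return A sorted character vector of protein ids.
#' @export
select_by_terms <- function(annotations, term_set, policy, positive = TRUE) {
  policy <- evidence_policy(policy)
  keep <- annotations$aspect == "molecular_function" &
    annotations$evidence_code %in% policy
  ann <- annotations[keep, , drop = FALSE]
  if (!nrow(ann)) return(character())
  in_set <- ann$go_term %in% term_set
  pos_ids <- unique(ann$protein_id[in_set])
  if (positive) return(sort(pos_ids))
  sort(setdiff(unique(ann$protein_id), pos_ids))
}
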