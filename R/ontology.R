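#' Read an ontology from an OBO 1.2/1.4 file
#'
#' Parses `[Term]` stanzas.  `is_a:` and `relationship: part_of` both become
#' parent links; obsolete terms are excluded; `alt_id`s are recorded and mapped
#' to their canonical term when annotations are read.  The hierarchy must be
#' acyclic and every parent reference must resolve.
#'
#' @param path OBO file path.
#' @return a `go_ontology`: list with `terms`, `parents` (named list),
#'   `ancestors` (named list, transitive closure, term itself excluded),
#'   `namespace` (named character), `alt_id` (named character map alt -> id).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ## split into stanzas
  stanza_starts <- grep("^\\[", lines)
  terms <- list()
  for (si in seq_along(stanza_starts)) {
    s <- stanza_starts[si]
    e <- if (si < length(stanza_starts)) stanza_starts[si + 1] - 1 else length(lines)
    if (trimws(lines[s]) != "[Term]") next
    body <- lines[(s + 1):e]
    body <- sub("!.*$", "", body)          # strip trailing comments
    body <- trimws(body)
    body <- body[nzchar(body)]
    field <- sub(":.*$", "", body)
    value <- trimws(sub("^[^:]+:", "", body))
    id <- value[field == "id"][1]
    if (is.na(id)) next
    if (any(field == "is_obsolete" & value == "true")) {
      terms[[id]] <- list(id = id, obsolete = TRUE)
      next
    }
    parents <- value[field == "is_a"]
    rel <- value[field == "relationship"]
    po <- rel[startsWith(rel, "part_of")]
    if (length(po))
      parents <- c(parents, trimws(sub("^part_of", "", po)))
    terms[[id]] <- list(
      id = id, obsolete = FALSE,
      parents = unique(parents),
      namespace = (value[field == "namespace"] %||% character())[1],
      alt_id = value[field == "alt_id"])
  }
  if (!length(terms)) stop("no [Term] stanzas in ", path)
  live <- terms[!vapply(terms, `[[`, TRUE, "obsolete")]
  ids <- names(live)
  parents <- lapply(live, `[[`, "parents")
  ## parent references must resolve to live terms
  for (id in ids) {
    bad <- setdiff(parents[[id]], ids)
    if (length(bad))
      stop("term ", id, " has unresolved or obsolete parent(s): ",
           paste(bad, collapse = ", "))
  }
  ns <- vapply(live, function(t) {
    n <- t$namespace
    if (is.null(n) || is.na(n)) NA_character_ else
      switch(n, biological_process = "BP", molecular_function = "MF",
             cellular_component = "CC", n)
  }, character(1))
  alt <- character()
  for (t in live) for (a in t$alt_id) alt[[a]] <- t$id
  anc <- ancestor_closure(ids, parents)   # errors on a cycle
  structure(list(terms = ids, parents = parents, ancestors = anc,
                 namespace = ns, alt_id = alt),
            class = "go_ontology")
}

## transitive ancestor closure by memoised DFS; detects cycles
ancestor_closure <- function(ids, parents) {
  anc <- stats::setNames(vector("list", length(ids)), ids)
  state <- stats::setNames(integer(length(ids)), ids)  # 0 new, 1 visiting, 2 done
  visit <- function(id) {
    if (state[[id]] == 2L) return(anc[[id]])
    if (state[[id]] == 1L) stop("cycle in ontology involving term ", id)
    state[id] <<- 1L
    res <- character()
    for (p in parents[[id]]) res <- c(res, p, visit(p))
    anc[[id]] <<- lex_sort(unique(res))
    state[id] <<- 2L
    anc[[id]]
  }
  for (id in ids) visit(id)
  anc
}

#' Read gene -> GO annotations
#'
#' GAF 2.x (`format = "gaf"`: column 3 = symbol, 4 = qualifier, 5 = GO id;
#' rows with a `NOT` qualifier dropped; `!` comment lines skipped) or a
#' two-column `gene<TAB>term` TSV (`format = "tsv"`).  Annotations to terms
#' absent from the ontology (after `alt_id` mapping) are dropped and counted.
#' Annotation sets are propagated to all ancestors (true-path rule), and the
#' reverse index `term_genes` maps every term to genes annotated to it or any
#' descendant.
#'
#' @param path annotation file path.
#' @param ontology a `go_ontology` from [read_obo()].
#' @param format `"gaf"` or `"tsv"`.
#' @param genes optional character vector restricting the annotated-gene
#'   universe (e.g. the network's node set); the background for information
#'   content is the annotated genes kept.
#' @param namespaces optional subset of `c("BP","MF","CC")` restricting the
#'   terms used; default uses all three.
#' @param evidence optional inclusion list of GAF evidence codes (column 7);
#'   default keeps all.
#' @return an `annotation_map`: list with `direct`, `propagated`, `term_genes`
#'   (named lists of character vectors), `background_size`, `genes`,
#'   `n_dropped_terms`.
#' @export
read_annotations <- function(path, ontology, format = c("gaf", "tsv"),
                             genes = NULL, namespaces = NULL,
                             evidence = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!") & !startsWith(lines, "#")]
  if (!length(lines)) stop("no annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gaf") {
    ok <- vapply(fields, length, 0L) >= 5
    fields <- fields[ok]
    gene <- vapply(fields, `[[`, "", 3L)
    qual <- vapply(fields, `[[`, "", 4L)
    term <- vapply(fields, `[[`, "", 5L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    if (!is.null(evidence)) {
      ev <- vapply(fields, function(f) if (length(f) >= 7) f[[7]] else "", "")
      keep <- keep & ev %in% evidence
    }
    gene <- gene[keep]; term <- term[keep]
  } else {
    ok <- vapply(fields, length, 0L) >= 2
    gene <- vapply(fields[ok], `[[`, "", 1L)
    term <- vapply(fields[ok], `[[`, "", 2L)
  }
  ## alt_id -> canonical
  hit <- term %in% names(ontology$alt_id)
  term[hit] <- ontology$alt_id[term[hit]]
  known <- term %in% ontology$terms
  n_dropped <- sum(!known)
  gene <- gene[known]; term <- term[known]
  if (!is.null(namespaces)) {
    ns_ok <- ontology$namespace[term] %in% namespaces
    ns_ok[is.na(ns_ok)] <- FALSE
    gene <- gene[ns_ok]; term <- term[ns_ok]
  }
  if (!is.null(genes)) {
    in_u <- gene %in% genes
    gene <- gene[in_u]; term <- term[in_u]
  }
  if (!length(gene)) stop("no surviving annotations in ", path)
  direct <- lapply(split(term, gene), function(x) lex_sort(unique(x)))
  annotation_map(direct, ontology)
}

#' Build an annotation map from direct gene -> term sets
#'
#' Computes the propagated (ancestor-closed) sets and the term -> genes
#' reverse index.  Used by [read_annotations()] and by the synthetic
#' generator.
#'
#' @param direct named list: gene -> character vector of directly annotated
#'   terms (must exist in `ontology`).
#' @param ontology a `go_ontology`.
#' @return an `annotation_map` (see [read_annotations()]).
#' @export
annotation_map <- function(direct, ontology) {
  direct <- direct[lex_sort(names(direct))]
  propagated <- lapply(direct, function(ts)
    lex_sort(unique(c(ts, unlist(ontology$ancestors[ts], use.names = FALSE)))))
  g <- rep(names(propagated), lengths(propagated))
  t <- unlist(propagated, use.names = FALSE)
  term_genes <- lapply(split(g, t), function(x) lex_sort(unique(x)))
  structure(list(direct = direct, propagated = propagated,
                 term_genes = term_genes,
                 background_size = length(direct),
                 genes = names(direct),
                 n_dropped_terms = 0L),
            class = "annotation_map")
}

#' Term information content
#'
#' For each term annotating at least one gene, `pro(t)` is the fraction of the
#' annotated-gene background carrying `t` or any descendant (the propagated
#' count) and `I(t) = -log(pro(t))` (natural log).  Terms with no annotated
#' genes are excluded, never reported as zero information.
#'
#' @param annotations an `annotation_map`.
#' @return a `term_ic`: list with named numeric `prob` and `info`.
#' @export
compute_ic <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  n <- annotations$background_size
  if (n < 1) stop("empty annotation background")
  cnt <- lengths(annotations$term_genes)
  cnt <- cnt[cnt > 0]
  prob <- cnt / n
  structure(list(prob = prob, info = -log(prob)), class = "term_ic")
}

#' Total information of a protein
#'
#' Sum of `I(t)` over the protein's propagated annotation set; 0 for an
#' unannotated gene or one annotated only to zero-information (root) terms.
#'
#' @param gene gene identifier.
#' @param annotations an `annotation_map`.
#' @param ic a `term_ic` from [compute_ic()].
#' @return non-negative scalar.
#' @export
protein_information <- function(gene, annotations, ic) {
  ts <- annotations$propagated[[gene]]
  if (is.null(ts)) return(0)
  sum(ic$info[ts], na.rm = TRUE)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("Ontology:", length(x$terms), "terms,",
      sum(lengths(x$parents) == 0), "root(s)\n")
  invisible(x)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("Annotation map:", x$background_size, "genes,",
      length(x$term_genes), "terms with annotations\n")
  invisible(x)
}
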