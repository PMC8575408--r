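#' Stopping-rule configuration
#'
#' Expansion stops when any configured disease signal is no longer
#' significantly enriched in the candidate set `C` (enrichment p-value at or
#' above `alpha`), or when `max_iterations` is reached, or when the disease
#' set has no remaining neighbours.
#'
#' @param signals subset of `c("de_genes", "pathways", "go_terms")`; only
#'   signals whose reference sets are supplied to [idmcss()] are tested.
#' @param alpha significance level (default 0.05).
#' @param max_iterations hard cap on accreted proteins; `NULL` means the
#'   network node count.
#' @param bh apply Benjamini-Hochberg adjustment across a signal's multiple
#'   reference sets before taking the minimum p (default `FALSE`).
#' @return a `stopping_config` list.
#' @export
stopping_config <- function(signals = c("de_genes", "pathways", "go_terms"),
                            alpha = 0.05, max_iterations = NULL, bh = FALSE) {
  signals <- match.arg(signals, several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(signals = signals, alpha = alpha,
                 max_iterations = max_iterations, bh = bh),
            class = "stopping_config")
}

#' Select the next candidate disease protein
#'
#' The neighbour with maximal combined similarity `sv`; ties broken by the
#' lexicographically smallest identifier.
#'
#' @param scores neighbour score frame from [score_neighbors()].
#' @return gene identifier, or `NULL` for an empty frame (natural
#'   termination).
#' @export
select_candidate <- function(scores) {
  if (!nrow(scores)) return(NULL)
  best <- scores$gene[scores$sv == max(scores$sv)]
  lex_sort(best)[1]
}

#' Test the enrichment stopping rule
#'
#' For each configured signal with reference sets available, computes the
#' over-representation p-value of the candidate set `C` (minimum over the
#' signal's sets, optionally BH-adjusted).  The rule fires — `stop = TRUE` —
#' as soon as ANY configured signal has `p >= alpha`.  Never stops on an
#' empty `C`.
#'
#' @param C character vector, the candidate (expanded) set.
#' @param signal_sets named list: signal name -> list of `gene_set` objects
#'   (or character vectors).
#' @param background character vector of background genes.
#' @param config a [stopping_config()].
#' @return list with `stop` (logical) and `p` (named numeric, one per tested
#'   signal).
#' @export
check_stopping <- function(C, signal_sets, background, config) {
  if (length(background) < length(C))
    stop("background smaller than the candidate set")
  tested <- intersect(config$signals, names(signal_sets))
  tested <- tested[lengths(signal_sets[tested]) > 0]
  p <- stats::setNames(rep(NA_real_, length(tested)), tested)
  if (!length(C) || !length(tested))
    return(list(stop = FALSE, p = p))
  for (sig in tested) {
    sets <- signal_sets[[sig]]
    ps <- vapply(sets, function(s) {
      ref <- if (inherits(s, "gene_set")) s$members else s
      enrichment_test(C, intersect(ref, background), background)$p_value
    }, 0)
    if (config$bh && length(ps) > 1) ps <- stats::p.adjust(ps, "BH")
    p[sig] <- min(ps)
  }
  list(stop = any(p >= config$alpha), p = p)
}

#' Extract the disease module from the expanded set
#'
#' Induces the subgraph on `S` in the (adjusted) network and returns the
#' connected component with the most disease proteins (every node of the
#' induced subgraph is a disease protein, so this is the largest component);
#' ties broken by most edges, then by smallest lexicographic node label.
#'
#' @param network igraph network (typically the final adjusted one).
#' @param S character vector, the expanded disease-protein set.
#' @return a `disease_module`: list with `nodes`, `edges` (data frame `u`,
#'   `v`), `seed_members`, `components_considered`.
#' @export
extract_module <- function(network, S) {
  if (!length(S)) stop("S must be non-empty")
  gs <- igraph::induced_subgraph(network, intersect(S, igraph::V(network)$name))
  comp <- igraph::components(gs)
  best <- NULL; best_key <- NULL
  for (ci in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    sub <- igraph::induced_subgraph(gs, nodes)
    key <- list(n = length(nodes), m = igraph::ecount(sub),
                label = lex_sort(nodes)[1])
    better <- is.null(best) ||
      key$n > best_key$n ||
      (key$n == best_key$n && key$m > best_key$m) ||
      (key$n == best_key$n && key$m == best_key$m && key$label < best_key$label)
    if (better) { best <- sub; best_key <- key }
  }
  el <- igraph::as_edgelist(best)
  structure(list(nodes = lex_sort(igraph::V(best)$name),
                 edges = data.frame(u = el[, 1], v = el[, 2],
                                    stringsAsFactors = FALSE),
                 seed_members = lex_sort(intersect(igraph::V(best)$name, S)),
                 components_considered = comp$no),
            class = "disease_module")
}

#' Detect a disease module by seed expansion on a locally adjusted network
#'
#' Starting from the known disease proteins, each iteration (i) collects the
#' neighbours of the current disease set `S`, (ii) locally adjusts the network
#' around `S` — adding links between strong-linked neighbours and `S` members
#' they plausibly interact with, removing links from weak-linked neighbours —
#' (iii) rescoring the neighbours of `S` on the adjusted network, and (iv)
#' accretes the neighbour with the best combined connectivity + semantic
#' similarity into `S`.  After each accretion the enrichment stopping rule is
#' tested on the expanded set `C`; when it fires, the failing iteration
#' (accretion and that iteration's edits) is rolled back, so the returned
#' state is the last one in which every configured signal was still enriched.
#' Finally the subgraph induced on `S` is extracted from the adjusted network
#' and its largest component returned as the disease module.
#'
#' @param network igraph PPI network (see [read_network()]).
#' @param seeds a `gene_set` or character vector of known disease proteins;
#'   members absent from the network are dropped with a warning.
#' @param annotations an `annotation_map` (see [read_annotations()]).
#' @param ic a `term_ic` (see [compute_ic()]); computed from `annotations`
#'   when `NULL`.
#' @param de_genes optional `gene_set`/character vector of differentially
#'   expressed genes (stopping signal).
#' @param pathways optional list of `gene_set`s (stopping signal).
#' @param go_reference optional `gene_set`/character vector for the GO signal;
#'   when `"derived"`, built once at startup as the union of genes annotated
#'   to the terms enriched in the seeds at `alpha`.
#' @param stopping a [stopping_config()].
#' @param strong_threshold connective-similarity cut-off for strong-linked
#'   neighbours (default 0.99).
#' @param enable_add,enable_remove switch either adjustment operator off.
#' @param semantic set `FALSE` for the connectivity-only ablation: semantic
#'   similarity forced to 0 in scoring and no edits qualify.
#' @return an object of class `idmcss`: list with the final `S`, seeds `S0`,
#'   expanded set `C`, `module` (a `disease_module`), final `network`,
#'   per-iteration `trace` data frame, `edit_log`, `iterations`, and the
#'   configuration used.
#' @export
idmcss <- function(network, seeds, annotations, ic = NULL,
                   de_genes = NULL, pathways = NULL, go_reference = NULL,
                   stopping = stopping_config(),
                   strong_threshold = 0.99,
                   enable_add = TRUE, enable_remove = TRUE,
                   semantic = TRUE) {
  seed_members <- if (inherits(seeds, "gene_set")) seeds$members else
    as.character(seeds)
  nodes <- igraph::V(network)$name
  missing <- setdiff(seed_members, nodes)
  if (length(missing))
    warning(length(missing), " seed(s) absent from the network dropped: ",
            paste(utils::head(lex_sort(missing), 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  S0 <- lex_sort(intersect(seed_members, nodes))
  if (!length(S0)) stop("no seed proteins present in the network")
  if (is.null(ic)) ic <- compute_ic(annotations)

  signal_sets <- list()
  if (!is.null(de_genes))
    signal_sets$de_genes <- list(de_genes)
  if (!is.null(pathways))
    signal_sets$pathways <- pathways
  if (!is.null(go_reference)) {
    if (identical(go_reference, "derived"))
      go_reference <- derive_go_reference(S0, annotations, stopping$alpha)
    signal_sets$go_terms <- list(go_reference)
  }
  max_iter <- stopping$max_iterations %||% igraph::vcount(network)
  cache <- ss_cache(annotations, ic)

  g <- network
  S <- S0
  C <- character()
  log <- empty_edit_log()
  trace <- list()
  iter <- 0L
  stop_reason <- "max_iterations"
  while (iter < max_iter) {
    snap <- list(g = g, S = S, C = C, log = log)
    if (!length(neighbor_set(g, S))) { stop_reason <- "no_neighbors"; break }
    scores0 <- score_neighbors(g, S, annotations, ic, semantic = semantic,
                               cache = cache)
    adj <- adjust_network(g, S, scores0, annotations, ic,
                          strong_threshold = strong_threshold,
                          enable_add = enable_add,
                          enable_remove = enable_remove,
                          semantic = semantic, cache = cache)
    g <- adj$network
    n_add <- nrow(adj$plan$additions); n_rem <- nrow(adj$plan$removals)
    if (n_add) log <- rbind(log, data.frame(
      u = adj$plan$additions$u, v = adj$plan$additions$v, action = "add",
      iteration = iter + 1L, semantic_similarity = adj$plan$additions$ss,
      stringsAsFactors = FALSE))
    if (n_rem) log <- rbind(log, data.frame(
      u = adj$plan$removals$u, v = adj$plan$removals$v, action = "remove",
      iteration = iter + 1L, semantic_similarity = adj$plan$removals$ss,
      stringsAsFactors = FALSE))
    scores <- score_neighbors(g, S, annotations, ic, semantic = semantic,
                              cache = cache)
    b <- select_candidate(scores)
    if (is.null(b)) { g <- snap$g; log <- snap$log
                      stop_reason <- "no_neighbors"; break }
    row <- scores[scores$gene == b, ]
    S <- lex_sort(c(S, b)); C <- lex_sort(c(C, b))
    iter <- iter + 1L
    chk <- check_stopping(C, signal_sets, nodes, stopping)
    trace[[iter]] <- data.frame(
      iteration = iter, accreted_gene = b, cs = row$cs, ss = row$ss,
      sv = row$sv, n_added = n_add, n_removed = n_rem,
      p_de = chk$p["de_genes"] %||% NA_real_,
      p_pathways = chk$p["pathways"] %||% NA_real_,
      p_go = chk$p["go_terms"] %||% NA_real_,
      accepted = !chk$stop, stringsAsFactors = FALSE, row.names = NULL)
    if (chk$stop) {
      g <- snap$g; S <- snap$S; C <- snap$C; log <- snap$log
      iter <- iter - 1L
      stop_reason <- "enrichment_lost"
      break
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else data.frame(
    iteration = integer(), accreted_gene = character(), cs = numeric(),
    ss = numeric(), sv = numeric(), n_added = integer(),
    n_removed = integer(), p_de = numeric(), p_pathways = numeric(),
    p_go = numeric(), accepted = logical(), stringsAsFactors = FALSE)
  module <- extract_module(g, S)
  structure(list(S = S, S0 = S0, C = C, module = module, network = g,
                 trace = trace, edit_log = log, iterations = iter,
                 stop_reason = stop_reason, stopping = stopping,
                 config = list(strong_threshold = strong_threshold,
                               enable_add = enable_add,
                               enable_remove = enable_remove,
                               semantic = semantic)),
            class = "idmcss")
}

#' Derive a GO reference gene set from the seeds
#'
#' The union of genes annotated to every term that is enriched
#' (over-represented, `p < alpha`) in the seed set against the annotated-gene
#' background — the package's stand-in for a curated disease-term list when
#' the GO stopping signal is requested.
#'
#' @param seeds character vector of seed proteins.
#' @param annotations an `annotation_map`.
#' @param alpha term-level significance level.
#' @return a `gene_set` named `"go_derived"` (empty `members` possible).
#' @export
derive_go_reference <- function(seeds, annotations, alpha = 0.05) {
  bg <- annotations$genes
  seeds <- intersect(seeds, bg)
  members <- character()
  for (t in names(annotations$term_genes)) {
    tg <- annotations$term_genes[[t]]
    if (length(tg) == length(bg)) next   # root: p = 1 by construction
    p <- enrichment_test(seeds, tg, bg)$p_value
    if (p < alpha) members <- c(members, tg)
  }
  structure(list(name = "go_derived", members = lex_sort(unique(members))),
            class = "gene_set")
}

#' @export
print.idmcss <- function(x, ...) {
  cat("IDMCSS disease module fit\n")
  cat("  seeds:", length(x$S0), " expanded:", length(x$C),
      " iterations:", x$iterations, sprintf("(%s)\n", x$stop_reason))
  cat("  module:", length(x$module$nodes), "nodes /",
      nrow(x$module$edges), "edges (",
      length(x$module$seed_members), "disease proteins;",
      x$module$components_considered, "component(s) considered )\n")
  cat("  edits: ", sum(x$edit_log$action == "add"), "added /",
      sum(x$edit_log$action == "remove"), "removed\n")
  invisible(x)
}

#' @export
summary.idmcss <- function(object, ...) {
  tr <- object$trace
  acc <- tr[tr$accepted, , drop = FALSE]
  out <- list(
    n_seeds = length(object$S0), n_expanded = length(object$C),
    iterations = object$iterations, stop_reason = object$stop_reason,
    module_nodes = length(object$module$nodes),
    module_edges = nrow(object$module$edges),
    seeds_in_module = sum(object$module$seed_members %in% object$S0),
    links_added = sum(object$edit_log$action == "add"),
    links_removed = sum(object$edit_log$action == "remove"),
    mean_sv = if (nrow(acc)) mean(acc$sv) else NA_real_)
  class(out) <- "summary.idmcss"
  out
}

#' @export
print.summary.idmcss <- function(x, ...) {
  cat("IDMCSS fit summary\n")
  for (f in names(x)) cat(sprintf("  %-16s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' @export
plot.idmcss <- function(x, ...) {
  g <- igraph::induced_subgraph(x$network, x$module$nodes)
  cols <- ifelse(igraph::V(g)$name %in% x$S0, "tomato", "grey70")
  igraph::plot.igraph(g, vertex.color = cols, vertex.size = 8,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}
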