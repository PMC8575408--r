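#' Classify neighbours as strong- or weak-linked
#'
#' A strong-linked node has connective similarity with `S` above
#' `strong_threshold` (default 0.99); a weak-linked node has connective
#' similarity strictly below the mean over the neighbour set.  The two classes
#' cannot intersect: whenever a node exceeds 0.99 the neighbour-set mean is
#' below it.
#'
#' @param scores neighbour score frame from [score_neighbors()] (non-empty).
#' @param strong_threshold strong cut-off in `(0, 1)`.
#' @return list with character vectors `strong` and `weak`.
#' @export
classify_neighbors <- function(scores, strong_threshold = 0.99) {
  if (!nrow(scores)) stop("no neighbour scores to classify")
  stopifnot(strong_threshold > 0, strong_threshold < 1)
  m <- mean(scores$cs)
  list(strong = scores$gene[scores$cs > strong_threshold],
       weak   = scores$gene[scores$cs < m])
}

## phi threshold: mean pairwise semantic similarity to a reference seed group
edit_threshold <- function(ss_values) mean(ss_values)

## strict decision rules of the two operators
link_addition_decision <- function(ss_candidate, phi1) ss_candidate > phi1
link_removal_decision  <- function(ss_connected, phi2) ss_connected < phi2

#' Adding-link operator for one strong-linked node
#'
#' Splits `S` into the members already connected to `p_strong` (`S1'`) and the
#' rest (`S2'`).  The threshold `phi1` is the mean pairwise semantic
#' similarity between `p_strong` and `S1'`; an edge to each `p` in `S2'` is
#' added iff `ss(p_strong, p) > phi1` (strict).
#'
#' @param network igraph network (adjacency snapshot the decision is taken on).
#' @param p_strong strong-linked node identifier.
#' @param S character vector of current disease proteins.
#' @param annotations,ic annotation map and information content.
#' @param pinfo optional named vector of precomputed protein informations for
#'   the members of `S` (performance cache; computed when `NULL`).
#' @return data frame of added pairs (`u` = `p_strong`, `v`, `ss`), plus
#'   attribute `phi1`.
#' @export
add_links <- function(network, p_strong, S, annotations, ic, pinfo = NULL,
                      cache = NULL) {
  nb <- igraph::as_ids(igraph::neighbors(network, p_strong))
  res <- op_add(nb, p_strong, S, annotations, ic, pinfo, cache)
  out <- data.frame(u = rep(p_strong, length(res$v)),
                    v = res$v %||% character(),
                    ss = res$ss %||% numeric(), stringsAsFactors = FALSE)
  structure(out, phi1 = res$phi %||% NA_real_)
}

## lean kernel used per strong node inside the adjustment sweep; S sorted
op_add <- function(nb, p, S, annotations, ic, pinfo, cache) {
  in_nb <- S %in% nb
  S1 <- S[in_nb]; S2 <- S[!in_nb]
  if (!length(S1) || !length(S2)) return(NULL)
  phi1 <- edit_threshold(pairwise_ss_vec(p, S1, annotations, ic, pinfo, cache))
  ssv <- pairwise_ss_vec(p, S2, annotations, ic, pinfo, cache)
  hit <- link_addition_decision(ssv, phi1)
  list(phi = phi1, v = S2[hit], ss = unname(ssv[hit]))
}

#' Removing-link operator for one weak-linked node
#'
#' Splits `S` into the members connected to `p_weak` (`S2''`) and the rest
#' (`S1''`).  The threshold `phi2` is the mean pairwise semantic similarity
#' between `p_weak` and the non-connected members `S1''`; the edge to each `p`
#' in `S2''` is removed iff `ss(p_weak, p) < phi2` (strict).  When `S1''` is
#' empty the threshold is undefined and nothing is removed.
#'
#' @inheritParams add_links
#' @param p_weak weak-linked node identifier.
#' @return data frame of removed pairs (`u` = `p_weak`, `v`, `ss`), plus
#'   attribute `phi2`.
#' @export
remove_links <- function(network, p_weak, S, annotations, ic, pinfo = NULL,
                         cache = NULL) {
  nb <- igraph::as_ids(igraph::neighbors(network, p_weak))
  res <- op_remove(nb, p_weak, S, annotations, ic, pinfo, cache)
  out <- data.frame(u = rep(p_weak, length(res$v)),
                    v = res$v %||% character(),
                    ss = res$ss %||% numeric(), stringsAsFactors = FALSE)
  structure(out, phi2 = res$phi %||% NA_real_)
}

## lean kernel used per weak node inside the adjustment sweep; S sorted
op_remove <- function(nb, p, S, annotations, ic, pinfo, cache) {
  in_nb <- S %in% nb
  S2 <- S[in_nb]                         # connected members
  S1 <- S[!in_nb]                        # non-connected members
  if (!length(S1) || !length(S2)) return(NULL)
  phi2 <- edit_threshold(pairwise_ss_vec(p, S1, annotations, ic, pinfo, cache))
  ssv <- pairwise_ss_vec(p, S2, annotations, ic, pinfo, cache)
  hit <- link_removal_decision(ssv, phi2)
  list(phi = phi2, v = S2[hit], ss = unname(ssv[hit]))
}

#' Locally adjust the network around the disease set
#'
#' Applies the adding-link operator to every strong-linked neighbour and the
#' removing-link operator to every weak-linked neighbour, in lexicographic
#' node order.  All decisions are taken against the adjacency snapshot at call
#' time and applied together, so the result does not depend on operator
#' order.  Node set is never changed; every edit has exactly one endpoint in
#' `S`.
#'
#' @param network igraph network.
#' @param S character vector of current disease proteins.
#' @param scores neighbour scores from [score_neighbors()] on `network`/`S`;
#'   recomputed when `NULL`.
#' @param annotations,ic annotation map and information content.
#' @param strong_threshold strong-linked cut-off (default 0.99).
#' @param enable_add,enable_remove switch either operator off.
#' @param semantic passed to [score_neighbors()] when scores are recomputed;
#'   with `semantic = FALSE` every phi decision sees zero similarity and no
#'   edit qualifies.
#' @param cache internal performance cache built by the expansion loop; leave
#'   `NULL` when calling directly.
#' @return list with `network` (the adjusted graph), `plan` (list: `strong`,
#'   `weak`, `additions`, `removals`, `phi1`, `phi2`).
#' @export
adjust_network <- function(network, S, scores = NULL, annotations, ic,
                           strong_threshold = 0.99,
                           enable_add = TRUE, enable_remove = TRUE,
                           semantic = TRUE, cache = NULL) {
  if (!all(S %in% igraph::V(network)$name))
    stop("S contains nodes absent from the network")
  if (is.null(scores))
    scores <- score_neighbors(network, S, annotations, ic, semantic = semantic)
  empty <- data.frame(u = character(), v = character(), ss = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(scores))
    return(list(network = network,
                plan = list(strong = character(), weak = character(),
                            additions = empty, removals = empty,
                            phi1 = numeric(), phi2 = numeric())))
  cls <- classify_neighbors(scores, strong_threshold)
  adds <- empty; rems <- empty
  phi1 <- stats::setNames(numeric(0), character(0))
  phi2 <- stats::setNames(numeric(0), character(0))
  pinfo <- if (is.null(cache))
    vapply(S, protein_information, 0, annotations, ic)
  else cache_pinfo(S, cache)
  S_sorted <- lex_sort(S)
  touched <- lex_sort(c(if (enable_add && semantic) cls$strong,
                        if (enable_remove && semantic) cls$weak))
  nbs <- if (length(touched))
    lapply(igraph::adjacent_vertices(network, touched), igraph::as_ids)
  else list()
  names(nbs) <- touched
  au <- av <- ru <- rv <- character(); ass <- rss <- numeric()
  if (enable_add && semantic) for (p in lex_sort(cls$strong)) {
    res <- op_add(nbs[[p]], p, S_sorted, annotations, ic, pinfo, cache)
    if (is.null(res)) next
    phi1[p] <- res$phi
    if (length(res$v)) {
      au <- c(au, rep(p, length(res$v))); av <- c(av, res$v)
      ass <- c(ass, res$ss)
    }
  }
  if (enable_remove && semantic) for (p in lex_sort(cls$weak)) {
    res <- op_remove(nbs[[p]], p, S_sorted, annotations, ic, pinfo, cache)
    if (is.null(res)) next
    phi2[p] <- res$phi
    if (length(res$v)) {
      ru <- c(ru, rep(p, length(res$v))); rv <- c(rv, res$v)
      rss <- c(rss, res$ss)
    }
  }
  adds <- data.frame(u = au, v = av, ss = ass, stringsAsFactors = FALSE)
  rems <- data.frame(u = ru, v = rv, ss = rss, stringsAsFactors = FALSE)
  g <- network
  if (nrow(adds)) g <- igraph::add_edges(g, rbind(adds$u, adds$v))
  if (nrow(rems)) g <- igraph::delete_edges(
    g, igraph::get_edge_ids(g, as.vector(rbind(rems$u, rems$v))))
  list(network = g,
       plan = list(strong = cls$strong, weak = cls$weak,
                   additions = adds, removals = rems,
                   phi1 = phi1, phi2 = phi2))
}
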