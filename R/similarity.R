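#' Connective similarity (hypergeometric connectivity score)
#'
#' For a neighbour with degree `k`, of which `k_s` links run into the current
#' disease set `S` of size `n`, in a network of `N` nodes:
#' \deqn{cs = 1 - \sum_{t=k_s}^{k} \frac{\binom{n}{t}\binom{N-n}{k-t}}{\binom{N}{k}}}
#' i.e. one minus the upper tail \eqn{P(X \ge k_s)} of a hypergeometric draw
#' of `k` from `N` with `n` successes.  Large values mean the node is more
#' connected to `S` than expected by chance.  Computed in log space
#' (`lchoose` + log-sum-exp) so interactome-scale `N` does not overflow.
#'
#' @param k node degree.
#' @param k_s links from the node into `S` (`0 <= k_s <= k`).
#' @param n size of `S` (`0 < n < N`).
#' @param N node count of the network.
#' @return a value in `[0, 1]`; 0 when `k_s = 0`.
#' @export
connective_similarity <- function(k, k_s, n, N) {
  if (any(k_s < 0) || any(k_s > k) || any(k > N) || n <= 0 || n >= N)
    stop("require 0 <= k_s <= k <= N and 0 < n < N")
  vapply(seq_along(k), function(i) {
    hi <- min(k[i], n)
    if (k_s[i] > hi) return(1)           # k_s exceeds every possible overlap
    t <- seq.int(k_s[i], hi)
    lw <- lchoose(n, t) + lchoose(N - n, k[i] - t) - lchoose(N, k[i])
    m <- max(lw)
    tail <- exp(m) * sum(exp(lw - m))
    max(0, min(1, 1 - tail))
  }, numeric(1))
}

#' Semantic similarity between a protein and the disease set
#'
#' Information-content weighted annotation overlap:
#' \deqn{ss(b, S) = \frac{\sum_{i=1}^{n} \sum_{t \in A_b \cap A_{p_i}} I(t)}{I_{max}(S)}}
#' where \eqn{A_x} is the propagated annotation set of `x`,
#' \eqn{I(t)} the term information content and
#' \eqn{I_{max}(S) = \max_{p \in S} I(p)} the largest protein information in
#' `S`.  Returns 0 when `gene` is unannotated, shares no terms with any
#' member, or `I_max(S) = 0`.  The double sum over members is normalised by a
#' single protein's information, so the score is not bounded by 1 and is used
#' unclamped.
#'
#' @param gene gene identifier.
#' @param S character vector of disease proteins (non-empty).
#' @param annotations an `annotation_map`.
#' @param ic a `term_ic`.
#' @return non-negative scalar.
#' @export
semantic_similarity <- function(gene, S, annotations, ic) {
  if (!length(S)) stop("S must be non-empty")
  imax <- max(vapply(S, protein_information, 0, annotations, ic))
  ss_against_counts(annotations$propagated[[gene]],
                    term_counts(S, annotations), ic$info, imax)
}

## how many members of S carry each term (propagated); the double sum of the
## semantic score factorises over these counts:
## sum_p sum_{t in A_b ∩ A_p} I(t)  =  sum_{t in A_b} I(t) * n_S(t)
term_counts <- function(S, annotations) {
  ts <- unlist(annotations$propagated[S], use.names = FALSE)
  if (!length(ts)) return(integer())
  c(table(ts))
}

ss_against_counts <- function(A_b, counts, info, imax) {
  if (is.null(A_b) || !length(A_b) || imax <= 0 || !length(counts)) return(0)
  n_S <- counts[A_b]
  n_S[is.na(n_S)] <- 0L
  total <- sum(info[A_b] * n_S, na.rm = TRUE)
  total / imax
}

## The semantic score with a singleton disease set: the pairwise similarity
## used by the phi thresholds of the adjustment operators.
pairwise_ss <- function(x, y, annotations, ic) {
  semantic_similarity(x, y, annotations, ic)
}

## Integer-indexed view of the propagated annotation sets and term
## informations.  The expansion loop evaluates the semantic score tens of
## thousands of times; integer term ids avoid repeated character hashing.
ss_cache <- function(annotations, ic) {
  terms <- names(ic$info)
  idx <- stats::setNames(seq_along(terms), terms)
  prop <- lapply(annotations$propagated, function(ts) {
    ts <- ts[ts %in% terms]
    unname(idx[ts])
  })
  info <- unname(ic$info)
  list(prop = prop, info = info,
       pinfo = vapply(prop, function(ii) sum(info[ii]), 0),
       nterms = length(terms))
}

## protein information under a cache; 0 for unannotated genes
cache_pinfo <- function(genes, cache) {
  out <- cache$pinfo[genes]
  out[is.na(out)] <- 0
  names(out) <- genes
  out
}

## vectorised pairwise similarity of one node against several, with an
## optional precomputed protein-information lookup for the y side
pairwise_ss_vec <- function(x, ys, annotations, ic, pinfo = NULL,
                            cache = NULL) {
  if (!is.null(cache)) {
    ii_x <- cache$prop[[x]]
    iy <- cache_pinfo(ys, cache)
    if (is.null(ii_x) || !length(ii_x)) return(rep(0, length(ys)))
    mask <- logical(cache$nterms)
    mask[ii_x] <- TRUE
    return(vapply(seq_along(ys), function(i) {
      if (iy[[i]] <= 0) return(0)
      jj <- cache$prop[[ys[[i]]]]
      if (is.null(jj)) return(0)
      jj <- jj[mask[jj]]
      if (!length(jj)) 0 else sum(cache$info[jj]) / iy[[i]]
    }, 0))
  }
  A_x <- annotations$propagated[[x]]
  iy <- if (is.null(pinfo))
    vapply(ys, protein_information, 0, annotations, ic)
  else pinfo[ys]
  vapply(seq_along(ys), function(i) {
    if (is.null(A_x) || iy[[i]] <= 0) return(0)
    A_y <- annotations$propagated[[ys[[i]]]]
    if (is.null(A_y)) return(0)
    common <- A_x[A_x %in% A_y]
    if (!length(common)) 0 else sum(ic$info[common], na.rm = TRUE) / iy[[i]]
  }, 0)
}

#' Combined similarity
#'
#' Arithmetic mean of the connective and semantic similarities; the score used
#' to prioritise neighbours during expansion.
#'
#' @param cs connective similarity in `[0, 1]`.
#' @param ss semantic similarity, non-negative.
#' @return `(cs + ss) / 2`.
#' @export
combined_similarity <- function(cs, ss) {
  stopifnot(all(cs >= 0 & cs <= 1), all(ss >= 0))
  (cs + ss) / 2
}

#' Score the neighbours of the disease set
#'
#' Computes `cs`, `ss` and `sv` for every node in
#' `NS = neighbours(S) \\ S`, one row per neighbour, sorted by identifier.
#'
#' @param network igraph PPI network.
#' @param S character vector of current disease proteins (subset of nodes).
#' @param annotations an `annotation_map`.
#' @param ic a `term_ic`.
#' @param semantic set `FALSE` to force `ss = 0` (connectivity-only scoring).
#' @param cache internal performance cache built by the expansion loop; leave
#'   `NULL` when calling directly.
#' @return data frame with columns `gene`, `cs`, `ss`, `sv`, `k`, `k_s`, `n`.
#' @export
score_neighbors <- function(network, S, annotations, ic, semantic = TRUE,
                            cache = NULL) {
  if (!length(S)) stop("S must be non-empty")
  if (!all(S %in% igraph::V(network)$name))
    stop("S contains nodes absent from the network")
  NS <- neighbor_set(network, S)
  N <- igraph::vcount(network)
  n <- length(S)
  if (!length(NS))
    return(data.frame(gene = character(), cs = numeric(), ss = numeric(),
                      sv = numeric(), k = integer(), k_s = integer(),
                      n = integer(), stringsAsFactors = FALSE))
  k <- as.integer(igraph::degree(network, NS))
  adj <- igraph::adjacent_vertices(network, NS)
  k_s <- vapply(adj, function(vs) sum(igraph::as_ids(vs) %in% S), 0L)
  cs <- connective_similarity(k, k_s, n, N)
  ss <- if (semantic && !is.null(cache)) {
    imax <- max(cache_pinfo(S, cache))
    counts <- tabulate(unlist(cache$prop[S], use.names = FALSE),
                       nbins = cache$nterms)
    vapply(NS, function(b) {
      ii <- cache$prop[[b]]
      if (is.null(ii) || !length(ii) || imax <= 0) 0
      else sum(cache$info[ii] * counts[ii]) / imax
    }, 0)
  } else if (semantic) {
    imax <- max(vapply(S, protein_information, 0, annotations, ic))
    counts <- term_counts(S, annotations)
    vapply(NS, function(b)
      ss_against_counts(annotations$propagated[[b]], counts, ic$info, imax),
      0)
  } else rep(0, length(NS))
  data.frame(gene = NS, cs = cs, ss = unname(ss),
             sv = combined_similarity(cs, unname(ss)),
             k = k, k_s = unname(k_s), n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

## neighbours of S, excluding S, in lexicographic order
neighbor_set <- function(network, S) {
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(network, S),
                             igraph::as_ids), use.names = FALSE))
  lex_sort(setdiff(nb, S))
}
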