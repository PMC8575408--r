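#' One-sided over-representation (enrichment) test
#'
#' Hypergeometric upper-tail probability of observing at least the measured
#' overlap when `|query|` genes are drawn from the background containing
#' `|reference|` successes — equivalent to a one-sided Fisher exact test on
#' the 2x2 table.
#'
#' @param query,reference,background character vectors; `query` and
#'   `reference` must be subsets of `background`.
#' @return an `enrichment_result`: list with `query_size`, `reference_size`,
#'   `overlap`, `background_size`, `p_value`.
#' @export
enrichment_test <- function(query, reference, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  query <- unique(query); reference <- unique(reference)
  if (!all(query %in% background) || !all(reference %in% background))
    stop("query and reference must be subsets of the background")
  ov <- length(intersect(query, reference))
  p <- stats::phyper(ov - 1, length(reference),
                     length(background) - length(reference),
                     length(query), lower.tail = FALSE)
  structure(list(query_size = length(query),
                 reference_size = length(reference),
                 overlap = ov,
                 background_size = length(background),
                 p_value = min(1, max(p, .Machine$double.xmin))),
            class = "enrichment_result")
}

#' Closeness ratio of a module
#'
#' The ratio of inner-links (both endpoints inside the module) to
#' external-links (exactly one endpoint inside).  A disease module is not a
#' locally dense community, so this ratio is typically well below 1, but it is
#' still significantly larger than for random node subsets of the same size.
#'
#' @param inner,external non-negative link counts; `external` must be
#'   positive.
#' @return `inner / external`.
#' @export
closeness_ratio <- function(inner, external) {
  if (external <= 0)
    stop("closeness undefined: module has no external links")
  inner / external
}

#' Closeness of a node set in a network
#'
#' Counts inner and external links of `module_nodes` and returns their ratio
#' (see [closeness_ratio()]).
#'
#' @param network igraph network.
#' @param module_nodes character vector of module members (subset of nodes).
#' @return list with `inner_links`, `external_links`, `closeness`.
#' @export
closeness <- function(network, module_nodes) {
  if (!all(module_nodes %in% igraph::V(network)$name))
    stop("module_nodes contains nodes absent from the network")
  el <- igraph::as_edgelist(network)
  inu <- el[, 1] %in% module_nodes
  inv <- el[, 2] %in% module_nodes
  inner <- sum(inu & inv)
  external <- sum(xor(inu, inv))
  list(inner_links = inner, external_links = external,
       closeness = closeness_ratio(inner, external))
}

#' Closeness significance against random node subsets
#'
#' Samples `n_samples` uniform random node subsets of the module's size
#' (subsets with zero external links are resampled), computes their closeness,
#' and tests whether the observed module closeness exceeds the null by a
#' one-sample Student t-test (one-sided).
#'
#' @param network igraph network.
#' @param module_nodes character vector of module members.
#' @param n_samples number of null subsets (default 100, minimum 30).
#' @param rng_seed integer seed.
#' @return list with the observed counts and `closeness`, `null_mean`,
#'   `t_statistic`, `p_value`, `n_samples`.
#' @export
closeness_null_test <- function(network, module_nodes, n_samples = 100,
                                rng_seed = 1) {
  stopifnot(n_samples >= 30)
  obs <- closeness(network, module_nodes)
  nodes <- igraph::V(network)$name
  set.seed(rng_seed)
  el <- igraph::as_edgelist(network)
  null <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    repeat {
      sub <- sample(nodes, length(unique(module_nodes)))
      inu <- el[, 1] %in% sub; inv <- el[, 2] %in% sub
      ext <- sum(xor(inu, inv))
      if (ext > 0) { null[i] <- sum(inu & inv) / ext; break }
    }
  }
  if (stats::sd(null) == 0)
    stop("degenerate null: zero variance across sampled subsets")
  ## observed greater than the null distribution <=> null values less than obs
  tt <- stats::t.test(null, mu = obs$closeness, alternative = "less")
  list(inner_links = obs$inner_links, external_links = obs$external_links,
       closeness = obs$closeness, null_mean = mean(null),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       n_samples = n_samples)
}

#' Recovery of deleted true edges against a degree-preserving random-edit null
#'
#' Given the additions an adjustment (or a whole run) made and the list of
#' true seed-incident edges a perturbation deleted, tests whether the
#' additions hit the deleted edges more often than random edits of the same
#' shape would.  Only seed-incident additions are compared (every deleted
#' edge has a seed endpoint, so recovery can only come from these).  The null
#' keeps each addition's seed endpoint and its edit count, and redraws the
#' other endpoint from the non-seed nodes not already adjacent to that seed,
#' with probability proportional to node degree (so the null respects the
#' degree structure instead of favouring low-degree nodes).
#'
#' @param network igraph network the additions were decided on (the perturbed
#'   network, before adjustment).
#' @param additions data frame of added pairs (`u`, `v`), e.g. the `add` rows
#'   of an edit log.
#' @param deleted data frame of deleted true pairs (`u`, `v`).
#' @param seeds character vector of seed proteins.
#' @param n_perm number of null redraws (default 500).
#' @param rng_seed integer seed.
#' @return list with `recovered`, `n_deleted`, `n_additions` (seed-incident),
#'   `null_mean`, `null` (the per-redraw overlaps, for pooling across
#'   fixtures), `p_value` (one-sided, recovery greater than null).
#' @export
edit_recovery_test <- function(network, additions, deleted, seeds,
                               n_perm = 500, rng_seed = 1) {
  seeds <- lex_sort(unique(seeds))
  del_keys <- unique(pair_key(deleted$u, deleted$v))
  ## orient seed-incident additions as (editor, seed)
  seed_side <- ifelse(additions$v %in% seeds, additions$v,
                      ifelse(additions$u %in% seeds, additions$u, NA))
  editor <- ifelse(additions$v %in% seeds, additions$u, additions$v)
  keep <- !is.na(seed_side) & !(editor %in% seeds)
  seed_side <- seed_side[keep]; editor <- editor[keep]
  obs <- sum(del_keys %in% unique(pair_key(editor, seed_side)))
  if (!length(seed_side))
    return(list(recovered = 0L, n_deleted = length(del_keys),
                n_additions = 0L, null_mean = 0,
                null = rep(0, n_perm), p_value = 1))
  nodes <- igraph::V(network)$name
  deg <- igraph::degree(network)
  pool0 <- setdiff(nodes, seeds)
  free <- lapply(unique(seed_side), function(s)
    setdiff(pool0, igraph::as_ids(igraph::neighbors(network, s))))
  names(free) <- unique(seed_side)
  set.seed(rng_seed)
  null <- vapply(seq_len(n_perm), function(i) {
    rx <- vapply(seed_side, function(s) {
      pool <- free[[s]]
      if (!length(pool)) NA_character_
      else pool[sample.int(length(pool), 1, prob = deg[pool] + 1)]
    }, "")
    ok <- !is.na(rx)
    sum(del_keys %in% unique(pair_key(rx[ok], seed_side[ok])))
  }, 0)
  list(recovered = obs, n_deleted = length(del_keys),
       n_additions = length(seed_side), null_mean = mean(null),
       null = null,
       p_value = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Seed-deletion robustness (recall experiment)
#'
#' Runs the full detection once with all seeds to obtain the reference
#' module, then repeatedly deletes a random fraction of the seeds, re-runs
#' detection, and measures the recall of the reference module.
#'
#' @param network igraph network.
#' @param seeds `gene_set` or character vector of seed proteins.
#' @param annotations,ic annotation map and information content.
#' @param deletion_fraction fraction of seeds deleted per repeat, in `[0, 1)`.
#' @param n_repeats number of repeats (default 30).
#' @param rng_seed integer seed.
#' @param reference optional character vector of reference-module nodes (the
#'   full-seed run is recomputed when `NULL`); lets a caller share one
#'   reference across several deletion fractions.
#' @param ... further arguments passed to [idmcss()] (signals, thresholds).
#' @return list with `mean_recall`, numeric `recalls` (one per repeat),
#'   `reference_module` (character vector of nodes).
#' @export
recall_experiment <- function(network, seeds, annotations, ic = NULL,
                              deletion_fraction, n_repeats = 30,
                              rng_seed = 1, reference = NULL, ...) {
  stopifnot(deletion_fraction >= 0, deletion_fraction < 1, n_repeats >= 1)
  members <- if (inherits(seeds, "gene_set")) seeds$members else
    as.character(seeds)
  members <- lex_sort(unique(members))
  if (is.null(ic)) ic <- compute_ic(annotations)
  ref <- reference %||%
    idmcss(network, members, annotations, ic, ...)$module$nodes
  n_del <- floor(deletion_fraction * length(members))
  if (n_del >= length(members)) stop("deletion would leave zero seeds")
  set.seed(rng_seed)
  recalls <- vapply(seq_len(n_repeats), function(i) {
    ## one permutation per repeat; deleting its head makes deletion sets
    ## nested across fractions run with the same seed (paired comparison)
    kept <- setdiff(members, sample(members)[seq_len(n_del)])
    mod <- idmcss(network, kept, annotations, ic, ...)$module$nodes
    length(intersect(mod, ref)) / length(ref)
  }, 0)
  list(mean_recall = mean(recalls), recalls = recalls,
       reference_module = ref)
}
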