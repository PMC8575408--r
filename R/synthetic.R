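#' Synthetic benchmark generator configuration
#'
#' Defaults describe a desk-scale planted-module interactome: one dense
#' module of 15 proteins inside a 400-node background, 10 of the module
#' members known as seeds, with 30% of the seeds' within-module links deleted
#' (emulating the interactome's missing interactions) and 2 decoy links per
#' seed injected (emulating spurious interactions), plus a 3-level / 3-way
#' toy ontology whose leaf subtrees act as module term pools.  The background
#' is large relative to the signal sets so that a single true accretion is
#' already significant at the default alpha, as in a genome-scale
#' interactome.
#'
#' @param n_nodes total node count.
#' @param module_sizes integer vector of planted module sizes.
#' @param p_in within-module edge probability.
#' @param p_out background / between-module edge probability.
#' @param n_seeds number of known disease proteins drawn from module 1.
#' @param fn_rate fraction of seed-incident within-module edges deleted.
#' @param fp_rate decoy seed-to-background edges injected per seed.
#' @param ontology_depth,branching shape of the toy term DAG.
#' @param terms_per_gene direct annotations drawn per gene.
#' @param coherence probability a module member draws each term from its
#'   module's pool (background genes always draw uniformly).
#' @param n_de_noise background genes added to the DE signal set.
#' @param rng_seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_nodes = 400, module_sizes = 15,
                             p_in = 0.6, p_out = 0.02, n_seeds = 10,
                             fn_rate = 0.3, fp_rate = 2,
                             ontology_depth = 4, branching = 4,
                             terms_per_gene = 5, coherence = 0.8,
                             n_de_noise = 2, rng_seed = 1) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            fn_rate >= 0, fn_rate < 1, fp_rate >= 0,
            coherence >= 0, coherence <= 1,
            sum(module_sizes) <= n_nodes,
            n_seeds <= module_sizes[1],
            ontology_depth >= 2, branching >= 2)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a planted-partition network
#'
#' Module members are wired with probability `p_in`, every other pair with
#' `p_out`.  Ground-truth membership is returned alongside so tests never
#' reverse-engineer it.
#'
#' @param config a [generator_config()].
#' @return list with `network` (igraph) and `membership` (named integer; 0 =
#'   background).
#' @export
generate_planted_network <- function(config) {
  set.seed(config$rng_seed)
  n <- config$n_nodes
  ids <- sprintf("g%03d", seq_len(n))
  membership <- stats::setNames(integer(n), ids)
  at <- 1L
  for (mi in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[mi]
    membership[at:(at + sz - 1)] <- mi
    at <- at + sz
  }
  pr <- utils::combn(n, 2)
  same <- membership[pr[1, ]] != 0 & membership[pr[1, ]] == membership[pr[2, ]]
  p <- ifelse(same, config$p_in, config$p_out)
  keep <- stats::runif(ncol(pr)) < p
  if (!any(keep)) stop("generator parameters produced an empty edge set")
  ## like an assembled interactome, the network carries interacting proteins
  ## only; membership still covers the whole gene universe
  net <- ppi_network(data.frame(u = ids[pr[1, keep]], v = ids[pr[2, keep]],
                                stringsAsFactors = FALSE))
  list(network = net, membership = membership)
}

#' Perturb a planted network with missing and spurious seed links
#'
#' Deletes `fn_rate` of the within-module edges incident to the seeds (never
#' disconnecting a seed completely — a seed's last edge is not deletable) and
#' injects exactly `fp_rate` decoy edges per seed towards random out-module
#' nodes not already adjacent.
#'
#' @param network igraph network.
#' @param membership ground-truth membership from
#'   [generate_planted_network()].
#' @param seeds character vector of seed nodes.
#' @param fn_rate,fp_rate perturbation rates (see [generator_config()]).
#' @param rng_seed integer seed.
#' @return list with `network`, `deleted` and `injected` (two-column
#'   data frames of node pairs).
#' @export
perturb_network <- function(network, membership, seeds, fn_rate, fp_rate,
                            rng_seed = 1) {
  set.seed(rng_seed)
  g <- network
  el <- igraph::as_edgelist(g)
  within <- membership[el[, 1]] != 0 &
    membership[el[, 1]] == membership[el[, 2]]
  seed_inc <- el[, 1] %in% seeds | el[, 2] %in% seeds
  cand <- which(within & seed_inc)
  n_del <- floor(fn_rate * length(cand))
  deleted <- data.frame(u = character(), v = character(),
                        stringsAsFactors = FALSE)
  if (n_del > 0) {
    ord <- sample(cand)                  # random deletion order
    for (i in ord) {
      if (nrow(deleted) >= n_del) break
      u <- el[i, 1]; v <- el[i, 2]
      du <- igraph::degree(g, u); dv <- igraph::degree(g, v)
      ## never strand a seed: keep a seed's last remaining edge
      if ((u %in% seeds && du <= 1) || (v %in% seeds && dv <= 1)) next
      g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
      deleted <- rbind(deleted, data.frame(u = u, v = v,
                                           stringsAsFactors = FALSE))
    }
  }
  injected <- data.frame(u = character(), v = character(),
                         stringsAsFactors = FALSE)
  out_nodes <- intersect(names(membership)[membership == 0],
                         igraph::V(g)$name)
  for (s in lex_sort(seeds)) {
    free <- setdiff(out_nodes, c(s, igraph::neighbors(g, s)$name))
    pick <- sample(free, min(fp_rate, length(free)))
    for (d in pick) {
      g <- igraph::add_edges(g, c(s, d))
      injected <- rbind(injected, data.frame(u = s, v = d,
                                             stringsAsFactors = FALSE))
    }
  }
  list(network = g, deleted = deleted, injected = injected)
}

#' Generate a toy ontology with module-coherent annotations
#'
#' Builds a balanced tree DAG of the configured depth and branching; each
#' planted module owns the leaf set under one depth-2 subtree (its "term
#' pool" — a small, specific slice of the term space, as a disease process is
#' within GO).  Module members draw each of their direct terms from the pool
#' with probability `coherence`, otherwise uniformly from all leaves;
#' background genes always draw uniformly.
#'
#' @param config a [generator_config()].
#' @param membership ground-truth membership.
#' @param rng_seed integer seed (defaults to the config seed).
#' @return list with `ontology` (`go_ontology`), `annotations`
#'   (`annotation_map`), `term_pools` (list: module index -> leaf terms).
#' @export
generate_ontology_and_annotations <- function(config, membership,
                                              rng_seed = config$rng_seed) {
  set.seed(rng_seed)
  depth <- config$ontology_depth; b <- config$branching
  ## balanced tree: levels 0..depth, level l has b^l terms
  parents <- list("T0" = character())
  level_ids <- list("T0")
  counter <- 0L
  for (l in seq_len(depth)) {
    ids <- character()
    for (par in level_ids[[l]]) {
      for (j in seq_len(b)) {
        counter <- counter + 1L
        id <- sprintf("T%04d", counter)
        parents[[id]] <- par
        ids <- c(ids, id)
      }
    }
    level_ids[[l + 1]] <- ids
  }
  terms <- names(parents)
  onto <- structure(list(
    terms = terms, parents = parents,
    ancestors = ancestor_closure(terms, parents),
    namespace = stats::setNames(rep("BP", length(terms)), terms),
    alt_id = character()), class = "go_ontology")
  leaves <- level_ids[[depth + 1]]
  ## module term pools: leaves under one subtree root each, two levels below
  ## the ontology root (or one level for a depth-2 ontology)
  pool_level <- min(2L, depth - 1L)
  subtree_roots <- level_ids[[pool_level + 1]]
  n_modules <- max(membership)
  if (n_modules > length(subtree_roots))
    stop("more modules than ontology subtrees; increase branching")
  pools <- lapply(seq_len(n_modules), function(mi) {
    r <- subtree_roots[mi]
    leaves[vapply(leaves, function(l) r %in% onto$ancestors[[l]], TRUE)]
  })
  direct <- list()
  for (gname in lex_sort(names(membership))) {
    mi <- membership[[gname]]
    picks <- character(config$terms_per_gene)
    for (j in seq_len(config$terms_per_gene)) {
      from_pool <- mi != 0 && stats::runif(1) < config$coherence
      picks[j] <- if (from_pool) sample(pools[[mi]], 1) else sample(leaves, 1)
    }
    direct[[gname]] <- unique(picks)
  }
  list(ontology = onto, annotations = annotation_map(direct, onto),
       term_pools = pools)
}

#' Generate planted signal gene sets
#'
#' The differential-expression set is module 1 plus `n_de_noise` random
#' background genes; each module's pathway set is the projection of its term
#' pool to genes (every gene directly annotated to a pool term).
#'
#' @param config a [generator_config()].
#' @param membership ground-truth membership.
#' @param annotations the generated `annotation_map`.
#' @param term_pools module term pools from
#'   [generate_ontology_and_annotations()].
#' @param rng_seed integer seed (defaults to the config seed).
#' @return list with `de_genes` (a `gene_set`) and `pathways` (list of
#'   `gene_set`s).
#' @export
generate_signal_sets <- function(config, membership, annotations, term_pools,
                                 rng_seed = config$rng_seed) {
  set.seed(rng_seed)
  mod1 <- names(membership)[membership == 1]
  bg <- names(membership)[membership == 0]
  noise <- if (config$n_de_noise > 0)
    sample(bg, min(config$n_de_noise, length(bg))) else character()
  de <- gene_set("de_planted", lex_sort(c(mod1, noise)))
  pathways <- lapply(seq_along(term_pools), function(mi) {
    pool <- term_pools[[mi]]
    members <- names(annotations$direct)[vapply(annotations$direct,
      function(ts) any(ts %in% pool), TRUE)]
    gene_set(sprintf("pathway_m%d", mi), lex_sort(members))
  })
  list(de_genes = de, pathways = pathways)
}

#' Generate a complete synthetic fixture
#'
#' Runs the whole generator — planted network, seed choice, perturbation,
#' ontology + annotations, signal sets — and optionally writes every artefact
#' in the external formats the readers consume (edge TSV, OBO, gene-term TSV,
#' seed list, DE list, GMT, ground-truth TSV), so I/O is exercised end to
#' end.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory; when given, files are written.
#' @return list with `network` (perturbed), `clean_network`, `membership`,
#'   `seeds` (`gene_set`), `truth` (module-1 members), `deleted`, `injected`,
#'   `ontology`, `annotations`, `term_pools`, `de_genes`, `pathways`,
#'   and `dir` when written.
#' @export
simulate_fixture <- function(config = generator_config(), dir = NULL) {
  gen <- generate_planted_network(config)
  set.seed(config$rng_seed + 1L)
  truth <- names(gen$membership)[gen$membership == 1]
  seeds <- gene_set("seeds", lex_sort(sample(truth, config$n_seeds)))
  pert <- perturb_network(gen$network, gen$membership, seeds$members,
                          config$fn_rate, config$fp_rate,
                          rng_seed = config$rng_seed + 2L)
  oa <- generate_ontology_and_annotations(config, gen$membership,
                                          rng_seed = config$rng_seed + 3L)
  sig <- generate_signal_sets(config, gen$membership, oa$annotations,
                              oa$term_pools, rng_seed = config$rng_seed + 4L)
  fx <- list(network = pert$network, clean_network = gen$network,
             membership = gen$membership, seeds = seeds,
             truth = lex_sort(truth),
             deleted = pert$deleted, injected = pert$injected,
             ontology = oa$ontology, annotations = oa$annotations,
             term_pools = oa$term_pools,
             de_genes = sig$de_genes, pathways = sig$pathways)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fixture_files(fx, dir)
    fx$dir <- dir
  }
  fx
}

write_fixture_files <- function(fx, dir) {
  el <- igraph::as_edgelist(fx$network)
  sw <- el[, 1] > el[, 2]
  el[sw, ] <- el[sw, c(2, 1)]
  el <- el[order(el[, 1], el[, 2], method = "radix"), , drop = FALSE]
  writeLines(paste(el[, 1], el[, 2], sep = "\t"),
             file.path(dir, "network.tsv"))
  writeLines(fx$seeds$members, file.path(dir, "seeds.txt"))
  writeLines(fx$de_genes$members, file.path(dir, "de_genes.txt"))
  writeLines(vapply(fx$pathways, function(s)
    paste(c(s$name, "synthetic", s$members), collapse = "\t"), ""),
    file.path(dir, "pathways.gmt"))
  ## OBO
  onto <- fx$ontology
  stanzas <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    ps <- onto$parents[[t]]
    stanzas <- c(stanzas, "[Term]", paste0("id: ", t),
                 paste0("name: synthetic term ", t),
                 "namespace: biological_process",
                 if (length(ps)) paste0("is_a: ", ps), "")
  }
  writeLines(stanzas, file.path(dir, "ontology.obo"))
  ## gene-term TSV (direct annotations)
  dm <- fx$annotations$direct
  writeLines(unlist(lapply(lex_sort(names(dm)), function(g)
    paste(g, dm[[g]], sep = "\t"))), file.path(dir, "annotations.tsv"))
  truth_df <- data.frame(node = lex_sort(names(fx$membership)),
                         module = fx$membership[lex_sort(names(fx$membership))],
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
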