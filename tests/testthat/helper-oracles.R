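# Independent oracles: exhaustive enumeration and literal formula
# transcriptions, deliberately kept free of the package's computational
# shortcuts (log-space tails, count factorisation).

# Upper tail P(X >= k_s) of the hypergeometric by enumerating every draw of
# k nodes from N, where the first n nodes are the disease set.  N <= 12.
enum_hyper_tail <- function(N, n, k, k_s) {
  if (k == 0) return(if (k_s <= 0) 1 else 0)
  draws <- utils::combn(N, k)
  overlap <- colSums(draws <= n)
  mean(overlap >= k_s)
}

# Literal double sum of the semantic score: over members of S, over the
# annotation intersection, summing term informations.
ss_bruteforce <- function(gene, S, annotations, ic) {
  A_b <- annotations$propagated[[gene]]
  if (is.null(A_b)) return(0)
  pinfo <- function(g) {
    ts <- annotations$propagated[[g]]
    if (is.null(ts)) return(0)
    tot <- 0
    for (t in ts) if (t %in% names(ic$info)) tot <- tot + ic$info[[t]]
    tot
  }
  imax <- max(sapply(S, pinfo))
  if (imax <= 0) return(0)
  total <- 0
  for (p in S) {
    A_p <- annotations$propagated[[p]]
    if (is.null(A_p)) next
    for (t in intersect(A_b, A_p))
      if (t %in% names(ic$info)) total <- total + ic$info[[t]]
  }
  total / imax
}

# Over-representation p-value by enumerating every possible query draw.
enum_enrichment_p <- function(query, reference, background) {
  q <- length(query)
  obs <- length(intersect(query, reference))
  draws <- utils::combn(length(background), q)
  hits <- colSums(matrix(background[draws] %in% reference, nrow = q))
  mean(hits >= obs)
}

# Small two-level ontology used across unit tests: root with two branches,
# each with two leaves.
toy_ontology <- function() {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: T0", "name: root", "namespace: biological_process", "",
           "[Term]", "id: T1", "name: branch a", "is_a: T0 ! root", "",
           "[Term]", "id: T2", "name: branch b", "is_a: T0 ! root", "",
           "[Term]", "id: T11", "name: leaf a1", "is_a: T1", "",
           "[Term]", "id: T12", "name: leaf a2", "is_a: T1", "",
           "[Term]", "id: T21", "name: leaf b1", "is_a: T2", "",
           "[Term]", "id: T22", "name: leaf b2", "relationship: part_of T2", "")
  path <- tempfile(fileext = ".obo")
  writeLines(obo, path)
  read_obo(path)
}

# Deterministic toy corpus on the toy ontology.
toy_corpus <- function() {
  onto <- toy_ontology()
  direct <- list(g1 = c("T11", "T12"), g2 = c("T11", "T21"),
                 g3 = c("T21", "T22"), g4 = "T0")
  ann <- annotation_map(direct, onto)
  list(ontology = onto, annotations = ann, ic = compute_ic(ann))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small labelled graph from an edge string like "a-b, b-c".
graph_from_spec <- function(spec, nodes = NULL) {
  pairs <- strsplit(trimws(strsplit(spec, ",")[[1]]), "-", fixed = TRUE)
  ppi_network(data.frame(u = vapply(pairs, `[[`, "", 1),
                         v = vapply(pairs, `[[`, "", 2),
                         stringsAsFactors = FALSE), nodes = nodes)
}

# Canonical unordered pair keys for edge-set comparisons.
edge_keys <- function(df) {
  if (!nrow(df)) return(character())
  paste(pmin(df[[1]], df[[2]]), pmax(df[[1]], df[[2]]))
}

# A small planted fixture shared by several slower tests.
small_fixture_config <- function(rng_seed = 1, ...) {
  over <- list(...)
  base <- list(n_nodes = 150, module_sizes = 10, n_seeds = 6,
               n_de_noise = 1, rng_seed = rng_seed)
  base[names(over)] <- over
  do.call(generator_config, base)
}
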