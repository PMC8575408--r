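test_that("neighbour classification follows the strong cut-off and NS mean", {
  sc <- function(genes, cs) data.frame(gene = genes, cs = cs,
                                       stringsAsFactors = FALSE)
  ## single neighbour at cs = 1: strong, not weak (not strictly below mean)
  cls <- classify_neighbors(sc("b", 1.0))
  expect_equal(cls$strong, "b"); expect_length(cls$weak, 0)
  ## {0.995, 0.5}: first strong, second weak (mean 0.7475)
  cls2 <- classify_neighbors(sc(c("a", "b"), c(0.995, 0.5)))
  expect_equal(cls2$strong, "a"); expect_equal(cls2$weak, "b")
  ## all equal: nobody strictly below the mean
  cls3 <- classify_neighbors(sc(c("a", "b"), c(0.4, 0.4)))
  expect_length(cls3$weak, 0)
  expect_error(classify_neighbors(sc(character(), numeric())))
})

test_that("edit decisions use strict inequalities around the phi means", {
  phi1 <- idmcss:::edit_threshold(c(0.68, 0.79))
  expect_equal(phi1, 0.735)
  expect_true(idmcss:::link_addition_decision(0.83, phi1))
  expect_false(idmcss:::link_addition_decision(phi1, phi1))  # boundary
  phi2 <- idmcss:::edit_threshold(c(0.35, 0.28))
  expect_equal(phi2, 0.315)
  expect_true(idmcss:::link_removal_decision(0.14, phi2))
  expect_false(idmcss:::link_removal_decision(phi2, phi2))   # boundary
})

## A corpus engineered so pairwise similarities are controllable:
## genes share leaf terms with known information content.
adjustment_fixture <- function() {
  tc <- toy_corpus()
  ## p shares T11 (I=ln2) with s1 and s2, nothing informative with s3
  direct <- list(s1 = c("T11", "T12"), s2 = c("T11", "T21"),
                 s3 = c("T22"), p = c("T11"), w = c("T22"))
  ann <- annotation_map(direct, tc$ontology)
  list(ann = ann, ic = compute_ic(ann))
}

test_that("adding-link operator adds exactly the above-threshold seed pairs", {
  fx <- adjustment_fixture()
  S <- c("s1", "s2", "s3")
  ## p connected to s1 and s2; candidate pair is (p, s3)
  net <- graph_from_spec("p-s1, p-s2, s1-s2, s2-s3")
  added <- add_links(net, "p", S, fx$ann, fx$ic)
  phi1 <- attr(added, "phi1")
  ss_cand <- semantic_similarity("p", "s3", fx$ann, fx$ic)
  expect_equal(phi1, mean(c(semantic_similarity("p", "s1", fx$ann, fx$ic),
                            semantic_similarity("p", "s2", fx$ann, fx$ic))))
  if (ss_cand > phi1) {
    expect_equal(edge_keys(added), "p s3")
  } else {
    expect_equal(nrow(added), 0)
  }
  ## strong node already connected to all of S: nothing to add
  net2 <- graph_from_spec("p-s1, p-s2, p-s3, s1-s2")
  expect_equal(nrow(add_links(net2, "p", S, fx$ann, fx$ic)), 0)
})

test_that("removing-link operator needs a non-connected reference group", {
  fx <- adjustment_fixture()
  S <- c("s1", "s2", "s3")
  ## w connected to every member: S1'' empty, removal skipped
  net_all <- graph_from_spec("w-s1, w-s2, w-s3")
  expect_equal(nrow(remove_links(net_all, "w", S, fx$ann, fx$ic)), 0)
  ## w connected only to s1; similarity to s1 is 0, to s3 positive -> removed
  net <- graph_from_spec("w-s1, s1-s2, s2-s3")
  removed <- remove_links(net, "w", S, fx$ann, fx$ic)
  phi2 <- attr(removed, "phi2")
  expect_equal(phi2,
               mean(c(semantic_similarity("w", "s2", fx$ann, fx$ic),
                      semantic_similarity("w", "s3", fx$ann, fx$ic))))
  expect_equal(edge_keys(removed), "s1 w")
})

test_that("network adjustment is local, node-preserving and snapshot-based", {
  fx <- simulate_fixture(small_fixture_config(rng_seed = 3))
  ic <- compute_ic(fx$annotations)
  S <- fx$seeds$members
  adj <- adjust_network(fx$network, S, NULL, fx$annotations, ic)
  ## node set unchanged
  expect_setequal(igraph::V(adj$network)$name, igraph::V(fx$network)$name)
  ## every edit touches exactly one member of S
  for (df in list(adj$plan$additions, adj$plan$removals)) {
    if (!nrow(df)) next
    n_in_S <- (df$u %in% S) + (df$v %in% S)
    expect_true(all(n_in_S == 1))
  }
  ## additions were non-edges, removals were edges of the snapshot
  if (nrow(adj$plan$additions))
    expect_true(all(igraph::get_edge_ids(
      fx$network, as.vector(rbind(adj$plan$additions$u,
                                  adj$plan$additions$v))) == 0))
  if (nrow(adj$plan$removals))
    expect_true(all(igraph::get_edge_ids(
      fx$network, as.vector(rbind(adj$plan$removals$u,
                                  adj$plan$removals$v))) > 0))
  ## no overlap between the two edit sets
  expect_length(intersect(edge_keys(adj$plan$additions),
                          edge_keys(adj$plan$removals)), 0)
  ## edge-count bookkeeping
  expect_equal(igraph::ecount(adj$network),
               igraph::ecount(fx$network) + nrow(adj$plan$additions) -
                 nrow(adj$plan$removals))
})

test_that("adjustment with no qualifying neighbours is the identity and
           a converged adjustment is a fixed point", {
  tc <- toy_corpus()
  ## isolated pair: S has no external neighbours
  g <- graph_from_spec("g1-g2", nodes = c("g3", "g4"))
  adj <- adjust_network(g, c("g1", "g2"), NULL, tc$annotations, tc$ic)
  expect_equal(igraph::ecount(adj$network), igraph::ecount(g))
  expect_length(adj$plan$strong, 0)

  ## iterating adjustment with unchanged S converges, and once converged a
  ## further application is the identity
  fx <- simulate_fixture(small_fixture_config(rng_seed = 5))
  ic <- compute_ic(fx$annotations)
  S <- fx$seeds$members
  net <- fx$network
  converged <- FALSE
  for (i in 1:15) {
    a <- adjust_network(net, S, NULL, fx$annotations, ic)
    if (!nrow(a$plan$additions) && !nrow(a$plan$removals)) {
      converged <- TRUE
      break
    }
    net <- a$network
  }
  expect_true(converged)
  a_again <- adjust_network(net, S, NULL, fx$annotations, ic)
  expect_equal(igraph::ecount(a_again$network), igraph::ecount(net))
  expect_equal(nrow(a_again$plan$additions) + nrow(a_again$plan$removals), 0)
})
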