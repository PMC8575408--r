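test_that("planted-partition generation honours its extreme parameters", {
  cfg <- generator_config(n_nodes = 12, module_sizes = 4, n_seeds = 2,
                          p_in = 1, p_out = 0, rng_seed = 1)
  gen <- generate_planted_network(cfg)
  mod <- names(gen$membership)[gen$membership == 1]
  sub <- igraph::induced_subgraph(gen$network, mod)
  expect_equal(igraph::ecount(sub), choose(4, 2))        # 4-clique
  expect_equal(igraph::ecount(gen$network), choose(4, 2)) # nothing else
  ## fixed seed reproducibility
  gen2 <- generate_planted_network(cfg)
  expect_identical(igraph::as_edgelist(gen$network),
                   igraph::as_edgelist(gen2$network))
})

test_that("within-module edge counts follow the binomial expectation", {
  m <- 10; p_in <- 0.6
  counts <- vapply(1:100, function(s) {
    cfg <- generator_config(n_nodes = 30, module_sizes = m, n_seeds = 3,
                            p_in = p_in, p_out = 0, rng_seed = s)
    gen <- generate_planted_network(cfg)
    mod <- intersect(names(gen$membership)[gen$membership == 1],
                     igraph::V(gen$network)$name)
    igraph::ecount(igraph::induced_subgraph(gen$network, mod))
  }, 0)
  n_pairs <- choose(m, 2)
  expect_lt(abs(mean(counts) - p_in * n_pairs),
            3 * sqrt(n_pairs * p_in * (1 - p_in) / 100))
})

test_that("perturbation deletes and injects exactly as contracted", {
  fx0 <- generate_planted_network(small_fixture_config(rng_seed = 3))
  seeds <- names(fx0$membership)[fx0$membership == 1][1:5]
  ## identity at zero rates
  p0 <- perturb_network(fx0$network, fx0$membership, seeds, 0, 0, rng_seed = 1)
  expect_equal(igraph::ecount(p0$network), igraph::ecount(fx0$network))
  expect_equal(nrow(p0$deleted) + nrow(p0$injected), 0)
  ## injection count is exact; deletions never strand a seed
  p1 <- perturb_network(fx0$network, fx0$membership, seeds, 0.4, 2,
                        rng_seed = 1)
  expect_equal(nrow(p1$injected), 2 * length(seeds))
  expect_true(all(igraph::degree(p1$network, seeds) >= 1))
  ## every deleted pair was a within-module seed-incident edge
  for (i in seq_len(nrow(p1$deleted))) {
    u <- p1$deleted$u[i]; v <- p1$deleted$v[i]
    expect_true(u %in% seeds || v %in% seeds)
    expect_equal(fx0$membership[[u]], fx0$membership[[v]])
  }
  ## injected decoys run from a seed to a background node
  expect_true(all(p1$injected$u %in% seeds))
  expect_true(all(fx0$membership[p1$injected$v] == 0))
})

test_that("annotation coherence controls semantic separation of the module", {
  base <- small_fixture_config(rng_seed = 11)
  mem <- generate_planted_network(base)$membership
  mod <- names(mem)[mem == 1]
  bgg <- names(mem)[mem == 0]
  pair_mean <- function(oa) {
    ic <- compute_ic(oa$annotations)
    set.seed(1)
    within <- mean(apply(expand.grid(mod[1:5], mod[6:10]), 1, function(r)
      semantic_similarity(r[1], r[2], oa$annotations, ic)))
    between <- mean(apply(cbind(mod[1:5], sample(bgg, 5)), 1, function(r)
      semantic_similarity(r[1], r[2], oa$annotations, ic)))
    c(within = within, between = between)
  }
  cfg1 <- small_fixture_config(rng_seed = 11, coherence = 1)
  m1 <- pair_mean(generate_ontology_and_annotations(cfg1, mem))
  expect_gt(m1[["within"]], m1[["between"]])
  ## reproducibility under a fixed seed
  oa_a <- generate_ontology_and_annotations(cfg1, mem)
  oa_b <- generate_ontology_and_annotations(cfg1, mem)
  expect_identical(oa_a$annotations$direct, oa_b$annotations$direct)
})

test_that("incoherent annotations show no module separation (permutation)", {
  cfg <- small_fixture_config(rng_seed = 12, coherence = 0)
  mem <- generate_planted_network(cfg)$membership
  oa <- generate_ontology_and_annotations(cfg, mem)
  ic <- compute_ic(oa$annotations)
  mod <- names(mem)[mem == 1]
  bgg <- names(mem)[mem == 0]
  set.seed(2)
  within <- apply(expand.grid(mod[1:5], mod[6:10]), 1, function(r)
    semantic_similarity(r[1], r[2], oa$annotations, ic))
  between <- apply(cbind(mod[1:5], sample(bgg, 25, replace = TRUE)), 1,
                   function(r)
    semantic_similarity(r[1], r[2], oa$annotations, ic))
  obs <- mean(within) - mean(between)
  pooled <- c(within, between)
  perm <- replicate(400, {
    idx <- sample(length(pooled), length(within))
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  p <- mean(perm >= obs)
  expect_gt(p, 0.05)
})

test_that("signal sets mirror the planted module and its term pools", {
  cfg <- small_fixture_config(rng_seed = 13, n_de_noise = 0)
  fx <- simulate_fixture(cfg)
  ## zero noise: the DE set is exactly the module
  expect_setequal(fx$de_genes$members, fx$truth)
  ## pathway projection covers every coherent module member
  pool_genes <- fx$pathways[[1]]$members
  direct <- fx$annotations$direct
  pool <- fx$term_pools[[1]]
  for (g in names(direct))
    expect_equal(g %in% pool_genes, any(direct[[g]] %in% pool))
})

test_that("written fixture files re-read to the in-memory objects", {
  dir <- tempfile("fx")
  fx <- simulate_fixture(small_fixture_config(rng_seed = 14), dir = dir)
  net <- read_network(file.path(dir, "network.tsv"))
  expect_equal(igraph::ecount(net), igraph::ecount(fx$network))
  expect_setequal(igraph::V(net)$name, igraph::V(fx$network)$name)
  onto <- read_obo(file.path(dir, "ontology.obo"))
  expect_setequal(onto$terms, fx$ontology$terms)
  ann <- read_annotations(file.path(dir, "annotations.tsv"), onto, "tsv")
  expect_identical(ann$propagated, fx$annotations$propagated)
  seeds <- read_gene_set(file.path(dir, "seeds.txt"))
  expect_setequal(seeds$members, fx$seeds$members)
  gmt <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_setequal(gmt[[1]]$members, fx$pathways[[1]]$members)
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_setequal(truth$node[truth$module == 1], fx$truth)
})
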