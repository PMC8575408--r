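test_that("candidate selection is argmax over sv with lexicographic ties", {
  sc <- function(genes, sv) data.frame(gene = genes, sv = sv,
                                       stringsAsFactors = FALSE)
  expect_equal(select_candidate(sc("x", 0.2)), "x")
  expect_equal(select_candidate(sc(c("b", "a", "c"), c(0.9, 0.9, 0.1))), "a")
  expect_null(select_candidate(sc(character(), numeric())))
})

test_that("stopping rule never fires on empty C and fires on lost enrichment", {
  cfg <- stopping_config("de_genes", alpha = 0.05)
  bg <- sprintf("g%02d", 1:40)
  sets <- list(de_genes = list(gene_set("de", bg[1:4])))
  expect_false(check_stopping(character(), sets, bg, cfg)$stop)
  ## C equals the reference: maximal overlap, strongly enriched
  chk <- check_stopping(bg[1:4], sets, bg, cfg)
  expect_false(chk$stop)
  expect_lt(chk$p[["de_genes"]], 1e-4)
  ## C disjoint from the reference: p = 1, stop
  chk2 <- check_stopping(bg[11:14], sets, bg, cfg)
  expect_true(chk2$stop)
  expect_equal(chk2$p[["de_genes"]], 1)
  expect_error(check_stopping(bg, sets, bg[1:3], cfg))
})

test_that("stopping flips at the iteration found by stepwise oracle", {
  ## planted drift: candidates enter the DE set first, then leave it
  bg <- sprintf("g%02d", 1:60)
  de <- bg[1:3]
  order_in <- c(de, bg[10:20])
  cfg <- stopping_config("de_genes", alpha = 0.05)
  sets <- list(de_genes = list(gene_set("de", de)))
  ## oracle: first c with P(X >= overlap) >= alpha by direct phyper
  oracle_stop <- NA
  for (c_len in seq_along(order_in)) {
    q <- order_in[seq_len(c_len)]
    ov <- length(intersect(q, de))
    p <- phyper(ov - 1, length(de), length(bg) - length(de), c_len,
                lower.tail = FALSE)
    if (p >= 0.05) { oracle_stop <- c_len; break }
  }
  fired <- NA
  for (c_len in seq_along(order_in)) {
    if (check_stopping(order_in[seq_len(c_len)], sets, bg, cfg)$stop) {
      fired <- c_len; break
    }
  }
  expect_equal(fired, oracle_stop)
})

test_that("module extraction picks the component with most disease proteins", {
  g <- graph_from_spec("a-b, b-c, c-a, c-d, x-y")
  ## connected G_s: the whole induced graph is the module
  m1 <- extract_module(g, c("a", "b", "c"))
  expect_setequal(m1$nodes, c("a", "b", "c"))
  expect_equal(m1$components_considered, 1)
  ## two components, sizes 4 and 2
  m2 <- extract_module(g, c("a", "b", "c", "d", "x", "y"))
  expect_setequal(m2$nodes, c("a", "b", "c", "d"))
  ## equal node counts: more edges wins
  g3 <- graph_from_spec("a-b, b-c, c-a, x-y, y-z")
  m3 <- extract_module(g3, c("a", "b", "c", "x", "y", "z"))
  expect_setequal(m3$nodes, c("a", "b", "c"))     # 3 edges beat 2
  ## fully tied: smallest lexicographic label wins
  g4 <- graph_from_spec("a-b, x-y")
  m4 <- extract_module(g4, c("a", "b", "x", "y"))
  expect_setequal(m4$nodes, c("a", "b"))
})

test_that("expansion accretes one protein per iteration and never retracts", {
  fx <- simulate_fixture(generator_config(rng_seed = 2))
  ic <- compute_ic(fx$annotations)
  fit <- idmcss(fx$network, fx$seeds, fx$annotations, ic,
                stopping = stopping_config(max_iterations = 12))
  expect_equal(fit$iterations, 12)
  expect_length(fit$C, 12)
  expect_setequal(fit$S, union(fit$S0, fit$C))
  expect_equal(nrow(fit$trace), 12)
  ## trace order is the accretion order; S grows monotonically by prefix
  for (k in seq_len(12))
    expect_true(all(fit$trace$accreted_gene[seq_len(k)] %in% fit$S))
  ## the module is a connected subgraph of the final adjusted network
  sub <- igraph::induced_subgraph(fit$network, fit$module$nodes)
  expect_true(igraph::is_connected(sub))
  expect_true(all(edge_keys(fit$module$edges) %in%
                  edge_keys(as.data.frame(igraph::as_edgelist(fit$network)))))
})

test_that("max_iterations = 0 returns the seed component untouched", {
  fx <- simulate_fixture(small_fixture_config(rng_seed = 9))
  ic <- compute_ic(fx$annotations)
  fit <- idmcss(fx$network, fx$seeds, fx$annotations, ic,
                stopping = stopping_config(max_iterations = 0))
  expect_equal(fit$iterations, 0)
  expect_length(fit$C, 0)
  expect_setequal(fit$S, fx$seeds$members)
  expect_identical(igraph::ecount(fit$network), igraph::ecount(fx$network))
})

test_that("seeds absent from the network are dropped with a warning", {
  tc <- toy_corpus()
  g <- graph_from_spec("g1-g2, g2-g3")
  expect_warning(
    fit <- idmcss(g, c("g1", "ghost"), tc$annotations, tc$ic,
                  stopping = stopping_config(max_iterations = 0)),
    "ghost")
  expect_equal(fit$S0, "g1")
  expect_error(suppressWarnings(
    idmcss(g, "ghost", tc$annotations, tc$ic)), "no seed")
})

test_that("identical inputs give identical fits and candidate order matches
           a pure hypergeometric greedy when semantics are off", {
  fx <- simulate_fixture(small_fixture_config(rng_seed = 4))
  ic <- compute_ic(fx$annotations)
  cfg <- stopping_config(max_iterations = 8)
  f1 <- idmcss(fx$network, fx$seeds, fx$annotations, ic, stopping = cfg,
               semantic = FALSE, enable_add = FALSE, enable_remove = FALSE)
  f2 <- idmcss(fx$network, fx$seeds, fx$annotations, ic, stopping = cfg,
               semantic = FALSE, enable_add = FALSE, enable_remove = FALSE)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$module$nodes, f2$module$nodes)
  ## oracle: greedy expansion ranked by phyper upper tail alone
  S <- fx$seeds$members
  g <- fx$network
  N <- igraph::vcount(g)
  picks <- character(8)
  for (i in 1:8) {
    NS <- setdiff(unique(unlist(lapply(
      igraph::adjacent_vertices(g, S), igraph::as_ids))), S)
    NS <- sort(NS, method = "radix")
    cs <- vapply(NS, function(b) {
      k <- unname(igraph::degree(g, b))
      ks <- sum(igraph::as_ids(igraph::neighbors(g, b)) %in% S)
      phyper(ks - 1, length(S), N - length(S), k)
    }, 0)
    best <- NS[cs == max(cs)][1]
    picks[i] <- best
    S <- sort(c(S, best), method = "radix")
  }
  expect_identical(f1$trace$accreted_gene, picks)
})
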