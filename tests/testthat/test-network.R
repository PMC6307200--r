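string_df <- function(a, b, score, experimental = 1, database = 0) {
  data.frame(protein1 = a, protein2 = b, combined_score = score,
             experimental = experimental, database = database)
}

test_that("per-source filters and merging behave as specified", {
  edges <- list(
    string = string_df(c("A", "B", "C"), c("X", "X", "X"),
                       c(350, 401, 900)),
    biogrid = data.frame(gene_a = c("D", "E", "B"),
                         gene_b = c("X", "X", "X"),
                         evidence = c("physical", "genetic", "physical")),
    bioplex = data.frame(gene_a = "F", gene_b = "X"))
  g <- build_ppi(edges)
  nm <- igraph::V(g)$name
  expect_false("A" %in% nm)  # score 350 is not above 400
  expect_false("E" %in% nm)  # genetic evidence excluded
  expect_true(all(c("B", "C", "D", "F", "X") %in% nm))
  # same pair in two sources collapses to one edge with merged sources
  eid <- igraph::get_edge_ids(g, c("B", "X"))
  expect_equal(igraph::E(g)$sources[eid], "biogrid,string")
  # score exactly 401 passes, strictly-above rule
  expect_true(igraph::are_adjacent(g, "B", "X"))
  # blacklist removes nodes and their edges
  g2 <- build_ppi(edges, node_blacklist = "C")
  expect_false("C" %in% igraph::V(g2)$name)
  expect_error(build_ppi(list(string = data.frame(x = 1))), "layout")
})

test_that("build_ppi is idempotent on its own exported edge list", {
  co <- small_cohort()
  g <- build_ppi(co$ppi, node_blacklist = co$truth$ubiquitin_nodes)
  el <- igraph::as_data_frame(g)
  g2 <- build_ppi(list(bioplex = data.frame(gene_a = el$from,
                                            gene_b = el$to)))
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
})

test_that("ADAR neighbourhood separates direct from 2-hop nodes", {
  g <- igraph::graph_from_literal(ADAR - X, ADARB1 - Y, Y - W, X - V,
                                  V - U, Q - R)
  nb <- adar_neighborhood(g)
  expect_setequal(nb$direct, c("X", "Y"))
  expect_setequal(nb$connected, c("X", "Y", "W", "V"))
  expect_equal(count_connected(c("W", "U", "Q", "nope"), nb), 1)
  expect_equal(count_connected(character(0), nb), 0)
  expect_error(adar_neighborhood(igraph::graph_from_literal(A - B)),
               "seed")
})

test_that("neighbourhood matches a brute-force BFS depth-2 oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 25
    adj <- matrix(runif(n * n) < 0.08, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    nm <- c("ADAR", paste0("n", 2:n))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- nm
    nb <- adar_neighborhood(g, "ADAR")
    d1 <- nm[adj[1, ]]
    d2 <- unique(nm[Reduce(`|`, lapply(which(adj[1, ]), function(j)
      adj[j, ]), rep(FALSE, n))])
    expect_setequal(nb$direct, d1)
    expect_setequal(nb$connected, setdiff(union(d1, d2), "ADAR"))
  }
})

test_that("empirical p uses the +1 correction and matches enumeration", {
  g <- igraph::graph_from_literal(ADAR - a, ADAR - b, c - a, d - e)
  nb <- adar_neighborhood(g, "ADAR")   # connected: a, b, c
  bg <- c("a", "b", "c", "d", "e")
  # exhaustive truth over all C(5,2)=10 subsets for observed = 2
  subs <- combn(bg, 2)
  true_frac <- mean(colSums(matrix(subs %in% nb$connected, 2)) >= 2)
  pe <- permutation_enrichment(connected = nb$connected, background = bg,
                               n_pick = 2, observed = 2, n_draws = 4000,
                               seed = 1)
  expect_equal(pe$p, true_frac, tolerance = 0.05)
  expect_equal(pe$p, (pe$n_ge_observed + 1) / (pe$n_draws + 1))
  # observed = 0 gives p = 1 exactly
  p0 <- permutation_enrichment(connected = nb$connected, background = bg,
                               n_pick = 2, observed = 0, n_draws = 200,
                               seed = 1)
  expect_equal(p0$p, 1)
  expect_error(permutation_enrichment(connected = "a", background = bg,
                                      n_pick = 2, observed = 3), "exceeds")
})

test_that("empirical p is non-increasing in the observed count", {
  co <- small_cohort()
  g <- build_ppi(co$ppi, node_blacklist = co$truth$ubiquitin_nodes)
  nb <- adar_neighborhood(g)
  bg <- setdiff(igraph::V(g)$name, adar_seed_ids())
  ps <- vapply(c(0, 5, 10, 20, 40), function(obs)
    permutation_enrichment(connected = nb$connected, background = bg,
                           n_pick = 40, observed = obs, n_draws = 500,
                           seed = 7)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("degree and betweenness match closed forms and brute force", {
  path <- igraph::graph_from_literal(A - B, B - C)
  ns <- node_statistics(path)
  expect_equal(ns$betweenness[ns$node == "B"], 1)
  expect_equal(ns$degree[ns$node == "B"], 2)
  star <- igraph::graph_from_literal(H - L1, H - L2, H - L3, H - L4)
  ns2 <- node_statistics(star)
  expect_equal(ns2$betweenness[ns2$node == "H"], 1)
  expect_equal(node_statistics(igraph::graph_from_literal(A - B))$
                 betweenness, c(0, 0))
  # 12-node random graph against an all-pairs shortest-path oracle
  set.seed(17)
  n <- 12
  adj <- matrix(runif(n * n) < 0.25, n)
  adj <- adj | t(adj); diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("v", 1:n)
  btw <- brute_betweenness(adj)
  ns3 <- node_statistics(g)
  expect_equal(ns3$betweenness, btw, tolerance = 1e-12)
  expect_equal(ns3$degree, rowSums(adj))
})

test_that("reconstructed subnetwork composition adds up", {
  co <- small_cohort()
  g <- build_ppi(co$ppi, node_blacklist = co$truth$ubiquitin_nodes)
  sig <- c(co$truth$assoc_genes, co$truth$mediated_genes)
  sub <- reconstruct_subnetwork(g, sig)
  comp <- sub$composition
  expect_equal(unname(comp["n_connected"] + comp["n_seeds"] +
                        comp["n_added_partners"]),
               unname(comp["total"]))
  expect_equal(unname(comp["total"]), igraph::vcount(sub$subgraph))
  expect_true(all(sub$connected_genes %in% sig))
  expect_false(any(sub$added_partners %in% sig))
})
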