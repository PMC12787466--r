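test_that("density and path statistics match closed forms", {
  expect_equal(graph_density(complete_net(6)), 1)
  expect_equal(graph_density(make_net(5)), 0)

  p3 <- path_net(3)
  ps <- path_stats(p3)
  expect_equal(ps$diameter, 2)
  expect_equal(ps$avg_path_length, 4 / 3)
  expect_true(ps$connected)

  k5 <- complete_net(5)
  ps <- path_stats(k5)
  expect_equal(ps$diameter, 1)
  expect_equal(ps$avg_path_length, 1)

  # disconnected graph: flag reported, diameter from the largest component
  net <- make_net(5, rbind(c(1, 2), c(2, 3)))
  ps <- path_stats(net)
  expect_false(ps$connected)
  expect_equal(ps$diameter, 2)
})

test_that("BFS distances agree with the matrix-power reachability oracle", {
  for (seed in 1:30) {
    n <- 4 + (seed %% 9)  # 4..12 nodes
    net <- random_net(n, p_edge = 0.3, seed = seed)
    expect_equal(all_pairs_distances(net), oracle_distances(net))
  }
})

test_that("closeness and harmonic closeness follow the (n-1) conventions", {
  s17 <- star_net(17)
  cl <- closeness(s17)
  expect_equal(unname(cl[1]), 1)          # centre: all at distance 1
  expect_equal(unname(cl[2]), 16 / 31)    # leaf: one at 1, fifteen at 2
  expect_equal(unname(harmonic_closeness(s17)[1]), 1)

  # published-table configuration: 9 neighbours, 7 nodes at distance 2
  net <- stress_config_net()
  expect_equal(round(closeness(net, "Focal"), 4), 0.6957)
  expect_equal(closeness(net, "Focal"), 16 / 23, tolerance = 1e-12)
  expect_equal(round_report(harmonic_closeness(net, "Focal"), 4), 0.7813)
  expect_equal(harmonic_closeness(net, "Focal"), (9 + 7 / 2) / 16,
               tolerance = 1e-12)

  # isolated node scores 0 on both; unreachable targets contribute 0
  net2 <- make_net(4, rbind(c(1, 2)))
  expect_equal(unname(closeness(net2)[3]), 0)
  expect_equal(unname(harmonic_closeness(net2)[1]), (1 / 3))
})

test_that("betweenness is the raw Brandes count over unordered pairs", {
  s17 <- star_net(17)
  b <- betweenness(s17)
  expect_equal(unname(b[1]), choose(16, 2))  # 120
  expect_equal(unname(b[-1]), rep(0, 16))
  expect_equal(unname(betweenness(complete_net(6))), rep(0, 6))

  # fractional credit for tied shortest paths: 4-cycle, each pair of
  # opposite corners splits credit 1/2 + 1/2
  c4 <- cycle_net(4)
  expect_equal(unname(betweenness(c4)), rep(0.5, 4))

  for (seed in 1:12) {
    n <- 5 + (seed %% 6)  # 5..10 nodes
    net <- random_net(n, p_edge = 0.35, seed = 100 + seed)
    mine <- betweenness(net)
    expect_equal(mine, oracle_betweenness(net), tolerance = 1e-9)
    # and against an independent library implementation
    expect_equal(unname(mine),
                 unname(igraph::betweenness(as_igraph(net), weights = NA)),
                 tolerance = 1e-9)
  }
})

test_that("eigenvector centrality is the max-normalised leading eigenvector", {
  # k-regular graphs: perfect symmetry, all scores 1
  expect_equal(unname(eigenvector_centrality(cycle_net(8))), rep(1, 8))
  expect_equal(unname(eigenvector_centrality(complete_net(5))), rep(1, 5))

  # star: leaves are 1/sqrt(n-1) of the centre
  ev <- eigenvector_centrality(star_net(17))
  expect_equal(unname(ev[1]), 1)
  expect_equal(unname(ev[-1]), rep(0.25, 16), tolerance = 1e-8)

  # weighted graphs agree with a direct eigendecomposition
  for (seed in 1:5) {
    net <- random_net(7, p_edge = 0.5, seed = 200 + seed, weighted = TRUE)
    if (!nrow(net$edges)) next
    a <- adjacency_matrix(net, "abs")
    lead <- abs(eigen(a, symmetric = TRUE)$vectors[, 1])
    expect_equal(unname(eigenvector_centrality(net)), lead / max(lead),
                 tolerance = 1e-7)
  }
  expect_error(eigenvector_centrality(make_net(3)), "no edges")
})

test_that("HITS returns unit-norm scores with hub = authority when undirected", {
  for (seed in 1:6) {
    net <- random_net(8, p_edge = 0.4, seed = 300 + seed, weighted = TRUE)
    if (!nrow(net$edges)) next
    h <- hits(net)
    expect_equal(h$hub, h$authority, tolerance = 1e-10)
    expect_equal(sum(h$authority^2), 1, tolerance = 1e-10)
  }
  h <- hits(star_net(9))
  expect_equal(names(which.max(h$authority)), "v1")

  # directed toy a->b, c->b: b is the sole authority (oracle: eigen of A'A)
  a <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  a["a", "b"] <- 1
  a["c", "b"] <- 1
  h <- hits(a)
  oracle <- abs(eigen(crossprod(a))$vectors[, 1])
  expect_equal(unname(h$authority), oracle / sqrt(sum(oracle^2)),
               tolerance = 1e-8)
  expect_equal(unname(h$authority), c(0, 1, 0), tolerance = 1e-8)
})

test_that("local clustering reproduces the published-table ego configurations", {
  # degree 4, 5 neighbour edges -> 10/12
  e45 <- local_clustering(ego_config_net(4, 5), "Ego")
  expect_equal(round(e45$clustering, 4), 0.8333)
  expect_equal(e45$triangles, 5L)
  # degree 9, 12 neighbour edges -> 24/72
  e912 <- local_clustering(ego_config_net(9, 12), "Ego")
  expect_equal(round(e912$clustering, 4), 0.3333)
  expect_equal(e912$triangles, 12L)
  # degree 8, 11 neighbour edges -> 22/56
  e811 <- local_clustering(ego_config_net(8, 11), "Ego")
  expect_equal(round(e811$clustering, 4), 0.3929)

  k3 <- complete_net(3)
  lc <- local_clustering(k3)
  expect_equal(lc$clustering, rep(1, 3))
  expect_equal(lc$triangles, rep(1L, 3))
  # degree < 2 scores 0
  expect_equal(local_clustering(star_net(5))$clustering[-1], rep(0, 4))
})

test_that("node metrics table is complete, coherent and deterministic", {
  empty <- make_net(4, names = c("a", "b", "c", "d"))
  nm <- node_metrics(empty)
  metric_cols <- setdiff(names(nm), c("ID", "Modularity"))
  expect_true(all(as.matrix(nm[metric_cols]) == 0))

  net <- stress_config_net()
  tab <- node_metrics(net)
  row <- tab[tab$ID == "Focal", ]
  expect_equal(round(row$ClosenessCentrality, 4), 0.6957)
  expect_equal(round_report(row$HarmonicClosenessCentrality, 4), 0.7813)
  expect_equal(row$Authority, row$HUB)
  expect_identical(names(tab),
                   c("ID", "ClosenessCentrality",
                     "HarmonicClosenessCentrality", "BetweennessCentrality",
                     "Authority", "HUB", "Modularity",
                     "Clustering.Coefficient", "NumberTriangles",
                     "EigenvectorCentrality"))

  cohort <- generate_cohort(generator_config(n = 188, seed = 5))
  hn <- select_edges(partial_correlations(cohort), 0.25)
  part <- louvain(hn, seed = 5)
  t1 <- node_metrics(hn, part$assignment)
  t2 <- node_metrics(hn, part$assignment)
  expect_identical(t1, t2)
  expect_equal(max(t1$EigenvectorCentrality), 1)
  expect_true(all(t1$Clustering.Coefficient >= 0 &
                    t1$Clustering.Coefficient <= 1))
  expect_true(all(t1$NumberTriangles >= 0))

  gm <- global_metrics(hn, part$assignment)
  expect_equal(gm$density * potential_edge_count(17), gm$edge_count)
  expect_gte(gm$diameter, gm$avg_path_length)
  expect_gte(gm$avg_path_length, 1)
  expect_true(gm$avg_clustering >= 0 && gm$avg_clustering <= 1)
})
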