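# Graph constructors used across the suite. Edges are given as a 2-column
# matrix of node indices (optionally with a weight vector).

make_net <- function(n, edges = NULL, weights = NULL,
                     names = paste0("v", seq_len(n))) {
  nodes <- data.frame(name = names, dimension = "physical",
                      stringsAsFactors = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    e <- data.frame(from = character(0), to = character(0),
                    weight = numeric(0), p = numeric(0))
  } else {
    edges <- matrix(edges, ncol = 2)
    if (is.null(weights)) weights <- rep(1, nrow(edges))
    e <- data.frame(from = names[edges[, 1]], to = names[edges[, 2]],
                    weight = weights, p = 0.01, stringsAsFactors = FALSE)
  }
  health_network(nodes, e)
}

star_net <- function(n) make_net(n, cbind(1, 2:n))

path_net <- function(n) make_net(n, cbind(1:(n - 1), 2:n))

cycle_net <- function(n) make_net(n, cbind(1:n, c(2:n, 1)))

complete_net <- function(n) {
  idx <- t(utils::combn(n, 2))
  make_net(n, idx)
}

two_k3_net <- function() {
  make_net(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
}

# Erdos-Renyi-ish random graph with optional random weights
random_net <- function(n, p_edge = 0.4, seed = 1, weighted = FALSE) {
  withr::with_seed(seed, {
    idx <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(idx)) < p_edge
    idx <- idx[keep, , drop = FALSE]
    w <- if (weighted) stats::runif(nrow(idx), 0.1, 2) else NULL
    make_net(n, idx, weights = w)
  })
}

# The published-table closeness configuration: a 17-node graph in which the
# focal node has 9 neighbours and the remaining 7 nodes all sit at distance 2.
stress_config_net <- function() {
  edges <- cbind(1, 2:10)                       # focal node 1, 9 neighbours
  edges <- rbind(edges, cbind(2:8, 11:17))      # each far node hangs off one
  make_net(17, edges, names = c("Focal", paste0("n", 2:17)))
}

# A node of given degree with a given number of edges among its neighbours
# (neighbour-edge pairs filled in a fixed order).
ego_config_net <- function(degree, nbr_edges) {
  pairs <- t(utils::combn(degree, 2))
  stopifnot(nbr_edges <= nrow(pairs))
  edges <- cbind(1, 1 + seq_len(degree))
  if (nbr_edges > 0) {
    edges <- rbind(edges, 1 + pairs[seq_len(nbr_edges), , drop = FALSE])
  }
  make_net(degree + 1, edges, names = c("Ego", paste0("n", seq_len(degree))))
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = net$nodes$name
  )
}
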