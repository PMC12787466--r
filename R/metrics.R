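## Node and global statistics under the conventions of the published table:
## path-based metrics on the unweighted topology, eigenvector/HITS on
## absolute edge weights, closeness = (n-1)/sum(d), HITS unit-L2-normalised,
## eigenvector max-normalised.

#' @keywords internal
neighbor_list <- function(net) {
  nm <- net$nodes$name
  nb <- stats::setNames(vector("list", length(nm)), nm)
  for (v in nm) nb[[v]] <- integer(0)
  if (nrow(net$edges)) {
    i <- match(net$edges$from, nm)
    j <- match(net$edges$to, nm)
    for (e in seq_along(i)) {
      nb[[i[e]]] <- c(nb[[i[e]]], j[e])
      nb[[j[e]]] <- c(nb[[j[e]]], i[e])
    }
  }
  nb
}

#' All-pairs shortest-path distances (unweighted)
#'
#' Breadth-first distances on the network topology, ignoring edge weights.
#' Unreachable pairs get `Inf`.
#'
#' @param net A `health_network`.
#' @return An n x n numeric matrix of hop distances, zero diagonal.
#' @export
all_pairs_distances <- function(net) {
  nm <- net$nodes$name
  n <- length(nm)
  nb <- neighbor_list(net)
  d <- matrix(Inf, n, n, dimnames = list(nm, nm))
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(nb[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

#' Network density
#'
#' Number of modelled edges divided by the number of potential edges
#' `n(n-1)/2`; 1 for a complete graph.
#'
#' @param net A `health_network` with at least one node.
#' @return Density in `[0, 1]`.
#' @export
#' @examples
#' # a 17-node, 50-edge graph has density 50/136 = 0.368
graph_density <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) return(0)
  nrow(net$edges) / potential_edge_count(n)
}

#' Diameter and average path length
#'
#' Unweighted breadth-first distances. The average path length is the mean
#' distance over ordered connected pairs (disconnected pairs excluded); the
#' diameter is the maximum eccentricity within the largest connected
#' component. A `connected` flag reports whether any pair was excluded.
#'
#' @param net A `health_network` with >= 2 nodes.
#' @return List with `diameter`, `avg_path_length`, `connected`.
#' @export
path_stats <- function(net) {
  stopifnot(nrow(net$nodes) >= 2)
  d <- all_pairs_distances(net)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  comp <- connected_components(net)
  sizes <- tabulate(comp)
  big <- which(comp == which.max(sizes))
  diam <- if (length(big) > 1) max(d[big, big]) else 0
  list(
    diameter = diam,
    avg_path_length = if (length(finite)) mean(finite) else NA_real_,
    connected = all(is.finite(off))
  )
}

#' @keywords internal
connected_components <- function(net) {
  n <- nrow(net$nodes)
  nb <- neighbor_list(net)
  comp <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(nb[frontier], use.names = FALSE)),
                     which(comp > 0))
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  comp
}

#' Closeness centrality (Gephi convention)
#'
#' `(n - 1) / sum(d)` over the node's reachable targets, with unweighted
#' distances; isolated nodes score 0. In a 17-node graph a node adjacent to
#' 9 others with the remaining 7 at distance 2 scores 16/23 = 0.6957.
#'
#' @param net A `health_network`.
#' @param node Optional node name; default returns all nodes.
#' @return Named numeric vector (or scalar when `node` is given).
#' @export
closeness <- function(net, node = NULL) {
  d <- all_pairs_distances(net)
  n <- nrow(d)
  res <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    reach <- reach[reach > 0]
    if (!length(reach)) 0 else (n - 1) / sum(reach)
  })
  if (is.null(node)) res else res[[node]]
}

#' Harmonic closeness centrality
#'
#' Mean reciprocal distance `sum(1/d) / (n - 1)` with `1/Inf = 0` for
#' unreachable targets; robust to disconnected graphs.
#'
#' @inheritParams closeness
#' @return Named numeric vector (or scalar when `node` is given).
#' @export
harmonic_closeness <- function(net, node = NULL) {
  d <- all_pairs_distances(net)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  res <- rowSums(inv) / (n - 1)
  if (is.null(node)) res else res[[node]]
}

#' Betweenness centrality (raw Brandes count)
#'
#' Number of shortest paths between other node pairs passing through each
#' node, with fractional credit when several shortest paths tie; unweighted
#' distances, unordered pairs, no normalisation (the star centre of a
#' 17-node star scores C(16,2) = 120).
#'
#' @inheritParams closeness
#' @return Named numeric vector (or scalar when `node` is given).
#' @export
betweenness <- function(net, node = NULL) {
  nm <- net$nodes$name
  n <- length(nm)
  nb <- neighbor_list(net)
  cb <- stats::setNames(numeric(n), nm)
  for (s in seq_len(n)) {
    # Brandes (2001): BFS from s, then dependency accumulation
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nb[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb <- cb / 2  # undirected: each unordered pair was counted from both ends
  if (is.null(node)) cb else cb[[node]]
}

#' Eigenvector centrality (power iteration, max-normalised)
#'
#' Leading eigenvector of the absolute-weight adjacency matrix, computed by
#' power iteration (tolerance 1e-10) and normalised so the maximum score is
#' 1. Signed weights are folded to magnitudes so the matrix is non-negative
#' (Perron-Frobenius); set `weights = "unit"` for the binary topology.
#'
#' @param net A `health_network` with >= 1 edge.
#' @param weights `"abs"` (default) or `"unit"`.
#' @param tol Convergence tolerance on the max-norm change.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Named numeric vector of scores with `max = 1`.
#' @export
eigenvector_centrality <- function(net, weights = c("abs", "unit"),
                                   tol = 1e-10, max_iter = 10000L) {
  weights <- match.arg(weights)
  a <- adjacency_matrix(net, weights)
  if (!nrow(net$edges)) stop("graph has no edges", call. = FALSE)
  # power-iterate on A + I: same eigenvectors, but the spectral shift makes
  # the leading eigenvalue strictly dominant (plain A oscillates on
  # bipartite graphs such as trees and stars)
  diag(a) <- diag(a) + 1
  x <- rep(1, nrow(a))
  for (it in seq_len(max_iter)) {
    xn <- as.vector(a %*% x)
    m <- max(xn)
    if (m == 0) stop("power iteration collapsed to zero", call. = FALSE)
    xn <- xn / m
    if (max(abs(xn - x)) < tol) {
      return(stats::setNames(xn / max(xn), net$nodes$name))
    }
    x <- xn
  }
  stop("eigenvector centrality did not converge in ", max_iter,
       " iterations", call. = FALSE)
}

#' HITS hub and authority scores
#'
#' Standard HITS power iteration on the absolute-weight adjacency matrix,
#' with unit-L2 normalisation of both score vectors. On an undirected graph
#' the matrix is symmetric, so hub and authority coincide entrywise.
#'
#' @param net A `health_network` with >= 1 edge, or a square (possibly
#'   asymmetric) adjacency matrix for directed toy graphs.
#' @param tol Convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return List with named numeric vectors `hub` and `authority`, each of
#'   unit Euclidean norm.
#' @export
hits <- function(net, tol = 1e-10, max_iter = 10000L) {
  if (inherits(net, "health_network")) {
    if (!nrow(net$edges)) stop("graph has no edges", call. = FALSE)
    a <- adjacency_matrix(net, "abs")
  } else {
    a <- abs(as.matrix(net))
    stopifnot(nrow(a) == ncol(a))
    if (all(a == 0)) stop("graph has no edges", call. = FALSE)
    if (is.null(rownames(a))) {
      dimnames(a) <- list(paste0("V", seq_len(nrow(a))),
                          paste0("V", seq_len(nrow(a))))
    }
  }
  n <- nrow(a)
  if (isSymmetric(unname(a))) {
    # undirected case: authority = hub = leading eigenvector of A, unit L2
    # norm; iterate on A + I so bipartite structures cannot oscillate
    m <- a
    diag(m) <- diag(m) + 1
    x <- rep(1 / sqrt(n), n)
    for (it in seq_len(max_iter)) {
      xn <- as.vector(m %*% x)
      xn <- xn / sqrt(sum(xn^2))
      if (max(abs(xn - x)) < tol) {
        v <- stats::setNames(xn, rownames(a))
        return(list(hub = v, authority = v))
      }
      x <- xn
    }
    stop("HITS did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  auth <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    auth_new <- as.vector(crossprod(a, a %*% auth))  # full A'A step
    auth_new <- auth_new / sqrt(sum(auth_new^2))
    if (max(abs(auth_new - auth)) < tol) {
      hub <- as.vector(a %*% auth_new)
      hub <- hub / sqrt(sum(hub^2))
      return(list(hub = stats::setNames(hub, rownames(a)),
                  authority = stats::setNames(auth_new, rownames(a))))
    }
    auth <- auth_new
  }
  stop("HITS did not converge in ", max_iter, " iterations", call. = FALSE)
}

#' Local clustering coefficient and triangle count
#'
#' For a node of degree `k` with `T` edges among its neighbours, the
#' coefficient is `2T / (k (k - 1))`; nodes of degree < 2 score 0.
#'
#' @inheritParams closeness
#' @return A data frame with columns `node`, `clustering`, `triangles` (or a
#'   single row when `node` is given).
#' @export
local_clustering <- function(net, node = NULL) {
  a <- adjacency_matrix(net, "unit")
  nm <- net$nodes$name
  res <- data.frame(node = nm, clustering = 0, triangles = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(nm)) {
    nbrs <- which(a[i, ] > 0)
    k <- length(nbrs)
    if (k < 2) next
    tri <- sum(a[nbrs, nbrs]) / 2
    res$triangles[i] <- as.integer(round(tri))
    res$clustering[i] <- 2 * tri / (k * (k - 1))
  }
  if (is.null(node)) res else res[res$node == node, ]
}

#' Assemble the per-node metrics table
#'
#' One row per node, in the published report's column order:
#' `ID, ClosenessCentrality, HarmonicClosenessCentrality,
#' BetweennessCentrality, Authority, HUB, Modularity,
#' Clustering.Coefficient, NumberTriangles, EigenvectorCentrality`.
#' (`Modularity` holds the node's community id.) Edgeless graphs get all-zero
#' metric columns.
#'
#' @param net A `health_network`.
#' @param partition Optional named community assignment (node -> id), e.g.
#'   from [louvain()]; `NA` ids are written when omitted.
#' @return A data frame of class `node_metrics`.
#' @export
node_metrics <- function(net, partition = NULL) {
  nm <- net$nodes$name
  has_edges <- nrow(net$edges) > 0
  lc <- local_clustering(net)
  if (has_edges) {
    h <- hits(net)
    eig <- eigenvector_centrality(net)
  } else {
    h <- list(hub = stats::setNames(numeric(length(nm)), nm),
              authority = stats::setNames(numeric(length(nm)), nm))
    eig <- stats::setNames(numeric(length(nm)), nm)
  }
  comm <- if (is.null(partition)) {
    rep(NA_integer_, length(nm))
  } else {
    if (!all(nm %in% names(partition))) {
      stop("partition must cover every node", call. = FALSE)
    }
    as.integer(partition[nm])
  }
  out <- data.frame(
    ID = nm,
    ClosenessCentrality = unname(closeness(net)),
    HarmonicClosenessCentrality = unname(harmonic_closeness(net)),
    BetweennessCentrality = unname(betweenness(net)),
    Authority = unname(h$authority[nm]),
    HUB = unname(h$hub[nm]),
    Modularity = comm,
    Clustering.Coefficient = lc$clustering,
    NumberTriangles = lc$triangles,
    EigenvectorCentrality = unname(eig[nm]),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  class(out) <- c("node_metrics", "data.frame")
  out
}

#' Global network metrics
#'
#' @param net A `health_network`.
#' @param partition Optional community assignment for the modularity score.
#' @return List with `edge_count`, `density`, `diameter`,
#'   `avg_path_length`, `avg_clustering`, `modularity_q`, `connected`.
#' @export
global_metrics <- function(net, partition = NULL) {
  ps <- path_stats(net)
  q <- if (!is.null(partition) && nrow(net$edges)) {
    modularity_q(net, partition)
  } else {
    NA_real_
  }
  list(
    edge_count = nrow(net$edges),
    density = graph_density(net),
    diameter = ps$diameter,
    avg_path_length = ps$avg_path_length,
    avg_clustering = mean(local_clustering(net)$clustering),
    modularity_q = q,
    connected = ps$connected
  )
}
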