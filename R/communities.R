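#' Modularity of a community partition
#'
#' `Q = sum_c [ e_c / m - gamma * (d_c / 2m)^2 ]` on absolute edge weights,
#' where `e_c` is the total within-community edge weight, `d_c` the total
#' (weighted) degree of community `c`, and `m` the total edge weight.
#' Unweighted graphs reduce to edge counts. Two disconnected triangles split
#' into their cliques score Q = 0.5; the all-in-one partition scores 0.
#'
#' @param net A `health_network` with >= 1 edge.
#' @param assignment Named vector mapping every node name to a community id.
#' @param resolution Resolution parameter gamma (default 1).
#' @return Modularity score in `[-1, 1]`.
#' @export
modularity_q <- function(net, assignment, resolution = 1) {
  if (!nrow(net$edges)) stop("modularity undefined: graph has no edges",
                             call. = FALSE)
  nm <- net$nodes$name
  if (!all(nm %in% names(assignment))) {
    stop("assignment must cover every node", call. = FALSE)
  }
  a <- adjacency_matrix(net, "abs")
  modularity_from_matrix(a, as.integer(factor(assignment[nm])), resolution)
}

## W: symmetric weight matrix whose diagonal carries TWICE any self-loop
## weight, so k_i = rowSums(W) and 2m = sum(W) hold uniformly (needed by the
## Louvain aggregation step).
#' @keywords internal
modularity_from_matrix <- function(w, comm, resolution = 1) {
  s <- sum(w)
  q <- 0
  for (c_id in unique(comm)) {
    idx <- which(comm == c_id)
    within <- sum(w[idx, idx, drop = FALSE])     # counts each edge twice
    deg <- sum(w[idx, , drop = FALSE])
    q <- q + within / s - resolution * (deg / s)^2
  }
  q
}

#' Louvain community detection
#'
#' Standard two-phase Louvain on absolute edge weights: greedy local moving
#' of nodes between neighbouring communities (in a seed-shuffled order)
#' until no move improves modularity by more than `1e-10`, then aggregation
#' of communities into super-nodes, repeated until the partition is stable.
#' Community ids are renumbered by descending community size (ties by the
#' smallest original node index), so the output is deterministic given the
#' seed.
#'
#' @param net A `health_network` with >= 1 edge.
#' @param resolution Resolution parameter gamma (default 1, the Gephi
#'   default).
#' @param seed Integer seed controlling the node-visiting order.
#' @return An object of class `community_partition`: list with `assignment`
#'   (named integer vector node -> community id), `q` (modularity of the
#'   final partition), `resolution`, `seed`.
#' @export
louvain <- function(net, resolution = 1, seed = 1L) {
  if (!nrow(net$edges)) stop("louvain needs at least one edge", call. = FALSE)
  nm <- net$nodes$name
  w <- adjacency_matrix(net, "abs")
  assignment <- withr::with_seed(as.integer(seed), {
    membership <- seq_along(nm)  # original node -> current super-node
    repeat {
      res <- louvain_local_pass(w, resolution)
      if (!res$improved && all(res$comm == seq_len(nrow(w)))) break
      membership <- res$comm[membership]
      # aggregate: communities become nodes; diagonal = 2 x internal weight
      f <- factor(res$comm)
      ind <- stats::model.matrix(~ f - 1)
      w <- crossprod(ind, w %*% ind)
      membership <- as.integer(factor(membership))
      if (!res$improved) break
    }
    membership
  })
  assignment <- renumber_by_size(assignment)
  names(assignment) <- nm
  q <- modularity_q(net, assignment, resolution)
  structure(
    list(assignment = assignment, q = q, resolution = resolution,
         seed = as.integer(seed)),
    class = "community_partition"
  )
}

## One local-moving phase over the (possibly aggregated) weight matrix.
## Returns comm: node -> community (renumbered 1..k) and whether any move
## with positive modularity gain was made.
#' @keywords internal
louvain_local_pass <- function(w, resolution) {
  n <- nrow(w)
  comm <- seq_len(n)
  s <- sum(w)
  k <- rowSums(w)
  tot <- k  # total degree per community (singletons initially)
  improved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      # neighbouring communities (excluding self-weight contribution)
      nbrs <- which(w[i, ] > 0 & seq_len(n) != i)
      cand <- unique(c(ci, comm[nbrs]))
      # weight from i to each candidate community
      w_ic <- vapply(cand, function(cc) {
        sum(w[i, nbrs[comm[nbrs] == cc]])
      }, 0)
      # remove i from its community
      tot[ci] <- tot[ci] - k[i]
      # gain of joining community cc: 2*w_ic/s - 2*gamma*k_i*tot_cc/s^2
      gains <- 2 * w_ic / s - 2 * resolution * k[i] * tot[cand] / s^2
      stay <- which(cand == ci)
      best <- which.max(gains)
      if (gains[best] > gains[stay] + 1e-10) {
        comm[i] <- cand[best]
        improved <- TRUE
        improved_any <- TRUE
      }
      tot[comm[i]] <- tot[comm[i]] + k[i]
    }
    if (!improved) break
  }
  list(comm = as.integer(factor(comm)), improved = improved_any)
}

#' @keywords internal
renumber_by_size <- function(assignment) {
  tab <- table(assignment)
  first_idx <- vapply(names(tab), function(cc) {
    min(which(assignment == as.integer(cc)))
  }, 0L)
  ord <- order(-as.integer(tab), first_idx)
  remap <- stats::setNames(seq_along(ord), names(tab)[ord])
  as.integer(remap[as.character(assignment)])
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Louvain partition:", length(unique(x$assignment)), "communities,",
      sprintf("Q = %.4f (resolution %.2f, seed %d)\n",
              x$q, x$resolution, x$seed))
  invisible(x)
}

#' Write a community partition as CSV
#'
#' @param partition A `community_partition` (or named assignment vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  a <- if (inherits(partition, "community_partition")) {
    partition$assignment
  } else {
    partition
  }
  utils::write.csv(
    data.frame(node = names(a), community = as.integer(a)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
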