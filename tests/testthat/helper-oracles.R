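# Independent oracles: deliberately naive implementations (regression
# residuals, matrix-power reachability, recursive path enumeration,
# exhaustive set-partition search, quadrature) used to verify the package's
# algorithms. None of them share code with the implementations they check.

# Partial correlations by the regress-out-residuals definition.
oracle_pcor_residual <- function(x) {
  p <- ncol(x)
  rp <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- stats::residuals(stats::lm(x[, i] ~ others))
      rj <- stats::residuals(stats::lm(x[, j] ~ others))
      rp[i, j] <- rp[j, i] <- stats::cor(ri, rj)
    }
  }
  dimnames(rp) <- list(colnames(x), colnames(x))
  rp
}

# Two-sided p-value by numerical quadrature of the t density.
oracle_p_quadrature <- function(r, n, k) {
  df <- n - k - 2
  tstat <- abs(r) * sqrt(df / (1 - r^2))
  2 * stats::integrate(function(x) stats::dt(x, df), tstat, Inf,
                       rel.tol = 1e-10)$value
}

# All-pairs distances via boolean matrix powers (reachability at depth k).
oracle_distances <- function(net) {
  a <- adjacency_matrix(net, "unit")
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  diag(d) <- 0
  reach <- diag(n)
  pow <- diag(n)
  for (depth in seq_len(n)) {
    pow <- (pow %*% a) > 0
    newly <- pow & !reach
    d[newly & is.infinite(d)] <- depth
    reach <- reach | pow
  }
  d
}

# Betweenness by exhaustive enumeration of every shortest path.
oracle_betweenness <- function(net) {
  nm <- net$nodes$name
  n <- length(nm)
  a <- adjacency_matrix(net, "unit")
  d <- oracle_distances(net)
  enumerate_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (u in which(a[, t] > 0)) {
      if (is.finite(d[s, u]) && d[s, u] == d[s, t] - 1) {
        out <- c(out, lapply(enumerate_paths(s, u), function(pp) c(pp, t)))
      }
    }
    out
  }
  cb <- stats::setNames(numeric(n), nm)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      paths <- enumerate_paths(s, t)
      for (pp in paths) {
        interior <- setdiff(pp, c(s, t))
        cb[interior] <- cb[interior] + 1 / length(paths)
      }
    }
  }
  cb
}

# All set partitions of n items as restricted-growth strings.
all_partitions <- function(n) {
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    m <- max(prefix)
    out <- list()
    for (v in seq_len(m + 1)) out <- c(out, grow(c(prefix, v)))
    out
  }
  grow(1L)
}

# Modularity by the direct per-community formula, straight off the edge list.
oracle_modularity <- function(net, assignment, resolution = 1) {
  e <- net$edges
  w <- abs(e$weight)
  m <- sum(w)
  deg <- stats::setNames(numeric(nrow(net$nodes)), net$nodes$name)
  for (i in seq_along(w)) {
    deg[e$from[i]] <- deg[e$from[i]] + w[i]
    deg[e$to[i]] <- deg[e$to[i]] + w[i]
  }
  q <- 0
  for (cc in unique(assignment)) {
    members <- names(assignment)[assignment == cc]
    inside <- e$from %in% members & e$to %in% members
    e_c <- sum(w[inside])
    d_c <- sum(deg[members])
    q <- q + e_c / m - resolution * (d_c / (2 * m))^2
  }
  q
}

# Best achievable modularity by exhaustive search over all partitions.
oracle_best_partition <- function(net, resolution = 1) {
  nm <- net$nodes$name
  best <- -Inf
  best_assign <- NULL
  for (pp in all_partitions(length(nm))) {
    assign <- stats::setNames(pp, nm)
    q <- oracle_modularity(net, assign, resolution)
    if (q > best) {
      best <- q
      best_assign <- assign
    }
  }
  list(q = best, assignment = best_assign)
}

# Expected correlation after pushing a latent bivariate normal through the
# generator's marginal maps (Monte-Carlo, independent of generate_cohort).
oracle_copula_cor <- function(rho, spec1, spec2, n = 2e5, seed = 99) {
  map <- function(z, s) {
    if (s$vartype == "continuous") {
      x <- s$mean + s$sd * z
      if (isTRUE(s$positive)) x <- pmax(x, 0.01 * s$mean)
      x
    } else {
      cuts <- stats::qnorm(cumsum(s$category_probs))
      rowSums(outer(z, cuts[-length(cuts)], `>`))
    }
  }
  withr::with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    stats::cor(map(z1, spec1), map(z2, spec2))
  })
}
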