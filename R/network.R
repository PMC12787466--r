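#' Construct a health network
#'
#' An undirected simple weighted signed graph: nodes are the cohort
#' variables (tagged with their display dimension), edges carry the selected
#' partial correlation as signed weight plus its p-value.
#'
#' @param nodes Data frame with columns `name` and `dimension`.
#' @param edges Data frame with columns `from`, `to`, `weight`, `p`
#'   (zero-row data frames allowed).
#' @return An object of class `health_network`.
#' @export
health_network <- function(nodes, edges) {
  stopifnot(all(c("name", "dimension") %in% names(nodes)),
            all(c("from", "to", "weight", "p") %in% names(edges)))
  nodes$name <- as.character(nodes$name)
  if (anyDuplicated(nodes$name)) stop("duplicate node names", call. = FALSE)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-loops not allowed", call. = FALSE)
    bad <- !(edges$from %in% nodes$name) | !(edges$to %in% nodes$name)
    if (any(bad)) stop("edge endpoints not in node set", call. = FALSE)
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("multi-edges not allowed", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "health_network")
}

#' @export
print.health_network <- function(x, ...) {
  cat("Health network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(density %.3f)\n", graph_density(x)))
  invisible(x)
}

#' Number of potential edges in a simple graph
#'
#' @param n_nodes Node count (>= 1).
#' @return `n_nodes * (n_nodes - 1) / 2`.
#' @export
#' @examples
#' potential_edge_count(17)  # 136
potential_edge_count <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  n_nodes * (n_nodes - 1) / 2
}

#' Prune the full partial-correlation matrix into the analysed network
#'
#' Retains exactly the variable pairs whose partial-correlation p-value is
#' strictly below `alpha` (the liberal p < 0.25 screen by default elsewhere
#' in the pipeline; no multiple-testing correction is applied). All nodes
#' stay in the graph even when isolated.
#'
#' @param pcor A `pcor_result`.
#' @param alpha Selection threshold in (0, 1]; strictly-below comparison.
#' @param dimensions Optional named character vector mapping node name to
#'   display dimension; defaults to the canonical 17-variable dimensions
#'   (unknown names fall back to `"physical"`).
#' @return A [health_network()].
#' @export
select_edges <- function(pcor, alpha = 0.25, dimensions = NULL) {
  stopifnot(inherits(pcor, "pcor_result"))
  if (!(alpha > 0 && alpha <= 1)) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  labels <- pcor$labels
  if (is.null(dimensions)) {
    sch <- default_schema()
    dimensions <- stats::setNames(schema_field(sch, "dimension"),
                                  schema_names(sch))
  }
  dim_of <- ifelse(labels %in% names(dimensions),
                   dimensions[labels], "physical")
  nodes <- data.frame(name = labels, dimension = unname(dim_of),
                      stringsAsFactors = FALSE)
  p <- length(labels)
  pairs <- which(upper.tri(pcor$pvals) & pcor$pvals < alpha, arr.ind = TRUE)
  edges <- data.frame(
    from = labels[pairs[, 1]],
    to = labels[pairs[, 2]],
    weight = pcor$rp[pairs],
    p = pcor$pvals[pairs],
    stringsAsFactors = FALSE
  )
  health_network(nodes, edges)
}

#' Adjacency matrix of a health network
#'
#' @param net A `health_network`.
#' @param weights `"abs"` (absolute partial correlations; default — used by
#'   eigenvector/HITS/modularity), `"signed"` (raw weights), or `"unit"`
#'   (binary topology).
#' @return A symmetric n x n matrix with node names on both margins.
#' @export
adjacency_matrix <- function(net, weights = c("abs", "signed", "unit")) {
  weights <- match.arg(weights)
  nm <- net$nodes$name
  a <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(net$edges)) {
    w <- switch(weights,
                abs = abs(net$edges$weight),
                signed = net$edges$weight,
                unit = rep(1, nrow(net$edges)))
    i <- match(net$edges$from, nm)
    j <- match(net$edges$to, nm)
    a[cbind(i, j)] <- w
    a[cbind(j, i)] <- w
  }
  a
}

#' Write the edge list as CSV
#'
#' Columns: `source, target, weight, p, sign`.
#'
#' @param net A `health_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list_csv <- function(net, path) {
  e <- net$edges
  out <- data.frame(source = e$from, target = e$to, weight = e$weight,
                    p = e$p,
                    sign = ifelse(e$weight >= 0, "positive", "negative"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-list CSV back into a health network
#'
#' Inverse of [write_edge_list_csv()]; node dimensions are taken from the
#' canonical schema (unknown names become `"physical"`).
#'
#' @param path Edge-list CSV path.
#' @param node_names Full node set (so isolated nodes survive the
#'   round-trip); defaults to the canonical 17 labels.
#' @return A [health_network()].
#' @export
read_edge_list_csv <- function(path, node_names = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(node_names)) node_names <- schema_names(default_schema())
  sch <- default_schema()
  dims <- stats::setNames(schema_field(sch, "dimension"), schema_names(sch))
  nodes <- data.frame(
    name = node_names,
    dimension = ifelse(node_names %in% names(dims),
                       dims[node_names], "physical"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = e$source, to = e$target, weight = e$weight,
                      p = e$p, stringsAsFactors = FALSE)
  health_network(nodes, edges)
}

#' Export a health network as GEXF
#'
#' Writes GEXF 1.3 with the node dimension as a node attribute and the edge
#' sign and p-value as edge attributes; edge weight is the signed partial
#' correlation.
#'
#' @param net A `health_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(net, path) {
  doc <- xml2::xml_new_root("gexf", xmlns = "http://gexf.net/1.3",
                            version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  nattr <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(nattr, "attribute", id = "0", title = "dimension",
                      type = "string")
  eattr <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattr, "attribute", id = "0", title = "sign",
                      type = "string")
  xml2::xml_add_child(eattr, "attribute", id = "1", title = "p",
                      type = "double")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node", id = net$nodes$name[i],
                              label = net$nodes$name[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = net$nodes$dimension[i])
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(
      edges, "edge", id = as.character(i - 1L),
      source = net$edges$from[i], target = net$edges$to[i],
      weight = format(net$edges$weight[i], digits = 15)
    )
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = if (net$edges$weight[i] >= 0) "positive" else "negative")
    xml2::xml_add_child(av, "attvalue", "for" = "1",
                        value = format(net$edges$p[i], digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a health network as GraphML
#'
#' Node dimension, signed edge weight, edge sign and p-value are written as
#' standard GraphML data keys, so the file loads in igraph, Gephi, Cytoscape
#' and friends.
#'
#' @param net A `health_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  xml2::xml_add_child(doc, "key", id = "d0", "for" = "node",
                      attr.name = "dimension", attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "d1", "for" = "edge",
                      attr.name = "weight", attr.type = "double")
  xml2::xml_add_child(doc, "key", id = "d2", "for" = "edge",
                      attr.name = "sign", attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "d3", "for" = "edge",
                      attr.name = "p", attr.type = "double")
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "undirected")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = net$nodes$name[i])
    d <- xml2::xml_add_child(nd, "data", key = "d0")
    xml2::xml_set_text(d, net$nodes$dimension[i])
  }
  for (i in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(graph, "edge", source = net$edges$from[i],
                              target = net$edges$to[i])
    d <- xml2::xml_add_child(ed, "data", key = "d1")
    xml2::xml_set_text(d, format(net$edges$weight[i], digits = 15))
    d <- xml2::xml_add_child(ed, "data", key = "d2")
    xml2::xml_set_text(d, if (net$edges$weight[i] >= 0) "positive" else "negative")
    d <- xml2::xml_add_child(ed, "data", key = "d3")
    xml2::xml_set_text(d, format(net$edges$p[i], digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
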