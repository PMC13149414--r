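#' Areal adjacency graph for spatial priors
#'
#' A `country_graph` wraps an undirected neighbor structure: node labels,
#' edge list, adjacency matrix, and connected components (needed because the
#' intrinsic CAR prior is improper with one null direction per component).
#'
#' @param nodes character vector of node (country) labels.
#' @param edges two-column matrix or data.frame of node labels, one row per
#'   undirected neighbor pair.
#' @return a `country_graph` list: nodes, edges, adjacency `W`, component
#'   membership `component`, component count `n_components`.
#' @export
country_graph <- function(nodes, edges) {
  nodes <- sort(as.character(nodes))   # canonical (alphabetical) node order
  if (length(nodes) < 2L) stop("need at least 2 nodes")
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    unknown <- setdiff(as.vector(edges), nodes)
    if (length(unknown)) stop("edge references unknown node(s): ",
                              paste(unknown, collapse = ", "))
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  }
  I <- length(nodes)
  W <- matrix(0, I, I, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1L]; j <- edges[k, 2L]
      W[i, j] <- 1; W[j, i] <- 1
    }
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
  comp <- igraph::components(g)
  structure(list(nodes = nodes, edges = edges, W = W,
                 component = unname(comp$membership),
                 n_components = comp$no),
            class = "country_graph")
}

#' @export
print.country_graph <- function(x, ...) {
  cat(sprintf("country_graph: %d nodes, %d edges, %d component(s)\n",
              length(x$nodes), nrow(x$edges), x$n_components))
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Neighbors of a node
#' @param graph a `country_graph`.
#' @param node node label.
#' @return character vector of neighbor labels.
#' @export
graph_neighbors <- function(graph, node) {
  stopifnot(inherits(graph, "country_graph"))
  sort(graph$nodes[graph$W[node, ] > 0])
}

# Land-border contiguity among the seven EAC member states. The COD-TZA pair
# faces across Lake Tanganyika and is excluded by default; include it via
# `lake_edges = TRUE` to treat lake adjacency as contiguity.
.eac_land_edges <- matrix(c(
  "BDI", "RWA",
  "BDI", "COD",
  "BDI", "TZA",
  "RWA", "COD",
  "RWA", "UGA",
  "RWA", "TZA",
  "COD", "UGA",
  "COD", "SSD",
  "UGA", "KEN",
  "UGA", "TZA",
  "UGA", "SSD",
  "KEN", "TZA",
  "KEN", "SSD"), ncol = 2L, byrow = TRUE)

#' Default East African Community adjacency graph
#'
#' Seven member states (Burundi BDI, DR Congo COD, Kenya KEN, Rwanda RWA,
#' South Sudan SSD, Tanzania TZA, Uganda UGA) joined by queen contiguity on
#' land borders. The lake-separated COD-TZA pair is excluded unless
#' `lake_edges = TRUE`.
#'
#' @param lake_edges logical; count lake adjacency (COD-TZA) as contiguity.
#' @return a connected `country_graph` with 7 nodes.
#' @export
build_eac_graph <- function(lake_edges = FALSE) {
  edges <- .eac_land_edges
  if (lake_edges) edges <- rbind(edges, c("COD", "TZA"))
  country_graph(c("BDI", "COD", "KEN", "RWA", "SSD", "TZA", "UGA"), edges)
}

#' Read / write a graph as an edge-list CSV
#'
#' Two columns of node labels (`from`, `to`), one row per undirected edge.
#' Isolated nodes can be listed via the optional `nodes` argument on read.
#' @param path file path.
#' @param nodes optional full node set (labels absent from the edge list).
#' @export
read_graph_csv <- function(path, nodes = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(e) < 2L) stop("edge-list CSV needs two columns")
  labs <- sort(unique(c(as.character(e[[1L]]), as.character(e[[2L]]), nodes)))
  country_graph(labs, as.matrix(e[, 1:2]))
}

#' @rdname read_graph_csv
#' @param graph a `country_graph`.
#' @export
write_graph_csv <- function(graph, path) {
  utils::write.csv(data.frame(from = graph$edges[, 1L], to = graph$edges[, 2L],
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
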