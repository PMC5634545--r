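#' Edge-dual (line) graph of the coherence clique
#'
#' Functional edges become vertices of the edge-dual graph; two vertices are
#' linked iff their region pairs share exactly one region. For a clique on N
#' regions the dual has `|E| = N(N-1)/2` vertices and `|L| = |E| (N-2)`
#' links. Connected vertex sets in the dual correspond exactly to connected
#' edge sets in the original network, which is what lets subgraph mining
#' operate on vertex sets.
#'
#' Vertices are ordered lexicographically on the sorted region pair `(i, j)`,
#' `i < j`, with 0-based region ids; every downstream index refers to this
#' canonical order.
#'
#' @param network a `functional_network`, or an integer number of regions.
#' @return an object of class `edge_dual` with fields `n_regions`, `pairs`
#'   (|E| x 2 integer matrix of 0-based region ids), `vertex_names`,
#'   `adjacency` (list of 1-based neighbor vertex ids), `n_links`, and
#'   `regions`.
#' @examples
#' d <- to_edge_dual(4)   # the 4-region worked example
#' d$n_links               # 12
#' @export
to_edge_dual <- function(network) {
  if (inherits(network, "functional_network")) {
    n <- network$n_regions
    regions <- network$regions
  } else {
    n <- as.integer(network)
    if (!.is_count(n) || n < 2L) stop("need at least 2 regions")
    regions <- sprintf("region_%03d", seq_len(n) - 1L)
  }
  pairs <- t(utils::combn(n, 2L)) - 1L  # 0-based, lexicographic by combn
  ne <- nrow(pairs)
  # Vertices sharing region r form a clique among themselves in the dual.
  by_region <- lapply(seq_len(n) - 1L,
                      function(r) which(pairs[, 1L] == r | pairs[, 2L] == r))
  adjacency <- vector("list", ne)
  for (v in seq_len(ne)) {
    nb <- c(by_region[[pairs[v, 1L] + 1L]], by_region[[pairs[v, 2L] + 1L]])
    adjacency[[v]] <- sort(unique(nb[nb != v]))
  }
  n_links <- sum(lengths(adjacency)) / 2L
  structure(list(n_regions = n,
                 pairs = pairs,
                 vertex_names = paste0(regions[pairs[, 1L] + 1L], "--",
                                       regions[pairs[, 2L] + 1L]),
                 adjacency = adjacency,
                 n_links = as.integer(n_links),
                 regions = regions),
            class = "edge_dual")
}

#' @export
print.edge_dual <- function(x, ...) {
  cat(sprintf("Edge-dual graph: %d regions -> %d vertices, %d links\n",
              x$n_regions, nrow(x$pairs), x$n_links))
  invisible(x)
}

#' Combinatorial Laplacian of an edge-dual graph
#'
#' `C = degree - adjacency` over dual vertices; row sums are zero and the
#' matrix is positive semidefinite. Used as the topology penalty of the
#' sub-network learning objective.
#'
#' @param dual an `edge_dual`.
#' @return a dense symmetric |E| x |E| matrix.
#' @export
dual_laplacian <- function(dual) {
  stopifnot(inherits(dual, "edge_dual"))
  ne <- nrow(dual$pairs)
  C <- matrix(0, ne, ne)
  for (v in seq_len(ne)) C[v, dual$adjacency[[v]]] <- -1
  diag(C) <- lengths(dual$adjacency)
  C
}

#' Vertex values of a network under the dual's canonical order
#'
#' @param network a `functional_network` built over the same region set as
#'   `dual`.
#' @param dual an `edge_dual`.
#' @return numeric vector of length |E|: `v[k]` is the coherence of the k-th
#'   region pair.
#' @export
vertex_values <- function(network, dual) {
  stopifnot(inherits(network, "functional_network"), inherits(dual, "edge_dual"))
  if (network$n_regions != dual$n_regions)
    stop(sprintf("region-set mismatch: network has %d regions, dual %d",
                 network$n_regions, dual$n_regions))
  network$coherence[cbind(dual$pairs[, 1L] + 1L, dual$pairs[, 2L] + 1L)]
}

#' Connected components of a dual vertex subset
#'
#' Partitions a set of dual vertices into maximal link-connected components.
#' Mapped back to region pairs, each component is a connected edge set of the
#' original functional network.
#'
#' @param vertex_subset integer vector of 1-based dual vertex ids.
#' @param dual an `edge_dual`.
#' @return a list of sorted integer vectors (one per component), ordered by
#'   decreasing size then by smallest vertex id.
#' @export
dual_connected_components <- function(vertex_subset, dual) {
  stopifnot(inherits(dual, "edge_dual"))
  vs <- sort(unique(as.integer(vertex_subset)))
  if (!length(vs)) return(list())
  if (any(vs < 1L) || any(vs > nrow(dual$pairs)))
    stop("unknown vertex id(s): ",
         paste(vs[vs < 1L | vs > nrow(dual$pairs)], collapse = ", "))
  in_set <- logical(nrow(dual$pairs))
  in_set[vs] <- TRUE
  seen <- logical(nrow(dual$pairs))
  comps <- list()
  for (v in vs) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, u)
      nb <- dual$adjacency[[u]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  ord <- order(-lengths(comps), vapply(comps, min, integer(1)))
  comps[ord]
}

# TRUE iff the vertex set is link-connected in the dual.
.dual_is_connected <- function(vs, dual) {
  length(dual_connected_components(vs, dual)) <= 1L
}

#' Export dual subgraphs to GraphML
#'
#' Writes the given dual vertex sets as a graph over brain regions (vertices
#' labeled with region names, edges are the functional edges of the sets).
#'
#' @param vertex_sets list of dual vertex id vectors.
#' @param dual an `edge_dual`.
#' @param atlas an `atlas_table` providing region names.
#' @param path output GraphML path.
#' @export
write_dual_graphml <- function(vertex_sets, dual, atlas, path) {
  stopifnot(inherits(dual, "edge_dual"), inherits(atlas, "atlas_table"))
  verts <- sort(unique(unlist(vertex_sets)))
  if (length(verts)) {
    prs <- dual$pairs[verts, , drop = FALSE]
    rids <- sort(unique(as.integer(prs)))
  } else {
    prs <- matrix(integer(0), 0L, 2L)
    rids <- integer(0)
  }
  names_ <- .region_name(atlas, rids)
  g <- igraph::make_empty_graph(n = length(rids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = names_)
  g <- igraph::set_vertex_attr(g, "region_id", value = rids)
  if (nrow(prs)) {
    ep <- rbind(match(prs[, 1L], rids), match(prs[, 2L], rids))
    g <- igraph::add_edges(g, as.vector(ep))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
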