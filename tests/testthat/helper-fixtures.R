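# Shared fixtures, memoized so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fx, inherits = FALSE))
    assign(key, builder(), envir = .fx)
  get(key, envir = .fx, inherits = FALSE)
}

# Small direct-mode study: 8 regions, 9 sessions/class, planted star 0-1,1-2,1-3.
small_study <- function(seed = 2) {
  memo(paste0("study8_", seed), function()
    generate_study(plant_spec(n_regions = 8L, n_sessions_per_class = 9L,
                              rng_seed = seed)))
}

small_V <- function(seed = 2) {
  st <- small_study(seed)
  dual <- to_edge_dual(8L)
  vapply(st$networks, vertex_values, numeric(nrow(dual$pairs)), dual = dual)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Independent edge-connectivity oracle: partition a set of dual vertices
# (functional edges) into connected edge sets using igraph on the ORIGINAL
# region graph, bypassing the package's dual adjacency entirely.
igraph_edge_components <- function(vertex_subset, dual) {
  if (!length(vertex_subset)) return(list())
  prs <- dual$pairs[vertex_subset, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(prs[, 1] + 1, prs[, 2] + 1),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  grp <- split(seq_along(vertex_subset), comp[prs[, 1] + 1])
  comps <- lapply(grp, function(i) sort(vertex_subset[i]))
  names(comps) <- NULL
  comps[order(-lengths(comps), vapply(comps, min, integer(1)))]
}

# Exhaustive enumeration of connected k-subsets of dual vertices.
enumerate_connected_sets <- function(dual, k) {
  ne <- nrow(dual$pairs)
  cmb <- utils::combn(ne, k)
  keep <- apply(cmb, 2, function(vs)
    length(igraph_edge_components(vs, dual)) == 1L)
  lapply(which(keep), function(j) cmb[, j])
}

set_key <- function(vs) paste(sort(vs), collapse = ",")
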