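# Spiral neighborhoods: for each vertex an ordered sequence of neighbors
# (the vertex, its one-ring ordered counter-clockwise by face winding
# starting from the smallest-index neighbor, then outward rings) truncated
# or zero-padded to a fixed length. Determined entirely by topology.

# Directed one-ring successor maps: for every vertex v, face (v,a,b) (in
# winding order at corner v) contributes link edge a->b. On a closed
# manifold these edges form one cycle per vertex.
vertex_link_cycles <- function(faces, n_vertices) {
  links <- vector("list", n_vertices)
  for (corner in 1:3) {
    v <- faces[, corner]
    a <- faces[, corner %% 3 + 1]
    b <- faces[, (corner + 1) %% 3 + 1]
    for (i in seq_along(v))
      links[[v[i]]] <- rbind(links[[v[i]]], c(a[i], b[i]))
  }
  lapply(seq_len(n_vertices), function(v) {
    le <- links[[v]]
    if (is.null(le)) stop2("vertex %d is isolated", v)
    if (anyDuplicated(le[, 1]) || anyDuplicated(le[, 2]))
      stop2("non-manifold vertex %d", v)
    succ <- integer(max(le)); succ[le[, 1]] <- le[, 2]
    start <- min(le[, 1])
    ring <- integer(nrow(le))
    cur <- start
    for (k in seq_len(nrow(le))) {
      ring[k] <- cur
      cur <- succ[cur]
      if (cur == 0L) stop2("non-manifold vertex %d (open or broken link)", v)
    }
    if (cur != start) stop2("non-manifold vertex %d (link is not one cycle)", v)
    ring
  })
}

#' Build spiral neighbor sequences for a mesh
#'
#' @param faces Triangle faces (n_faces x 3, 1-based) or a `mesh_topology`.
#' @param n_vertices Number of vertices (ignored when a topology is given).
#' @param L Spiral length; sequences shorter than `L` (exhausted
#'   neighborhoods) are padded with 0.
#' @return Integer matrix (n_vertices x L); first column is the vertex
#'   itself; 0 marks padding.
#' @export
build_spiral_indexing <- function(faces, n_vertices = max(faces), L = 9L) {
  if (inherits(faces, "mesh_topology")) {
    n_vertices <- faces$n_vertices
    faces <- faces$faces
  }
  rings1 <- vertex_link_cycles(faces, n_vertices)
  out <- matrix(0L, n_vertices, L)
  for (v in seq_len(n_vertices)) {
    spiral <- c(v, rings1[[v]])
    seen <- rep(FALSE, n_vertices)
    seen[spiral] <- TRUE
    frontier <- rings1[[v]]
    while (length(spiral) < L && length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        cand <- rings1[[u]]
        cand <- cand[!seen[cand]]
        if (length(cand)) {
          seen[cand] <- TRUE
          nxt <- c(nxt, cand)
        }
      }
      spiral <- c(spiral, nxt)
      frontier <- nxt
    }
    out[v, ] <- c(spiral, integer(L))[seq_len(L)]
  }
  out
}
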