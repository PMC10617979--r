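# Mesh and population data model: fixed-topology triangle meshes in dense
# point correspondence, per-vertex attribute segmentations, train/val/test
# splits and template standardization statistics.

#' Derive the undirected edge list of a triangle mesh
#'
#' Each undirected edge appears exactly once, with the smaller vertex index
#' first; rows are sorted lexicographically.
#'
#' @param faces Integer matrix (n_faces x 3) of 1-based vertex indices.
#' @return Integer matrix (n_edges x 2).
#' @export
edges_from_faces <- function(faces) {
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Construct a validated mesh topology
#'
#' A `mesh_topology` is the invariant backbone of the pipeline: faces, the
#' induced undirected edge set, and (optionally) a hard partition of vertices
#' into anatomical attributes. All meshes of a population share one topology.
#'
#' @param faces Integer matrix (n_faces x 3), 1-based vertex indices.
#' @param n_vertices Number of vertices; defaults to `max(faces)`.
#' @param attribute_labels Optional integer vector of length `n_vertices`
#'   with labels in `1..n_attributes` (0-based label files are shifted on
#'   read, see [read_segmentation()]). Every vertex has exactly one label and
#'   each attribute subgraph must be non-empty and connected.
#' @param validate If `FALSE`, skip the (quadratic-free but not free)
#'   connectivity checks. Used internally on already-validated topologies.
#' @return An object of class `mesh_topology` with fields `n_vertices`,
#'   `faces`, `edges`, `attribute_labels`, `n_attributes`.
#' @export
mesh_topology <- function(faces, n_vertices = max(faces),
                          attribute_labels = NULL, validate = TRUE) {
  faces <- matrix(as.integer(faces), ncol = 3)
  if (validate) {
    if (any(faces < 1L) || any(faces > n_vertices))
      stop2("face indices out of range [1, %d]", n_vertices)
    dg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(dg))
      stop2("degenerate face with repeated vertex indices (face %d)",
            which(dg)[1])
  }
  edges <- edges_from_faces(faces)
  topo <- structure(
    list(n_vertices = as.integer(n_vertices), faces = faces, edges = edges,
         attribute_labels = NULL, n_attributes = 0L),
    class = "mesh_topology"
  )
  if (validate) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n_vertices)
      g <- igraph::add_vertices(g, n_vertices - igraph::vcount(g))
    if (!igraph::is_connected(g))
      stop2("mesh graph is not connected")
  }
  if (!is.null(attribute_labels))
    topo <- set_attribute_labels(topo, attribute_labels, validate = validate)
  topo
}

#' Attach a per-vertex attribute segmentation to a topology
#'
#' @param topology A `mesh_topology`.
#' @param labels Integer vector, one label per vertex, values in
#'   `1..n_attributes` (labels starting at 0 are shifted up by one).
#' @param validate Check partition and per-attribute connectivity.
#' @return The topology with `attribute_labels` and `n_attributes` set.
#' @export
set_attribute_labels <- function(topology, labels, validate = TRUE) {
  labels <- as.integer(labels)
  if (length(labels) != topology$n_vertices)
    stop2("expected %d labels, got %d", topology$n_vertices, length(labels))
  if (min(labels) == 0L) labels <- labels + 1L
  nf <- max(labels)
  if (validate) {
    if (any(is.na(labels)) || any(labels < 1L))
      stop2("attribute labels must be non-missing positive integers")
    if (!setequal(unique(labels), seq_len(nf)))
      stop2("attribute labels must use every value in 1..%d", nf)
    for (w in seq_len(nf)) {
      vs <- which(labels == w)
      sub <- topology$edges[labels[topology$edges[, 1]] == w &
                              labels[topology$edges[, 2]] == w, ,
                            drop = FALSE]
      if (length(vs) == 0L) stop2("attribute %d has no vertices", w)
      if (length(vs) > 1L) {
        remap <- integer(topology$n_vertices); remap[vs] <- seq_along(vs)
        g <- igraph::graph_from_edgelist(
          cbind(remap[sub[, 1]], remap[sub[, 2]]), directed = FALSE)
        if (igraph::vcount(g) < length(vs))
          g <- igraph::add_vertices(g, length(vs) - igraph::vcount(g))
        if (!igraph::is_connected(g))
          stop2("attribute %d subgraph is not connected", w)
      }
    }
  }
  topology$attribute_labels <- labels
  topology$n_attributes <- as.integer(nf)
  topology
}

#' Vertex index sets of each attribute
#' @param topology A labelled `mesh_topology`.
#' @return List of integer vectors, one per attribute.
#' @export
attribute_vertices <- function(topology) {
  if (is.null(topology$attribute_labels))
    stop2("topology has no attribute labels")
  lapply(seq_len(topology$n_attributes),
         function(w) which(topology$attribute_labels == w))
}

# Fingerprint used to verify that bases/checkpoints refer to one topology.
topology_hash <- function(topology) {
  content_hash(topology$n_vertices, as.vector(topology$faces),
               topology$attribute_labels %||% integer(0))
}

same_topology <- function(a, b) {
  identical(dim(a$faces), dim(b$faces)) && all(a$faces == b$faces) &&
    a$n_vertices == b$n_vertices
}

#' Assemble corresponded meshes into a shape population
#'
#' All meshes must share one topology (identical faces); vertices are stacked
#' into an `n_shapes x N x 3` array and split into train/validation/test
#' subsets by a seeded shuffle.
#'
#' @param meshes List of meshes, each a list with `vertices` (N x 3) and
#'   `faces`, e.g. as returned by [read_mesh()]; alternatively an
#'   `n x N x 3` array together with `topology`.
#' @param topology Optional `mesh_topology` to validate against (required if
#'   `meshes` is an array).
#' @param fractions Numeric length-3 train/val/test fractions summing to 1.
#' @param seed Seed for the split shuffle.
#' @return A `shape_population`: `topology`, `vertices` (n x N x 3), `split`
#'   (character vector "train"/"val"/"test").
#' @export
shape_population <- function(meshes, topology = NULL,
                             fractions = c(0.9, 0.05, 0.05), seed = 1L) {
  if (is.array(meshes) && length(dim(meshes)) == 3) {
    if (is.null(topology)) stop2("array input requires an explicit topology")
    verts <- meshes
  } else {
    if (length(meshes) < 1L) stop2("need at least one mesh")
    if (is.null(topology))
      topology <- mesh_topology(meshes[[1]]$faces,
                                n_vertices = nrow(meshes[[1]]$vertices))
    for (i in seq_along(meshes)) {
      f <- matrix(as.integer(meshes[[i]]$faces), ncol = 3)
      if (!identical(dim(f), dim(topology$faces)) || any(f != topology$faces)) {
        bad <- if (identical(dim(f), dim(topology$faces)))
          which(rowSums(f != topology$faces) > 0)[1] else 1L
        stop2("mesh %d is not in correspondence: face %d differs from the shared topology",
              i, bad)
      }
      if (nrow(meshes[[i]]$vertices) != topology$n_vertices)
        stop2("mesh %d has %d vertices, expected %d", i,
              nrow(meshes[[i]]$vertices), topology$n_vertices)
    }
    n <- length(meshes)
    verts <- array(0, c(n, topology$n_vertices, 3))
    for (i in seq_len(n)) verts[i, , ] <- as.matrix(meshes[[i]]$vertices)
  }
  n <- dim(verts)[1]
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    stop2("split fractions must be non-negative and sum to 1")
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  n_te <- n - n_tr - n_va
  if (n_te < 0) { n_va <- n_va + n_te; n_te <- 0 }
  ord <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[ord[seq_len(n_tr)]] <- "train"
  if (n_va > 0) split[ord[n_tr + seq_len(n_va)]] <- "val"
  if (n_te > 0) split[ord[n_tr + n_va + seq_len(n_te)]] <- "test"
  structure(list(topology = topology, vertices = verts, split = split),
            class = "shape_population")
}

#' @export
print.shape_population <- function(x, ...) {
  cat(sprintf("shape_population: %d shapes, %d vertices, %d faces (%s)\n",
              dim(x$vertices)[1], x$topology$n_vertices,
              nrow(x$topology$faces),
              paste(sprintf("%s=%d", c("train", "val", "test"),
                            c(sum(x$split == "train"), sum(x$split == "val"),
                              sum(x$split == "test"))), collapse = ", ")))
  invisible(x)
}

#' Subset of population vertex arrays by split tag
#' @param pop A `shape_population`.
#' @param split One of "train", "val", "test", or "all".
#' @return An `n x N x 3` array.
#' @export
population_vertices <- function(pop, split = "all") {
  if (split == "all") return(pop$vertices)
  pop$vertices[pop$split == split, , , drop = FALSE]
}

#' Area-weighted vertex normals of a mesh
#'
#' Face normals (cross products, magnitude proportional to face area) are
#' accumulated onto their vertices and the result normalized row-wise.
#' Orientation follows the face winding.
#'
#' @param vertices N x 3 matrix.
#' @param faces n_faces x 3 integer matrix.
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, faces[, k])
    idx <- as.integer(rownames(acc))
    nrm[idx, ] <- nrm[idx, ] + acc
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

#' Template statistics of a training split
#'
#' Computes the per-vertex mean shape M, the per-vertex per-coordinate
#' standard deviation Sigma (sample sd, floored at `eps` so rigid regions do
#' not blow up standardization), and unit vertex normals of the mean mesh.
#' Normals are computed once on M and frozen; they define the sign of the
#' signed-distance descriptor.
#'
#' @param pop A `shape_population` (statistics use only the train split).
#' @param eps Positive floor for Sigma, in template units.
#' @return A `template_stats` object: `mean` (N x 3), `sd` (N x 3),
#'   `normals` (N x 3), `eps`, `n_train`.
#' @export
compute_template_stats <- function(pop, eps = 1e-8) {
  tr <- population_vertices(pop, "train")
  n <- dim(tr)[1]
  if (n < 2) stop2("need at least 2 training shapes for a standard deviation")
  N <- dim(tr)[2]
  M <- apply(tr, c(2, 3), mean)
  S <- apply(tr, c(2, 3), stats::sd)
  S <- pmax(S, eps)
  nrm <- vertex_normals(M, pop$topology$faces)
  structure(list(mean = M, sd = S, normals = nrm, eps = eps, n_train = n),
            class = "template_stats")
}

#' Standardize vertex coordinates against template statistics
#'
#' Elementwise `(X - M) / Sigma`. The inverse, [destandardize()], recovers X
#' exactly up to floating point.
#'
#' @param X N x 3 vertex matrix (or n x N x 3 array).
#' @param stats A `template_stats`.
#' @return Standardized array of the same shape.
#' @export
standardize <- function(X, stats) {
  if (length(dim(X)) == 3) {
    out <- X
    for (i in seq_len(dim(X)[1])) out[i, , ] <- (X[i, , ] - stats$mean) / stats$sd
    return(out)
  }
  if (!all(dim(X) == dim(stats$mean))) stop2("vertex array does not match template")
  (X - stats$mean) / stats$sd
}

#' @rdname standardize
#' @export
destandardize <- function(X, stats) {
  if (length(dim(X)) == 3) {
    out <- X
    for (i in seq_len(dim(X)[1])) out[i, , ] <- X[i, , ] * stats$sd + stats$mean
    return(out)
  }
  X * stats$sd + stats$mean
}
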