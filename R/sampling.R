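# Mesh hierarchy by quadric-error edge collapse, with fixed (non-learned)
# down/up transformation matrices: down-sampling selects kept vertices,
# up-sampling maps removed vertices to barycentric coordinates in their
# nearest coarse face. Deterministic under a fixed tie-breaking rule.

# 4x4 error quadric of a plane through triangle (p1,p2,p3).
face_quadric <- function(p1, p2, p3) {
  n <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
         (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
         (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
  ln <- sqrt(sum(n^2))
  if (ln < 1e-14) return(matrix(0, 4, 4))
  n <- n / ln
  p <- c(n, -sum(n * p1))
  outer(p, p)
}

quadric_cost <- function(Q, v) {
  p <- c(v, 1)
  as.numeric(p %*% Q %*% p)
}

# Collapse edges until `target` vertices remain. Kept vertices stay at their
# original positions (vertex subset scheme). Returns kept ids (original
# indexing, sorted), coarse faces (coarse indexing), and the fine->coarse
# vertex map for kept vertices.
quadric_decimate <- function(vertices, faces, target) {
  n <- nrow(vertices)
  if (target >= n) stop2("target must be below the current vertex count")
  Q <- vector("list", n)
  for (v in seq_len(n)) Q[[v]] <- matrix(0, 4, 4)
  for (i in seq_len(nrow(faces))) {
    fq <- face_quadric(vertices[faces[i, 1], ], vertices[faces[i, 2], ],
                       vertices[faces[i, 3], ])
    for (k in 1:3) Q[[faces[i, k]]] <- Q[[faces[i, k]]] + fq
  }
  adj <- vector("list", n)
  e <- edges_from_faces(faces)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  alive <- rep(TRUE, n)
  fc <- faces
  f_alive <- rep(TRUE, nrow(fc))
  n_alive <- n

  edge_cost <- function(a, b) {
    Qs <- Q[[a]] + Q[[b]]
    ca <- quadric_cost(Qs, vertices[a, ])
    cb <- quadric_cost(Qs, vertices[b, ])
    if (ca <= cb) c(ca, a, b) else c(cb, b, a)  # (cost, keep, drop)
  }

  # cost table over alive edges, refreshed incrementally
  emat <- e
  costs <- t(apply(emat, 1, function(r) edge_cost(r[1], r[2])))
  e_alive <- rep(TRUE, nrow(emat))

  while (n_alive > target) {
    ok <- which(e_alive)
    if (!length(ok)) stop2("edge collapse stalled before reaching %d vertices",
                           target)
    # lowest cost; ties broken by lexicographic edge index
    oc <- costs[ok, 1]
    best <- ok[order(oc, emat[ok, 1], emat[ok, 2])[1]]
    a <- emat[best, 1]; b <- emat[best, 2]
    keep <- as.integer(costs[best, 2]); drop <- as.integer(costs[best, 3])
    # link condition: shared neighbors must be exactly the two opposite
    # vertices of the edge's two incident faces
    common <- intersect(adj[[a]], adj[[b]])
    if (length(common) != 2 || length(adj[[keep]]) + length(adj[[drop]]) - 4 < 3) {
      e_alive[best] <- FALSE  # illegal now; may become legal later, re-add
      next
    }
    # collapse: drop -> keep
    alive[drop] <- FALSE
    n_alive <- n_alive - 1
    Q[[keep]] <- Q[[keep]] + Q[[drop]]
    # faces: remap and kill degenerate
    touch <- which(f_alive & (fc[, 1] == drop | fc[, 2] == drop | fc[, 3] == drop))
    fc[touch, ][fc[touch, ] == drop] <- keep
    dg <- touch[fc[touch, 1] == fc[touch, 2] | fc[touch, 2] == fc[touch, 3] |
                  fc[touch, 1] == fc[touch, 3]]
    f_alive[dg] <- FALSE
    # adjacency
    nbrs <- setdiff(adj[[drop]], c(keep))
    for (u in nbrs) {
      adj[[u]] <- setdiff(adj[[u]], drop)
      if (!(keep %in% adj[[u]])) adj[[u]] <- c(adj[[u]], keep)
    }
    adj[[keep]] <- sort(unique(c(setdiff(adj[[keep]], drop), nbrs)))
    adj[[drop]] <- integer(0)
    # retire edges touching drop; add/update edges of keep
    dead <- which(e_alive & (emat[, 1] == drop | emat[, 2] == drop))
    e_alive[dead] <- FALSE
    for (u in adj[[keep]]) {
      r <- c(min(keep, u), max(keep, u))
      hit <- which(e_alive & emat[, 1] == r[1] & emat[, 2] == r[2])
      if (length(hit)) {
        costs[hit[1], ] <- edge_cost(r[1], r[2])
      } else {
        emat <- rbind(emat, r)
        costs <- rbind(costs, edge_cost(r[1], r[2]))
        e_alive <- c(e_alive, TRUE)
      }
    }
  }
  kept <- which(alive)
  remap <- integer(n); remap[kept] <- seq_along(kept)
  cfaces <- fc[f_alive, , drop = FALSE]
  cfaces <- matrix(remap[cfaces], ncol = 3)
  cfaces <- unique(cfaces)
  list(kept = kept, faces = cfaces, remap = remap)
}

# Closest point on triangle (p1,p2,p3) to point p; returns barycentric
# coordinates (w1,w2,w3) and squared distance. Ericson's method.
closest_point_triangle <- function(p, p1, p2, p3) {
  ab <- p2 - p1; ac <- p3 - p1; ap <- p - p1
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(list(bary = c(1, 0, 0), pt = p1))
  bp <- p - p2
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(list(bary = c(0, 1, 0), pt = p2))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(list(bary = c(1 - v, v, 0), pt = p1 + v * ab))
  }
  cp <- p - p3
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(list(bary = c(0, 0, 1), pt = p3))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(list(bary = c(1 - w, 0, w), pt = p1 + w * ac))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(list(bary = c(0, 1 - w, w), pt = p2 + w * (p3 - p2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  list(bary = c(1 - v - w, v, w), pt = p1 + ab * v + ac * w)
}

#' Build the fixed mesh-sampling hierarchy
#'
#' Each level halves-and-more the vertex count by quadric-error edge
#' collapse (to `ceiling(n / factor)` vertices), producing a row-stochastic
#' down-transform (coarse vertex = selected fine vertex) and an up-transform
#' mapping removed fine vertices to clamped barycentric coordinates in their
#' nearest coarse face (template geometry). The transforms are fixed and
#' shared by all networks built on one topology.
#'
#' @param topology A `mesh_topology` (full resolution).
#' @param vertices Template vertex positions used for collapse costs and
#'   barycentric placement.
#' @param factor Down-sampling factor per level (> 1).
#' @param levels Number of coarsening levels.
#' @return List with `sizes` (vertex counts per level, full first), `faces`
#'   (faces per level), `down` and `up` (lists of sparse matrices).
#' @export
build_sampling_transforms <- function(topology, vertices, factor = 4,
                                      levels = 3L) {
  if (factor <= 1) stop2("factor must exceed 1")
  sizes <- topology$n_vertices
  faces_l <- list(topology$faces)
  down <- list(); up <- list()
  cur_faces <- topology$faces
  cur_verts <- vertices
  for (l in seq_len(levels)) {
    n1 <- nrow(cur_verts)
    target <- ceiling(n1 / factor)
    dec <- quadric_decimate(cur_verts, cur_faces, target)
    n2 <- length(dec$kept)
    D <- Matrix::sparseMatrix(i = seq_len(n2), j = dec$kept, x = 1,
                              dims = c(n2, n1))
    coarse_verts <- cur_verts[dec$kept, , drop = FALSE]
    # up transform: kept -> identity; removed -> barycentric in nearest face
    removed <- setdiff(seq_len(n1), dec$kept)
    ui <- seq_len(n1)[dec$kept]; uj <- seq_len(n2); ux <- rep(1, n2)
    ui <- dec$kept; # rows are fine indices
    if (length(removed)) {
      for (v in removed) {
        p <- cur_verts[v, ]
        d2v <- colSums((t(coarse_verts) - p)^2)
        nearest <- which.min(d2v)
        cand <- which(dec$faces[, 1] == nearest | dec$faces[, 2] == nearest |
                        dec$faces[, 3] == nearest)
        if (!length(cand)) cand <- seq_len(min(nrow(dec$faces), 20))
        best <- NULL; bestd <- Inf
        for (fi in cand) {
          tri <- dec$faces[fi, ]
          cp <- closest_point_triangle(p, coarse_verts[tri[1], ],
                                       coarse_verts[tri[2], ],
                                       coarse_verts[tri[3], ])
          d <- sum((p - cp$pt)^2)
          if (d < bestd) { bestd <- d; best <- list(tri = tri, bary = cp$bary) }
        }
        ui <- c(ui, rep(v, 3)); uj <- c(uj, best$tri); ux <- c(ux, best$bary)
      }
    }
    U <- Matrix::sparseMatrix(i = ui, j = uj, x = ux, dims = c(n1, n2))
    down[[l]] <- D; up[[l]] <- U
    sizes <- c(sizes, n2)
    faces_l[[l + 1]] <- dec$faces
    cur_faces <- dec$faces
    cur_verts <- coarse_verts
  }
  list(sizes = sizes, faces = faces_l, down = down, up = up)
}
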