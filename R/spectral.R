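# Combinatorial Laplacians, per-attribute graph Fourier bases, signed
# distances from the template mean, high-variance basis selection, and the
# local eigenprojection (LE) loss.

#' Kirchhoff graph Laplacian K = D - A
#'
#' Determined only by connectivity: symmetric, positive semidefinite, rows
#' summing to zero.
#'
#' @param edges Integer matrix (n_edges x 2) of undirected edges (1-based),
#'   or a `mesh_topology`.
#' @param n_vertices Number of vertices (ignored when a topology is given).
#' @return A sparse symmetric `Matrix`.
#' @export
kirchhoff_laplacian <- function(edges, n_vertices = max(edges)) {
  if (inherits(edges, "mesh_topology")) {
    n_vertices <- edges$n_vertices
    edges <- edges$edges
  }
  if (is.null(dim(edges)) || nrow(edges) == 0)
    stop2("empty graph: no edges")
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n_vertices, n_vertices))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(x = deg) - A
}

#' Tutte Laplacian T = I - D^-1 A
#'
#' Row-stochastic-neighbour smoothing operator; rows sum to zero. Used as the
#' smoothing regularizer on generated meshes.
#'
#' @inheritParams kirchhoff_laplacian
#' @return A sparse `Matrix`.
#' @export
tutte_laplacian <- function(edges, n_vertices = max(edges)) {
  if (inherits(edges, "mesh_topology")) {
    n_vertices <- edges$n_vertices
    edges <- edges$edges
  }
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n_vertices, n_vertices))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) stop2("vertex %d has degree zero", which(deg == 0)[1])
  Matrix::Diagonal(n_vertices) - Matrix::Diagonal(x = 1 / deg) %*% A
}

# Kirchhoff Laplacian of the subgraph induced by an attribute's vertices.
attribute_laplacian <- function(topology, vs) {
  remap <- integer(topology$n_vertices)
  remap[vs] <- seq_along(vs)
  e <- topology$edges
  keep <- remap[e[, 1]] > 0 & remap[e[, 2]] > 0
  sub <- cbind(remap[e[keep, 1]], remap[e[keep, 2]])
  kirchhoff_laplacian(sub, n_vertices = length(vs))
}

#' Eigenbasis of a Kirchhoff Laplacian (graph Fourier modes)
#'
#' Dense symmetric eigendecomposition with eigenvalues in ascending order and
#' a deterministic sign/ordering convention: in each eigenvector the entry of
#' largest absolute value (ties broken by lowest index) is made positive, and
#' within a numerically degenerate eigenspace vectors are ordered by the
#' index of that largest-magnitude entry.
#'
#' @param K Symmetric PSD matrix (sparse or dense).
#' @param k_modes Number of leading (low-frequency) modes to return.
#' @param tol Relative tolerance grouping degenerate eigenvalues.
#' @return List with `vectors` (N x k_modes, orthonormal) and `values`
#'   (ascending).
#' @export
eigenbasis <- function(K, k_modes = nrow(K), tol = 1e-8) {
  n <- nrow(K)
  if (k_modes > n) stop2("k_modes (%d) exceeds matrix size (%d)", k_modes, n)
  es <- eigen(as.matrix(K), symmetric = TRUE)
  vals <- rev(es$values)
  vecs <- es$vectors[, n:1, drop = FALSE]
  anchor <- apply(vecs, 2, function(v) which.max(abs(v)))
  # stable order inside degenerate eigenspaces, then fix signs
  scale <- max(abs(vals), 1)
  grp <- cumsum(c(TRUE, diff(vals) > tol * scale))
  ord <- order(grp, anchor)
  vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]; anchor <- anchor[ord]
  sgn <- sign(vecs[cbind(anchor, seq_len(ncol(vecs)))])
  sgn[sgn == 0] <- 1
  vecs <- sweep(vecs, 2, sgn, "*")
  list(vectors = vecs[, seq_len(k_modes), drop = FALSE],
       values = vals[seq_len(k_modes)])
}

#' Signed distance of mesh vertices from the template mean
#'
#' Per vertex, the Euclidean distance to the corresponding mean-template
#' vertex, signed by the dot product of the displacement with the frozen
#' template normal: `sd_i = sign(<X_i - M_i, N_i>) * ||X_i - M_i||`.
#' For standardized input the equivalent form
#' `sd_i = sign(<X_i * Sigma_i, N_i>) * ||X_i * Sigma_i||` is used;
#' `sign(0)` is taken as +1.
#'
#' @param X N x 3 vertex matrix (raw or standardized coordinates).
#' @param stats A `template_stats`.
#' @param standardized Set `TRUE` when `X` is already standardized.
#' @return Numeric vector of length N (template units).
#' @export
signed_distance <- function(X, stats, standardized = FALSE) {
  if (!all(dim(X) == dim(stats$mean)))
    stop2("vertex array does not match the template")
  D <- if (standardized) X * stats$sd else X - stats$mean
  s <- rowSums(D * stats$normals)
  g <- ifelse(s >= 0, 1, -1)
  g * sqrt(rowSums(D^2))
}

#' Fit the per-attribute high-variance spectral basis
#'
#' For each attribute, the training shapes' local signed distances are
#' projected onto the `k_modes` lowest-frequency eigenvectors of the
#' attribute's Kirchhoff Laplacian; the `kappa` components with the highest
#' projection variance over the training split are selected (ties broken by
#' lower eigenvalue index; the constant mode is eligible). The mean and
#' standard deviation of the selected projections are stored so that
#' projections of training shapes standardize to mean 0, sd 1.
#'
#' @param pop A `shape_population` with a labelled topology.
#' @param stats `template_stats` of the same training split.
#' @param kappa Latent variables per attribute.
#' @param k_modes Candidate modes per attribute (default `10 * kappa`,
#'   capped at the attribute size).
#' @param use_standardized Project signed distances computed from
#'   standardized coordinates (the two forms agree; kept as a switch for
#'   inspection).
#' @param s_floor Floor for projection standard deviations; components at the
#'   floor trigger a warning.
#' @return A `spectral_basis` object.
#' @export
fit_spectral_basis <- function(pop, stats, kappa, k_modes = 10L * kappa,
                               use_standardized = TRUE, s_floor = 1e-8) {
  topo <- pop$topology
  if (is.null(topo$attribute_labels))
    stop2("population topology has no attribute labels")
  avs <- attribute_vertices(topo)
  k_modes <- min(k_modes, min(lengths(avs)))
  if (kappa > k_modes)
    stop2("kappa (%d) exceeds candidate modes (%d)", kappa, k_modes)
  tr <- population_vertices(pop, "train")
  n_tr <- dim(tr)[1]
  # signed distances of every training shape (n_train x N)
  sd_mat <- t(vapply(seq_len(n_tr), function(i) {
    Xi <- tr[i, , ]
    if (use_standardized)
      signed_distance(standardize(Xi, stats), stats, standardized = TRUE)
    else signed_distance(Xi, stats)
  }, numeric(topo$n_vertices)))
  attrs <- vector("list", length(avs))
  for (w in seq_along(avs)) {
    vs <- avs[[w]]
    Kw <- attribute_laplacian(topo, vs)
    eb <- eigenbasis(Kw, k_modes)
    P <- sd_mat[, vs, drop = FALSE] %*% eb$vectors      # n_train x k_modes
    v <- apply(P, 2, stats::var)
    sel <- order(-v, seq_along(v))[seq_len(kappa)]
    sel <- sort(sel)                                    # keep spectral order
    m <- colMeans(P[, sel, drop = FALSE])
    s <- apply(P[, sel, drop = FALSE], 2, stats::sd)
    if (any(s <= s_floor))
      warning(sprintf("attribute %d: %d selected component(s) have ~zero variance; flooring s at %g",
                      w, sum(s <= s_floor), s_floor))
    s <- pmax(s, s_floor)
    attrs[[w]] <- list(vertices = vs, U = eb$vectors[, sel, drop = FALSE],
                       selected = sel, eigenvalues = eb$values[sel],
                       m = m, s = s, variance = v[sel])
  }
  structure(list(attributes = attrs, kappa = as.integer(kappa),
                 k_modes = as.integer(k_modes),
                 n_attributes = length(avs),
                 use_standardized = use_standardized,
                 topology_hash = topology_hash(topo)),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("spectral_basis: %d attributes x kappa=%d (K=%d candidates)\n",
              x$n_attributes, x$kappa, x$k_modes))
  invisible(x)
}

basis_hash <- function(basis) {
  content_hash(basis$topology_hash, basis$kappa, basis$k_modes,
               unlist(lapply(basis$attributes, function(a) a$selected)))
}

# Standardized local eigenprojection of a signed-distance vector.
project_sd <- function(sdv, basis) {
  unlist(lapply(basis$attributes, function(a)
    (as.vector(crossprod(a$U, sdv[a$vertices])) - a$m) / a$s),
    use.names = FALSE)
}

#' Standardized local eigenprojection of a shape
#'
#' The length-`F * kappa` spectral descriptor: for each attribute, the signed
#' distances restricted to its vertices are projected onto the selected
#' Fourier modes and standardized by the training-set projection statistics.
#'
#' @param X N x 3 vertex matrix (raw coordinates unless
#'   `standardized = TRUE`).
#' @param basis A fitted `spectral_basis`.
#' @param stats Matching `template_stats`.
#' @param standardized Whether `X` is already standardized.
#' @return Numeric vector of length `n_attributes * kappa`.
#' @export
local_eigenprojection <- function(X, basis, stats, standardized = FALSE) {
  if (!inherits(basis, "spectral_basis")) stop2("basis is not fitted")
  sdv <- signed_distance(X, stats, standardized = standardized)
  project_sd(sdv, basis)
}

#' Local eigenprojection loss
#'
#' Mean absolute deviation between a latent code and the shape's standardized
#' local eigenprojection: the `1/(F*kappa)`-scaled sum over attributes of the
#' L1 norm of `z_w - z*_w(X)`.
#'
#' @param X N x 3 vertex matrix.
#' @param z Latent code of length `n_attributes * kappa`.
#' @inheritParams local_eigenprojection
#' @return Non-negative scalar.
#' @export
le_loss <- function(X, z, basis, stats, standardized = FALSE) {
  zs <- local_eigenprojection(X, basis, stats, standardized = standardized)
  if (length(z) != length(zs))
    stop2("latent length %d does not match basis (%d)", length(z), length(zs))
  mean(abs(z - zs))
}

# LE loss with gradients, on standardized coordinates (training path).
# Returns loss, d/dXstd (N x 3) and d/dz. The sign gamma and the selection
# are treated as locally constant (a.e. correct subgradient).
le_loss_grad <- function(Xstd, z, basis, stats) {
  Y <- Xstd * stats$sd                       # = X - M
  ip <- rowSums(Y * stats$normals)
  g <- ifelse(ip >= 0, 1, -1)
  nrmY <- sqrt(rowSums(Y^2))
  sdv <- g * nrmY
  zs <- project_sd(sdv, basis)
  r <- z - zs
  Fk <- length(zs)
  loss <- mean(abs(r))
  dz <- sign(r) / Fk
  # d loss / d sd = -(U/s) %*% dz per attribute block
  dsd <- numeric(nrow(Xstd))
  off <- 0
  for (a in basis$attributes) {
    k <- length(a$m)
    dzb <- dz[off + seq_len(k)]
    dsd[a$vertices] <- dsd[a$vertices] - as.vector(a$U %*% (dzb / a$s))
    off <- off + k
  }
  # d sd_i / d Y_i = g_i * Y_i / ||Y_i|| ; d Y / d Xstd = * Sigma
  safe <- pmax(nrmY, 1e-12)
  dY <- (dsd * g / safe) * Y
  dY[nrmY == 0, ] <- 0
  list(loss = loss, dX = dY * stats$sd, dz = dz)
}

#' Normality diagnostics of local eigenprojections
#'
#' Projects every shape of a split and tests each standardized component
#' against the standard normal with a Kolmogorov-Smirnov test. For neutral
#' shape populations the projections are expected to be approximately
#' Gaussian; multi-regime populations (e.g. expression mixtures) break
#' normality on the affected components.
#'
#' @param pop A `shape_population`.
#' @param basis A fitted `spectral_basis`.
#' @param stats `template_stats`.
#' @param split Which split to diagnose (default "train").
#' @return A data.frame with one row per component: attribute, mode index,
#'   mean, sd, KS statistic and p-value; the projection matrix is attached as
#'   attribute `"projections"`.
#' @export
projection_distribution_report <- function(pop, basis, stats,
                                           split = "train") {
  V <- population_vertices(pop, split)
  n <- dim(V)[1]
  if (n < 8) stop2("need more shapes for distribution diagnostics")
  P <- t(vapply(seq_len(n), function(i)
    local_eigenprojection(V[i, , ], basis, stats),
    numeric(basis$n_attributes * basis$kappa)))
  comp <- 0
  rows <- list()
  for (w in seq_len(basis$n_attributes)) {
    a <- basis$attributes[[w]]
    for (k in seq_len(length(a$m))) {
      comp <- comp + 1
      x <- P[, comp]
      ks <- suppressWarnings(stats::ks.test(x, "pnorm"))
      rows[[comp]] <- data.frame(
        component = comp, attribute = w, mode = a$selected[k],
        mean = mean(x), sd = stats::sd(x),
        ks_stat = unname(ks$statistic), ks_p = ks$p.value)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "projections") <- P
  attr(out, "histograms") <- lapply(seq_len(ncol(P)), function(k) {
    h <- graphics::hist(P[, k], breaks = 30, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  out
}

#' Save / load a fitted spectral basis
#'
#' The basis is persisted as a single JSON archive including kappa, the
#' candidate-mode count, selected indices and the topology hash, so training
#' and evaluation can verify they use the basis fitted on the same topology
#' and split.
#'
#' @param basis A `spectral_basis`.
#' @param path Output `.json` path.
#' @return `path` invisibly; `load_spectral_basis` returns the basis.
#' @export
save_spectral_basis <- function(basis, path) {
  obj <- list(
    kappa = basis$kappa, k_modes = basis$k_modes,
    n_attributes = basis$n_attributes,
    use_standardized = basis$use_standardized,
    topology_hash = basis$topology_hash,
    attributes = lapply(basis$attributes, function(a)
      list(vertices = a$vertices, U = as.vector(a$U), selected = a$selected,
           eigenvalues = a$eigenvalues, m = a$m, s = a$s,
           variance = a$variance))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_spectral_basis
#' @export
load_spectral_basis <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  attrs <- lapply(obj$attributes, function(a) {
    vs <- as.integer(unlist(a$vertices))
    list(vertices = vs,
         U = matrix(num(a$U), length(vs), as.integer(obj$kappa)),
         selected = as.integer(unlist(a$selected)),
         eigenvalues = num(a$eigenvalues),
         m = num(a$m), s = num(a$s), variance = num(a$variance))
  })
  structure(list(attributes = attrs, kappa = as.integer(obj$kappa),
                 k_modes = as.integer(obj$k_modes),
                 n_attributes = as.integer(obj$n_attributes),
                 use_standardized = obj$use_standardized,
                 topology_hash = obj$topology_hash),
            class = "spectral_basis")
}
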