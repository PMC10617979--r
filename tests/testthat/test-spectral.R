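# Combinatorial Laplacians, eigenbases, signed distances, high-variance
# basis selection and the local eigenprojection loss.

triangle_edges <- rbind(c(1, 2), c(2, 3), c(1, 3))
path_edges <- rbind(c(1, 2), c(2, 3))

test_that("Kirchhoff Laplacian matches closed forms and is PSD", {
  K3 <- as.matrix(kirchhoff_laplacian(triangle_edges, 3))
  expect_equal(K3, rbind(c(2, -1, -1), c(-1, 2, -1), c(-1, -1, 2)),
               ignore_attr = TRUE)
  Kp <- as.matrix(kirchhoff_laplacian(path_edges, 3))
  expect_equal(Kp, rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  expect_equal(unname(Matrix::rowSums(kirchhoff_laplacian(
    mesh_topology(icosphere(1)$faces)))), rep(0, 42))

  # attribute subgraph: smallest eigenvalue 0 with the constant eigenvector
  pop <- small_population()
  vs <- attribute_vertices(pop$topology)[[2]]
  Kw <- ledmesh:::attribute_laplacian(pop$topology, vs)
  eb <- eigenbasis(Kw, 3)
  expect_lt(abs(eb$values[1]), 1e-9)
  expect_equal(eb$vectors[, 1], rep(1 / sqrt(length(vs)), length(vs)),
               tolerance = 1e-9)
  expect_error(kirchhoff_laplacian(matrix(integer(0), 0, 2)), "empty")
})

test_that("Tutte Laplacian smooths and annihilates constants", {
  T3 <- as.matrix(tutte_laplacian(triangle_edges, 3))
  expect_equal(T3, rbind(c(1, -0.5, -0.5), c(-0.5, 1, -0.5),
                         c(-0.5, -0.5, 1)), ignore_attr = TRUE)
  m <- icosphere(2)
  topo <- mesh_topology(m$faces)
  Tm <- tutte_laplacian(topo)
  expect_lt(max(abs(Tm %*% rep(2.5, topo$n_vertices))), 1e-12)
  # zero-degree vertex rejected
  expect_error(tutte_laplacian(rbind(c(1, 2)), n_vertices = 3), "degree zero")
  # repeated neighbor averaging drives the differential down monotonically
  set.seed(1)
  X <- m$vertices + matrix(rnorm(topo$n_vertices * 3, sd = 0.1),
                           ncol = 3)
  A <- Matrix::Diagonal(topo$n_vertices) - Tm      # D^-1 A
  norms <- numeric(100)
  for (i in 1:100) {
    norms[i] <- sqrt(sum(as.matrix(Tm %*% X)^2))
    X <- as.matrix(A %*% X)
  }
  expect_true(all(diff(norms) < 1e-12))
})

test_that("eigenbasis is orthonormal, exact, and deterministic", {
  K3 <- kirchhoff_laplacian(triangle_edges, 3)
  expect_equal(eigenbasis(K3)$values, c(0, 3, 3), tolerance = 1e-10)
  expect_equal(eigenbasis(kirchhoff_laplacian(path_edges, 3))$values,
               c(0, 1, 3), tolerance = 1e-10)

  pop <- small_population()
  vs <- attribute_vertices(pop$topology)[[1]]
  expect_gte(length(vs), 30)
  Kw <- ledmesh:::attribute_laplacian(pop$topology, vs)
  eb <- eigenbasis(Kw)
  U <- eb$vectors
  expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), 1e-8)
  expect_lt(max(abs(U %*% diag(eb$values) %*% t(U) - as.matrix(Kw))), 1e-8)
  expect_lt(max(abs(as.matrix(Kw %*% U) - U %*% diag(eb$values))), 1e-6)
  # two runs produce identical bases (sign and order convention)
  expect_identical(eb$vectors, eigenbasis(Kw)$vectors)
  # sign convention: largest-magnitude entry positive
  amax <- apply(U, 2, function(v) v[which.max(abs(v))])
  expect_true(all(amax > 0))
  expect_error(eigenbasis(K3, k_modes = 5), "exceeds")
})

test_that("signed distance matches its defining identities", {
  st <- small_stats()
  N <- nrow(st$mean)
  expect_equal(signed_distance(st$mean, st), rep(0, N))
  expect_equal(signed_distance(st$mean + 0.1 * st$normals, st),
               rep(0.1, N), tolerance = 1e-9)
  expect_equal(signed_distance(st$mean - 0.1 * st$normals, st),
               rep(-0.1, N), tolerance = 1e-9)
  # raw and standardized forms agree
  X <- small_population()$vertices[5, , ]
  expect_equal(signed_distance(X, st),
               signed_distance(standardize(X, st), st, standardized = TRUE),
               tolerance = 1e-6)
  expect_error(signed_distance(X[-1, ], st), "match")
})

test_that("basis selection finds the driving eigenvector of a single-mode population", {
  spec <- small_spec()
  tpl <- make_template(spec)
  topo <- tpl$topology
  nrm <- vertex_normals(tpl$vertices, topo$faces)
  vs <- attribute_vertices(topo)[[1]]
  Kw <- ledmesh:::attribute_laplacian(topo, vs)
  j <- 3L                                   # drive only eigenvector j
  u <- eigenbasis(Kw, j)$vectors[, j]
  field <- numeric(topo$n_vertices); field[vs] <- u
  n <- 60
  verts <- array(0, c(n, topo$n_vertices, 3))
  cs <- with_seed(4, stats::rnorm(n, sd = 0.05))
  for (s in seq_len(n))
    verts[s, , ] <- tpl$vertices + cs[s] * field * nrm
  pop <- shape_population(verts, topology = topo, fractions = c(1, 0, 0))
  st <- compute_template_stats(pop)
  suppressWarnings(b <- fit_spectral_basis(pop, st, kappa = 2))
  a1 <- b$attributes[[1]]
  expect_true(j %in% a1$selected)
  expect_gt(max(a1$variance) / sum(a1$variance), 0.99)

  # identical shapes: all projection variances zero, flooring warning
  verts0 <- verts; for (s in seq_len(n)) verts0[s, , ] <- tpl$vertices
  pop0 <- shape_population(verts0, topology = topo, fractions = c(1, 0, 0))
  st0 <- compute_template_stats(pop0)
  w <- capture_warnings(fit_spectral_basis(pop0, st0, kappa = 2))
  expect_true(all(grepl("flooring", w)))
  expect_length(w, spec$n_attributes)
})

test_that("local eigenprojections standardize to mean 0, sd 1 on the train split", {
  pop <- small_population()
  st <- small_stats()
  b <- small_basis()
  tr <- population_vertices(pop, "train")
  P <- t(vapply(seq_len(dim(tr)[1]), function(i)
    local_eigenprojection(tr[i, , ], b, st),
    numeric(b$n_attributes * b$kappa)))
  expect_lt(max(abs(colMeans(P))), 1e-6)
  expect_lt(max(abs(apply(P, 2, stats::sd) - 1)), 1e-6)
  # X = M projects to the standardized origin offset
  zM <- local_eigenprojection(st$mean, b, st)
  expect_equal(zM, unlist(lapply(b$attributes, function(a) -a$m / a$s)),
               tolerance = 1e-9)
})

test_that("projection is local: signals on one attribute leave other blocks at baseline", {
  pop <- small_population()
  st <- small_stats()
  b <- small_basis()
  base <- local_eigenprojection(st$mean, b, st)
  vs <- b$attributes[[2]]$vertices
  X <- st$mean
  bump <- numeric(nrow(X))
  bump[vs] <- 0.05 * b$attributes[[2]]$U[, 1]   # signal inside attribute 2
  X <- X + bump * st$normals
  z <- local_eigenprojection(X, b, st)
  blocks <- rep(seq_len(b$n_attributes), each = b$kappa)
  expect_equal(z[blocks != 2], base[blocks != 2], tolerance = 1e-9)
  expect_gt(max(abs(z[blocks == 2] - base[blocks == 2])), 1e-3)
})

test_that("projection is affine along a fixed normal field", {
  st <- small_stats()
  b <- small_basis()
  set.seed(8)
  delta <- stats::rnorm(nrow(st$mean), sd = 0.05)
  z_at <- function(a)
    local_eigenprojection(st$mean + a * delta * st$normals, b, st)
  z0 <- z_at(0); z1 <- z_at(1); z2 <- z_at(2)
  expect_equal(z2 - z1, z1 - z0, tolerance = 1e-7)
})

test_that("LE loss identities hold and match a loop oracle", {
  pop <- small_population()
  st <- small_stats()
  b <- small_basis()
  X <- pop$vertices[7, , ]
  zs <- local_eigenprojection(X, b, st)
  expect_equal(le_loss(X, zs, b, st), 0)
  expect_equal(le_loss(X, zs + 0.37, b, st), 0.37, tolerance = 1e-12)
  expect_equal(le_loss(X, zs - 0.2, b, st), 0.2, tolerance = 1e-12)
  set.seed(5)
  z <- stats::rnorm(length(zs))
  # independent loop-based oracle
  sdv <- signed_distance(X, st)
  acc <- 0
  for (w in seq_len(b$n_attributes)) {
    a <- b$attributes[[w]]
    for (k in seq_len(b$kappa)) {
      proj <- (sum(a$U[, k] * sdv[a$vertices]) - a$m[k]) / a$s[k]
      acc <- acc + abs(z[(w - 1) * b$kappa + k] - proj)
    }
  }
  expect_equal(le_loss(X, z, b, st), acc / length(zs), tolerance = 1e-9)
  # halving residuals halves the loss
  zh <- zs + (z - zs) / 2
  expect_equal(le_loss(X, zh, b, st), le_loss(X, z, b, st) / 2,
               tolerance = 1e-9)
  expect_error(le_loss(X, z[-1], b, st), "length")
})

test_that("LE loss gradient matches finite differences", {
  st <- small_stats()
  b <- small_basis()
  X <- small_population()$vertices[2, , ]
  Xs <- standardize(X, st)
  set.seed(11)
  z <- stats::rnorm(b$n_attributes * b$kappa)
  g <- ledmesh:::le_loss_grad(Xs, z, b, st)
  eps <- 1e-6; err <- 0
  set.seed(12)
  for (t in 1:6) {
    i <- sample(nrow(Xs), 1); j <- sample(3, 1)
    Xp <- Xs; Xp[i, j] <- Xp[i, j] + eps
    Xm <- Xs; Xm[i, j] <- Xm[i, j] - eps
    fd <- (le_loss(Xp, z, b, st, standardized = TRUE) -
             le_loss(Xm, z, b, st, standardized = TRUE)) / (2 * eps)
    err <- max(err, abs(fd - g$dX[i, j]))
  }
  expect_lt(err, 1e-7)
})

test_that("basis archives round-trip and carry the topology fingerprint", {
  b <- small_basis()
  p <- tempfile(fileext = ".json")
  save_spectral_basis(b, p)
  b2 <- load_spectral_basis(p)
  expect_equal(b2$attributes[[1]]$U, b$attributes[[1]]$U)
  expect_equal(b2$attributes[[3]]$m, b$attributes[[3]]$m)
  expect_identical(b2$topology_hash, b$topology_hash)
  expect_identical(ledmesh:::basis_hash(b2), ledmesh:::basis_hash(b))
})

test_that("normality diagnostics separate Gaussian from bimodal populations", {
  spec <- small_spec()
  pop <- sample_population(spec, 400, seed = 21)
  st <- compute_template_stats(pop)
  b <- fit_spectral_basis(pop, st, kappa = 2)
  rep_g <- projection_distribution_report(pop, b, st)
  expect_gte(mean(rep_g$ks_p > 0.01), 0.9)

  bim <- sample_bimodal_population(spec, 400, separation = 6, seed = 21)
  stb <- compute_template_stats(bim)
  bb <- fit_spectral_basis(bim, stb, kappa = 2)
  rep_b <- projection_distribution_report(bim, bb, stb)
  # the bimodal factor is the highest-variance mode of each attribute
  affected <- vapply(seq_len(bb$n_attributes), function(w)
    (w - 1) * bb$kappa + which.max(bb$attributes[[w]]$variance),
    numeric(1))
  expect_true(all(rep_b$ks_p[affected] < 0.01))
  expect_gt(mean(rep_b$ks_p[-affected] > 0.01), 0.5)
})
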