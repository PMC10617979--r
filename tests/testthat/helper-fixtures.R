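# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Single-triangle OBJ / tetrahedron PLY written to temp files.
write_triangle_obj <- function(path = tempfile(fileext = ".obj")) {
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  path
}

tetra_mesh <- function() {
  list(vertices = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                        c(-1, -1, 1)),
       faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

# Small synthetic study used across files: N=162, 4 attributes.
small_spec <- function() synthetic_spec(subdivision = 2L, seed = 42L)

small_population <- function(n = 80) {
  cached(paste0("pop", n), sample_population(small_spec(), n, seed = 42L))
}

small_stats <- function(n = 80) {
  cached(paste0("stats", n), compute_template_stats(small_population(n)))
}

small_basis <- function(n = 80, kappa = 2) {
  cached(paste0("basis", n, "-", kappa),
         fit_spectral_basis(small_population(n), small_stats(n), kappa))
}

# Tiny network context on the level-1 icosphere (N=42).
tiny_ctx <- function(latent_dim = 4L) {
  cached(paste0("ctx", latent_dim), {
    m <- icosphere(1)
    mesh_net_context(mesh_topology(m$faces), m$vertices,
                     network_arch(channels = c(4L, 6L), spiral_length = 5L,
                                  latent_dim = latent_dim))
  })
}

# Small-mesh context matching the small population (for training smokes).
small_ctx <- function(latent_dim = 8L) {
  cached(paste0("smallctx", latent_dim), {
    pop <- small_population()
    st <- small_stats()
    mesh_net_context(pop$topology, st$mean,
                     network_arch(channels = c(6L, 8L, 12L),
                                  spiral_length = 7L,
                                  latent_dim = latent_dim))
  })
}

# Finite-difference check of a named gradient list against a scalar loss of
# the parameter list; returns the max relative error over sampled entries.
fd_check_params <- function(lossfn, params, grads, n = 8, eps = 1e-6,
                            seed = 99) {
  pn <- setdiff(names(params), "role")
  v <- params_to_vector(params)
  g <- params_to_vector(c(list(role = "x"), grads[pn]))
  idx <- with_seed(seed, sample(length(v), n))
  err <- 0
  for (i in idx) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    fd <- (lossfn(vector_to_params(vp, params)) -
             lossfn(vector_to_params(vm, params))) / (2 * eps)
    err <- max(err, abs(fd - g[i]) / max(1, abs(fd)))
  }
  err
}

stack_batch <- function(arr, idx, stats = NULL) {
  N <- dim(arr)[2]
  out <- matrix(0, length(idx) * N, 3)
  for (k in seq_along(idx)) {
    X <- arr[idx[k], , ]
    if (!is.null(stats)) X <- standardize(X, stats)
    out[(k - 1) * N + seq_len(N), ] <- X
  }
  out
}
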