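# Mesh neural networks built from spiral convolutions, fixed quadric
# sampling transforms and dense heads, with hand-authored reverse-mode
# gradients. Four roles share the building blocks: encoder (mu, log-sigma
# heads), generator (latent -> mesh), discriminator and critic (scalar
# head); the variation-predictability classifier reuses the encoder trunk
# with a softmax head.
#
# Batches are stored as (B * n_level) x channels matrices (shapes stacked
# along rows). Gather/scatter for spiral convolutions and pooling are
# expressed as fixed sparse matrices cached per batch size, so forward and
# backward passes reduce to (sparse) matrix products.

#' Default network architecture
#'
#' @param channels Spiral-convolution channels per level (finest first).
#' @param spiral_length Spiral sequence length L.
#' @param pool_factor Vertex down-sampling factor between levels.
#' @param latent_dim Latent size (`n_attributes * kappa` for LED models).
#' @return A list of architecture settings.
#' @export
network_arch <- function(channels = c(16, 32, 64, 128), spiral_length = 9L,
                         pool_factor = 4, latent_dim = 12L) {
  list(channels = as.integer(channels),
       spiral_length = as.integer(spiral_length),
       pool_factor = pool_factor, latent_dim = as.integer(latent_dim))
}

#' Shared mesh-network context for one topology
#'
#' Precomputes the sampling hierarchy and per-level spiral indexings; all
#' four network roles built on a topology share this context (the sampling
#' transforms are fixed, non-learned, and identical across networks).
#'
#' @param topology A `mesh_topology`.
#' @param template_vertices N x 3 template coordinates (collapse geometry).
#' @param arch A [network_arch()] list.
#' @return A `mesh_net_context`.
#' @export
mesh_net_context <- function(topology, template_vertices,
                             arch = network_arch()) {
  n_levels <- length(arch$channels)
  tr <- build_sampling_transforms(topology, template_vertices,
                                  factor = arch$pool_factor,
                                  levels = n_levels - 1L)
  spirals <- lapply(seq_len(n_levels), function(l)
    build_spiral_indexing(tr$faces[[l]], tr$sizes[l], L = arch$spiral_length))
  ctx <- list(arch = arch, sizes = tr$sizes, faces = tr$faces,
              down = tr$down, up = tr$up, spirals = spirals,
              n_levels = n_levels,
              flat_dim = tr$sizes[n_levels] * arch$channels[n_levels],
              topology_hash = topology_hash(topology),
              cache = new.env(parent = emptyenv()))
  class(ctx) <- "mesh_net_context"
  ctx
}

# Batched gather indices for a spiral indexing at batch size B: a
# (B*n) x L integer matrix, entry ((b-1)*n + i, l) pointing at batched
# vertex row ((b-1)*n + idx[i,l]); padded entries hold the sentinel
# B*n + 1 (treated as a zero row by the kernels).
spiral_gather_index <- function(idx, B) {
  n <- nrow(idx); L <- ncol(idx)
  base <- rep(seq_len(B) - 1L, each = n) * n      # (b-1)*n for stacked rows
  out <- matrix(0L, B * n, L)
  for (l in seq_len(L)) {
    tgt <- rep(idx[, l], times = B)
    v <- base + tgt
    v[tgt == 0L] <- B * n + 1L
    out[, l] <- v
  }
  out
}

# Batch-size-cached operators: gather index vectors, pooling row selections
# (the down transform picks one fine vertex per coarse vertex) and batched
# barycentric up transforms.
ctx_ops <- function(ctx, B) {
  key <- paste0("B", B)
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  down_sel <- lapply(ctx$down, function(D) {
    s <- Matrix::summary(D)
    kept <- s$j[order(s$i)]
    n1 <- ncol(D); n2 <- nrow(D)
    rep(seq_len(B) - 1L, each = n2) * n1 + rep(kept, times = B)
  })
  ops <- list(
    gather = lapply(ctx$spirals, spiral_gather_index, B = B),
    down_sel = down_sel,
    down_n1 = vapply(ctx$down, ncol, numeric(1)),
    up = lapply(ctx$up, function(U) Matrix::bdiag(rep(list(U), B)))
  )
  ctx$cache[[key]] <- ops
  ops
}

elu <- function(x) {
  neg <- x <= 0
  x[neg] <- exp(pmin(x[neg], 30)) - 1
  x
}

# One spiral convolution: per-neighbor gather + linear accumulation, then
# optional ELU. The weight matrix W is (L*Cin) x Cout with rows ordered
# neighbor-major: rows ((l-1)*Cin + 1):(l*Cin) belong to spiral position l,
# i.e. Y_i = sum_l X[spiral_i[l], ] %*% W_l + b. The gather/scatter loops
# run in compiled code (see src/spiral_conv.cpp).
spiral_conv_fwd <- function(X, W, b, gidx, act = TRUE) {
  Z <- conv_gather_mm(X, gidx, W, b)
  if (act) {
    neg <- Z <= 0
    Y <- Z
    Y[neg] <- exp(pmin(Z[neg], 30)) - 1
  } else {
    neg <- NULL
    Y <- Z
  }
  list(Y = Y, cache = list(X = X, Y = Y, neg = neg, act = act))
}

spiral_conv_bwd <- function(dY, cache, W, gidx) {
  if (cache$act) {
    dZ <- dY
    dZ[cache$neg] <- dY[cache$neg] * (cache$Y[cache$neg] + 1)
  } else dZ <- dY
  r <- conv_gather_bwd(cache$X, gidx, W, dZ)
  list(dX = r$dX, dW = r$dW, db = colSums(dZ))
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize parameters for one network role
#'
#' @param ctx A `mesh_net_context`.
#' @param role One of "encoder", "generator", "discriminator", "critic",
#'   or "classifier".
#' @param seed RNG seed for the initial weights.
#' @param n_classes Output classes (classifier role only).
#' @return A named list of parameter matrices/vectors.
#' @export
init_network <- function(ctx, role, seed = 1L, n_classes = NULL) {
  arch <- ctx$arch
  ch <- arch$channels
  L <- arch$spiral_length
  nl <- ctx$n_levels
  with_seed(seed, {
    p <- list(role = role)
    if (role == "generator") {
      p$dense_W <- glorot(arch$latent_dim, ctx$flat_dim)
      p$dense_b <- numeric(ctx$flat_dim)
      # convs from coarsest to finest; final conv maps to 3 coords, linear
      cin <- c(ch[nl], rev(ch[-nl]))
      cout <- c(rev(ch[-nl]), 3L)
      for (k in seq_len(nl)) {
        p[[paste0("conv", k, "_W")]] <- glorot(L * cin[k], cout[k])
        p[[paste0("conv", k, "_b")]] <- numeric(cout[k])
      }
    } else {
      cin <- c(3L, ch[-nl])
      for (k in seq_len(nl)) {
        p[[paste0("conv", k, "_W")]] <- glorot(L * cin[k], ch[k])
        p[[paste0("conv", k, "_b")]] <- numeric(ch[k])
      }
      heads <- switch(role,
                      encoder = c(mu = arch$latent_dim, logsig = arch$latent_dim),
                      classifier = c(logits = n_classes),
                      c(score = 1L))
      for (h in names(heads)) {
        p[[paste0(h, "_W")]] <- glorot(ctx$flat_dim, heads[[h]])
        p[[paste0(h, "_b")]] <- numeric(heads[[h]])
      }
    }
    p
  })
}

# (B*n) x C -> B x (n*C) with columns ordered (vertex within channel)
flatten_batch <- function(X, n, B) {
  C <- ncol(X)
  t(matrix(aperm(array(X, c(n, B, C)), c(1, 3, 2)), n * C, B))
}
unflatten_batch <- function(Xf, n, B) {
  C <- ncol(Xf) / n
  matrix(aperm(array(t(Xf), c(n, C, B)), c(1, 3, 2)), n * B, C)
}

# Trunk forward for encoder/discriminator/critic/classifier.
trunk_fwd <- function(ctx, params, X, B) {
  ops <- ctx_ops(ctx, B)
  nl <- ctx$n_levels
  caches <- vector("list", nl)
  H <- X
  for (k in seq_len(nl)) {
    cv <- spiral_conv_fwd(H, params[[paste0("conv", k, "_W")]],
                          params[[paste0("conv", k, "_b")]],
                          ops$gather[[k]])
    caches[[k]] <- cv$cache
    H <- cv$Y
    if (k < nl) H <- H[ops$down_sel[[k]], , drop = FALSE]
  }
  flat <- flatten_batch(H, ctx$sizes[nl], B)
  list(flat = flat, caches = caches, B = B)
}

trunk_bwd <- function(ctx, params, fw, dflat) {
  ops <- ctx_ops(ctx, fw$B)
  nl <- ctx$n_levels
  grads <- list()
  dH <- unflatten_batch(dflat, ctx$sizes[nl], fw$B)
  for (k in rev(seq_len(nl))) {
    if (k < nl) {
      up_dH <- matrix(0, fw$B * ops$down_n1[k], ncol(dH))
      up_dH[ops$down_sel[[k]], ] <- dH
      dH <- up_dH
    }
    bw <- spiral_conv_bwd(dH, fw$caches[[k]],
                          params[[paste0("conv", k, "_W")]], ops$gather[[k]])
    grads[[paste0("conv", k, "_W")]] <- bw$dW
    grads[[paste0("conv", k, "_b")]] <- bw$db
    dH <- bw$dX
  }
  list(grads = grads, dX = dH)
}

#' Encoder forward pass
#'
#' @param ctx A `mesh_net_context`.
#' @param params Encoder parameters from [init_network()].
#' @param X Standardized batch, `(B*N) x 3`.
#' @param B Batch size.
#' @return List with `mu`, `logsig` (B x latent), `sigma`, and the forward
#'   cache needed by [encoder_backward()].
#' @export
encoder_forward <- function(ctx, params, X, B) {
  fw <- trunk_fwd(ctx, params, X, B)
  mu <- sweep(fw$flat %*% params$mu_W, 2, params$mu_b, "+")
  logsig <- sweep(fw$flat %*% params$logsig_W, 2, params$logsig_b, "+")
  list(mu = mu, logsig = logsig, sigma = exp(logsig), fw = fw)
}

#' Encoder backward pass
#' @param out Output of [encoder_forward()].
#' @param dmu,dlogsig Gradients w.r.t. `mu` and `logsig` (B x latent).
#' @inheritParams encoder_forward
#' @return List with `grads` (named like params) and `dX`.
#' @export
encoder_backward <- function(ctx, params, out, dmu, dlogsig) {
  fw <- out$fw
  grads <- list(
    mu_W = crossprod(fw$flat, dmu), mu_b = colSums(dmu),
    logsig_W = crossprod(fw$flat, dlogsig), logsig_b = colSums(dlogsig))
  dflat <- tcrossprod(dmu, params$mu_W) + tcrossprod(dlogsig, params$logsig_W)
  tb <- trunk_bwd(ctx, params, fw, dflat)
  list(grads = c(grads, tb$grads), dX = tb$dX)
}

#' Scalar-head forward (discriminator / critic)
#' @inheritParams encoder_forward
#' @return List with `score` (length-B vector) and cache.
#' @export
scalar_forward <- function(ctx, params, X, B) {
  fw <- trunk_fwd(ctx, params, X, B)
  s <- as.vector(fw$flat %*% params$score_W) + params$score_b
  list(score = s, fw = fw)
}

#' Scalar-head backward
#' @param out Output of [scalar_forward()].
#' @param dscore Gradient w.r.t. the scores (length B).
#' @inheritParams encoder_forward
#' @export
scalar_backward <- function(ctx, params, out, dscore) {
  fw <- out$fw
  dsc <- matrix(dscore, ncol = 1)
  grads <- list(score_W = crossprod(fw$flat, dsc),
                score_b = sum(dscore))
  dflat <- dsc %*% t(params$score_W)
  tb <- trunk_bwd(ctx, params, fw, dflat)
  list(grads = c(grads, tb$grads), dX = tb$dX)
}

classifier_forward <- function(ctx, params, X, B) {
  fw <- trunk_fwd(ctx, params, X, B)
  logits <- sweep(fw$flat %*% params$logits_W, 2, params$logits_b, "+")
  list(logits = logits, fw = fw)
}

classifier_backward <- function(ctx, params, out, dlogits) {
  fw <- out$fw
  grads <- list(logits_W = crossprod(fw$flat, dlogits),
                logits_b = colSums(dlogits))
  dflat <- tcrossprod(dlogits, params$logits_W)
  tb <- trunk_bwd(ctx, params, fw, dflat)
  list(grads = c(grads, tb$grads), dX = tb$dX)
}

#' Generator forward pass
#'
#' @param ctx A `mesh_net_context`.
#' @param params Generator parameters.
#' @param z Latent batch, B x latent_dim (a vector is treated as B = 1).
#' @return List with `X` (standardized output, `(B*N) x 3`) and cache.
#' @export
generator_forward <- function(ctx, params, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  B <- nrow(z)
  if (ncol(z) != ctx$arch$latent_dim)
    stop2("latent length %d does not match architecture (%d)",
          ncol(z), ctx$arch$latent_dim)
  ops <- ctx_ops(ctx, B)
  nl <- ctx$n_levels
  flat <- sweep(z %*% params$dense_W, 2, params$dense_b, "+")
  H <- unflatten_batch(flat, ctx$sizes[nl], B)
  caches <- vector("list", nl)
  for (k in seq_len(nl)) {
    level <- nl - k + 1L                      # mesh level of this conv
    cv <- spiral_conv_fwd(H, params[[paste0("conv", k, "_W")]],
                          params[[paste0("conv", k, "_b")]],
                          ops$gather[[level]], act = k < nl)
    caches[[k]] <- cv$cache
    H <- cv$Y
    if (k < nl) H <- as.matrix(ops$up[[level - 1L]] %*% H)
  }
  list(X = H, caches = caches, B = B, z = z)
}

#' Generator backward pass
#' @param out Output of [generator_forward()].
#' @param dX Gradient w.r.t. the generated batch (`(B*N) x 3`).
#' @inheritParams generator_forward
#' @return List with `grads` and `dz` (B x latent).
#' @export
generator_backward <- function(ctx, params, out, dX) {
  B <- out$B
  ops <- ctx_ops(ctx, B)
  nl <- ctx$n_levels
  grads <- list()
  dH <- dX
  for (k in rev(seq_len(nl))) {
    level <- nl - k + 1L
    if (k < nl) dH <- as.matrix(Matrix::crossprod(ops$up[[level - 1L]], dH))
    bw <- spiral_conv_bwd(dH, out$caches[[k]],
                          params[[paste0("conv", k, "_W")]],
                          ops$gather[[level]])
    grads[[paste0("conv", k, "_W")]] <- bw$dW
    grads[[paste0("conv", k, "_b")]] <- bw$db
    dH <- bw$dX
  }
  dflat <- flatten_batch(dH, ctx$sizes[nl], B)
  grads$dense_W <- crossprod(out$z, dflat)
  grads$dense_b <- colSums(dflat)
  dz <- tcrossprod(dflat, params$dense_W)
  list(grads = grads, dz = dz)
}

# ---- parameter-list arithmetic and the adam optimizer ----

param_names <- function(p) setdiff(names(p), "role")

#' Flatten parameters to a numeric vector (and back)
#' @param params,template Parameter lists from [init_network()].
#' @param v Numeric vector of the right total length.
#' @return A numeric vector / a parameter list.
#' @export
params_to_vector <- function(params) {
  unlist(lapply(param_names(params), function(nm) as.vector(params[[nm]])),
         use.names = FALSE)
}

#' @rdname params_to_vector
#' @export
vector_to_params <- function(v, template) {
  out <- template
  off <- 0
  for (nm in param_names(template)) {
    k <- length(template[[nm]])
    x <- v[off + seq_len(k)]
    out[[nm]] <- if (is.matrix(template[[nm]]))
      matrix(x, nrow(template[[nm]]), ncol(template[[nm]])) else x
    off <- off + k
  }
  out
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) {
  for (nm in names(g)) g[[nm]] <- g[[nm]] * s
  g
}

#' Adam optimizer state and update
#'
#' @param params Parameter list to optimize.
#' @return `adam_init`: an optimizer state.
#' @export
adam_init <- function(params) {
  zero <- lapply(params[param_names(params)], function(p) p * 0)
  list(m = zero, v = zero, t = 0)
}

#' @rdname adam_init
#' @param state Optimizer state.
#' @param grads Named gradient list (missing entries are skipped).
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return `adam_update`: list with updated `params` and `state`.
#' @export
adam_update <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Clip all parameters of a network into the interval from -c to c
#' @param params Parameter list (critic).
#' @param c Positive clip bound.
#' @return Clipped parameter list.
#' @export
clip_params <- function(params, c) {
  for (nm in param_names(params)) params[[nm]] <- pmin(pmax(params[[nm]], -c), c)
  params
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON archives holding the architecture, parameters of all
#' networks, and topology/basis hashes; loading verifies the hashes against
#' the supplied context (and basis, if any) and refuses mismatches.
#'
#' @param models Named list of parameter lists (e.g. `list(E = ..., G = ...)`).
#' @param ctx The `mesh_net_context` used to build them.
#' @param path Output `.json` path.
#' @param basis Optional `spectral_basis` to fingerprint.
#' @param extra Optional metadata list stored verbatim.
#' @export
save_checkpoint <- function(models, ctx, path, basis = NULL, extra = NULL) {
  ser <- lapply(models, function(p) {
    lapply(p[param_names(p)], function(x)
      list(dim = if (is.matrix(x)) dim(x) else length(x), x = as.vector(x)))
  })
  obj <- list(arch = ctx$arch, topology_hash = ctx$topology_hash,
              basis_hash = if (!is.null(basis)) basis_hash(basis) else NULL,
              roles = lapply(models, function(p) p$role),
              params = ser, extra = extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, ctx, basis = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$topology_hash, ctx$topology_hash))
    stop2("checkpoint topology hash does not match this context")
  if (!is.null(basis) && !is.null(obj$basis_hash) &&
      !identical(obj$basis_hash, basis_hash(basis)))
    stop2("checkpoint was trained with a different spectral basis")
  models <- lapply(names(obj$params), function(mn) {
    p <- list(role = obj$roles[[mn]])
    for (nm in names(obj$params[[mn]])) {
      ent <- obj$params[[mn]][[nm]]
      x <- as.numeric(unlist(ent$x))
      d <- as.integer(unlist(ent$dim))
      p[[nm]] <- if (length(d) == 2) matrix(x, d[1], d[2]) else x
    }
    p
  })
  names(models) <- names(obj$params)
  list(models = models, extra = obj$extra, arch = obj$arch)
}
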