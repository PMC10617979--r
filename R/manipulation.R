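# Latent-space shape editing: per-attribute latent resampling and direct
# manipulation by vertex-handle optimization over one attribute's latent
# block at a time.

#' Resample one attribute's latent block
#'
#' Returns the latent with block `omega` redrawn from
#' `N(0, sigma_sample^2 I)`; all other blocks are untouched.
#'
#' @param z Latent vector of length `n_attributes * kappa`.
#' @param omega Attribute index (1-based).
#' @param kappa Latents per attribute.
#' @param seed RNG seed.
#' @param sigma_sample Sampling std (0 zeroes the block).
#' @return The edited latent vector.
#' @export
attribute_resample <- function(z, omega, kappa, seed = 1L,
                               sigma_sample = 1) {
  nf <- length(z) / kappa
  if (omega < 1 || omega > nf) stop2("attribute index %d out of range", omega)
  idx <- (omega - 1) * kappa + seq_len(kappa)
  z[idx] <- with_seed(seed, stats::rnorm(kappa, sd = sigma_sample))
  z
}

#' Direct manipulation of a generated shape by vertex handles
#'
#' Given selected vertices `S` and target positions `Y` (template units),
#' minimizes `||S o G(z) - Y||^2` with adam (50 iterations, lr 0.1 by
#' default), optimizing only the latent block of the attribute containing
#' the selected vertices; handles on several attributes trigger sequential
#' per-attribute optimizations in ascending attribute order. Latent blocks
#' without any selected vertex are returned bit-identical.
#'
#' @param model A `led_model`.
#' @param stats `template_stats`.
#' @param labels Per-vertex attribute labels.
#' @param z0 Starting latent (length `latent_dim`).
#' @param S Integer vector of selected vertex indices.
#' @param Y Target positions (`length(S) x 3`, template units).
#' @param kappa Latents per attribute.
#' @param iterations,lr Optimizer settings.
#' @return List with `z` (optimized latent), `shape` (N x 3, template
#'   units), `initial_loss`, `final_loss`, and the per-attribute loss
#'   trajectories (`trace`).
#' @export
direct_manipulate <- function(model, stats, labels, z0, S, Y, kappa,
                              iterations = 50L, lr = 0.1) {
  if (length(S) != nrow(Y)) stop2("one target row per selected vertex needed")
  if (any(S < 1 | S > length(labels))) stop2("selected vertex out of range")
  ctx <- model$ctx
  N <- ctx$sizes[1]
  z <- as.numeric(z0)

  handle_loss_grad <- function(z) {
    gen <- generator_forward(ctx, model$models$G, matrix(z, 1))
    Xt <- destandardize(gen$X, stats)
    R <- Xt[S, , drop = FALSE] - Y
    dX <- matrix(0, N, 3)
    dX[S, ] <- 2 * R
    # chain through de-standardization (X = Xstd * Sigma + M)
    bw <- generator_backward(ctx, model$models$G, gen, dX * stats$sd)
    list(loss = sum(R^2), dz = as.numeric(bw$dz), shape = Xt)
  }

  first <- handle_loss_grad(z)
  initial_loss <- first$loss
  attrs <- sort(unique(labels[S]))
  trace <- list()
  for (w in attrs) {
    idx <- (w - 1) * kappa + seq_len(kappa)
    m <- numeric(kappa); v <- numeric(kappa); tstep <- 0
    losses <- numeric(iterations)
    z_last <- z
    for (it in seq_len(iterations)) {
      g <- handle_loss_grad(z)
      if (!is.finite(g$loss)) {
        warning("handle loss diverged; returning last finite iterate")
        z <- z_last
        break
      }
      z_last <- z
      losses[it] <- g$loss
      gd <- g$dz[idx]
      tstep <- tstep + 1
      m <- 0.9 * m + 0.1 * gd
      v <- 0.999 * v + 0.001 * gd^2
      mh <- m / (1 - 0.9^tstep); vh <- v / (1 - 0.999^tstep)
      z[idx] <- z[idx] - lr * mh / (sqrt(vh) + 1e-8)
    }
    trace[[as.character(w)]] <- losses
  }
  final <- handle_loss_grad(z)
  list(z = z, shape = final$shape, initial_loss = initial_loss,
       final_loss = final$loss, trace = trace)
}
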