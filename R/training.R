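# Loss assembly and training engines for the local-eigenprojection
# disentangled (LED) VAE, LSGAN and WGAN, plus their vanilla ablations
# (all LE weights zero).

#' Training configuration
#'
#' @param model One of "vae", "lsgan", "wgan".
#' @param alpha Weight of the Tutte-Laplacian smoothing loss.
#' @param beta KL weight (VAE); linearly warmed up over `beta_warmup`
#'   epochs.
#' @param eta1,eta2 LE-loss weights of the VAE: `eta1` ties the predicted
#'   mean to the input's eigenprojection (encoder-routed), `eta2` ties the
#'   reconstruction's eigenprojection to the predicted mean
#'   (generator-routed). Set both to 0 for the vanilla VAE.
#' @param eta LE-loss weight of the GAN generators (0 = vanilla GAN).
#' @param clip Weight-clipping bound `c` of the WGAN critic.
#' @param n_critic Critic updates per generator update (WGAN).
#' @param batch_size,epochs,lr Optimization settings (adam).
#' @param beta_warmup Epochs of linear KL warm-up.
#' @param sigma_sample Truncation-trick sampling std (1 = off).
#' @param seed Training seed.
#' @return A `train_config` list.
#' @export
train_config <- function(model = c("vae", "lsgan", "wgan"),
                         alpha = 1, beta = 1e-3, eta1 = 0.5, eta2 = 0.5,
                         eta = 0.5, clip = 0.01, n_critic = 5L,
                         batch_size = 16L, epochs = 20L, lr = 1e-3,
                         beta_warmup = 5L, sigma_sample = 1, seed = 1L) {
  model <- match.arg(model)
  stopifnot(alpha >= 0, beta >= 0, eta1 >= 0, eta2 >= 0, eta >= 0, clip > 0)
  structure(list(model = model, alpha = alpha, beta = beta, eta1 = eta1,
                 eta2 = eta2, eta = eta, clip = clip,
                 n_critic = as.integer(n_critic),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 beta_warmup = as.integer(beta_warmup),
                 sigma_sample = sigma_sample, seed = as.integer(seed)),
            class = "train_config")
}

check_finite <- function(loss, what) {
  if (!is.finite(loss))
    stop2("%s became non-finite (%g); aborting training", what, loss)
  loss
}

#' One VAE training step
#'
#' Total loss `LR + alpha*LL + beta*LKL + eta1*LLE(X, mu) + eta2*LLE(X', mu)`
#' with the gradient-routing contract: the `eta1` term updates only the
#' encoder, the `eta2` term only the generator (its dependence on `mu` —
#' both as the LE target and through the sampled latent — is severed).
#'
#' @param Xb Standardized input batch (`(B*N) x 3`).
#' @param models List with `E` and `G` parameter lists.
#' @param ctx Shared `mesh_net_context`.
#' @param basis `spectral_basis` (may be `NULL` when `eta1 = eta2 = 0`).
#' @param stats `template_stats`.
#' @param Tm Tutte Laplacian of the full mesh.
#' @param config A `train_config`.
#' @param beta_eff Effective KL weight for this step (warm-up).
#' @param eps_noise Optional pre-drawn reparameterization noise
#'   (B x latent); drawn internally if `NULL`.
#' @return List with `losses`, `grads` (named `E`, `G`), and the forward
#'   pass (`mu`, `sigma`, `z`, `Xp`).
#' @export
vae_step <- function(Xb, models, ctx, basis, stats, Tm, config,
                     beta_eff = config$beta, eps_noise = NULL) {
  N <- ctx$sizes[1]
  B <- nrow(Xb) / N
  enc <- encoder_forward(ctx, models$E, Xb, B)
  if (is.null(eps_noise))
    eps_noise <- matrix(stats::rnorm(B * ctx$arch$latent_dim), B)
  z <- enc$mu + enc$sigma * eps_noise
  gen <- generator_forward(ctx, models$G, z)
  Xp <- gen$X

  rec <- reconstruction_loss_grad(Xb, Xp, N)
  lap <- laplacian_loss_grad(Xp, Tm)
  kl <- kl_loss_grad(enc$mu, enc$logsig)
  use_le <- config$eta1 > 0 || config$eta2 > 0
  le1 <- if (config$eta1 > 0)
    le_loss_batch(Xb, enc$mu, basis, stats) else list(loss = 0)
  le2 <- if (config$eta2 > 0)
    le_loss_batch(Xp, enc$mu, basis, stats) else list(loss = 0)

  # generator backward, main path (recon + laplacian): grads + dz to E
  dXp_main <- rec$dXp + config$alpha * lap$dXp
  bw_main <- generator_backward(ctx, models$G, gen, dXp_main)
  grads_G <- bw_main$grads
  dz <- bw_main$dz
  # eta2 term routed only through G: second generator backward, dz discarded
  if (config$eta2 > 0) {
    bw_le <- generator_backward(ctx, models$G, gen, config$eta2 * le2$dX)
    grads_G <- add_grads(grads_G, bw_le$grads)
  }
  # encoder gradients: reparameterization + KL + eta1 LE on mu
  dmu <- dz + beta_eff * kl$dmu
  dlogsig <- dz * enc$sigma * eps_noise + beta_eff * kl$dlogsig
  if (config$eta1 > 0) dmu <- dmu + config$eta1 * le1$dZ
  bw_E <- encoder_backward(ctx, models$E, enc, dmu, dlogsig)

  total <- rec$loss + config$alpha * lap$loss + beta_eff * kl$loss +
    config$eta1 * le1$loss + config$eta2 * le2$loss
  check_finite(total, "VAE loss")
  list(losses = c(total = total, recon = rec$loss, laplacian = lap$loss,
                  kl = kl$loss, le_enc = le1$loss, le_gen = le2$loss),
       grads = list(E = bw_E$grads, G = grads_G),
       mu = enc$mu, sigma = enc$sigma, z = z, Xp = Xp)
}

#' One LSGAN training step (gradients for D and G)
#'
#' Discriminator minimizes `1/2 E[(D(X)-1)^2] + 1/2 E[D(G(z))^2]`; the
#' generator minimizes `1/2 E[(D(G(z))-1)^2] + alpha*LL + eta*LLE(X', z)`.
#'
#' @inheritParams vae_step
#' @param models List with `G` and `D`.
#' @param z_d,z_g Latent draws for the two phases (drawn if `NULL`).
#' @return List with `losses` and `grads` (`D`, `G`).
#' @export
lsgan_step <- function(Xb, models, ctx, basis, stats, Tm, config,
                       z_d = NULL, z_g = NULL) {
  N <- ctx$sizes[1]
  B <- nrow(Xb) / N
  Zd <- ctx$arch$latent_dim
  if (is.null(z_d)) z_d <- matrix(stats::rnorm(B * Zd), B)
  if (is.null(z_g)) z_g <- matrix(stats::rnorm(B * Zd), B)

  # --- discriminator phase (generator frozen)
  fake_d <- generator_forward(ctx, models$G, z_d)
  dr <- scalar_forward(ctx, models$D, Xb, B)
  df <- scalar_forward(ctx, models$D, fake_d$X, B)
  loss_D <- 0.5 * mean((dr$score - 1)^2) + 0.5 * mean(df$score^2)
  gD <- add_grads(
    scalar_backward(ctx, models$D, dr, (dr$score - 1) / B)$grads,
    scalar_backward(ctx, models$D, df, df$score / B)$grads)

  # --- generator phase (discriminator frozen)
  fake_g <- generator_forward(ctx, models$G, z_g)
  dg <- scalar_forward(ctx, models$D, fake_g$X, B)
  lap <- laplacian_loss_grad(fake_g$X, Tm)
  le <- if (config$eta > 0) le_loss_batch(fake_g$X, z_g, basis, stats)
        else list(loss = 0, dX = fake_g$X * 0)
  loss_G_adv <- 0.5 * mean((dg$score - 1)^2)
  dXp <- scalar_backward(ctx, models$D, dg, (dg$score - 1) / B)$dX +
    config$alpha * lap$dXp + config$eta * le$dX
  gG <- generator_backward(ctx, models$G, fake_g, dXp)$grads
  loss_G <- loss_G_adv + config$alpha * lap$loss + config$eta * le$loss
  check_finite(loss_D + loss_G, "LSGAN loss")
  list(losses = c(d = loss_D, g = loss_G, g_adv = loss_G_adv,
                  laplacian = lap$loss, le = le$loss),
       grads = list(D = gD, G = gG))
}

#' One WGAN critic step (gradients only)
#'
#' Critic minimizes `E[C(G(z))] - E[C(X)]`; after each update the caller
#' clips the critic parameters to `[-c, c]` (see [clip_params()]).
#'
#' @inheritParams lsgan_step
#' @param models List with `G` and `C`.
#' @export
wgan_critic_step <- function(Xb, models, ctx, config, z = NULL) {
  N <- ctx$sizes[1]
  B <- nrow(Xb) / N
  if (is.null(z)) z <- matrix(stats::rnorm(B * ctx$arch$latent_dim), B)
  fake <- generator_forward(ctx, models$G, z)
  cr <- scalar_forward(ctx, models$C, Xb, B)
  cf <- scalar_forward(ctx, models$C, fake$X, B)
  loss_C <- mean(cf$score) - mean(cr$score)
  gC <- add_grads(
    scalar_backward(ctx, models$C, cf, rep(1 / B, B))$grads,
    scalar_backward(ctx, models$C, cr, rep(-1 / B, B))$grads)
  check_finite(loss_C, "WGAN critic loss")
  list(loss = loss_C, grads = gC)
}

#' One WGAN generator step (gradients only)
#'
#' Generator minimizes `-E[C(G(z))] + alpha*LL + eta*LLE(X', z)`.
#'
#' @inheritParams lsgan_step
#' @export
wgan_generator_step <- function(models, ctx, basis, stats, Tm, config, B,
                                z = NULL) {
  if (is.null(z)) z <- matrix(stats::rnorm(B * ctx$arch$latent_dim), B)
  fake <- generator_forward(ctx, models$G, z)
  cf <- scalar_forward(ctx, models$C, fake$X, B)
  lap <- laplacian_loss_grad(fake$X, Tm)
  le <- if (config$eta > 0) le_loss_batch(fake$X, z, basis, stats)
        else list(loss = 0, dX = fake$X * 0)
  dXp <- scalar_backward(ctx, models$C, cf, rep(-1 / B, B))$dX +
    config$alpha * lap$dXp + config$eta * le$dX
  gG <- generator_backward(ctx, models$G, fake, dXp)$grads
  loss_G <- -mean(cf$score) + config$alpha * lap$loss + config$eta * le$loss
  check_finite(loss_G, "WGAN generator loss")
  list(loss = loss_G, laplacian = lap$loss, le = le$loss, grads = gG)
}

#' Train a generative model on a shape population
#'
#' Runs the epoch loop of the configured flavour (`vae`, `lsgan`, `wgan`)
#' with plain shuffled mini-batches (no curated attribute-swapping),
#' tracking validation reconstruction loss for VAEs and a fixed-epoch
#' schedule for GANs. LED flavours (non-zero LE weights) require a
#' `spectral_basis` fitted on the same topology and train split.
#'
#' @param pop A `shape_population`.
#' @param stats `template_stats` of its train split.
#' @param config A `train_config`.
#' @param basis A `spectral_basis` (required when any LE weight is > 0).
#' @param ctx Optional prebuilt `mesh_net_context` (rebuilt if `NULL`).
#' @param arch A [network_arch()]; its `latent_dim` must match the basis.
#' @param log_path Optional JSONL file receiving one record per epoch.
#' @param verbose Print per-epoch losses.
#' @return A `led_model`: `models` (parameter lists), `ctx`, `config`,
#'   `history` (per-epoch loss data.frame), hashes.
#' @export
fit_generative_model <- function(pop, stats, config, basis = NULL,
                                 ctx = NULL, arch = NULL, log_path = NULL,
                                 verbose = FALSE) {
  use_le <- (config$model == "vae" && (config$eta1 > 0 || config$eta2 > 0)) ||
    (config$model != "vae" && config$eta > 0)
  if (use_le) {
    if (is.null(basis)) stop2("LED training requires a fitted spectral basis")
    if (!identical(basis$topology_hash, topology_hash(pop$topology)))
      stop2("spectral basis was fitted on a different topology")
  }
  if (is.null(arch)) {
    latent <- if (!is.null(basis)) basis$n_attributes * basis$kappa else 12L
    arch <- network_arch(latent_dim = latent)
  }
  if (!is.null(basis) && arch$latent_dim != basis$n_attributes * basis$kappa)
    stop2("architecture latent_dim (%d) must equal n_attributes * kappa (%d)",
          arch$latent_dim, basis$n_attributes * basis$kappa)
  if (is.null(ctx)) ctx <- mesh_net_context(pop$topology, stats$mean, arch)
  Tm <- tutte_laplacian(pop$topology)
  Xtr <- standardize(population_vertices(pop, "train"), stats)
  Xva <- standardize(population_vertices(pop, "val"), stats)
  n_tr <- dim(Xtr)[1]
  N <- ctx$sizes[1]
  Bsz <- min(config$batch_size, n_tr)

  stack_rows <- function(A, idx) {
    out <- matrix(0, length(idx) * N, 3)
    for (k in seq_along(idx)) out[(k - 1) * N + seq_len(N), ] <- A[idx[k], , ]
    out
  }

  models <- switch(config$model,
    vae = list(E = init_network(ctx, "encoder",
                                seed = fanout_seed(config$seed, "E")),
               G = init_network(ctx, "generator",
                                seed = fanout_seed(config$seed, "G"))),
    lsgan = list(G = init_network(ctx, "generator",
                                  seed = fanout_seed(config$seed, "G")),
                 D = init_network(ctx, "discriminator",
                                  seed = fanout_seed(config$seed, "D"))),
    wgan = list(G = init_network(ctx, "generator",
                                 seed = fanout_seed(config$seed, "G")),
                C = init_network(ctx, "critic",
                                 seed = fanout_seed(config$seed, "C"))))
  opt <- lapply(models, adam_init)

  history <- list()
  if (!is.null(log_path) && file.exists(log_path)) unlink(log_path)
  set.seed(fanout_seed(config$seed, "epochs"))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    n_batches <- floor(n_tr / Bsz)
    ep_losses <- NULL
    for (bi in seq_len(n_batches)) {
      idx <- ord[(bi - 1) * Bsz + seq_len(Bsz)]
      Xb <- stack_rows(Xtr, idx)
      if (config$model == "vae") {
        beta_eff <- config$beta *
          min(1, ep / max(1, config$beta_warmup))
        st <- vae_step(Xb, models, ctx, basis, stats, Tm, config,
                       beta_eff = beta_eff)
        up <- adam_update(models$E, st$grads$E, opt$E, lr = config$lr)
        models$E <- up$params; opt$E <- up$state
        up <- adam_update(models$G, st$grads$G, opt$G, lr = config$lr)
        models$G <- up$params; opt$G <- up$state
        ep_losses <- rbind(ep_losses, st$losses)
      } else if (config$model == "lsgan") {
        st <- lsgan_step(Xb, models, ctx, basis, stats, Tm, config)
        up <- adam_update(models$D, st$grads$D, opt$D, lr = config$lr)
        models$D <- up$params; opt$D <- up$state
        up <- adam_update(models$G, st$grads$G, opt$G, lr = config$lr)
        models$G <- up$params; opt$G <- up$state
        ep_losses <- rbind(ep_losses, st$losses)
      } else {
        for (k in seq_len(config$n_critic)) {
          idc <- sample(n_tr, Bsz, replace = Bsz > n_tr)
          cs <- wgan_critic_step(stack_rows(Xtr, idc), models, ctx, config)
          up <- adam_update(models$C, cs$grads, opt$C, lr = config$lr)
          models$C <- clip_params(up$params, config$clip); opt$C <- up$state
        }
        gs <- wgan_generator_step(models, ctx, basis, stats, Tm, config, Bsz)
        up <- adam_update(models$G, gs$grads, opt$G, lr = config$lr)
        models$G <- up$params; opt$G <- up$state
        ep_losses <- rbind(ep_losses,
                           c(critic = cs$loss, g = gs$loss,
                             laplacian = gs$laplacian, le = gs$le))
      }
    }
    rec <- as.list(colMeans(ep_losses))
    rec$epoch <- ep
    if (config$model == "vae" && dim(Xva)[1] > 0) {
      vb <- stack_rows(Xva, seq_len(dim(Xva)[1]))
      enc <- encoder_forward(ctx, models$E, vb, dim(Xva)[1])
      gen <- generator_forward(ctx, models$G, enc$mu)
      rec$val_recon <- reconstruction_loss(vb, gen$X, N)
    }
    history[[ep]] <- rec
    if (!is.null(log_path))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 8), "\n",
          file = log_path, append = TRUE)
    if (verbose)
      message(sprintf("epoch %d: %s", ep,
                      paste(sprintf("%s=%.4f", names(rec), unlist(rec)),
                            collapse = " ")))
  }
  structure(list(models = models, ctx = ctx, config = config,
                 history = do.call(rbind, lapply(history, as.data.frame)),
                 topology_hash = ctx$topology_hash,
                 basis_hash = if (!is.null(basis)) basis_hash(basis) else NULL),
            class = "led_model")
}

#' Sample shapes from a trained generator
#'
#' Latents are drawn from `N(0, sigma_sample^2 I)` (the truncation trick
#' uses `sigma_sample < 1` to avoid low-density latent regions).
#'
#' @param model A `led_model` (or list with `models$G` and `ctx`).
#' @param n Number of shapes.
#' @param stats `template_stats` for de-standardization.
#' @param sigma_sample Sampling std.
#' @param seed RNG seed.
#' @return `n x N x 3` array of generated shapes (template units).
#' @export
sample_shapes <- function(model, n, stats, sigma_sample = 1, seed = 1L) {
  ctx <- model$ctx
  Z <- with_seed(seed,
    matrix(stats::rnorm(n * ctx$arch$latent_dim, sd = sigma_sample), n))
  gen <- generator_forward(ctx, model$models$G, Z)
  N <- ctx$sizes[1]
  out <- array(0, c(n, N, 3))
  for (i in seq_len(n))
    out[i, , ] <- destandardize(gen$X[(i - 1) * N + seq_len(N), ], stats)
  out
}
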