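# Losses, gradient routing, ablation identities, WGAN clipping and the
# training loop.

test_that("reconstruction loss identities and oracle", {
  set.seed(1)
  N <- 20; B <- 2
  X <- matrix(rnorm(B * N * 3), B * N, 3)
  expect_equal(reconstruction_loss(X, X, N), 0)
  expect_equal(reconstruction_loss(X, X + 1, N), 3)
  Xp <- X + matrix(rnorm(B * N * 3), B * N, 3)
  acc <- 0
  for (b in 1:B) for (i in 1:N) for (c in 1:3)
    acc <- acc + (Xp[(b - 1) * N + i, c] - X[(b - 1) * N + i, c])^2
  expect_equal(reconstruction_loss(X, Xp, N), acc / N / B, tolerance = 1e-12)
  expect_error(reconstruction_loss(X, Xp[-1, ]), "mismatch")
})

test_that("KL loss matches its closed forms", {
  z <- matrix(0, 2, 3)
  expect_equal(kl_loss(z, z), 0)
  expect_equal(kl_loss(z + 1, z), 1)
  expect_equal(kl_loss(z, z + 1), exp(2) - 2)
  g <- ledmesh:::kl_loss_grad(z + 0.3, z - 0.2)
  eps <- 1e-7
  fd <- (kl_loss(z + 0.3 + eps * (row(z) == 1 & col(z) == 2), z - 0.2) -
           kl_loss(z + 0.3 - eps * (row(z) == 1 & col(z) == 2), z - 0.2)) /
    (2 * eps)
  expect_equal(g$dmu[1, 2], fd, tolerance = 1e-6)
})

test_that("Laplacian loss is zero at neighbor centroids and penalizes spikes", {
  m <- icosphere(1)
  topo <- mesh_topology(m$faces)
  Tm <- tutte_laplacian(topo)
  # a constant mesh has every vertex at its neighbors' centroid
  Xc <- matrix(1, topo$n_vertices, 3)
  expect_lt(laplacian_loss(Xc, Tm), 1e-20)
  set.seed(2)
  X <- m$vertices
  base <- laplacian_loss(X, Tm)
  spike <- X; spike[5, ] <- spike[5, ] + 0.5
  expect_gt(laplacian_loss(spike, Tm), base)
  # explicit neighbor-averaging oracle
  A <- igraph::as_adjacency_matrix(
    igraph::graph_from_edgelist(topo$edges, directed = FALSE))
  deg <- Matrix::rowSums(A)
  avg <- as.matrix(A %*% X) / deg
  expect_equal(laplacian_loss(X, Tm),
               sum((X - avg)^2) / topo$n_vertices, tolerance = 1e-10)
})

make_small_batch <- function(B = 4) {
  pop <- small_population()
  st <- small_stats()
  list(Xb = stack_batch(pop$vertices, seq_len(B), st), pop = pop, st = st)
}

test_that("VAE step routes LE gradients as specified", {
  d <- make_small_batch()
  b <- small_basis()
  ctx <- small_ctx()
  Tm <- tutte_laplacian(d$pop$topology)
  cfg <- train_config("vae", eta1 = 0.5, eta2 = 0.5, seed = 1)
  B <- 4
  models <- list(E = init_network(ctx, "encoder", seed = 11),
                 G = init_network(ctx, "generator", seed = 12))
  eps_noise <- with_seed(3, matrix(rnorm(B * 8), B))
  stp <- vae_step(d$Xb, models, ctx, b, d$st, Tm, cfg,
                  eps_noise = eps_noise)
  expect_true(all(is.finite(unlist(stp$losses))))
  expect_true(all(stp$losses[c("recon", "laplacian", "kl", "le_enc",
                               "le_gen")] >= 0))

  # routed objective: eta1 is seen only by E, eta2 only by G with the
  # latent path frozen at the base parameters
  enc_base <- encoder_forward(ctx, models$E, d$Xb, B)
  z_base <- enc_base$mu + enc_base$sigma * eps_noise
  routed <- function(pE, pG) {
    enc <- encoder_forward(ctx, pE, d$Xb, B)
    z <- enc$mu + enc$sigma * eps_noise
    gen <- generator_forward(ctx, pG, z)
    gen_f <- generator_forward(ctx, pG, z_base)
    reconstruction_loss(d$Xb, gen$X, ctx$sizes[1]) +
      cfg$alpha * laplacian_loss(gen$X, Tm) +
      cfg$beta * kl_loss(enc$mu, enc$logsig) +
      cfg$eta1 * ledmesh:::le_loss_batch(d$Xb, enc$mu, b, d$st,
                                         want_grad = FALSE)$loss +
      cfg$eta2 * ledmesh:::le_loss_batch(gen_f$X, enc_base$mu, b, d$st,
                                         want_grad = FALSE)$loss
  }
  err_e <- fd_check_params(function(p) routed(p, models$G), models$E,
                           stp$grads$E, n = 5, eps = 1e-5)
  err_g <- fd_check_params(function(p) routed(models$E, p), models$G,
                           stp$grads$G, n = 5, eps = 1e-5)
  expect_lt(err_e, 1e-5)
  expect_lt(err_g, 1e-5)

  # the eta1 term itself never touches G: it is a function of E and X only
  le1 <- ledmesh:::le_loss_batch(d$Xb, enc_base$mu, b, d$st,
                                 want_grad = FALSE)$loss
  pG2 <- models$G
  pG2$conv1_W <- pG2$conv1_W + 0.1
  enc_after <- encoder_forward(ctx, models$E, d$Xb, B)
  expect_identical(ledmesh:::le_loss_batch(d$Xb, enc_after$mu, b, d$st,
                                           want_grad = FALSE)$loss, le1)

  # determinism of a full step under identical inputs
  stp2 <- vae_step(d$Xb, models, ctx, b, d$st, Tm, cfg,
                   eps_noise = eps_noise)
  expect_identical(stp$losses, stp2$losses)
  expect_equal(stp$grads, stp2$grads, tolerance = 0)
})

test_that("LED flavours with zero LE weights reduce to the vanilla models", {
  d <- make_small_batch()
  b <- small_basis()
  ctx <- small_ctx()
  Tm <- tutte_laplacian(d$pop$topology)
  B <- 4
  models <- list(E = init_network(ctx, "encoder", seed = 21),
                 G = init_network(ctx, "generator", seed = 22),
                 D = init_network(ctx, "discriminator", seed = 23),
                 C = init_network(ctx, "critic", seed = 24))
  eps_noise <- with_seed(9, matrix(rnorm(B * 8), B))

  led0 <- train_config("vae", eta1 = 0, eta2 = 0, seed = 1)
  s_led <- vae_step(d$Xb, models, ctx, b, d$st, Tm, led0,
                    eps_noise = eps_noise)
  s_van <- vae_step(d$Xb, models, ctx, NULL, d$st, Tm, led0,
                    eps_noise = eps_noise)
  for (nm in names(s_van$grads$E))
    expect_equal(s_led$grads$E[[nm]], s_van$grads$E[[nm]],
                 tolerance = 1e-7)
  for (nm in names(s_van$grads$G))
    expect_equal(s_led$grads$G[[nm]], s_van$grads$G[[nm]],
                 tolerance = 1e-7)
  expect_equal(s_led$losses[["le_enc"]], 0)
  expect_equal(s_led$losses[["le_gen"]], 0)

  lsg0 <- train_config("lsgan", eta = 0, alpha = 0, seed = 1)
  zd <- with_seed(31, matrix(rnorm(B * 8), B))
  zg <- with_seed(32, matrix(rnorm(B * 8), B))
  g_led <- lsgan_step(d$Xb, models, ctx, b, d$st, Tm, lsg0,
                      z_d = zd, z_g = zg)
  g_van <- lsgan_step(d$Xb, models, ctx, NULL, d$st, Tm, lsg0,
                      z_d = zd, z_g = zg)
  for (nm in names(g_van$grads$G))
    expect_equal(g_led$grads$G[[nm]], g_van$grads$G[[nm]], tolerance = 1e-7)

  wg0 <- train_config("wgan", eta = 0, alpha = 0, seed = 1)
  zg2 <- with_seed(33, matrix(rnorm(B * 8), B))
  w_led <- wgan_generator_step(models, ctx, b, d$st, Tm, wg0, B, z = zg2)
  w_van <- wgan_generator_step(models, ctx, NULL, d$st, Tm, wg0, B, z = zg2)
  for (nm in names(w_van$grads))
    expect_equal(w_led$grads[[nm]], w_van$grads[[nm]], tolerance = 1e-7)
})

test_that("LSGAN losses take their plug-in values for constant discriminators", {
  d <- make_small_batch()
  ctx <- small_ctx()
  Tm <- tutte_laplacian(d$pop$topology)
  B <- 4
  G <- init_network(ctx, "generator", seed = 41)
  # constant discriminator: zero everything, set the score bias
  const_D <- function(v) {
    D <- init_network(ctx, "discriminator", seed = 42)
    for (nm in setdiff(names(D), "role")) D[[nm]] <- D[[nm]] * 0
    D$score_b <- v
    D
  }
  cfg <- train_config("lsgan", eta = 0, alpha = 0, seed = 1)
  zd <- with_seed(5, matrix(rnorm(B * 8), B))
  # D == 1: L_D = 1/2 E[D(G(z))^2] = 1/2 ; generator loss = 0
  s1 <- lsgan_step(d$Xb, list(G = G, D = const_D(1)), ctx, NULL, d$st, Tm,
                   cfg, z_d = zd, z_g = zd)
  expect_equal(unname(s1$losses["d"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(s1$losses["g_adv"]), 0, tolerance = 1e-12)
  # D == 1/2: L_D = 1/2 * 1/4 + 1/2 * 1/4 = 1/4 ; L_G = 1/8
  s2 <- lsgan_step(d$Xb, list(G = G, D = const_D(0.5)), ctx, NULL, d$st, Tm,
                   cfg, z_d = zd, z_g = zd)
  expect_equal(unname(s2$losses["d"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(s2$losses["g_adv"]), 0.125, tolerance = 1e-12)
  # D == 0 on fakes, 1 on reals is the perfect discriminator: L_D = 0 and
  # the generator's adversarial loss is 1/2; covered by the formulas above
  s3 <- lsgan_step(d$Xb, list(G = G, D = const_D(0)), ctx, NULL, d$st, Tm,
                   cfg, z_d = zd, z_g = zd)
  expect_equal(unname(s3$losses["g_adv"]), 0.5, tolerance = 1e-12)
})

test_that("WGAN critic parameters are clipped into the bound after updates", {
  d <- make_small_batch()
  ctx <- small_ctx()
  cfg <- train_config("wgan", clip = 0.01, seed = 1)
  models <- list(G = init_network(ctx, "generator", seed = 51),
                 C = init_network(ctx, "critic", seed = 52))
  # clip identity: a parameter at 10c lands exactly at c
  models$C$score_b <- 10 * cfg$clip
  clipped <- clip_params(models$C, cfg$clip)
  expect_equal(clipped$score_b, cfg$clip)
  expect_true(all(vapply(clipped[setdiff(names(clipped), "role")],
                         function(p) all(abs(p) <= cfg$clip), logical(1))))
  # after a real critic update + clip, every parameter is inside the bound
  opt <- adam_init(models$C)
  z <- with_seed(6, matrix(rnorm(4 * 8), 4))
  cs <- wgan_critic_step(d$Xb, models, ctx, cfg, z = z)
  up <- adam_update(models$C, cs$grads, opt, lr = 1e-3)
  cl <- clip_params(up$params, cfg$clip)
  expect_true(all(vapply(cl[setdiff(names(cl), "role")],
                         function(p) all(p >= -cfg$clip & p <= cfg$clip),
                         logical(1))))
})

test_that("critic scores separate real from fake over critic-only training", {
  pop <- small_population()
  st <- small_stats()
  ctx <- small_ctx()
  cfg <- train_config("wgan", clip = 0.05, seed = 2)
  models <- list(G = init_network(ctx, "generator", seed = 61),
                 C = init_network(ctx, "critic", seed = 62))
  # start from a near-neutral critic so the initial gap is ~0
  for (nm in setdiff(names(models$C), "role"))
    models$C[[nm]] <- models$C[[nm]] * 0.01
  B <- 8
  Xb <- stack_batch(pop$vertices, 1:B, st)
  opt <- adam_init(models$C)
  gap <- function() {
    fake <- generator_forward(ctx, models$G,
                              with_seed(7, matrix(rnorm(B * 8), B)))$X
    cr <- scalar_forward(ctx, models$C, Xb, B)$score
    cf <- scalar_forward(ctx, models$C, fake, B)$score
    mean(cr) - mean(cf)
  }
  g0 <- gap()
  set.seed(8)
  for (k in 1:60) {
    cs <- wgan_critic_step(Xb, models, ctx, cfg)
    up <- adam_update(models$C, cs$grads, opt, lr = 1e-3)
    models$C <- clip_params(up$params, cfg$clip)
    opt <- up$state
  }
  expect_gt(gap(), g0)
  expect_gt(gap(), 0)
})

test_that("the training loop runs end to end, logs, and is deterministic", {
  pop <- small_population(60)
  st <- compute_template_stats(pop)
  b <- fit_spectral_basis(pop, st, kappa = 2)
  arch <- network_arch(channels = c(6L, 8L, 12L), spiral_length = 7L,
                       latent_dim = 8L)
  log <- tempfile(fileext = ".jsonl")
  cfg <- train_config("vae", epochs = 2, batch_size = 8, seed = 3)
  fit <- fit_generative_model(pop, st, cfg, basis = b, arch = arch,
                              log_path = log)
  expect_s3_class(fit, "led_model")
  expect_true(all(is.finite(as.matrix(fit$history[, c("total", "recon")]))))
  expect_equal(nrow(fit$history), 2)
  recs <- lapply(readLines(log), jsonlite::fromJSON)
  expect_length(recs, 2)
  expect_true(all(c("total", "epoch", "val_recon") %in% names(recs[[1]])))

  fit2 <- fit_generative_model(pop, st, cfg, basis = b, arch = arch)
  expect_equal(fit$models$G$dense_W, fit2$models$G$dense_W, tolerance = 0)
  expect_equal(fit$history$total, fit2$history$total, tolerance = 0)

  # refuses a basis fitted on a different topology
  spec2 <- synthetic_spec(subdivision = 1L, seed = 1L)
  pop2 <- sample_population(spec2, 20)
  st2 <- compute_template_stats(pop2)
  b2 <- fit_spectral_basis(pop2, st2, kappa = 2)
  expect_error(fit_generative_model(pop, st, cfg, basis = b2, arch = arch),
               "different topology")
  # GAN smoke runs with finite losses
  cfg_g <- train_config("lsgan", epochs = 1, batch_size = 8, seed = 3)
  fit_g <- fit_generative_model(pop, st, cfg_g, basis = b, arch = arch)
  expect_true(all(is.finite(as.matrix(fit_g$history))))
  cfg_w <- train_config("wgan", epochs = 1, batch_size = 8, n_critic = 2,
                        seed = 3)
  fit_w <- fit_generative_model(pop, st, cfg_w, basis = b, arch = arch)
  expect_true(all(is.finite(as.matrix(fit_w$history))))
  # critic ends inside the clip bound
  expect_true(all(vapply(
    fit_w$models$C[setdiff(names(fit_w$models$C), "role")],
    function(p) all(abs(p) <= cfg_w$clip), logical(1))))
})
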