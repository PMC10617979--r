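# Training losses. All operate on standardized coordinates; batches are
# (B*N) x 3 matrices. Reductions are means over batch (and latent dims for
# the KL term) so weights stay comparable across sizes.

#' Reconstruction loss
#'
#' Squared Frobenius distance per shape divided by the vertex count,
#' averaged over the batch: `mean_b ||X'_b - X_b||_F^2 / N`.
#'
#' @param X,Xp Input and reconstructed batches (`(B*N) x 3`).
#' @param N Vertices per shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(X, Xp, N = nrow(X)) {
  if (!all(dim(X) == dim(Xp))) stop2("shape mismatch in reconstruction loss")
  B <- nrow(X) / N
  sum((Xp - X)^2) / N / B
}

reconstruction_loss_grad <- function(X, Xp, N = nrow(X)) {
  B <- nrow(X) / N
  list(loss = sum((Xp - X)^2) / N / B, dXp = 2 * (Xp - X) / N / B)
}

#' KL divergence to the standard normal prior
#'
#' Per latent dimension `sigma^2 + mu^2 - log(sigma) - 1`, averaged over
#' dimensions and batch. Zero exactly when `mu = 0, sigma = 1`.
#'
#' @param mu,logsig B x latent matrices (`sigma = exp(logsig)`).
#' @return Non-negative scalar.
#' @export
kl_loss <- function(mu, logsig) {
  sig2 <- exp(2 * logsig)
  mean(sig2 + mu^2 - logsig - 1)
}

kl_loss_grad <- function(mu, logsig) {
  n <- length(mu)
  sig2 <- exp(2 * logsig)
  list(loss = mean(sig2 + mu^2 - logsig - 1),
       dmu = 2 * mu / n,
       dlogsig = (2 * sig2 - 1) / n)
}

#' Tutte-Laplacian smoothing loss
#'
#' `mean_b ||T X'_b||_F^2 / N` with the Tutte Laplacian of the full mesh:
#' penalizes vertices far from the centroid of their neighbors.
#'
#' @param Xp Generated batch (`(B*N) x 3`).
#' @param Tm Tutte Laplacian (N x N sparse) from [tutte_laplacian()].
#' @return Non-negative scalar.
#' @export
laplacian_loss <- function(Xp, Tm) {
  N <- nrow(Tm)
  B <- nrow(Xp) / N
  tot <- 0
  for (b in seq_len(B)) {
    TX <- as.matrix(Tm %*% Xp[(b - 1) * N + seq_len(N), , drop = FALSE])
    tot <- tot + sum(TX^2)
  }
  tot / N / B
}

laplacian_loss_grad <- function(Xp, Tm) {
  N <- nrow(Tm)
  B <- nrow(Xp) / N
  dXp <- Xp * 0
  tot <- 0
  for (b in seq_len(B)) {
    rows <- (b - 1) * N + seq_len(N)
    TX <- as.matrix(Tm %*% Xp[rows, , drop = FALSE])
    tot <- tot + sum(TX^2)
    dXp[rows, ] <- as.matrix(Matrix::crossprod(Tm, TX)) * 2 / N / B
  }
  list(loss = tot / N / B, dXp = dXp)
}

# Batched LE loss (mean over batch of per-shape LE loss) with gradients on
# standardized coordinates. `Z` is B x (F*kappa).
le_loss_batch <- function(Xstd, Z, basis, stats, want_grad = TRUE) {
  N <- nrow(stats$mean)
  B <- nrow(Xstd) / N
  loss <- 0
  dX <- if (want_grad) Xstd * 0 else NULL
  dZ <- if (want_grad) Z * 0 else NULL
  for (b in seq_len(B)) {
    rows <- (b - 1) * N + seq_len(N)
    if (want_grad) {
      g <- le_loss_grad(Xstd[rows, , drop = FALSE], Z[b, ], basis, stats)
      loss <- loss + g$loss
      dX[rows, ] <- g$dX / B
      dZ[b, ] <- g$dz / B
    } else {
      loss <- loss + le_loss(Xstd[rows, , drop = FALSE], Z[b, ], basis,
                             stats, standardized = TRUE)
    }
  }
  list(loss = loss / B, dX = dX, dZ = dZ)
}
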