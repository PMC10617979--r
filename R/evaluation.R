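# Generation-quality metrics (diversity, JSD, MMD, COV, 1-NNA with the
# Chamfer distance), the variation-predictability (VP) disentanglement
# metric, and per-attribute latent-traversal analysis.

#' Symmetric Chamfer distance between two point sets
#'
#' Mean over A of the squared distance to the nearest point of B, plus the
#' same with the roles swapped.
#'
#' @param A,B Point matrices (n x 3, m x 3).
#' @return Non-negative scalar.
#' @export
chamfer_distance <- function(A, B) {
  if (!nrow(A) || !nrow(B)) stop2("empty point set")
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  mean(apply(d2, 1, min)) + mean(apply(d2, 2, min))
}

# Pairwise chamfer matrix between two lists/arrays of shapes.
chamfer_cross <- function(gen, ref) {
  ng <- dim(gen)[1]; nr <- dim(ref)[1]
  out <- matrix(0, ng, nr)
  for (i in seq_len(ng)) {
    A <- gen[i, , ]
    a2 <- rowSums(A^2)
    for (j in seq_len(nr)) {
      B <- ref[j, , ]
      d2 <- outer(a2, rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      d2[d2 < 0] <- 0
      out[i, j] <- mean(apply(d2, 1, min)) + mean(apply(d2, 2, min))
    }
  }
  out
}

#' Diversity of a generated set
#'
#' Average over sampled pairs of the mean per-vertex Euclidean distance
#' (correspondence-based, not Chamfer).
#'
#' @param gen `n x N x 3` array of generated shapes.
#' @param n_pairs Number of random pairs (`Inf` = all pairs).
#' @param seed Pair-sampling seed.
#' @return Non-negative scalar (template units).
#' @export
diversity <- function(gen, n_pairs = 500L, seed = 1L) {
  n <- dim(gen)[1]
  if (n < 2) stop2("need at least two shapes")
  pairs <- utils::combn(n, 2)
  if (is.finite(n_pairs) && n_pairs < ncol(pairs))
    pairs <- pairs[, with_seed(seed, sample(ncol(pairs), n_pairs)),
                   drop = FALSE]
  mean(apply(pairs, 2, function(p)
    mean(sqrt(rowSums((gen[p[1], , ] - gen[p[2], , ])^2)))))
}

#' Jensen-Shannon divergence of marginal point distributions
#'
#' All vertices of each set are pooled and histogrammed on a fixed voxel
#' grid spanning the reference set's bounding box; the JSD (natural log)
#' between the two normalized histograms is returned.
#'
#' @param gen,ref `n x N x 3` arrays.
#' @param grid Voxels per axis.
#' @return Scalar in `[0, log 2]`.
#' @export
jsd_metric <- function(gen, ref, grid = 28L) {
  pts_g <- matrix(aperm(gen, c(2, 1, 3)), ncol = 3)
  pts_r <- matrix(aperm(ref, c(2, 1, 3)), ncol = 3)
  lo <- apply(pts_r, 2, min); hi <- apply(pts_r, 2, max)
  span <- pmax(hi - lo, 1e-12)
  bin <- function(P) {
    ix <- pmin(pmax(floor((sweep(P, 2, lo) %*% diag(1 / span)) * grid), 0),
               grid - 1)
    id <- ix[, 1] + grid * ix[, 2] + grid^2 * ix[, 3] + 1
    tabulate(id, nbins = grid^3)
  }
  p <- bin(pts_g); q <- bin(pts_r)
  if (sum(p) == 0 || sum(q) == 0) stop2("empty histogram")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Minimum matching distance and coverage
#'
#' MMD: mean over reference shapes of the Chamfer distance to the nearest
#' generated shape. COV: percentage of reference shapes that are the
#' Chamfer-nearest reference of at least one generated shape.
#'
#' @param gen,ref `n x N x 3` arrays.
#' @return List with `mmd` and `cov_percent`.
#' @export
mmd_cov <- function(gen, ref) {
  D <- chamfer_cross(gen, ref)
  mmd <- mean(apply(D, 2, min))
  matched <- unique(apply(D, 1, which.min))
  list(mmd = mmd, cov_percent = 100 * length(matched) / dim(ref)[1])
}

#' 1-nearest-neighbour accuracy deviation from 50%
#'
#' Leave-one-out 1-NN classification accuracy (Chamfer distance) over the
#' pooled generated + reference set; perfectly matched distributions give
#' 50%, so the absolute deviation `|accuracy - 50|` is returned.
#'
#' @param gen,ref `n x N x 3` arrays.
#' @return Scalar in `[0, 50]`.
#' @export
one_nna_delta <- function(gen, ref) {
  ng <- dim(gen)[1]; nr <- dim(ref)[1]
  pool <- array(0, c(ng + nr, dim(gen)[2], 3))
  pool[seq_len(ng), , ] <- gen
  pool[ng + seq_len(nr), , ] <- ref
  lab <- c(rep(1L, ng), rep(2L, nr))
  D <- chamfer_cross(pool, pool)
  diag(D) <- Inf
  pred <- lab[apply(D, 1, which.min)]
  abs(100 * mean(pred == lab) - 50)
}

#' Variation-predictability (VP) disentanglement metric
#'
#' Pairs of latents differing in exactly one (uniformly chosen) dimension
#' are decoded; a classifier (the encoder trunk with a softmax head) is
#' trained on the vertex-difference fields to predict the varied dimension.
#' The score is the mean test accuracy (in percent) over `s_rep` few-shot
#' repetitions, each training on a fraction `eta_vp` of the `n_pairs` pairs
#' for five epochs. Chance level is `100 / latent_dim`. The default
#' classifier rate (1e-3) compensates for the reduced pair count: at 100
#' training pairs the few-shot classifier barely moves at 1e-4 and the
#' metric loses its power to separate models.
#'
#' @param model A `led_model` (needs `models$G` and `ctx`). A function
#'   element `generate(z)` returning stacked standardized vertices
#'   overrides the network generator (useful for oracle generators in
#'   diagnostics).
#' @param n_pairs Number of generated pairs.
#' @param eta_vp Training fraction of the pairs.
#' @param s_rep Number of train/test repetitions.
#' @param epochs,lr,batch_size Classifier training settings.
#' @param seed RNG seed.
#' @return Mean test accuracy in percent.
#' @export
vp_metric <- function(model, n_pairs = 1000L, eta_vp = 0.1, s_rep = 3L,
                      epochs = 5L, lr = 1e-3, batch_size = 16L, seed = 1L) {
  ctx <- model$ctx
  Z <- ctx$arch$latent_dim
  N <- ctx$sizes[1]
  gen_fn <- model$generate %||%
    function(z) generator_forward(ctx, model$models$G, z)$X
  gen_chunk <- 25L
  labels <- integer(n_pairs)
  diffs <- array(0, c(n_pairs, N, 3))
  set.seed(fanout_seed(seed, "vp-pairs"))
  done <- 0L
  while (done < n_pairs) {
    k <- min(gen_chunk, n_pairs - done)
    z1 <- matrix(stats::rnorm(k * Z), k)
    dims <- sample.int(Z, k, replace = TRUE)
    z2 <- z1
    z2[cbind(seq_len(k), dims)] <- stats::rnorm(k)   # resampled coordinate
    g1 <- gen_fn(z1)
    g2 <- gen_fn(z2)
    for (i in seq_len(k)) {
      rows <- (i - 1) * N + seq_len(N)
      diffs[done + i, , ] <- g2[rows, ] - g1[rows, ]
    }
    labels[done + seq_len(k)] <- dims
    done <- done + k
  }
  accs <- numeric(s_rep)
  for (r in seq_len(s_rep)) {
    set.seed(fanout_seed(seed, paste0("vp-rep", r)))
    n_tr <- max(batch_size, round(eta_vp * n_pairs))
    ord <- sample.int(n_pairs)
    tr_idx <- ord[seq_len(n_tr)]
    te_idx <- ord[-seq_len(n_tr)]
    cls <- init_network(ctx, "classifier",
                        seed = fanout_seed(seed, paste0("vp-init", r)),
                        n_classes = Z)
    opt <- adam_init(cls)
    for (ep in seq_len(epochs)) {
      ord_tr <- sample(tr_idx)
      nb <- ceiling(length(ord_tr) / batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord_tr[((bi - 1) * batch_size + 1):min(bi * batch_size,
                                                      length(ord_tr))]
        B <- length(idx)
        Xb <- matrix(0, B * N, 3)
        for (k in seq_len(B))
          Xb[(k - 1) * N + seq_len(N), ] <- diffs[idx[k], , ]
        out <- classifier_forward(ctx, cls, Xb, B)
        lo <- out$logits
        lo <- lo - apply(lo, 1, max)
        p <- exp(lo) / rowSums(exp(lo))
        dlogits <- p
        dlogits[cbind(seq_len(B), labels[idx])] <-
          dlogits[cbind(seq_len(B), labels[idx])] - 1
        dlogits <- dlogits / B
        bw <- classifier_backward(ctx, cls, out, dlogits)
        up <- adam_update(cls, bw$grads, opt, lr = lr)
        cls <- up$params; opt <- up$state
      }
    }
    # test accuracy
    correct <- 0L
    nb <- ceiling(length(te_idx) / batch_size)
    for (bi in seq_len(nb)) {
      idx <- te_idx[((bi - 1) * batch_size + 1):min(bi * batch_size,
                                                    length(te_idx))]
      B <- length(idx)
      Xb <- matrix(0, B * N, 3)
      for (k in seq_len(B))
        Xb[(k - 1) * N + seq_len(N), ] <- diffs[idx[k], , ]
      out <- classifier_forward(ctx, cls, Xb, B)
      correct <- correct + sum(max.col(out$logits) == labels[idx])
    }
    accs[r] <- 100 * correct / length(te_idx)
  }
  mean(accs)
}

#' Latent-traversal distance map
#'
#' For each latent dimension, two shapes are generated with all latents at
#' their mean (0) and the chosen dimension at its minimum / maximum
#' (default -3 / +3); the per-vertex Euclidean distances between the two are
#' averaged within each attribute.
#'
#' @param model A `led_model`.
#' @param stats `template_stats` (distances are in template units).
#' @param labels Per-vertex attribute labels (defaults to the labels used
#'   by `topology` at fit time must be supplied here).
#' @param endpoints Traversal endpoints.
#' @return Matrix `latent_dim x n_attributes` of mean distances, with the
#'   per-vertex distance fields attached as attribute `"vertex_distances"`
#'   (`latent_dim x N`).
#' @export
traversal_distance_map <- function(model, stats, labels,
                                   endpoints = c(-3, 3)) {
  ctx <- model$ctx
  Z <- ctx$arch$latent_dim
  N <- ctx$sizes[1]
  nf <- max(labels)
  gen_fn <- model$generate %||%
    function(z) generator_forward(ctx, model$models$G, z)$X
  Zlo <- matrix(0, Z, Z); Zhi <- matrix(0, Z, Z)
  diag(Zlo) <- endpoints[1]; diag(Zhi) <- endpoints[2]
  Xlo <- gen_fn(Zlo)
  Xhi <- gen_fn(Zhi)
  out <- matrix(0, Z, nf)
  vd <- matrix(0, Z, N)
  for (d in seq_len(Z)) {
    rows <- (d - 1) * N + seq_len(N)
    a <- destandardize(Xlo[rows, ], stats)
    b <- destandardize(Xhi[rows, ], stats)
    dist <- sqrt(rowSums((a - b)^2))
    vd[d, ] <- dist
    out[d, ] <- vapply(seq_len(nf), function(w) mean(dist[labels == w]),
                       numeric(1))
  }
  attr(out, "vertex_distances") <- vd
  out
}

#' Per-latent localization score of a traversal map
#'
#' Ratio of the mean traversal distance inside the latent's designated
#' attribute (its block) to the largest mean distance among the other
#' attributes. Large ratios indicate that the latent moves only its own
#' attribute; all-zero rows (unused latents) report 1.
#'
#' @param map Output of [traversal_distance_map()].
#' @param kappa Latents per attribute (block size); dimension `d` belongs
#'   to attribute `ceiling(d / kappa)`.
#' @return Numeric vector of length `latent_dim`.
#' @export
disentanglement_localization_score <- function(map, kappa) {
  Z <- nrow(map)
  vapply(seq_len(Z), function(d) {
    w <- ceiling(d / kappa)
    own <- map[d, w]
    other <- max(map[d, -w])
    if (own == 0 && other == 0) return(1)
    own / max(other, 1e-12)
  }, numeric(1))
}

#' Full metric report for a trained model
#'
#' @param model A `led_model`.
#' @param pop Reference `shape_population` (its test split is the
#'   reference set unless too small, then all shapes).
#' @param stats `template_stats`.
#' @param n_generate Generated shapes per metric.
#' @param sigma_sample Sampling std (truncation trick).
#' @param seed RNG seed.
#' @return A list of metric values (a `metric_report`).
#' @export
evaluate_generation <- function(model, pop, stats, n_generate = 30L,
                                sigma_sample = 1, seed = 1L) {
  ref <- population_vertices(pop, "test")
  if (dim(ref)[1] < 5) ref <- population_vertices(pop, "all")
  if (dim(ref)[1] > n_generate)
    ref <- ref[seq_len(n_generate), , , drop = FALSE]
  gen <- sample_shapes(model, n_generate, stats,
                       sigma_sample = sigma_sample,
                       seed = fanout_seed(seed, "gen"))
  mc <- mmd_cov(gen, ref)
  lab <- pop$topology$attribute_labels
  tmap <- traversal_distance_map(model, stats, lab)
  kappa <- model$ctx$arch$latent_dim / pop$topology$n_attributes
  loc <- disentanglement_localization_score(tmap, kappa)
  structure(list(
    diversity = diversity(gen, seed = fanout_seed(seed, "div")),
    jsd = jsd_metric(gen, ref),
    mmd = mc$mmd,
    cov_percent = mc$cov_percent,
    one_nna_delta_percent = one_nna_delta(gen, ref),
    localization = loc,
    median_localization = stats::median(loc),
    traversal_map = tmap,
    n_generated = n_generate, n_reference = dim(ref)[1]),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report (%d generated vs %d reference)\n", x$n_generated,
    x$n_reference))
  cat(sprintf("  diversity: %.4f  jsd: %.4f  mmd: %.5f  cov: %.1f%%  1-NNA delta: %.1f%%\n",
              x$diversity, x$jsd, x$mmd, x$cov_percent,
              x$one_nna_delta_percent))
  cat(sprintf("  median localization: %.2f\n", x$median_localization))
  invisible(x)
}
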