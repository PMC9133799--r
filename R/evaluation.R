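#' Perceptual distance between two images
#'
#' Symmetric block-wise dissimilarity of channel-normalized backbone
#' features (same functional form as the perceptual reconstruction loss):
#' 0 iff the features agree at every block.
#'
#' @param a,b Images of identical shape.
#' @param backbone Backbone spec or model.
#' @return Scalar `>= 0`.
#' @export
perceptual_distance <- function(a, b, backbone) {
  perceptual_loss(a, b, backbone)
}

#' n-way identification accuracy of reconstructions
#'
#' For each reconstruction, a candidate set of its ground-truth image and
#' `n - 1` distractors (sampled seeded from `pool`) is scored by perceptual
#' distance; the trial is correct when the ground truth is the nearest
#' candidate. Ties are broken toward the lower candidate index (the ground
#' truth is placed first, so exact ties favour it deterministically; real
#' ties are measure-zero for continuous metrics). Distractor sets are fixed
#' by the seed, so compared methods see identical candidate sets.
#'
#' @param recons List of reconstructed images.
#' @param truths List of matching ground-truth images.
#' @param pool List of distractor images (may include the truths; the
#'   truth itself is excluded per trial when `pool_ids` identifies it).
#' @param n Number of candidates (`>= 2`).
#' @param n_draws Candidate-set draws per item (default 20).
#' @param seed Seed fixing the distractor sets.
#' @param backbone Backbone for the perceptual metric.
#' @param n_boot Bootstrap replicates for the 95% CI.
#' @param pool_ids Optional integer: for each recon, the index of its truth
#'   inside `pool` (so it is never drawn as its own distractor).
#' @return List with `accuracy`, `ci`, `per_item`.
#' @export
nway_identification <- function(recons, truths, pool, n, n_draws = 20L,
                                seed = 1L, backbone, n_boot = 1000L,
                                pool_ids = NULL) {
  vr_assert(n >= 2, "n must be at least 2")
  vr_assert(length(recons) == length(truths), "recons/truths misaligned")
  avail <- length(pool) - if (is.null(pool_ids)) 0L else 1L
  vr_assert(n - 1L <= avail, "n exceeds distractor pool size")
  bb <- as_backbone(backbone)
  ## precompute pyramids once: distances reuse them
  pyr <- function(img) extract_features(img, bb)
  pool_py <- lapply(pool, pyr)
  per_item <- numeric(length(recons))
  with_seed(seed, {
    for (i in seq_along(recons)) {
      rp <- pyr(recons[[i]])
      d_truth <- perceptual_core(rp$blocks, pyr(truths[[i]])$blocks)$value
      cand_pool <- seq_along(pool)
      if (!is.null(pool_ids)) cand_pool <- setdiff(cand_pool, pool_ids[i])
      hits <- 0L
      for (dr in seq_len(n_draws)) {
        distract <- sample(cand_pool, n - 1L)
        dd <- vapply(distract, function(j) {
          perceptual_core(rp$blocks, pool_py[[j]]$blocks)$value
        }, numeric(1))
        if (d_truth <= min(dd)) hits <- hits + 1L  # tie -> lower index wins
      }
      per_item[i] <- hits / n_draws
    }
    boots <- replicate(n_boot, mean(per_item[sample.int(
      length(per_item), replace = TRUE)]))
  })
  list(accuracy = mean(per_item),
       ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       per_item = per_item)
}

#' Split-half noise ceiling of repeated measurements
#'
#' Per voxel: repeats are split into random halves, the half-means are
#' correlated across stimuli, the correlation is Spearman-Brown corrected
#' (`2r / (1 + r)`), and the result is averaged over `n_splits` seeded
#' splits and clipped to `[0, 1]`.
#'
#' @param repeats Array `[n_stimuli, n_repeats, n_voxels]`.
#' @param n_splits Number of random splits (default 50).
#' @param seed Split seed.
#' @return A `NoiseCeilingEstimate`: list with `ceiling` (per-voxel vector
#'   in `[0, 1]`), `n_repeats`, `n_splits`.
#' @export
noise_ceiling <- function(repeats, n_splits = 50L, seed = 1L) {
  d <- dim(repeats)
  vr_assert(length(d) == 3, "repeats must be [stimuli, repeats, voxels]")
  K <- d[2]
  if (K < 2) {
    return(structure(list(ceiling = rep(NA_real_, d[3]), n_repeats = K,
                          n_splits = 0L, defined = FALSE),
                     class = "vr_noise_ceiling"))
  }
  nv <- d[3]
  acc <- matrix(0, n_splits, nv)
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      h1 <- sample(K, floor(K / 2))
      h2 <- setdiff(seq_len(K), h1)
      m1 <- apply(repeats[, h1, , drop = FALSE], c(1, 3), mean)
      m2 <- apply(repeats[, h2, , drop = FALSE], c(1, 3), mean)
      for (v in seq_len(nv)) {
        s1 <- stats::sd(m1[, v])
        s2 <- stats::sd(m2[, v])
        r <- if (s1 < 1e-12 || s2 < 1e-12) {
          if (s1 < 1e-12 && s2 < 1e-12) 1 else 0   # identical halves
        } else {
          stats::cor(m1[, v], m2[, v])
        }
        acc[s, v] <- 2 * r / (1 + r)
      }
    }
  })
  ceiling <- pmin(pmax(colMeans(acc), 0), 1)
  structure(list(ceiling = ceiling, n_repeats = K, n_splits = n_splits,
                 defined = TRUE),
            class = "vr_noise_ceiling")
}

#' Voxelwise prediction accuracy, raw and noise-corrected
#'
#' Raw accuracy is the Pearson correlation across stimuli between predicted
#' and measured responses per voxel; the corrected accuracy divides by the
#' voxel's noise ceiling where the ceiling exceeds `ceiling_floor` (0.1 by
#' default) and is `NA` (flagged) elsewhere.
#'
#' @param pred `[n_stimuli, n_voxels]` predicted responses.
#' @param measured `[n_stimuli, n_voxels]` measured (repeat-averaged)
#'   responses.
#' @param ceiling Optional [noise_ceiling()] result or per-voxel vector.
#' @param ceiling_floor Minimum ceiling for a stable ratio.
#' @return List with `raw`, `corrected` (per-voxel vectors), `flagged`
#'   (logical: ceiling at/below floor or degenerate variance).
#' @export
prediction_accuracy <- function(pred, measured, ceiling = NULL,
                                ceiling_floor = 0.1) {
  vr_assert(all(dim(pred) == dim(measured)), "pred/measured shape mismatch")
  vr_assert(nrow(pred) >= 3, "need at least 3 stimuli")
  nv <- ncol(pred)
  raw <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    if (stats::sd(pred[, v]) < 1e-12 || stats::sd(measured[, v]) < 1e-12) next
    raw[v] <- stats::cor(pred[, v], measured[, v])
  }
  corrected <- rep(NA_real_, nv)
  flagged <- !is.finite(raw)
  if (!is.null(ceiling)) {
    cl <- if (inherits(ceiling, "vr_noise_ceiling")) ceiling$ceiling else
      ceiling
    vr_assert(length(cl) == nv, "ceiling length mismatch")
    ok <- is.finite(raw) & is.finite(cl) & cl > ceiling_floor
    corrected[ok] <- raw[ok] / cl[ok]
    flagged <- flagged | !ok
  }
  list(raw = raw, corrected = corrected, flagged = flagged)
}
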