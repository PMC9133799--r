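#' Encoder configuration
#'
#' The encoder maps an image to a predicted voxel-response vector through
#' parallel branches built on backbone blocks (default blocks 1-4). Each
#' branch reduces its block to a compact `g x g x branch_channels` tensor
#' (batch norm, 3x3 convolution, ReLU, resize to the branch grid, batch
#' norm), then a space-feature locally-connected layer reads out one value
#' per voxel; a non-negative per-voxel mixing layer combines the branches.
#' Branch grids default to `side/4` for all but the last branch and
#' `side/8` for the last, which at 112 px input reproduces the reference
#' tensor shapes (28x28x32 for branches 1-3, 14x14x32 for branch 4; after
#' 3x3 neighbour stacking 26x26x288 and 12x12x288).
#'
#' @param n_voxels Number of voxels Nv.
#' @param image_side Input image side in pixels (default 112).
#' @param in_channels Image channels (3 RGB or 1 grayscale).
#' @param branch_levels Backbone block indices feeding the branches.
#' @param branch_channels Reduced channel count per branch (default 32).
#' @param alpha Mixing weight of the MSE term in the fMRI loss (default 0.9).
#' @param shift_augment_px Max absolute random shift (pixels) during
#'   training; defaults to 3 px at 112 input, scaled proportionally.
#' @param spatial_tv_weight Weight of the total-variation penalty on the
#'   voxel spatial maps (default 0.1).
#' @param branch_grids Optional integer vector of branch grid sides.
#' @return A `vr_encoder_config`.
#' @export
encoder_config <- function(n_voxels, image_side = 112L, in_channels = 3L,
                           branch_levels = 1:4, branch_channels = 32L,
                           alpha = 0.9, shift_augment_px = NULL,
                           spatial_tv_weight = 0.1, branch_grids = NULL,
                           nonneg_spatial_maps = FALSE) {
  vr_assert(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  vr_assert(image_side %% 8 == 0, "image_side must be divisible by 8")
  nb <- length(branch_levels)
  if (is.null(branch_grids)) {
    branch_grids <- c(rep(image_side %/% 4L, nb - 1L), image_side %/% 8L)
  }
  vr_assert(all(branch_grids >= 3), "branch grids too small for 3x3 stacking")
  if (is.null(shift_augment_px)) {
    shift_augment_px <- as.integer(round(3 * image_side / 112))
  }
  vr_assert(shift_augment_px >= 0, "shift_augment_px must be >= 0")
  structure(list(n_voxels = as.integer(n_voxels),
                 image_side = as.integer(image_side),
                 in_channels = as.integer(in_channels),
                 branch_levels = as.integer(branch_levels),
                 branch_channels = as.integer(branch_channels),
                 alpha = alpha,
                 shift_augment_px = as.integer(shift_augment_px),
                 spatial_tv_weight = spatial_tv_weight,
                 branch_grids = as.integer(branch_grids),
                 nonneg_spatial_maps = isTRUE(nonneg_spatial_maps)),
            class = "vr_encoder_config")
}

#' Build an untrained encoder
#'
#' Weights are Glorot-normal except the final branch-mixing layer, which is
#' 1-initialized and constrained to remain non-negative during training.
#'
#' @param cfg An [encoder_config()].
#' @param backbone Backbone spec or model providing the branch features.
#' @param seed Seed for weight initialization.
#' @return A `vr_encoder` model.
#' @export
build_encoder <- function(cfg, backbone, seed = 1L) {
  vr_assert(inherits(cfg, "vr_encoder_config"), "cfg must be encoder_config")
  bb <- as_backbone(backbone)
  vr_assert(max(cfg$branch_levels) <= bb$spec$n_blocks,
            "branch level exceeds backbone depth")
  Nv <- cfg$n_voxels
  bc <- cfg$branch_channels
  params <- list()
  buffers <- list()
  with_seed(seed, {
    for (i in seq_along(cfg$branch_levels)) {
      lev <- cfg$branch_levels[i]
      cin <- bb$spec$channels[lev]
      g <- cfg$branch_grids[i]
      P <- (g - 2L)^2
      pre <- paste0("br", i, "_")
      params[[paste0(pre, "bn0g")]] <- rep(1, cin)
      params[[paste0(pre, "bn0b")]] <- rep(0, cin)
      params[[paste0(pre, "convW")]] <-
        glorot_normal(c(9L * cin, bc), 9L * cin, bc)
      params[[paste0(pre, "convb")]] <- rep(0, bc)
      params[[paste0(pre, "bn1g")]] <- rep(1, bc)
      params[[paste0(pre, "bn1b")]] <- rep(0, bc)
      sp0 <- glorot_normal(c(P, Nv), P, 1L)
      if (cfg$nonneg_spatial_maps) sp0 <- abs(sp0)
      params[[paste0(pre, "sp")]] <- sp0
      params[[paste0(pre, "ch")]] <- glorot_normal(c(9L * bc, Nv), 9L * bc, 1L)
      buffers[[paste0(pre, "bn0")]] <- bn_buf_init(cin)
      buffers[[paste0(pre, "bn1")]] <- bn_buf_init(bc)
    }
    params$mix <- matrix(1, length(cfg$branch_levels), Nv)
    params$bias <- rep(0, Nv)
  })
  structure(list(cfg = cfg, backbone = bb, params = params,
                 buffers = buffers), class = "vr_encoder")
}

## Full forward pass on a batch [H,W,C,N]. Returns responses [N, Nv] and,
## when want_cache, everything needed for the backward pass.
encoder_fw <- function(enc, x, training = FALSE, want_cache = FALSE) {
  cfg <- enc$cfg
  d <- dim(x)
  vr_assert(d[1] == cfg$image_side && d[2] == cfg$image_side,
            "image resolution does not match encoder config")
  N <- d[4]
  Nv <- cfg$n_voxels
  bbf <- backbone_fw(enc$backbone, x, levels = cfg$branch_levels,
                     want_cache = want_cache)
  nb <- length(cfg$branch_levels)
  outs <- array(0, c(nb, Nv, N))
  brc <- if (want_cache) vector("list", nb) else NULL
  for (i in seq_len(nb)) {
    pre <- paste0("br", i, "_")
    f <- bbf$features[[cfg$branch_levels[i]]]
    bn0 <- bn_fw(f, enc$params[[paste0(pre, "bn0g")]],
                 enc$params[[paste0(pre, "bn0b")]],
                 enc$buffers[[paste0(pre, "bn0")]], training)
    if (training) enc$buffers[[paste0(pre, "bn0")]] <- bn0$buf
    cv <- conv2d_fw(bn0$out, enc$params[[paste0(pre, "convW")]],
                    enc$params[[paste0(pre, "convb")]], k = 3L, pad = 1L)
    rl <- relu_fw(cv$out)
    rs <- resize_to_fw(rl$out, cfg$branch_grids[i])
    bn1 <- bn_fw(rs$out, enc$params[[paste0(pre, "bn1g")]],
                 enc$params[[paste0(pre, "bn1b")]],
                 enc$buffers[[paste0(pre, "bn1")]], training)
    if (training) enc$buffers[[paste0(pre, "bn1")]] <- bn1$buf
    Wsp <- enc$params[[paste0(pre, "sp")]]
    Wch <- enc$params[[paste0(pre, "ch")]]
    ## neighbour stacking + per-voxel spatial pooling + channel weighting
    z <- bn1$out
    outs[i, , ] <- cpp_readout_fw(z, as.integer(dim(z)), Wsp, Wch)
    if (want_cache) {
      brc[[i]] <- list(bn0 = bn0$cache, conv = cv$cache, mask = rl$mask,
                       rs_ops = rs$ops, bn1 = bn1$cache, z = z)
    }
  }
  Y <- matrix(0, N, Nv)
  for (n in seq_len(N)) {
    Y[n, ] <- colSums(enc$params$mix * matrix(outs[, , n], nb, Nv)) +
      enc$params$bias
  }
  list(Y = Y, enc = enc,
       cache = if (want_cache) {
         list(bbf = bbf, brc = brc, outs = outs, N = N, dims = d)
       })
}

## Backward pass from dY [N, Nv]. Returns flat gradient list matching the
## encoder parameter names, and when want_dx the input-image gradient.
encoder_bw <- function(enc, cache, dY, want_dx = FALSE) {
  cfg <- enc$cfg
  N <- cache$N
  Nv <- cfg$n_voxels
  nb <- length(cfg$branch_levels)
  grads <- lapply(enc$params, function(p) p * 0)
  dfeats <- vector("list", max(cfg$branch_levels))
  for (n in seq_len(N)) {
    grads$mix <- grads$mix +
      matrix(cache$outs[, , n], nb, Nv) *
      matrix(dY[n, ], nb, Nv, byrow = TRUE)
  }
  grads$bias <- colSums(dY)
  for (i in seq_len(nb)) {
    pre <- paste0("br", i, "_")
    ca <- cache$brc[[i]]
    Wsp <- enc$params[[paste0(pre, "sp")]]
    Wch <- enc$params[[paste0(pre, "ch")]]
    ## upstream per-voxel gradient of this branch's output, per sample
    doutb <- t(dY * matrix(enc$params$mix[i, ], N, Nv, byrow = TRUE))
    rb <- cpp_readout_bw(ca$z, as.integer(dim(ca$z)), Wsp, Wch, doutb)
    grads[[paste0(pre, "ch")]] <- rb$dWch
    grads[[paste0(pre, "sp")]] <- rb$dWsp
    dz4 <- rb$dz
    b1 <- bn_bw(dz4, ca$bn1)
    grads[[paste0(pre, "bn1g")]] <- b1$dgamma
    grads[[paste0(pre, "bn1b")]] <- b1$dbeta
    dr <- resize_to_bw(b1$dx, ca$rs_ops)
    dr <- relu_bw(dr, ca$mask)
    cv <- conv2d_bw(dr, ca$conv, need_dx = TRUE)
    grads[[paste0(pre, "convW")]] <- cv$dW
    grads[[paste0(pre, "convb")]] <- cv$db
    b0 <- bn_bw(cv$dx, ca$bn0)
    grads[[paste0(pre, "bn0g")]] <- b0$dgamma
    grads[[paste0(pre, "bn0b")]] <- b0$dbeta
    lev <- cfg$branch_levels[i]
    dfeats[[lev]] <- if (is.null(dfeats[[lev]])) b0$dx else
      dfeats[[lev]] + b0$dx
  }
  dx <- NULL
  if (want_dx) dx <- backbone_bw(enc$backbone, cache$bbf, dfeats)
  list(grads = grads, dx = dx)
}

#' Predict voxel responses for images
#'
#' @param model A trained (or freshly built) `vr_encoder`.
#' @param image A single `[H, W, C]` image or a list of such images.
#' @return A length-`Nv` vector for a single image, else an `[N, Nv]` matrix.
#' @export
encode <- function(model, image) {
  vr_assert(inherits(model, "vr_encoder"), "model must be a vr_encoder")
  single <- !is.list(image)
  imgs <- if (single) list(image) else image
  x <- batch_images(imgs, model$cfg$image_side, model$cfg$in_channels)
  Y <- encoder_fw(model, x, training = FALSE)$Y
  if (single) Y[1, ] else Y
}

batch_images <- function(imgs, side, channels) {
  x <- array(0, c(side, side, channels, length(imgs)))
  for (n in seq_along(imgs)) {
    im <- imgs[[n]]
    d <- dim(im)
    vr_assert(length(d) == 3 && d[1] == side && d[2] == side,
              "image resolution does not match configured resolution")
    if (d[3] == 1L && channels == 3L) im <- im[, , c(1L, 1L, 1L)]
    vr_assert(dim(im)[3] == channels, "image channel mismatch")
    x[, , , n] <- im
  }
  x
}

#' Neighbour-stack a feature tensor
#'
#' For every interior spatial coordinate, the channel values of the 3x3
#' neighbourhood are stacked along the channel axis: a `g x g x C` tensor
#' becomes `(g-2) x (g-2) x 9C` (the one-pixel boundary is dropped).
#'
#' @param tensor Numeric array `[g, g, C]`.
#' @return Array `[(g-2), (g-2), 9C]`.
#' @export
neighbor_stack <- function(tensor) {
  d <- dim(tensor)
  vr_assert(length(d) == 3 && d[1] >= 3 && d[2] == d[1],
            "tensor must be square with side >= 3")
  pl <- im2col_plan(d[1], d[2], d[3], 3L, 0L)
  X <- matrix(as.vector(tensor)[pl$M], nrow = nrow(pl$M))
  array(t(X), c(d[1] - 2L, d[2] - 2L, 9L * d[3]))
}

#' Space-feature locally-connected readout
#'
#' Applies the voxel readout of the encoder to one feature tensor: (i) 3x3
#' neighbour stacking with boundary trim, (ii) per-voxel spatial pooling by
#' the voxel's spatial map (yielding a `9C x Nv` space-reduced tensor), and
#' (iii) per-voxel cross-channel weighting, yielding one value per voxel.
#'
#' @param tensor Numeric array `[g, g, C]`.
#' @param spatial_maps `[(g-2)^2, Nv]` matrix (or `[(g-2), (g-2), Nv]`
#'   array) of per-voxel spatial maps.
#' @param channel_weights `[9C, Nv]` matrix of per-voxel channel weights.
#' @return List with `values` (length `Nv`), `reduced` (`9C x Nv`) and
#'   `stacked` (`(g-2) x (g-2) x 9C`).
#' @export
space_feature_locally_connected <- function(tensor, spatial_maps,
                                            channel_weights) {
  st <- neighbor_stack(tensor)
  P <- dim(st)[1] * dim(st)[2]
  C9 <- dim(st)[3]
  if (length(dim(spatial_maps)) == 3) {
    vr_assert(dim(spatial_maps)[1] == dim(st)[1] &&
                dim(spatial_maps)[2] == dim(st)[2],
              "spatial map grid does not match trimmed tensor")
    spatial_maps <- matrix(spatial_maps, nrow = P)
  }
  vr_assert(nrow(spatial_maps) == P,
            "spatial map size does not match trimmed tensor")
  vr_assert(nrow(channel_weights) == C9,
            "channel weight rows must equal stacked channel count")
  vr_assert(ncol(spatial_maps) == ncol(channel_weights),
            "spatial maps and channel weights disagree on voxel count")
  X <- t(matrix(st, nrow = P))                 # [9C, P]
  reduced <- X %*% spatial_maps                # [9C, Nv]
  list(values = colSums(reduced * channel_weights), reduced = reduced,
       stacked = st)
}

#' fMRI loss: convex mix of MSE and negative cosine proximity
#'
#' `alpha * MSE(r_hat, r) - (1 - alpha) * cos(r_hat, r)`; the minimum
#' `-(1 - alpha)` is attained iff `r_hat = r` (nonzero). The cosine of a
#' zero vector is defined as 0 (and flagged via a warning-free log
#' attribute) so degenerate predictions never produce NaN.
#'
#' @param r_hat Predicted responses (vector, or `[N, Nv]` matrix averaged
#'   over rows).
#' @param r Measured responses of matching shape.
#' @param alpha Mixing weight in `[0, 1]`.
#' @return Scalar loss.
#' @export
fmri_loss <- function(r_hat, r, alpha = 0.9) {
  fmri_loss_grad(r_hat, r, alpha, want_grad = FALSE)$value
}

fmri_loss_grad <- function(r_hat, r, alpha, want_grad = TRUE) {
  vr_assert(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  if (is.null(dim(r_hat))) r_hat <- matrix(r_hat, nrow = 1)
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  vr_assert(all(dim(r_hat) == dim(r)), "response lengths differ")
  N <- nrow(r_hat)
  Nv <- ncol(r_hat)
  total <- 0
  grad <- if (want_grad) matrix(0, N, Nv) else NULL
  for (n in seq_len(N)) {
    a <- r_hat[n, ]
    b <- r[n, ]
    e <- a - b
    mse <- mean(e * e)
    cf <- cos_flat(a, b, want_grad = want_grad)
    total <- total + alpha * mse - (1 - alpha) * cf$cos
    if (want_grad) {
      g <- alpha * 2 * e / Nv
      if (!cf$degenerate) g <- g - (1 - alpha) * as.vector(cf$da)
      grad[n, ] <- g / N
    }
  }
  list(value = total / N, grad = grad)
}

#' Randomly shift an image by up to `max_px` pixels (edge replication)
#'
#' Emulates fixation jitter: the image is translated by integer offsets
#' drawn uniformly from `[-max_px, max_px]^2`, padding by edge replication.
#'
#' @param image `[H, W, C]` array.
#' @param max_px Maximum absolute shift.
#' @param rng_seed Optional seed for a reproducible draw; when `NULL` the
#'   current RNG stream is used (as during training).
#' @return Shifted image of the same shape.
#' @export
shift_augment <- function(image, max_px, rng_seed = NULL) {
  vr_assert(max_px >= 0, "max_px must be >= 0")
  if (max_px == 0) return(image)
  draw <- function() sample(seq(-max_px, max_px), 2, replace = TRUE)
  s <- if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
  shift_image(image, dy = s[1], dx = s[2])
}

## translate by (dy, dx): positive dx moves content toward larger columns.
shift_image <- function(image, dy, dx) {
  d <- dim(image)
  ri <- pmin(pmax(seq_len(d[1]) - dy, 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2]) - dx, 1L), d[2])
  image[ri, ci, , drop = FALSE]
}

## TV penalty over all branch spatial maps (value + per-branch gradients).
spatial_map_tv <- function(enc, want_grad = TRUE) {
  cfg <- enc$cfg
  nb <- length(cfg$branch_levels)
  total <- 0
  grads <- list()
  for (i in seq_len(nb)) {
    pre <- paste0("br", i, "_")
    g <- cfg$branch_grids[i] - 2L
    maps <- array(enc$params[[paste0(pre, "sp")]], c(g, g, cfg$n_voxels))
    tv <- tv_value_grad(maps, want_grad = want_grad)
    total <- total + tv$value / nb
    if (want_grad) {
      grads[[paste0(pre, "sp")]] <-
        matrix(tv$grad, g * g, cfg$n_voxels) / nb
    }
  }
  list(value = total, grads = grads)
}
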