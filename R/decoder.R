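#' Decoder configuration
#'
#' The decoder maps a voxel-response vector to an image: a per-output-unit
#' (locally-connected) linear layer reshapes the responses into
#' `base_resolution x base_resolution x base_channels` feature maps,
#' followed by `n_up_blocks` blocks of x2 nearest-neighbour upsampling,
#' convolution + ReLU, and group normalization, and a final convolution
#' with a sigmoid that keeps outputs in (0, 1). With the defaults
#' (14, 64 channels, 3 blocks, 5x5 kernels) the output is 112 x 112.
#'
#' @param n_voxels Number of input voxels.
#' @param base_resolution Initial spatial side (default 14).
#' @param base_channels Initial feature map count (default 64).
#' @param n_up_blocks Number of upsampling blocks (default 3).
#' @param up_channels Channels per up block (default `base_channels` each).
#' @param out_channels 3 (RGB) or 1 (grayscale).
#' @param kernel Convolution kernel side (default 5).
#' @param gn_groups Group-normalization groups (default 16, reduced when a
#'   block has fewer channels).
#' @param loss_weights Named numeric: weights of the rgb, perceptual and tv
#'   components of the image loss (defaults 1, 1, 0.1).
#' @return A `vr_decoder_config`.
#' @export
decoder_config <- function(n_voxels, base_resolution = 14L,
                           base_channels = 64L, n_up_blocks = 3L,
                           up_channels = rep(base_channels, n_up_blocks),
                           out_channels = 3L, kernel = 5L, gn_groups = 16L,
                           loss_weights = c(rgb = 1, perceptual = 1,
                                            tv = 0.1)) {
  vr_assert(length(up_channels) == n_up_blocks,
            "one channel count per up block")
  vr_assert(out_channels %in% c(1L, 3L), "out_channels must be 1 or 3")
  vr_assert(all(c("rgb", "perceptual", "tv") %in% names(loss_weights)),
            "loss_weights needs rgb, perceptual, tv entries")
  structure(list(n_voxels = as.integer(n_voxels),
                 base_resolution = as.integer(base_resolution),
                 base_channels = as.integer(base_channels),
                 n_up_blocks = as.integer(n_up_blocks),
                 up_channels = as.integer(up_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel),
                 gn_groups = as.integer(gn_groups),
                 loss_weights = loss_weights,
                 out_side = as.integer(base_resolution * 2^n_up_blocks)),
            class = "vr_decoder_config")
}

#' Build an untrained decoder
#'
#' @param cfg A [decoder_config()].
#' @param seed Seed for Glorot-normal initialization.
#' @return A `vr_decoder` model.
#' @export
build_decoder <- function(cfg, seed = 1L) {
  vr_assert(inherits(cfg, "vr_decoder_config"), "cfg must be decoder_config")
  k <- cfg$kernel
  D0 <- cfg$base_resolution^2 * cfg$base_channels
  params <- list()
  with_seed(seed, {
    params$W0 <- glorot_normal(c(cfg$n_voxels, D0), cfg$n_voxels, 1L)
    params$b0 <- rep(0, D0)
    cin <- cfg$base_channels
    for (i in seq_len(cfg$n_up_blocks)) {
      cout <- cfg$up_channels[i]
      params[[paste0("upW", i)]] <-
        glorot_normal(c(k * k * cin, cout), k * k * cin, cout)
      params[[paste0("upb", i)]] <- rep(0, cout)
      params[[paste0("gng", i)]] <- rep(1, cout)
      params[[paste0("gnb", i)]] <- rep(0, cout)
      cin <- cout
    }
    params$outW <- glorot_normal(c(k * k * cin, cfg$out_channels),
                                 k * k * cin, cfg$out_channels)
    params$outb <- rep(0, cfg$out_channels)
  })
  structure(list(cfg = cfg, params = params), class = "vr_decoder")
}

## Forward on a batch of responses R [N, Nv] -> images [side, side, C, N].
decoder_fw <- function(dec, R, want_cache = FALSE) {
  cfg <- dec$cfg
  vr_assert(ncol(R) == cfg$n_voxels, "response length does not match Nv")
  N <- nrow(R)
  k <- cfg$kernel
  pad <- (k - 1L) %/% 2L
  z0 <- R %*% dec$params$W0
  z0 <- sweep(z0, 2, dec$params$b0, `+`)         # [N, D0]
  cur <- array(t(z0), c(cfg$base_resolution, cfg$base_resolution,
                        cfg$base_channels, N))
  blocks <- if (want_cache) vector("list", cfg$n_up_blocks) else NULL
  for (i in seq_len(cfg$n_up_blocks)) {
    up <- upsample2_fw(cur)
    cv <- conv2d_fw(up, dec$params[[paste0("upW", i)]],
                    dec$params[[paste0("upb", i)]], k = k, pad = pad)
    rl <- relu_fw(cv$out)
    groups <- min(cfg$gn_groups, cfg$up_channels[i])
    gn <- gn_fw(rl$out, dec$params[[paste0("gng", i)]],
                dec$params[[paste0("gnb", i)]], groups)
    cur <- gn$out
    if (want_cache) {
      blocks[[i]] <- list(conv = cv$cache, mask = rl$mask, gn = gn$cache)
    }
  }
  cv <- conv2d_fw(cur, dec$params$outW, dec$params$outb, k = k, pad = pad)
  sg <- sigmoid_fw(cv$out)
  list(out = sg$out,
       cache = if (want_cache) {
         list(blocks = blocks, outconv = cv$cache, s = sg$s, N = N,
              R = R)
       })
}

## Backward from d out [side, side, C, N]; gradients for decoder params only.
decoder_bw <- function(dec, cache, dout) {
  cfg <- dec$cfg
  grads <- list()
  dcur <- sigmoid_bw(dout, cache$s)
  cv <- conv2d_bw(dcur, cache$outconv, need_dx = TRUE)
  grads$outW <- cv$dW
  grads$outb <- cv$db
  dcur <- cv$dx
  for (i in rev(seq_len(cfg$n_up_blocks))) {
    bl <- cache$blocks[[i]]
    gn <- gn_bw(dcur, bl$gn)
    grads[[paste0("gng", i)]] <- gn$dgamma
    grads[[paste0("gnb", i)]] <- gn$dbeta
    dcur <- relu_bw(gn$dx, bl$mask)
    cv <- conv2d_bw(dcur, bl$conv, need_dx = TRUE)
    grads[[paste0("upW", i)]] <- cv$dW
    grads[[paste0("upb", i)]] <- cv$db
    dcur <- upsample2_bw(cv$dx)
  }
  D0 <- cfg$base_resolution^2 * cfg$base_channels
  dz0 <- t(matrix(dcur, D0, cache$N))            # [N, D0]
  grads$W0 <- crossprod(cache$R, dz0)
  grads$b0 <- colSums(dz0)
  grads
}

#' Reconstruct an image from a voxel-response vector
#'
#' @param model A `vr_decoder`.
#' @param r Length-`Nv` response vector, or an `[N, Nv]` matrix.
#' @return A `[side, side, C]` image in (0, 1), or a list of images.
#' @export
decode <- function(model, r) {
  vr_assert(inherits(model, "vr_decoder"), "model must be a vr_decoder")
  single <- is.null(dim(r))
  R <- if (single) matrix(r, nrow = 1) else r
  vr_assert(ncol(R) == model$cfg$n_voxels,
            "response length does not match decoder voxel count")
  out <- decoder_fw(model, R)$out
  if (single) return(from_batch(out))
  lapply(seq_len(nrow(R)), function(n) array(out[, , , n], dim(out)[1:3]))
}

#' Mean absolute pixel difference between two images
#'
#' @param s_hat,s Images of identical shape with values in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
rgb_loss <- function(s_hat, s) {
  vr_assert(identical(dim(s_hat), dim(s)), "image shapes differ")
  mean(abs(s_hat - s))
}

#' Perceptual dissimilarity between two images
#'
#' Block-wise cosine between channel-normalized backbone features, combined
#' as `(1/B) * sum_b (1 - cos_b) / 2`, which lies in `[0, 1]` and is 0 iff
#' the features agree at every block.
#'
#' @param s_hat,s Images of identical shape.
#' @param backbone Backbone spec or model.
#' @param levels Blocks to use (default: all).
#' @return Scalar in `[0, 1]`.
#' @export
perceptual_loss <- function(s_hat, s, backbone, levels = NULL) {
  vr_assert(identical(dim(s_hat), dim(s)), "image shapes differ")
  bb <- as_backbone(backbone)
  if (is.null(levels)) levels <- seq_len(bb$spec$n_blocks)
  fa <- backbone_fw(bb, as_batch(s_hat), levels = levels)$features[levels]
  fb <- backbone_fw(bb, as_batch(s), levels = levels)$features[levels]
  perceptual_core(fa, fb)$value
}

#' Total-variation regularizer of an image
#'
#' Mean absolute first difference over horizontal and vertical neighbour
#' pairs; 0 iff the image is constant and exactly 1 for a binary
#' checkerboard.
#'
#' @param s_hat Image array.
#' @return Scalar `>= 0`.
#' @export
tv_reg <- function(s_hat) {
  if (length(dim(s_hat)) == 2) s_hat <- array(s_hat, c(dim(s_hat), 1))
  tv_value_grad(s_hat, want_grad = FALSE)$value
}

#' Composite image reconstruction loss
#'
#' `total = w_rgb * L_RGB + w_perceptual * L_perceptual + w_tv * TV`, with
#' each component normalized into `[0, 1]` and equal default weights for
#' the two data terms.
#'
#' @param s_hat,s Images of identical shape.
#' @param backbone Backbone spec or model for the perceptual term.
#' @param weights Named weights (default from the decoder config scheme:
#'   rgb 1, perceptual 1, tv 0.1).
#' @return An `ImageLossReport`: list with `l_rgb`, `l_perceptual`, `tv`,
#'   `total`.
#' @export
image_loss <- function(s_hat, s, backbone,
                       weights = c(rgb = 1, perceptual = 1, tv = 0.1)) {
  l1 <- rgb_loss(s_hat, s)
  lp <- perceptual_loss(s_hat, s, backbone)
  tv <- tv_reg(s_hat)
  list(l_rgb = l1, l_perceptual = lp, tv = tv,
       total = weights[["rgb"]] * l1 + weights[["perceptual"]] * lp +
         weights[["tv"]] * tv)
}

## Batched image loss with gradient w.r.t. s_hat (mean over the batch).
## Ground-truth features may be precomputed; gradient flows through the
## backbone on the s_hat side only.
image_loss_grad <- function(s_hat4, s4, bb, weights, levels = NULL) {
  if (is.null(levels)) levels <- seq_len(bb$spec$n_blocks)
  d <- dim(s_hat4)
  N <- d[4]
  fa_fwd <- backbone_fw(bb, s_hat4, levels = levels, want_cache = TRUE)
  fb_fwd <- backbone_fw(bb, s4, levels = levels)
  l1 <- 0
  lp <- 0
  tv <- 0
  g <- array(0, d)
  dfeats_all <- vector("list", max(levels))
  for (n in seq_len(N)) {
    a <- s_hat4[, , , n, drop = FALSE]
    b <- s4[, , , n, drop = FALSE]
    ## rgb
    l1 <- l1 + mean(abs(a - b)) / N
    g[, , , n] <- g[, , , n, drop = FALSE] +
      weights[["rgb"]] * sign(a - b) / length(a) / N
    ## tv
    tvr <- tv_value_grad(array(a, d[1:3]))
    tv <- tv + tvr$value / N
    g[, , , n] <- g[, , , n, drop = FALSE] +
      weights[["tv"]] * array(tvr$grad, c(d[1:3], 1)) / N
    ## perceptual
    fa <- lapply(fa_fwd$features[levels],
                 function(f) array(f[, , , n], dim(f)[1:3]))
    fb <- lapply(fb_fwd$features[levels],
                 function(f) array(f[, , , n], dim(f)[1:3]))
    pc <- perceptual_core(fa, fb, want_grad = TRUE)
    lp <- lp + pc$value / N
    for (j in seq_along(levels)) {
      lev <- levels[j]
      dfl <- array(pc$dA[[j]], c(dim(pc$dA[[j]]), 1)) *
        (weights[["perceptual"]] / N)
      if (is.null(dfeats_all[[lev]])) {
        dim4 <- c(dim(pc$dA[[j]]), N)
        dfeats_all[[lev]] <- array(0, dim4)
      }
      dfeats_all[[lev]][, , , n] <- dfl
    }
  }
  gp <- backbone_bw(bb, fa_fwd, dfeats_all)
  g <- g + gp
  list(l_rgb = l1, l_perceptual = lp, tv = tv,
       total = weights[["rgb"]] * l1 + weights[["perceptual"]] * lp +
         weights[["tv"]] * tv,
       grad = g)
}
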