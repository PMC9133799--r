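#' Describe a hierarchical feature backbone
#'
#' The backbone is a pluggable multi-block convolutional pyramid used in four
#' places: the encoder's branch inputs, the perceptual reconstruction loss,
#' the perceptual-similarity identification metric, and the classification
#' embedding. The default is a seeded random-weight pyramid (5 blocks, each
#' conv 3x3 + ReLU + x2 average pooling): the framework's mathematics does
#' not depend on what the backbone weights are, only on its hierarchy, so a
#' deterministic random pyramid makes the whole package self-contained.
#' Pretrained weights can be plugged in through `weights`.
#'
#' @param name Identifier.
#' @param n_blocks Number of blocks (spatial resolution is non-increasing).
#' @param channels Integer vector of output channels per block.
#' @param in_channels Image channels the backbone expects (1 or 3).
#' @param downsample Per-block integer downsampling factor (1 or 2).
#' @param kernel Convolution kernel side.
#' @param seed Seed for the random weight draw (bit-reproducible).
#' @param input_mean,input_sd Input preprocessing (identity by default).
#' @return A `vr_backbone_spec` object.
#' @export
backbone_spec <- function(name = "synthetic", n_blocks = 5L,
                          channels = rep(16L, n_blocks),
                          in_channels = 3L,
                          downsample = rep(2L, n_blocks),
                          kernel = 3L, seed = 1L,
                          input_mean = 0, input_sd = 1) {
  vr_assert(n_blocks >= 1, "n_blocks must be >= 1")
  vr_assert(length(channels) == n_blocks, "one channel count per block")
  vr_assert(length(downsample) == n_blocks && all(downsample %in% c(1L, 2L)),
            "downsample factors must be 1 or 2 per block")
  structure(list(name = name, n_blocks = as.integer(n_blocks),
                 channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 downsample = as.integer(downsample),
                 kernel = as.integer(kernel), seed = as.integer(seed),
                 input_mean = input_mean, input_sd = input_sd),
            class = "vr_backbone_spec")
}

#' Instantiate backbone weights from a spec
#'
#' @param spec A [backbone_spec()].
#' @return A `vr_backbone` model with Glorot-normal seeded weights.
#' @export
build_backbone <- function(spec) {
  vr_assert(inherits(spec, "vr_backbone_spec"), "spec must be a backbone_spec")
  k <- spec$kernel
  params <- list()
  with_seed(spec$seed, {
    cin <- spec$in_channels
    for (b in seq_len(spec$n_blocks)) {
      cout <- spec$channels[b]
      fan_in <- k * k * cin
      params[[paste0("W", b)]] <- glorot_normal(c(fan_in, cout), fan_in, cout)
      params[[paste0("b", b)]] <- rep(0, cout)
      cin <- cout
    }
  })
  structure(list(spec = spec, params = params), class = "vr_backbone")
}

as_backbone <- function(x) {
  if (inherits(x, "vr_backbone")) return(x)
  if (inherits(x, "vr_backbone_spec")) return(build_backbone(x))
  vr_stop("expected a backbone_spec or built backbone")
}

## Internal batched forward. Returns features at each requested level plus
## (optionally) the caches needed for a backward pass.
backbone_fw <- function(bb, x, levels = seq_len(bb$spec$n_blocks),
                        want_cache = FALSE) {
  sp <- bb$spec
  vr_assert(all(levels >= 1 & levels <= sp$n_blocks),
            "unknown backbone level requested")
  if (dim(x)[3] == 1L && sp$in_channels == 3L) {
    x <- x[, , c(1L, 1L, 1L), , drop = FALSE]
  }
  vr_assert(dim(x)[3] == sp$in_channels, "image channel count mismatch")
  x <- (x - sp$input_mean) / sp$input_sd
  top <- max(levels)
  feats <- vector("list", top)
  caches <- if (want_cache) vector("list", top) else NULL
  cur <- x
  for (b in seq_len(top)) {
    cv <- conv2d_fw(cur, bb$params[[paste0("W", b)]],
                    bb$params[[paste0("b", b)]], k = sp$kernel,
                    pad = (sp$kernel - 1L) %/% 2L)
    rl <- relu_fw(cv$out)
    cur <- if (sp$downsample[b] == 2L) pool2_avg_fw(rl$out) else rl$out
    feats[[b]] <- cur
    if (want_cache) {
      caches[[b]] <- list(conv = cv$cache, mask = rl$mask,
                          pooled = sp$downsample[b] == 2L)
    }
  }
  list(features = feats, caches = caches, top = top, in_sd = sp$input_sd)
}

## Backward: dfeats is a list (indexed by block) of gradients w.r.t. block
## outputs (NULL where unused). Returns the gradient w.r.t. the input image.
backbone_bw <- function(bb, fwd, dfeats) {
  dcur <- NULL
  for (b in rev(seq_len(fwd$top))) {
    df <- if (b <= length(dfeats)) dfeats[[b]] else NULL
    if (!is.null(df)) dcur <- if (is.null(dcur)) df else dcur + df
    if (is.null(dcur)) next
    ca <- fwd$caches[[b]]
    if (ca$pooled) dcur <- pool2_avg_bw(dcur)
    dcur <- relu_bw(dcur, ca$mask)
    dcur <- conv2d_bw(dcur, ca$conv, need_dx = TRUE)$dx
  }
  dcur / fwd$in_sd
}

#' Extract a feature pyramid from an image
#'
#' @param image Numeric array `[H, W, C]` with values in `[0, 1]`.
#' @param backbone A [backbone_spec()] or built backbone.
#' @param levels Block indices to return (default all).
#' @return A `vr_pyramid`: list with `blocks` (one `[h, w, c]` array per
#'   requested level) and `levels`.
#' @export
extract_features <- function(image, backbone,
                             levels = NULL) {
  bb <- as_backbone(backbone)
  if (is.null(levels)) levels <- seq_len(bb$spec$n_blocks)
  levels <- as.integer(levels)
  vr_assert(all(levels >= 1 & levels <= bb$spec$n_blocks),
            "unknown backbone level requested")
  vr_assert(all(is.finite(image)), "image contains non-finite pixels")
  fwd <- backbone_fw(bb, as_batch(image), levels = levels)
  structure(list(blocks = lapply(fwd$features[levels], from_batch),
                 levels = levels),
            class = "vr_pyramid")
}

#' Channel-normalize a feature map
#'
#' At every spatial location the channel vector is scaled to unit Euclidean
#' norm; vectors with norm below `eps` are left as zero vectors (this keeps
#' the downstream cosine terms free of NaN on degenerate inputs).
#'
#' @param fmap Numeric array `[H, W, C]` (or batched `[H, W, C, N]`).
#' @param eps Zero-norm guard.
#' @return Array of the same shape.
#' @export
channel_normalize <- function(fmap, eps = 1e-8) {
  cn_fw(fmap, eps)$out
}

cn_fw <- function(x, eps = 1e-8) {
  d <- dim(x)
  single <- length(d) == 3L
  if (single) x <- as_batch(x)
  d4 <- dim(x)
  C <- d4[3]
  xp <- aperm(x, c(1, 2, 4, 3))
  xm <- matrix(xp, ncol = C)
  nrm <- sqrt(rowSums(xm * xm))
  scale <- ifelse(nrm < eps, 0, 1 / nrm)
  ym <- xm * scale
  y <- aperm(array(ym, dim(xp)), c(1, 2, 4, 3))
  if (single) y <- from_batch(y)
  list(out = y, cache = list(ym = ym, scale = scale, d4 = d4,
                             single = single))
}

cn_bw <- function(dout, cache) {
  d4 <- cache$d4
  C <- d4[3]
  if (cache$single) dout <- as_batch(dout)
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  proj <- rowSums(dm * cache$ym)
  dxm <- (dm - cache$ym * proj) * cache$scale
  dx <- aperm(array(dxm, c(d4[1], d4[2], d4[4], C)), c(1, 2, 4, 3))
  if (cache$single) dx <- from_batch(dx)
  dx
}

## Cosine between two flattened arrays; optionally d(cos)/d(a).
cos_flat <- function(a, b, want_grad = FALSE, eps = 1e-12) {
  av <- as.vector(a)
  bv <- as.vector(b)
  na <- sqrt(sum(av * av))
  nb <- sqrt(sum(bv * bv))
  if (na < eps || nb < eps) {
    return(list(cos = 0, da = if (want_grad) a * 0 else NULL,
                degenerate = TRUE))
  }
  cs <- sum(av * bv) / (na * nb)
  da <- NULL
  if (want_grad) {
    da <- bv / (na * nb) - cs * av / (na * na)
    if (!is.null(dim(a))) dim(da) <- dim(a)
  }
  list(cos = cs, da = da, degenerate = FALSE)
}

## Shared core of the perceptual similarity: block-wise cosine between
## channel-normalized features of two images, mapped to the normalized
## dissimilarity (1/B) * sum_b (1 - cos_b) / 2 in [0, 1]. Optionally the
## gradient with respect to the first image's raw block features.
perceptual_core <- function(feats_a, feats_b, want_grad = FALSE) {
  B <- length(feats_a)
  vr_assert(B == length(feats_b) && B >= 1, "feature pyramids must align")
  coss <- numeric(B)
  dA <- if (want_grad) vector("list", B) else NULL
  for (b in seq_len(B)) {
    ca <- cn_fw(feats_a[[b]])
    cb <- cn_fw(feats_b[[b]])
    cf <- cos_flat(ca$out, cb$out, want_grad = want_grad)
    coss[b] <- cf$cos
    if (want_grad) {
      ## d total / d cos_b = -1 / (2B)
      dA[[b]] <- cn_bw(cf$da * (-1 / (2 * B)), ca$cache)
    }
  }
  list(value = mean((1 - coss) / 2), block_cos = coss, dA = dA)
}
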