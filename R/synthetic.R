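## Virtual subject and procedural stimulus generator.
##
## The simulator provides the ground truth the rest of the package is
## tested against: each voxel has a Gaussian population receptive field
## (center, width), a tuning vector over a small fixed bank of image
## features (color channels, oriented edge energy, local contrast), a
## gain calibrated so the clean signal has unit standard deviation across
## stimuli, and i.i.d. Gaussian repeat noise of width sigma_n (in
## signal-SD units).

N_FILTERS <- 8L

## fixed filter bank: per-pixel feature maps [H*W, 8]
## 1-3 color deviation from mid-gray, 4-7 oriented edge energy (Sobel-type),
## 8 local contrast.
feature_bank <- function(image) {
  d <- dim(image)
  H <- d[1]
  W <- d[2]
  img3 <- if (d[3] == 1L) image[, , c(1, 1, 1), drop = FALSE] else image
  lum <- (img3[, , 1] + img3[, , 2] + img3[, , 3]) / 3
  kern <- cbind(
    c(-1, -2, -1, 0, 0, 0, 1, 2, 1) / 4,       # d/dy
    c(-1, 0, 1, -2, 0, 2, -1, 0, 1) / 4,       # d/dx
    c(-2, -1, 0, -1, 0, 1, 0, 1, 2) / 4,       # diagonal
    c(0, -1, -2, 1, 0, -1, 2, 1, 0) / 4,       # anti-diagonal
    rep(1 / 9, 9)                              # box mean
  )
  cv <- conv2d_fw(array(lum, c(H, W, 1, 1)), kern, rep(0, 5), k = 3L,
                  pad = 1L)$out
  F <- matrix(0, H * W, N_FILTERS)
  F[, 1] <- as.vector(img3[, , 1]) - 0.5
  F[, 2] <- as.vector(img3[, , 2]) - 0.5
  F[, 3] <- as.vector(img3[, , 3]) - 0.5
  ## zero-padding at the image border fabricates edge/contrast responses;
  ## trim the one-pixel rim of the convolution-derived features
  rim <- matrix(FALSE, H, W)
  rim[c(1, H), ] <- TRUE
  rim[, c(1, W)] <- TRUE
  rim <- as.vector(rim)
  for (j in 1:4) {
    f <- abs(as.vector(cv[, , j, 1]))
    f[rim] <- 0
    F[, 3 + j] <- f
  }
  f8 <- abs(as.vector(lum) - as.vector(cv[, , 5, 1]))
  f8[rim] <- 0
  F[, 8] <- f8
  F
}

#' Create a ground-truth virtual subject
#'
#' @param n_voxels Number of voxels (default 200).
#' @param image_side Stimulus side in pixels (default 64).
#' @param sigma_n Repeat-noise SD in units of the (unit) clean-signal SD
#'   (default 0.25).
#' @param sigma_prf_frac Range of pRF widths as a fraction of the side.
#' @param center_margin Fraction of the side kept clear of pRF centers at
#'   each border.
#' @param nonlinearity `"identity"` or `"rectified"`.
#' @param n_uniform_controls Number of trailing control voxels whose
#'   spatial weighting is uniform over the image (no confined pRF); used
#'   to test confinement screening.
#' @param seed Seed for the subject draw and gain calibration.
#' @return A `vr_subject` with per-voxel pRF centers (0-based x, y), widths
#'   (pixels), unit tuning vectors, calibrated gains and `truth` table.
#' @export
virtual_subject <- function(n_voxels = 200L, image_side = 64L,
                            sigma_n = 0.25, sigma_prf_frac = c(0.08, 0.16),
                            center_margin = 0.15,
                            nonlinearity = c("identity", "rectified"),
                            n_uniform_controls = 0L, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  vr_assert(sigma_n >= 0, "sigma_n must be >= 0")
  vr_assert(n_uniform_controls >= 0 && n_uniform_controls < n_voxels,
            "invalid control voxel count")
  side <- as.integer(image_side)
  Nv <- as.integer(n_voxels)
  sub <- with_seed(derive_seed(seed, "subject"), {
    lo <- center_margin * (side - 1)
    hi <- (1 - center_margin) * (side - 1)
    centers <- cbind(x = stats::runif(Nv, lo, hi),
                     y = stats::runif(Nv, lo, hi))
    sigma_prf <- stats::runif(Nv, sigma_prf_frac[1] * side,
                              sigma_prf_frac[2] * side)
    tuning <- matrix(stats::rnorm(N_FILTERS * Nv), N_FILTERS, Nv)
    tuning <- sweep(tuning, 2, sqrt(colSums(tuning^2)), `/`)
    list(centers = centers, sigma_prf = sigma_prf, tuning = tuning)
  })
  uniform <- rep(FALSE, Nv)
  if (n_uniform_controls > 0) {
    uniform[(Nv - n_uniform_controls + 1L):Nv] <- TRUE
  }
  ## spatial weights [H*W, Nv]: normalized Gaussians (uniform for controls)
  ys <- rep(seq_len(side) - 1, times = side)   # row index, column-major
  xs <- rep(seq_len(side) - 1, each = side)
  G <- matrix(0, side * side, Nv)
  for (v in seq_len(Nv)) {
    if (uniform[v]) {
      G[, v] <- 1 / (side * side)
    } else {
      g <- exp(-((xs - sub$centers[v, 1])^2 + (ys - sub$centers[v, 2])^2) /
                 (2 * sub$sigma_prf[v]^2))
      G[, v] <- g / sum(g)
    }
  }
  subject <- structure(list(n_voxels = Nv, image_side = side,
                            sigma_n = sigma_n, centers = sub$centers,
                            sigma_prf = sub$sigma_prf,
                            tuning = sub$tuning, G = G,
                            uniform = uniform,
                            nonlinearity = nonlinearity,
                            gain = rep(1, Nv), seed = as.integer(seed)),
                       class = "vr_subject")
  ## calibrate gains to unit clean-signal SD on a probe stimulus set
  cal_spec <- stimulus_spec(image_side = side)
  cal <- sample_images(cal_spec, 40L, seed = derive_seed(seed, "calib"))
  S <- vapply(cal, function(it) clean_signal(subject, it$image),
              numeric(Nv))
  sds <- apply(S, 1, stats::sd)
  subject$gain <- ifelse(sds > 1e-9, 1 / sds, 1)
  subject$truth <- data.frame(voxel = seq_len(Nv),
                              x = sub$centers[, 1], y = sub$centers[, 2],
                              sigma_prf = sub$sigma_prf,
                              uniform = uniform)
  subject
}

clean_signal <- function(subject, image) {
  F <- feature_bank(image)                     # [HW, 8]
  U <- F %*% subject$tuning                    # [HW, Nv]
  s <- colSums(subject$G * U)
  if (subject$nonlinearity == "rectified") s <- pmax(s, 0)
  s * subject$gain
}

#' Simulate voxel responses to an image
#'
#' Per voxel: `gain * f( sum_xy GaussianPRF(x, y) * tuned feature value )`
#' plus i.i.d. Gaussian repeat noise of SD `sigma_n`.
#'
#' @param subject A [virtual_subject()].
#' @param image Stimulus matching the subject's resolution.
#' @param n_repeats Number of noisy repeats.
#' @param seed Noise seed.
#' @return `[n_repeats, Nv]` matrix (all rows identical when
#'   `sigma_n = 0`).
#' @export
simulate_response <- function(subject, image, n_repeats = 1L, seed = 1L) {
  d <- dim(image)
  vr_assert(d[1] == subject$image_side && d[2] == subject$image_side,
            "image resolution does not match subject")
  s <- clean_signal(subject, image)
  noise <- with_seed(seed, matrix(stats::rnorm(n_repeats * subject$n_voxels,
                                               0, subject$sigma_n),
                                  n_repeats, subject$n_voxels))
  sweep(noise, 2, s, `+`)
}

#' Procedural stimulus specification
#'
#' Classes are cells of a shape x color x texture grid (default
#' 5 x 5 x 4 = 100 classes); images are anti-aliased parametric shapes
#' with jittered position, scale, hue and texture phase on a mildly
#' textured background. The default split sizes mirror the scarce-paired /
#' abundant-unpaired structure of real paired-fMRI datasets at desk scale:
#' 96 paired training stimuli from 12 classes, 16 paired test stimuli
#' (8 repeats) from 8 disjoint classes, 2000 unpaired images from 80
#' further disjoint classes.
#'
#' @param image_side Side in pixels (default 32).
#' @param channels 3 (RGB) or 1 (grayscale).
#' @param n_shapes,n_colors,n_textures Grid dimensions (classes =
#'   product, capped at 5, 5, 4).
#' @param n_train,train_classes Paired training images / classes.
#' @param n_test,test_classes,test_repeats Paired test images / disjoint
#'   classes / fMRI repeats per test stimulus.
#' @param n_unpaired,unpaired_classes Unpaired pool size / disjoint
#'   classes.
#' @return A `vr_stimspec`.
#' @export
stimulus_spec <- function(image_side = 32L, channels = 3L, n_shapes = 5L,
                          n_colors = 5L, n_textures = 4L, n_train = 96L,
                          train_classes = 12L, n_test = 16L,
                          test_classes = 8L, test_repeats = 8L,
                          n_unpaired = 2000L, unpaired_classes = 80L) {
  vr_assert(n_shapes <= 5 && n_colors <= 5 && n_textures <= 4,
            "class grid supports up to 5 shapes, 5 colors, 4 textures")
  grid <- expand.grid(shape = seq_len(n_shapes), color = seq_len(n_colors),
                      texture = seq_len(n_textures))
  ids <- sprintf("s%d_c%d_t%d", grid$shape, grid$color, grid$texture)
  structure(list(image_side = as.integer(image_side),
                 channels = as.integer(channels), grid = grid,
                 class_ids = ids, n_classes = length(ids),
                 n_train = as.integer(n_train),
                 train_classes = as.integer(train_classes),
                 n_test = as.integer(n_test),
                 test_classes = as.integer(test_classes),
                 test_repeats = as.integer(test_repeats),
                 n_unpaired = as.integer(n_unpaired),
                 unpaired_classes = as.integer(unpaired_classes)),
            class = "vr_stimspec")
}

hue_to_rgb <- function(h) {
  h <- (h %% 1) * 6
  x <- 1 - abs(h %% 2 - 1)
  if (h < 1) c(1, x, 0) else if (h < 2) c(x, 1, 0) else
    if (h < 3) c(0, 1, x) else if (h < 4) c(0, x, 1) else
      if (h < 5) c(x, 0, 1) else c(1, 0, x)
}

shape_distance <- function(shape, xs, ys, cx, cy, r) {
  dx <- xs - cx
  dy <- ys - cy
  switch(shape,
         sqrt(dx^2 + dy^2) - r,                       # disc
         pmax(abs(dx), abs(dy)) - 0.85 * r,           # square
         abs(dx) + abs(dy) - 1.2 * r,                 # diamond
         abs(sqrt(dx^2 + dy^2) - 0.85 * r) - 0.3 * r, # annulus
         pmin(pmax(abs(dx) - 0.35 * r, abs(dy) - r),  # cross
              pmax(abs(dx) - r, abs(dy) - 0.35 * r)))
}

texture_field <- function(texture, xs, ys, freq, phase) {
  switch(texture,
         xs * 0 + 1,
         0.72 + 0.28 * sign(sin(freq * ys + phase)),
         0.72 + 0.28 * sign(sin(freq * xs + phase)),
         0.72 + 0.28 * sign(sin(freq * xs + phase) *
                              sin(freq * ys + phase)))
}

## render one image of a given class cell; consumes the current RNG stream.
## The scene holds 1-2 compact instances of the class shape plus 2-3
## distractor shapes, all scattered across the field: class-defining
## content recurs globally while local content varies independently
## across locations, which keeps voxel receptive fields identifiable from
## the paired data (natural-image-like clutter). Distractor attributes are
## drawn from the same split's class set (`allowed_idx`), so a split's
## images expose only that split's appearance statistics -- the coverage
## gap between scarce paired classes and the wide unpaired pool that
## self-supervision exploits.
render_image <- function(spec, class_index,
                         allowed_idx = seq_len(spec$n_classes)) {
  side <- spec$image_side
  cell <- spec$grid[class_index, ]
  ys <- matrix(seq_len(side) - 1, side, side)
  xs <- matrix(seq_len(side) - 1, side, side, byrow = TRUE)
  freq <- 2 * pi * 6 / side
  bg <- 0.5 + stats::rnorm(1, 0, 0.02)
  img <- array(bg, c(side, side, 3))
  paint <- function(img, shape, hue, texture) {
    cx <- stats::runif(1, 0.10, 0.90) * (side - 1)
    cy <- stats::runif(1, 0.10, 0.90) * (side - 1)
    r <- side * stats::runif(1, 0.09, 0.15)
    d <- shape_distance(shape, xs, ys, cx, cy, r)
    mask <- pmin(pmax(0.5 - d / 1.2, 0), 1)
    rgb <- 0.15 + 0.75 * hue_to_rgb(hue)
    tex <- texture_field(texture, xs, ys, freq,
                         stats::runif(1, 0, 2 * pi))
    for (c in 1:3) {
      img[, , c] <- img[, , c] * (1 - mask) + mask * rgb[c] * tex
    }
    img
  }
  for (j in seq_len(sample(2:3, 1))) {   # same-split clutter first
    di <- if (length(allowed_idx) == 1) allowed_idx else
      sample(allowed_idx, 1)
    dcell <- spec$grid[di, ]
    img <- paint(img, dcell$shape,
                 (dcell$color - 1) / 5 + stats::rnorm(1, 0, 0.03),
                 dcell$texture)
  }
  for (j in seq_len(sample(1:2, 1))) {   # class shapes painted on top
    img <- paint(img, cell$shape,
                 (cell$color - 1) / 5 + stats::rnorm(1, 0, 0.015),
                 cell$texture)
  }
  img <- pmin(pmax(img, 0), 1)
  if (spec$channels == 1L) {
    img <- array((img[, , 1] + img[, , 2] + img[, , 3]) / 3,
                 c(side, side, 1))
  }
  ## quantize to the 8-bit grid so PNG round trips are exact
  round(img * 255) / 255
}

#' Sample procedural stimulus images
#'
#' @param spec A [stimulus_spec()].
#' @param n Number of images.
#' @param seed Seed (same seed, same bits).
#' @param classes Optional class-id subset to draw from (default all).
#' @return List of `list(image, class_id)`.
#' @export
sample_images <- function(spec, n, seed = 1L, classes = NULL) {
  vr_assert(n >= 1, "n must be >= 1")
  allowed <- if (is.null(classes)) spec$class_ids else classes
  vr_assert(all(allowed %in% spec$class_ids), "unknown class id")
  with_seed(seed, {
    aidx <- match(allowed, spec$class_ids)
    lapply(seq_len(n), function(i) {
      cid <- if (length(allowed) == 1) allowed else sample(allowed, 1)
      ci <- match(cid, spec$class_ids)
      list(image = render_image(spec, ci, allowed_idx = aidx),
           class_id = cid)
    })
  })
}

#' Build the full synthetic benchmark
#'
#' Draws three pairwise-disjoint class sets (paired-train, paired-test,
#' unpaired), renders the stimuli, and simulates the subject's responses
#' (single repeat for training, `test_repeats` for test). Class labels are
#' carried for evaluation only; training code never reads them.
#'
#' @param spec A [stimulus_spec()].
#' @param subject A [virtual_subject()] with matching `image_side`.
#' @param seed Root seed (split into substreams for splits, images and
#'   noise).
#' @return List with `train`, `test` (paired datasets), `unpaired` (pool),
#'   `subject`, `spec`, and `truth` (the subject's pRF table).
#' @export
make_benchmark <- function(spec, subject, seed = 1L) {
  vr_assert(inherits(spec, "vr_stimspec"), "spec must be a stimulus_spec")
  vr_assert(inherits(subject, "vr_subject"), "subject must be a vr_subject")
  vr_assert(spec$image_side == subject$image_side,
            "spec and subject disagree on image side")
  need <- spec$train_classes + spec$test_classes + spec$unpaired_classes
  vr_assert(need <= spec$n_classes,
            "class budget exceeded: need ", need, " of ", spec$n_classes)
  cls <- with_seed(derive_seed(seed, "splits"), {
    perm <- sample(spec$class_ids, need)
    list(train = perm[seq_len(spec$train_classes)],
         test = perm[spec$train_classes + seq_len(spec$test_classes)],
         unpaired = perm[spec$train_classes + spec$test_classes +
                           seq_len(spec$unpaired_classes)])
  })
  tr_items <- sample_images(spec, spec$n_train,
                            seed = derive_seed(seed, "train-img"),
                            classes = cls$train)
  te_items <- sample_images(spec, spec$n_test,
                            seed = derive_seed(seed, "test-img"),
                            classes = cls$test)
  un_items <- sample_images(spec, spec$n_unpaired,
                            seed = derive_seed(seed, "unpaired-img"),
                            classes = cls$unpaired)
  Nv <- subject$n_voxels
  R_tr <- matrix(0, spec$n_train, Nv)
  for (i in seq_len(spec$n_train)) {
    R_tr[i, ] <- simulate_response(subject, tr_items[[i]]$image, 1L,
                                   seed = derive_seed(seed,
                                                      paste0("trn", i)))
  }
  R_te <- array(0, c(spec$n_test, spec$test_repeats, Nv))
  for (i in seq_len(spec$n_test)) {
    R_te[i, , ] <- simulate_response(subject, te_items[[i]]$image,
                                     spec$test_repeats,
                                     seed = derive_seed(seed,
                                                        paste0("ten", i)))
  }
  train <- structure(list(images = lapply(tr_items, `[[`, "image"),
                          responses = R_tr,
                          ids = sprintf("train_%04d",
                                        seq_len(spec$n_train)),
                          classes = vapply(tr_items, `[[`, "",
                                           "class_id"),
                          split = "train"), class = "vr_paired")
  test <- structure(list(images = lapply(te_items, `[[`, "image"),
                         responses = R_te,
                         ids = sprintf("test_%04d", seq_len(spec$n_test)),
                         classes = vapply(te_items, `[[`, "", "class_id"),
                         split = "test"), class = "vr_paired")
  unpaired <- structure(list(images = lapply(un_items, `[[`, "image"),
                             ids = sprintf("unp_%05d",
                                           seq_len(spec$n_unpaired)),
                             classes = vapply(un_items, `[[`, "",
                                              "class_id"),
                             split = "unpaired"), class = "vr_unpaired")
  list(train = train, test = test, unpaired = unpaired, subject = subject,
       spec = spec, truth = subject$truth, class_sets = cls)
}

#' Render fresh per-class images for gallery building
#'
#' Renders `n_per_class` new images of each requested class (never the test
#' stimuli themselves), for use with [build_gallery()].
#'
#' @param spec A [stimulus_spec()].
#' @param classes Class ids.
#' @param n_per_class Images per class.
#' @param seed Seed.
#' @return Named list: class id -> list of images.
#' @export
render_class_images <- function(spec, classes, n_per_class = 20L,
                                seed = 1L) {
  out <- lapply(seq_along(classes), function(j) {
    items <- sample_images(spec, n_per_class,
                           seed = derive_seed(seed, classes[j]),
                           classes = classes[j])
    lapply(items, `[[`, "image")
  })
  names(out) <- classes
  out
}
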