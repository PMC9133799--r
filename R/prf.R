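#' Gradient-based population receptive field of a voxel
#'
#' Differentiates the trained encoder: given a probe image (uniform random
#' in `[0, 1]`, seeded, one per voxel), the gradient of the voxel's
#' predicted response with respect to the input pixels is squared, averaged
#' across color channels and normalized to sum 1.
#'
#' @param enc Trained `vr_encoder`.
#' @param voxel_index Voxel (1-based), or an integer vector for a batched
#'   computation.
#' @param probe_image Optional probe image; default seeded uniform noise.
#' @param seed Probe seed.
#' @param n_probes Number of probe images averaged per voxel (default 3;
#'   averaging suppresses the dependence of the map on the probe's
#'   activation pattern).
#' @return For one voxel a `vr_prf` (list with `heatmap` summing to 1,
#'   `voxel`, `method`); for several, a list of them.
#' @export
gradient_prf <- function(enc, voxel_index, probe_image = NULL, seed = 1L,
                         n_probes = 3L) {
  cfg <- enc$cfg
  Nv <- cfg$n_voxels
  voxel_index <- as.integer(voxel_index)
  vr_assert(all(voxel_index >= 1 & voxel_index <= Nv),
            "voxel_index out of range")
  nsel <- length(voxel_index)
  side <- cfg$image_side
  if (!is.null(probe_image)) n_probes <- 1L
  hms <- vector("list", nsel)
  for (p in seq_len(n_probes)) {
    x <- array(0, c(side, side, cfg$in_channels, nsel))
    for (j in seq_len(nsel)) {
      x[, , , j] <- if (is.null(probe_image)) {
        with_seed(derive_seed(seed, paste0("probe", p, "_",
                                           voxel_index[j])),
                  array(stats::runif(side * side * cfg$in_channels),
                        c(side, side, cfg$in_channels)))
      } else {
        probe_image
      }
    }
    fwd <- encoder_fw(enc, x, training = FALSE, want_cache = TRUE)
    dY <- matrix(0, nsel, Nv)
    for (j in seq_len(nsel)) dY[j, voxel_index[j]] <- 1
    dx <- encoder_bw(enc, fwd$cache, dY, want_dx = TRUE)$dx
    for (j in seq_len(nsel)) {
      g2 <- array(dx[, , , j], c(side, side, cfg$in_channels))^2
      hm <- apply(g2, c(1, 2), mean)
      hms[[j]] <- if (p == 1L) hm / n_probes else
        hms[[j]] + hm / n_probes
    }
  }
  out <- lapply(seq_len(nsel), function(j) {
    hm <- hms[[j]]
    tot <- sum(hm)
    if (tot > 0) hm <- hm / tot
    structure(list(heatmap = hm, voxel = voxel_index[j],
                   method = "gradient"), class = "vr_prf")
  })
  if (nsel == 1L) out[[1]] else out
}

## separable Gaussian smoothing with edge renormalization
smooth_gauss <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(m) {   # along rows (dim 1)
    H <- nrow(m)
    out <- m * 0
    wt <- m * 0
    for (o in seq(-r, r)) {
      src <- seq_len(H) + o
      ok <- src >= 1 & src <= H
      out[ok, ] <- out[ok, ] + k[o + r + 1] * m[src[ok], , drop = FALSE]
      wt[ok, ] <- wt[ok, ] + k[o + r + 1]
    }
    out / wt
  }
  t(sm1(t(sm1(mat))))
}

#' Locate the pRF center and test spatial confinement
#'
#' The heatmap is smoothed with a Gaussian kernel (default `sigma = 3` px),
#' raised to a power (default 10) to emphasize the mode, and renormalized;
#' the center is the resulting center of mass (0-based `(x, y)` pixel
#' coordinates). The map counts as spatially confined when at least `tau`
#' of the preprocessed mass lies within `rho * side` pixels of the center.
#'
#' @param heatmap Non-negative matrix (normalized or not).
#' @param sigma Smoothing kernel width in pixels.
#' @param power Exponent applied after smoothing.
#' @param rho Confinement radius as a fraction of the image side.
#' @param tau Mass fraction required inside the radius.
#' @return List with `center` (`c(x, y)`, 0-based), `confined` (logical)
#'   and `mass_fraction`.
#' @export
prf_center <- function(heatmap, sigma = 3, power = 10, rho = 0.15,
                       tau = 0.5) {
  vr_assert(is.matrix(heatmap) && all(heatmap >= -1e-12),
            "heatmap must be a non-negative matrix")
  tot <- sum(heatmap)
  if (tot <= 0) {
    return(list(center = c(NA_real_, NA_real_), confined = FALSE,
                mass_fraction = 0))
  }
  m <- smooth_gauss(heatmap / tot, sigma)
  m <- pmax(m, 0)^power
  s <- sum(m)
  if (s <= 0) {
    return(list(center = c(NA_real_, NA_real_), confined = FALSE,
                mass_fraction = 0))
  }
  m <- m / s
  H <- nrow(m)
  W <- ncol(m)
  ys <- matrix(seq_len(H) - 1, H, W)
  xs <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  cx <- sum(xs * m)
  cy <- sum(ys * m)
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  frac <- sum(m[rr <= rho * max(H, W)])
  list(center = c(cx, cy), confined = frac >= tau, mass_fraction = frac)
}

#' Retinotopy quantities of a pRF center
#'
#' Converts a pixel-space center to eccentricity (degrees of visual angle)
#' and polar angle (radians; 0 at the right horizontal meridian,
#' counterclockwise positive, i.e. the upper visual field has positive
#' angles although pixel rows grow downward).
#'
#' @param center `c(x, y)` 0-based pixel coordinates.
#' @param image_side Image side in pixels.
#' @param fov_deg Field of view spanned by the image, in degrees of visual
#'   angle.
#' @return List with `eccentricity_deg` and `polar_angle`.
#' @export
retinotopy <- function(center, image_side, fov_deg) {
  vr_assert(fov_deg > 0, "fov_deg must be positive")
  mid <- (image_side - 1) / 2
  dx <- center[1] - mid
  dy <- center[2] - mid
  scale <- fov_deg / image_side
  list(eccentricity_deg = sqrt(dx^2 + dy^2) * scale,
       polar_angle = atan2(-dy, dx))
}

## nearest-neighbour resize of a matrix to a square side
nearest_resize <- function(m, side) {
  H <- nrow(m)
  W <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(side) - 0.5) * H / side) + 1L, 1L), H)
  ci <- pmin(pmax(floor((seq_len(side) - 0.5) * W / side) + 1L, 1L), W)
  m[ri, ci, drop = FALSE]
}

#' Weight-based receptive field map of a voxel
#'
#' Encoder: the voxel's learned spatial maps (squared, normalized) are
#' resized to a common grid and averaged across branches. Decoder: the
#' voxel's row of the input locally-connected layer is reshaped to the base
#' grid and the mean squared weight across channels forms the map.
#'
#' @param model `vr_encoder` or `vr_decoder`.
#' @param voxel_index Voxel (1-based).
#' @param which `"encoder"` or `"decoder"` (inferred from the model class
#'   by default).
#' @param target_side Side to resize the map to (default: the image side
#'   for encoders, the native base grid for decoders).
#' @return A `vr_prf` (heatmap sums to 1).
#' @export
weight_prf <- function(model, voxel_index, which = NULL,
                       target_side = NULL) {
  if (is.null(which)) {
    which <- if (inherits(model, "vr_encoder")) "encoder" else "decoder"
  }
  if (which == "encoder") {
    cfg <- model$cfg
    vr_assert(voxel_index >= 1 && voxel_index <= cfg$n_voxels,
              "voxel_index out of range")
    if (is.null(target_side)) target_side <- cfg$image_side
    acc <- matrix(0, target_side, target_side)
    ## average across the branches sharing the finest grid: the coarsest
    ## branch (side/8) has too few cells to express a center
    sel <- which(cfg$branch_grids == max(cfg$branch_grids))
    for (i in sel) {
      g <- cfg$branch_grids[i] - 2L
      mp <- matrix(model$params[[paste0("br", i, "_sp")]][, voxel_index],
                   g, g)^2
      if (sum(mp) > 0) mp <- mp / sum(mp)
      acc <- acc + nearest_resize(mp, target_side) / length(sel)
    }
    hm <- acc / sum(acc)
  } else {
    cfg <- model$cfg
    vr_assert(voxel_index >= 1 && voxel_index <= cfg$n_voxels,
              "voxel_index out of range")
    base <- cfg$base_resolution
    w <- array(model$params$W0[voxel_index, ],
               c(base, base, cfg$base_channels))
    hm <- apply(w^2, c(1, 2), mean)
    if (!is.null(target_side)) hm <- nearest_resize(hm, target_side)
    hm <- hm / sum(hm)
  }
  structure(list(heatmap = hm, voxel = as.integer(voxel_index),
                 method = paste0("weights-", which)), class = "vr_prf")
}

#' Per-voxel pRF summary table
#'
#' Runs [gradient_prf()] (or [weight_prf()]) for the requested voxels and
#' derives center, confinement and retinotopy per voxel.
#'
#' @param model Trained encoder (or decoder for `method = "weights"`).
#' @param voxels Integer vector (default: all).
#' @param method `"gradient"` or `"weights"`.
#' @param fov_deg Field of view for the retinotopy columns.
#' @param seed Probe seed for the gradient method.
#' @param sigma,power,rho,tau Passed to [prf_center()].
#' @return Data frame: voxel, x, y, confined, eccentricity_deg,
#'   polar_angle.
#' @export
prf_table <- function(model, voxels = NULL, method = c("gradient",
                                                       "weights"),
                      fov_deg = 10, seed = 1L, sigma = 3, power = 10,
                      rho = 0.15, tau = 0.5) {
  method <- match.arg(method)
  Nv <- model$cfg$n_voxels
  if (is.null(voxels)) voxels <- seq_len(Nv)
  side <- if (inherits(model, "vr_encoder")) model$cfg$image_side else
    model$cfg$base_resolution
  maps <- if (method == "gradient") {
    vr_assert(inherits(model, "vr_encoder"),
              "gradient method requires an encoder")
    res <- gradient_prf(model, voxels, seed = seed)
    if (inherits(res, "vr_prf")) list(res) else res
  } else {
    lapply(voxels, function(v) {
      weight_prf(model, v, target_side = if (inherits(model, "vr_encoder"))
        side else NULL)
    })
  }
  rows <- lapply(seq_along(voxels), function(j) {
    pc <- prf_center(maps[[j]]$heatmap, sigma = sigma, power = power,
                     rho = rho, tau = tau)
    rt <- if (all(is.finite(pc$center))) {
      retinotopy(pc$center, nrow(maps[[j]]$heatmap), fov_deg)
    } else {
      list(eccentricity_deg = NA_real_, polar_angle = NA_real_)
    }
    data.frame(voxel = voxels[j], x = pc$center[1], y = pc$center[2],
               confined = pc$confined,
               eccentricity_deg = rt$eccentricity_deg,
               polar_angle = rt$polar_angle)
  })
  do.call(rbind, rows)
}
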