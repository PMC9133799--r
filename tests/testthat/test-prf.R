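test_that("gradient heatmaps are normalized and match finite differences", {
  ts <- tiny_encoder_setup(n_voxels = 4L)
  prf <- gradient_prf(ts$enc, 2L, seed = 7, n_probes = 1L)
  expect_true(all(prf$heatmap >= 0))
  expect_equal(sum(prf$heatmap), 1)
  ## finite-difference oracle on the probe image
  probe <- with_seed(derive_seed(7, "probe1_2"),
                     array(runif(16 * 16 * 3), c(16, 16, 3)))
  f <- function(img) encode(ts$enc, img)[2]
  eps <- 1e-5
  grad_fd <- matrix(0, 16, 16)
  for (i in seq(1, 16, by = 5)) for (j in seq(1, 16, by = 5)) {
    g2 <- 0
    for (c in 1:3) {
      p1 <- probe
      p2 <- probe
      p1[i, j, c] <- p1[i, j, c] + eps
      p2[i, j, c] <- p2[i, j, c] - eps
      g2 <- g2 + ((f(p1) - f(p2)) / (2 * eps))^2 / 3
    }
    grad_fd[i, j] <- g2
  }
  ## the heatmap is grad^2 up to one global normalization constant, so the
  ## probed entries must be proportional to the finite-difference values
  sel <- as.vector(outer(seq(1, 16, 5), (seq(1, 16, 5) - 1) * 16, `+`))
  got <- prf$heatmap[sel] / sum(prf$heatmap[sel])
  want <- grad_fd[sel] / sum(grad_fd[sel])
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("gradient maps of a linearized encoder are probe-independent", {
  ts <- tiny_encoder_setup(n_voxels = 3L)
  enc <- ts$enc
  ## push every pre-activation far positive: ReLUs become identity and the
  ## whole model is affine, so the gradient cannot depend on the probe
  for (b in 1:4) enc$backbone$params[[paste0("b", b)]] <- rep(50, 4)
  for (i in 1:4) enc$params[[paste0("br", i, "_convb")]] <- rep(50, 8)
  h1 <- gradient_prf(enc, 1L, seed = 1)$heatmap
  h2 <- gradient_prf(enc, 1L, seed = 2)$heatmap
  expect_lt(max(abs(h1 - h2)), 1e-6)
})

test_that("center estimation and confinement behave on canonical maps", {
  side <- 32L
  delta <- matrix(0, side, side)
  delta[11, 21] <- 1                       # row 11 -> y = 10, col 21 -> x = 20
  pc <- prf_center(delta)
  expect_equal(pc$center, c(20, 10), tolerance = 0.5)
  expect_true(pc$confined)
  ## uniform map: center of mass at the middle, not confined
  pu <- prf_center(matrix(1 / side^2, side, side))
  expect_equal(pu$center, c((side - 1) / 2, (side - 1) / 2),
               tolerance = 1e-6)
  expect_false(pu$confined)
  ## two equal Gaussians at opposite corners: bimodal, not confined;
  ## verified against a direct mass-fraction computation
  xs <- matrix(seq_len(side) - 1, side, side, byrow = TRUE)
  ys <- matrix(seq_len(side) - 1, side, side)
  bimodal <- exp(-((xs - 4)^2 + (ys - 4)^2) / 8) +
    exp(-((xs - 27)^2 + (ys - 27)^2) / 8)
  pb <- prf_center(bimodal / sum(bimodal))
  expect_false(pb$confined)
  m <- voxrecon:::smooth_gauss(bimodal / sum(bimodal), 3)^10
  m <- m / sum(m)
  cx <- sum(xs * m)
  cy <- sum(ys * m)
  frac <- sum(m[sqrt((xs - cx)^2 + (ys - cy)^2) <= 0.15 * side])
  expect_equal(pb$mass_fraction, frac, tolerance = 1e-8)
  ## all-zero map: not confined
  expect_false(prf_center(matrix(0, 8, 8))$confined)
})

test_that("retinotopy converts centers to eccentricity and polar angle", {
  rt0 <- retinotopy(c(55.5, 55.5), 112, 10)
  expect_equal(rt0$eccentricity_deg, 0)
  rt <- retinotopy(c(55.5 + 28, 55.5), 112, 10)
  expect_equal(rt$eccentricity_deg, 2.5)
  expect_equal(rt$polar_angle, 0)
  ## reflecting across the vertical midline negates cos, keeps eccentricity
  rtm <- retinotopy(c(55.5 - 28, 55.5), 112, 10)
  expect_equal(rtm$eccentricity_deg, 2.5)
  expect_equal(cos(rtm$polar_angle), -cos(rt$polar_angle))
  ## upper visual field (smaller row) has positive angle
  up <- retinotopy(c(55.5, 25.5), 112, 10)
  expect_gt(up$polar_angle, 0)
})

test_that("weight-based maps visualize spatial map and input-layer structure", {
  ts <- tiny_encoder_setup(n_voxels = 3L)
  enc <- ts$enc
  ## one-hot spatial maps on the finest-grid branches -> one-hot heatmap
  for (i in 1:4) {
    sp <- enc$params[[paste0("br", i, "_sp")]] * 0
    sp[2, 1] <- 1
    enc$params[[paste0("br", i, "_sp")]] <- sp
  }
  wp <- weight_prf(enc, 1L, target_side = 2L)   # native trimmed grid
  expect_equal(sum(wp$heatmap > 1e-12), 1L)
  expect_equal(sum(wp$heatmap), 1)
  ## decoder with all-equal input weights -> uniform heatmap
  dcfg <- tiny_decoder_config(n_voxels = 3L, side = 16L)
  dec <- build_decoder(dcfg, seed = 1)
  dec$params$W0[2, ] <- 1
  wd <- weight_prf(dec, 2L)
  expect_true(all(abs(wd$heatmap - 1 / length(wd$heatmap)) < 1e-12))
})

test_that("confinement screening rejects uniform control voxels with full sensitivity", {
  subj <- virtual_subject(n_voxels = 30L, image_side = 32L,
                          n_uniform_controls = 6L, seed = 4)
  side <- subj$image_side
  screened <- vapply(seq_len(30L), function(v) {
    prf_center(matrix(subj$G[, v], side, side))$confined
  }, logical(1))
  expect_true(all(!screened[subj$uniform]))      # 100% sensitivity
  expect_true(mean(screened[!subj$uniform]) > 0.8)
})
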