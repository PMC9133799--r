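test_that("branch tensors and neighbour stacking match the reference shapes at 112 px", {
  bb <- build_backbone(backbone_spec(channels = rep(4L, 5), seed = 2))
  cfg <- encoder_config(n_voxels = 4L, image_side = 112L)
  expect_equal(cfg$branch_grids, c(28L, 28L, 28L, 14L))
  enc <- build_encoder(cfg, bb, seed = 1)
  x <- batch_images(rand_images(1, side = 112L), 112L, 3L)
  fwd <- encoder_fw(enc, x, training = FALSE, want_cache = TRUE)
  ## reduced branch tensors: 28x28x32 (branches 1-3) and 14x14x32 (branch 4)
  for (i in 1:3) {
    expect_equal(fwd$cache$brc[[i]]$bn1$d[1:3], c(28, 28, 32))
  }
  expect_equal(fwd$cache$brc[[4]]$bn1$d[1:3], c(14, 14, 32))
  ## stacked tensors: 26x26x288 and 12x12x288
  z1 <- fwd$cache$brc[[1]]$z
  z4 <- fwd$cache$brc[[4]]$z
  expect_equal(dim(neighbor_stack(array(z1[, , , 1], dim(z1)[1:3]))),
               c(26, 26, 288))
  expect_equal(dim(neighbor_stack(array(z4[, , , 1], dim(z4)[1:3]))),
               c(12, 12, 288))
  expect_length(fwd$Y[1, ], 4L)
})

test_that("neighbour stacking trims one pixel and multiplies channels by 9", {
  st <- neighbor_stack(array(rnorm(28 * 28 * 32), c(28, 28, 32)))
  expect_equal(dim(st), c(26, 26, 288))
  st2 <- neighbor_stack(array(rnorm(14 * 14 * 32), c(14, 14, 32)))
  expect_equal(dim(st2), c(12, 12, 288))
})

test_that("space-feature locally-connected readout selects and pools correctly", {
  set.seed(4)
  g <- 6L
  C <- 3L
  tensor <- array(rnorm(g * g * C), c(g, g, C))
  st <- neighbor_stack(tensor)
  P <- (g - 2L)^2
  ## delta spatial map + one-hot channel weights pick one stacked value
  i <- 2L; j <- 3L; ch <- 11L
  sp <- matrix(0, P, 1); sp[i + (j - 1) * (g - 2L), 1] <- 1
  cw <- matrix(0, 9 * C, 1); cw[ch, 1] <- 1
  out <- space_feature_locally_connected(tensor, sp, cw)
  expect_equal(out$values, st[i, j, ch])
  ## uniform spatial map equals the spatial mean, against a loop oracle
  spu <- matrix(1 / P, P, 2)
  cwr <- matrix(rnorm(9 * C * 2), 9 * C, 2)
  got <- space_feature_locally_connected(tensor, spu, cwr)$values
  oracle <- numeric(2)
  for (v in 1:2) {
    acc <- 0
    for (a in seq_len(g - 2L)) for (b in seq_len(g - 2L)) {
      acc <- acc + sum(st[a, b, ] * cwr[, v]) / P
    }
    oracle[v] <- acc
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(space_feature_locally_connected(tensor, matrix(0, 5, 1), cw),
               "spatial map")
})

test_that("fmri loss matches hand computations and its invariants", {
  r <- c(1, 2, -1, 0.5)
  expect_equal(fmri_loss(r, r, 0.9), -0.1)
  expect_equal(fmri_loss(c(0, 1, 0, 0), c(1, 0, 0, 0), 0.9), 0.45)
  ## colinearity: cosine term saturates, MSE term is alpha * mean(r^2)
  a <- 0.7
  expect_equal(fmri_loss(2 * r, r, a), a * mean(r^2) - (1 - a))
  ## voxel-permutation invariance
  p <- sample(4)
  rh <- c(0.3, -1, 2, 0.1)
  expect_equal(fmri_loss(rh, r, 0.9), fmri_loss(rh[p], r[p], 0.9))
  ## zero vectors: cosine defined as 0
  expect_equal(fmri_loss(rep(0, 3), c(1, 1, 1), 0.9), 0.9)
})

test_that("shift augmentation is bounded, seeded, and moves content", {
  img <- rand_image()
  expect_identical(shift_augment(img, 0L), img)
  s1 <- shift_augment(img, 3L, rng_seed = 11)
  s2 <- shift_augment(img, 3L, rng_seed = 11)
  expect_identical(s1, s2)
  ## a delta moves by exactly the applied shift
  delta <- array(0, c(16, 16, 1))
  delta[8, 8, 1] <- 1
  moved <- voxrecon:::shift_image(delta, dy = 0, dx = 2)
  expect_equal(which(moved[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 8, col = 10))
})

test_that("encoder backward matches finite differences", {
  ts <- tiny_encoder_setup()
  x <- batch_images(rand_images(2, seed = 20), 16L, 3L)
  R <- with_seed(21, matrix(rnorm(2 * 6), 2, 6))
  fwd <- encoder_fw(ts$enc, x, training = TRUE, want_cache = TRUE)
  fl <- voxrecon:::fmri_loss_grad(fwd$Y, R, 0.9)
  bw <- voxrecon:::encoder_bw(ts$enc, fwd$cache, fl$grad)
  loss_of <- function(params) {
    e2 <- ts$enc
    e2$params <- params
    fmri_loss(voxrecon:::encoder_fw(e2, x, training = TRUE)$Y, R, 0.9)
  }
  eps <- 1e-6
  for (k in c("br1_convW", "br2_sp", "br4_ch", "mix", "bias", "br3_bn1g")) {
    p <- ts$enc$params[[k]]
    ii <- with_seed(30, sample(length(p), min(3, length(p))))
    for (i in ii) {
      pp <- ts$enc$params
      pm <- ts$enc$params
      pp[[k]][i] <- pp[[k]][i] + eps
      pm[[k]][i] <- pm[[k]][i] - eps
      expect_equal(bw$grads[[k]][i], (loss_of(pp) - loss_of(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("branch-mixing weights stay non-negative through training", {
  bench <- tiny_benchmark(n_train = 8L, n_voxels = 8L)
  cfg <- encoder_config(n_voxels = 8L, image_side = 32L)
  fit <- train_encoder(bench$train, cfg, tiny_backbone_spec(5L, rep(4L, 5)),
                       train_schedule(epochs = 2, batch_paired = 4,
                                      seed = 3))
  expect_true(all(fit$model$params$mix >= 0))
  expect_length(encode(fit$model, bench$train$images[[1]]), 8L)
  expect_error(encode(fit$model, rand_image(side = 16L)), "resolution")
})
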