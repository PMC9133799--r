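test_that("perceptual distance is a symmetric premetric on images", {
  bb <- tiny_backbone_spec()
  a <- rand_image(seed = 1)
  b <- rand_image(seed = 2)
  expect_equal(perceptual_distance(a, a, bb), 0, tolerance = 1e-12)
  expect_equal(perceptual_distance(a, b, bb),
               perceptual_distance(b, a, bb), tolerance = 1e-12)
  expect_gt(perceptual_distance(a, b, bb), 0)
})

test_that("identification is perfect for exact reconstructions and chance for noise", {
  bb <- tiny_backbone_spec()
  truths <- rand_images(5, seed = 10)
  pool <- rand_images(30, seed = 50)
  ## reconstruction identical to ground truth: 100% at any n
  acc <- nway_identification(truths, truths, pool, n = 5, n_draws = 10,
                             seed = 1, backbone = bb)
  expect_equal(acc$accuracy, 1)
  ## pure-noise reconstructions: accuracy about 1/n
  noise <- rand_images(5, seed = 99)
  ## truths drawn from the same distribution as the pool
  acc2 <- nway_identification(noise, pool[1:5], pool[6:30], n = 2,
                              n_draws = 60, seed = 2, backbone = bb)
  se <- sqrt(0.25 / (5 * 60))
  expect_lt(abs(acc2$accuracy - 0.5), 5 * se)
  expect_error(nway_identification(truths, truths, pool, n = 40,
                                   seed = 1, backbone = bb), "pool")
})

test_that("identification accuracy does not increase with n", {
  bb <- tiny_backbone_spec()
  bench <- tiny_benchmark(n_train = 4L, n_test = 6L, n_unpaired = 25L,
                          n_voxels = 6L)
  ## blurred truths as stand-in reconstructions of middling quality
  recons <- lapply(bench$test$images, function(im) {
    k <- array(im, dim(im))
    (k + k[c(2:32, 32), , ] + k[, c(2:32, 32), ]) / 3
  })
  accs <- vapply(c(2, 5, 10), function(n) {
    nway_identification(recons, bench$test$images, bench$unpaired$images,
                        n = n, n_draws = 30, seed = 4,
                        backbone = bb)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.15))   # Monte-Carlo slack
})

test_that("noise ceiling is 1 without noise, near 0 for pure noise, monotone in repeats", {
  n_stim <- 30L
  nv <- 5L
  signal <- with_seed(3, matrix(rnorm(n_stim * nv), n_stim, nv))
  stack_with_noise <- function(K, sd, seed) {
    reps <- array(0, c(n_stim, K, nv))
    with_seed(seed, {
      for (k in seq_len(K)) {
        reps[, k, ] <- signal + rnorm(n_stim * nv, 0, sd)
      }
    })
    reps
  }
  ## identical repeats, non-constant signal: ceiling exactly 1
  nc0 <- noise_ceiling(stack_with_noise(4L, 0, 1), n_splits = 5, seed = 1)
  expect_equal(nc0$ceiling, rep(1, nv))
  ## pure noise: ceiling near 0
  pure <- with_seed(8, array(rnorm(n_stim * 8 * nv), c(n_stim, 8, nv)))
  ncp <- noise_ceiling(pure, n_splits = 30, seed = 2)
  expect_lt(mean(ncp$ceiling), 0.25)
  ## monotone in repeat count
  meds <- vapply(c(2L, 8L, 32L), function(K) {
    stats::median(noise_ceiling(stack_with_noise(K, 1, 7), n_splits = 20,
                                seed = 3)$ceiling)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  ## fewer than 2 repeats: flagged missing
  nc1 <- noise_ceiling(stack_with_noise(1L, 0, 1))
  expect_true(all(is.na(nc1$ceiling)))
})

test_that("noise ceiling matches an independently coded Monte-Carlo oracle", {
  ## known variances: signal sd 1, noise sd 1, 12 repeats, 40 stimuli
  n_stim <- 40L
  K <- 12L
  ## independent loop-based implementation of the same estimator
  oracle_est <- function(reps, splits, seed) {
    set.seed(seed)
    vals <- numeric(splits)
    for (s in seq_len(splits)) {
      h1 <- sample(K, K / 2)
      m1 <- rowMeans(reps[, h1])
      m2 <- rowMeans(reps[, -h1, drop = FALSE])
      r <- cor(m1, m2)
      vals[s] <- 2 * r / (1 + r)
    }
    mean(pmin(pmax(vals, 0), 1))
  }
  mc <- with_seed(21, vapply(1:30, function(i) {
    sig <- rnorm(n_stim)
    reps <- matrix(sig, n_stim, K) + rnorm(n_stim * K)
    oracle_est(reps, 10, i)
  }, numeric(1)))
  ## package estimate on one fresh draw of the same process
  reps <- with_seed(77, {
    sig <- rnorm(n_stim)
    array(matrix(sig, n_stim, K) + rnorm(n_stim * K), c(n_stim, K, 1))
  })
  est <- noise_ceiling(reps, n_splits = 30, seed = 5)$ceiling
  expect_lt(abs(est - mean(mc)), 4 * stats::sd(mc))
})

test_that("prediction accuracy reports raw and ceiling-corrected correlations", {
  measured <- with_seed(4, matrix(rnorm(20 * 3), 20, 3))
  pa <- prediction_accuracy(measured, measured,
                            ceiling = c(1, 0.5, 0.05))
  expect_equal(pa$raw, rep(1, 3))
  expect_equal(pa$corrected[1:2], c(1, 2))
  expect_true(is.na(pa$corrected[3]) && pa$flagged[3])   # below floor
  pa2 <- prediction_accuracy(-measured, measured)
  expect_equal(pa2$raw, rep(-1, 3))
  ## degenerate variance is flagged
  pred <- measured
  pred[, 2] <- 0
  pa3 <- prediction_accuracy(pred, measured)
  expect_true(pa3$flagged[2])
})
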