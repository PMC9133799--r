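test_that("milestone schedule multiplies the rate per crossed milestone", {
  sched <- encoder_schedule()
  expect_equal(voxrecon:::schedule_lr(sched, 1), 1e-3)
  expect_equal(voxrecon:::schedule_lr(sched, 21), 1e-3 * 0.1)
  expect_equal(voxrecon:::schedule_lr(sched, 36), 1e-3 * 0.1^3)
  dsched <- decoder_schedule()
  expect_equal(voxrecon:::schedule_lr(dsched, 31), 1e-3 * 0.2)
  expect_equal(voxrecon:::schedule_lr(dsched, 121), 1e-3 * 0.2^4)
})

test_that("encoder training reduces the loss and is reproducible", {
  bench <- tiny_benchmark(n_train = 16L, n_voxels = 10L, sigma_n = 0)
  cfg <- encoder_config(n_voxels = 10L, image_side = 32L)
  bb <- tiny_backbone_spec(5L, rep(4L, 5))
  sched <- train_schedule(epochs = 4, lr = 3e-3, batch_paired = 8, seed = 5)
  fit1 <- train_encoder(bench$train, cfg, bb, sched)
  expect_lt(tail(fit1$log$loss, 1), fit1$log$loss[1])
  fit2 <- train_encoder(bench$train, cfg, bb, sched)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_error(train_encoder(list(images = list()), cfg, bb, sched),
               "empty")
})

test_that("phase II keeps the encoder frozen and decomposes its loss", {
  bench <- tiny_benchmark(n_train = 8L, n_voxels = 8L, n_unpaired = 12L)
  ecfg <- encoder_config(n_voxels = 8L, image_side = 32L)
  bb <- tiny_backbone_spec(5L, rep(4L, 5))
  enc <- train_encoder(bench$train, ecfg, bb,
                       train_schedule(epochs = 1, batch_paired = 8,
                                      seed = 2))$model
  sum_before <- voxrecon:::param_checksum(enc$params)
  dcfg <- tiny_decoder_config(n_voxels = 8L)
  fit <- train_decoder(bench$train, bench$unpaired, enc, dcfg,
                       train_schedule(epochs = 2, batch_paired = 8,
                                      batch_unpaired = 6, seed = 3))
  expect_identical(voxrecon:::param_checksum(enc$params), sum_before)
  ## recorded total equals the recorded components at every step
  expect_equal(fit$log$total, fit$log$l_d + fit$log$l_ed)
  expect_true(all(fit$log$l_ed > 0))
})

test_that("an empty unpaired pool reduces phase II to the supervised loss", {
  bench <- tiny_benchmark(n_train = 8L, n_voxels = 6L)
  ecfg <- encoder_config(n_voxels = 6L, image_side = 32L)
  enc <- build_encoder(ecfg, tiny_backbone_spec(5L, rep(4L, 5)), seed = 2)
  dcfg <- tiny_decoder_config(n_voxels = 6L)
  fit <- train_decoder(bench$train, NULL, enc, dcfg,
                       train_schedule(epochs = 1, batch_paired = 8,
                                      seed = 3))
  expect_equal(fit$log$l_ed, rep(0, nrow(fit$log)))
  expect_equal(fit$log$total, fit$log$l_d)
})

test_that("training never consults class labels", {
  bench <- tiny_benchmark(n_train = 8L, n_voxels = 6L, n_unpaired = 10L)
  scrambled <- bench
  scrambled$train$classes <- rev(scrambled$train$classes)
  scrambled$unpaired$classes <- rep("bogus", 10L)
  ecfg <- encoder_config(n_voxels = 6L, image_side = 32L)
  bb <- tiny_backbone_spec(5L, rep(4L, 5))
  sched <- train_schedule(epochs = 1, batch_paired = 8, seed = 9)
  f1 <- train_encoder(bench$train, ecfg, bb, sched)
  f2 <- train_encoder(scrambled$train, ecfg, bb, sched)
  expect_identical(f1$model$params, f2$model$params)
  dcfg <- tiny_decoder_config(n_voxels = 6L)
  dsched <- train_schedule(epochs = 1, batch_paired = 8,
                           batch_unpaired = 6, seed = 9)
  d1 <- train_decoder(bench$train, bench$unpaired, f1$model, dcfg, dsched)
  d2 <- train_decoder(scrambled$train, scrambled$unpaired, f2$model, dcfg,
                      dsched)
  expect_identical(d1$model$params, d2$model$params)
})

test_that("cycle-consistency loss is the image loss of the reconstruction", {
  bench <- tiny_benchmark(n_train = 6L, n_voxels = 6L)
  ecfg <- encoder_config(n_voxels = 6L, image_side = 32L)
  enc <- build_encoder(ecfg, tiny_backbone_spec(5L, rep(4L, 5)), seed = 1)
  dec <- build_decoder(tiny_decoder_config(n_voxels = 6L), seed = 2)
  s <- bench$train$images[[1]]
  got <- cycle_consistency_loss(s, enc, dec)
  manual <- image_loss(decode(dec, encode(enc, s)), s, enc$backbone,
                       dec$cfg$loss_weights)
  expect_equal(got, manual)
})
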