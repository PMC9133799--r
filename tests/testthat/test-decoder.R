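test_that("the default decoder configuration targets 14x14x64 -> 112x112", {
  cfg <- decoder_config(n_voxels = 4L)
  expect_equal(cfg$base_resolution, 14L)
  expect_equal(cfg$base_channels, 64L)
  expect_equal(cfg$out_side, 112L)
  ## (the full-size forward pass is exercised in the acceptance suite)
  small <- tiny_decoder_config(n_voxels = 4L, side = 16L)
  img <- decode(build_decoder(small, seed = 1), with_seed(2, rnorm(4)))
  expect_equal(dim(img), c(16, 16, 3))
  expect_true(all(img > 0 & img < 1))
})

test_that("up-blocks double the side from the base resolution", {
  cfg <- tiny_decoder_config(n_voxels = 5L, side = 32L)
  dec <- build_decoder(cfg, seed = 2)
  fwd <- voxrecon:::decoder_fw(dec, matrix(rnorm(5), 1), want_cache = TRUE)
  sides <- vapply(fwd$cache$blocks,
                  function(b) b$gn$d[1], numeric(1))
  expect_equal(sides, c(8, 16, 32))        # 4 -> 8 -> 16 -> 32
  expect_error(decode(dec, rnorm(7)), "voxel count")
})

test_that("rgb loss matches hand computations", {
  s <- rand_image(side = 4L)
  expect_equal(rgb_loss(s, s), 0)
  z <- array(0, c(2, 2, 1))
  expect_equal(rgb_loss(z, z + 1), 1)
  checker <- array(c(0, 1, 1, 0), c(2, 2, 1))
  expect_equal(rgb_loss(z + 0.5, checker), 0.5)
  expect_error(rgb_loss(z, array(0, c(3, 3, 1))), "shape")
})

test_that("total variation is 0 iff constant, 1 on a checkerboard, symmetric", {
  expect_equal(tv_reg(array(0.3, c(5, 5, 3))), 0)
  expect_equal(tv_reg(matrix(c(0, 1), 1, 2)), 1)
  checker <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  expect_equal(tv_reg(checker), 1)
  m <- matrix(runif(12), 3, 4)
  expect_equal(tv_reg(m), tv_reg(t(m)))
})

test_that("perceptual loss is 0 at identity, 1 for negated features, matches a hand oracle", {
  bb <- tiny_backbone_spec()
  s <- rand_image(seed = 5)
  expect_equal(perceptual_loss(s, s, bb), 0, tolerance = 1e-12)
  ## negated features at every block -> cos_b = -1 -> loss 1
  feats <- lapply(1:3, function(b) array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  neg <- lapply(feats, function(f) -f)
  expect_equal(voxrecon:::perceptual_core(feats, neg)$value, 1)
  ## brute-force oracle with explicit dot products on a 2-block backbone
  bb2 <- build_backbone(backbone_spec(n_blocks = 2L, channels = c(3L, 4L),
                                      seed = 11))
  a <- rand_image(side = 4L, seed = 6)
  b <- rand_image(side = 4L, seed = 7)
  got <- perceptual_loss(a, b, bb2)
  pa <- extract_features(a, bb2)
  pb <- extract_features(b, bb2)
  oracle <- 0
  for (blk in 1:2) {
    fa <- pa$blocks[[blk]]
    fb <- pb$blocks[[blk]]
    cn <- function(f) {
      for (i in seq_len(dim(f)[1])) for (j in seq_len(dim(f)[2])) {
        nrm <- sqrt(sum(f[i, j, ]^2))
        if (nrm >= 1e-8) f[i, j, ] <- f[i, j, ] / nrm else f[i, j, ] <- 0
      }
      f
    }
    u <- as.vector(cn(fa))
    v <- as.vector(cn(fb))
    cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    oracle <- oracle + (1 - cs) / 2 / 2
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  ## symmetry
  expect_equal(got, perceptual_loss(b, a, bb2), tolerance = 1e-12)
})

test_that("composite image loss is additive with equal default weights", {
  bb <- tiny_backbone_spec()
  s <- array(0.5, c(16, 16, 3))
  il <- image_loss(s, s, bb)
  expect_equal(il$l_rgb, 0)
  expect_equal(il$l_perceptual, 0, tolerance = 1e-12)
  expect_equal(il$tv, 0)
  expect_equal(il$total, 0, tolerance = 1e-12)
  a <- rand_image(seed = 8)
  b <- rand_image(seed = 9)
  il2 <- image_loss(a, b, bb)
  expect_equal(il2$total,
               rgb_loss(a, b) + perceptual_loss(a, b, bb) +
                 0.1 * tv_reg(a), tolerance = 1e-12)
  ## identity scores no worse than random perturbations (TV-free weights)
  w0 <- c(rgb = 1, perceptual = 1, tv = 0)
  base <- image_loss(b, b, bb, w0)$total
  perturbed <- vapply(1:5, function(i) {
    image_loss(pmin(pmax(b + with_seed(40 + i,
      array(rnorm(length(b), 0, 0.1), dim(b))), 0), 1), b, bb, w0)$total
  }, numeric(1))
  expect_true(all(base <= perturbed))
})

test_that("decoder output contract holds for random weights and inputs", {
  cfg <- tiny_decoder_config(n_voxels = 9L, side = 16L)
  for (sd in 1:3) {
    dec <- build_decoder(cfg, seed = sd)
    out <- decode(dec, with_seed(sd, rnorm(9, 0, 3)))
    expect_equal(dim(out), c(16, 16, 3))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("decoder backward matches finite differences through the image loss", {
  bb <- build_backbone(tiny_backbone_spec())
  cfg <- tiny_decoder_config(n_voxels = 5L, side = 16L)
  dec <- build_decoder(cfg, seed = 2)
  R <- with_seed(3, matrix(rnorm(2 * 5), 2, 5))
  s4 <- with_seed(4, array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  w <- c(rgb = 1, perceptual = 1, tv = 0.1)
  fwd <- voxrecon:::decoder_fw(dec, R, want_cache = TRUE)
  il <- voxrecon:::image_loss_grad(fwd$out, s4, bb, w)
  gr <- voxrecon:::decoder_bw(dec, fwd$cache, il$grad)
  loss_of <- function(params) {
    d2 <- dec
    d2$params <- params
    out <- voxrecon:::decoder_fw(d2, R)$out
    tot <- 0
    for (n in 1:2) {
      tot <- tot + image_loss(array(out[, , , n], c(16, 16, 3)),
                              array(s4[, , , n], c(16, 16, 3)),
                              bb, w)$total / 2
    }
    tot
  }
  eps <- 1e-6
  for (k in c("W0", "upW2", "gng1", "outW", "outb")) {
    p <- dec$params[[k]]
    ii <- with_seed(50, sample(length(p), min(3, length(p))))
    for (i in ii) {
      pp <- dec$params
      pm <- dec$params
      pp[[k]][i] <- pp[[k]][i] + eps
      pm[[k]][i] <- pm[[k]][i] - eps
      expect_equal(gr[[k]][i], (loss_of(pp) - loss_of(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})
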