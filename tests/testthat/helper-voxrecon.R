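## Shared tiny fixtures, built in code.

tiny_backbone_spec <- function(n_blocks = 4L, channels = rep(4L, n_blocks),
                               seed = 3L) {
  backbone_spec(n_blocks = n_blocks, channels = channels, seed = seed)
}

tiny_encoder_setup <- function(n_voxels = 6L, side = 16L, seed = 5L) {
  bb <- build_backbone(tiny_backbone_spec())
  cfg <- encoder_config(n_voxels = n_voxels, image_side = side,
                        branch_levels = 1:4, branch_channels = 8L,
                        shift_augment_px = 0L,
                        branch_grids = c(4L, 4L, 4L, 4L))
  list(bb = bb, cfg = cfg, enc = build_encoder(cfg, bb, seed = seed))
}

rand_image <- function(side = 16L, channels = 3L, seed = 1L) {
  with_seed(seed, array(stats::runif(side * side * channels),
                        c(side, side, channels)))
}

rand_images <- function(n, side = 16L, channels = 3L, seed = 1L) {
  lapply(seq_len(n), function(i) rand_image(side, channels, seed + i))
}

## small paired dataset from a virtual subject (images rendered, responses
## simulated); kept tiny so unit tests stay fast
tiny_benchmark <- function(side = 32L, n_voxels = 20L, sigma_n = 0.3,
                           n_train = 24L, n_test = 6L, repeats = 4L,
                           n_unpaired = 30L, seed = 7L) {
  spec <- stimulus_spec(image_side = side, n_train = n_train,
                        n_test = n_test, test_repeats = repeats,
                        n_unpaired = n_unpaired)
  subj <- virtual_subject(n_voxels = n_voxels, image_side = side,
                          sigma_n = sigma_n, seed = seed)
  make_benchmark(spec, subj, seed = seed + 1L)
}

tiny_decoder_config <- function(n_voxels, side = 32L, channels = 3L) {
  decoder_config(n_voxels = n_voxels, base_resolution = side %/% 8L,
                 base_channels = 16L, up_channels = c(16L, 8L, 8L),
                 out_channels = channels, kernel = 3L, gn_groups = 4L)
}
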