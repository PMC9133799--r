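## On-disk layout of a benchmark directory:
##   config.yaml           spec + subject summary + class sets
##   images/<id>.png       all stimuli (8-bit PNG; images are quantized to
##                         the 8-bit grid at render time so the round trip
##                         is exact)
##   responses_train.csv   id, V1..VNv (single repeat)
##   responses_test.csv    id, repeat, V1..VNv
##   meta.csv              id, class, split
##   subject_truth.csv     per-voxel ground-truth pRF table

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE,
                              trim = TRUE)

#' Write a synthetic benchmark to a directory
#'
#' @param bench A [make_benchmark()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  all_sets <- list(bench$train, bench$test, bench$unpaired)
  meta <- do.call(rbind, lapply(all_sets, function(s) {
    data.frame(id = s$ids, class = s$classes, split = s$split)
  }))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  for (s in all_sets) {
    for (i in seq_along(s$images)) {
      img <- s$images[[i]]
      if (dim(img)[3] == 1L) img <- img[, , 1]
      png::writePNG(img, file.path(dir, "images",
                                   paste0(s$ids[i], ".png")))
    }
  }
  Nv <- bench$subject$n_voxels
  vn <- paste0("V", seq_len(Nv))
  tr <- as.data.frame(apply(bench$train$responses, 2, fmt_num))
  names(tr) <- vn
  utils::write.csv(cbind(id = bench$train$ids, tr),
                   file.path(dir, "responses_train.csv"),
                   row.names = FALSE, quote = FALSE)
  K <- dim(bench$test$responses)[2]
  te_rows <- do.call(rbind, lapply(seq_along(bench$test$ids), function(i) {
    m <- as.data.frame(matrix(fmt_num(bench$test$responses[i, , ]),
                              K, Nv))
    names(m) <- vn
    cbind(data.frame(id = bench$test$ids[i], rep = seq_len(K)), m)
  }))
  utils::write.csv(te_rows, file.path(dir, "responses_test.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bench$truth, file.path(dir, "subject_truth.csv"),
                   row.names = FALSE)
  sp <- bench$spec
  cfg <- list(image_side = sp$image_side, channels = sp$channels,
              n_voxels = Nv, sigma_n = bench$subject$sigma_n,
              test_repeats = sp$test_repeats,
              n_train = sp$n_train, n_test = sp$n_test,
              n_unpaired = sp$n_unpaired,
              train_classes = sp$train_classes,
              test_classes = sp$test_classes,
              unpaired_classes = sp$unpaired_classes,
              class_sets = bench$class_sets)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a PNG image as an `[H, W, C]` array
#'
#' @param path PNG file.
#' @param channels Channels to keep (1 or 3).
#' @return Numeric array `[H, W, channels]` in `[0, 1]`.
#' @export
read_png_image <- function(path, channels = 3L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  if (dim(img)[3] > channels) img <- img[, , seq_len(channels), drop = FALSE]
  img
}

read_responses_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vn <- grep("^V[0-9]+$", names(df), value = TRUE)
  list(df = df, mat = as.matrix(df[, vn, drop = FALSE]))
}

#' Read a dataset split from a benchmark directory
#'
#' Validates image/response id alignment, preserves the repeat axis, and
#' rejects non-finite responses with the offending id named.
#'
#' @param path Benchmark directory.
#' @param split `"train"`, `"test"` or `"unpaired"`.
#' @return A `vr_paired` (train/test) or `vr_unpaired` dataset.
#' @export
read_dataset <- function(path, split = c("train", "test", "unpaired")) {
  split <- match.arg(split)
  cfg <- yaml::read_yaml(file.path(path, "config.yaml"))
  meta <- utils::read.csv(file.path(path, "meta.csv"))
  meta <- meta[meta$split == split, ]
  vr_assert(nrow(meta) > 0, "no '", split, "' entries in meta.csv")
  imgs <- lapply(meta$id, function(id) {
    f <- file.path(path, "images", paste0(id, ".png"))
    vr_assert(file.exists(f), "image file missing for id '", id, "'")
    read_png_image(f, cfg$channels)
  })
  if (split == "unpaired") {
    return(structure(list(images = imgs, ids = meta$id,
                          classes = meta$class, split = split),
                     class = "vr_unpaired"))
  }
  if (split == "train") {
    rr <- read_responses_csv(file.path(path, "responses_train.csv"))
    pos <- match(meta$id, rr$df$id)
    bad <- meta$id[is.na(pos)]
    vr_assert(length(bad) == 0,
              "responses missing for id '", bad[1], "'")
    R <- rr$mat[pos, , drop = FALSE]
    nf <- !is.finite(R)
    vr_assert(!any(nf), "non-finite response for id '",
              meta$id[which(rowSums(nf) > 0)[1]], "'")
    return(structure(list(images = imgs, responses = R, ids = meta$id,
                          classes = meta$class, split = split),
                     class = "vr_paired"))
  }
  rr <- read_responses_csv(file.path(path, "responses_test.csv"))
  K <- max(rr$df$rep)
  Nv <- ncol(rr$mat)
  R <- array(NA_real_, c(nrow(meta), K, Nv))
  for (i in seq_len(nrow(meta))) {
    rows <- which(rr$df$id == meta$id[i])
    vr_assert(length(rows) == K, "responses missing for id '",
              meta$id[i], "'")
    R[i, rr$df$rep[rows], ] <- rr$mat[rows, ]
  }
  vr_assert(all(is.finite(R)), "non-finite responses in test split")
  structure(list(images = imgs, responses = R, ids = meta$id,
                 classes = meta$class, split = split),
            class = "vr_paired")
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files holding the model object (config + weights +
#' normalization buffers).
#'
#' @param model `vr_encoder`, `vr_decoder` or `vr_backbone`.
#' @param path File path.
#' @rdname checkpoints
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname checkpoints
#' @export
load_model <- function(path) readRDS(path)

#' Write a machine-readable run manifest
#'
#' Records the resolved configuration, seed, package version and a config
#' checksum next to a CLI output, enabling bit-for-bit re-runs of
#' deterministic stages.
#'
#' @param path Manifest path (JSON).
#' @param command Subcommand name.
#' @param args Named list of resolved arguments.
#' @param seed Seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, args, seed) {
  bytes <- as.integer(serialize(args, NULL))
  hash <- 0
  for (b in bytes) hash <- (hash * 31 + b) %% 2147483647
  jsonlite::write_json(
    list(command = command, args = args, seed = seed,
         config_hash = hash,
         package = as.character(utils::packageVersion("voxrecon")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
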