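#' Training schedule
#'
#' @param epochs Number of epochs.
#' @param lr Initial Adam learning rate.
#' @param milestones Epochs after which the learning rate drops.
#' @param drop_factor Multiplicative factor applied at each milestone
#'   (e.g. 0.1 for a 90% drop).
#' @param batch_paired Paired sub-batch size (default 16).
#' @param batch_unpaired Unpaired sub-batch size (default 16).
#' @param seed RNG seed driving shuffling, augmentation and sampling.
#' @return A `vr_schedule`.
#' @export
train_schedule <- function(epochs, lr = 1e-3, milestones = integer(0),
                           drop_factor = 0.1, batch_paired = 16L,
                           batch_unpaired = 16L, seed = 1L) {
  vr_assert(epochs >= 1 && batch_paired >= 1 && batch_unpaired >= 1,
            "all counts must be positive")
  vr_assert(drop_factor > 0 && drop_factor < 1,
            "drop_factor must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 milestones = as.integer(milestones),
                 drop_factor = drop_factor,
                 batch_paired = as.integer(batch_paired),
                 batch_unpaired = as.integer(batch_unpaired),
                 seed = as.integer(seed)),
            class = "vr_schedule")
}

#' Reference schedules
#'
#' `encoder_schedule()` mirrors the reference recipe: Adam, 50 epochs,
#' lr 1e-3, 90% drops at epochs 20/30/35. `decoder_schedule()`: 150
#' epochs, lr 1e-3, 80% drop after every 30 epochs. Pass smaller values
#' for desk-scale experiments.
#'
#' @param epochs,seed Overridable.
#' @rdname reference_schedules
#' @export
encoder_schedule <- function(epochs = 50L, seed = 1L) {
  train_schedule(epochs = epochs, lr = 1e-3,
                 milestones = c(20L, 30L, 35L), drop_factor = 0.1,
                 seed = seed)
}

#' @rdname reference_schedules
#' @export
decoder_schedule <- function(epochs = 150L, seed = 1L) {
  train_schedule(epochs = epochs, lr = 1e-3,
                 milestones = seq(30L, 149L, by = 30L), drop_factor = 0.2,
                 seed = seed)
}

## normalize a paired dataset's responses to an [N, Nv] matrix
## (repeat-stacked responses are averaged across repeats).
response_matrix <- function(data) {
  R <- data$responses
  if (length(dim(R)) == 3) R <- apply(R, c(1, 3), mean)
  R
}

#' Phase I: supervised encoder training
#'
#' Minimizes the fMRI loss (convex mix of MSE and negative cosine) plus the
#' total-variation penalty on the voxel spatial maps, with per-batch random
#' shift augmentation. Class labels are never consulted. Fully reproducible
#' under the schedule seed.
#'
#' @param data Paired dataset (list with `images` and `responses`).
#' @param cfg An [encoder_config()].
#' @param backbone Backbone spec or model (kept frozen).
#' @param sched A [train_schedule()].
#' @return List with `model` (trained `vr_encoder`) and `log` (per-epoch
#'   data frame of the training loss).
#' @export
train_encoder <- function(data, cfg, backbone, sched) {
  vr_assert(length(data$images) >= 1, "empty training data")
  R <- response_matrix(data)
  vr_assert(nrow(R) == length(data$images), "images/responses misaligned")
  vr_assert(all(is.finite(R)), "non-finite responses in training data")
  enc <- build_encoder(cfg, backbone, seed = derive_seed(sched$seed, "enc-init"))
  st <- adam_init(enc$params)
  N <- length(data$images)
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0))
  with_seed(derive_seed(sched$seed, "enc-train"), {
    for (epoch in seq_len(sched$epochs)) {
      lr <- schedule_lr(sched, epoch)
      ord <- sample.int(N)
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1, N, by = sched$batch_paired)) {
        idx <- ord[start:min(start + sched$batch_paired - 1L, N)]
        imgs <- lapply(data$images[idx], shift_augment,
                       max_px = cfg$shift_augment_px)
        x <- batch_images(imgs, cfg$image_side, cfg$in_channels)
        fwd <- encoder_fw(enc, x, training = TRUE, want_cache = TRUE)
        enc <- fwd$enc
        fl <- fmri_loss_grad(fwd$Y, R[idx, , drop = FALSE], cfg$alpha)
        tv <- spatial_map_tv(enc)
        loss <- fl$value + cfg$spatial_tv_weight * tv$value
        if (!is.finite(loss)) {
          vr_stop("NaN/Inf training loss at epoch ", epoch,
                  "; aborting encoder training")
        }
        bw <- encoder_bw(enc, fwd$cache, fl$grad)
        grads <- bw$grads
        for (k in names(tv$grads)) {
          grads[[k]] <- grads[[k]] + cfg$spatial_tv_weight * tv$grads[[k]]
        }
        enc$params <- adam_step(enc$params, grads, st, lr)
        enc$params$mix <- pmax(enc$params$mix, 0)   # non-negativity
        if (cfg$nonneg_spatial_maps) {
          for (i in seq_along(cfg$branch_levels)) {
            k <- paste0("br", i, "_sp")
            enc$params[[k]] <- pmax(enc$params[[k]], 0)
          }
        }
        epoch_loss <- epoch_loss + loss
        nb <- nb + 1L
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   loss = epoch_loss / nb))
    }
  })
  list(model = enc, log = log)
}

#' Phase II: decoder training with self-supervision
#'
#' Each step combines a supervised term `L_D` (decode measured responses of
#' a paired sub-batch and compare to their images) with a cycle-consistency
#' term `L_ED` (map unpaired images through the frozen encoder and the
#' decoder back to themselves), both measured by the composite image loss.
#' With an empty unpaired pool the loss reduces exactly to the supervised
#' term. The encoder is never updated: its parameters are bit-identical
#' before and after training (asserted internally).
#'
#' @param paired Paired dataset (images + responses).
#' @param unpaired Unpaired pool (list with `images`), or `NULL` for the
#'   supervised-only baseline.
#' @param enc Trained, frozen `vr_encoder`.
#' @param cfg A [decoder_config()].
#' @param sched A [train_schedule()].
#' @param backbone Backbone for the perceptual loss; defaults to the
#'   encoder's backbone.
#' @return List with `model` (trained `vr_decoder`), `log` (per-step data
#'   frame with `l_d`, `l_ed`, `total`) and `log_epochs`.
#' @export
train_decoder <- function(paired, unpaired = NULL, enc, cfg, sched,
                          backbone = NULL) {
  vr_assert(inherits(enc, "vr_encoder"), "enc must be a trained vr_encoder")
  bb <- if (is.null(backbone)) enc$backbone else as_backbone(backbone)
  R <- response_matrix(paired)
  N <- length(paired$images)
  vr_assert(N >= 1, "empty paired data")
  n_unp <- if (is.null(unpaired)) 0L else length(unpaired$images)
  dec <- build_decoder(cfg, seed = derive_seed(sched$seed, "dec-init"))
  st <- adam_init(dec$params)
  enc_sum_before <- param_checksum(enc$params)
  w <- cfg$loss_weights
  side <- cfg$out_side
  log <- data.frame()
  with_seed(derive_seed(sched$seed, "dec-train"), {
    step <- 0L
    for (epoch in seq_len(sched$epochs)) {
      lr <- schedule_lr(sched, epoch)
      ord <- sample.int(N)
      unp_ord <- if (n_unp > 0) sample.int(n_unp) else integer(0)
      unp_pos <- 1L
      for (start in seq(1, N, by = sched$batch_paired)) {
        step <- step + 1L
        idx <- ord[start:min(start + sched$batch_paired - 1L, N)]
        s4 <- batch_images(paired$images[idx], side, cfg$out_channels)
        fwd <- decoder_fw(dec, R[idx, , drop = FALSE], want_cache = TRUE)
        ld <- image_loss_grad(fwd$out, s4, bb, w)
        grads <- decoder_bw(dec, fwd$cache, ld$grad)
        l_ed <- 0
        if (n_unp > 0) {
          take <- min(sched$batch_unpaired, n_unp - unp_pos + 1L)
          if (take < 1L) {            # reshuffle pool within long epochs
            unp_ord <- sample.int(n_unp)
            unp_pos <- 1L
            take <- min(sched$batch_unpaired, n_unp)
          }
          uidx <- unp_ord[unp_pos:(unp_pos + take - 1L)]
          unp_pos <- unp_pos + take
          su <- batch_images(unpaired$images[uidx], enc$cfg$image_side,
                             enc$cfg$in_channels)
          r_u <- encoder_fw(enc, su, training = FALSE)$Y
          su_t <- batch_images(unpaired$images[uidx], side,
                               cfg$out_channels)
          fwd_u <- decoder_fw(dec, r_u, want_cache = TRUE)
          led <- image_loss_grad(fwd_u$out, su_t, bb, w)
          g_u <- decoder_bw(dec, fwd_u$cache, led$grad)
          for (k in names(grads)) grads[[k]] <- grads[[k]] + g_u[[k]]
          l_ed <- led$total
        }
        total <- ld$total + l_ed
        if (!is.finite(total)) {
          vr_stop("NaN/Inf training loss at step ", step,
                  "; aborting decoder training")
        }
        dec$params <- adam_step(dec$params, grads, st, lr)
        log <- rbind(log, data.frame(step = step, epoch = epoch, lr = lr,
                                     l_d = ld$total, l_ed = l_ed,
                                     total = total))
      }
    }
  })
  vr_assert(identical(param_checksum(enc$params), enc_sum_before),
            "internal error: encoder parameters mutated during phase II")
  log_epochs <- stats::aggregate(cbind(l_d, l_ed, total) ~ epoch,
                                 data = log, FUN = mean)
  list(model = dec, log = log, log_epochs = log_epochs)
}

#' Cycle-consistency loss of an image through encoder and decoder
#'
#' `image_loss(D(E(s)), s)`: the self-supervision objective applied to a
#' single image. No class labels are consulted.
#'
#' @param s Image `[H, W, C]`.
#' @param enc `vr_encoder`.
#' @param dec `vr_decoder`.
#' @param backbone Backbone for the perceptual term (default: encoder's).
#' @param weights Image-loss weights (default: decoder config's).
#' @return An `ImageLossReport` list (`l_rgb`, `l_perceptual`, `tv`,
#'   `total`).
#' @export
cycle_consistency_loss <- function(s, enc, dec, backbone = NULL,
                                   weights = NULL) {
  bb <- if (is.null(backbone)) enc$backbone else as_backbone(backbone)
  if (is.null(weights)) weights <- dec$cfg$loss_weights
  s_hat <- decode(dec, encode(enc, s))
  s_cmp <- s
  if (dim(s)[3] == 1L && dim(s_hat)[3] == 3L) s_cmp <- s[, , c(1, 1, 1)]
  image_loss(s_hat, s_cmp, bb, weights)
}
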