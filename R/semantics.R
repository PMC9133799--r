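#' Deep-feature embedding of an image
#'
#' Flattened backbone features at one block (default block 4, a mid-level
#' "semantic" representation), used for class centroids and classification.
#'
#' @param image `[H, W, C]` array in `[0, 1]`.
#' @param backbone Backbone spec or model.
#' @param block Block index (default 4).
#' @return Numeric vector.
#' @export
embed_image <- function(image, backbone, block = 4L) {
  bb <- as_backbone(backbone)
  py <- extract_features(image, bb, levels = block)
  as.vector(py$blocks[[1]])
}

#' Build a class-centroid gallery
#'
#' For every class, up to `n_per_class` images are sampled (seeded) and the
#' centroid is the arithmetic mean of their embeddings. Classification then
#' ranks gallery classes by Pearson correlation with a query embedding.
#'
#' @param images_by_class Named list: class id -> list of images (each an
#'   embedding-compatible array), or a list of precomputed embedding
#'   vectors when `embedded = TRUE`.
#' @param backbone Backbone spec or model.
#' @param block Embedding block index.
#' @param n_per_class Images sampled per class (default 100).
#' @param seed Sampling seed.
#' @param embedded Set `TRUE` when `images_by_class` already holds
#'   embedding vectors.
#' @return A `vr_gallery`: list with `class_ids`, `centroids` (one column
#'   per class), `block`, `n_per_class`.
#' @export
build_gallery <- function(images_by_class, backbone = NULL, block = 4L,
                          n_per_class = 100L, seed = 1L,
                          embedded = FALSE) {
  vr_assert(length(images_by_class) >= 1, "gallery needs at least one class")
  ids <- names(images_by_class)
  vr_assert(!is.null(ids) && !anyDuplicated(ids),
            "images_by_class must have unique class names")
  for (ci in seq_along(images_by_class)) {
    vr_assert(length(images_by_class[[ci]]) >= 1,
              "class '", ids[ci], "' has no images")
  }
  bb <- if (embedded) NULL else as_backbone(backbone)
  cent <- NULL
  with_seed(seed, {
    for (ci in seq_along(images_by_class)) {
      imgs <- images_by_class[[ci]]
      take <- sample(seq_along(imgs), min(n_per_class, length(imgs)))
      embs <- vapply(imgs[take], function(im) {
        if (embedded) as.numeric(im) else embed_image(im, bb, block)
      }, numeric(if (embedded) length(imgs[[1]]) else
        length(embed_image(imgs[[1]], bb, block))))
      if (is.null(dim(embs))) embs <- matrix(embs, nrow = 1)
      if (is.null(cent)) cent <- matrix(0, nrow(embs), length(images_by_class))
      cent[, ci] <- rowMeans(embs)
    }
  })
  structure(list(class_ids = ids, centroids = cent, block = block,
                 n_per_class = n_per_class), class = "vr_gallery")
}

## Pearson correlation against every centroid; zero-variance vectors give 0.
gallery_similarity <- function(emb, gallery) {
  cent <- gallery$centroids
  ec <- emb - mean(emb)
  se <- sqrt(sum(ec * ec))
  sims <- numeric(ncol(cent))
  if (se < 1e-12) return(sims)
  for (j in seq_len(ncol(cent))) {
    cc <- cent[, j] - mean(cent[, j])
    sc <- sqrt(sum(cc * cc))
    sims[j] <- if (sc < 1e-12) 0 else sum(ec * cc) / (se * sc)
  }
  sims
}

#' Classify an image against a class-centroid gallery
#'
#' Similarity is the Pearson correlation between the image's embedding and
#' each class centroid; classes are ranked by descending correlation with
#' deterministic ties broken by class order.
#'
#' @param image `[H, W, C]` array, or a precomputed embedding vector when
#'   `embedded = TRUE`.
#' @param gallery A [build_gallery()] result.
#' @param true_class Optional ground-truth class id; when given,
#'   `rank_of_truth` is filled in.
#' @param backbone Backbone used to embed (required unless `embedded`).
#' @param embedded Set `TRUE` if `image` is already an embedding.
#' @return A `ClassificationResult`: list with `ranked_ids`, `scores`
#'   (sorted non-increasing), `rank_of_truth` (or `NA`), `top1`/`top5`
#'   flags.
#' @export
classify <- function(image, gallery, true_class = NULL, backbone = NULL,
                     embedded = FALSE) {
  vr_assert(inherits(gallery, "vr_gallery"), "gallery must be a vr_gallery")
  emb <- if (embedded) as.numeric(image) else
    embed_image(image, as_backbone(backbone), gallery$block)
  sims <- gallery_similarity(emb, gallery)
  ord <- order(-sims, seq_along(sims))          # ties -> class order
  rk <- NA_integer_
  top1 <- NA
  top5 <- NA
  if (!is.null(true_class)) {
    pos <- match(true_class, gallery$class_ids)
    vr_assert(!is.na(pos), "true_class not present in gallery")
    rk <- match(pos, ord)
    top1 <- rk == 1L
    top5 <- rk <= 5L
  }
  structure(list(ranked_ids = gallery$class_ids[ord], scores = sims[ord],
                 similarities = sims, class_ids = gallery$class_ids,
                 rank_of_truth = rk, top1 = top1, top5 = top5,
                 true_class = true_class),
            class = "vr_classification")
}

#' n-way classification accuracy from classification results
#'
#' For each result and each draw, `n - 1` distractor classes are sampled
#' from the gallery alongside the ground truth; the trial counts as correct
#' when the truth is among the top `k` candidates by similarity. Reports
#' the mean accuracy with a bootstrap 95% confidence interval over test
#' items.
#'
#' @param results List of [classify()] results with known `true_class`.
#' @param n Number of candidate classes (`>= 2`).
#' @param k Top-k criterion (default 1; `k = n` is always correct).
#' @param n_draws Monte-Carlo draws per item (default 200).
#' @param seed Seed for distractor sampling and the bootstrap.
#' @param n_boot Bootstrap replicates (default 1000).
#' @return List with `accuracy`, `ci` (95% bootstrap), `per_item`.
#' @export
nway_classification <- function(results, n, k = 1L, n_draws = 200L,
                                seed = 1L, n_boot = 1000L) {
  vr_assert(n >= 2, "n must be at least 2")
  vr_assert(k >= 1 && k <= n, "k must lie in 1..n")
  G <- length(results[[1]]$class_ids)
  vr_assert(n <= G, "n exceeds gallery size")
  per_item <- numeric(length(results))
  with_seed(seed, {
    for (i in seq_along(results)) {
      res <- results[[i]]
      truth <- match(res$true_class, res$class_ids)
      vr_assert(!is.na(truth), "results must carry true_class")
      sims <- res$similarities
      hits <- 0L
      for (d in seq_len(n_draws)) {
        distract <- sample(setdiff(seq_len(G), truth), n - 1L)
        cand <- c(truth, distract)
        ord <- cand[order(-sims[cand], cand)]
        if (match(truth, ord) <= k) hits <- hits + 1L
      }
      per_item[i] <- hits / n_draws
    }
    boots <- replicate(n_boot, mean(per_item[sample.int(
      length(per_item), replace = TRUE)]))
  })
  list(accuracy = mean(per_item),
       ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       per_item = per_item)
}

#' Median classification rank (lower is better)
#'
#' @param results List of [classify()] results with known ranks, or an
#'   integer vector of ranks.
#' @param n_boot Bootstrap replicates for the standard error (default
#'   1000).
#' @param seed Bootstrap seed.
#' @param compare Optional second set of results/ranks; when given a
#'   Mann-Whitney (Wilcoxon rank-sum) test compares the two.
#' @return List with `median`, `se` (bootstrap SE of the median), `ranks`,
#'   and optionally `p_value` of the comparison.
#' @export
median_rank <- function(results, n_boot = 1000L, seed = 1L,
                        compare = NULL) {
  as_ranks <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, function(r) as.numeric(r$rank_of_truth), numeric(1))
  }
  ranks <- as_ranks(results)
  vr_assert(length(ranks) >= 1 && all(is.finite(ranks)),
            "ranks must be known for all results")
  out <- with_seed(seed, {
    boots <- replicate(n_boot, stats::median(
      ranks[sample.int(length(ranks), replace = TRUE)]))
    list(median = stats::median(ranks), se = stats::sd(boots),
         ranks = ranks)
  })
  if (!is.null(compare)) {
    r2 <- as_ranks(compare)
    out$p_value <- suppressWarnings(
      stats::wilcox.test(ranks, r2)$p.value)
  }
  out
}
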