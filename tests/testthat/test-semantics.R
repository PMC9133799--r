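test_that("gallery centroids are embedding means", {
  bb <- tiny_backbone_spec()
  img <- rand_image(seed = 2)
  gal <- build_gallery(list(a = list(img)), bb, block = 3L)
  expect_equal(gal$centroids[, 1], embed_image(img, bb, 3L))
  ## duplicating every image leaves the centroid unchanged
  gal2 <- build_gallery(list(a = list(img, img, img)), bb, block = 3L,
                        seed = 4)
  expect_equal(gal2$centroids, gal$centroids)
  ## hand-specified embeddings: centroid of (1,0),(0,1),(1,1) is (2/3,2/3)
  gal3 <- build_gallery(list(z = list(c(1, 0), c(0, 1), c(1, 1))),
                        embedded = TRUE, n_per_class = 3L)
  expect_equal(gal3$centroids[, 1], c(2 / 3, 2 / 3))
  expect_error(build_gallery(list(a = list())), "no images")
})

## small embedded gallery used by several blocks below
embedded_gallery <- function(G = 12L, dim = 10L, seed = 3L) {
  cents <- with_seed(seed, matrix(rnorm(dim * G), dim, G))
  by_class <- lapply(seq_len(G), function(j) list(cents[, j]))
  names(by_class) <- sprintf("c%02d", seq_len(G))
  list(gallery = build_gallery(by_class, embedded = TRUE), cents = cents)
}

test_that("classification ranks by Pearson correlation, invariant to affine maps", {
  eg <- embedded_gallery()
  res <- classify(eg$cents[, 4], eg$gallery, true_class = "c04",
                  embedded = TRUE)
  expect_equal(res$rank_of_truth, 1L)
  expect_true(res$top1)
  expect_true(all(diff(res$scores) <= 1e-12))   # sorted non-increasing
  ## affine rescaling of the query embedding leaves ranking unchanged
  res2 <- classify(3.2 * eg$cents[, 4] + 1.7, eg$gallery,
                   true_class = "c04", embedded = TRUE)
  expect_identical(res2$ranked_ids, res$ranked_ids)
  expect_error(classify(eg$cents[, 1], eg$gallery, true_class = "nope",
                        embedded = TRUE), "not present")
})

test_that("null embeddings give uniform ranks (chi-square over seeded draws)", {
  eg <- embedded_gallery(G = 10L, dim = 40L)
  n_draws <- 1500L
  ranks <- with_seed(99, vapply(seq_len(n_draws), function(i) {
    q <- rnorm(40)
    classify(q, eg$gallery, true_class = "c01",
             embedded = TRUE)$rank_of_truth
  }, numeric(1)))
  tab <- tabulate(ranks, nbins = 10L)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("n-way classification hits 100% for perfect embeddings and 1/n under the null", {
  eg <- embedded_gallery(G = 25L, dim = 12L)
  perfect <- lapply(1:8, function(j) {
    classify(eg$cents[, j], eg$gallery,
             true_class = eg$gallery$class_ids[j], embedded = TRUE)
  })
  for (n in c(2, 10, 25)) {
    expect_equal(nway_classification(perfect, n = n, n_draws = 50,
                                     seed = 1)$accuracy, 1)
  }
  ## k = n: truth always within the candidate set
  expect_equal(nway_classification(perfect, n = 5, k = 5, n_draws = 20,
                                   seed = 2)$accuracy, 1)
  ## null: random query embeddings, top-1 accuracy about 1/n
  null_res <- with_seed(7, lapply(1:40, function(i) {
    classify(rnorm(12), eg$gallery, true_class = "c01", embedded = TRUE)
  }))
  for (n in c(2, 10)) {
    acc <- nway_classification(null_res, n = n, n_draws = 100, seed = 3)
    se <- sqrt((1 / n) * (1 - 1 / n) / 40)
    expect_lt(abs(acc$accuracy - 1 / n), 4 * se)
  }
  expect_error(nway_classification(perfect, n = 1), "at least 2")
})

test_that("full-gallery n-way agrees with the overall top-1 rate", {
  eg <- embedded_gallery(G = 8L, dim = 6L)
  res <- with_seed(5, lapply(1:12, function(i) {
    classify(rnorm(6), eg$gallery,
             true_class = sample(eg$gallery$class_ids, 1),
             embedded = TRUE)
  }))
  acc <- nway_classification(res, n = 8L, n_draws = 1, seed = 1)$accuracy
  top1 <- mean(vapply(res, function(r) r$rank_of_truth == 1L, logical(1)))
  expect_equal(acc, top1)
})

test_that("median rank summarizes and compares rank distributions", {
  expect_equal(median_rank(rep(1, 10))$median, 1)
  expect_equal(median_rank(c(1, 3, 5))$median, 3)
  ## uniform null over a 1030-class gallery has median near 515
  ranks <- with_seed(12, sample.int(1030, 200, replace = TRUE))
  mr <- median_rank(ranks)
  expect_lt(abs(mr$median - 515.5), 4 * mr$se + 1)
  cmp <- median_rank(ranks, compare = ranks + 200)
  expect_true(is.finite(cmp$p_value))
})
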