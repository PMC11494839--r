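# Stratified splitting and SMOTE oversampling.

make_label_manifest <- function(n_sdh, n_edh, px = 4) {
  # minimal records: tiny constant images so splitting logic is isolated
  recs <- c(
    lapply(seq_len(n_sdh), function(i) {
      structure(list(id = sprintf("s%03d", i), image = matrix(i / 999, px, px),
                     mask = matrix(0L, px, px), label = "SDH",
                     synthetic = FALSE), class = "sample_record")
    }),
    lapply(seq_len(n_edh), function(i) {
      structure(list(id = sprintf("e%03d", i), image = matrix(i / 999, px, px),
                     mask = matrix(0L, px, px), label = "EDH",
                     synthetic = FALSE), class = "sample_record")
    }))
  duralseg:::new_manifest(recs)
}

test_that("stratified split reproduces the published 56/173 dural counts", {
  m <- make_label_manifest(56, 173)
  sp <- stratified_split(m, test_fraction = 0.2, seed = 1)
  expect_equal(unname(sp$test$counts_by_class["SDH"]), 11)
  expect_equal(unname(sp$test$counts_by_class["EDH"]), 35)
  expect_equal(unname(sp$train$counts_by_class["SDH"]), 45)
  expect_equal(unname(sp$train$counts_by_class["EDH"]), 138)
  expect_length(sp$test$records, 46)
  # disjoint and exhaustive
  ids <- function(mm) vapply(mm$records, `[[`, character(1), "id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(m))
})

test_that("split is deterministic under a seed and handles fraction 0", {
  m <- make_label_manifest(9, 14)
  a <- stratified_split(m, 0.25, seed = 42)
  b <- stratified_split(m, 0.25, seed = 42)
  expect_identical(a, b)
  c <- stratified_split(m, 0.25, seed = 43)
  expect_false(identical(a, c))
  z <- stratified_split(m, 0, seed = 1)
  expect_length(z$test$records, 0)
  expect_length(z$train$records, 23)
})

test_that("nearest neighbors match a brute-force distance sort", {
  # collinear 1-pixel images: obvious nearest
  vecs <- list(0, 1, 10)
  expect_equal(nearest_neighbors(vecs, 1, 1), 2)
  # self-exclusion on every query
  set.seed(99)
  V <- matrix(rnorm(20 * 6), 20, 6)
  for (q in 1:20) {
    for (metric in c("euclidean", "cosine")) {
      nn <- nearest_neighbors(V, q, 3, metric)
      expect_false(q %in% nn)
      # brute-force oracle: full pairwise distances, sorted with index ties
      d <- if (metric == "euclidean") {
        sqrt(colSums((t(V) - V[q, ])^2))
      } else {
        1 - as.numeric(V %*% V[q, ]) /
          (sqrt(rowSums(V^2)) * sqrt(sum(V[q, ]^2)))
      }
      d[q] <- Inf
      expect_equal(nn, order(d)[1:3])
    }
  }
  expect_error(nearest_neighbors(V, 1, 20), "smaller")
  expect_error(nearest_neighbors(V, 1, 0), "k")
})

test_that("ties in the neighbor search break toward the lower index", {
  vecs <- list(c(0, 0), c(1, 0), c(0, 1), c(-1, 0))  # three ties at d = 1
  expect_equal(nearest_neighbors(vecs, 1, 3), c(2, 3, 4))
})

test_that("SMOTE reaches per-class targets with convex synthetic samples", {
  set.seed(10)
  d <- tiny_dataset(6, 9, seed = 31, size = 32)
  out <- smote_oversample(d, per_class_target = c(SDH = 14, EDH = 14),
                          k_neighbors = 3, seed = 5)
  labs <- vapply(out$records, `[[`, character(1), "label")
  expect_equal(sum(labs == "SDH"), 14)
  expect_equal(sum(labs == "EDH"), 14)
  # real records pass through unmodified, in order
  expect_identical(out$records[seq_along(d$records)], d$records)
  # convexity: every synthetic pixel within [min, max] of its two parents
  for (r in out$records[(length(d$records) + 1):length(out$records)]) {
    expect_true(isTRUE(r$synthetic))
    pa <- d$records[[r$parent_idx[1]]]$image
    pb <- d$records[[r$parent_idx[2]]]$image
    expect_true(all(r$image >= pmin(pa, pb) - 1e-12))
    expect_true(all(r$image <= pmax(pa, pb) + 1e-12))
    expect_true(all(r$mask %in% c(0, 1)))
  }
  # determinism
  out2 <- smote_oversample(d, per_class_target = c(SDH = 14, EDH = 14),
                           k_neighbors = 3, seed = 5)
  expect_identical(out, out2)
})

test_that("SMOTE no-op targets and degenerate parents behave as specified", {
  d <- tiny_dataset(4, 5, seed = 77, size = 32)
  noop <- smote_oversample(d, per_class_target = c(SDH = 4, EDH = 5),
                           k_neighbors = 2, seed = 1)
  expect_identical(noop$records, d$records)
  # two identical parents: the interpolation is the parent itself
  recs <- d$records[1:2]
  recs[[2]] <- recs[[1]]
  recs[[2]]$id <- "twin"
  m <- duralseg:::new_manifest(recs)
  out <- smote_oversample(m, per_class_target = c(SDH = 3), k_neighbors = 1,
                          seed = 2)
  syn <- out$records[[3]]
  expect_equal(syn$image, recs[[1]]$image)
  expect_equal(syn$mask, recs[[1]]$mask * 1L)
  # parameter validation
  expect_error(smote_oversample(d, per_class_target = c(SDH = 2)), "below")
  expect_error(smote_oversample(d, per_class_target = c(SDH = 9),
                                k_neighbors = 4), "k_neighbors")
})
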