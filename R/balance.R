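# Stratified train/test splitting and SMOTE oversampling of image samples.

#' Stratified train/test split of a dataset manifest
#'
#' Per class, `round(test_fraction * n)` records go to the test set via a
#' seeded permutation; train and test are disjoint and exhaustive.  For the
#' 56 SDH / 173 EDH dural collection at 20% this reproduces the published
#' split: train 45/138, test 11/35.
#'
#' @param manifest a `dataset_manifest` with labeled records.
#' @param test_fraction proportion held out per class, in \[0, 1) (default
#'   0.2).
#' @param seed integer seed for the permutation.
#' @return a list with `train` and `test` manifests.
#' @export
stratified_split <- function(manifest, test_fraction = 0.2, seed = NULL) {
  check_number(test_fraction, "test_fraction", lower = 0, upper = 0.999)
  labels <- vapply(manifest$records, `[[`, character(1), "label")
  if (any(is.na(labels) | labels == "")) {
    stop_param("every record must carry a class label")
  }
  if (any(table(labels) == 0)) stop_param("empty class in manifest")
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_test <- floor(test_fraction * length(idx) + 0.5)  # nearest integer
      perm <- sample(idx)
      test_idx <- c(test_idx, perm[seq_len(n_test)])
    }
  })
  is_test <- seq_along(labels) %in% test_idx
  train <- new_manifest(manifest$records[!is_test], split_tag = "train")
  test <- new_manifest(manifest$records[is_test], split_tag = "test")
  list(train = train, test = test)
}

#' k nearest neighbors among flattened pixel vectors
#'
#' Returns the indices of the `k` smallest distances to the query vector,
#' excluding the query itself, with ties broken by lower index.
#'
#' @param vectors a list of numeric vectors (flattened images) or a matrix
#'   with one row per sample.
#' @param query_index index of the query sample.
#' @param k number of neighbors, `0 < k < n`.
#' @param metric `"euclidean"` (default) or `"cosine"` (distance
#'   `1 - cosine similarity`).
#' @return integer vector of `k` neighbor indices, nearest first.
#' @export
nearest_neighbors <- function(vectors, query_index, k,
                              metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (is.list(vectors)) vectors <- do.call(rbind, lapply(vectors, as.numeric))
  n <- nrow(vectors)
  check_number(k, "k", lower = 1)
  if (k >= n) stop_param("`k` must be smaller than the number of vectors")
  q <- vectors[query_index, ]
  d <- if (metric == "euclidean") {
    sqrt(rowSums(sweep(vectors, 2, q)^2))
  } else {
    qn <- sqrt(sum(q^2))
    vn <- sqrt(rowSums(vectors^2))
    sim <- as.numeric(vectors %*% q) / pmax(vn * qn, .Machine$double.eps)
    1 - sim
  }
  d[query_index] <- Inf
  order(d, seq_len(n))[seq_len(k)]   # ties -> lower index first
}

#' SMOTE oversampling of an image dataset
#'
#' Brings every class up to a common per-class target count by synthesizing
#' new samples on the segment between a seeded-random real sample and one of
#' its `k` nearest same-class neighbors (distances on flattened pixel
#' vectors): `x_new = x_i + u * (x_nn - x_i)`, `u ~ Uniform(0, 1)`.  The
#' paired mask is interpolated with the same `u` and thresholded at 0.5 back
#' to binary, preserving spatial correspondence.  Real records pass through
#' unmodified; synthetic records are flagged `synthetic = TRUE`.
#'
#' @param train a `dataset_manifest` of preprocessed, same-size images.
#' @param per_class_target named vector of target counts per class, each >=
#'   the class's current count (default: every class raised to the largest
#'   class's current count; the published dural pipeline raises both classes
#'   to 414 = 3 x 138, so pass that explicitly to reproduce it).
#' @param k_neighbors number of candidate neighbors (default 5, the
#'   classical SMOTE setting); must be smaller than each oversampled class.
#' @param metric neighbor metric, `"euclidean"` or `"cosine"`.
#' @param seed integer seed.
#' @return a `dataset_manifest` with exactly `per_class_target` records per
#'   class; synthetic records carry their parent record indices/ids and the
#'   interpolation weight `u` as provenance.
#' @export
smote_oversample <- function(train, per_class_target = NULL, k_neighbors = 5,
                             metric = c("euclidean", "cosine"), seed = NULL) {
  metric <- match.arg(metric)
  labels <- vapply(train$records, `[[`, character(1), "label")
  counts <- table(labels)
  if (is.null(per_class_target)) {
    per_class_target <- stats::setNames(rep(max(counts), length(counts)),
                                        names(counts))
  }
  for (cl in names(per_class_target)) {
    cur <- sum(labels == cl)
    if (per_class_target[[cl]] < cur) {
      stop_param(sprintf("target for class %s (%d) below current count (%d)",
                         cl, per_class_target[[cl]], cur))
    }
    if (per_class_target[[cl]] > cur && k_neighbors >= cur) {
      stop_param(sprintf("k_neighbors = %d must be < class %s size (%d)",
                         k_neighbors, cl, cur))
    }
  }
  dims <- lapply(train$records, function(r) dim(r$image))
  if (length(unique(dims)) > 1L) {
    stop_param("all images must share the same shape before SMOTE")
  }

  synth <- list()
  with_seed(seed, {
    for (cl in names(per_class_target)) {
      idx <- which(labels == cl)
      need <- per_class_target[[cl]] - length(idx)
      if (need <= 0) next
      vecs <- do.call(rbind, lapply(train$records[idx],
                                    function(r) as.numeric(r$image)))
      nn <- lapply(seq_along(idx), function(i) {
        nearest_neighbors(vecs, i, min(k_neighbors, length(idx) - 1), metric)
      })
      for (s in seq_len(need)) {
        i <- sample.int(length(idx), 1)
        j <- nn[[i]][sample.int(length(nn[[i]]), 1)]
        u <- runif(1)
        r_i <- train$records[[idx[i]]]
        r_j <- train$records[[idx[j]]]
        img <- r_i$image + u * (r_j$image - r_i$image)
        rec <- r_i
        rec$image <- img
        if (!is.null(r_i$mask)) {
          mm <- r_i$mask + u * (r_j$mask - r_i$mask)
          rec$mask <- (mm >= 0.5) * 1L
        }
        rec$id <- sprintf("%s_syn_%04d", tolower(cl), s)
        rec$synthetic <- TRUE
        rec$parents <- c(r_i$id %||% NA_character_, r_j$id %||% NA_character_)
        rec$parent_idx <- c(idx[i], idx[j])
        rec$u <- u
        synth[[length(synth) + 1L]] <- rec
      }
    }
  })
  new_manifest(c(train$records, synth), split_tag = train$split_tag)
}
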