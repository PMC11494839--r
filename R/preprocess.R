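# CT preprocessing stack: resize -> CLAHE -> gamma -> [0,1] normalization.
# The enhancement steps (CLAHE, gamma) are applied to training data only;
# test images are only resized and normalized.

# Bilinear resampling with half-pixel centers (the convention used by the
# common imaging libraries).  Exact identity when target equals input size.
bilinear_resize <- function(img, target) {
  h_in <- nrow(img); w_in <- ncol(img)
  h_out <- target[1]; w_out <- target[2]
  if (h_out == h_in && w_out == w_in) return(img)
  src <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  sy <- src(h_out, h_in); sx <- src(w_out, w_in)
  y0 <- pmin(floor(sy), h_in - 1); y1 <- pmin(y0 + 1, h_in - 1)
  x0 <- pmin(floor(sx), w_in - 1); x1 <- pmin(x0 + 1, w_in - 1)
  wy <- sy - y0; wx <- sx - x0
  # gather four corners with outer weights
  a <- img[y0 + 1, x0 + 1, drop = FALSE]
  b <- img[y1 + 1, x0 + 1, drop = FALSE]
  c_ <- img[y0 + 1, x1 + 1, drop = FALSE]
  d <- img[y1 + 1, x1 + 1, drop = FALSE]
  wym <- matrix(wy, h_out, w_out)
  wxm <- matrix(wx, h_out, w_out, byrow = TRUE)
  a * (1 - wym) * (1 - wxm) + b * wym * (1 - wxm) +
    c_ * (1 - wym) * wxm + d * wym * wxm
}

nearest_resize <- function(img, target) {
  h_in <- nrow(img); w_in <- ncol(img)
  h_out <- target[1]; w_out <- target[2]
  if (h_out == h_in && w_out == w_in) return(img)
  sy <- pmin(pmax(floor((seq_len(h_out) - 0.5) * h_in / h_out), 0), h_in - 1)
  sx <- pmin(pmax(floor((seq_len(w_out) - 0.5) * w_in / w_out), 0), w_in - 1)
  img[sy + 1, sx + 1, drop = FALSE]
}

#' Resize a grayscale image
#'
#' Bilinear resampling for intensity images; use `method = "nearest"` for
#' masks so they stay binary.
#'
#' @param img numeric matrix.
#' @param target integer vector `(height, width)`, both >= 8.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return a matrix of the requested size.
#' @export
resize <- function(img, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (length(target) != 2L || any(target < 8)) {
    stop_param("`target` must be (height, width), both >= 8")
  }
  target <- as.integer(target)
  if (method == "bilinear") bilinear_resize(img, target)
  else nearest_resize(img, target)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization on 256 gray bins with the per-tile
#' histogram clipped at `clip_limit` times the mean bin count; the clipped
#' excess is redistributed uniformly over all bins, and per-pixel mappings
#' are blended bilinearly between the four nearest tile mappings, so block
#' seams are smooth.  Output stays in \[0, 1\].
#'
#' @param img matrix with values in \[0, 1\].
#' @param clip_limit clip factor > 0 (default 2): a tile histogram bin may
#'   hold at most `clip_limit * n_tile_pixels / n_bins` counts.
#' @param tile_grid integer `(rows, cols)` of the tile grid (default 8x8).
#' @param n_bins number of gray bins (default 256).
#' @return an equalized matrix in \[0, 1\].
#' @export
clahe <- function(img, clip_limit = 2, tile_grid = c(8, 8), n_bins = 256) {
  check_number(clip_limit, "clip_limit", lower = 0, strict_lower = TRUE)
  if (any(img < 0) || any(img > 1)) {
    stop_param("`img` must be in [0, 1] for clahe()")
  }
  tg <- as.integer(tile_grid)
  h <- nrow(img); w <- ncol(img)
  if (tg[1] > h || tg[2] > w) {
    stop_param("tile_grid larger than the image")
  }
  bins <- pmin(pmax(floor(img * n_bins), 0), n_bins - 1)  # 0-based bin index

  # tile boundaries (near-equal partition) and per-tile clipped-CDF mapping
  rb <- floor(seq(0, h, length.out = tg[1] + 1))
  cb <- floor(seq(0, w, length.out = tg[2] + 1))
  maps <- array(0, dim = c(tg[1], tg[2], n_bins))
  centers_r <- numeric(tg[1]); centers_c <- numeric(tg[2])
  for (i in seq_len(tg[1])) {
    for (j in seq_len(tg[2])) {
      rows <- (rb[i] + 1):rb[i + 1]
      cols <- (cb[j] + 1):cb[j + 1]
      tb <- bins[rows, cols]
      np <- length(tb)
      hist <- tabulate(tb + 1L, nbins = n_bins)
      clip <- max(1, clip_limit * np / n_bins)
      excess <- sum(pmax(hist - clip, 0))
      hist <- pmin(hist, clip) + excess / n_bins
      maps[i, j, ] <- cumsum(hist) / np
      centers_r[i] <- (rb[i] + rb[i + 1] + 1) / 2
      centers_c[j] <- (cb[j] + cb[j + 1] + 1) / 2
    }
  }

  # bilinear blend of the four surrounding tile mappings, clamped at borders
  ri <- findInterval(seq_len(h), centers_r)          # tile index below
  ci <- findInterval(seq_len(w), centers_c)
  r0 <- pmin(pmax(ri, 1L), tg[1]); r1 <- pmin(r0 + 1L, tg[1])
  c0 <- pmin(pmax(ci, 1L), tg[2]); c1 <- pmin(c0 + 1L, tg[2])
  fr <- ifelse(r1 > r0,
               (seq_len(h) - centers_r[r0]) / (centers_r[r1] - centers_r[r0]),
               0)
  fr <- pmin(pmax(fr, 0), 1)
  fc <- ifelse(c1 > c0,
               (seq_len(w) - centers_c[c0]) / (centers_c[c1] - centers_c[c0]),
               0)
  fc <- pmin(pmax(fc, 0), 1)

  out <- matrix(0, h, w)
  idx_bin <- bins + 1L
  lookup <- function(ti, tj) {
    m <- matrix(maps[cbind(rep(ti, times = w), rep(tj, each = h),
                           as.vector(idx_bin))], h, w)
    m
  }
  m00 <- lookup(r0, c0); m10 <- lookup(r1, c0)
  m01 <- lookup(r0, c1); m11 <- lookup(r1, c1)
  frm <- matrix(fr, h, w); fcm <- matrix(fc, h, w, byrow = TRUE)
  out <- m00 * (1 - frm) * (1 - fcm) + m10 * frm * (1 - fcm) +
    m01 * (1 - frm) * fcm + m11 * frm * fcm
  pmax(pmin(out, 1), 0)
}

#' Gamma correction
#'
#' Elementwise power-law remapping `out = img^gamma` on the \[0,1\] scale.
#' `gamma < 1` brightens shadows, `gamma > 1` darkens; `gamma = 1` is the
#' identity.  Strictly monotone for any fixed `gamma > 0`.
#'
#' @param img matrix with values in \[0, 1\].
#' @param gamma exponent > 0.
#' @return the remapped matrix.
#' @export
gamma_correct <- function(img, gamma) {
  check_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  if (any(img < 0) || any(img > 1)) {
    stop_param("`img` must be in [0, 1] for gamma_correct()")
  }
  img^gamma
}

#' Normalize an image to \[0, 1\]
#'
#' Affine map of a declared value range onto \[0, 1\].  A degenerate range
#' (`hi == lo`) maps everything to 0 rather than erroring.
#'
#' @param img numeric matrix.
#' @param value_range declared `(lo, hi)` of the input; defaults to
#'   `c(0, 255)` for integer-valued input outside \[0,1\], else `c(0, 1)`.
#' @return a matrix in \[0, 1\].
#' @export
normalize <- function(img, value_range = NULL) {
  if (is.null(value_range)) {
    value_range <- if (max(img) > 1 || min(img) < 0) c(0, 255) else c(0, 1)
  }
  lo <- value_range[1]; hi <- value_range[2]
  if (hi == lo) return(matrix(0, nrow(img), ncol(img)))
  out <- (img - lo) / (hi - lo)
  pmax(pmin(out, 1), 0)
}

#' Preprocessing configuration
#'
#' @param target_size `(height, width)` the pipeline resizes to (default
#'   `c(256, 256)`).
#' @param clahe_clip_limit CLAHE clip factor (default 2).
#' @param clahe_tile_grid CLAHE tile grid `(rows, cols)` (default 8x8).
#' @param gamma gamma-correction exponent (default 0.8, mildly brightening
#'   dark parenchyma).
#' @param apply_enhancement `TRUE` for the training path (resize -> CLAHE ->
#'   gamma -> normalize), `FALSE` for the test path (resize -> normalize
#'   only).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = c(256, 256), clahe_clip_limit = 2,
                              clahe_tile_grid = c(8, 8), gamma = 0.8,
                              apply_enhancement = TRUE) {
  if (length(target_size) != 2L || any(target_size < 8)) {
    stop_param("`target_size` components must be >= 8")
  }
  check_number(clahe_clip_limit, "clahe_clip_limit", lower = 0,
               strict_lower = TRUE)
  check_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  structure(list(target_size = as.integer(target_size),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 gamma = gamma,
                 apply_enhancement = isTRUE(apply_enhancement)),
            class = "preprocess_config")
}

#' Preprocess one sample record
#'
#' Training path (`apply_enhancement = TRUE`): resize -> CLAHE -> gamma ->
#' normalize.  Test path: resize -> normalize.  The paired mask, when
#' present, is resized with nearest-neighbor so it stays strictly binary.
#'
#' @param rec a `sample_record` (image, optional mask, label).
#' @param cfg a [preprocess_config()].
#' @param require_mask error if the record lacks a mask (default `TRUE`,
#'   since segmentation needs one).
#' @return the preprocessed record.
#' @export
preprocess_record <- function(rec, cfg = preprocess_config(),
                              require_mask = TRUE) {
  if (require_mask && is.null(rec$mask)) {
    stop_param(sprintf("record %s has no mask", rec$id %||% "<unnamed>"))
  }
  # bilinear resampling commutes exactly with the affine [0,1] normalization,
  # so normalizing directly after the resize matches the stated stage order
  img <- resize(rec$image, cfg$target_size, method = "bilinear")
  img <- normalize(img, value_range = rec$value_range)
  if (cfg$apply_enhancement) {
    tg <- pmin(cfg$clahe_tile_grid, cfg$target_size)
    img <- clahe(img, cfg$clahe_clip_limit, tg)
    img <- gamma_correct(img, cfg$gamma)
  }
  rec$image <- img
  if (!is.null(rec$mask)) {
    m <- resize(rec$mask, cfg$target_size, method = "nearest")
    rec$mask <- (m >= 0.5) * 1L
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess every record of a dataset manifest
#'
#' @param manifest a `dataset_manifest`.
#' @inheritParams preprocess_record
#' @return the manifest with all records preprocessed.
#' @export
preprocess_dataset <- function(manifest, cfg = preprocess_config(),
                               require_mask = TRUE) {
  manifest$records <- lapply(manifest$records, preprocess_record, cfg = cfg,
                             require_mask = require_mask)
  manifest
}
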