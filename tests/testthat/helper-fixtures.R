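# Shared fixtures and independent oracles for the test suite.

# Convex-hull area of a binary mask, measured as the number of pixel centers
# lying inside (or on) the hull polygon of the foreground pixel centers.
# Brute-force point-in-polygon; independent of any package geometry code.
hull_pixel_area <- function(mask) {
  pts <- which(mask == 1, arr.ind = TRUE)
  if (nrow(pts) < 3) return(nrow(pts))
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]
  hy <- pts[h, 2]
  n <- length(h)
  all_pts <- which(mask >= 0, arr.ind = TRUE)   # every pixel center
  lo <- rep(Inf, nrow(all_pts))
  hi <- rep(-Inf, nrow(all_pts))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    ex <- hx[k2] - hx[k]
    ey <- hy[k2] - hy[k]
    cross <- ex * (all_pts[, 2] - hy[k]) - ey * (all_pts[, 1] - hx[k])
    lo <- pmin(lo, cross)
    hi <- pmax(hi, cross)
  }
  # inside the hull iff on one side of every edge (either orientation)
  sum(hi <= 1e-9 | lo >= -1e-9)
}

hull_ratio <- function(mask) hull_pixel_area(mask) / sum(mask)

tiny_phantom <- function(seed, size = 64) {
  phantom_params(image_size = size, seed = seed)
}

tiny_model <- function(seed = 1, base = 2) {
  build_model(model_config(base_filters = base, se_reduction = 2,
                           cls_channels = c(3, 2)), seed = seed)
}

# small preprocessed phantom manifest for training tests
tiny_dataset <- function(n_sdh, n_edh, seed, size = 64) {
  d <- generate_dataset(n_sdh, n_edh, tiny_phantom(seed, size))
  preprocess_dataset(d, preprocess_config(target_size = c(size, size)))
}
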