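#' Parameters for the synthetic head-CT phantom generator
#'
#' The phantom emulates the structure of an axial head-CT slice with a dural
#' hemorrhage: a bright elliptical skull ring, a textured brain interior, a
#' hyperdense peripheral lesion hugging the inner skull table -- a thin
#' crescent for subdural (SDH), a biconvex lens for epidural (EDH) -- plus
#' additive noise, with a pixel-accurate ground-truth mask.
#'
#' Relative intensities follow the qualitative Hounsfield ordering of CT
#' (skull ~0.95 > fresh blood ~0.7 > brain ~0.4 > air ~0.05 on a \[0,1\]
#' scale); absolute HU are not modeled.
#'
#' @param image_size pixels per side of the square slice (default 256).
#' @param skull_thickness skull-ring thickness in pixels (default 5% of the
#'   image size, at least 3).
#' @param lesion_area_fraction target lesion area as a fraction of the brain
#'   interior area, in \[0, 0.2\] (default 0.05; 0 means no lesion).
#' @param sdh_arc_span angular span of the subdural crescent in degrees
#'   (default 120).
#' @param edh_lens_eccentricity epidural lens shape factor: thickness over
#'   half-chord, in (0, 2\] (default 0.7; larger = plumper lens).
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   \[0,1\] intensity scale (default 0.03; truncated at 3 sigma so tissue
#'   intensity bands stay ordered).
#' @param seed integer seed making every slice reproducible; `NULL` uses the
#'   current RNG state.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(image_size = 256, skull_thickness = NULL,
                           lesion_area_fraction = 0.05, sdh_arc_span = 120,
                           edh_lens_eccentricity = 0.7, noise_sigma = 0.03,
                           seed = NULL) {
  check_number(image_size, "image_size", lower = 32)
  if (is.null(skull_thickness)) {
    skull_thickness <- max(3, round(0.05 * image_size))
  }
  check_number(skull_thickness, "skull_thickness", lower = 1)
  check_number(lesion_area_fraction, "lesion_area_fraction", lower = 0,
               upper = 0.2)
  check_number(sdh_arc_span, "sdh_arc_span", lower = 10, upper = 270)
  check_number(edh_lens_eccentricity, "edh_lens_eccentricity", lower = 0,
               upper = 2, strict_lower = TRUE)
  check_number(noise_sigma, "noise_sigma", lower = 0, upper = 0.2)
  structure(list(image_size = as.integer(image_size),
                 skull_thickness = skull_thickness,
                 lesion_area_fraction = lesion_area_fraction,
                 sdh_arc_span = sdh_arc_span,
                 edh_lens_eccentricity = edh_lens_eccentricity,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_params")
}

# Intensity bands of the phantom tissue model.
PHANTOM_LEVELS <- list(background = 0.05, brain = 0.40, lesion = 0.70,
                       skull = 0.95, texture_amp = 0.05)

#' Generate one synthetic head-CT slice with a dural lesion
#'
#' @param class_label `"SDH"` (crescent-shaped lesion along the inner skull)
#'   or `"EDH"` (biconvex lens abutting the inner skull).
#' @param params a [phantom_params()].
#' @return a `sample_record` list with elements `image` (matrix in \[0,1\]),
#'   `mask` (0/1 matrix), `label`, `synthetic = TRUE`.
#' @details Identical `params` (including `seed`) give bit-identical output.
#'   The SDH crescent is non-convex (its convex hull is noticeably larger
#'   than the lesion); the EDH lens is convex up to the pixel grid.  Lesions
#'   never extend onto or beyond the skull ring.
#' @export
generate_slice <- function(class_label, params = phantom_params()) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% c("SDH", "EDH")) {
    stop_param("`class_label` must be \"SDH\" or \"EDH\"")
  }
  with_seed(params$seed, generate_slice_impl(class_label, params))
}

generate_slice_impl <- function(class_label, params) {
  n <- params$image_size
  cx <- (n + 1) / 2 + runif(1, -0.02, 0.02) * n
  cy <- (n + 1) / 2 + runif(1, -0.02, 0.02) * n
  a <- 0.44 * n * runif(1, 0.95, 1.05)   # horizontal semi-axis (cols)
  b <- 0.38 * n * runif(1, 0.95, 1.05)   # vertical semi-axis (rows)

  row <- matrix(seq_len(n), n, n)        # row = y, col = x
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  rho <- sqrt(((col - cx) / a)^2 + ((row - cy) / b)^2)
  rho_in <- 1 - params$skull_thickness / min(a, b)
  if (rho_in <= 0.2) {
    stop_param("degenerate geometry: skull_thickness leaves no brain interior")
  }
  interior <- rho < rho_in
  skull <- rho >= rho_in & rho <= 1

  # low-frequency parenchymal texture: coarse Gaussian grid, bilinearly
  # upsampled to the slice
  gsize <- max(4L, n %/% 16L)
  grid <- matrix(rnorm(gsize * gsize), gsize, gsize)
  texture <- bilinear_resize(grid, c(n, n))
  texture <- pmax(pmin(texture, 2), -2)

  theta0 <- runif(1, -pi, pi)
  frac <- params$lesion_area_fraction * runif(1, 0.7, 1.3)
  frac <- min(frac, 0.2)
  target <- frac * sum(interior)

  mask <- if (target < 1) {
    matrix(0L, n, n)
  } else if (class_label == "SDH") {
    sdh_crescent(rho, row, col, cx, cy, rho_in, theta0,
                 params$sdh_arc_span * runif(1, 0.85, 1.15), target, interior)
  } else {
    edh_lens(row, col, cx, cy, a, b, rho_in, theta0,
             params$edh_lens_eccentricity, target, interior)
  }

  lv <- PHANTOM_LEVELS
  img <- matrix(lv$background, n, n)
  img[interior] <- lv$brain + lv$texture_amp * texture[interior]
  img[skull] <- lv$skull
  img[mask == 1L] <- lv$lesion
  if (params$noise_sigma > 0) {
    noise <- rnorm(n * n)
    noise <- pmax(pmin(noise, 3), -3) * params$noise_sigma
    img <- img + matrix(noise, n, n)
  }
  img <- pmax(pmin(img, 1), 0)

  structure(list(image = img, mask = mask, label = class_label,
                 synthetic = TRUE),
            class = "sample_record")
}

# Crescent: annular sector under the inner skull table, thickness tapering
# cosine-like toward the arc ends so the ends come to points.
sdh_crescent <- function(rho, row, col, cx, cy, rho_in, theta0, span_deg,
                         target, interior) {
  theta <- atan2(row - cy, col - cx)
  dtheta <- abs(atan2(sin(theta - theta0), cos(theta - theta0)))
  half <- (span_deg / 2) * pi / 180
  taper <- ifelse(dtheta < half, cos(dtheta / half * pi / 2), 0)
  area_at <- function(d) {
    m <- interior & taper > 0 & rho >= (rho_in - d * taper)
    sum(m)
  }
  d <- bisect_area(area_at, target, d_max = rho_in - 0.05)
  m <- interior & taper > 0 & rho >= (rho_in - d * taper)
  out <- matrix(0L, nrow(rho), ncol(rho))
  out[m] <- 1L
  out
}

# Biconvex lens: intersection of two discs whose axis points inward from a
# point on the inner skull table; convex by construction, clipped to the
# brain interior.
edh_lens <- function(row, col, cx, cy, a, b, rho_in, theta0, shape, target,
                     interior) {
  px <- cx + a * rho_in * cos(theta0)
  py <- cy + b * rho_in * sin(theta0)
  ux <- cx - px
  uy <- cy - py
  nu <- sqrt(ux^2 + uy^2)
  ux <- ux / nu
  uy <- uy / nu
  area_at <- function(L) {
    w <- shape * L                      # lens thickness along the axis
    R <- L^2 / w + w / 4               # disc radius through both lens edges
    e <- R - w / 2
    mx <- px + ux * (w / 2 + 1)        # lens center, 1 px inside the table
    my <- py + uy * (w / 2 + 1)
    c1x <- mx - ux * e; c1y <- my - uy * e
    c2x <- mx + ux * e; c2y <- my + uy * e
    m <- interior &
      ((col - c1x)^2 + (row - c1y)^2 <= R^2) &
      ((col - c2x)^2 + (row - c2y)^2 <= R^2)
    m
  }
  L <- bisect_area(function(L) sum(area_at(L)), target, d_max = nu * 0.9)
  m <- area_at(L)
  out <- matrix(0L, nrow(row), ncol(row))
  out[m] <- 1L
  out
}

# Monotone bisection of f (pixel area as a function of a size parameter)
# toward `target`; errors if even the largest admissible size cannot reach
# half the target (the lesion cannot fit).
bisect_area <- function(f, target, d_max, iters = 30) {
  if (f(d_max) < target / 2) {
    stop_param("degenerate geometry: lesion of requested size cannot fit")
  }
  lo <- 0
  hi <- d_max
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' Generate a labeled phantom dataset
#'
#' Emulates the class structure of a dural-hemorrhage CT collection (for the
#' published collection this is 56 SDH and 173 EDH slices).  Every slice gets
#' an id, and per-slice seeds are derived from `params$seed`, so equal
#' `(seed, params)` give byte-identical datasets.
#'
#' @param n_sdh,n_edh number of SDH / EDH slices (>= 0).
#' @param params a [phantom_params()]; `params$seed` drives all randomness.
#' @param out_dir optional directory; when given, images and masks are
#'   written as 8-bit grayscale PNGs under `images/` and `masks/` plus a
#'   `manifest.csv` (columns id, label, split, synthetic).
#' @return a `dataset_manifest`: list with `records`, `counts_by_class`,
#'   `split_tag`.
#' @export
generate_dataset <- function(n_sdh, n_edh, params = phantom_params(),
                             out_dir = NULL) {
  check_number(n_sdh, "n_sdh", lower = 0)
  check_number(n_edh, "n_edh", lower = 0)
  labels <- c(rep("SDH", n_sdh), rep("EDH", n_edh))
  ids <- c(sprintf("sdh_%03d", seq_len(n_sdh)),
           sprintf("edh_%03d", seq_len(n_edh)))
  records <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    p <- params
    p$seed <- derive_seed(if (is.null(params$seed)) 0L else params$seed,
                          ids[i])
    rec <- generate_slice(labels[i], p)
    rec$id <- ids[i]
    records[[i]] <- rec
  }
  manifest <- new_manifest(records, split_tag = "unsplit")
  if (!is.null(out_dir)) save_dataset(manifest, out_dir)
  manifest
}

new_manifest <- function(records, split_tag = "unsplit") {
  counts <- table(factor(vapply(records, `[[`, character(1), "label"),
                         levels = c("SDH", "EDH")))
  structure(list(records = records,
                 counts_by_class = c(SDH = unname(counts["SDH"]),
                                     EDH = unname(counts["EDH"])),
                 split_tag = split_tag),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d records (%s): SDH %d, EDH %d\n",
              length(x$records), x$split_tag, x$counts_by_class[["SDH"]],
              x$counts_by_class[["EDH"]]))
  invisible(x)
}
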