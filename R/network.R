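# The spatial-attention CSR-Unet: four encoder stages of double
# Conv-BN-ReLU, each with a CSR (convolution + squeeze-excitation +
# residual-skip) block on its skip path, a bottleneck with a full
# pre-activation residual unit, four decoder stages with transposed-conv
# upsampling and spatial-attention-gated fusion, a 1x1-conv sigmoid
# segmentation head, and a CBL classification branch off the bottleneck.

## ------- composite blocks (internal fwd/bwd) -------

cbr_init <- function(cin, cout, kernel = 3) {
  list(conv = init_conv(kernel, kernel, cin, cout), bn = init_bn(cout))
}

cbr_fwd <- function(x, p, s, training) {
  c1 <- conv_fwd(x, p$conv$W, p$conv$b)
  b1 <- bn_fwd(c1$y, p$bn$g, p$bn$b, s$rm, s$rv, training)
  r1 <- relu_fwd(b1$y)
  list(y = r1$y, state = list(rm = b1$rm, rv = b1$rv),
       cache = list(c = c1$cache, b = b1$cache, r = r1$cache))
}

cbr_bwd <- function(dy, cache) {
  d1 <- relu_bwd(dy, cache$r)
  d2 <- bn_bwd(d1, cache$b)
  d3 <- conv_bwd(d2$dx, cache$c)
  list(dx = d3$dx,
       grads = list(conv = list(W = d3$dW, b = d3$db),
                    bn = list(g = d2$dgamma, b = d2$dbeta)))
}

se_init <- function(c, reduction) {
  cr <- max(1L, c %/% reduction)
  list(fc1 = init_dense(c, cr), fc2 = init_dense(cr, c))
}

se_fwd <- function(x, p) {
  g1 <- gap_fwd(x)
  d1 <- dense_fwd(g1$y, p$fc1$W, p$fc1$b)
  r1 <- relu_fwd(d1$y)
  d2 <- dense_fwd(r1$y, p$fc2$W, p$fc2$b)
  g <- sigmoid_(d2$y)
  list(y = scale_channels(x, g), gates = g,
       cache = list(x = x, g = g, g1 = g1$cache, d1 = d1$cache,
                    r1 = r1$cache, d2 = d2$cache))
}

se_bwd <- function(dy, cache) {
  dg <- scale_channels_grad(dy, cache$x)
  dx <- scale_channels(dy, cache$g)
  dz2 <- dg * cache$g * (1 - cache$g)
  b2 <- dense_bwd(dz2, cache$d2)
  dr <- relu_bwd(b2$dx, cache$r1)
  b1 <- dense_bwd(dr, cache$d1)
  dx <- dx + gap_bwd(b1$dx, cache$g1)
  list(dx = dx, grads = list(fc1 = list(W = b1$dW, b = b1$db),
                             fc2 = list(W = b2$dW, b = b2$db)))
}

res_init <- function(cin, cout = cin) {
  p <- list(bn1 = init_bn(cin), c1 = init_conv(3, 3, cin, cout),
            bn2 = init_bn(cout), c2 = init_conv(3, 3, cout, cout))
  if (cin != cout) {
    p$proj <- init_conv(1, 1, cin, cout)
    p$projbn <- init_bn(cout)
  }
  p
}

res_state <- function(cin, cout = cin) {
  s <- list(bn1 = init_bn_state(cin), bn2 = init_bn_state(cout))
  if (cin != cout) s$projbn <- init_bn_state(cout)
  s
}

res_fwd <- function(x, p, s, training) {
  b1 <- bn_fwd(x, p$bn1$g, p$bn1$b, s$bn1$rm, s$bn1$rv, training)
  r1 <- relu_fwd(b1$y)
  c1 <- conv_fwd(r1$y, p$c1$W, p$c1$b)
  b2 <- bn_fwd(c1$y, p$bn2$g, p$bn2$b, s$bn2$rm, s$bn2$rv, training)
  r2 <- relu_fwd(b2$y)
  c2 <- conv_fwd(r2$y, p$c2$W, p$c2$b)
  cache <- list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache, b2 = b2$cache,
                r2 = r2$cache, c2 = c2$cache, has_proj = !is.null(p$proj))
  state <- list(bn1 = list(rm = b1$rm, rv = b1$rv),
                bn2 = list(rm = b2$rm, rv = b2$rv))
  if (is.null(p$proj)) {
    shortcut <- x
  } else {
    pc <- conv_fwd(x, p$proj$W, p$proj$b)
    pb <- bn_fwd(pc$y, p$projbn$g, p$projbn$b, s$projbn$rm, s$projbn$rv,
                 training)
    shortcut <- pb$y
    cache$pc <- pc$cache
    cache$pb <- pb$cache
    state$projbn <- list(rm = pb$rm, rv = pb$rv)
  }
  list(y = shortcut + c2$y, state = state, cache = cache)
}

res_bwd <- function(dy, cache) {
  d_c2 <- conv_bwd(dy, cache$c2)
  d_r2 <- relu_bwd(d_c2$dx, cache$r2)
  d_b2 <- bn_bwd(d_r2, cache$b2)
  d_c1 <- conv_bwd(d_b2$dx, cache$c1)
  d_r1 <- relu_bwd(d_c1$dx, cache$r1)
  d_b1 <- bn_bwd(d_r1, cache$b1)
  grads <- list(bn1 = list(g = d_b1$dgamma, b = d_b1$dbeta),
                c1 = list(W = d_c1$dW, b = d_c1$db),
                bn2 = list(g = d_b2$dgamma, b = d_b2$dbeta),
                c2 = list(W = d_c2$dW, b = d_c2$db))
  if (cache$has_proj) {
    d_pb <- bn_bwd(dy, cache$pb)
    d_pc <- conv_bwd(d_pb$dx, cache$pc)
    grads$proj <- list(W = d_pc$dW, b = d_pc$db)
    grads$projbn <- list(g = d_pb$dgamma, b = d_pb$dbeta)
    dx <- d_b1$dx + d_pc$dx
  } else {
    dx <- d_b1$dx + dy
  }
  list(dx = dx, grads = grads)
}

csr_init <- function(cin, cout, reduction) {
  p <- list(cbr = cbr_init(cin, cout), se = se_init(cout, reduction))
  if (cin != cout) p$proj <- init_conv(1, 1, cin, cout)
  p
}

csr_fwd <- function(x, p, s, training) {
  cb <- cbr_fwd(x, p$cbr, s$cbr, training)
  se <- se_fwd(cb$y, p$se)
  cache <- list(cbr = cb$cache, se = se$cache, has_proj = !is.null(p$proj))
  if (is.null(p$proj)) {
    shortcut <- x
  } else {
    pc <- conv_fwd(x, p$proj$W, p$proj$b)
    shortcut <- pc$y
    cache$pc <- pc$cache
  }
  list(y = se$y + shortcut, state = list(cbr = cb$state), cache = cache)
}

csr_bwd <- function(dy, cache) {
  d_se <- se_bwd(dy, cache$se)
  d_cb <- cbr_bwd(d_se$dx, cache$cbr)
  grads <- list(cbr = d_cb$grads, se = d_se$grads)
  if (cache$has_proj) {
    d_pc <- conv_bwd(dy, cache$pc)
    grads$proj <- list(W = d_pc$dW, b = d_pc$db)
    dx <- d_cb$dx + d_pc$dx
  } else {
    dx <- d_cb$dx + dy
  }
  list(dx = dx, grads = grads)
}

sa_init <- function(kernel = 7) {
  p <- init_conv(kernel, kernel, 2, 1)
  # start near-neutral: small weights give attention maps near 0.5
  p$W <- p$W * 0.1
  p
}

broadcast_map <- function(a, d) {
  # a: (H, W, 1, N) -> (H, W, C, N), replicated across channels
  av <- matrix(a, nrow = d[1] * d[2])        # (HW, N)
  out <- av[, rep(seq_len(d[4]), each = d[3]), drop = FALSE]
  dim(out) <- d
  out
}

sum_channels <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dim(x) <- c(HW, C, N)
  out <- array(0, c(d[1], d[2], 1L, N))
  for (n in seq_len(N)) out[, , 1L, n] <- rowSums(x[, , n])
  out
}

sa_fwd <- function(x, p) {
  cs <- chan_stats_fwd(x)
  cv <- conv_fwd(cs$y, p$W, p$b)
  a <- sigmoid_(cv$y)                        # (H, W, 1, N)
  ab <- broadcast_map(a, dim(x))
  list(y = x * ab, attention = a,
       cache = list(x = x, a = a, ab = ab, cs = cs$cache, cv = cv$cache))
}

sa_bwd <- function(dy, cache) {
  d <- dim(cache$x)
  da <- sum_channels(dy * cache$x)           # (H, W, 1, N)
  dx <- dy * cache$ab
  dz <- da * cache$a * (1 - cache$a)
  d_cv <- conv_bwd(dz, cache$cv)
  dx <- dx + chan_stats_bwd(d_cv$dx, cache$cs)
  list(dx = dx, grads = list(W = d_cv$dW, b = d_cv$db))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , (c1 + 1):d[3], , drop = FALSE])
}

## ------- exported elementary ops -------

#' Leaky rectified linear unit
#'
#' `q` for `q >= 0`, `slope * q` otherwise.  The small default slope keeps a
#' gradient alive for negative inputs (the "dying ReLU" fix) and is the
#' activation of the CBL classifier branch.
#'
#' @param q numeric vector/array.
#' @param slope leak factor `l >= 0` (default 0.001).
#' @return the activated values, same shape as `q`.
#' @export
leaky_relu <- function(q, slope = 0.001) {
  check_number(slope, "slope", lower = 0)
  ifelse(q >= 0, q, slope * q)
}

#' Numerically stable softmax
#'
#' Exponentiates logits (after subtracting the row max, so arbitrarily large
#' logits do not overflow) and normalizes each row to sum to 1.
#'
#' @param y numeric vector of logits, or a matrix with one row per sample.
#' @return probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(y) {
  vec <- is.null(dim(y))
  if (vec) y <- matrix(y, nrow = 1)
  z <- exp(y - apply(y, 1, max))
  out <- z / rowSums(z)
  if (vec) out <- drop(out)
  out
}

#' Conv-BN-ReLU block (forward)
#'
#' A 3x3 same-padding convolution with `filters` output channels, batch
#' normalization, and ReLU.  Spatial size is preserved.
#'
#' @param x feature map, array `(H, W, C, N)` (a plain matrix is treated as
#'   `(H, W, 1, 1)`).
#' @param filters number of output channels.
#' @param kernel odd kernel size (default 3).
#' @param params optional parameter list (`conv$W`, `conv$b`, `bn$g`,
#'   `bn$b`) for reproducible/hand-set weights; freshly initialized when
#'   `NULL`.
#' @param training use batch statistics (`TRUE`) or running statistics in
#'   the BN step.
#' @return the output feature map `(H, W, filters, N)`.
#' @export
conv_bn_relu <- function(x, filters, kernel = 3, params = NULL,
                         training = TRUE) {
  check_number(filters, "filters", lower = 1)
  x <- as_feature_map(x)
  if (is.null(params)) params <- cbr_init(dim(x)[3], filters, kernel)
  s <- init_bn_state(filters)
  cbr_fwd(x, params, s, training)$y
}

#' Squeeze-and-excitation channel recalibration (forward)
#'
#' Global-average-pools each channel, passes the channel descriptor through
#' a bottleneck (`C -> C/r`, ReLU) and expansion (`C/r -> C`, sigmoid) pair
#' of fully connected layers, and rescales each channel of `x` by its gate
#' in (0, 1).
#'
#' @param x feature map `(H, W, C, N)`.
#' @param reduction bottleneck ratio `r` (default 16; width floors at 1).
#' @param params optional list with dense layers `fc1`, `fc2`.
#' @param return_gates also return the per-channel gates.
#' @return the recalibrated feature map (shape preserved), or a list
#'   `(y, gates)` when `return_gates = TRUE`.
#' @export
se_block <- function(x, reduction = 16, params = NULL, return_gates = FALSE) {
  x <- as_feature_map(x)
  if (is.null(params)) params <- se_init(dim(x)[3], reduction)
  r <- se_fwd(x, params)
  if (return_gates) list(y = r$y, gates = r$gates) else r$y
}

#' Full pre-activation residual unit (forward)
#'
#' `y = shortcut(x) + G(x)` with the residual branch
#' `BN -> ReLU -> conv3x3 -> BN -> ReLU -> conv3x3`; the shortcut is the
#' identity when channel counts match, else a 1x1 convolution + BN.
#'
#' @param x feature map `(H, W, C, N)`.
#' @param filters output channels (default: same as input, identity
#'   shortcut).
#' @param params optional parameter list (see `res_init`).
#' @param training batch vs running BN statistics.
#' @return the output feature map.
#' @export
residual_unit <- function(x, filters = NULL, params = NULL, training = TRUE) {
  x <- as_feature_map(x)
  cin <- dim(x)[3]
  if (is.null(filters)) filters <- cin
  if (is.null(params)) params <- res_init(cin, filters)
  s <- res_state(cin, filters)
  res_fwd(x, params, s, training)$y
}

#' CSR block: convolution + squeeze-excitation + residual skip (forward)
#'
#' A Conv-BN-ReLU block followed by squeeze-and-excitation recalibration,
#' plus a direct additive skip from the block input to the output (1x1
#' projection when channel counts differ).
#'
#' @param x feature map `(H, W, C, N)`.
#' @param filters output channels.
#' @param reduction squeeze-excitation bottleneck ratio.
#' @param params optional parameter list (`cbr`, `se`, optional `proj`).
#' @param training batch vs running BN statistics.
#' @return the output feature map `(H, W, filters, N)`.
#' @export
csr_block <- function(x, filters, reduction = 16, params = NULL,
                      training = TRUE) {
  x <- as_feature_map(x)
  cin <- dim(x)[3]
  if (is.null(params)) params <- csr_init(cin, filters, reduction)
  s <- list(cbr = init_bn_state(filters))
  csr_fwd(x, params, s, training)$y
}

#' Spatial attention gate (forward)
#'
#' Builds a 2-channel descriptor from the channel-wise max and mean maps,
#' convolves it with a single wide (default 7x7) kernel, squashes through a
#' sigmoid into a per-pixel attention map in (0, 1), and multiplies the map
#' (broadcast over channels) into the input.
#'
#' @param g feature map `(H, W, C, N)`.
#' @param params optional list with the conv `W` `(k, k, 2, 1)` and bias
#'   `b`.
#' @param kernel odd kernel size used when initializing (default 7).
#' @param return_map also return the attention map.
#' @return the gated feature map (shape preserved), or a list
#'   `(y, attention)` when `return_map = TRUE`.
#' @export
spatial_attention <- function(g, params = NULL, kernel = 7,
                              return_map = FALSE) {
  g <- as_feature_map(g)
  if (kernel %% 2 == 0) stop_param("`kernel` must be odd")
  if (is.null(params)) params <- sa_init(kernel)
  r <- sa_fwd(g, params)
  if (return_map) list(y = r$y, attention = r$attention) else r$y
}

## ------- model configuration / construction -------

#' Model configuration for the spatial-attention CSR-Unet
#'
#' Encoder channel counts double per stage (`base_filters * 1, 2, 4, 8`; the
#' published network uses 64/128/256/512 with a 1024-channel bottleneck).
#'
#' @param in_channels input image channels (1 for grayscale CT).
#' @param base_filters channels of the first encoder stage E1 (default 64;
#'   use 8 or 16 for desk-scale experiments).
#' @param se_reduction squeeze-excitation bottleneck ratio (default 16).
#' @param leaky_slope leak factor of the classifier branch's LeakyReLU
#'   (default 0.001).
#' @param attention_kernel spatial-attention kernel size, odd (default 7).
#' @param num_classes classification classes (2: SDH vs EDH).
#' @param cls_channels channel widths of the two classifier convolutions
#'   (default `base_filters * c(2, 1)`).
#' @return a `model_config` list.
#' @export
model_config <- function(in_channels = 1, base_filters = 64,
                         se_reduction = 16, leaky_slope = 0.001,
                         attention_kernel = 7, num_classes = 2,
                         cls_channels = NULL) {
  check_number(base_filters, "base_filters", lower = 1)
  check_number(se_reduction, "se_reduction", lower = 1)
  check_number(leaky_slope, "leaky_slope", lower = 0)
  if (attention_kernel %% 2 == 0) {
    stop_param("`attention_kernel` must be odd")
  }
  if (is.null(cls_channels)) cls_channels <- base_filters * c(2, 1)
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 encoder_filters = as.integer(base_filters * c(1, 2, 4, 8)),
                 bottleneck_filters = as.integer(base_filters * 16),
                 se_reduction = as.integer(se_reduction),
                 leaky_slope = leaky_slope,
                 attention_kernel = as.integer(attention_kernel),
                 num_classes = as.integer(num_classes),
                 cls_channels = as.integer(cls_channels)),
            class = "model_config")
}

#' Build a spatial-attention CSR-Unet
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return a `csr_unet` model object (configuration, parameters, batch-norm
#'   state).
#' @export
build_model <- function(cfg = model_config(), seed = NULL) {
  with_seed(seed, build_model_impl(cfg))
}

build_model_impl <- function(cfg) {
  ef <- cfg$encoder_filters
  bf <- cfg$bottleneck_filters
  k <- cfg$attention_kernel
  r <- cfg$se_reduction
  p <- list(enc = list(), csr = list(), dec = list())
  s <- list(enc = list(), csr = list(), dec = list())
  cin <- cfg$in_channels
  for (i in 1:4) {
    p$enc[[i]] <- list(c1 = cbr_init(cin, ef[i]), c2 = cbr_init(ef[i], ef[i]))
    s$enc[[i]] <- list(c1 = init_bn_state(ef[i]), c2 = init_bn_state(ef[i]))
    p$csr[[i]] <- csr_init(ef[i], ef[i], r)
    s$csr[[i]] <- list(cbr = init_bn_state(ef[i]))
    cin <- ef[i]
  }
  p$bot <- cbr_init(ef[4], bf)
  s$bot <- init_bn_state(bf)
  p$res <- res_init(bf)
  s$res <- res_state(bf)
  up_in <- bf
  for (i in 4:1) {
    p$dec[[i]] <- list(up = init_conv(2, 2, up_in, ef[i]),
                       att = sa_init(k),
                       c1 = cbr_init(2 * ef[i], ef[i]),
                       c2 = cbr_init(ef[i], ef[i]))
    s$dec[[i]] <- list(c1 = init_bn_state(ef[i]), c2 = init_bn_state(ef[i]))
    up_in <- ef[i]
  }
  p$seg <- init_conv(1, 1, ef[1], 1)
  cc <- cfg$cls_channels
  p$cls <- list(c1 = init_conv(3, 3, bf, cc[1]), bn1 = init_bn(cc[1]),
                c2 = init_conv(3, 3, cc[1], cc[2]),
                fc = init_dense(cc[2], cfg$num_classes))
  s$cls <- list(bn1 = init_bn_state(cc[1]))
  structure(list(cfg = cfg, params = p, state = s), class = "csr_unet")
}

#' @export
print.csr_unet <- function(x, ...) {
  cat(sprintf(
    "<csr_unet> encoder %s, bottleneck %d, %d classes, %d parameters\n",
    paste(x$cfg$encoder_filters, collapse = "/"), x$cfg$bottleneck_filters,
    x$cfg$num_classes, n_parameters(x)))
  invisible(x)
}

n_parameters <- function(model) {
  n <- 0L
  walk <- function(l) {
    for (el in l) {
      if (is.list(el)) walk(el) else n <<- n + length(el)
    }
  }
  walk(model$params)
  n
}

## ------- full forward / backward -------

model_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  s <- model$state
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    stop_param("input height and width must be divisible by 16")
  }
  caches <- list(enc = list(), csr = list(), pool = list(), dec = list())
  skips <- list()
  h <- x
  for (i in 1:4) {
    e1 <- cbr_fwd(h, p$enc[[i]]$c1, s$enc[[i]]$c1, training)
    e2 <- cbr_fwd(e1$y, p$enc[[i]]$c2, s$enc[[i]]$c2, training)
    s$enc[[i]]$c1 <- e1$state
    s$enc[[i]]$c2 <- e2$state
    k <- csr_fwd(e2$y, p$csr[[i]], s$csr[[i]], training)
    s$csr[[i]]$cbr <- k$state$cbr
    skips[[i]] <- k$y
    pl <- pool_fwd(e2$y)
    caches$enc[[i]] <- list(c1 = e1$cache, c2 = e2$cache)
    caches$csr[[i]] <- k$cache
    caches$pool[[i]] <- pl$cache
    h <- pl$y
  }
  bo <- cbr_fwd(h, p$bot, s$bot, training)
  s$bot <- bo$state
  re <- res_fwd(bo$y, p$res, s$res, training)
  s$res <- re$state
  caches$bot <- bo$cache
  caches$res <- re$cache
  bottleneck <- re$y

  h <- bottleneck
  for (i in 4:1) {
    up <- upconv_fwd(h, p$dec[[i]]$up$W, p$dec[[i]]$up$b)
    fused <- concat_ch(up$y, skips[[i]])
    at <- sa_fwd(fused, p$dec[[i]]$att)
    d1 <- cbr_fwd(at$y, p$dec[[i]]$c1, s$dec[[i]]$c1, training)
    d2 <- cbr_fwd(d1$y, p$dec[[i]]$c2, s$dec[[i]]$c2, training)
    s$dec[[i]]$c1 <- d1$state
    s$dec[[i]]$c2 <- d2$state
    caches$dec[[i]] <- list(up = up$cache, at = at$cache, c1 = d1$cache,
                            c2 = d2$cache,
                            up_ch = dim(up$y)[3])
    h <- d2$y
  }
  sg <- conv_fwd(h, p$seg$W, p$seg$b)
  seg_probs <- sigmoid_(sg$y)
  caches$seg <- sg$cache
  caches$seg_probs <- seg_probs

  cc1 <- conv_fwd(bottleneck, p$cls$c1$W, p$cls$c1$b)
  cb1 <- bn_fwd(cc1$y, p$cls$bn1$g, p$cls$bn1$b, s$cls$bn1$rm, s$cls$bn1$rv,
                training)
  s$cls$bn1 <- list(rm = cb1$rm, rv = cb1$rv)
  cl1 <- leaky_fwd(cb1$y, cfg$leaky_slope)
  cc2 <- conv_fwd(cl1$y, p$cls$c2$W, p$cls$c2$b)
  gp <- gap_fwd(cc2$y)
  fc <- dense_fwd(gp$y, p$cls$fc$W, p$cls$fc$b)
  class_probs <- softmax(fc$y)
  if (is.null(dim(class_probs))) class_probs <- matrix(class_probs, nrow = 1)
  caches$cls <- list(c1 = cc1$cache, b1 = cb1$cache, l1 = cl1$cache,
                     c2 = cc2$cache, gp = gp$cache, fc = fc$cache)
  caches$class_probs <- class_probs

  list(seg_probs = seg_probs, class_probs = class_probs,
       class_logits = fc$y, caches = caches, state = s)
}

# dz_seg: gradient w.r.t. the segmentation head's pre-sigmoid logits
# dz_cls: gradient w.r.t. the classifier logits (N x num_classes)
model_backward <- function(model, caches, dz_seg, dz_cls) {
  p <- model$params
  g <- list(enc = list(), csr = list(), dec = list())

  # classifier branch
  d_fc <- dense_bwd(dz_cls, caches$cls$fc)
  d_gp <- gap_bwd(d_fc$dx, caches$cls$gp)
  d_cc2 <- conv_bwd(d_gp, caches$cls$c2)
  d_cl1 <- leaky_bwd(d_cc2$dx, caches$cls$l1)
  d_cb1 <- bn_bwd(d_cl1, caches$cls$b1)
  d_cc1 <- conv_bwd(d_cb1$dx, caches$cls$c1)
  g$cls <- list(c1 = list(W = d_cc1$dW, b = d_cc1$db),
                bn1 = list(g = d_cb1$dgamma, b = d_cb1$dbeta),
                c2 = list(W = d_cc2$dW, b = d_cc2$db),
                fc = list(W = d_fc$dW, b = d_fc$db))
  d_bottleneck_cls <- d_cc1$dx

  # segmentation head
  d_sg <- conv_bwd(dz_seg, caches$seg)
  g$seg <- list(W = d_sg$dW, b = d_sg$db)
  dh <- d_sg$dx

  # decoder, shallow to deep
  d_skips <- list()
  for (i in 1:4) {
    ci <- caches$dec[[i]]
    d_d2 <- cbr_bwd(dh, ci$c2)
    d_d1 <- cbr_bwd(d_d2$dx, ci$c1)
    d_at <- sa_bwd(d_d1$dx, ci$at)
    sp <- split_ch(d_at$dx, ci$up_ch)
    d_skips[[i]] <- sp$b
    d_up <- upconv_bwd(sp$a, ci$up)
    g$dec[[i]] <- list(up = list(W = d_up$dW, b = d_up$db),
                       att = d_at$grads,
                       c1 = d_d1$grads, c2 = d_d2$grads)
    dh <- d_up$dx
  }
  d_bottleneck <- dh + d_bottleneck_cls

  # bottleneck
  d_re <- res_bwd(d_bottleneck, caches$res)
  g$res <- d_re$grads
  d_bo <- cbr_bwd(d_re$dx, caches$bot)
  g$bot <- d_bo$grads
  dh <- d_bo$dx

  # encoder, deep to shallow
  for (i in 4:1) {
    d_pool <- pool_bwd(dh, caches$pool[[i]])
    d_csr <- csr_bwd(d_skips[[i]], caches$csr[[i]])
    g$csr[[i]] <- d_csr$grads
    d_e2 <- cbr_bwd(d_pool + d_csr$dx, caches$enc[[i]]$c2)
    d_e1 <- cbr_bwd(d_e2$dx, caches$enc[[i]]$c1)
    g$enc[[i]] <- list(c1 = d_e1$grads, c2 = d_e2$grads)
    dh <- d_e1$dx
  }
  list(grads = g, dx = dh)
}

#' Run the model on a batch of images
#'
#' @param object a `csr_unet` model.
#' @param images matrix (single image), 3-d array `(H, W, N)`, or 4-d array
#'   `(H, W, 1, N)` of preprocessed intensities in \[0, 1\].
#' @param ... unused.
#' @return a list with `seg_probs` (per-pixel lesion probabilities,
#'   `(H, W, 1, N)`), `class_probs` (N x 2 matrix, columns SDH/EDH order per
#'   the model's class levels), evaluated in deterministic evaluation mode.
#' @export
predict.csr_unet <- function(object, images, ...) {
  x <- images_to_batch(images)
  out <- model_forward(object, x, training = FALSE)
  list(seg_probs = out$seg_probs, class_probs = out$class_probs)
}

images_to_batch <- function(images) {
  if (is.matrix(images)) {
    array(images, c(dim(images), 1L, 1L))
  } else if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(0, c(d[1], d[2], 1L, length(images)))
    for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]
    x
  } else if (length(dim(images)) == 3L) {
    d <- dim(images)
    array(images, c(d[1], d[2], 1L, d[3]))
  } else {
    images
  }
}
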