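# Layer primitives for the CSR-Unet: each has a `_fwd` returning the output
# plus a cache, and a `_bwd` mapping the upstream gradient and cache to input
# and parameter gradients.  Tensors are R arrays with dim (H, W, C, N).

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) != 4L) stop_param("feature maps must be 4-d (H,W,C,N)")
  x
}

## ---- convolution (stride 1, same padding, odd kernel) ----

conv_fwd <- function(x, W, b) {
  y <- conv2d_fwd_cpp(x, W, b, dim(x), dim(W))
  list(y = y, cache = list(x = x, W = W))
}

conv_bwd <- function(dy, cache) {
  g <- conv2d_bwd_cpp(cache$x, cache$W, dy, dim(cache$x), dim(cache$W))
  list(dx = g$dx, dW = g$dw, db = g$db)
}

## ---- 2x2 max pool / 2x2 transposed convolution ----

pool_fwd <- function(x) {
  r <- maxpool2_fwd_cpp(x, dim(x))
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}

pool_bwd <- function(dy, cache) {
  maxpool2_bwd_cpp(dy, cache$idx, cache$xdim)
}

upconv_fwd <- function(x, W, b) {
  y <- convt2_fwd_cpp(x, W, b, dim(x), dim(W))
  list(y = y, cache = list(x = x, W = W))
}

upconv_bwd <- function(dy, cache) {
  g <- convt2_bwd_cpp(cache$x, cache$W, dy, dim(cache$x), dim(cache$W))
  list(dx = g$dx, dW = g$dw, db = g$db)
}

## ---- batch normalization (per channel over H, W, N) ----

# column-wise ops via recycling (sweep() would aperm the whole matrix)
col_sub <- function(m, v) m - rep(v, each = nrow(m))
col_mul <- function(m, v) m * rep(v, each = nrow(m))
col_add <- function(m, v) m + rep(v, each = nrow(m))

# The (H,W,C,N) tensor is viewed as an (H*W) x (C*N) matrix -- no permuted
# copy -- with channel index cidx recycled over samples; per-channel moments
# come from per-(c,n) column moments averaged over n.
bn_fwd <- function(x, gamma, beta, rm, rv, training = TRUE, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  C <- d[3]; N <- d[4]
  dim(x) <- c(d[1] * d[2], C * N)
  cidx <- rep(seq_len(C), N)
  if (training) {
    mcn <- colMeans(x)
    m2cn <- colMeans(x * x)
    mu <- rowMeans(matrix(mcn, C, N))
    v <- pmax(rowMeans(matrix(m2cn, C, N)) - mu * mu, 0)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm
    v <- rv
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- col_mul(col_sub(x, mu[cidx]), inv[cidx])
  y <- col_add(col_mul(xhat, gamma[cidx]), beta[cidx])
  dim(y) <- d
  list(y = y, rm = rm, rv = rv,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d,
                    cidx = cidx, training = training))
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims
  C <- d[3]; N <- d[4]
  dim(dy) <- c(d[1] * d[2], C * N)
  cidx <- cache$cidx
  per_chan_sum <- function(m) rowSums(matrix(colSums(m), C, N))
  dgamma <- per_chan_sum(dy * cache$xhat)
  dbeta <- per_chan_sum(dy)
  dxhat <- col_mul(dy, cache$gamma[cidx])
  if (cache$training) {
    m <- d[1] * d[2] * N
    mean1 <- per_chan_sum(dxhat) / m
    mean2 <- per_chan_sum(dxhat * cache$xhat) / m
    dx <- col_mul(col_sub(dxhat, mean1[cidx]) -
                    col_mul(cache$xhat, mean2[cidx]),
                  cache$inv[cidx])
  } else {
    dx <- col_mul(dxhat, cache$inv[cidx])
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- activations ----

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

leaky_fwd <- function(x, slope) {
  pos <- x >= 0
  list(y = pmax(x, 0) + slope * pmin(x, 0), cache = list(pos = pos,
                                                         slope = slope))
}
leaky_bwd <- function(dy, cache) {
  dy * (cache$pos + cache$slope * (1 - cache$pos))
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

## ---- global average pool over space: (H,W,C,N) -> (N,C) matrix ----

gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])        # cols ordered (c, n)
  s <- t(matrix(colMeans(m), d[3], d[4]))   # (N, C)
  list(y = s, cache = d)
}

gap_bwd <- function(ds, d) {
  # ds: (N, C) -> spread evenly over pixels
  gc <- t(ds) / (d[1] * d[2])               # (C, N)
  array(rep(as.vector(gc), each = d[1] * d[2]), d)
}

## ---- channel-broadcast scaling: y = x * g, g per (channel, sample) ----

scale_channels <- function(x, g_nc) {
  d <- dim(x)
  gc <- t(g_nc)                              # (C, N)
  x * array(rep(as.vector(gc), each = d[1] * d[2]), d)
}

# gradient of sum(dy * x) per (channel, sample)
scale_channels_grad <- function(dy, x) {
  d <- dim(x)
  m <- matrix(dy * x, nrow = d[1] * d[2])
  t(matrix(colSums(m), d[3], d[4]))          # (N, C)
}

## ---- dense layer on (N, C) matrices ----

dense_fwd <- function(x, W, b) {
  z <- x %*% W
  z <- sweep(z, 2, b, `+`)
  list(y = z, cache = list(x = x, W = W))
}

dense_bwd <- function(dz, cache) {
  list(dx = dz %*% t(cache$W), dW = t(cache$x) %*% dz, db = colSums(dz))
}

## ---- channel-wise max / mean maps for spatial attention ----

chan_stats_fwd <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dim(x) <- c(HW, C * N)
  desc <- array(0, c(d[1], d[2], 2L, N))
  imax <- matrix(0L, HW, N)
  for (n in seq_len(N)) {
    sl <- x[, (n - 1) * C + seq_len(C), drop = FALSE]
    im <- max.col(sl, ties.method = "first")
    imax[, n] <- im
    desc[, , 1L, n] <- sl[cbind(seq_len(HW), im)]
    desc[, , 2L, n] <- rowMeans(sl)
  }
  list(y = desc, cache = list(imax = imax, dims = d))
}

chan_stats_bwd <- function(ddesc, cache) {
  d <- cache$dims
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dxm <- matrix(0, HW, C * N)
  for (n in seq_len(N)) {
    cols <- (n - 1) * C + seq_len(C)
    dxm[, cols] <- as.vector(ddesc[, , 2L, n]) / C
    sel <- cbind(seq_len(HW), (n - 1) * C + cache$imax[, n])
    dxm[sel] <- dxm[sel] + as.vector(ddesc[, , 1L, n])
  }
  dim(dxm) <- d
  dxm
}

## ---- parameter initialization ----

init_conv <- function(kh, kw, cin, cout) {
  list(W = array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_bn <- function(c) list(g = rep(1, c), b = rep(0, c))

init_bn_state <- function(c) list(rm = rep(0, c), rv = rep(1, c))

init_dense <- function(cin, cout) {
  list(W = matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}
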