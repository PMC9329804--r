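# Layer primitives for the compact CNN. Tensors are numeric arrays with
# dimensions (maps, height, width, batch); convolutions run as im2col
# gathers plus BLAS matrix products, chunked over the batch to bound the
# size of the column matrix. Everything is plain R on purpose: the model is
# small (~24k parameters) and the GEMMs dominate the cost.

conv_geometry <- function(c_in, h, w, k_h, k_w, s_h, s_w, p_h, p_w) {
  hp <- h + 2L * p_h
  wp <- w + 2L * p_w
  if ((hp - k_h) %% s_h != 0 || (wp - k_w) %% s_w != 0)
    stop("convolution geometry does not tile the input exactly")
  oh <- (hp - k_h) %/% s_h + 1L
  ow <- (wp - k_w) %/% s_w + 1L
  list(c_in = c_in, h = h, w = w, hp = hp, wp = wp, oh = oh, ow = ow,
       k_h = k_h, k_w = k_w, s_h = s_h, s_w = s_w, p_h = p_h, p_w = p_w,
       ckk = c_in * k_h * k_w)
}

pad_input <- function(x, g) {
  d <- dim(x)
  if (g$p_h == 0 && g$p_w == 0) return(x)
  xp <- array(0, dim = c(g$c_in, g$hp, g$wp, d[4]))
  xp[, g$p_h + seq_len(g$h), g$p_w + seq_len(g$w), ] <- x
  xp
}

# The weight matrix W is (c_out x c_in*k_h*k_w), kernel elements ordered
# input-channel fastest, then k_h, then k_w. im2col assembly runs in C++
# (src/conv.cpp); the products are BLAS GEMMs.
conv_par <- function(g) {
  as.integer(c(g$k_h, g$k_w, g$s_h, g$s_w, g$p_h, g$p_w))
}

conv_forward <- function(layer, x) {
  conv_fwd_cpp(x, dim(x), layer$W, layer$b, conv_par(layer$geom))
}

conv_backward <- function(layer, x, dy) {
  conv_bwd_cpp(x, dim(x), dy, layer$W, conv_par(layer$geom))
}

# Batch normalization without learnable affine (the layer table carries no
# parameters for its normalization rows): y = (x - mean) / sqrt(var + eps)
# per feature map, batch statistics in training, running statistics at eval.
bn_forward <- function(layer, x, train) {
  c_out <- dim(x)[1]
  xm <- matrix(x, nrow = c_out)
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - mu) * inv
  y <- xhat
  dim(y) <- dim(x)
  list(y = y, xhat = xhat, inv = inv, mu = mu, v = v)
}

bn_backward <- function(cache, dy) {
  c_out <- length(cache$mu)
  dym <- matrix(dy, nrow = c_out)
  m <- ncol(dym)
  dx <- cache$inv * (dym - rowMeans(dym) -
                       cache$xhat * rowMeans(dym * cache$xhat))
  dim(dx) <- dim(dy)
  dx
}

elu_forward <- function(x) {
  pmax(x, 0) + expm1(pmin(x, 0))
}

elu_backward <- function(y, dy) {
  g <- y + 1
  g[y > 0] <- 1
  dy * g
}

avgpool_forward <- function(x, k_h, k_w) {
  d <- dim(x)
  oh <- d[2] %/% k_h
  ow <- d[3] %/% k_w
  y <- array(0, dim = c(d[1], oh, ow, d[4]))
  for (i in seq_len(k_h)) for (j in seq_len(k_w))
    y <- y + x[, seq(i, by = k_h, length.out = oh),
               seq(j, by = k_w, length.out = ow), , drop = FALSE]
  y / (k_h * k_w)
}

avgpool_backward <- function(dy, k_h, k_w, in_dim) {
  d <- in_dim
  oh <- d[2] %/% k_h
  ow <- d[3] %/% k_w
  dx <- array(0, dim = d)
  g <- dy / (k_h * k_w)
  for (i in seq_len(k_h)) for (j in seq_len(k_w))
    dx[, seq(i, by = k_h, length.out = oh),
       seq(j, by = k_w, length.out = ow), ] <- g
  dx
}

# Spatial dropout: zeroes whole feature maps per sample (inverted scaling).
spatial_dropout_mask <- function(c_out, n, rate) {
  matrix(stats::rbinom(c_out * n, 1, 1 - rate) / (1 - rate),
         nrow = c_out, ncol = n)
}

apply_channel_mask <- function(x, mask) {
  d <- dim(x)
  for (k in seq_len(d[4])) x[, , , k] <- x[, , , k] * mask[, k]
  x
}

softmax_rows <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

cross_entropy <- function(prob, y_idx) {
  n <- ncol(prob)
  -mean(log(pmax(prob[cbind(y_idx, seq_len(n))], 1e-12)))
}
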