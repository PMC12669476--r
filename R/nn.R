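# Minimal convolutional-network framework used by the virtual-staining
# module: im2col convolutions, nearest-neighbour-upsample decoding,
# instance normalisation, standard activations and an Adam optimiser.
# Tensors are plain 3-d arrays [H, W, C]; batches are processed one sample
# at a time (instance-norm regime). Everything is deterministic given the
# RNG seed.

conv_index_cache <- new.env(parent = emptyenv())

# im2col gather indices for x of size (h, w, cin) padded by `pad`,
# kernel k x k, stride s. Returns list(idx = matrix [n_out, k*k*cin],
# out_h, out_w, pad_dim).
im2col_indices <- function(h, w, cin, k, s, pad) {
  key <- paste(h, w, cin, k, s, pad, sep = "_")
  if (!is.null(conv_index_cache[[key]])) return(conv_index_cache[[key]])
  ph <- h + 2 * pad; pw <- w + 2 * pad
  out_h <- (ph - k) %/% s + 1; out_w <- (pw - k) %/% s + 1
  r0 <- (seq_len(out_h) - 1) * s + 1
  c0 <- (seq_len(out_w) - 1) * s + 1
  # linear indices into the padded array, column-major [ph, pw, cin]
  base <- outer(r0, (c0 - 1) * ph, `+`)          # out_h x out_w start cells
  offs <- integer(0)
  for (ch in seq_len(cin) - 1) for (dc in seq_len(k) - 1) for (dr in seq_len(k) - 1)
    offs <- c(offs, dr + dc * ph + ch * ph * pw)
  idx <- outer(as.vector(base), offs, `+`)       # n_out x (k*k*cin)
  storage.mode(idx) <- "integer"
  val <- list(idx = idx, out_h = out_h, out_w = out_w, ph = ph, pw = pw)
  conv_index_cache[[key]] <- val
  val
}

pad_hw <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# forward convolution; W is [k*k*cin, cout] (flattened kernel), b length cout
conv_fwd <- function(x, W, b, k, s, pad) {
  d <- dim(x)
  ii <- im2col_indices(d[1], d[2], d[3], k, s, pad)
  xp <- pad_hw(x, pad)
  cols <- matrix(xp[as.vector(ii$idx)], nrow(ii$idx), ncol(ii$idx))
  out <- cols %*% W
  out <- sweep(out, 2, b, `+`)
  list(y = array(out, c(ii$out_h, ii$out_w, ncol(W))), cols = cols, ii = ii,
       dim_in = d)
}

conv_bwd <- function(cache, dy, W, k, s, pad) {
  d <- cache$dim_in; ii <- cache$ii
  dmat <- matrix(dy, ii$out_h * ii$out_w, dim(dy)[3])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(W)
  # scatter-add back into the padded input, one kernel offset at a time
  # (indices within a column are distinct, so vectorised += is exact)
  dxp <- numeric(ii$ph * ii$pw * d[3])
  for (j in seq_len(ncol(ii$idx))) {
    tgt <- ii$idx[, j]
    dxp[tgt] <- dxp[tgt] + dcols[, j]
  }
  dxp <- array(dxp, c(ii$ph, ii$pw, d[3]))
  dx <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

upsample_nn_fwd <- function(x, f = 2) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , drop = FALSE]
}

upsample_nn_bwd <- function(dy, f = 2) {
  d <- dim(dy)
  h <- d[1] %/% f; w <- d[2] %/% f
  out <- array(0, c(h, w, d[3]))
  for (dr in seq_len(f)) for (dc in seq_len(f))
    out <- out + dy[seq(dr, d[1], by = f), seq(dc, d[2], by = f), ,
                    drop = FALSE]
  out
}

inorm_fwd <- function(x, gamma, beta, eps = 1e-5, run = NULL) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  if (is.null(run)) {               # training: per-sample statistics
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
  } else {                          # eval: frozen running statistics
    mu <- run$mu; v <- run$v
  }
  xh <- sweep(sweep(m, 2, mu), 2, sqrt(v + eps), `/`)
  y <- sweep(sweep(xh, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, d), xh = xh, mu = mu, v = v, eps = eps)
}

# momentum update of running normalisation statistics (batchnorm-style)
update_running <- function(stats_env, key, mu, v, momentum = 0.1) {
  cur <- stats_env[[key]]
  if (is.null(cur)) stats_env[[key]] <- list(mu = mu, v = v)
  else stats_env[[key]] <- list(mu = (1 - momentum) * cur$mu + momentum * mu,
                                v = (1 - momentum) * cur$v + momentum * v)
}

inorm_bwd <- function(cache, dy, gamma) {
  d <- dim(dy)
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dgamma <- colSums(dym * cache$xh)
  dbeta <- colSums(dym)
  dxh <- sweep(dym, 2, gamma, `*`)
  istd <- 1 / sqrt(cache$v + cache$eps)
  dx <- sweep(dxh - matrix(colMeans(dxh), n, d[3], byrow = TRUE) -
                cache$xh * matrix(colMeans(dxh * cache$xh), n, d[3],
                                  byrow = TRUE),
              2, istd, `*`)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, a = 0.2) list(y = ifelse(x > 0, x, a * x), x = x, a = a)
lrelu_bwd <- function(cache, dy) dy * ifelse(cache$x > 0, 1, cache$a)
tanh_fwd <- function(x) { y <- tanh(x); list(y = y, y2 = y) }
tanh_bwd <- function(cache, dy) dy * (1 - cache$y2^2)

# numerically stable sigmoid BCE on logits; target is scalar 0/1
bce_logits <- function(z, target) {
  # mean over elements of: max(z,0) - z*t + log(1 + exp(-|z|))
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}
bce_logits_grad <- function(z, target) {
  (1 / (1 + exp(-z)) - target) / length(z)
}

init_conv_w <- function(k, cin, cout, gain = 0.02) {
  matrix(stats::rnorm(k * k * cin * cout, 0, gain), k * k * cin, cout)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(params, grads, state, lr, beta1 = 0.5,
                        beta2 = 0.999, t = 1, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mh <- st$m / (1 - beta1^t); vh <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
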