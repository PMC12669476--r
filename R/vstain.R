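# Conditional-GAN virtual staining: a pix2pix-style U-Net generator and
# patch discriminator trained on registered (unstained-phase, stained-RGB)
# patch pairs with the L1-regularised adversarial objective
#   G* = arg min_G max_D  L_cGAN(G, D) + lambda * L_L1(G),
# and tiled full-field inference. The network code is the compact
# framework in nn.R; the decoder uses nearest-neighbour-upsample
# convolutions (a standard checkerboard-free alternative to strided
# transposed convolutions).

#' Virtual-staining model configuration
#'
#' @param width base channel width of the U-Net generator.
#' @param depth number of 2x down/up-sampling levels (input patches must be
#'   divisible by `2^depth`).
#' @param disc_width base width of the patch discriminator.
#' @param disc_strides per-layer strides of the discriminator convolutions;
#'   the default (2,2,2,1) plus the 1-stride output layer gives the
#'   classic 70x70-receptive-field patch critic.
#' @param lambda_l1 weight of the L1 term in the generator objective.
#' @param epochs training epochs.
#' @param lr,betas Adam step size and moment decays.
#' @param jitter_px random crop-jitter amplitude (reflect-padded), px.
#' @param mirror random horizontal/vertical mirroring.
#' @param tile_size inference tile, px.
#' @param tile_overlap blend overlap between inference tiles, px.
#' @param seed RNG seed controlling initialisation and augmentation.
#' @return list of class `vs_config`.
#' @export
vs_config <- function(width = 16, depth = 6, disc_width = 16,
                      disc_strides = c(2, 2, 2, 1), lambda_l1 = 100,
                      epochs = 100, lr = 2e-4, betas = c(0.5, 0.999),
                      jitter_px = 4, mirror = TRUE, tile_size = 1024,
                      tile_overlap = 64, seed = 1) {
  if (lambda_l1 < 0) stop("lambda_l1 must be >= 0", call. = FALSE)
  if (tile_size %% 2^depth != 0)
    stop("tile_size must be a multiple of 2^depth", call. = FALSE)
  structure(list(width = width, depth = depth, disc_width = disc_width,
                 disc_strides = disc_strides, lambda_l1 = lambda_l1,
                 epochs = epochs, lr = lr, betas = betas,
                 jitter_px = jitter_px, mirror = mirror,
                 tile_size = tile_size, tile_overlap = tile_overlap,
                 seed = seed),
            class = "vs_config")
}

gen_channels <- function(cfg) {
  vapply(seq_len(cfg$depth), function(i) cfg$width * min(2^(i - 1), 8),
         numeric(1))
}

init_generator <- function(cfg, in_ch = 1, out_ch = 3) {
  ch <- gen_channels(cfg)
  p <- list()
  cin <- in_ch
  for (i in seq_len(cfg$depth)) {
    p[[paste0("e", i, "_W")]] <- init_conv_w(4, cin, ch[i])
    p[[paste0("e", i, "_b")]] <- numeric(ch[i])
    if (i > 1) {
      p[[paste0("e", i, "_g")]] <- rep(1, ch[i])
      p[[paste0("e", i, "_be")]] <- numeric(ch[i])
    }
    cin <- ch[i]
  }
  for (i in (cfg$depth - 1):0) {
    cout <- if (i >= 1) ch[i] else cfg$width
    cin_dec <- if (i == cfg$depth - 1) ch[cfg$depth] else 2 * ch[i + 1]
    p[[paste0("d", i, "_W")]] <- init_conv_w(3, cin_dec, cout)
    p[[paste0("d", i, "_b")]] <- numeric(cout)
    p[[paste0("d", i, "_g")]] <- rep(1, cout)
    p[[paste0("d", i, "_be")]] <- numeric(cout)
  }
  p[["out_W"]] <- init_conv_w(3, cfg$width, out_ch)
  p[["out_b"]] <- numeric(out_ch)
  p
}

gen_forward <- function(p, x, cfg, stats_env = NULL, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  run_of <- function(key) {
    if (mode == "eval" && !is.null(stats_env)) stats_env[[key]] else NULL
  }
  track <- function(key, nm) {
    if (mode == "train" && !is.null(stats_env))
      update_running(stats_env, key, nm$mu, nm$v)
  }
  caches <- list(enc = vector("list", cfg$depth),
                 dec = vector("list", cfg$depth))
  e <- vector("list", cfg$depth + 1)
  e[[1]] <- x
  for (i in seq_len(cfg$depth)) {
    cv <- conv_fwd(e[[i]], p[[paste0("e", i, "_W")]],
                   p[[paste0("e", i, "_b")]], 4, 2, 1)
    h <- cv$y
    nm <- NULL
    if (i > 1) {
      nm <- inorm_fwd(h, p[[paste0("e", i, "_g")]], p[[paste0("e", i, "_be")]],
                      run = run_of(paste0("e", i)))
      track(paste0("e", i), nm)
      h <- nm$y
    }
    ac <- lrelu_fwd(h)
    caches$enc[[i]] <- list(cv = cv, nm = nm, ac = ac)
    e[[i + 1]] <- ac$y
  }
  h <- e[[cfg$depth + 1]]
  for (i in (cfg$depth - 1):0) {
    up <- upsample_nn_fwd(h)
    cv <- conv_fwd(up, p[[paste0("d", i, "_W")]], p[[paste0("d", i, "_b")]],
                   3, 1, 1)
    nm <- inorm_fwd(cv$y, p[[paste0("d", i, "_g")]],
                    p[[paste0("d", i, "_be")]],
                    run = run_of(paste0("d", i)))
    track(paste0("d", i), nm)
    ac <- lrelu_fwd(nm$y, a = 0)          # plain ReLU in the decoder
    t_i <- ac$y
    caches$dec[[i + 1]] <- list(cv = cv, nm = nm, ac = ac,
                                in_ch_t = dim(t_i)[3])
    h <- if (i >= 1) {
      skip <- e[[i + 1]]
      arr <- array(0, c(dim(t_i)[1], dim(t_i)[2], dim(t_i)[3] + dim(skip)[3]))
      arr[, , seq_len(dim(t_i)[3])] <- t_i
      arr[, , dim(t_i)[3] + seq_len(dim(skip)[3])] <- skip
      arr
    } else t_i
  }
  ocv <- conv_fwd(h, p$out_W, p$out_b, 3, 1, 1)
  oth <- tanh_fwd(ocv$y)
  caches$out <- list(cv = ocv, th = oth)
  list(y = oth$y, caches = caches)
}

gen_backward <- function(p, caches, dy, cfg) {
  g <- list()
  dz <- tanh_bwd(caches$out$th, dy)
  cb <- conv_bwd(caches$out$cv, dz, p$out_W, 3, 1, 1)
  g$out_W <- cb$dW; g$out_b <- cb$db
  dh <- cb$dx
  denc_skip <- vector("list", cfg$depth)    # grads flowing into e[[i+1]]
  for (i in 0:(cfg$depth - 1)) {
    cc <- caches$dec[[i + 1]]
    if (i >= 1) {
      nt <- cc$in_ch_t
      d_t <- dh[, , seq_len(nt), drop = FALSE]
      denc_skip[[i]] <- dh[, , nt + seq_len(dim(dh)[3] - nt), drop = FALSE]
    } else d_t <- dh
    da <- lrelu_bwd(cc$ac, d_t)
    nb <- inorm_bwd(cc$nm, da, p[[paste0("d", i, "_g")]])
    g[[paste0("d", i, "_g")]] <- nb$dgamma
    g[[paste0("d", i, "_be")]] <- nb$dbeta
    cb <- conv_bwd(cc$cv, nb$dx, p[[paste0("d", i, "_W")]], 3, 1, 1)
    g[[paste0("d", i, "_W")]] <- cb$dW
    g[[paste0("d", i, "_b")]] <- cb$db
    dh <- upsample_nn_bwd(cb$dx)
    # dh now flows into the PREVIOUS decoder stage's output h_{i+1};
    # at the bottleneck it flows into e[[depth+1]]
  }
  de_next <- dh                              # gradient w.r.t. e[[depth+1]]
  for (i in cfg$depth:1) {
    if (i < cfg$depth && !is.null(denc_skip[[i]]))
      de_next <- de_next + denc_skip[[i]]
    cc <- caches$enc[[i]]
    da <- lrelu_bwd(cc$ac, de_next)
    if (i > 1) {
      nb <- inorm_bwd(cc$nm, da, p[[paste0("e", i, "_g")]])
      g[[paste0("e", i, "_g")]] <- nb$dgamma
      g[[paste0("e", i, "_be")]] <- nb$dbeta
      da <- nb$dx
    }
    cb <- conv_bwd(cc$cv, da, p[[paste0("e", i, "_W")]], 4, 2, 1)
    g[[paste0("e", i, "_W")]] <- cb$dW
    g[[paste0("e", i, "_b")]] <- cb$db
    de_next <- cb$dx
  }
  g
}

init_discriminator <- function(cfg, in_ch = 4) {
  w <- cfg$disc_width
  strides <- cfg$disc_strides
  chans <- pmin(w * 2^(seq_along(strides) - 1), 8 * w)
  p <- list(); cin <- in_ch
  for (i in seq_along(strides)) {
    p[[paste0("c", i, "_W")]] <- init_conv_w(4, cin, chans[i])
    p[[paste0("c", i, "_b")]] <- numeric(chans[i])
    if (i > 1) {
      p[[paste0("c", i, "_g")]] <- rep(1, chans[i])
      p[[paste0("c", i, "_be")]] <- numeric(chans[i])
    }
    cin <- chans[i]
  }
  p[["f_W"]] <- init_conv_w(4, cin, 1)
  p[["f_b"]] <- numeric(1)
  p
}

disc_forward <- function(p, x, cfg) {
  strides <- cfg$disc_strides
  caches <- vector("list", length(strides))
  h <- x
  for (i in seq_along(strides)) {
    cv <- conv_fwd(h, p[[paste0("c", i, "_W")]], p[[paste0("c", i, "_b")]],
                   4, strides[i], 1)
    y <- cv$y
    nm <- NULL
    if (i > 1) {
      nm <- inorm_fwd(y, p[[paste0("c", i, "_g")]], p[[paste0("c", i, "_be")]])
      y <- nm$y
    }
    ac <- lrelu_fwd(y)
    caches[[i]] <- list(cv = cv, nm = nm, ac = ac)
    h <- ac$y
  }
  fcv <- conv_fwd(h, p$f_W, p$f_b, 4, 1, 1)
  list(z = fcv$y, caches = caches, fcv = fcv)
}

disc_backward <- function(p, fw, dz, cfg) {
  g <- list()
  cb <- conv_bwd(fw$fcv, dz, p$f_W, 4, 1, 1)
  g$f_W <- cb$dW; g$f_b <- cb$db
  dh <- cb$dx
  strides <- cfg$disc_strides
  for (i in rev(seq_along(strides))) {
    cc <- fw$caches[[i]]
    da <- lrelu_bwd(cc$ac, dh)
    if (i > 1) {
      nb <- inorm_bwd(cc$nm, da, p[[paste0("c", i, "_g")]])
      g[[paste0("c", i, "_g")]] <- nb$dgamma
      g[[paste0("c", i, "_be")]] <- nb$dbeta
      da <- nb$dx
    }
    cb <- conv_bwd(cc$cv, da, p[[paste0("c", i, "_W")]], 4, strides[i], 1)
    g[[paste0("c", i, "_W")]] <- cb$dW
    g[[paste0("c", i, "_b")]] <- cb$db
    dh <- cb$dx
  }
  list(grads = g, dx = dh)
}

#' Conditional-GAN loss terms
#'
#' Decomposes the generator objective: `l_l1` is the mean absolute error
#' between generated and target images, `l_cgan` the adversarial
#' (non-saturating binary cross-entropy) term on the critic logits, and
#' `total = l_cgan + lambda_l1 * l_l1`.
#'
#' @param generated,target arrays of equal shape.
#' @param critic_logits critic output logits for the generated pair.
#' @param lambda_l1 L1 weight.
#' @return list with `l_cgan`, `l_l1`, `total`.
#' @export
loss_terms <- function(generated, target, critic_logits, lambda_l1 = 100) {
  stopifnot(all(dim(generated) == dim(target)))
  l_l1 <- mean(abs(generated - target))
  l_cgan <- bce_logits(critic_logits, 1)
  list(l_cgan = l_cgan, l_l1 = l_l1, total = l_cgan + lambda_l1 * l_l1)
}

normalise_phase <- function(x, lo, hi) {
  2 * (x - lo) / max(hi - lo, 1e-9) - 1
}

augment_pair <- function(x, y, jitter_px, mirror) {
  if (jitter_px > 0) {
    d <- dim(x)
    px <- function(a, j) {
      # reflect-pad by j on each side
      ridx <- c(rev(seq_len(j) + 1), seq_len(d[1]), d[1] - seq_len(j))
      cidx <- c(rev(seq_len(j) + 1), seq_len(d[2]), d[2] - seq_len(j))
      a[ridx, cidx, , drop = FALSE]
    }
    xp <- px(x, jitter_px); yp <- px(y, jitter_px)
    r0 <- sample.int(2 * jitter_px + 1, 1); c0 <- sample.int(2 * jitter_px + 1, 1)
    x <- xp[r0:(r0 + d[1] - 1), c0:(c0 + d[2] - 1), , drop = FALSE]
    y <- yp[r0:(r0 + d[1] - 1), c0:(c0 + d[2] - 1), , drop = FALSE]
  }
  if (mirror) {
    if (stats::runif(1) < 0.5) {
      x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
      y <- y[rev(seq_len(dim(y)[1])), , , drop = FALSE]
    }
    if (stats::runif(1) < 0.5) {
      x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
      y <- y[, rev(seq_len(dim(y)[2])), , drop = FALSE]
    }
  }
  list(x = x, y = y)
}

#' Train the virtual-staining cGAN
#'
#' Alternating discriminator/generator updates over the accepted patch
#' pairs with random jitter and mirror augmentation. Phase inputs are
#' robustly scaled to `[-1, 1]` by the 1st/99th percentiles pooled over
#' the training set (stored with the model); RGB targets are mapped to
#' `[-1, 1]`. The loss trajectory is deterministic for a fixed seed.
#'
#' @param pairs a [curate_pairs()] result, or a list of pairs each with
#'   `phase_patch` and `rgb_patch`.
#' @param cfg a [vs_config()].
#' @return object of class `vs_model`: generator/discriminator parameters,
#'   normalisation constants, `cfg`, and `report` (class `train_report`):
#'   per-epoch mean `l1`, `l_cgan`, `d_loss`, wall-clock seconds, seed and
#'   a config hash.
#' @export
train_vstain <- function(pairs, cfg = vs_config()) {
  plist <- if (inherits(pairs, "patch_pairs")) pairs$pairs else pairs
  if (!length(plist)) stop("no accepted training pairs", call. = FALSE)
  d0 <- dim(plist[[1]]$phase_patch)
  if (any((d0 %% 2^cfg$depth) != 0))
    stop("patch size must be divisible by 2^depth", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  allphase <- unlist(lapply(plist, function(p) as.vector(p$phase_patch)))
  qs <- stats::quantile(allphase, c(0.01, 0.99), names = FALSE)
  xs <- lapply(plist, function(p)
    array(normalise_phase(p$phase_patch, qs[1], qs[2]), c(d0, 1)))
  ys <- lapply(plist, function(p) 2 * p$rgb_patch - 1)
  G <- init_generator(cfg); D <- init_discriminator(cfg)
  bn_stats <- new.env(parent = emptyenv())
  sG <- adam_state(G); sD <- adam_state(D)
  n_ep <- cfg$epochs
  rep_l1 <- rep_adv <- rep_d <- numeric(n_ep)
  t_start <- Sys.time(); t_step <- 0
  for (ep in seq_len(n_ep)) {
    ord <- sample.int(length(xs))
    e_l1 <- e_adv <- e_d <- 0
    for (ix in ord) {
      t_step <- t_step + 1
      aug <- augment_pair(xs[[ix]], ys[[ix]], cfg$jitter_px, cfg$mirror)
      x <- aug$x; y <- aug$y
      gf <- gen_forward(G, x, cfg, stats_env = bn_stats, mode = "train")
      yhat <- gf$y
      pair_real <- abind3(x, y); pair_fake <- abind3(x, yhat)
      # --- discriminator step ---
      fr <- disc_forward(D, pair_real, cfg)
      ff <- disc_forward(D, pair_fake, cfg)
      dr <- disc_backward(D, fr, 0.5 * bce_logits_grad(fr$z, 1), cfg)$grads
      dfk <- disc_backward(D, ff, 0.5 * bce_logits_grad(ff$z, 0), cfg)$grads
      gD <- Map(`+`, dr, dfk[names(dr)])
      up <- adam_update(D, gD, sD, cfg$lr, cfg$betas[1], cfg$betas[2],
                        t = t_step)
      D <- up$params; sD <- up$state
      e_d <- e_d + 0.5 * (bce_logits(fr$z, 1) + bce_logits(ff$z, 0))
      # --- generator step ---
      ff2 <- disc_forward(D, pair_fake, cfg)
      db <- disc_backward(D, ff2, bce_logits_grad(ff2$z, 1), cfg)
      dy_adv <- db$dx[, , 2:4, drop = FALSE]
      l1 <- mean(abs(yhat - y))
      dy_l1 <- cfg$lambda_l1 * sign(yhat - y) / length(yhat)
      gG <- gen_backward(G, gf$caches, dy_adv + dy_l1, cfg)
      up <- adam_update(G, gG, sG, cfg$lr, cfg$betas[1], cfg$betas[2],
                        t = t_step)
      G <- up$params; sG <- up$state
      e_l1 <- e_l1 + l1
      e_adv <- e_adv + bce_logits(ff2$z, 1)
    }
    rep_l1[ep] <- e_l1 / length(xs)
    rep_adv[ep] <- e_adv / length(xs)
    rep_d[ep] <- e_d / length(xs)
  }
  report <- structure(list(
    l1 = rep_l1, l_cgan = rep_adv, d_loss = rep_d,
    wall_clock_s = as.numeric(Sys.time() - t_start, units = "secs"),
    seed = cfg$seed,
    config_hash = config_hash(cfg)), class = "train_report")
  structure(list(G = G, D = D, cfg = cfg,
                 norm = list(lo = qs[1], hi = qs[2]),
                 bn_stats = as.list(bn_stats),
                 report = report),
            class = "vs_model")
}

abind3 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

config_hash <- function(cfg) {
  s <- paste(names(unlist(cfg)), unlist(cfg), collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

#' @export
print.vs_model <- function(x, ...) {
  cat(sprintf("<vs_model> U-Net width %d depth %d, lambda_l1 %g, %d epochs trained\n",
              x$cfg$width, x$cfg$depth, x$cfg$lambda_l1,
              length(x$report$l1)))
  cat(sprintf("  final L1 %.4f (epoch 1: %.4f)\n",
              utils::tail(x$report$l1, 1), x$report$l1[1]))
  invisible(x)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d epochs, %.1f s; L1 %.4f -> %.4f\n",
              length(x$l1), x$wall_clock_s, x$l1[1], utils::tail(x$l1, 1)))
  invisible(x)
}

#' Virtually stain a phase field
#'
#' Normalises the phase field with the model's stored constants and runs
#' tiled generator inference: tiles of `tile_size` with `tile_overlap`
#' blending (via [stitch()]), output clipped to `[0,1]^3`. Inputs smaller
#' than the tile run in a single pass (reflect-padded to the U-Net
#' granularity).
#'
#' @param model a [train_vstain()] result.
#' @param phase phase field, radians (matrix).
#' @param tile_size tile side, px; defaults to the model config.
#' @return rows x cols x 3 RGB array in `[0,1]`.
#' @export
stain <- function(model, phase, tile_size = NULL) {
  cfg <- model$cfg
  if (is.null(tile_size)) tile_size <- cfg$tile_size
  if (tile_size %% 2^cfg$depth != 0)
    stop("tile_size must be a multiple of 2^depth", call. = FALSE)
  xn <- normalise_phase(phase, model$norm$lo, model$norm$hi)
  frac_out <- mean(xn < -2 | xn > 2)
  if (frac_out > 0.5)
    stop("input normalisation mismatch: field far outside the training range",
         call. = FALSE)
  nr <- nrow(xn); nc <- ncol(xn)
  run_tile <- function(tile) {
    d <- dim(tile)
    m <- 2^cfg$depth
    pr <- ceiling(d[1] / m) * m - d[1]
    pc <- ceiling(d[2] / m) * m - d[2]
    if (pr > 0 || pc > 0) {
      ridx <- c(seq_len(d[1]), d[1] - seq_len(pr) + 0)
      cidx <- c(seq_len(d[2]), d[2] - seq_len(pc) + 0)
      tile <- tile[ridx, cidx]
    }
    y <- gen_forward(model$G, array(tile, c(dim(tile), 1)), cfg,
                     stats_env = list2env(model$bn_stats), mode = "eval")$y
    y[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  }
  if (nr <= tile_size && nc <= tile_size) {
    out <- run_tile(xn)
  } else {
    ov <- cfg$tile_overlap
    step <- tile_size - ov
    r0 <- unique(pmin(seq(1, nr, by = step), max(nr - tile_size + 1, 1)))
    c0 <- unique(pmin(seq(1, nc, by = step), max(nc - tile_size + 1, 1)))
    chans <- vector("list", 3)
    patches_rgb <- list(); offs <- NULL
    for (r in r0) for (cc in c0) {
      ir <- r:min(r + tile_size - 1, nr); ic <- cc:min(cc + tile_size - 1, nc)
      patches_rgb[[length(patches_rgb) + 1]] <- run_tile(xn[ir, ic])
      offs <- rbind(offs, c(r, cc))
    }
    out <- array(0, c(nr, nc, 3))
    for (ch in 1:3) {
      pl <- lapply(patches_rgb, function(p) p[, , ch])
      out[, , ch] <- stitch(pl, offs, blend = "linear")
    }
  }
  pmin(pmax((out + 1) / 2, 0), 1)
}
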