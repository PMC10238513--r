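## Internal neural-network engine for the segment classifier.
##
## Tensors are column-major R arrays with dim (C, H, W, N): channels, mel
## bands, frames, batch. Convolution weights are (C_out, C_in * 9) matrices
## matching the im2col ordering of the C++ kernels. The architecture is a
## stack of convolutional blocks (2 x [conv 3x3 -> batch norm -> ReLU]) with
## ceil-mode 2x2 average pooling and dropout after every block but the last,
## frequency reduction by average pooling, time smoothing (max + average
## pooling, size 3, stride 1, summed), a per-segment fully connected layer
## with ReLU, and two per-segment heads: a sigmoid prediction head p(x_i) and
## a tanh attention head v(x_i), softmax-normalized into attention g(x_i).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

init_params <- function(cfg) {
  set.seed(cfg$init_seed)
  params <- list()
  run <- list()
  unif <- function(n, fan_in) stats::runif(n, -1, 1) / sqrt(fan_in)
  params[["bn0.gamma"]] <- rep(1, cfg$n_mels)
  params[["bn0.beta"]] <- rep(0, cfg$n_mels)
  run[["bn0.mean"]] <- rep(0, cfg$n_mels)
  run[["bn0.var"]] <- rep(1, cfg$n_mels)
  cin <- 1L
  for (i in seq_len(cfg$n_blocks)) {
    co <- cfg$channels[i]
    for (j in 1:2) {
      ci <- if (j == 1L) cin else co
      key <- sprintf("b%d.conv%d", i, j)
      params[[paste0(key, ".W")]] <- matrix(unif(co * ci * 9L, ci * 9L), co, ci * 9L)
      params[[paste0(key, ".b")]] <- unif(co, ci * 9L)
      bn <- sprintf("b%d.bn%d", i, j)
      params[[paste0(bn, ".gamma")]] <- rep(1, co)
      params[[paste0(bn, ".beta")]] <- rep(0, co)
      run[[paste0(bn, ".mean")]] <- rep(0, co)
      run[[paste0(bn, ".var")]] <- rep(1, co)
    }
    cin <- co
  }
  fcw <- cfg$fc_width
  params[["fc.W"]] <- matrix(unif(fcw * cin, cin), fcw, cin)
  params[["fc.b"]] <- unif(fcw, cin)
  params[["att_p.w"]] <- unif(fcw, fcw)
  params[["att_p.b"]] <- unif(1L, fcw)
  params[["att_v.w"]] <- unif(fcw, fcw)
  params[["att_v.b"]] <- unif(1L, fcw)
  list(params = params, run = run)
}

## Batch norm over the first dimension of a (C x M) matrix view.
bn_fwd <- function(xm, gamma, beta, rmean, rvar, training) {
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    inv <- 1 / sqrt(va + BN_EPS)
    xhat <- xc * inv
    m <- ncol(xm)
    ub <- if (m > 1L) va * m / (m - 1L) else va   # unbiased, as running stat
    new_mean <- (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu
    new_var <- (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * ub
    list(y = xhat * gamma + beta, xhat = xhat, inv = inv,
         mean = new_mean, var = new_var)
  } else {
    inv <- 1 / sqrt(rvar + BN_EPS)
    xhat <- (xm - rmean) * inv
    list(y = xhat * gamma + beta, xhat = xhat, inv = inv,
         mean = rmean, var = rvar)
  }
}

bn_bwd <- function(dy, cache, gamma, training) {
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  if (training) {
    m <- ncol(dy)
    dx <- (gamma * cache$inv) *
      (dy - dbeta / m - cache$xhat * (dgamma / m))
  } else {
    dx <- dy * (gamma * cache$inv)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_mask <- function(dims, p) {
  if (p <= 0) return(NULL)
  array((stats::runif(prod(dims)) >= p) / (1 - p), dim = dims)
}

## Forward pass. x3: (n_mels, T_frames, N). Returns heads and, when
## keep_cache, everything the backward pass needs.
nn_forward <- function(model, x3, training = FALSE, keep_cache = training) {
  cfg <- model$cfg
  params <- model$params
  run <- model$run
  d <- dim(x3)
  n_mels <- d[1L]; n_frames <- d[2L]; n <- d[3L]
  cache <- list(training = training, in_dim = d)

  # input band normalization (one BN channel per mel band)
  xm <- matrix(x3, nrow = n_mels)
  bn0 <- bn_fwd(xm, params[["bn0.gamma"]], params[["bn0.beta"]],
                run[["bn0.mean"]], run[["bn0.var"]], training)
  if (training) { run[["bn0.mean"]] <- bn0$mean; run[["bn0.var"]] <- bn0$var }
  if (keep_cache) cache$bn0 <- bn0[c("xhat", "inv")]
  x <- array(bn0$y, dim = c(1L, n_mels, n_frames, n))

  p_drop <- cfg$dropout
  for (i in seq_len(cfg$n_blocks)) {
    for (j in 1:2) {
      key <- sprintf("b%d.conv%d", i, j)
      bnk <- sprintf("b%d.bn%d", i, j)
      if (keep_cache) cache[[paste0(key, ".x")]] <- x
      y <- .conv2d_fwd(x, params[[paste0(key, ".W")]], params[[paste0(key, ".b")]])
      co <- dim(y)[1L]
      bn <- bn_fwd(matrix(y, nrow = co), params[[paste0(bnk, ".gamma")]],
                   params[[paste0(bnk, ".beta")]], run[[paste0(bnk, ".mean")]],
                   run[[paste0(bnk, ".var")]], training)
      if (training) {
        run[[paste0(bnk, ".mean")]] <- bn$mean
        run[[paste0(bnk, ".var")]] <- bn$var
      }
      if (keep_cache) cache[[paste0(bnk, ".c")]] <- bn[c("xhat", "inv")]
      x <- array(pmax(bn$y, 0), dim = dim(y))
      if (keep_cache) cache[[paste0(bnk, ".relu")]] <- x > 0
    }
    if (i < cfg$n_blocks) {
      if (keep_cache) cache[[sprintf("b%d.predim", i)]] <- dim(x)
      x <- .avgpool2_fwd(x)
      if (training && p_drop > 0) {
        mk <- dropout_mask(dim(x), p_drop)
        x <- x * mk
        if (keep_cache) cache[[sprintf("b%d.drop", i)]] <- mk
      }
    }
  }

  # frequency reduction: average over mel
  dd <- dim(x)
  C <- dd[1L]; Hh <- dd[2L]; Wt <- dd[3L]
  x3d <- array(x, dim = c(C, Hh, Wt * n))
  fm <- matrix(0, C, Wt * n)
  for (h in seq_len(Hh)) fm <- fm + x3d[, h, , drop = TRUE]
  f <- array(fm / Hh, dim = c(C, Wt, n))
  if (keep_cache) cache$freq_h <- Hh

  tp <- .timepool3_fwd(f)
  if (keep_cache) cache$tp_argmax <- tp$argmax
  z <- tp$y
  if (training && p_drop > 0) {
    mk <- dropout_mask(dim(z), p_drop)
    z <- z * mk
    if (keep_cache) cache$drop_tp <- mk
  }
  if (keep_cache) cache$fc_x <- z

  zm <- matrix(z, nrow = C)                       # C x (T' * N)
  fcz <- params[["fc.W"]] %*% zm + params[["fc.b"]]
  feat <- pmax(fcz, 0)
  if (keep_cache) cache$fc_relu <- feat > 0
  if (training && p_drop > 0) {
    mk <- matrix(dropout_mask(dim(feat), p_drop), nrow(feat))
    feat <- feat * mk
    if (keep_cache) cache$drop_fc <- mk
  }
  if (keep_cache) cache$feat <- feat

  Tseg <- dim(z)[2L]
  zp <- drop(crossprod(params[["att_p.w"]], feat)) + params[["att_p.b"]]
  zv <- drop(crossprod(params[["att_v.w"]], feat)) + params[["att_v.b"]]
  p <- matrix(1 / (1 + exp(-zp)), Tseg, n)
  v <- matrix(tanh(zv), Tseg, n)
  ev <- exp(v - rep(apply(v, 2L, max), each = Tseg))
  g <- ev / rep(colSums(ev), each = Tseg)
  clip_p <- colSums(g * p)

  list(p = p, v = v, g = g, clip_p = clip_p,
       features = array(feat, dim = c(cfg$fc_width, Tseg, n)),
       run = run, cache = if (keep_cache) cache else NULL)
}

## Backward pass from head gradients. dp, dv: (T', N) gradients w.r.t. the
## post-activation outputs p(x_i) and v(x_i); dclip: optional gradient w.r.t.
## clip_p, folded through Eq. 1-2. Returns parameter gradients and, when
## want_dx, the gradient w.r.t. the input spectrogram array.
nn_backward <- function(model, out, dp = NULL, dv = NULL, dclip = NULL,
                        want_dx = FALSE) {
  cfg <- model$cfg
  params <- model$params
  cache <- out$cache
  training <- cache$training
  Tseg <- nrow(out$p); n <- ncol(out$p)
  if (is.null(dp)) dp <- matrix(0, Tseg, n)
  if (is.null(dv)) dv <- matrix(0, Tseg, n)
  if (!is.null(dclip)) {
    dp <- dp + out$g * rep(dclip, each = Tseg)
    dg <- out$p * rep(dclip, each = Tseg)
    # softmax backward
    dv <- dv + out$g * (dg - rep(colSums(dg * out$g), each = Tseg))
  }
  grads <- list()

  dzp <- dp * out$p * (1 - out$p)
  dzv <- dv * (1 - out$v * out$v)
  feat <- cache$feat                                # fc_width x (T'*N)
  dzp_f <- as.numeric(dzp); dzv_f <- as.numeric(dzv)
  grads[["att_p.w"]] <- drop(feat %*% dzp_f)
  grads[["att_p.b"]] <- sum(dzp_f)
  grads[["att_v.w"]] <- drop(feat %*% dzv_f)
  grads[["att_v.b"]] <- sum(dzv_f)
  dfeat <- outer(params[["att_p.w"]], dzp_f) + outer(params[["att_v.w"]], dzv_f)

  if (!is.null(cache$drop_fc)) dfeat <- dfeat * cache$drop_fc
  dfcz <- dfeat * cache$fc_relu
  zm <- matrix(cache$fc_x, nrow = ncol(params[["fc.W"]]))
  grads[["fc.W"]] <- dfcz %*% t(zm)
  grads[["fc.b"]] <- rowSums(dfcz)
  dz <- t(params[["fc.W"]]) %*% dfcz                # C x (T'*N)
  C <- nrow(dz)
  dz <- array(dz, dim = c(C, Tseg, n))
  if (!is.null(cache$drop_tp)) dz <- dz * cache$drop_tp
  df <- .timepool3_bwd(dz, cache$tp_argmax)

  # frequency-average backward
  Hh <- cache$freq_h
  dfm <- matrix(df, nrow = C) / Hh                  # C x (T'*N)
  dx3 <- array(0, dim = c(C, Hh, Tseg * n))
  for (h in seq_len(Hh)) dx3[, h, ] <- dfm
  dx <- array(dx3, dim = c(C, Hh, Tseg, n))

  for (i in rev(seq_len(cfg$n_blocks))) {
    if (i < cfg$n_blocks) {
      mk <- cache[[sprintf("b%d.drop", i)]]
      if (!is.null(mk)) dx <- dx * mk
      pre <- cache[[sprintf("b%d.predim", i)]]
      dx <- .avgpool2_bwd(dx, pre[2L], pre[3L])
    }
    for (j in 2:1) {
      key <- sprintf("b%d.conv%d", i, j)
      bnk <- sprintf("b%d.bn%d", i, j)
      dd <- dim(dx)
      dy <- dx * cache[[paste0(bnk, ".relu")]]
      bb <- bn_bwd(matrix(dy, nrow = dd[1L]), cache[[paste0(bnk, ".c")]],
                   params[[paste0(bnk, ".gamma")]], training)
      grads[[paste0(bnk, ".gamma")]] <- bb$dgamma
      grads[[paste0(bnk, ".beta")]] <- bb$dbeta
      dconv <- array(bb$dx, dim = dd)
      cb <- .conv2d_bwd(cache[[paste0(key, ".x")]], params[[paste0(key, ".W")]],
                        dconv)
      grads[[paste0(key, ".W")]] <- cb$dw
      grads[[paste0(key, ".b")]] <- cb$db
      dx <- cb$dx
    }
  }

  # input band normalization backward
  d0 <- cache$in_dim
  bb <- bn_bwd(matrix(dx, nrow = d0[1L]), cache$bn0, params[["bn0.gamma"]],
               training)
  grads[["bn0.gamma"]] <- bb$dgamma
  grads[["bn0.beta"]] <- bb$dbeta
  if (want_dx) grads$dx <- array(bb$dx, dim = d0)
  grads
}

## Decoupled-weight-decay Adam (AdamW), PyTorch defaults otherwise.
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.005,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    step <- (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    params[[k]] <- params[[k]] - lr * (step + weight_decay * params[[k]])
  }
  list(params = params, state = state)
}
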