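# Minimal feed-forward neural-network engine: dense and valid 3x3-style
# convolution layers with hand-derived backprop, 2x2 max pooling, ReLU /
# sigmoid, and SGD-with-momentum / Adam optimizers. Everything is plain
# base R on top of BLAS matrix products (convolution via im2col), which is
# ample for the low-complexity encoders this package trains.
#
# Parameter sets are flat named lists of numeric arrays ("conv1.W", ...);
# gradients mirror the subset of parameters being trained, so frozen
# sub-networks are simply never touched by the optimizer.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results within 32-bit range.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) * 1009 + as.double(k) * 9176) %% 2147483629
  as.integer(s) + 1L
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

nn_softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Binary cross-entropy on probabilities, clamped away from 0/1.
nn_bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

tt_mse <- function(x, r) mean((x - r)^2)

## ---- dense layers -----------------------------------------------------

nn_dense_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(
    W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
    b = numeric(n_out)
  )
}

nn_dense_fwd <- function(X, W, b) {
  X %*% W + rep(b, each = nrow(X))
}

# Returns gradients w.r.t. weights, bias and input.
nn_dense_bwd <- function(X, W, dY) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = tcrossprod(dY, W))
}

## ---- convolution (valid, stride 1) ------------------------------------

nn_conv_init <- function(k, c_in, c_out) {
  fan_in <- k * k * c_in
  list(
    W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
               fan_in, c_out),
    b = numeric(c_out)
  )
}

# X: array (N, H, W, C) -> matrix (N*Ho*Wo, k*k*C); column blocks are
# ordered offset-major, channel-minor, matching nn_conv_init's row layout.
nn_im2col <- function(X, k) {
  d <- dim(X)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Ho <- H - k + 1; Wo <- W - k + 1
  cols <- matrix(0, N * Ho * Wo, k * k * C)
  idx <- 0L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      sl <- X[, di + seq_len(Ho), dj + seq_len(Wo), , drop = FALSE]
      cols[, idx + seq_len(C)] <- matrix(sl, N * Ho * Wo, C)
      idx <- idx + C
    }
  }
  cols
}

# Scatter-add column gradients back onto the input array.
nn_col2im <- function(dcols, dimX, k) {
  N <- dimX[1]; H <- dimX[2]; W <- dimX[3]; C <- dimX[4]
  Ho <- H - k + 1; Wo <- W - k + 1
  dX <- array(0, dimX)
  idx <- 0L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      block <- array(dcols[, idx + seq_len(C)], c(N, Ho, Wo, C))
      dX[, di + seq_len(Ho), dj + seq_len(Wo), ] <-
        dX[, di + seq_len(Ho), dj + seq_len(Wo), , drop = FALSE] + block
      idx <- idx + C
    }
  }
  dX
}

nn_conv_fwd <- function(X, W, b, k) {
  d <- dim(X)
  Ho <- d[2] - k + 1; Wo <- d[3] - k + 1
  cols <- nn_im2col(X, k)
  Z <- cols %*% W + rep(b, each = nrow(cols))
  list(Y = array(Z, c(d[1], Ho, Wo, ncol(W))), cols = cols, dimX = d)
}

nn_conv_bwd <- function(cache, W, dY, k) {
  dYm <- matrix(dY, nrow = nrow(cache$cols))
  dcols <- tcrossprod(dYm, W)
  list(
    dW = crossprod(cache$cols, dYm),
    db = colSums(dYm),
    dX = nn_col2im(dcols, cache$dimX, k)
  )
}

## ---- 2x2 max pooling, stride 2 ----------------------------------------

# Trailing odd rows/columns are cropped (their gradient is zero). Ties take
# the first cell in a fixed (top-left, bottom-left, top-right, bottom-right)
# order so backprop is deterministic.
nn_pool_fwd <- function(X) {
  d <- dim(X)
  H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  io <- seq(1L, 2L * H2, 2L); ie <- io + 1L
  jo <- seq(1L, 2L * W2, 2L); je <- jo + 1L
  s <- list(
    X[, io, jo, , drop = FALSE],
    X[, ie, jo, , drop = FALSE],
    X[, io, je, , drop = FALSE],
    X[, ie, je, , drop = FALSE]
  )
  Y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  sel <- array(1L, dim(Y))
  taken <- s[[1]] == Y
  for (kidx in 2:4) {
    m <- !taken & s[[kidx]] == Y
    sel[m] <- kidx
    taken <- taken | m
  }
  list(Y = Y, sel = sel, dimX = d)
}

nn_pool_bwd <- function(cache, dY) {
  d <- dim(dY)
  H2 <- d[2]; W2 <- d[3]
  rows <- list(seq(1L, 2L * H2, 2L), seq(2L, 2L * H2, 2L),
               seq(1L, 2L * H2, 2L), seq(2L, 2L * H2, 2L))
  colsj <- list(seq(1L, 2L * W2, 2L), seq(1L, 2L * W2, 2L),
                seq(2L, 2L * W2, 2L), seq(2L, 2L * W2, 2L))
  dX <- array(0, cache$dimX)
  for (kidx in 1:4) {
    g <- dY * (cache$sel == kidx)
    dX[, rows[[kidx]], colsj[[kidx]], ] <-
      dX[, rows[[kidx]], colsj[[kidx]], , drop = FALSE] + g
  }
  dX
}

## ---- optimizers -------------------------------------------------------

nn_opt_init <- function(params, optimizer) {
  if (!optimizer %in% c("SGD", "Adam")) {
    tt_stop("ConfigError", sprintf("unknown optimizer '%s'", optimizer))
  }
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  if (optimizer == "SGD") {
    list(name = "SGD", v = zeros, t = 0L)
  } else {
    list(name = "Adam", m = zeros, v = zeros, t = 0L)
  }
}

# One optimizer step over the parameters named in `grads`. The learning
# rate decays multiplicatively per step: lr_t = lr * (1 - decay)^t.
# `l2` adds a weight-decay gradient l2 * parameter (biases included).
nn_opt_step <- function(params, grads, opt, lr, momentum = 0.9, decay = 0,
                        l2 = 0) {
  if (l2 > 0) {
    for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + l2 * params[[nm]]
  }
  lr_t <- lr * (1 - decay)^opt$t
  if (opt$name == "SGD") {
    for (nm in names(grads)) {
      opt$v[[nm]] <- momentum * opt$v[[nm]] - lr_t * grads[[nm]]
      params[[nm]] <- params[[nm]] + opt$v[[nm]]
    }
  } else {
    b1 <- momentum; b2 <- 0.999; eps <- 1e-8
    tn <- opt$t + 1L
    for (nm in names(grads)) {
      g <- grads[[nm]]
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[nm]] / (1 - b1^tn)
      vhat <- opt$v[[nm]] / (1 - b2^tn)
      params[[nm]] <- params[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
    }
  }
  opt$t <- opt$t + 1L
  list(params = params, opt = opt)
}

# Seeded per-epoch mini-batch index sets.
nn_batches <- function(n, batch_size, seed) {
  ord <- with_seed(seed, sample.int(n))
  split(ord, ceiling(seq_along(ord) / batch_size))
}
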