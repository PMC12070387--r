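#' Configuration of the convolutional image encoder
#'
#' The image tower is a low-complexity CNN: three blocks of (valid
#' convolution, 2x2 max pooling, ReLU) followed by dense layers of 32 and
#' 16 nodes. Its 16-dimensional output is the image feature vector fed to
#' the fusion head; a detachable single-sigmoid unit on top serves stage-1
#' training and the image-only ablation model.
#'
#' @param input_channels Number of input channels (default 5: T1, T2,
#'   T1ce, FLAIR, SEG).
#' @param input_size Input height/width in pixels (default 240).
#' @param conv_filters Integer vector of exactly 3 filter counts
#'   (default `c(8, 16, 32)`).
#' @param kernel_size Convolution kernel size (default 3).
#' @param pool_size Max-pooling window (only 2 is supported).
#' @param dense_nodes Widths of the two dense layers; the final width must
#'   be 16 (the image feature dimension).
#' @param seed Integer seed for deterministic initialization.
#' @return An `image_tower_config` object.
#' @export
image_tower_config <- function(input_channels = 5L, input_size = 240L,
                               conv_filters = c(8L, 16L, 32L),
                               kernel_size = 3L, pool_size = 2L,
                               dense_nodes = c(32L, 16L), seed = 1L) {
  tt_assert(length(conv_filters) == 3, "ConfigError",
            "exactly 3 convolutional blocks are required")
  tt_assert(all(c(input_channels, input_size, conv_filters, kernel_size,
                  dense_nodes) > 0), "ConfigError",
            "all dimensions must be positive")
  tt_assert(pool_size == 2, "ConfigError", "only pool_size = 2 is supported")
  tt_assert(length(dense_nodes) == 2 && dense_nodes[2] == 16, "ConfigError",
            "dense head must have two layers ending in 16 features")
  cfg <- structure(
    list(input_channels = as.integer(input_channels),
         input_size = as.integer(input_size),
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         pool_size = 2L,
         dense_nodes = as.integer(dense_nodes),
         seed = as.integer(seed)),
    class = "image_tower_config"
  )
  tt_assert(img_map_size(cfg) > 0, "ConfigError",
            "input_size too small for three conv/pool blocks")
  cfg
}

# Spatial size after the three conv/pool blocks, and flattened width.
img_map_size <- function(cfg) {
  s <- cfg$input_size
  for (i in 1:3) s <- (s - cfg$kernel_size + 1L) %/% 2L
  s
}

img_flat_size <- function(cfg) {
  img_map_size(cfg)^2 * cfg$conv_filters[3]
}

#' Initialize an image tower
#'
#' Parameters are drawn deterministically from `config$seed` (He-normal
#' for convolutions, Glorot-uniform for dense layers). The returned state
#' is unfrozen.
#'
#' @param config An [image_tower_config].
#' @return An `image_tower` state: list with `params`, `config`, `frozen`,
#'   and an empty training `history`.
#' @export
init_image_tower <- function(config = image_tower_config()) {
  stopifnot(inherits(config, "image_tower_config"))
  k <- config$kernel_size
  f <- config$conv_filters
  params <- with_seed(config$seed, {
    c1 <- nn_conv_init(k, config$input_channels, f[1])
    c2 <- nn_conv_init(k, f[1], f[2])
    c3 <- nn_conv_init(k, f[2], f[3])
    d1 <- nn_dense_init(img_flat_size(config), config$dense_nodes[1])
    d2 <- nn_dense_init(config$dense_nodes[1], config$dense_nodes[2])
    # down-scaled output unit: untrained classification stays near 0.5
    cl <- nn_dense_init(config$dense_nodes[2], 1L)
    cl$W <- cl$W * 0.1
    list(
      "conv1.W" = c1$W, "conv1.b" = c1$b,
      "conv2.W" = c2$W, "conv2.b" = c2$b,
      "conv3.W" = c3$W, "conv3.b" = c3$b,
      "dense1.W" = d1$W, "dense1.b" = d1$b,
      "dense2.W" = d2$W, "dense2.b" = d2$b,
      "cls.W" = cl$W, "cls.b" = cl$b
    )
  })
  structure(
    list(params = params, config = config, frozen = FALSE, history = list()),
    class = "image_tower"
  )
}

# Batch of slice stacks -> array (N, H, W, C). Accepts a single
# slice_stack, a list of them, or a ready-made (N, C, H, W) array.
img_batch_array <- function(batch, cfg) {
  if (inherits(batch, "slice_stack")) batch <- list(batch)
  if (is.list(batch)) {
    X <- array(0, c(length(batch), cfg$input_size, cfg$input_size,
                    cfg$input_channels))
    for (i in seq_along(batch)) {
      px <- batch[[i]]$pixels
      tt_assert(length(dim(px)) == 3 &&
                  all(dim(px) == c(cfg$input_channels, cfg$input_size,
                                   cfg$input_size)),
                "ShapeMismatchError",
                sprintf("slice stack %d has shape (%s); expected (%d, %d, %d)",
                        i, paste(dim(px), collapse = ", "),
                        cfg$input_channels, cfg$input_size, cfg$input_size))
      X[i, , , ] <- aperm(px, c(2, 3, 1))
    }
    X
  } else {
    tt_assert(length(dim(batch)) == 4 &&
                all(dim(batch)[-1] == c(cfg$input_channels, cfg$input_size,
                                        cfg$input_size)),
              "ShapeMismatchError", "batch array must be (N, C, H, W)")
    aperm(batch, c(1, 3, 4, 2))
  }
}

# Full forward pass; caches all intermediates needed for backprop.
img_forward <- function(params, X, cfg) {
  k <- cfg$kernel_size
  caches <- vector("list", 3)
  A <- X
  for (i in 1:3) {
    cv <- nn_conv_fwd(A, params[[paste0("conv", i, ".W")]],
                      params[[paste0("conv", i, ".b")]], k)
    pl <- nn_pool_fwd(cv$Y)
    A <- pmax(pl$Y, 0)
    caches[[i]] <- list(conv = cv, pool = pl, pre_relu = pl$Y)
  }
  flat <- matrix(A, nrow = dim(A)[1])
  h1 <- nn_dense_fwd(flat, params$`dense1.W`, params$`dense1.b`)
  h1r <- pmax(h1, 0)
  feats <- nn_dense_fwd(h1r, params$`dense2.W`, params$`dense2.b`)
  logits <- nn_dense_fwd(feats, params$`cls.W`, params$`cls.b`)
  list(features = feats, logits = logits, flat = flat, h1 = h1, h1r = h1r,
       dimA3 = dim(A), caches = caches)
}

# Backprop from gradients on logits (and/or directly on features).
img_backward <- function(params, fwd, cfg, dlogits = NULL, dfeats = NULL) {
  grads <- list()
  if (is.null(dfeats)) dfeats <- matrix(0, nrow(fwd$features), ncol(fwd$features))
  if (!is.null(dlogits)) {
    g <- nn_dense_bwd(fwd$features, params$`cls.W`, dlogits)
    grads$`cls.W` <- g$dW; grads$`cls.b` <- g$db
    dfeats <- dfeats + g$dX
  }
  g2 <- nn_dense_bwd(fwd$h1r, params$`dense2.W`, dfeats)
  grads$`dense2.W` <- g2$dW; grads$`dense2.b` <- g2$db
  dh1 <- g2$dX * (fwd$h1 > 0)
  g1 <- nn_dense_bwd(fwd$flat, params$`dense1.W`, dh1)
  grads$`dense1.W` <- g1$dW; grads$`dense1.b` <- g1$db
  dA <- array(g1$dX, fwd$dimA3)
  for (i in 3:1) {
    ch <- fwd$caches[[i]]
    dpre <- dA * (ch$pre_relu > 0)
    dz <- nn_pool_bwd(ch$pool, dpre)
    gc_ <- nn_conv_bwd(ch$conv, params[[paste0("conv", i, ".W")]], dz,
                       cfg$kernel_size)
    grads[[paste0("conv", i, ".W")]] <- gc_$dW
    grads[[paste0("conv", i, ".b")]] <- gc_$db
    dA <- gc_$dX
  }
  grads
}

#' Encode tumor slices into 16-dimensional image features
#'
#' Runs the forward pass of the image tower up to (and including) the
#' 16-node dense layer. Each sample's features depend only on its own
#' pixels, so results are independent of batch composition.
#'
#' @param state An `image_tower` state.
#' @param batch A `slice_stack`, a list of them, or an `(N, C, H, W)`
#'   array matching the tower's configuration.
#' @return Numeric matrix `N x 16` of image features.
#' @export
encode_image <- function(state, batch) {
  stopifnot(inherits(state, "image_tower"))
  X <- img_batch_array(batch, state$config)
  img_forward(state$params, X, state$config)$features
}

#' Stage-1 image classification probabilities
#'
#' Applies the detachable sigmoid unit on top of the 16 image features,
#' yielding the per-sample probability of a positive therapy response.
#' Used for stage-1 tower training and as the image-only ablation model.
#'
#' @inheritParams encode_image
#' @return Numeric vector of probabilities in (0, 1).
#' @export
image_classify <- function(state, batch) {
  stopifnot(inherits(state, "image_tower"))
  X <- img_batch_array(batch, state$config)
  as.vector(nn_sigmoid(img_forward(state$params, X, state$config)$logits))
}

#' Freeze or unfreeze an encoder tower
#'
#' A frozen tower is left bit-identical by any training routine; this is
#' the transfer-learning contract of stage 2, where only the fusion head
#' is tuned.
#'
#' @param state An `image_tower` or `gene_tower` state.
#' @param frozen Logical.
#' @return The state with its `frozen` flag set.
#' @export
freeze_tower <- function(state, frozen = TRUE) {
  stopifnot(inherits(state, "image_tower") || inherits(state, "gene_tower"))
  state$frozen <- isTRUE(frozen)
  state
}

#' Save or load an encoder/fusion checkpoint
#'
#' Checkpoints bundle parameters and configuration in one file; loading
#' restores bit-identical forward passes.
#'
#' @param state A tower or fusion-head state (or a full `twin_tower`
#'   model).
#' @param path File path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the
#'   restored state.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}

#' @export
print.image_tower <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 1L))
  cat("Image tower (CNN encoder)\n")
  cat(sprintf("  input: %d x %d x %d; conv filters: %s; dense: %s -> 16 features\n",
              cfg$input_channels, cfg$input_size, cfg$input_size,
              paste(cfg$conv_filters, collapse = "/"),
              cfg$dense_nodes[1]))
  cat(sprintf("  parameters: %d; frozen: %s\n", n_par, x$frozen))
  invisible(x)
}
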