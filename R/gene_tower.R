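#' Configuration of the autoencoder gene tower
#'
#' The gene tower compresses an expression profile through a dense
#' encoder (64, then 32 nodes); the 32-dimensional bottleneck activation
#' is the gene feature vector consumed by the fusion head. The decoder
#' mirrors the encoder (32, 64 nodes, linear output) and is trained by
#' mean-squared-error reconstruction. A classifier head (64, 16 nodes,
#' single sigmoid) attached to the bottleneck serves stage-1 supervised
#' training and the gene-only ablation model.
#'
#' @param input_dim Number of genes per profile (19196 for the full
#'   TCGA-derived panel; any positive value is accepted).
#' @param encoder_nodes Encoder layer widths (default `c(64, 32)`); the
#'   second entry is the bottleneck width, which must be 32 unless
#'   `strict = FALSE`.
#' @param decoder_nodes Decoder layer widths; must mirror the encoder.
#' @param classifier_nodes Classifier head widths (default `c(64, 16)`).
#' @param seed Integer seed for deterministic initialization.
#' @param strict Enforce the canonical 32-wide bottleneck (default TRUE).
#' @return A `gene_tower_config` object.
#' @export
gene_tower_config <- function(input_dim, encoder_nodes = c(64L, 32L),
                              decoder_nodes = rev(encoder_nodes),
                              classifier_nodes = c(64L, 16L), seed = 1L,
                              strict = TRUE) {
  tt_assert(length(input_dim) == 1 && input_dim >= 1, "ConfigError",
            "input_dim must be a positive integer")
  tt_assert(length(encoder_nodes) == 2 && all(encoder_nodes > 0),
            "ConfigError", "encoder needs two positive layer widths")
  tt_assert(all(decoder_nodes == rev(encoder_nodes)), "ConfigError",
            "decoder must mirror the encoder")
  if (strict) {
    tt_assert(encoder_nodes[2] == 32, "ConfigError",
              "bottleneck width must be 32 (use strict = FALSE to override)")
  }
  structure(
    list(input_dim = as.integer(input_dim),
         encoder_nodes = as.integer(encoder_nodes),
         decoder_nodes = as.integer(decoder_nodes),
         classifier_nodes = as.integer(classifier_nodes),
         seed = as.integer(seed)),
    class = "gene_tower_config"
  )
}

#' Initialize a gene tower
#'
#' @param config A [gene_tower_config].
#' @return A `gene_tower` state: list with `params`, `config`, `frozen`,
#'   `pre` (input preprocessing statistics, `NULL` until fitted by
#'   [train_stage1_gene]) and an empty `history`.
#' @export
init_gene_tower <- function(config) {
  stopifnot(inherits(config, "gene_tower_config"))
  e <- config$encoder_nodes
  cl <- config$classifier_nodes
  params <- with_seed(config$seed, {
    enc1 <- nn_dense_init(config$input_dim, e[1])
    enc2 <- nn_dense_init(e[1], e[2])
    dec1 <- nn_dense_init(e[2], e[1])
    dec2 <- nn_dense_init(e[1], config$input_dim)
    cls1 <- nn_dense_init(e[2], cl[1])
    cls2 <- nn_dense_init(cl[1], cl[2])
    # down-scaled output unit: untrained probabilities stay near 0.5
    cls3 <- nn_dense_init(cl[2], 1L)
    cls3$W <- cls3$W * 0.1
    list(
      "enc1.W" = enc1$W, "enc1.b" = enc1$b,
      "enc2.W" = enc2$W, "enc2.b" = enc2$b,
      "dec1.W" = dec1$W, "dec1.b" = dec1$b,
      "dec2.W" = dec2$W, "dec2.b" = dec2$b,
      "cls1.W" = cls1$W, "cls1.b" = cls1$b,
      "cls2.W" = cls2$W, "cls2.b" = cls2$b,
      "cls3.W" = cls3$W, "cls3.b" = cls3$b
    )
  })
  structure(
    list(params = params, config = config, frozen = FALSE, pre = NULL,
         history = list()),
    class = "gene_tower"
  )
}

# Fit the input transform (log1p then per-gene standardization) on raw
# training expression; stored on the state and reused everywhere after.
fit_gene_preprocess <- function(X, log_transform = TRUE) {
  if (log_transform) X <- log1p(X)
  mu <- colMeans(X)
  sd_ <- pmax(apply(X, 2, stats::sd), 1e-8)
  list(log_transform = log_transform, mean = mu, sd = sd_)
}

gene_preprocess <- function(state, X) {
  if (is.null(state$pre)) return(X)
  if (state$pre$log_transform) X <- log1p(X)
  n <- nrow(X)
  (X - rep(state$pre$mean, each = n)) / rep(state$pre$sd, each = n)
}

# Accepts a vector (one profile) or an N x input_dim matrix; applies the
# fitted preprocessing.
gene_batch_matrix <- function(state, batch, preprocess = TRUE) {
  if (is.null(dim(batch))) batch <- matrix(batch, nrow = 1)
  tt_assert(ncol(batch) == state$config$input_dim, "ShapeMismatchError",
            sprintf("gene vectors have length %d; tower expects %d",
                    ncol(batch), state$config$input_dim))
  if (preprocess) gene_preprocess(state, batch) else batch
}

gene_forward_ae <- function(params, X) {
  h1 <- pmax(nn_dense_fwd(X, params$`enc1.W`, params$`enc1.b`), 0)
  z_pre <- nn_dense_fwd(h1, params$`enc2.W`, params$`enc2.b`)
  z <- pmax(z_pre, 0)
  d1 <- pmax(nn_dense_fwd(z, params$`dec1.W`, params$`dec1.b`), 0)
  recon <- nn_dense_fwd(d1, params$`dec2.W`, params$`dec2.b`)
  list(h1 = h1, z_pre = z_pre, z = z, d1 = d1, recon = recon)
}

gene_backward_ae <- function(params, fwd, X, drecon) {
  g4 <- nn_dense_bwd(fwd$d1, params$`dec2.W`, drecon)
  dd1 <- g4$dX * (fwd$d1 > 0)
  g3 <- nn_dense_bwd(fwd$z, params$`dec1.W`, dd1)
  dz <- g3$dX * (fwd$z_pre > 0)
  g2 <- nn_dense_bwd(fwd$h1, params$`enc2.W`, dz)
  dh1 <- g2$dX * (fwd$h1 > 0)
  g1 <- nn_dense_bwd(X, params$`enc1.W`, dh1)
  list(
    "dec2.W" = g4$dW, "dec2.b" = g4$db,
    "dec1.W" = g3$dW, "dec1.b" = g3$db,
    "enc2.W" = g2$dW, "enc2.b" = g2$db,
    "enc1.W" = g1$dW, "enc1.b" = g1$db
  )
}

gene_forward_cls <- function(params, z) {
  c1 <- pmax(nn_dense_fwd(z, params$`cls1.W`, params$`cls1.b`), 0)
  c2 <- pmax(nn_dense_fwd(c1, params$`cls2.W`, params$`cls2.b`), 0)
  logits <- nn_dense_fwd(c2, params$`cls3.W`, params$`cls3.b`)
  list(c1 = c1, c2 = c2, logits = logits)
}

#' Reconstruct expression profiles through the autoencoder
#'
#' Profiles are passed through the fitted input transform, the encoder and
#' the mirrored decoder; the mean squared error is computed in the
#' transformed space the autoencoder is trained in.
#'
#' @param state A `gene_tower` state.
#' @param batch A numeric vector (one profile) or `N x input_dim` matrix
#'   of raw expression values.
#' @return A list with `reconstructions` (matrix, transformed space) and
#'   the scalar `mse`.
#' @export
reconstruct <- function(state, batch) {
  stopifnot(inherits(state, "gene_tower"))
  X <- gene_batch_matrix(state, batch)
  fwd <- gene_forward_ae(state$params, X)
  list(reconstructions = fwd$recon, mse = tt_mse(X, fwd$recon))
}

#' Encode expression profiles into 32-dimensional gene features
#'
#' Returns the bottleneck activations of the autoencoder: the compressed
#' representation consumed by the fusion head.
#'
#' @inheritParams reconstruct
#' @return Numeric matrix `N x 32` of gene features.
#' @export
encode_gene <- function(state, batch) {
  stopifnot(inherits(state, "gene_tower"))
  X <- gene_batch_matrix(state, batch)
  gene_forward_ae(state$params, X)$z
}

#' Stage-1 gene classification probabilities
#'
#' Applies the classifier head (64, 16 nodes, sigmoid output) attached to
#' the autoencoder bottleneck. This is the gene-only ablation model.
#'
#' @inheritParams reconstruct
#' @return Numeric vector of probabilities in (0, 1).
#' @export
gene_classify <- function(state, batch) {
  stopifnot(inherits(state, "gene_tower"))
  X <- gene_batch_matrix(state, batch)
  z <- gene_forward_ae(state$params, X)$z
  as.vector(nn_sigmoid(gene_forward_cls(state$params, z)$logits))
}

#' @export
print.gene_tower <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 1L))
  cat("Gene tower (autoencoder)\n")
  cat(sprintf("  input: %d genes; encoder: %s (bottleneck %d); classifier head: %s -> 1\n",
              cfg$input_dim, paste(cfg$encoder_nodes, collapse = "/"),
              cfg$encoder_nodes[2],
              paste(cfg$classifier_nodes, collapse = "/")))
  cat(sprintf("  parameters: %d; frozen: %s; preprocessing fitted: %s\n",
              n_par, x$frozen, !is.null(x$pre)))
  invisible(x)
}
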