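#' Fit a per-dimension Gaussian feature scaler
#'
#' Stores per-column sample means and standard deviations so features can
#' be standardized to zero mean and unit variance. Standard deviations are
#' floored at `eps` so constant columns map to zero rather than NaN.
#' The image and gene feature blocks are scaled separately, each with a
#' scaler fitted on stage-2 *training* features only.
#'
#' @param features Numeric matrix with at least 2 rows.
#' @param eps Lower floor for the standard deviation (default 1e-8).
#' @return A `feature_scaler` object.
#' @export
fit_scaler <- function(features, eps = 1e-8) {
  features <- as.matrix(features)
  tt_assert(nrow(features) >= 2, "ScalerError",
            "at least 2 rows are required to fit a scaler")
  structure(
    list(mean = colMeans(features),
         sd = pmax(apply(features, 2, stats::sd), eps),
         eps = eps),
    class = "feature_scaler"
  )
}

#' Apply / invert a fitted feature scaler
#'
#' @param scaler A [fit_scaler] result.
#' @param features Numeric matrix with matching column count.
#' @return The standardized (or de-standardized) matrix.
#' @export
scale_features <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  features <- as.matrix(features)
  tt_assert(ncol(features) == length(scaler$mean), "ShapeMismatchError",
            "feature width does not match the fitted scaler")
  n <- nrow(features)
  (features - rep(scaler$mean, each = n)) / rep(scaler$sd, each = n)
}

#' @rdname scale_features
#' @export
unscale_features <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  features <- as.matrix(features)
  n <- nrow(features)
  features * rep(scaler$sd, each = n) + rep(scaler$mean, each = n)
}

#' Configuration of the fusion/classification head
#'
#' In `concat` mode (the default) the standardized 16 image features and
#' 32 gene features are concatenated (width 48) and classified by an MLP
#' with 64, 128 and 16 nodes followed by a single sigmoid output unit. In
#' `moe` mode a softmax gating network over the 48-dimensional input
#' weights `n_experts` expert MLPs (same widths); the prediction is the
#' gate-weighted mean of the expert sigmoid outputs.
#'
#' @param mode `"concat"` or `"moe"`.
#' @param head_nodes Hidden widths of the classification MLP / experts
#'   (default `c(64, 128, 16)`).
#' @param n_experts Number of experts in `moe` mode (default 2).
#' @param image_dim,gene_dim Widths of the incoming feature blocks
#'   (defaults 16 and 32).
#' @param seed Integer seed for deterministic initialization.
#' @return A `fusion_config` object.
#' @export
fusion_config <- function(mode = c("concat", "moe"),
                          head_nodes = c(64L, 128L, 16L), n_experts = 2L,
                          image_dim = 16L, gene_dim = 32L, seed = 1L) {
  mode <- match.arg(mode)
  tt_assert(length(head_nodes) == 3 && all(head_nodes > 0), "ConfigError",
            "head_nodes must be three positive widths")
  tt_assert(n_experts >= 1, "ConfigError", "n_experts must be >= 1")
  structure(
    list(mode = mode, head_nodes = as.integer(head_nodes),
         n_experts = as.integer(n_experts),
         image_dim = as.integer(image_dim), gene_dim = as.integer(gene_dim),
         seed = as.integer(seed)),
    class = "fusion_config"
  )
}

# One classification stack: in -> 64 -> 128 -> 16 -> 1 (widths from cfg).
fusion_stack_init <- function(width_in, head_nodes, prefix) {
  h <- head_nodes
  l1 <- nn_dense_init(width_in, h[1])
  l2 <- nn_dense_init(h[1], h[2])
  l3 <- nn_dense_init(h[2], h[3])
  # down-scaled output unit: untrained probabilities stay near 0.5
  lo <- nn_dense_init(h[3], 1L)
  lo$W <- lo$W * 0.1
  p <- list(l1$W, l1$b, l2$W, l2$b, l3$W, l3$b, lo$W, lo$b)
  names(p) <- paste0(prefix, c("h1.W", "h1.b", "h2.W", "h2.b",
                               "h3.W", "h3.b", "out.W", "out.b"))
  p
}

#' Initialize a fusion head
#'
#' @param config A [fusion_config].
#' @return A `fusion_head` state: list with `params`, `config`, and
#'   `scalers` (`NULL` until fitted with [fit_fusion_scalers]).
#' @export
init_fusion_head <- function(config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  width_in <- config$image_dim + config$gene_dim
  params <- with_seed(config$seed, {
    if (config$mode == "concat") {
      fusion_stack_init(width_in, config$head_nodes, "")
    } else {
      p <- list()
      for (e in seq_len(config$n_experts)) {
        p <- c(p, fusion_stack_init(width_in, config$head_nodes,
                                    paste0("expert", e, ".")))
      }
      g <- nn_dense_init(width_in, config$n_experts)
      c(p, list("gate.W" = g$W, "gate.b" = g$b))
    }
  })
  structure(
    list(params = params, config = config, scalers = NULL),
    class = "fusion_head"
  )
}

#' Fit the per-modality Gaussian scalers of a fusion head
#'
#' @param state A `fusion_head`.
#' @param image_features,gene_features Stage-2 training feature matrices
#'   from [encode_image] and [encode_gene].
#' @param eps Standard-deviation floor.
#' @return The state with `scalers` populated.
#' @export
fit_fusion_scalers <- function(state, image_features, gene_features,
                               eps = 1e-8) {
  stopifnot(inherits(state, "fusion_head"))
  state$scalers <- list(image = fit_scaler(image_features, eps),
                        gene = fit_scaler(gene_features, eps))
  state
}

# Standardized image-then-gene concatenation (width 48).
fusion_scaled_input <- function(state, image_features, gene_features) {
  tt_assert(!is.null(state$scalers), "ScalerError",
            "fusion scalers are not fitted; call fit_fusion_scalers() first")
  cbind(scale_features(state$scalers$image, as.matrix(image_features)),
        scale_features(state$scalers$gene, as.matrix(gene_features)))
}

fusion_stack_fwd <- function(params, X, prefix = "") {
  p <- function(nm) params[[paste0(prefix, nm)]]
  a1 <- pmax(nn_dense_fwd(X, p("h1.W"), p("h1.b")), 0)
  a2 <- pmax(nn_dense_fwd(a1, p("h2.W"), p("h2.b")), 0)
  a3 <- pmax(nn_dense_fwd(a2, p("h3.W"), p("h3.b")), 0)
  logits <- nn_dense_fwd(a3, p("out.W"), p("out.b"))
  list(a1 = a1, a2 = a2, a3 = a3, logits = logits)
}

fusion_stack_bwd <- function(params, fwd, X, dlogits, prefix = "") {
  p <- function(nm) params[[paste0(prefix, nm)]]
  go <- nn_dense_bwd(fwd$a3, p("out.W"), dlogits)
  da3 <- go$dX * (fwd$a3 > 0)
  g3 <- nn_dense_bwd(fwd$a2, p("h3.W"), da3)
  da2 <- g3$dX * (fwd$a2 > 0)
  g2 <- nn_dense_bwd(fwd$a1, p("h2.W"), da2)
  da1 <- g2$dX * (fwd$a1 > 0)
  g1 <- nn_dense_bwd(X, p("h1.W"), da1)
  grads <- list(go$dW, go$db, g3$dW, g3$db, g2$dW, g2$db, g1$dW, g1$db)
  names(grads) <- paste0(prefix, c("out.W", "out.b", "h3.W", "h3.b",
                                   "h2.W", "h2.b", "h1.W", "h1.b"))
  grads
}

moe_gate <- function(params, X) {
  gl <- nn_dense_fwd(X, params$`gate.W`, params$`gate.b`)
  gl <- gl - apply(gl, 1, max)
  eg <- exp(gl)
  eg / rowSums(eg)
}

#' Fuse image and gene features
#'
#' Standardizes each modality's features with its fitted scaler, then
#' combines them. In `concat` mode the result is the 48-dimensional
#' image-then-gene concatenation. In `moe` mode the result is the
#' gate-weighted mixture of the experts' 16-dimensional final hidden
#' representations (the expert output width, whatever `n_experts`); the
#' softmax gate weights are attached as attribute `"gate"`.
#'
#' @param image_features `N x 16` matrix from [encode_image].
#' @param gene_features `N x 32` matrix from [encode_gene].
#' @param state A `fusion_head` with fitted scalers.
#' @return The fused feature matrix.
#' @export
fuse_features <- function(image_features, gene_features, state) {
  stopifnot(inherits(state, "fusion_head"))
  X <- fusion_scaled_input(state, image_features, gene_features)
  if (state$config$mode == "concat") return(X)
  G <- moe_gate(state$params, X)
  mix <- 0
  for (e in seq_len(state$config$n_experts)) {
    fe <- fusion_stack_fwd(state$params, X, paste0("expert", e, "."))
    mix <- mix + fe$a3 * G[, e]
  }
  attr(mix, "gate") <- G
  mix
}

#' Classify fused features
#'
#' In `concat` mode, runs the classification MLP (64, 128, 16 nodes,
#' sigmoid output) on the 48-wide fused input. In `moe` mode, the input is
#' the same 48-wide standardized concatenation; the returned probability
#' is the gate-weighted mean of the expert sigmoid outputs.
#'
#' @param state A `fusion_head`.
#' @param fused Numeric matrix of width `image_dim + gene_dim` (48 by
#'   default), as produced by [fusion_scaled_input]/[fuse_features]
#'   (`concat` mode).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
classify_fused <- function(state, fused) {
  stopifnot(inherits(state, "fusion_head"))
  fused <- as.matrix(fused)
  width_in <- state$config$image_dim + state$config$gene_dim
  tt_assert(ncol(fused) == width_in, "ShapeMismatchError",
            sprintf("fused width %d does not match configured width %d",
                    ncol(fused), width_in))
  if (state$config$mode == "concat") {
    return(as.vector(nn_sigmoid(fusion_stack_fwd(state$params, fused)$logits)))
  }
  G <- moe_gate(state$params, fused)
  p <- 0
  for (e in seq_len(state$config$n_experts)) {
    pe <- nn_sigmoid(fusion_stack_fwd(state$params, fused,
                                      paste0("expert", e, "."))$logits)
    p <- p + as.vector(pe) * G[, e]
  }
  p
}

#' End-to-end fusion prediction from encoder features
#'
#' @param state A `fusion_head` with fitted scalers.
#' @param image_features,gene_features Encoder feature matrices.
#' @return Probabilities in (0, 1).
#' @export
predict_fusion <- function(state, image_features, gene_features) {
  classify_fused(state,
                 fusion_scaled_input(state, image_features, gene_features))
}

#' @export
print.fusion_head <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Fusion head (%s): input %d + %d, MLP %s -> 1%s\n",
              cfg$mode, cfg$image_dim, cfg$gene_dim,
              paste(cfg$head_nodes, collapse = "/"),
              if (cfg$mode == "moe")
                sprintf(", %d experts", cfg$n_experts) else ""))
  cat(sprintf("  scalers fitted: %s\n", !is.null(x$scalers)))
  invisible(x)
}
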