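#' Per-phase optimization settings
#'
#' @param optimizer `"SGD"` or `"Adam"`.
#' @param momentum SGD momentum coefficient (also Adam's first-moment
#'   decay).
#' @param loss `"cross_entropy"` or `"mse"`.
#' @param lr Learning rate.
#' @param decay Multiplicative per-step learning-rate decay.
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param l2 Optional L2 weight-decay coefficient (default 0, matching the
#'   published setup; useful against overfitting on very small transfer
#'   sets).
#' @return A `phase_config` object.
#' @export
phase_config <- function(optimizer, momentum = 0.9, loss = "cross_entropy",
                         lr = 1e-4, decay = 2e-7, epochs = 10L,
                         batch_size = 16L, l2 = 0) {
  tt_assert(optimizer %in% c("SGD", "Adam"), "ConfigError",
            "optimizer must be 'SGD' or 'Adam'")
  tt_assert(loss %in% c("cross_entropy", "mse"), "ConfigError",
            "loss must be 'cross_entropy' or 'mse'")
  tt_assert(lr > 0 && epochs >= 1 && batch_size >= 1 && decay >= 0 &&
              decay < 1, "ConfigError",
            "rates, epochs and batch size must be positive")
  tt_assert(l2 >= 0, "ConfigError", "l2 must be non-negative")
  structure(
    list(optimizer = optimizer, momentum = momentum, loss = loss, lr = lr,
         decay = decay, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), l2 = l2),
    class = "phase_config"
  )
}

#' Training configuration of the two-stage procedure
#'
#' Defaults follow the published hyperparameter table: the image encoder
#' is trained with SGD (momentum 0.9, learning rate 2e-5) and
#' cross-entropy for 20 epochs; the gene autoencoder with Adam (learning
#' rate 1e-4) and MSE for 20 epochs; the stage-2 transfer of the fusion
#' head with SGD (learning rate 1e-4) and cross-entropy for 10 epochs.
#' All phases use batch size 16 and per-step multiplicative learning-rate
#' decay 2e-7. The gene classifier phase (supervised head on the frozen
#' bottleneck) reuses the gene-encoder optimizer settings.
#'
#' @param image,gene_ae,gene_classifier,transfer [phase_config]s for the
#'   four training phases.
#' @param seed Master seed; all initialization and shuffling derive from
#'   it.
#' @param k_folds Default number of cross-validation folds (3).
#' @return A `train_config` object.
#' @export
train_config <- function(
    image = phase_config("SGD", momentum = 0.9, loss = "cross_entropy",
                         lr = 2e-5, decay = 2e-7, epochs = 20L,
                         batch_size = 16L),
    gene_ae = phase_config("Adam", momentum = 0.9, loss = "mse",
                           lr = 1e-4, decay = 2e-7, epochs = 20L,
                           batch_size = 16L),
    gene_classifier = phase_config("Adam", momentum = 0.9,
                                   loss = "cross_entropy", lr = 1e-4,
                                   decay = 2e-7, epochs = 20L,
                                   batch_size = 16L),
    transfer = phase_config("SGD", momentum = 0.9, loss = "cross_entropy",
                            lr = 1e-4, decay = 2e-7, epochs = 10L,
                            batch_size = 16L),
    seed = 1L, k_folds = 3L) {
  tt_assert(k_folds >= 2, "ConfigError", "k_folds must be >= 2")
  structure(
    list(image = image, gene_ae = gene_ae,
         gene_classifier = gene_classifier, transfer = transfer,
         seed = as.integer(seed), k_folds = as.integer(k_folds)),
    class = "train_config"
  )
}

cohort_subset_ids <- function(chrt, split) {
  chrt$samples$sample_id[chrt$samples$split %in% split]
}

cohort_labels <- function(chrt, ids) {
  s <- chrt$samples
  s$label[match(ids, s$sample_id)]
}

#' Stage 1: train the image tower on image-only samples
#'
#' Trains the CNN encoder plus its sigmoid classification unit with the
#' image-phase optimizer and binary cross-entropy on the
#' `stage1_image_train` samples. If `state` is frozen, the epochs run as
#' no-ops (loss is still recorded) and parameters are left bit-identical.
#'
#' @param chrt A partitioned `twin_cohort`.
#' @param cfg A [train_config].
#' @param state Optional pre-initialized `image_tower`; by default one is
#'   initialized from the cohort's image size and `cfg$seed`.
#' @return The trained `image_tower` (unfrozen unless it came in frozen),
#'   with per-epoch training losses appended to `history$classifier`.
#' @export
train_stage1_image <- function(chrt, cfg = train_config(), state = NULL) {
  stopifnot(inherits(chrt, "twin_cohort"), inherits(cfg, "train_config"))
  ids <- cohort_subset_ids(chrt, "stage1_image_train")
  tt_assert(length(ids) > 0, "EmptyTrainingSetError",
            "cohort has no stage1_image_train samples")
  if (is.null(state)) {
    px <- chrt$images[[ids[1]]]$pixels
    state <- init_image_tower(image_tower_config(
      input_channels = dim(px)[1], input_size = dim(px)[2],
      seed = derive_seed(cfg$seed, 1L)
    ))
  }
  ph <- cfg$image
  X <- img_batch_array(chrt$images[ids], state$config)
  y <- cohort_labels(chrt, ids)
  opt <- nn_opt_init(state$params, ph$optimizer)
  losses <- numeric(ph$epochs)
  for (ep in seq_len(ph$epochs)) {
    batches <- nn_batches(length(ids), ph$batch_size,
                          derive_seed(cfg$seed, 100L + ep))
    tot <- 0
    for (b in batches) {
      Xb <- X[b, , , , drop = FALSE]
      fwd <- img_forward(state$params, Xb, state$config)
      p <- nn_sigmoid(fwd$logits)
      tot <- tot + nn_bce(p, y[b]) * length(b)
      if (!state$frozen) {
        dlogits <- (p - y[b]) / length(b)
        grads <- img_backward(state$params, fwd, state$config,
                              dlogits = dlogits)
        stepped <- nn_opt_step(state$params, grads, opt, ph$lr,
                               ph$momentum, ph$decay)
        state$params <- stepped$params
        opt <- stepped$opt
      }
    }
    losses[ep] <- tot / length(ids)
  }
  state$history$classifier <- c(state$history$classifier, losses)
  state
}

#' Stage 1: train the gene tower on gene-only samples
#'
#' Two sequential phases on the `stage1_gene_train` samples: (1) the
#' autoencoder is trained with the gene-phase optimizer and MSE
#' reconstruction loss; (2) the classifier head on the bottleneck is
#' trained with binary cross-entropy, the encoder being frozen by default.
#' The input transform (log1p + per-gene standardization) is fitted on the
#' training samples before phase 1.
#'
#' @inheritParams train_stage1_image
#' @param state Optional pre-initialized `gene_tower`.
#' @param freeze_encoder Keep encoder weights fixed during the classifier
#'   phase (default `TRUE`).
#' @return The trained `gene_tower`, with `history$ae` and
#'   `history$classifier` loss traces.
#' @export
train_stage1_gene <- function(chrt, cfg = train_config(), state = NULL,
                              freeze_encoder = TRUE) {
  stopifnot(inherits(chrt, "twin_cohort"), inherits(cfg, "train_config"))
  ids <- cohort_subset_ids(chrt, "stage1_gene_train")
  tt_assert(length(ids) > 0, "EmptyTrainingSetError",
            "cohort has no stage1_gene_train samples")
  Xraw <- chrt$genes[ids, , drop = FALSE]
  if (is.null(state)) {
    state <- init_gene_tower(gene_tower_config(
      input_dim = ncol(Xraw), seed = derive_seed(cfg$seed, 2L)
    ))
  }
  if (is.null(state$pre)) state$pre <- fit_gene_preprocess(Xraw)
  X <- gene_preprocess(state, Xraw)
  y <- cohort_labels(chrt, ids)
  n <- length(ids)
  d <- ncol(X)

  # phase 1: autoencoder reconstruction
  ph <- cfg$gene_ae
  ae_names <- grep("^(enc|dec)", names(state$params), value = TRUE)
  opt <- nn_opt_init(state$params[ae_names], ph$optimizer)
  ae_losses <- numeric(ph$epochs)
  for (ep in seq_len(ph$epochs)) {
    batches <- nn_batches(n, ph$batch_size, derive_seed(cfg$seed, 200L + ep))
    tot <- 0
    for (b in batches) {
      Xb <- X[b, , drop = FALSE]
      fwd <- gene_forward_ae(state$params, Xb)
      tot <- tot + tt_mse(Xb, fwd$recon) * length(b)
      if (!state$frozen) {
        drecon <- 2 * (fwd$recon - Xb) / (length(b) * d)
        grads <- gene_backward_ae(state$params, fwd, Xb, drecon)
        stepped <- nn_opt_step(state$params[ae_names], grads, opt, ph$lr,
                               ph$momentum, ph$decay)
        state$params[ae_names] <- stepped$params
        opt <- stepped$opt
      }
    }
    ae_losses[ep] <- tot / n
  }

  # phase 2: supervised classifier on the bottleneck
  ph <- cfg$gene_classifier
  cls_names <- grep("^cls", names(state$params), value = TRUE)
  train_names <- if (freeze_encoder || state$frozen) cls_names else
    c(grep("^enc", names(state$params), value = TRUE), cls_names)
  opt <- nn_opt_init(state$params[train_names], ph$optimizer)
  cls_losses <- numeric(ph$epochs)
  for (ep in seq_len(ph$epochs)) {
    batches <- nn_batches(n, ph$batch_size, derive_seed(cfg$seed, 300L + ep))
    tot <- 0
    for (b in batches) {
      Xb <- X[b, , drop = FALSE]
      ae <- gene_forward_ae(state$params, Xb)
      cl <- gene_forward_cls(state$params, ae$z)
      p <- nn_sigmoid(cl$logits)
      tot <- tot + nn_bce(p, y[b]) * length(b)
      if (!state$frozen) {
        dlogits <- (p - y[b]) / length(b)
        g3 <- nn_dense_bwd(cl$c2, state$params$`cls3.W`, dlogits)
        dc2 <- g3$dX * (cl$c2 > 0)
        g2 <- nn_dense_bwd(cl$c1, state$params$`cls2.W`, dc2)
        dc1 <- g2$dX * (cl$c1 > 0)
        g1 <- nn_dense_bwd(ae$z, state$params$`cls1.W`, dc1)
        grads <- list("cls3.W" = g3$dW, "cls3.b" = g3$db,
                      "cls2.W" = g2$dW, "cls2.b" = g2$db,
                      "cls1.W" = g1$dW, "cls1.b" = g1$db)
        if (!freeze_encoder) {
          dz <- g1$dX * (ae$z_pre > 0)
          ge2 <- nn_dense_bwd(ae$h1, state$params$`enc2.W`, dz)
          dh1 <- ge2$dX * (ae$h1 > 0)
          ge1 <- nn_dense_bwd(Xb, state$params$`enc1.W`, dh1)
          grads <- c(grads, list("enc2.W" = ge2$dW, "enc2.b" = ge2$db,
                                 "enc1.W" = ge1$dW, "enc1.b" = ge1$db))
        }
        stepped <- nn_opt_step(state$params[train_names], grads, opt, ph$lr,
                               ph$momentum, ph$decay)
        state$params[train_names] <- stepped$params
        opt <- stepped$opt
      }
    }
    cls_losses[ep] <- tot / n
  }
  state$history$ae <- c(state$history$ae, ae_losses)
  state$history$classifier <- c(state$history$classifier, cls_losses)
  state
}

# BCE gradient w.r.t. a mixture probability (not a single sigmoid).
dbce_dprob <- function(p, y, n) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  ((p - y) / (p * (1 - p))) / n
}

# One optimization run of the fusion head on fixed scaled inputs.
fusion_train <- function(head, X, y, ph, seed) {
  n <- nrow(X)
  opt <- nn_opt_init(head$params, ph$optimizer)
  losses <- numeric(ph$epochs)
  E <- head$config$n_experts
  for (ep in seq_len(ph$epochs)) {
    batches <- nn_batches(n, ph$batch_size, derive_seed(seed, 400L + ep))
    tot <- 0
    for (b in batches) {
      Xb <- X[b, , drop = FALSE]
      yb <- y[b]
      m <- length(b)
      if (head$config$mode == "concat") {
        fwd <- fusion_stack_fwd(head$params, Xb)
        p <- nn_sigmoid(fwd$logits)
        tot <- tot + nn_bce(p, yb) * m
        dlogits <- (p - yb) / m
        grads <- fusion_stack_bwd(head$params, fwd, Xb, dlogits)
      } else {
        G <- moe_gate(head$params, Xb)
        fe <- lapply(seq_len(E), function(e) {
          fusion_stack_fwd(head$params, Xb, paste0("expert", e, "."))
        })
        pe <- vapply(fe, function(f) as.vector(nn_sigmoid(f$logits)),
                     numeric(m))
        pe <- matrix(pe, nrow = m)
        p <- rowSums(G * pe)
        tot <- tot + nn_bce(p, yb) * m
        dp <- dbce_dprob(p, yb, m)
        grads <- list()
        dG <- matrix(0, m, E)
        for (e in seq_len(E)) {
          dlog_e <- matrix(dp * G[, e] * pe[, e] * (1 - pe[, e]), ncol = 1)
          grads <- c(grads, fusion_stack_bwd(head$params, fe[[e]], Xb,
                                             dlog_e,
                                             paste0("expert", e, ".")))
          dG[, e] <- dp * pe[, e]
        }
        dgate_logits <- G * (dG - rowSums(dG * G))
        gg <- nn_dense_bwd(Xb, head$params$`gate.W`, dgate_logits)
        grads$`gate.W` <- gg$dW
        grads$`gate.b` <- gg$db
      }
      stepped <- nn_opt_step(head$params, grads, opt, ph$lr, ph$momentum,
                             ph$decay, ph$l2)
      head$params <- stepped$params
      opt <- stepped$opt
    }
    losses[ep] <- tot / n
  }
  list(head = head, losses = losses)
}

#' Stage 2: frozen-encoder transfer of the fusion head
#'
#' Freezes both towers, computes their features on the `stage2_train`
#' samples, fits the per-modality Gaussian scalers on those training
#' features only, and trains the fusion head with the transfer-phase
#' optimizer and binary cross-entropy. Tower parameters are bit-identical
#' before and after.
#'
#' @param chrt A partitioned `twin_cohort` with dual-modality samples.
#' @param image A trained `image_tower`.
#' @param gene A trained `gene_tower`.
#' @param cfg A [train_config].
#' @param fusion_cfg A [fusion_config].
#' @return A fitted model of class `twin_tower`: list with `image_tower`,
#'   `gene_tower` (both frozen), `fusion_head`, `history` and the config
#'   snapshots.
#' @export
train_stage2_transfer <- function(chrt, image, gene, cfg = train_config(),
                                  fusion_cfg = fusion_config()) {
  stopifnot(inherits(chrt, "twin_cohort"), inherits(image, "image_tower"),
            inherits(gene, "gene_tower"))
  ids <- cohort_subset_ids(chrt, "stage2_train")
  tt_assert(length(ids) > 0, "EmptyTrainingSetError",
            "cohort has no stage2_train samples")
  s <- chrt$samples[match(ids, chrt$samples$sample_id), ]
  tt_assert(all(s$has_image & s$has_gene), "ModalityError",
            "every stage2 sample must carry both modalities")
  image <- freeze_tower(image, TRUE)
  gene <- freeze_tower(gene, TRUE)
  img_f <- encode_image(image, chrt$images[ids])
  gen_f <- encode_gene(gene, chrt$genes[ids, , drop = FALSE])
  y <- cohort_labels(chrt, ids)
  head <- init_fusion_head(fusion_cfg)
  head <- fit_fusion_scalers(head, img_f, gen_f)
  X <- fusion_scaled_input(head, img_f, gen_f)
  run <- fusion_train(head, X, y, cfg$transfer, cfg$seed)
  structure(
    list(
      image_tower = image, gene_tower = gene, fusion_head = run$head,
      history = list(image = image$history, gene = gene$history,
                     transfer = run$losses),
      train_config = cfg, fusion_config = fusion_cfg
    ),
    class = "twin_tower"
  )
}

#' Fit the full twin-tower model
#'
#' One-call interface running the complete two-stage procedure on a
#' partitioned cohort: stage-1 training of the image tower (image-only
#' samples) and gene tower (gene-only samples), then stage-2 transfer of
#' the fusion head on the dual-modality training samples with both
#' encoders frozen.
#'
#' @param chrt A partitioned `twin_cohort` (see [partition_cohort] or
#'   [generate_cohort]).
#' @param cfg A [train_config].
#' @param fusion_cfg A [fusion_config].
#' @return A fitted `twin_tower` model; see [train_stage2_transfer].
#' @examples
#' \donttest{
#' chrt <- generate_cohort(synth_config(n_image_only = 24, n_gene_only = 40,
#'                                      n_multimodal = 20, image_size = 24,
#'                                      n_genes = 60, seed = 7))
#' fit <- twin_tower(chrt)
#' summary(fit)
#' }
#' @export
twin_tower <- function(chrt, cfg = train_config(),
                       fusion_cfg = fusion_config()) {
  image <- train_stage1_image(chrt, cfg)
  gene <- train_stage1_gene(chrt, cfg)
  train_stage2_transfer(chrt, image, gene, cfg, fusion_cfg)
}

#' Predict therapy response with a fitted twin-tower model
#'
#' @param object A fitted `twin_tower` model.
#' @param chrt A `twin_cohort` holding the samples to score.
#' @param split Which split to score (default `"stage2_test"`); use
#'   `NULL` to score every dual-modality sample.
#' @param type `"prob"` for probabilities, `"class"` for hard 0/1 labels
#'   at the 0.5 threshold, `"features"` for the scaled fused features.
#' @param ... Unused.
#' @return Named vector of predictions (or feature matrix).
#' @export
predict.twin_tower <- function(object, chrt, split = "stage2_test",
                               type = c("prob", "class", "features"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(chrt, "twin_cohort"))
  s <- chrt$samples
  ids <- if (is.null(split)) s$sample_id[s$has_image & s$has_gene] else
    cohort_subset_ids(chrt, split)
  tt_assert(length(ids) > 0, "EmptyEvalError", "no samples to score")
  sm <- s[match(ids, s$sample_id), ]
  tt_assert(all(sm$has_image & sm$has_gene), "ModalityError",
            "fusion predictions need both modalities for every sample")
  img_f <- encode_image(object$image_tower, chrt$images[ids])
  gen_f <- encode_gene(object$gene_tower, chrt$genes[ids, , drop = FALSE])
  X <- fusion_scaled_input(object$fusion_head, img_f, gen_f)
  if (type == "features") {
    rownames(X) <- ids
    return(X)
  }
  p <- stats::setNames(classify_fused(object$fusion_head, X), ids)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' Evaluate a fitted model on a cohort split
#'
#' Thresholds fusion probabilities at 0.5, computes confusion-matrix
#' metrics and fills in the ROC AUC.
#'
#' @param object A fitted `twin_tower`.
#' @param chrt A `twin_cohort`.
#' @param split Split to evaluate (default `"stage2_test"`).
#' @return A `metric_report`.
#' @export
evaluate_model <- function(object, chrt, split = "stage2_test") {
  p <- predict(object, chrt, split = split, type = "prob")
  y <- cohort_labels(chrt, names(p))
  rep <- compute_metrics(confusion_counts(y, as.integer(p >= 0.5)))
  if (length(unique(y)) == 2) rep$auc <- roc_auc(y, p)$auc
  rep
}

#' Evaluate a single-modality tower as an ablation model
#'
#' Scores a cohort split with the stage-1 classifier of one tower
#' ([image_classify] or [gene_classify]) — the image-only / gene-only
#' baselines of the ablation comparison.
#'
#' @param state An `image_tower` or `gene_tower`.
#' @param chrt A `twin_cohort`.
#' @param split Split to evaluate.
#' @return A `metric_report`.
#' @export
evaluate_tower <- function(state, chrt, split) {
  ids <- cohort_subset_ids(chrt, split)
  tt_assert(length(ids) > 0, "EmptyEvalError", "no samples to score")
  p <- if (inherits(state, "image_tower")) {
    image_classify(state, chrt$images[ids])
  } else {
    gene_classify(state, chrt$genes[ids, , drop = FALSE])
  }
  y <- cohort_labels(chrt, ids)
  rep <- compute_metrics(confusion_counts(y, as.integer(p >= 0.5)))
  if (length(unique(y)) == 2) rep$auc <- roc_auc(y, p)$auc
  rep
}

# Stratified fold assignment: per class, a seeded permutation dealt
# round-robin into k folds.
make_folds <- function(ids, labels, k, seed) {
  fold <- integer(length(ids))
  names(fold) <- ids
  for (cl in sort(unique(labels))) {
    cl_ids <- sort(ids[labels == cl])
    tt_assert(length(cl_ids) >= k, "FoldError",
              sprintf("class %s has fewer than %d samples", cl, k))
    perm <- with_seed(derive_seed(seed, 500L + cl), sample(cl_ids))
    fold[perm] <- rep_len(seq_len(k), length(perm))
  }
  fold
}

#' Stratified k-fold cross-validation of the stage-2 transfer
#'
#' The stage-1 towers are trained once on the single-modality samples and
#' reused; the dual-modality subset is split into `k` label-stratified
#' folds, and for each fold the fusion head is trained from scratch on the
#' remaining folds and evaluated on the held-out fold.
#'
#' @param chrt A partitioned `twin_cohort`.
#' @param cfg A [train_config].
#' @param fusion_cfg A [fusion_config].
#' @param k Number of folds (default `cfg$k_folds`, i.e. 3).
#' @param image,gene Optional pre-trained towers; trained via stage 1 when
#'   omitted.
#' @return An object of class `twin_cv`: list with `folds` (k
#'   `metric_report`s) and `mean` (their unweighted metric means).
#' @export
cross_validate <- function(chrt, cfg = train_config(),
                           fusion_cfg = fusion_config(), k = cfg$k_folds,
                           image = NULL, gene = NULL) {
  stopifnot(inherits(chrt, "twin_cohort"))
  tt_assert(k >= 2, "ConfigError", "k must be >= 2")
  if (is.null(image)) image <- train_stage1_image(chrt, cfg)
  if (is.null(gene)) gene <- train_stage1_gene(chrt, cfg)
  s <- chrt$samples
  dual <- s$sample_id[s$has_image & s$has_gene]
  labels <- cohort_labels(chrt, dual)
  fold <- make_folds(dual, labels, k, cfg$seed)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    cv_chrt <- chrt
    cv_chrt$samples$split[match(dual, s$sample_id)] <-
      ifelse(fold[dual] == i, "stage2_test", "stage2_train")
    fit <- train_stage2_transfer(cv_chrt, image, gene, cfg, fusion_cfg)
    reports[[i]] <- evaluate_model(fit, cv_chrt, "stage2_test")
  }
  mean_metrics <- vapply(c("accuracy", "precision", "recall", "f1", "auc"),
                         function(m) {
                           mean(vapply(reports, function(r) r[[m]],
                                       numeric(1)))
                         }, numeric(1))
  structure(list(folds = reports, mean = mean_metrics, k = k,
                 fold_assignment = fold),
            class = "twin_cv")
}

#' @export
print.twin_cv <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold cross-validation of the stage-2 transfer\n", x$k))
  df <- do.call(rbind, lapply(x$folds, as.data.frame))
  df <- df[, c("accuracy", "precision", "recall", "f1", "auc")]
  rownames(df) <- paste("fold", seq_len(x$k))
  print(round(df, digits))
  cat("mean:\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' @export
print.twin_tower <- function(x, ...) {
  cat("Twin-tower multimodal classifier (fitted)\n")
  cat(sprintf("  fusion mode: %s\n", x$fusion_config$mode))
  cat(sprintf("  towers frozen: image %s, gene %s\n",
              x$image_tower$frozen, x$gene_tower$frozen))
  cat(sprintf("  final transfer loss: %.4f (%d epochs)\n",
              x$history$transfer[length(x$history$transfer)],
              length(x$history$transfer)))
  invisible(x)
}

#' @export
summary.twin_tower <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  image classifier loss: %.4f -> %.4f (%d epochs)\n",
              h$image$classifier[1],
              h$image$classifier[length(h$image$classifier)],
              length(h$image$classifier)))
  cat(sprintf("  gene AE mse: %.4f -> %.4f (%d epochs)\n",
              h$gene$ae[1], h$gene$ae[length(h$gene$ae)], length(h$gene$ae)))
  cat(sprintf("  gene classifier loss: %.4f -> %.4f\n",
              h$gene$classifier[1],
              h$gene$classifier[length(h$gene$classifier)]))
  invisible(object)
}

#' Plot training histories of a fitted twin-tower model
#'
#' @param x A fitted `twin_tower`.
#' @param ... Passed to [graphics::matplot].
#' @export
plot.twin_tower <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  graphics::plot(h$image$classifier, type = "l", xlab = "epoch",
                 ylab = "cross-entropy", main = "Image tower", ...)
  graphics::plot(h$gene$ae, type = "l", xlab = "epoch", ylab = "MSE",
                 main = "Gene autoencoder", ...)
  graphics::plot(h$transfer, type = "l", xlab = "epoch",
                 ylab = "cross-entropy", main = "Stage-2 transfer", ...)
  invisible(x)
}
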