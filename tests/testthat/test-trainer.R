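test_that("SGD-with-momentum matches a hand-computed two-step update", {
  # quadratic loss f(w) = w^2 / 2, gradient = w, lr 0.1, momentum 0.9
  params <- list(w = 1)
  opt <- twintower:::nn_opt_init(params, "SGD")
  s1 <- twintower:::nn_opt_step(params, list(w = params$w), opt,
                                lr = 0.1, momentum = 0.9, decay = 0)
  expect_equal(s1$params$w, 0.9) # v1 = -0.1
  s2 <- twintower:::nn_opt_step(s1$params, list(w = s1$params$w), s1$opt,
                                lr = 0.1, momentum = 0.9, decay = 0)
  expect_equal(s2$params$w, 0.9 + (0.9 * (-0.1) - 0.1 * 0.9)) # 0.72
  # multiplicative per-step decay scales the second step's rate
  opt <- twintower:::nn_opt_init(params, "SGD")
  d1 <- twintower:::nn_opt_step(params, list(w = 1), opt,
                                lr = 0.1, momentum = 0, decay = 0.5)
  d2 <- twintower:::nn_opt_step(d1$params, list(w = 1), d1$opt,
                                lr = 0.1, momentum = 0, decay = 0.5)
  expect_equal(d1$params$w, 1 - 0.1)
  expect_equal(d2$params$w, 1 - 0.1 - 0.1 * 0.5)
})

test_that("training histories record exactly the configured epoch counts", {
  chrt <- tiny_cohort(seed = 2)
  cfg <- train_config(seed = 2) # published defaults: 20 / 20 / 10 epochs
  fit <- twin_tower(chrt, cfg)
  expect_length(fit$history$image$classifier, 20)
  expect_length(fit$history$gene$ae, 20)
  expect_length(fit$history$transfer, 10)
})

test_that("stage-2 transfer freezes both towers bit-exactly", {
  chrt <- tiny_cohort(seed = 3)
  cfg <- fast_config(seed = 3)
  img <- train_stage1_image(chrt, cfg)
  gen <- train_stage1_gene(chrt, cfg)
  fit <- train_stage2_transfer(chrt, img, gen, cfg)
  expect_true(fit$image_tower$frozen)
  expect_true(fit$gene_tower$frozen)
  expect_identical(fit$image_tower$params, img$params)
  expect_identical(fit$gene_tower$params, gen$params)
  # a stage2 sample lacking a modality is rejected
  bad <- chrt
  gene_only <- which(!bad$samples$has_image & bad$samples$has_gene)[1]
  bad$samples$split[gene_only] <- "stage2_train"
  expect_error(train_stage2_transfer(bad, img, gen, cfg),
               class = "ModalityError")
})

test_that("the full two-stage run is bit-reproducible from its seed", {
  chrt <- tiny_cohort(seed = 5)
  a <- twin_tower(chrt, fast_config(seed = 9))
  b <- twin_tower(chrt, fast_config(seed = 9))
  expect_identical(a$image_tower$params, b$image_tower$params)
  expect_identical(a$gene_tower$params, b$gene_tower$params)
  expect_identical(a$fusion_head$params, b$fusion_head$params)
  expect_identical(a$history, b$history)
  expect_identical(predict(a, chrt), predict(b, chrt))
  c_ <- twin_tower(chrt, fast_config(seed = 10))
  expect_false(identical(a$fusion_head$params, c_$fusion_head$params))
})

test_that("held-out samples cannot influence the fitted model", {
  chrt <- tiny_cohort(seed = 6)
  perturbed <- chrt
  s <- perturbed$samples
  test_ids <- s$sample_id[grepl("test$", s$split)]
  set.seed(99)
  for (id in intersect(test_ids, names(perturbed$images))) {
    perturbed$images[[id]]$pixels <-
      perturbed$images[[id]]$pixels + runif(1)
  }
  gids <- intersect(test_ids, rownames(perturbed$genes))
  perturbed$genes[gids, ] <- perturbed$genes[gids, ] + 5
  a <- twin_tower(chrt, fast_config(seed = 4))
  b <- twin_tower(perturbed, fast_config(seed = 4))
  expect_identical(a$image_tower$params, b$image_tower$params)
  expect_identical(a$gene_tower$params, b$gene_tower$params)
  expect_identical(a$fusion_head$params, b$fusion_head$params)
  expect_identical(a$fusion_head$scalers, b$fusion_head$scalers)
})

test_that("training-set preconditions raise classed errors", {
  chrt <- generate_cohort(synth_config(n_image_only = 0, n_gene_only = 20,
                                       n_multimodal = 0, n_genes = 30,
                                       seed = 7))
  expect_error(train_stage1_image(chrt, fast_config()),
               class = "EmptyTrainingSetError")
})

test_that("cross-validation folds partition the dual-modality subset", {
  chrt <- tiny_cohort(seed = 8, n_multimodal = 18)
  cfg <- fast_config(seed = 8)
  cv <- cross_validate(chrt, cfg, k = 3)
  expect_length(cv$folds, 3)
  s <- chrt$samples
  dual <- s$sample_id[s$has_image & s$has_gene]
  expect_setequal(names(cv$fold_assignment), dual)
  expect_setequal(unique(cv$fold_assignment), 1:3)
  sizes <- table(cv$fold_assignment)
  expect_lte(max(sizes) - min(sizes), 2) # stratified round-robin
  expect_true(all(is.finite(cv$mean[c("accuracy", "precision",
                                      "recall", "f1")])))
  # evaluated counts per fold sum to the dual subset
  n_eval <- sum(vapply(cv$folds, function(r) {
    r$counts$tp + r$counts$tn + r$counts$fp + r$counts$fn
  }, numeric(1)))
  expect_equal(n_eval, length(dual))
  # a class thinner than k folds cannot be stratified
  expect_error(cross_validate(tiny_cohort(seed = 9), cfg, k = 8),
               class = "FoldError")
})

test_that("training losses descend on a learnable cohort", {
  chrt <- tiny_cohort(seed = 10)
  fit <- twin_tower(chrt, fast_config(seed = 10, epochs = 8))
  expect_lt(utils::tail(fit$history$gene$ae, 1), fit$history$gene$ae[1])
  expect_lt(utils::tail(fit$history$transfer, 1), fit$history$transfer[1])
})
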