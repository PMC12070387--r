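test_that("gene tower configuration enforces the bottleneck contract", {
  expect_error(gene_tower_config(input_dim = 0), class = "ConfigError")
  expect_error(gene_tower_config(100, encoder_nodes = c(64, 16)),
               class = "ConfigError")
  cfg <- gene_tower_config(100, encoder_nodes = c(64, 16), strict = FALSE)
  expect_equal(cfg$encoder_nodes[2], 16L)
  expect_error(gene_tower_config(100, encoder_nodes = c(64, 32),
                                 decoder_nodes = c(64, 32)),
               class = "ConfigError")
  # full-panel dimensioning: 19196 -> 64 -> 32
  st <- init_gene_tower(gene_tower_config(19196))
  expect_equal(dim(st$params$`enc1.W`), c(19196L, 64L))
  expect_equal(dim(st$params$`enc2.W`), c(64L, 32L))
  # seeded determinism
  a <- init_gene_tower(gene_tower_config(50, seed = 2))
  b <- init_gene_tower(gene_tower_config(50, seed = 2))
  expect_identical(a$params, b$params)
})

test_that("reconstruction MSE matches its arithmetic definition", {
  # hand oracle on a 2 x 3 table with fixed fake reconstructions
  x <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  r <- matrix(c(1, 1, 4, 4, 5, 8), 2, 3)
  expect_equal(twintower:::tt_mse(x, r), mean((x - r)^2))
  expect_equal(twintower:::tt_mse(x, r), (0 + 1 + 1 + 0 + 0 + 4) / 6)
  expect_equal(twintower:::tt_mse(x, x), 0) # identity reconstruction
  st <- init_gene_tower(gene_tower_config(30, seed = 1))
  set.seed(6)
  out <- reconstruct(st, matrix(rexp(5 * 30), 5, 30))
  expect_gte(out$mse, 0)
  expect_equal(dim(out$reconstructions), c(5L, 30L))
  expect_error(reconstruct(st, matrix(1, 2, 31)),
               class = "ShapeMismatchError")
})

test_that("the bottleneck encoding is the restriction of the AE forward pass", {
  st <- init_gene_tower(gene_tower_config(40, seed = 5))
  set.seed(12)
  X <- matrix(rexp(8 * 40), 8, 40)
  z <- encode_gene(st, X)
  expect_equal(dim(z), c(8L, 32L))
  # recompute through the full AE forward pass
  Xp <- twintower:::gene_batch_matrix(st, X)
  expect_identical(z, twintower:::gene_forward_ae(st$params, Xp)$z)
  # batch-order invariance
  expect_equal(as.vector(encode_gene(st, X[3, ])), z[3, ], tolerance = 1e-12)
  zdup <- encode_gene(st, X[c(1, 1), ])
  expect_identical(zdup[1, ], zdup[2, ])
})

test_that("classifier probabilities are valid and leave a frozen encoder intact", {
  chrt <- tiny_cohort(seed = 4)
  st <- train_stage1_gene(chrt, fast_config(seed = 4, epochs = 2))
  ids <- chrt$samples$sample_id[chrt$samples$split == "stage1_gene_test"]
  p <- gene_classify(st, chrt$genes[ids, ])
  expect_true(all(p > 0 & p < 1))
  # frozen tower: a full training run is a parameter no-op
  frozen <- freeze_tower(st, TRUE)
  out <- train_stage1_gene(chrt, fast_config(seed = 4, epochs = 2),
                           state = frozen)
  expect_identical(out$params, frozen$params)
})

test_that("the classifier phase trains the head but not the frozen encoder", {
  chrt <- tiny_cohort(seed = 5)
  enc_names <- c("enc1.W", "enc1.b", "enc2.W", "enc2.b",
                 "dec1.W", "dec1.b", "dec2.W", "dec2.b")
  cfg_a <- fast_config(seed = 5, epochs = 3)
  cfg_b <- fast_config(seed = 5, epochs = 3)
  cfg_b$gene_classifier <- phase_config("Adam", lr = 5e-3, epochs = 3)
  a <- train_stage1_gene(chrt, cfg_a)
  b <- train_stage1_gene(chrt, cfg_b)
  # different classifier optimizers cannot reach the encoder/decoder
  expect_identical(a$params[enc_names], b$params[enc_names])
  expect_false(identical(a$params$`cls1.W`, b$params$`cls1.W`))
})

test_that("AE training descends on low-rank expression and beats mean imputation", {
  chrt <- generate_cohort(synth_config(
    n_image_only = 0, n_gene_only = 80, n_multimodal = 0,
    n_genes = 120, latent_dim = 4, seed = 6
  ))
  cfg <- fast_config(seed = 6, epochs = 20)
  st0 <- init_gene_tower(gene_tower_config(120, seed = 60))
  trained <- train_stage1_gene(chrt, cfg, state = st0)
  ids <- chrt$samples$sample_id[chrt$samples$split == "stage1_gene_train"]
  Xtrain <- chrt$genes[ids, ]
  final_mse <- reconstruct(trained, Xtrain)$mse
  st_init <- st0
  st_init$pre <- trained$pre
  init_mse <- reconstruct(st_init, Xtrain)$mse
  # column-mean baseline in the transformed space the AE is trained in
  Xp <- twintower:::gene_preprocess(trained, Xtrain)
  mean_mse <- mean(sweep(Xp, 2, colMeans(Xp))^2)
  expect_lt(final_mse, init_mse)
  expect_lt(final_mse, mean_mse)
  expect_lt(utils::tail(trained$history$ae, 1), trained$history$ae[1])
})

test_that("a trained classifier recovers a simple linear gene signal", {
  set.seed(77)
  n <- 60; g <- 20
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rexp(n * g), n, g)
  X[, 1] <- X[, 1] + 3 * y
  X[, 2] <- X[, 2] + 3 * (1 - y)
  ids <- sprintf("G%03d", 1:n)
  rownames(X) <- ids
  chrt <- cohort(ids, y, genes = X, split = rep("stage1_gene_train", n))
  cfg <- fast_config(seed = 7, epochs = 20)
  st <- train_stage1_gene(chrt, cfg)
  acc <- mean((gene_classify(st, X) >= 0.5) == y)
  expect_gt(acc, 0.8)
})
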