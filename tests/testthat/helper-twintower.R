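# Shared fixtures, all generated in code at test time.

# A small cohort exercising all three modality strata quickly.
tiny_cohort <- function(seed = 1, n_image_only = 16, n_gene_only = 30,
                        n_multimodal = 14, image_size = 24, n_slices = 6,
                        n_genes = 60, ...) {
  generate_cohort(synth_config(
    n_image_only = n_image_only, n_gene_only = n_gene_only,
    n_multimodal = n_multimodal, image_size = image_size,
    n_slices = n_slices, n_genes = n_genes, seed = seed, ...
  ))
}

# Short training schedule for contract tests (not a performance config).
fast_config <- function(seed = 1, epochs = 4L) {
  train_config(
    image = phase_config("SGD", lr = 1e-2, epochs = epochs),
    gene_ae = phase_config("Adam", loss = "mse", lr = 1e-3, epochs = epochs),
    gene_classifier = phase_config("Adam", lr = 1e-3, epochs = epochs),
    transfer = phase_config("SGD", lr = 1e-2, epochs = epochs),
    seed = seed
  )
}

# A random normalized slice stack (valid image-tower input).
rand_slice_stack <- function(id = "S1", size = 24) {
  px <- array(runif(5 * size * size), c(5, size, size))
  px[5, , ] <- round(px[5, , ])
  structure(list(sample_id = id, pixels = px, slice_index = 1L),
            class = "slice_stack")
}

# A toy volume whose per-slice nonzero SEG counts are given exactly.
toy_volume <- function(counts, side = 4, id = "T1") {
  nz <- length(counts)
  seg <- array(0, c(side, side, nz))
  for (z in seq_len(nz)) {
    if (counts[z] > 0) seg[, , z][seq_len(counts[z])] <- 1
  }
  ch <- lapply(1:4, function(i) array(runif(side * side * nz),
                                      c(side, side, nz)))
  names(ch) <- c("T1", "T2", "T1ce", "FLAIR")
  ch$SEG <- seg
  volume_set(id, ch)
}

# A fake minimal slice stack for cohorts that never touch pixel data.
stub_stack <- function(id) {
  structure(list(sample_id = id, pixels = array(0, c(5, 4, 4)),
                 slice_index = 1L),
            class = "slice_stack")
}

# Cohort of n image-only stubs with given labels, all in one split.
stub_image_cohort <- function(n, labels, split = "unassigned") {
  ids <- sprintf("S%03d", seq_len(n))
  images <- setNames(lapply(ids, stub_stack), ids)
  cohort(ids, labels, images = images, split = rep(split, n))
}
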