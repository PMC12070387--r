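test_that("volume sets validate channel completeness and shape", {
  v <- toy_volume(c(1, 2, 1))
  expect_s3_class(v, "volume_set")
  expect_equal(v$voxel_shape, c(4L, 4L, 3L))
  ch <- v$channels
  expect_error(volume_set("X", ch[c("T1", "T2", "T1ce", "FLAIR")]),
               class = "ModalityFileError")
  bad <- ch
  bad$T2 <- array(0, c(4, 4, 2))
  expect_error(volume_set("X", bad), class = "ShapeMismatchError")
})

test_that("NIfTI volume sets round-trip through files", {
  d <- withr::local_tempdir()
  set.seed(5)
  v <- toy_volume(c(3, 5, 2), side = 8)
  paths <- sapply(names(v$channels), function(ch) {
    p <- file.path(d, paste0(ch, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(v$channels[[ch]]), p)
    p
  })
  loaded <- load_volume_set(paths, sample_id = "RT")
  expect_equal(loaded$voxel_shape, c(8L, 8L, 3L))
  expect_equal(loaded$channels$SEG, v$channels$SEG, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(load_volume_set(paths[c("T1", "T2", "T1ce", "FLAIR")]),
               class = "ModalityFileError")
})

test_that("maximum-tumor-slice extraction picks the argmax, lowest on ties", {
  set.seed(9)
  v <- toy_volume(c(2, 7, 7))
  st <- extract_max_tumor_slice(v)
  expect_equal(st$slice_index, 2L)
  expect_equal(dim(st$pixels), c(5L, 4L, 4L))
  # all-zero segmentation
  expect_error(extract_max_tumor_slice(toy_volume(c(0, 0, 0))),
               class = "NoTumorError")
  # exhaustive per-slice count oracle on random toy volumes
  for (rep in 1:100) {
    nz <- sample(2:6, 1)
    counts <- sample(0:10, nz, replace = TRUE)
    if (all(counts == 0)) counts[sample(nz, 1)] <- 1
    v <- toy_volume(counts, side = 5)
    oracle <- which.max(apply(v$channels$SEG != 0, 3, sum))
    expect_equal(extract_max_tumor_slice(v)$slice_index, oracle)
  }
})

test_that("slice normalization bounds intensities and binarizes SEG", {
  set.seed(2)
  v <- toy_volume(c(4, 9))
  v$channels$T1 <- v$channels$T1 * 1000 + 37 # arbitrary intensity scale
  v$channels$SEG <- v$channels$SEG * 3 # multi-label mask
  st <- extract_max_tumor_slice(v)
  expect_true(all(st$pixels >= 0 & st$pixels <= 1))
  expect_true(all(st$pixels[5, , ] %in% c(0, 1)))
  raw <- extract_max_tumor_slice(v, normalize = FALSE)
  expect_true(max(raw$pixels[1, , ]) > 1)
})

test_that("gene matrix construction follows the keep-first-duplicate rule", {
  ann <- data.frame(
    transcript_id = paste0("TX", 1:5),
    gene_id = c("A", "A", "B", "B", "C")
  )
  tab <- data.frame(transcript_id = paste0("TX", 1:5), value = c(1, 9, 2, 8, 3))
  gm <- build_gene_matrix(list(S1 = tab), ann)
  expect_equal(gm$gene_ids, c("A", "B", "C"))
  expect_equal(unname(gm$values["S1", ]), c(1, 2, 3))
  expect_false(any(duplicated(gm$gene_ids)))

  # no duplicates: values reordered by sorted gene ID
  ann2 <- data.frame(transcript_id = c("T1", "T2", "T3"),
                     gene_id = c("Z", "M", "A"))
  tab2 <- data.frame(transcript_id = c("T1", "T2", "T3"), value = c(10, 20, 30))
  gm2 <- build_gene_matrix(list(S1 = tab2), ann2)
  expect_equal(gm2$gene_ids, c("A", "M", "Z"))
  expect_equal(unname(gm2$values["S1", ]), c(30, 20, 10))

  # disjoint annotated transcripts across samples -> empty intersection
  tabA <- data.frame(transcript_id = "TX1", value = 1)
  tabB <- data.frame(transcript_id = "TX3", value = 2)
  annD <- data.frame(transcript_id = c("TX1", "TX3"), gene_id = c("A", "B"))
  expect_error(build_gene_matrix(list(S1 = tabA, S2 = tabB), annD),
               class = "EmptyMatrixError")
})

test_that("versioned transcript IDs and GTF annotations are handled", {
  skip_if_not_installed("rtracklayer")
  d <- withr::local_tempdir()
  gtf <- file.path(d, "anno.gtf")
  writeLines(c(
    paste0("chr1\ttest\ttranscript\t1\t100\t.\t+\t.\t",
           'gene_id "ENSG001.2"; transcript_id "ENST001.5";'),
    paste0("chr1\ttest\ttranscript\t200\t300\t.\t+\t.\t",
           'gene_id "ENSG002.1"; transcript_id "ENST002.3";')
  ), gtf)
  qt <- file.path(d, "S1.tsv")
  writeLines(c("ENST001.5\t4.5", "ENST002.3\t1.25", "ENST999.1\t7"), qt)
  gm <- build_gene_matrix(list(S1 = qt), gtf)
  expect_equal(gm$gene_ids, c("ENSG001", "ENSG002"))
  expect_equal(unname(gm$values["S1", ]), c(4.5, 1.25))
})

test_that("clinical responses binarize with explicit positive categories", {
  pos <- c("Complete Response", "Partial Response")
  expect_equal(binarize_response("Complete Response", pos)$response_label, 1L)
  expect_equal(binarize_response("Progressive Disease", pos)$response_label, 0L)
  expect_error(binarize_response("", pos), class = "LabelError")
  expect_error(binarize_response(NA_character_, pos), class = "LabelError")
  d <- withr::local_tempdir()
  csv <- file.path(d, "clinical.csv")
  writeLines(c("sample_id,response", "S1,Complete Response",
               "S2,Stable Disease"), csv)
  labs <- read_clinical_labels(csv, pos)
  expect_equal(labs$label, c(1L, 0L))
})

test_that("cohort partitioning reproduces the 80:20 and 3:2 arithmetic", {
  set.seed(1)
  # 95 image-only samples at 0.8
  ch95 <- stub_image_cohort(95, rbinom(95, 1, 0.5))
  p95 <- partition_cohort(ch95, split_spec(seed = 4))
  tab <- table(p95$samples$split)
  expect_equal(unname(tab[["stage1_image_train"]]), 76)
  expect_equal(unname(tab[["stage1_image_test"]]), 19)

  # 50 dual-modality samples at 0.6
  ids <- sprintf("D%03d", 1:50)
  genes <- matrix(runif(50 * 5), 50, 5, dimnames = list(ids, NULL))
  images <- setNames(lapply(ids, stub_stack), ids)
  ch50 <- cohort(ids, rbinom(50, 1, 0.5), images = images, genes = genes)
  p50 <- partition_cohort(ch50, split_spec(seed = 4))
  tab50 <- table(p50$samples$split)
  expect_equal(unname(tab50[["stage2_train"]]), 30)
  expect_equal(unname(tab50[["stage2_test"]]), 20)
})

test_that("splits are deterministic, stratified, disjoint and exhaustive", {
  set.seed(8)
  labels <- rbinom(40, 1, 0.4)
  ch <- stub_image_cohort(40, labels)
  a <- partition_cohort(ch, split_spec(seed = 7))$samples
  b <- partition_cohort(ch, split_spec(seed = 7))$samples
  expect_identical(a, b)
  c_ <- partition_cohort(ch, split_spec(seed = 8))$samples
  expect_equal(table(a$split), table(c_$split)) # sizes preserved
  expect_false(identical(a$split, c_$split)) # assignment changes
  expect_setequal(a$split, c("stage1_image_train", "stage1_image_test"))
  # stratification: class proportions preserved within +-1 sample
  tr <- a[a$split == "stage1_image_train", ]
  expect_lte(abs(sum(tr$label) - 0.8 * sum(labels)), 1)
  # tiny stratum fails loudly
  expect_error(partition_cohort(stub_image_cohort(1, 1), split_spec()),
               class = "SplitError")
})

test_that("synthetic cohorts round-trip through the on-disk layout", {
  d <- withr::local_tempdir()
  chrt <- generate_cohort(synth_config(n_image_only = 4, n_gene_only = 6,
                                       n_multimodal = 4, image_size = 16,
                                       n_slices = 4, n_genes = 20, seed = 2))
  write_cohort(chrt, d)
  back <- read_cohort(d)
  expect_identical(back$samples, chrt$samples)
  expect_equal(back$genes, chrt$genes, tolerance = 1e-9)
  for (id in names(chrt$images)) {
    expect_equal(back$images[[id]]$pixels, chrt$images[[id]]$pixels,
                 tolerance = 1e-6)
    expect_equal(back$images[[id]]$slice_index, chrt$images[[id]]$slice_index)
  }
})
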