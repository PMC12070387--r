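# Channel order is fixed throughout the package.
CHANNELS <- c("T1", "T2", "T1ce", "FLAIR", "SEG")

#' Load a multi-sequence MRI volume set from NIfTI files
#'
#' Reads the four MRI pulse sequences (T1, T2, T1ce, FLAIR) and the tumor
#' segmentation mask for one sample and checks that all five 3D volumes
#' share a common shape. Upstream co-registration, resampling and
#' skull-stripping are assumed to have been performed by the source data.
#'
#' @param paths_by_channel Named character vector or list mapping each of
#'   `"T1"`, `"T2"`, `"T1ce"`, `"FLAIR"`, `"SEG"` to a `.nii`/`.nii.gz`
#'   file path.
#' @param sample_id Sample identifier to attach; defaults to the T1
#'   file name stem.
#' @return An object of class `volume_set`: list with `sample_id`,
#'   `channels` (named list of 3D arrays) and `voxel_shape`.
#' @export
load_volume_set <- function(paths_by_channel, sample_id = NULL) {
  paths <- unlist(paths_by_channel)
  missing_ch <- setdiff(CHANNELS, names(paths))
  tt_assert(length(missing_ch) == 0, "ModalityFileError",
            paste("missing channel(s):", paste(missing_ch, collapse = ", ")))
  tt_assert(all(file.exists(paths[CHANNELS])), "ModalityFileError",
            paste("file not found:",
                  paste(paths[CHANNELS][!file.exists(paths[CHANNELS])],
                        collapse = ", ")))
  channels <- lapply(paths[CHANNELS], function(p) {
    v <- unclass(as.array(RNifti::readNifti(p)))
    attributes(v)[setdiff(names(attributes(v)), "dim")] <- NULL
    tt_assert(length(dim(v)) == 3, "ModalityFileError",
              paste("not a 3D volume:", p))
    v
  })
  names(channels) <- CHANNELS
  if (is.null(sample_id)) {
    sample_id <- sub("\\.nii(\\.gz)?$", "", basename(paths[["T1"]]))
  }
  volume_set(sample_id, channels)
}

#' Construct a volume set from in-memory arrays
#'
#' @param sample_id Sample identifier.
#' @param channels Named list of five 3D arrays (`T1`, `T2`, `T1ce`,
#'   `FLAIR`, `SEG`); `SEG` must hold non-negative integer labels with 0 as
#'   background.
#' @return A `volume_set` object.
#' @export
volume_set <- function(sample_id, channels) {
  missing_ch <- setdiff(CHANNELS, names(channels))
  tt_assert(length(missing_ch) == 0, "ModalityFileError",
            paste("missing channel(s):", paste(missing_ch, collapse = ", ")))
  channels <- channels[CHANNELS]
  shapes <- lapply(channels, dim)
  tt_assert(all(vapply(shapes, length, 1L) == 3), "ModalityFileError",
            "all channels must be 3D arrays")
  ref <- shapes[[1]]
  same <- vapply(shapes, function(s) all(s == ref), TRUE)
  tt_assert(all(same), "ShapeMismatchError",
            paste("channel shapes differ:",
                  paste(names(channels)[!same], collapse = ", ")))
  seg <- channels$SEG
  tt_assert(all(seg >= 0) && all(seg == round(seg)), "ModalityFileError",
            "SEG must contain non-negative integer labels")
  structure(
    list(sample_id = sample_id, channels = channels, voxel_shape = ref),
    class = "volume_set"
  )
}

#' Extract the transverse slice with the largest tumor cross-section
#'
#' Maximum voxel layer sampling: scans the transverse (third) axis, counts
#' nonzero segmentation voxels per slice, and cuts all five channels at the
#' slice with the maximal count (ties broken towards the lowest index).
#' By default the four MRI channels are min-max scaled to `[0, 1]` within
#' the slice and the segmentation is binarized, so downstream encoders see
#' a fixed intensity range.
#'
#' @param vol A `volume_set`.
#' @param normalize Logical; apply per-slice intensity normalization
#'   (default `TRUE`).
#' @return An object of class `slice_stack`: list with `sample_id`,
#'   `pixels` (array `5 x H x W`, channel order T1, T2, T1ce, FLAIR, SEG)
#'   and the 1-based `slice_index` of extraction.
#' @export
extract_max_tumor_slice <- function(vol, normalize = TRUE) {
  stopifnot(inherits(vol, "volume_set"))
  seg <- vol$channels$SEG
  counts <- apply(seg != 0, 3, sum)
  tt_assert(any(counts > 0), "NoTumorError",
            paste0("segmentation mask of sample '", vol$sample_id,
                   "' contains no tumor voxels"))
  z <- which.max(counts) # first maximum = lowest index on ties
  h <- vol$voxel_shape[1]
  w <- vol$voxel_shape[2]
  pixels <- array(0, c(5L, h, w), dimnames = list(CHANNELS, NULL, NULL))
  for (i in seq_along(CHANNELS)) {
    sl <- vol$channels[[CHANNELS[i]]][, , z]
    if (normalize) {
      if (CHANNELS[i] == "SEG") {
        sl <- (sl != 0) * 1
      } else {
        rng <- range(sl)
        sl <- if (rng[2] > rng[1]) (sl - rng[1]) / (rng[2] - rng[1]) else sl * 0
      }
    }
    pixels[i, , ] <- sl
  }
  structure(
    list(sample_id = vol$sample_id, pixels = pixels, slice_index = z),
    class = "slice_stack"
  )
}

#' Read a two-column transcript quantification table
#'
#' Tab-separated file with transcript IDs in the first column and
#' expression values in the second; lines starting with `#` and a header
#' line (detected by a non-numeric second field) are skipped.
#'
#' @param path File path.
#' @return A data.frame with columns `transcript_id` and `value`.
#' @export
read_quant_table <- function(path) {
  tt_assert(file.exists(path), "ModalityFileError",
            paste("file not found:", path))
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  tt_assert(ncol(df) >= 2, "EmptyMatrixError",
            paste("expected two tab-separated columns in", path))
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df[1, 2])))) {
    df <- df[-1, , drop = FALSE]
  }
  out <- data.frame(
    transcript_id = as.character(df[[1]]),
    value = as.numeric(df[[2]]),
    stringsAsFactors = FALSE
  )
  tt_assert(nrow(out) > 0, "EmptyMatrixError",
            paste("empty quantification table:", path))
  out
}

# Strip Ensembl version suffixes ("ENST....15" -> "ENST....").
strip_version <- function(ids) sub("\\.\\d+$", "", ids)

#' Read a transcript-to-gene map from a GTF annotation
#'
#' Parses `transcript_id` / `gene_id` attribute pairs from transcript
#' records of a GTF file (via \pkg{rtracklayer}).
#'
#' @param path Path to a GTF file (optionally gzipped).
#' @return A data.frame with columns `transcript_id` and `gene_id`,
#'   version suffixes stripped.
#' @export
read_tx2gene_gtf <- function(path) {
  tt_assert(file.exists(path), "ModalityFileError",
            paste("file not found:", path))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    tt_stop("ConfigError", "rtracklayer is required to parse GTF annotations")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  md <- md[!is.na(md$transcript_id), c("transcript_id", "gene_id")]
  md <- unique(md)
  data.frame(
    transcript_id = strip_version(as.character(md$transcript_id)),
    gene_id = strip_version(as.character(md$gene_id)),
    stringsAsFactors = FALSE
  )
}

#' Build a samples-by-genes expression matrix
#'
#' Maps each sample's transcript-level quantification to stable gene IDs
#' using the annotation, drops transcripts absent from the annotation,
#' keeps only the first occurrence (in table order) when several rows map
#' to the same gene ID, and intersects the gene sets across samples so all
#' rows share one gene panel.
#'
#' @param quant_tables Named list (names = sample IDs) of quantification
#'   tables: data.frames with columns `transcript_id`/`value` as returned
#'   by [read_quant_table], or file paths.
#' @param annotation Transcript-to-gene map: a data.frame with columns
#'   `transcript_id` and `gene_id`, or a GTF file path (parsed with
#'   [read_tx2gene_gtf]).
#' @return An object of class `gene_matrix`: list with `sample_ids`,
#'   `gene_ids` (unique, sorted) and `values` (samples x genes matrix).
#' @export
build_gene_matrix <- function(quant_tables, annotation) {
  tt_assert(length(quant_tables) > 0 && !is.null(names(quant_tables)),
            "EmptyMatrixError", "quant_tables must be a non-empty named list")
  if (is.character(annotation)) annotation <- read_tx2gene_gtf(annotation)
  tt_assert(all(c("transcript_id", "gene_id") %in% names(annotation)),
            "ConfigError",
            "annotation needs columns 'transcript_id' and 'gene_id'")
  tx2gene <- stats::setNames(as.character(annotation$gene_id),
                             strip_version(as.character(annotation$transcript_id)))
  tx2gene <- tx2gene[!duplicated(names(tx2gene))]
  per_sample <- lapply(names(quant_tables), function(sid) {
    tab <- quant_tables[[sid]]
    if (is.character(tab)) tab <- read_quant_table(tab)
    tt_assert(nrow(tab) > 0, "EmptyMatrixError",
              paste("empty quantification table for sample", sid))
    genes <- unname(tx2gene[strip_version(as.character(tab$transcript_id))])
    keep <- !is.na(genes)
    genes <- genes[keep]
    vals <- as.numeric(tab$value[keep])
    first <- !duplicated(genes)
    stats::setNames(vals[first], genes[first])
  })
  names(per_sample) <- names(quant_tables)
  shared <- Reduce(intersect, lapply(per_sample, names))
  tt_assert(length(shared) > 0, "EmptyMatrixError",
            "no gene IDs shared across all samples after annotation mapping")
  shared <- sort(shared)
  values <- do.call(rbind, lapply(per_sample, function(v) v[shared]))
  dimnames(values) <- list(names(per_sample), shared)
  structure(
    list(sample_ids = names(per_sample), gene_ids = shared, values = values),
    class = "gene_matrix"
  )
}

#' Binarize a clinical therapy-response category
#'
#' Maps a raw clinical response string to the binary label used throughout
#' the package: 1 for a positive response to therapy, 0 otherwise. Which
#' categories count as positive is study-specific and must be supplied.
#'
#' @param raw_response Character scalar, the recorded clinical response.
#' @param positive_categories Character vector of categories mapped to 1.
#' @param sample_id Optional sample identifier carried into the record.
#' @return A `clinical_record`: list with `sample_id` and `response_label`
#'   in `{0, 1}`.
#' @export
binarize_response <- function(raw_response, positive_categories,
                              sample_id = NA_character_) {
  tt_assert(length(raw_response) == 1 && !is.na(raw_response) &&
              nzchar(trimws(raw_response)), "LabelError",
            paste0("invalid clinical response value: '",
                   paste(raw_response, collapse = ""), "'"))
  structure(
    list(sample_id = sample_id,
         response_label = as.integer(raw_response %in% positive_categories)),
    class = "clinical_record"
  )
}

#' Read a clinical label table
#'
#' CSV with header columns `sample_id,response`; responses are binarized
#' with [binarize_response].
#'
#' @param path CSV file path.
#' @param positive_categories Character vector of responses mapped to 1.
#' @return A data.frame with columns `sample_id` and `label`.
#' @export
read_clinical_labels <- function(path, positive_categories) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tt_assert(all(c("sample_id", "response") %in% names(df)), "LabelError",
            "clinical table needs columns 'sample_id' and 'response'")
  labels <- vapply(seq_len(nrow(df)), function(i) {
    binarize_response(df$response[i], positive_categories,
                      df$sample_id[i])$response_label
  }, integer(1))
  data.frame(sample_id = df$sample_id, label = labels,
             stringsAsFactors = FALSE)
}

## ---- cohort container -------------------------------------------------

#' Assemble a multimodal cohort
#'
#' Bundles per-sample tumor slices, gene expression vectors, binary labels
#' and modality availability into the container consumed by the trainer.
#' Every sample must carry at least one modality.
#'
#' @param sample_ids Character vector of sample IDs.
#' @param labels Integer vector of binary labels, parallel to `sample_ids`.
#' @param images Named list of `slice_stack` objects for image-bearing
#'   samples.
#' @param genes Numeric matrix (rows named by sample ID) of expression
#'   values for gene-bearing samples, or `NULL`.
#' @param split Optional character vector of split assignments; defaults
#'   to `"unassigned"` (use [partition_cohort]).
#' @return An object of class `twin_cohort`: list with a `samples`
#'   data.frame (`sample_id`, `has_image`, `has_gene`, `label`, `split`),
#'   the `images` list and the `genes` matrix.
#' @export
cohort <- function(sample_ids, labels, images = list(), genes = NULL,
                   split = NULL) {
  tt_assert(length(sample_ids) == length(labels) && length(sample_ids) > 0,
            "ConfigError", "sample_ids and labels must be parallel, non-empty")
  tt_assert(all(labels %in% 0:1), "LabelError", "labels must be binary 0/1")
  has_image <- sample_ids %in% names(images)
  has_gene <- if (is.null(genes)) rep(FALSE, length(sample_ids)) else
    sample_ids %in% rownames(genes)
  tt_assert(all(has_image | has_gene), "ConfigError",
            "every sample must carry at least one modality")
  if (is.null(split)) split <- rep("unassigned", length(sample_ids))
  samples <- data.frame(
    sample_id = sample_ids, has_image = has_image, has_gene = has_gene,
    label = as.integer(labels), split = split, stringsAsFactors = FALSE
  )
  structure(list(samples = samples, images = images, genes = genes),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  s <- x$samples
  cat("Multimodal cohort:", nrow(s), "samples\n")
  cat(sprintf("  image-only: %d, gene-only: %d, dual-modality: %d\n",
              sum(s$has_image & !s$has_gene),
              sum(!s$has_image & s$has_gene),
              sum(s$has_image & s$has_gene)))
  cat(sprintf("  label prevalence: %.3f\n", mean(s$label)))
  if (!all(s$split == "unassigned")) {
    print(table(s$split))
  }
  invisible(x)
}

#' Split specification for cohort partitioning
#'
#' @param unimodal_train_fraction Training fraction for modality-exclusive
#'   samples (default 0.8, i.e. 80:20).
#' @param multimodal_train_fraction Training fraction for dual-modality
#'   samples (default 0.6, i.e. 3:2).
#' @param seed Integer seed making the assignment deterministic.
#' @return A `split_spec` object.
#' @export
split_spec <- function(unimodal_train_fraction = 0.8,
                       multimodal_train_fraction = 0.6, seed = 1L) {
  tt_assert(unimodal_train_fraction > 0 && unimodal_train_fraction < 1 &&
              multimodal_train_fraction > 0 && multimodal_train_fraction < 1,
            "ConfigError", "train fractions must lie in (0, 1)")
  structure(list(unimodal_train_fraction = unimodal_train_fraction,
                 multimodal_train_fraction = multimodal_train_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Stratified train/test assignment within one stratum. Deterministic given
# (seed, sorted sample IDs); class proportions preserved within +-1 sample.
assign_stratum <- function(ids, labels, frac, seed) {
  ord <- order(ids)
  ids <- ids[ord]; labels <- labels[ord]
  n <- length(ids)
  n_train <- floor(frac * n + 0.5)
  classes <- sort(unique(labels))
  base <- vapply(classes, function(cl) floor(frac * sum(labels == cl)), 0)
  rem <- vapply(classes, function(cl) frac * sum(labels == cl), 0) - base
  leftover <- n_train - sum(base)
  if (leftover > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(leftover)]
    base[take] <- base[take] + 1
  }
  train_ids <- character(0)
  for (j in seq_along(classes)) {
    cl_ids <- ids[labels == classes[j]]
    perm <- with_seed(derive_seed(seed, j), sample(cl_ids))
    train_ids <- c(train_ids, perm[seq_len(base[j])])
  }
  list(train = train_ids, test = setdiff(ids, train_ids))
}

#' Partition a cohort into training and testing splits
#'
#' Image-only and gene-only samples are split train:test by the unimodal
#' fraction (default 80:20) into the stage-1 splits of their modality;
#' dual-modality samples are split by the multimodal fraction (default 3:2)
#' into the stage-2 transfer splits. Splits are stratified by label and a
#' deterministic function of the seed and the sorted sample IDs.
#'
#' @param chrt A `twin_cohort`.
#' @param spec A [split_spec].
#' @return The cohort with its `split` column populated with
#'   `stage1_image_train/test`, `stage1_gene_train/test`,
#'   `stage2_train/test`.
#' @export
partition_cohort <- function(chrt, spec = split_spec()) {
  stopifnot(inherits(chrt, "twin_cohort"), inherits(spec, "split_spec"))
  s <- chrt$samples
  strata <- list(
    list(mask = s$has_image & !s$has_gene, frac = spec$unimodal_train_fraction,
         train = "stage1_image_train", test = "stage1_image_test", off = 11L),
    list(mask = !s$has_image & s$has_gene, frac = spec$unimodal_train_fraction,
         train = "stage1_gene_train", test = "stage1_gene_test", off = 23L),
    list(mask = s$has_image & s$has_gene, frac = spec$multimodal_train_fraction,
         train = "stage2_train", test = "stage2_test", off = 37L)
  )
  split <- s$split
  for (st in strata) {
    n <- sum(st$mask)
    if (n == 0) next
    tt_assert(n >= 2, "SplitError",
              paste("stratum", st$train, "has fewer than 2 samples"))
    a <- assign_stratum(s$sample_id[st$mask], s$label[st$mask], st$frac,
                        derive_seed(spec$seed, st$off))
    split[s$sample_id %in% a$train] <- st$train
    split[s$sample_id %in% a$test] <- st$test
  }
  chrt$samples$split <- split
  chrt
}

## ---- on-disk cohort layout --------------------------------------------

#' Write a cohort to a directory
#'
#' Writes `manifest.csv` (sample_id, has_image, has_gene, label, split,
#' slice_index), `genes.tsv` (samples x genes, tab-separated) and one
#' NIfTI file per image-bearing sample under `images/` holding the
#' `H x W x 5` slice stack.
#'
#' @param chrt A `twin_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(chrt, dir) {
  stopifnot(inherits(chrt, "twin_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  s <- chrt$samples
  s$slice_index <- vapply(s$sample_id, function(id) {
    if (!is.null(chrt$images[[id]])) chrt$images[[id]]$slice_index else NA_integer_
  }, integer(1))
  utils::write.csv(s, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(chrt$genes)) {
    utils::write.table(
      data.frame(sample_id = rownames(chrt$genes), chrt$genes,
                 check.names = FALSE),
      file.path(dir, "genes.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  for (id in names(chrt$images)) {
    px <- chrt$images[[id]]$pixels
    vol <- aperm(px, c(2, 3, 1)) # H x W x channel
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(dir, "images", paste0(id, ".nii.gz")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort]
#'
#' @param dir Directory containing `manifest.csv` and friends.
#' @return A `twin_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  genes <- NULL
  gpath <- file.path(dir, "genes.tsv")
  if (file.exists(gpath)) {
    gdf <- utils::read.delim(gpath, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.matrix(gdf[, -1, drop = FALSE])
    rownames(genes) <- gdf$sample_id
  }
  images <- list()
  for (i in which(man$has_image)) {
    id <- man$sample_id[i]
    vol <- unclass(as.array(RNifti::readNifti(
      file.path(dir, "images", paste0(id, ".nii.gz")))))
    px <- aperm(vol, c(3, 1, 2))
    dimnames(px) <- list(CHANNELS, NULL, NULL)
    images[[id]] <- structure(
      list(sample_id = id, pixels = px, slice_index = man$slice_index[i]),
      class = "slice_stack"
    )
  }
  cohort(man$sample_id, man$label, images = images, genes = genes,
         split = man$split)
}
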