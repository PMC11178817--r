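# Loading, QC-filtering, normalizing and ontology-annotating sample-based
# expression datasets. Voxel-backed image collections reuse the same
# container with one sample per voxel (annotation = voxel linear index),
# so the query layer has a single code path for both data kinds.

#' Expression dataset
#'
#' Genes x samples expression matrix with per-sample metadata, per-sample
#' region (or voxel) annotation, and a normalization state. The matrix is
#' stored genes-in-rows, matching the usual count-matrix convention.
#'
#' @param mat numeric matrix, genes x samples; rownames = gene ids,
#'   colnames = sample ids (generated if missing).
#' @param meta data frame of per-sample metadata (cell_type, age, phenotype,
#'   ...), one row per sample, or `NULL`.
#' @param annotation per-sample region ids (integer), or for voxel-backed
#'   datasets 0-based voxel linear indices; `NA` = unannotated.
#' @param state one of `"raw"`, `"cpm"`, `"tpm"`, `"log2p1"`,
#'   `"sigmoid-unit"`, `"rpkm"`.
#' @param voxel_backed logical; `TRUE` when samples are voxels of the
#'   reference space and `annotation` holds voxel linear indices.
#' @param dataset_id identifier used in reports and coverage tables.
#' @return An `expression_dataset`.
#' @export
expression_dataset <- function(mat, meta = NULL, annotation = NULL,
                               state = "raw", voxel_backed = FALSE,
                               dataset_id = "dataset") {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  if (any(!is.finite(mat))) stop("matrix entries must be finite")
  if (state != "log2p1" && any(mat < 0)) stop("negative expression values")
  if (is.null(meta)) meta <- data.frame(row.names = colnames(mat))
  if (nrow(meta) != ncol(mat)) stop("metadata rows must match sample count")
  rownames(meta) <- colnames(mat)
  if (!is.null(annotation) && length(annotation) != ncol(mat))
    stop("annotation length must match sample count")
  structure(list(mat = mat, meta = meta,
                 annotation = if (is.null(annotation))
                   rep(NA_real_, ncol(mat)) else as.numeric(annotation),
                 state = state, voxel_backed = voxel_backed,
                 dataset_id = dataset_id),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s'> %d genes x %d samples [%s]%s\n",
              x$dataset_id, nrow(x$mat), ncol(x$mat), x$state,
              if (x$voxel_backed) " (voxel-backed)" else ""))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$mat)

genes <- function(ds) rownames(ds$mat)
samples <- function(ds) colnames(ds$mat)

subset_samples <- function(ds, keep) {
  # keep: logical or index vector over samples
  ds$mat <- ds$mat[, keep, drop = FALSE]
  ds$meta <- ds$meta[keep, , drop = FALSE]
  ds$annotation <- ds$annotation[keep]
  ds
}

## ---------------------------------------------------------------------------
## Quality control

#' QC filter for single-cell/nucleus samples
#'
#' Two-stage filter on the number of unique genes detected per sample
#' (entries > 0): first samples below `min_genes` or above `max_genes` are
#' removed (low-quality cells, empty droplets, doublets); then, among the
#' remaining samples, those whose unique-gene count deviates from the median
#' by more than `mad_k` times the median absolute deviation are removed as
#' outliers. The MAD is unscaled (no normal-consistency constant).
#'
#' @param ds raw-count [expression_dataset()].
#' @param min_genes,max_genes inclusive retention bounds on unique genes
#'   detected (defaults 50 and 5000).
#' @param mad_k MAD multiplier for the outlier stage (default 5).
#' @return Filtered dataset; attribute `"qc_report"` lists removed counts.
#' @export
qc_filter_cells <- function(ds, min_genes = 50, max_genes = 5000, mad_k = 5) {
  if (ds$state != "raw") stop("QC expects raw counts, got state '", ds$state, "'")
  if (any(ds$mat != round(ds$mat))) stop("QC expects an integer count matrix")
  ngene <- colSums(ds$mat > 0)
  keep_range <- ngene >= min_genes & ngene <= max_genes
  n_range <- sum(!keep_range)
  ds2 <- subset_samples(ds, keep_range)
  ngene2 <- ngene[keep_range]
  med <- median(ngene2)
  madv <- median(abs(ngene2 - med))
  bound <- mad_k * madv
  if (is.nan(bound)) bound <- Inf       # infinite multiplier on a zero MAD
  keep_mad <- abs(ngene2 - med) <= bound
  n_mad <- sum(!keep_mad)
  out <- subset_samples(ds2, keep_mad)
  attr(out, "qc_report") <- list(removed_range = n_range, removed_mad = n_mad,
                                 retained = ncol(out$mat))
  out
}

## ---------------------------------------------------------------------------
## Normalization

#' Counts-per-million normalization
#'
#' Rescales every sample (column) to a total of 1e6 so expression is
#' comparable across samples within a dataset.
#'
#' @param ds raw-count [expression_dataset()].
#' @return Dataset with state `"cpm"`.
#' @export
normalize_cpm <- function(ds) {
  tot <- colSums(ds$mat)
  if (any(tot <= 0))
    stop("zero-total sample(s): ",
         paste(colnames(ds$mat)[tot <= 0], collapse = ", "),
         " (should have been removed by QC)")
  ds$mat <- sweep(ds$mat, 2, tot, `/`) * 1e6
  ds$state <- "cpm"
  ds
}

#' RPKM to TPM conversion
#'
#' Within each sample, TPM is the RPKM value divided by the sample's RPKM
#' total, times 1e6 — length normalization is already in RPKM, so only the
#' per-sample rescale remains.
#'
#' @param ds [expression_dataset()] holding RPKM values.
#' @return Dataset with state `"tpm"`.
#' @export
rpkm_to_tpm <- function(ds) {
  tot <- colSums(ds$mat)
  if (any(tot <= 0))
    stop("zero-sum column(s): ", paste(colnames(ds$mat)[tot <= 0], collapse = ", "))
  ds$mat <- sweep(ds$mat, 2, tot, `/`) * 1e6
  ds$state <- "tpm"
  ds
}

#' log2(x + 1) transform
#'
#' @param ds [expression_dataset()] with nonnegative values.
#' @return Dataset with state `"log2p1"`.
#' @export
log2p1 <- function(ds) {
  if (any(ds$mat < 0)) stop("log2p1 requires nonnegative values")
  ds$mat <- log2(ds$mat + 1)
  ds$state <- "log2p1"
  ds
}

#' Scaled robust sigmoid normalization
#'
#' Outlier-robust sigmoid around the median with an IQR-based scale
#' (IQR / 1.349, the normal-consistent spread estimate), followed by min-max
#' rescaling to the unit interval. Used for microarray expression so values
#' are comparable across probes regardless of outliers.
#'
#' @param values numeric vector (one gene across samples), length >= 2.
#' @return Vector in `[0, 1]`; all zeros (with a warning) when the IQR is 0.
#' @export
scaled_robust_sigmoid <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  iqr <- IQR(values)
  if (iqr == 0) {
    warning("IQR is zero; returning constant 0")
    return(rep(0, length(values)))
  }
  y <- 1 / (1 + exp(-(values - median(values)) / (iqr / 1.349)))
  (y - min(y)) / (max(y) - min(y))
}

## ---------------------------------------------------------------------------
## Gene matching

#' Gene reference table
#'
#' @param symbol,ensembl,entrez,gene_id character vectors of equal length;
#'   `gene_id` is the canonical identifier (unique).
#' @return A `gene_reference` data frame.
#' @export
gene_reference <- function(symbol, ensembl, entrez, gene_id) {
  if (anyDuplicated(gene_id)) stop("canonical gene ids must be unique")
  structure(data.frame(symbol = as.character(symbol),
                       ensembl = as.character(ensembl),
                       entrez = as.character(entrez),
                       gene_id = as.character(gene_id),
                       stringsAsFactors = FALSE),
            class = c("gene_reference", "data.frame"))
}

#' @rdname gene_reference
#' @param path TSV with columns symbol, ensembl, entrez, gene_id.
#' @export
read_gene_reference <- function(path) {
  df <- read.delim(path, colClasses = "character")
  gene_reference(df$symbol, df$ensembl, df$entrez, df$gene_id)
}

#' Match dataset genes to a canonical gene reference
#'
#' Each gene id is looked up first as a symbol, then as an Ensembl id, then
#' as an Entrez id; the first hit wins. Unmatched genes are dropped. When two
#' dataset rows collapse onto the same canonical gene, the row with the
#' larger total expression is kept.
#'
#' @param ds [expression_dataset()].
#' @param ref a [gene_reference()].
#' @return Dataset keyed by canonical gene ids; attribute `"match_report"`
#'   carries matched/dropped/collapsed counts.
#' @export
match_genes <- function(ds, ref) {
  ids <- genes(ds)
  hit <- ref$gene_id[match(ids, ref$symbol)]
  miss <- is.na(hit)
  hit[miss] <- ref$gene_id[match(ids[miss], ref$ensembl)]
  miss <- is.na(hit)
  hit[miss] <- ref$gene_id[match(ids[miss], ref$entrez)]
  matched <- !is.na(hit)
  n_dropped <- sum(!matched)
  mat <- ds$mat[matched, , drop = FALSE]
  canon <- hit[matched]
  n_collapsed <- 0L
  if (anyDuplicated(canon)) {
    tot <- rowSums(mat)
    keep <- unlist(lapply(split(seq_along(canon), canon), function(i)
      i[which.max(tot[i])]), use.names = FALSE)
    n_collapsed <- length(canon) - length(keep)
    mat <- mat[sort(keep), , drop = FALSE]
    canon <- canon[sort(keep)]
  }
  rownames(mat) <- canon
  if (!nrow(mat)) warning("no genes matched the reference")
  ds$mat <- mat
  attr(ds, "match_report") <- list(matched = nrow(mat), dropped = n_dropped,
                                   collapsed = n_collapsed)
  ds
}

## ---------------------------------------------------------------------------
## Region annotation

#' Annotate samples with ontology region ids
#'
#' Maps each sample's original region name (metadata column `region`) to a
#' reference-ontology region id through a curated name-to-id table. Samples
#' whose region has no mapping are removed and reported, mirroring how cells
#' that cannot be matched to a brain region are excluded.
#'
#' @param ds [expression_dataset()] whose metadata has a `region` column.
#' @param ont the reference ontology.
#' @param mapping data frame with columns `region` (name in the dataset) and
#'   `region_id` (ontology id).
#' @return Annotated dataset; attribute `"annotation_report"` lists the
#'   number of removed samples.
#' @export
annotate_samples <- function(ds, ont, mapping) {
  if (!"region" %in% names(ds$meta)) stop("metadata must contain a 'region' column")
  bad <- setdiff(mapping$region_id, ont$id)
  if (length(bad)) stop("mapping targets not in ontology: ", paste(bad, collapse = ", "))
  rid <- mapping$region_id[match(ds$meta$region, mapping$region)]
  keep <- !is.na(rid)
  out <- subset_samples(ds, keep)
  out$annotation <- as.numeric(rid[keep])
  attr(out, "annotation_report") <- list(removed = sum(!keep), retained = sum(keep))
  out
}

## ---------------------------------------------------------------------------
## TSV I/O

#' Read / write expression matrices and metadata as TSV
#'
#' Matrix layout is genes x samples with a header row of sample ids and the
#' gene id in the first column; metadata is one row per sample with a
#' `sample_id` column.
#'
#' @param path file path.
#' @param meta_path optional metadata TSV.
#' @param ... passed to [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, meta_path = NULL, ...) {
  df <- read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read.delim(meta_path, check.names = FALSE)
    rownames(meta) <- meta$sample_id
    meta <- meta[colnames(mat), setdiff(names(meta), "sample_id"), drop = FALSE]
  }
  expression_dataset(mat, meta = meta, ...)
}

#' @rdname read_expression_tsv
#' @param ds dataset to write.
#' @export
write_expression_tsv <- function(ds, path, meta_path = NULL) {
  df <- data.frame(gene_id = genes(ds), ds$mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    md <- data.frame(sample_id = samples(ds), ds$meta,
                     region_id = ds$annotation, check.names = FALSE)
    write.table(md, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
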