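# VOI gene-expression queries. All four queries are ratios of per-gene means
# over intersections of three sample subsets:
#   V - samples inside the volume of interest,
#   C - samples of the chosen cell type(s),
#   F - samples passing the remaining metadata filters.
# A region-annotated sample belongs to V when its annotation region's voxel
# set intersects the VOI (unweighted); a voxel-backed sample belongs to V
# when its voxel is in the VOI. This makes a query at any VOI contained in
# the annotation region identical to a query at the region itself, which is
# the hierarchical-aggregation contract of the ontology mapping.

#' Select samples by VOI, cell type and metadata filters
#'
#' @param ds annotated [expression_dataset()].
#' @param voi a [voi()].
#' @param parc,ont parcellation and ontology (needed for region-annotated
#'   datasets; ignored for voxel-backed ones).
#' @param cell_types character vector of cell types, or `NULL` for all.
#'   Read from metadata column `cell_type`.
#' @param meta named list mapping metadata attribute to the set of accepted
#'   categories, or `NULL` for no filter.
#' @return A `sample_selection`: logical vectors `V`, `C`, `F` over samples
#'   and their intersection `selected`.
#' @export
select_samples <- function(ds, voi, parc = NULL, ont = NULL,
                           cell_types = NULL, meta = NULL) {
  n <- ncol(ds$mat)
  ann <- ds$annotation
  if (ds$voxel_backed) {
    V <- !is.na(ann) & ann %in% voi$lin
  } else {
    V <- rep(FALSE, n)
    regs <- unique(ann[!is.na(ann)])
    if (length(regs)) {
      if (is.null(parc) || is.null(ont))
        stop("`parc` and `ont` required for region-annotated datasets")
      hit <- vapply(regs, function(r)
        length(intersect(region_voxels(parc, ont, r)$lin, voi$lin)) > 0, TRUE)
      V <- !is.na(ann) & ann %in% regs[hit]
    }
  }
  C <- rep(TRUE, n)
  if (!is.null(cell_types)) {
    if (!"cell_type" %in% names(ds$meta)) stop("no 'cell_type' metadata attribute")
    C <- ds$meta$cell_type %in% cell_types
  }
  F_ <- rep(TRUE, n)
  if (!is.null(meta)) {
    for (attr_ in names(meta)) {
      if (!attr_ %in% names(ds$meta))
        stop("unknown metadata attribute: ", attr_)
      F_ <- F_ & ds$meta[[attr_]] %in% meta[[attr_]]
    }
  }
  structure(list(V = V, C = C, F = F_, selected = V & C & F_),
            class = "sample_selection")
}

#' @export
print.sample_selection <- function(x, ...) {
  cat(sprintf("<sample_selection> |V|=%d |C|=%d |F|=%d |V&C&F|=%d\n",
              sum(x$V), sum(x$C), sum(x$F), sum(x$selected)))
  invisible(x)
}

new_query_result <- function(gene, score, type, ds, voi_prov = NA, filters = NULL) {
  structure(data.frame(gene = gene, score = score,
                       rank = rep(NA_real_, length(gene)),
                       stringsAsFactors = FALSE),
            descriptor = list(dataset = ds$dataset_id, query = type,
                              voi = voi_prov, filters = filters,
                              state = ds$state),
            class = c("query_result", "data.frame"))
}

empty_result <- function(type, ds) {
  warning("empty sample selection for ", type, " query on '", ds$dataset_id,
          "'; returning empty result", call. = FALSE)
  structure(new_query_result(character(0), numeric(0), type, ds),
            class = c("empty_result", "query_result", "data.frame"))
}

row_mean <- function(mat, keep) {
  if (!sum(keep)) return(NULL)
  rowMeans(mat[, keep, drop = FALSE])
}

ratio_result <- function(ds, num_keep, den_keep, type) {
  num <- row_mean(ds$mat, num_keep)
  if (is.null(num)) return(empty_result(type, ds))
  den <- row_mean(ds$mat, den_keep)
  if (is.null(den)) return(empty_result(type, ds))
  score <- ifelse(den == 0, NA_real_, num / den)   # undefined, not Inf/NaN
  new_query_result(genes(ds), score, type, ds)
}

#' Mean expression query
#'
#' Per-gene mean expression over the selected samples (V, C and F
#' intersected).
#'
#' @param ds [expression_dataset()].
#' @param sel a [select_samples()] selection.
#' @return A `query_result` data frame (gene, score, rank); an
#'   `empty_result` when no sample is selected.
#' @export
mean_expression <- function(ds, sel) {
  m <- row_mean(ds$mat, sel$selected)
  if (is.null(m)) return(empty_result("mean", ds))
  new_query_result(genes(ds), m, "mean", ds)
}

#' Region specificity query
#'
#' Mean expression inside the VOI divided by the mean over all samples of the
#' same cell type/filter selection across the whole brain (denominator over
#' C intersected with F). Values above 1 mark genes expressed more strongly
#' in the VOI than brain-wide.
#'
#' @inheritParams mean_expression
#' @export
region_specificity <- function(ds, sel)
  ratio_result(ds, sel$selected, sel$C & sel$F, "region-specificity")

#' Cell type specificity query
#'
#' Mean expression of the chosen cell type inside the VOI divided by the mean
#' over samples of all cell types inside the VOI (denominator over V
#' intersected with F). Emphasizes genes whose VOI expression is carried by
#' the chosen cell type.
#'
#' @inheritParams mean_expression
#' @export
cell_type_specificity <- function(ds, sel)
  ratio_result(ds, sel$selected, sel$V & sel$F, "celltype-specificity")

#' Enrichment query
#'
#' Mean expression of the filtered selection inside the VOI divided by the
#' mean over all samples inside the VOI (denominator over V alone).
#'
#' @inheritParams mean_expression
#' @export
enrichment <- function(ds, sel)
  ratio_result(ds, sel$selected, sel$V, "enrichment")

#' Gene ranks for a query result
#'
#' Rank 1 is the highest score; tied scores share the average rank; genes
#' with undefined scores stay unranked. Ranks give a batch-robust relative
#' measure when absolute values are not comparable across datasets.
#'
#' @param res a `query_result`.
#' @return The result with the `rank` column filled.
#' @export
gene_ranks <- function(res) {
  if (!nrow(res) || all(is.na(res$score)))
    stop("no defined scores to rank")
  res$rank <- rank(-res$score, na.last = "keep", ties.method = "average")
  res
}

#' Dataset coverage table
#'
#' Tabulates, for every region column and dataset (optionally subdivided by
#' metadata attributes), how many samples a VOI query on that region would
#' select, together with the original region annotations of those samples
#' ("sample region annotations", kept for provenance).
#'
#' @param datasets list of annotated [expression_dataset()]s.
#' @param ont,parc ontology and parcellation.
#' @param regions region ids forming the table columns.
#' @param group_by character vector of metadata attributes to subdivide
#'   dataset rows by (e.g. `"cell_type"`).
#' @return Long-format data frame: dataset, group columns, region,
#'   `n_samples`, `annotations` (comma-separated original region ids).
#' @export
coverage_table <- function(datasets, ont, parc, regions, group_by = character(0)) {
  rows <- list()
  for (ds in datasets) {
    grp <- if (length(group_by)) {
      interaction(ds$meta[, group_by, drop = FALSE], drop = TRUE, sep = "/")
    } else factor(rep("all", ncol(ds$mat)))
    for (r in regions) {
      sel <- select_samples(ds, region_voxels(parc, ont, r), parc, ont)
      for (g in levels(grp)) {
        in_cell <- sel$selected & grp == g
        ann <- sort(unique(ds$annotation[in_cell]))
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds$dataset_id, group = g, region = r,
          n_samples = sum(in_cell),
          annotations = paste(ann, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Region-by-gene expression matrix from repeated VOI queries
#'
#' Runs one VOI query per region (VOI = the region's voxel set) and stacks
#' the per-gene scores into a regions x genes matrix — the expression input
#' to region-level expression-connectivity correlations.
#'
#' @param ds annotated [expression_dataset()].
#' @param regions region ids (matrix rows).
#' @param parc,ont parcellation and ontology.
#' @param cell_types,meta filters as in [select_samples()].
#' @param query `"mean"` (mean expression) or `"celltype-specificity"`.
#' @return Numeric matrix, regions x genes; a region with no selected
#'   samples yields a row of `NA`.
#' @export
region_expression_matrix <- function(ds, regions, parc, ont,
                                     cell_types = NULL, meta = NULL,
                                     query = c("mean", "celltype-specificity")) {
  query <- match.arg(query)
  out <- matrix(NA_real_, length(regions), nrow(ds$mat),
                dimnames = list(as.character(regions), genes(ds)))
  for (i in seq_along(regions)) {
    sel <- select_samples(ds, region_voxels(parc, ont, regions[i]), parc, ont,
                          cell_types = cell_types, meta = meta)
    if (!sum(sel$selected)) next
    res <- if (query == "mean") mean_expression(ds, sel)
           else cell_type_specificity(ds, sel)
    out[i, res$gene] <- res$score
  }
  out
}

#' Export a query result as tabulated text
#'
#' Writes gene/score/rank as TSV preceded by a `#`-prefixed header block
#' recording the dataset, query type, VOI provenance, filters, package
#' version and an optional seed, so every exported artifact is
#' self-describing.
#'
#' @param res a `query_result`.
#' @param path output path.
#' @param extra named list of extra header fields (e.g. seed, config hash).
#' @export
write_query_result <- function(res, path, extra = NULL) {
  d <- attr(res, "descriptor")
  hdr <- c(dataset = d$dataset, query = d$query, voi = as.character(d$voi),
           filters = if (is.null(d$filters)) "none" else
             paste(names(d$filters), vapply(d$filters, paste, "", collapse = "|"),
                   sep = "=", collapse = ";"),
           state = d$state, version = as.character(packageVersion("atlasfuse")))
  if (!is.null(extra)) hdr <- c(hdr, unlist(lapply(extra, as.character)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
  write.table(as.data.frame(res), con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
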