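# Morton z-order spatial indexing. Items (connectome rows/columns, per-voxel
# image stacks, located samples) are keyed by bit-interleaving their voxel
# coordinates, so items close in 3D stay close in key order and a VOI can be
# fetched as a small number of contiguous key ranges instead of a full scan.

#' Morton z-order key
#'
#' Interleaves the bits of the three voxel coordinates into one nonnegative
#' integer key; the x bit is the least significant of each triplet, so
#' `(1,0,0) -> 1`, `(0,1,0) -> 2`, `(0,0,1) -> 4`. Keys are exact doubles for
#' `bits <= 17` (3 x 17 = 51 bits), far beyond any practical grid here.
#'
#' @param x,y,z voxel indices in `[0, 2^bits)`, or `x` an n x 3 matrix.
#' @param bits bits per axis.
#' @return Numeric vector of keys.
#' @export
morton_key <- function(x, y = NULL, z = NULL, bits) {
  if (is.matrix(x)) { y <- x[, 2]; z <- x[, 3]; x <- x[, 1] }
  if (any(c(x, y, z) < 0) || any(c(x, y, z) >= 2^bits))
    stop("coordinate out of range for ", bits, " bits per axis")
  key <- numeric(length(x))
  for (b in seq_len(bits) - 1L) {
    key <- key +
      ((x %/% 2^b) %% 2) * 2^(3 * b) +
      ((y %/% 2^b) %% 2) * 2^(3 * b + 1) +
      ((z %/% 2^b) %% 2) * 2^(3 * b + 2)
  }
  key
}

#' Build a spatial index over located items
#'
#' Sorts items by Morton key; items at equal keys keep their original
#' relative order (stable), so the permutation is deterministic.
#'
#' @param ids item identifiers (any vector).
#' @param locations n x 3 matrix of 0-based voxel indices.
#' @param space [reference_space()] the locations live in; the grid is
#'   padded to the next power of two for the key computation.
#' @return A `spatial_index`: `ids`, `locations`, `keys`, `perm` (order of
#'   original positions sorted by key), `bits`.
#' @export
build_index <- function(ids, locations, space) {
  locations <- rbind(locations)
  voxel_lin(locations, space)              # bounds check against the grid
  bits <- max(1L, ceiling(log2(max(space$shape))))
  keys <- morton_key(locations, bits = bits)
  perm <- order(keys, seq_along(keys))     # stable on ties
  structure(list(ids = ids, locations = locations, keys = keys,
                 perm = perm, bits = bits, space = space),
            class = "spatial_index")
}

#' @export
print.spatial_index <- function(x, ...) {
  cat(sprintf("<spatial_index> %d items, %d bits/axis\n",
              length(x$keys), x$bits))
  invisible(x)
}

# Collapse a sorted vector of integer keys into runs of consecutive values.
key_ranges <- function(keys) {
  if (!length(keys)) return(matrix(numeric(0), ncol = 2))
  brk <- c(0L, which(diff(keys) > 1), length(keys))
  cbind(from = keys[head(brk, -1) + 1L], to = keys[brk[-1]])
}

#' Retrieve the items of a VOI through the spatial index
#'
#' Converts the VOI's voxels to Morton keys, collapses them into contiguous
#' key ranges, and fetches each range as one slice of the key-sorted item
#' order — the access pattern that makes on-disk retrieval near-sequential.
#' The returned multiset of items is exactly what a naive scan over all item
#' locations would select.
#'
#' @param idx a [build_index()] index.
#' @param store vector or list of per-item payloads in the *original* item
#'   order (e.g. expression columns), or `NULL` for ids only.
#' @param voi a [voi()] on the same grid.
#' @return List with `ids`, `values` (subset of `store`), `positions`
#'   (original item positions) and `n_ranges` (contiguous key ranges
#'   touched).
#' @export
range_query <- function(idx, store = NULL, voi) {
  vox_keys <- sort(unique(morton_key(lin_voxel(voi$lin, voi$space), bits = idx$bits)))
  ranges <- key_ranges(vox_keys)
  sorted_keys <- idx$keys[idx$perm]
  pos_sorted <- integer(0)
  for (i in seq_len(nrow(ranges))) {
    lo <- findInterval(ranges[i, 1] - 0.5, sorted_keys) + 1L
    hi <- findInterval(ranges[i, 2] + 0.5, sorted_keys)
    if (hi >= lo) pos_sorted <- c(pos_sorted, lo:hi)
  }
  positions <- idx$perm[pos_sorted]
  list(ids = idx$ids[positions],
       values = if (is.null(store)) NULL else store[positions],
       positions = positions,
       n_ranges = nrow(ranges))
}

## ---------------------------------------------------------------------------
## Metadata pre-aggregation

#' Pre-aggregate samples by metadata group and annotation region
#'
#' Stores, per (metadata group x annotation region), the per-gene mean and
#' the sample count, so a mean-expression query whose cell-type/metadata
#' filters align with the grouping attributes can be answered from the
#' aggregate alone as a count-weighted mean of group means — no per-sample
#' pass needed.
#'
#' @param ds annotated [expression_dataset()].
#' @param keys metadata attributes to group by (e.g.
#'   `c("cell_type", "age")`).
#' @return A `preaggregate`: `means` (groups x genes), `counts`, `groups`
#'   (data frame of key values + `region`), `keys`.
#' @export
preaggregate <- function(ds, keys = character(0)) {
  bad <- setdiff(keys, names(ds$meta))
  if (length(bad)) stop("unknown attribute(s): ", paste(bad, collapse = ", "))
  located <- !is.na(ds$annotation)
  meta <- ds$meta[located, keys, drop = FALSE]
  meta$region <- ds$annotation[located]
  grp <- interaction(meta, drop = TRUE, sep = "\r")
  idx_by_grp <- split(which(located), grp)
  means <- do.call(rbind, lapply(idx_by_grp, function(i)
    rowMeans(ds$mat[, i, drop = FALSE])))
  counts <- vapply(idx_by_grp, length, integer(1))
  first_row <- vapply(split(seq_len(nrow(meta)), grp), `[`, integer(1), 1L)
  groups <- meta[first_row, , drop = FALSE]
  rownames(groups) <- NULL
  structure(list(means = means, counts = counts, groups = groups,
                 keys = keys, genes = genes(ds), dataset_id = ds$dataset_id),
            class = "preaggregate")
}

#' @export
print.preaggregate <- function(x, ...) {
  cat(sprintf("<preaggregate '%s'> %d groups (%s x region), %d genes\n",
              x$dataset_id, nrow(x$means),
              if (length(x$keys)) paste(x$keys, collapse = "+") else "none",
              length(x$genes)))
  invisible(x)
}

#' Answer a mean-expression query from a pre-aggregate
#'
#' Valid only when every requested filter attribute is one of the
#' aggregate's grouping keys (filters aligned with group boundaries);
#' otherwise returns `NULL` so the caller can fall back to the raw
#' per-sample path.
#'
#' @param pre a [preaggregate()].
#' @param voi query [voi()].
#' @param parc,ont parcellation and ontology.
#' @param cell_types,meta filters as in [select_samples()].
#' @return Named per-gene mean vector, `NULL` if the query does not align,
#'   or a zero-length vector if no group matches.
#' @export
preaggregate_mean <- function(pre, voi, parc, ont, cell_types = NULL, meta = NULL) {
  wanted <- c(if (!is.null(cell_types)) "cell_type", names(meta))
  if (length(setdiff(wanted, pre$keys))) return(NULL)   # fall back to raw path
  regs <- unique(pre$groups$region)
  hit <- regs[vapply(regs, function(r)
    length(intersect(region_voxels(parc, ont, r)$lin, voi$lin)) > 0, TRUE)]
  keep <- pre$groups$region %in% hit
  if (!is.null(cell_types)) keep <- keep & pre$groups$cell_type %in% cell_types
  for (attr_ in names(meta)) keep <- keep & pre$groups[[attr_]] %in% meta[[attr_]]
  if (!sum(keep)) return(setNames(numeric(0), character(0)))
  w <- pre$counts[keep]
  setNames(colSums(pre$means[keep, , drop = FALSE] * w) / sum(w), pre$genes)
}
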