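# Voxel-level structural connectome assembly from tracer injection records,
# grayordinate-to-voxel mapping for functional connectivity, and VOI-level
# aggregation of connectivity.

#' Injection record
#'
#' One tracer experiment: the injection site coordinate, the injection
#' volume (set of source voxels the tracer infected), and a per-voxel image
#' of projection strength to every target voxel of the reference space.
#'
#' @param site numeric length 3, 0-based voxel coordinate of the site.
#' @param volume [voi()] or n x 3 voxel index matrix: the injection volume.
#' @param image 3D array of projection strength, reference-space shape.
#' @param space the [reference_space()].
#' @return An `injection_record`.
#' @export
injection_record <- function(site, volume, image, space) {
  if (!inherits(volume, "voi")) volume <- make_voi(rbind(volume), space)
  if (!length(volume)) stop("injection volume must be nonempty")
  image <- as.array(image)
  if (!identical(dim(image), as.integer(space$shape)))
    stop("image shape must equal reference shape")
  structure(list(site = as.numeric(site), volume = volume,
                 image = image, space = space),
            class = "injection_record")
}

mirror_index <- function(idx, n) n - 1L - idx

mirror_record <- function(rec, axis) {
  s <- rec$space$shape
  vox <- voi_voxels(rec$volume)
  vox[, axis] <- mirror_index(vox[, axis], s[axis])
  site <- rec$site
  site[axis] <- mirror_index(site[axis], s[axis])
  flip <- switch(axis,
                 rec$image[s[1]:1, , , drop = FALSE],
                 rec$image[, s[2]:1, , drop = FALSE],
                 rec$image[, , s[3]:1, drop = FALSE])
  injection_record(site, make_voi(vox, rec$space), array(flip, dim = s), rec$space)
}

#' Assemble a voxel-level structural connectome from injection records
#'
#' Every source voxel covered by at least one injection volume receives a
#' row of target weights taken from the covering record's image; voxels
#' covered by several injection volumes are resolved by the per-target
#' maximum. With `mirror` set, each record is duplicated reflected about the
#' mid-plane of that axis before assembly (compensating hemispheric
#' injection imbalance), doubling the effective injection-site count.
#' Finally all weights strictly below `threshold` are zeroed to suppress
#' false-positive projections.
#'
#' @param records list of [injection_record()]s sharing one reference space.
#' @param threshold projection-strength floor (default `10^-4.5`).
#' @param mirror reflection axis (1-3) or `NULL` for none.
#' @return A `connectome`: `sources` (0-based linear voxel indices, one per
#'   covered voxel), dense `weights` (sources x all voxels), `space`,
#'   `n_effective_sites`, `threshold`.
#' @export
assemble_structural <- function(records, threshold = 10^-4.5, mirror = NULL) {
  if (!length(records)) stop("empty record list")
  space <- records[[1L]]$space
  if (!all(vapply(records, function(r) identical(r$space$shape, space$shape), TRUE)))
    stop("records must share the reference space")
  if (!is.null(mirror)) {
    if (!mirror %in% 1:3) stop("mirror axis must be 1, 2 or 3")
    records <- c(records, lapply(records, mirror_record, axis = mirror))
  }
  nv <- n_voxels(space)
  covered <- sort(unique(unlist(lapply(records, function(r) r$volume$lin))))
  weights <- matrix(0, nrow = length(covered), ncol = nv)
  for (rec in records) {
    rows <- match(rec$volume$lin, covered)
    img <- as.vector(rec$image)
    weights[rows, ] <- pmax(weights[rows, , drop = FALSE],
                            matrix(img, nrow = length(rows), ncol = nv, byrow = TRUE))
  }
  weights[weights < threshold] <- 0
  structure(list(sources = covered, weights = weights, space = space,
                 directed = TRUE, provenance = "assembled",
                 n_effective_sites = length(records), threshold = threshold),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d source voxels x %d targets (%s, %d injection sites)\n",
              length(x$sources), ncol(x$weights), x$provenance,
              x$n_effective_sites))
  invisible(x)
}

#' Map grayordinates to reference-space voxels
#'
#' Assigns every requested voxel the grayordinate (cortical surface vertex
#' or subcortical voxel) whose physical coordinate is nearest to the voxel
#' center (Euclidean distance); equidistant ties go to the lowest
#' grayordinate index. Used to bring a grayordinate-space dense connectome
#' into the voxel reference space.
#'
#' @param gmap data frame with columns `index`, `x`, `y`, `z` (physical
#'   coordinates) and optionally `kind` (`"vertex"`/`"voxel"`).
#' @param space target [reference_space()].
#' @param voxels n x 3 matrix of 0-based voxel indices to assign (default:
#'   the full grid).
#' @return Integer vector: the grayordinate `index` per voxel.
#' @export
map_grayordinates <- function(gmap, space, voxels = NULL) {
  if (!nrow(gmap)) stop("empty grayordinate map")
  if (any(!is.finite(as.matrix(gmap[, c("x", "y", "z")]))))
    stop("grayordinate coordinates must be finite")
  if (is.null(voxels)) voxels <- lin_voxel(seq_len(n_voxels(space)) - 1, space)
  centers <- voxel_centers(voxels, space)
  coords <- as.matrix(gmap[, c("x", "y", "z")])
  ord <- order(gmap$index)           # ties resolved to lowest index
  coords <- coords[ord, , drop = FALSE]
  idx <- gmap$index[ord]
  assign <- integer(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    d2 <- colSums((t(coords) - centers[i, ])^2)
    assign[i] <- idx[which.min(d2)]  # which.min takes the first = lowest index
  }
  assign
}

#' Aggregate outgoing connectivity of a VOI
#'
#' Per target voxel, the mean projection weight over the VOI's source voxels
#' that carry data (source voxels without a connectome row are excluded from
#' the mean, not counted as zero). `statistic = "max"` takes the per-target
#' maximum instead.
#'
#' @param conn a [assemble_structural()] connectome.
#' @param voi source [voi()].
#' @param statistic `"mean"` (default) or `"max"`.
#' @return A `target_map`: 3D array of aggregated strength over the
#'   reference space, with attribute `n_sources` (covered VOI voxels);
#'   `NULL` when the VOI covers no source voxel (empty-result signal, with a
#'   warning).
#' @export
aggregate_outgoing <- function(conn, voi, statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  rows <- match(intersect(voi$lin, conn$sources), conn$sources)
  if (!length(rows)) {
    warning("VOI covers no connectome source voxel; empty result")
    return(NULL)
  }
  w <- conn$weights[rows, , drop = FALSE]
  strength <- if (statistic == "mean") colMeans(w) else apply(w, 2, max)
  structure(array(strength, dim = conn$space$shape),
            n_sources = length(rows), space = conn$space, class = "target_map")
}

#' Strongest targets of an aggregated connectivity map
#'
#' The `k` strongest target voxels (or, for fractional `k` < 1, the top
#' fraction of positive-strength voxels), ties broken by Morton z-order key
#' so the cutoff is deterministic.
#'
#' @param tmap a `target_map` from [aggregate_outgoing()].
#' @param k positive count, or a fraction in (0, 1).
#' @return A [voi()] of target voxels (provenance `"targets"`).
#' @export
strongest_targets <- function(tmap, k) {
  if (k <= 0) stop("k must be positive")
  space <- attr(tmap, "space")
  strength <- as.vector(tmap)
  pos <- which(strength > 0) - 1L
  if (!length(pos)) stop("target map has no positive strength")
  if (k < 1) k <- ceiling(k * length(pos))
  k <- min(k, length(pos))
  bits <- ceiling(log2(max(space$shape)))
  keys <- morton_key(lin_voxel(pos, space), bits = max(bits, 1L))
  ord <- order(-strength[pos + 1L], keys)
  new_voi(pos[ord[seq_len(k)]], space, "targets")
}

#' Region-level connectivity profile of a source VOI
#'
#' Aggregates the VOI's outgoing (or incoming) connectivity and averages the
#' resulting target strength over each requested region's voxels, yielding
#' one strength per region — the region-profile vectors correlated against
#' regional gene expression.
#'
#' @param conn a connectome.
#' @param source_voi source (or target, for `direction = "incoming"`) VOI.
#' @param regions region ids.
#' @param ont,parc ontology and parcellation.
#' @param direction `"outgoing"` (rows = VOI) or `"incoming"` (transposed
#'   weights: columns = VOI, rows aggregated over regions).
#' @param statistic passed to [aggregate_outgoing()].
#' @return Named numeric vector, one entry per region (`NA` for a region
#'   with no voxels).
#' @export
region_profile <- function(conn, source_voi, regions, ont, parc,
                           direction = c("outgoing", "incoming"),
                           statistic = "mean") {
  direction <- match.arg(direction)
  if (!length(regions)) stop("regions must be nonempty")
  if (direction == "incoming") conn <- transpose_connectome(conn)
  tmap <- aggregate_outgoing(conn, source_voi, statistic = statistic)
  if (is.null(tmap)) stop("VOI covers no connectome source voxel")
  strength <- as.vector(tmap)
  out <- vapply(regions, function(r) {
    voxr <- region_voxels(parc, ont, r)
    if (!length(voxr)) return(NA_real_)
    mean(strength[voxr$lin + 1L])
  }, numeric(1))
  names(out) <- as.character(regions)
  out
}

# Incoming profiles reuse aggregate_outgoing on the transpose: rows become
# all voxels (the original targets) and columns all voxels, zero where the
# original source was uncovered. Materializing the full grid is fine at the
# scales the package targets.
transpose_connectome <- function(conn) {
  nv <- n_voxels(conn$space)
  w <- matrix(0, nrow = nv, ncol = nv)
  w[, conn$sources + 1L] <- t(conn$weights)
  structure(list(sources = seq_len(nv) - 1, weights = w, space = conn$space,
                 directed = TRUE, provenance = conn$provenance,
                 n_effective_sites = conn$n_effective_sites,
                 threshold = conn$threshold),
            class = "connectome")
}

#' Read / write a small connectome as CSV
#'
#' Plain-text interchange for fixture-scale connectomes: one row per source
#' voxel, first column the 0-based source linear index, remaining columns
#' the dense target weights in linear-voxel order.
#'
#' @param conn connectome to write.
#' @param path file path.
#' @export
write_connectome_csv <- function(conn, path) {
  df <- data.frame(source_lin = conn$sources, conn$weights, check.names = FALSE)
  colnames(df) <- c("source_lin", paste0("t", seq_len(ncol(conn$weights)) - 1L))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @param space the [reference_space()] the file refers to.
#' @param threshold threshold recorded on the restored object.
#' @export
read_connectome_csv <- function(path, space, threshold = 10^-4.5) {
  df <- read.delim(path, sep = ",", check.names = FALSE)
  structure(list(sources = as.numeric(df$source_lin),
                 weights = as.matrix(df[, -1, drop = FALSE]),
                 space = space, directed = TRUE, provenance = "loaded",
                 n_effective_sites = NA_integer_, threshold = threshold),
            class = "connectome")
  }
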