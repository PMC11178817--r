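# Hierarchical region ontology, voxel parcellation, reference grid and VOIs.
#
# Conventions (fixed across the package):
#   * voxel indices are 0-based; the first axis is fastest when linearized:
#       lin = x + nx * (y + ny * z)
#   * the physical center of voxel (x, y, z) is origin + (index + 0.5) * voxel_size
#   * label 0 in a parcellation means outside-brain and is never a region id

#' Reference voxel grid
#'
#' Describes the common voxel space all data are mapped to: grid shape,
#' physical voxel size per axis (mm), and physical origin of the grid corner.
#'
#' @param shape integer vector of length 3, voxels per axis (all > 0).
#' @param voxel_size numeric length 1 or 3, mm per voxel (all > 0).
#' @param origin numeric length 3, physical coordinate of the grid corner.
#' @return A `reference_space` object.
#' @export
reference_space <- function(shape, voxel_size = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape <= 0L))
    stop("`shape` must be 3 positive integers")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be positive (length 1 or 3)")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "reference_space")
}

#' @export
print.reference_space <- function(x, ...) {
  cat(sprintf("<reference_space> %s voxels @ %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

n_voxels <- function(space) prod(space$shape)

#' Linearize / delinearize voxel indices
#'
#' 0-based linear index with the first axis fastest.
#'
#' @param vox integer matrix (n x 3) of 0-based voxel indices.
#' @param space a [reference_space()].
#' @return `voxel_lin`: 0-based linear indices; `lin_voxel`: an n x 3 matrix.
#' @export
voxel_lin <- function(vox, space) {
  vox <- rbind(vox)
  s <- space$shape
  if (any(vox < 0L) || any(vox[, 1] >= s[1]) || any(vox[, 2] >= s[2]) ||
      any(vox[, 3] >= s[3]))
    stop("voxel index outside space shape")
  as.numeric(vox[, 1]) + s[1] * (as.numeric(vox[, 2]) + s[2] * as.numeric(vox[, 3]))
}

#' @rdname voxel_lin
#' @param lin 0-based linear indices.
#' @export
lin_voxel <- function(lin, space) {
  s <- space$shape
  x <- lin %% s[1]
  y <- (lin %/% s[1]) %% s[2]
  z <- lin %/% (s[1] * s[2])
  cbind(x = as.integer(x), y = as.integer(y), z = as.integer(z))
}

voxel_centers <- function(vox, space) {
  vox <- rbind(vox)
  sweep(sweep(vox + 0.5, 2, space$voxel_size, `*`), 2, space$origin, `+`)
}

## ---------------------------------------------------------------------------
## Ontology

#' Brain-region ontology
#'
#' A tree of named brain regions. Parents anatomically subsume their children;
#' every node except the single root has a parent inside the tree.
#'
#' `load_ontology()` reads an Allen-structure-graph-style document: either a
#' flat JSON array of `{id, name, acronym, parent_structure_id}` records, or a
#' nested document where each node carries a `children` array (normalized to
#' the flat form on load). A data frame with columns `id`, `name`, `acronym`,
#' `parent` is accepted directly.
#'
#' @param doc path to a JSON file, a parsed list, or a data frame.
#' @return An `ontology`: data frame of nodes with attributes `root` (the root
#'   region id) and `children` (adjacency list keyed by id).
#' @export
load_ontology <- function(doc) {
  if (is.character(doc) && length(doc) == 1L)
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  if (is.data.frame(doc)) {
    nodes <- doc
  } else {
    if (!is.null(doc$msg)) doc <- doc$msg       # Allen API wrapper
    if (!is.null(doc$id) && !is.null(doc$children)) doc <- list(doc)
    flat <- list()
    walk <- function(node, parent) {
      pid <- if (is.null(node$parent_structure_id)) parent else node$parent_structure_id
      flat[[length(flat) + 1L]] <<- data.frame(
        id = as.integer(node$id),
        name = as.character(node$name %||% paste0("region_", node$id)),
        acronym = as.character(node$acronym %||% paste0("R", node$id)),
        parent = if (is.null(pid)) NA_integer_ else as.integer(pid))
      for (ch in node$children %||% list()) walk(ch, node$id)
    }
    for (node in doc) walk(node, NULL)
    nodes <- do.call(rbind, flat)
  }
  nodes <- nodes[, c("id", "name", "acronym", "parent")]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  validate_ontology(nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_ontology <- function(nodes) {
  if (anyDuplicated(nodes$id))
    stop("duplicate region ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (any(nodes$id == 0L))
    stop("region id 0 is reserved for outside-brain")
  is_root <- is.na(nodes$parent)
  if (sum(is_root) != 1L)
    stop("ontology must have exactly one root, found ", sum(is_root))
  known <- nodes$id
  orphan <- !is_root & !(nodes$parent %in% known)
  if (any(orphan))
    stop("parent of region ", paste(nodes$id[orphan], collapse = ", "),
         " not in ontology")
  # cycle check: every node must reach the root
  parent_of <- setNames(nodes$parent, nodes$id)
  root <- nodes$id[is_root]
  for (id in nodes$id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle in ontology involving region ", id)
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  children <- split(nodes$id[!is_root], factor(nodes$parent[!is_root], levels = nodes$id))
  structure(nodes, root = root, children = children, class = c("ontology", "data.frame"))
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d regions, root = %d (%s)\n", nrow(x),
              attr(x, "root"), x$name[x$id == attr(x, "root")]))
  invisible(x)
}

#' Transitive descendants of a region
#'
#' Returns the region itself plus all regions below it in the ontology tree.
#' This is the hierarchy closure used to expand a region query to every
#' anatomical level beneath it.
#'
#' @param ont an ontology from [load_ontology()].
#' @param r a region id present in `ont`.
#' @return Integer vector of region ids (always includes `r`).
#' @export
descendants <- function(ont, r) {
  r <- as.integer(r)
  if (!r %in% ont$id) stop("unknown region id: ", r)
  children <- attr(ont, "children")
  out <- integer(0)
  queue <- r
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    out <- c(out, cur)
    queue <- c(queue, children[[as.character(cur)]])
  }
  sort(out)
}

## ---------------------------------------------------------------------------
## Parcellation

#' Voxel parcellation of a reference space
#'
#' Binds a 3D integer label volume to a [reference_space()]; each voxel holds
#' the id of the (usually leaf-level) region it belongs to, 0 outside brain.
#'
#' @param space a [reference_space()].
#' @param labels 3D integer array of region ids, same shape as `space`.
#' @param ont optional ontology; if given, nonzero labels are checked.
#' @return A `parcellation` object.
#' @export
parcellation <- function(space, labels, ont = NULL) {
  labels <- as.array(labels)
  if (!identical(dim(labels), as.integer(space$shape)))
    stop("labels shape must equal space shape")
  storage.mode(labels) <- "integer"
  if (!is.null(ont)) {
    used <- setdiff(unique(as.vector(labels)), 0L)
    bad <- setdiff(used, ont$id)
    if (length(bad)) stop("labels contain non-ontology ids: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(space = space, labels = labels), class = "parcellation")
}

#' Voxels of a region (VOI construction from the ontology)
#'
#' Union of label-voxel sets over all descendants of `r`, so a query on a
#' parent region covers every voxel labeled with any of its subregions.
#'
#' @param parc a [parcellation()].
#' @param ont the matching ontology.
#' @param r region id.
#' @return A [voi()] with provenance `"region"` (possibly empty).
#' @export
region_voxels <- function(parc, ont, r) {
  ids <- descendants(ont, r)
  lin <- which(parc$labels %in% ids) - 1L   # R arrays are x-fastest already
  new_voi(lin, parc$space, provenance = sprintf("region:%d", r))
}

## ---------------------------------------------------------------------------
## VOI

new_voi <- function(lin, space, provenance) {
  lin <- sort(unique(as.numeric(lin)))
  structure(list(lin = lin, space = space, provenance = provenance),
            class = "voi")
}

#' Volume of interest
#'
#' A deduplicated set of reference-space voxels, built from a brain region,
#' a binary brush mask, or a union of existing VOIs.
#'
#' @param source a region id (requires `parc` and `ont`), a logical/0-1 3D
#'   array matching the space shape, an n x 3 matrix of 0-based voxel indices,
#'   or a list of `voi` objects to union.
#' @param space the [reference_space()] (taken from `parc` if given).
#' @param parc,ont parcellation and ontology, required for a region id source.
#' @return A `voi` object; `length()` gives the voxel count.
#' @export
make_voi <- function(source, space = NULL, parc = NULL, ont = NULL) {
  if (inherits(source, "voi")) return(source)
  if (is.list(source) && all(vapply(source, inherits, TRUE, "voi"))) {
    if (!length(source)) stop("empty VOI list")
    sp <- source[[1L]]$space
    return(new_voi(unlist(lapply(source, `[[`, "lin")), sp, "union"))
  }
  if (is.array(source) && length(dim(source)) == 3L) {
    if (is.null(space)) space <- reference_space(dim(source))
    if (!identical(dim(source), as.integer(space$shape)))
      stop("mask shape must equal space shape")
    return(new_voi(which(source != 0) - 1L, space, "brush"))
  }
  if (is.matrix(source) && ncol(source) == 3L) {
    if (is.null(space)) stop("`space` required for a voxel-index source")
    return(new_voi(voxel_lin(source, space), space, "brush"))
  }
  if (is.numeric(source) && length(source) == 1L) {
    if (is.null(parc) || is.null(ont))
      stop("`parc` and `ont` required for a region-id source")
    return(region_voxels(parc, ont, source))
  }
  stop("unsupported VOI source")
}

#' @export
length.voi <- function(x) length(x$lin)

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> %d voxels (%s)\n", length(x$lin), x$provenance))
  invisible(x)
}

#' Voxel indices of a VOI
#' @param voi a [voi()].
#' @return n x 3 integer matrix of 0-based voxel indices.
#' @export
voi_voxels <- function(voi) lin_voxel(voi$lin, voi$space)

## ---------------------------------------------------------------------------
## Resampling

#' Nearest-neighbor resampling between reference spaces
#'
#' Each target voxel takes the value of the source voxel whose physical center
#' is nearest to the target voxel's center. Because both grids are axis
#' aligned the nearest source voxel factorizes per axis. Equidistant ties go
#' to the lower source index on each axis, i.e. the lowest linearized source
#' index overall, so resampling is deterministic.
#'
#' @param vol 3D array (or `RNifti` image, in which case `src` defaults to a
#'   space built from its `pixdim`).
#' @param target the target [reference_space()].
#' @param src the source [reference_space()]; required for a plain array.
#' @return 3D array with `target$shape` dimensions.
#' @export
resample_nearest <- function(vol, target, src = NULL) {
  if (is.null(src)) {
    pd <- tryCatch(RNifti::pixdim(vol), error = function(e) NULL)
    if (is.null(pd)) stop("`src` space required for a plain array")
    src <- reference_space(dim(vol), pd[seq_len(3L)])
  }
  if (!identical(dim(vol), as.integer(src$shape)))
    stop("volume shape must equal src shape")
  lo <- pmax(src$origin, target$origin)
  hi <- pmin(src$origin + src$shape * src$voxel_size,
             target$origin + target$shape * target$voxel_size)
  if (any(hi <= lo)) stop("source and target physical extents do not overlap")
  idx <- lapply(1:3, function(a) {
    centers <- target$origin[a] + (seq_len(target$shape[a]) - 0.5) * target$voxel_size[a]
    t_real <- (centers - src$origin[a]) / src$voxel_size[a] - 0.5
    j <- ceiling(t_real - 0.5)          # round half down: tie -> lower index
    pmin(pmax(j, 0), src$shape[a] - 1L) + 1L   # back to 1-based for R indexing
  })
  out <- vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  array(as.vector(out), dim = target$shape)
}

## ---------------------------------------------------------------------------
## NIfTI I/O

#' Read / write label and expression volumes as NIfTI-1
#'
#' Voxel sizes are taken from (written to) the NIfTI header `pixdim`.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param origin physical origin to attach on read.
#' @return `read_volume`: list with `data` (3D array) and `space`.
#' @export
read_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  space <- reference_space(dim(img)[1:3], RNifti::pixdim(img)[1:3], origin)
  list(data = array(as.vector(img), dim = dim(img)[1:3]), space = space)
}

#' @rdname read_volume
#' @param data 3D array.
#' @param space a [reference_space()].
#' @export
write_volume <- function(data, space, path) {
  img <- RNifti::asNifti(array(data, dim = space$shape))
  RNifti::pixdim(img) <- space$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
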