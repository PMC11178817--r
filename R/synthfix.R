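# Deterministic synthetic fixtures with planted ground truth: toy atlases,
# annotated count matrices with planted region/cell-type markers, injection
# records with planted projections, and matched two-species bundles. Every
# output is reproducible from the seed and passes the target modules'
# validators, so fixtures double as format round-trip material.

#' Balanced toy atlas
#'
#' A balanced region tree of the given depth and fanout whose leaves tile
#' the voxel grid as contiguous blocks (in x-fastest linear order), each
#' block the same size up to one voxel. Region ids are assigned
#' breadth-first starting at 1 (the root); names/acronyms follow the ids.
#'
#' @param shape grid shape (default 8 x 8 x 8).
#' @param depth tree depth including the root (>= 2).
#' @param fanout children per internal node; leaves = `fanout^(depth-1)`.
#' @param voxel_size mm per voxel.
#' @return List with `ont` (ontology) and `parc` (parcellation).
#' @export
make_toy_atlas <- function(shape = c(8, 8, 8), depth = 3, fanout = 2,
                           voxel_size = 1) {
  if (depth < 2) stop("depth must be >= 2")
  n_leaves <- fanout^(depth - 1)
  space <- reference_space(shape, voxel_size)
  nvox <- n_voxels(space)
  if (nvox < n_leaves) stop("grid too small for ", n_leaves, " leaf regions")
  # breadth-first ids: root = 1, then each level in order
  nodes <- data.frame(id = 1L, name = "region_1", acronym = "R1",
                      parent = NA_integer_)
  level_ids <- 1L
  next_id <- 2L
  for (l in seq_len(depth - 1)) {
    new_ids <- integer(0)
    for (p in level_ids) {
      ids <- next_id:(next_id + fanout - 1L)
      next_id <- next_id + fanout
      nodes <- rbind(nodes, data.frame(
        id = ids, name = paste0("region_", ids), acronym = paste0("R", ids),
        parent = p))
      new_ids <- c(new_ids, ids)
    }
    level_ids <- new_ids
  }
  ont <- validate_ontology(nodes)
  leaf_ids <- level_ids
  block <- rep(leaf_ids, each = ceiling(nvox / n_leaves))[seq_len(nvox)]
  parc <- parcellation(space, array(block, dim = shape), ont)
  list(ont = ont, parc = parc)
}

#' Synthetic annotated count dataset with planted markers
#'
#' Counts are lognormal noise around a per-gene baseline, rounded half-even;
#' marker fold-changes multiply the baseline for the targeted (gene, cell
#' type) or (gene, region) combination before rounding. Samples are laid out
#' as `n_per_group` per (leaf region x cell type), annotated with their leaf
#' region id and carrying `cell_type`, `age` and `phenotype` metadata.
#'
#' @param atlas a [make_toy_atlas()] result.
#' @param seed RNG seed (full determinism per seed).
#' @param n_genes number of genes.
#' @param cell_types character vector of cell-type labels.
#' @param n_per_group samples per (leaf region x cell type).
#' @param markers data frame with columns `gene` (index), `kind`
#'   (`"cell_type"` or `"region"`), `group` (cell-type label or region id),
#'   `fold` (> 0), or `NULL`.
#' @param base_mean baseline mean count per gene.
#' @param noise_sdlog lognormal noise sd (log scale).
#' @param regions leaf region ids to sample from (default: all leaves).
#' @param dataset_id dataset identifier.
#' @return A raw-count annotated [expression_dataset()].
#' @export
make_expression_dataset <- function(atlas, seed = 1, n_genes = 100,
                                    cell_types = c("excitatory", "inhibitory"),
                                    n_per_group = 20, markers = NULL,
                                    base_mean = 50, noise_sdlog = 0.5,
                                    regions = NULL, dataset_id = "synthetic") {
  set.seed(seed)
  ont <- atlas$ont
  labs <- unique(as.vector(atlas$parc$labels))
  leaves <- sort(labs[labs != 0L])
  if (is.null(regions)) regions <- leaves
  if (!is.null(markers) && any(markers$gene > n_genes))
    stop("marker gene index out of range")
  grid <- expand.grid(region = regions, cell_type = cell_types,
                      rep = seq_len(n_per_group), stringsAsFactors = FALSE)
  n_s <- nrow(grid)
  mu <- rlnorm(n_genes, meanlog = log(base_mean), sdlog = 0.25)
  lambda <- matrix(mu, nrow = n_genes, ncol = n_s)
  if (!is.null(markers)) {
    for (i in seq_len(nrow(markers))) {
      g <- markers$gene[i]
      hit <- if (markers$kind[i] == "cell_type")
        grid$cell_type == markers$group[i]
      else grid$region == as.integer(markers$group[i])
      lambda[g, hit] <- lambda[g, hit] * markers$fold[i]
    }
  }
  counts <- round(lambda * matrix(rlnorm(n_genes * n_s, 0, noise_sdlog),
                                  n_genes, n_s))
  rownames(counts) <- paste0("g", seq_len(n_genes))
  colnames(counts) <- paste0(dataset_id, "_s", seq_len(n_s))
  meta <- data.frame(cell_type = grid$cell_type, age = "adult",
                     phenotype = "control",
                     region = ont$name[match(grid$region, ont$id)])
  expression_dataset(counts, meta = meta, annotation = grid$region,
                     state = "raw", dataset_id = dataset_id)
}

#' Synthetic injection records with planted projections
#'
#' One record per planted projection: the injection volume is the source
#' region's voxel set, the image carries `weight` on every voxel of the
#' target region, and background noise drawn strictly below the assembly
#' threshold everywhere else — so thresholding behavior is deterministic and
#' a planted projection is the only surviving signal.
#'
#' @param atlas a [make_toy_atlas()] result.
#' @param projections data frame with columns `source`, `target` (region
#'   ids) and `weight` (projection strength, should exceed the threshold).
#' @param seed RNG seed.
#' @param threshold the downstream assembly threshold the background must
#'   stay below (default `10^-4.5`).
#' @return List of [injection_record()]s, one per projection row.
#' @export
make_connectome_records <- function(atlas, projections, seed = 1,
                                    threshold = 10^-4.5) {
  set.seed(seed)
  ont <- atlas$ont; parc <- atlas$parc
  if (!all(c(projections$source, projections$target) %in% ont$id))
    stop("projection regions must exist in the ontology")
  space <- parc$space
  lapply(seq_len(nrow(projections)), function(i) {
    src <- region_voxels(parc, ont, projections$source[i])
    if (!length(src)) stop("source region has no voxels")
    tgt <- region_voxels(parc, ont, projections$target[i])
    img <- array(runif(n_voxels(space), 0, threshold * 0.5), dim = space$shape)
    img[tgt$lin + 1L] <- projections$weight[i]
    site <- voi_voxels(src)[1L, ]
    injection_record(site, src, img, space)
  })
}

#' Matched two-species fixture with planted conserved correlates
#'
#' Builds, for each of two synthetic species, an atlas, an annotated
#' expression dataset over shared consensus regions, and an assembled
#' connectome with one planted projection per consensus region from a
#' dedicated source region — plus a homolog map pairing the species' genes
#' one-to-one.
#'
#' The first `n_conserved` genes are constructed with an exactly monotone
#' (sign `conserved_sign`) relationship between their regional expression
#' and the species' own source-region connectivity profile, in the
#' `conserved_cell_type`, in both species. All other genes get a latent
#' expression-connectivity correlation drawn per cell type from
#' `N(shift, rho_sd)` where `shift` is 0 for excitatory genes and
#' `inhibitory_shift` for inhibitory ones (when enabled) — emulating a
#' cell-type-specific shift of the correlation distribution.
#'
#' @param seed RNG seed; species use derived sub-seeds.
#' @param n_consensus number of shared consensus regions (>= 3, default 10).
#' @param n_genes genes per species (>= `n_conserved / q` for quantile work).
#' @param n_conserved planted conserved correlates (0 disables).
#' @param conserved_sign +1 or -1: direction of the planted relationship.
#' @param conserved_cell_type the cell type carrying the planted genes.
#' @param inhibitory_shift mean shift of the latent correlation for
#'   inhibitory-cell genes (0 disables the cell-type contrast).
#' @param rho_sd sd of the latent correlation around its cell-type mean.
#' @param n_per_group samples per (region x cell type).
#' @param sample_noise_sd within-region per-sample noise sd.
#' @return List with `A`, `B` (each: `atlas`, `dataset`, `records`,
#'   `connectome`, `conn_profile`, `source_region`, `consensus_regions`) and
#'   `hmap`.
#' @export
make_species_pair <- function(seed = 1, n_consensus = 10, n_genes = 500,
                              n_conserved = 5, conserved_sign = -1,
                              conserved_cell_type = "inhibitory",
                              inhibitory_shift = -0.3, rho_sd = 0.1,
                              n_per_group = 20, sample_noise_sd = 0.1) {
  if (n_consensus < 3) stop("need at least 3 consensus regions")
  if (n_conserved > n_genes) stop("more conserved genes requested than genes")
  make_species <- function(sp_seed, prefix) {
    set.seed(sp_seed)
    # 16 leaves on an 8^3 grid: consensus regions + a dedicated source leaf
    atlas <- make_toy_atlas(shape = c(8, 8, 8), depth = 3, fanout = 4)
    labs <- unique(as.vector(atlas$parc$labels))
    leaves <- sort(labs[labs != 0L])
    if (length(leaves) < n_consensus + 1)
      stop("toy atlas too small for ", n_consensus, " consensus regions")
    consensus <- leaves[seq_len(n_consensus)]
    source_region <- leaves[n_consensus + 1L]
    # distinct projection strengths with a fixed gap, randomly assigned
    w <- sample(seq(0.2, by = 0.2, length.out = n_consensus))
    records <- make_connectome_records(
      atlas, data.frame(source = source_region, target = consensus, weight = w),
      seed = sp_seed + 1L)
    conn <- assemble_structural(records)
    cell_types <- c("excitatory", "inhibitory")
    grid <- expand.grid(region = consensus, cell_type = cell_types,
                        rep = seq_len(n_per_group), stringsAsFactors = FALSE)
    z <- as.vector(scale(w))
    names(z) <- as.character(consensus)
    base <- 8
    # per-(gene, cell type) latent correlation and regional program
    prog <- array(0, dim = c(n_genes, n_consensus, 2),
                  dimnames = list(NULL, as.character(consensus), cell_types))
    for (ct_i in 1:2) {
      shift <- if (cell_types[ct_i] == "inhibitory") inhibitory_shift else 0
      rho <- pmin(pmax(rnorm(n_genes, shift, rho_sd), -0.95), 0.95)
      eta <- matrix(rnorm(n_genes * n_consensus), n_genes, n_consensus)
      prog[, , ct_i] <- base + rho * matrix(z, n_genes, n_consensus, byrow = TRUE) +
        sqrt(1 - rho^2) * eta
    }
    if (n_conserved > 0) {
      planted <- if (conserved_sign < 0) max(w) - w + base else w + base
      ct_i <- match(conserved_cell_type, cell_types)
      prog[seq_len(n_conserved), , ct_i] <-
        matrix(planted, n_conserved, n_consensus, byrow = TRUE)
    }
    mat <- matrix(0, n_genes, nrow(grid))
    for (s in seq_len(nrow(grid))) {
      r_i <- match(grid$region[s], consensus)
      ct_i <- match(grid$cell_type[s], cell_types)
      mat[, s] <- prog[, r_i, ct_i] + rnorm(n_genes, 0, sample_noise_sd)
    }
    mat <- pmax(mat, 0)
    rownames(mat) <- paste0(prefix, "_g", seq_len(n_genes))
    colnames(mat) <- paste0(prefix, "_s", seq_len(nrow(grid)))
    meta <- data.frame(cell_type = grid$cell_type, age = "adult",
                       phenotype = "control",
                       region = atlas$ont$name[match(grid$region, atlas$ont$id)])
    ds <- expression_dataset(mat, meta = meta, annotation = grid$region,
                             state = "log2p1",
                             dataset_id = paste0("species_", prefix))
    profile <- region_profile(conn, region_voxels(atlas$parc, atlas$ont, source_region),
                              consensus, atlas$ont, atlas$parc)
    list(atlas = atlas, dataset = ds, records = records, connectome = conn,
         conn_profile = profile, source_region = source_region,
         consensus_regions = consensus)
  }
  A <- make_species(seed * 2L + 11L, "A")
  B <- make_species(seed * 2L + 12L, "B")
  hmap <- homolog_map(paste0("A_g", seq_len(n_genes)),
                      paste0("B_g", seq_len(n_genes)))
  list(A = A, B = B, hmap = hmap)
}
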