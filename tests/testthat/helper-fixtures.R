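# Fixture builders and independent brute-force oracles. Oracles are written
# as plain loops/scans so they share no code path with the package.

# Random tree as a flat node table: node i's parent is uniform over 1..i-1.
random_tree_nodes <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  data.frame(id = seq_len(n), name = paste0("region_", seq_len(n)),
             acronym = paste0("R", seq_len(n)), parent = parent)
}

# Reachability oracle: repeated edge-list scan (no recursion shared with the
# package's BFS).
oracle_descendants <- function(nodes, r) {
  reach <- r
  repeat {
    more <- nodes$id[!is.na(nodes$parent) & nodes$parent %in% reach &
                       !(nodes$id %in% reach)]
    if (!length(more)) return(sort(reach))
    reach <- c(reach, more)
  }
}

# Random annotated expression fixture on a toy atlas.
random_query_fixture <- function(seed, n_genes = 12, n_per_group = 3) {
  set.seed(seed)
  atlas <- make_toy_atlas(shape = c(4, 4, 4), depth = 3, fanout = 2)
  leaves <- 4:7
  grid <- expand.grid(region = leaves,
                      cell_type = c("exc", "inh", "glia"),
                      rep = seq_len(n_per_group), stringsAsFactors = FALSE)
  mat <- matrix(runif(n_genes * nrow(grid), 0, 10), n_genes)
  rownames(mat) <- paste0("g", seq_len(n_genes))
  meta <- data.frame(cell_type = grid$cell_type,
                     age = sample(c("adult", "juvenile"), nrow(grid), TRUE),
                     phenotype = "control")
  ds <- expression_dataset(mat, meta = meta, annotation = grid$region,
                           state = "cpm", dataset_id = paste0("fx", seed))
  list(atlas = atlas, ds = ds, leaves = leaves)
}

# Per-sample full scan: which samples fall in the VOI / cell types / filters.
oracle_selection <- function(ds, voi, parc, ont, cell_types = NULL, meta = NULL) {
  nodes <- as.data.frame(ont)
  n <- ncol(ds$mat)
  sel <- logical(n)
  for (s in seq_len(n)) {
    r <- ds$annotation[s]
    if (is.na(r)) next
    ids <- oracle_descendants(nodes, r)
    vox <- which(array(parc$labels %in% ids, dim = dim(parc$labels))) - 1L
    inV <- length(intersect(vox, voi$lin)) > 0
    inC <- is.null(cell_types) || ds$meta$cell_type[s] %in% cell_types
    inF <- TRUE
    if (!is.null(meta))
      for (a in names(meta)) inF <- inF && ds$meta[[a]][s] %in% meta[[a]]
    sel[s] <- inV && inC && inF
  }
  sel
}

# Literal evaluation of the four query formulas by explicit loops.
oracle_queries <- function(ds, V, C, F_) {
  G <- nrow(ds$mat)
  m <- ds$mat
  sets <- list(sel = which(V & C & F_), CF = which(C & F_),
               VF = which(V & F_), V = which(V))
  avg <- function(g, idx) if (length(idx)) sum(m[g, idx]) / length(idx) else NA_real_
  out <- list(mean = numeric(G), region = numeric(G),
              cell = numeric(G), enrich = numeric(G))
  for (g in seq_len(G)) {
    num <- avg(g, sets$sel)
    out$mean[g] <- num
    d1 <- avg(g, sets$CF); d2 <- avg(g, sets$VF); d3 <- avg(g, sets$V)
    out$region[g] <- if (!is.na(d1) && d1 != 0) num / d1 else NA_real_
    out$cell[g] <- if (!is.na(d2) && d2 != 0) num / d2 else NA_real_
    out$enrich[g] <- if (!is.na(d3) && d3 != 0) num / d3 else NA_real_
  }
  out
}

# A random brush VOI over the fixture grid.
random_voi <- function(space, seed, p = 0.3) {
  set.seed(seed)
  mask <- array(runif(prod(space$shape)) < p, dim = space$shape)
  make_voi(mask, space)
}
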