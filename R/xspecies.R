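# Expression-connectivity correlation statistics across species: per-gene
# Spearman profiles over matched regions, extreme-gene (top/bottom quantile)
# selection, homolog-mapped cross-species overlap, distribution-shift tests
# between cell types, directionality tests, and inter-dataset rank
# concordance.

#' Per-gene expression-connectivity correlation profile
#'
#' Spearman rank correlation, per gene, between the gene's per-region mean
#' expression (a regions x genes matrix, typically a query-module output)
#' and a region-level connectivity profile. Spearman is used because
#' absolute expression is not comparable across datasets while ranks are.
#' Average ranks on ties; genes or profiles constant across regions get an
#' undefined (NA) coefficient. No per-gene p-values are computed: the
#' workflow selects genes by coefficient quantile, not significance.
#'
#' @param expr numeric matrix, regions x genes, rownames = region ids.
#' @param conn named numeric vector of connectivity strength per region.
#' @param kind label for provenance (`"SC-source"`, `"FC-target"`, ...).
#' @return A `correlation_profile` data frame (gene, r) with attributes
#'   `n_regions` and `kind`.
#' @export
gene_connectivity_correlation <- function(expr, conn, kind = "SC-source") {
  if (is.null(rownames(expr)) || is.null(names(conn)))
    stop("expr rownames and conn names must carry region ids")
  if (!setequal(rownames(expr), names(conn)))
    stop("region sets of expression and connectivity do not match")
  conn <- conn[rownames(expr)]
  if (nrow(expr) < 3L) stop("need at least 3 regions")
  ok_conn <- stats::sd(conn) > 0
  r <- suppressWarnings(as.vector(cor(rank(conn), apply(expr, 2, rank),
                                      method = "pearson")))
  const <- apply(expr, 2, function(x) length(unique(x)) == 1L)
  r[const | !ok_conn] <- NA_real_
  structure(data.frame(gene = colnames(expr), r = r, stringsAsFactors = FALSE),
            n_regions = nrow(expr), kind = kind,
            class = c("correlation_profile", "data.frame"))
}

#' Top and bottom quantile of correlated genes
#'
#' The `ceiling(q * n)` genes with the highest and the lowest defined
#' coefficients. Ties at either cutoff are broken by gene-id order so the
#' sets are deterministic; the two sets are disjoint.
#'
#' @param prof a [gene_connectivity_correlation()] profile.
#' @param q quantile fraction in (0, 0.5); default 0.01 (top/bottom 1%).
#' @return List with character vectors `top` and `bottom`.
#' @export
extreme_genes <- function(prof, q = 0.01) {
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  def <- prof[!is.na(prof$r), ]
  n <- nrow(def)
  if (n < 1 / q) stop("need at least 1/q defined coefficients")
  k <- ceiling(q * n)
  top <- def$gene[order(-def$r, def$gene)][seq_len(k)]
  bottom <- def$gene[order(def$r, def$gene)][seq_len(k)]
  list(top = top, bottom = bottom)
}

#' Homolog map between two species' gene identifiers
#'
#' @param a,b equal-length character vectors of paired gene ids
#'   (species A, species B); pairs must be unique.
#' @return A `homolog_map` data frame.
#' @export
homolog_map <- function(a, b) {
  df <- data.frame(a = as.character(a), b = as.character(b),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop("homolog pairs must be unique")
  structure(df, class = c("homolog_map", "data.frame"))
}

#' @rdname homolog_map
#' @param path two-column TSV (species A id, species B id).
#' @export
read_homolog_map <- function(path) {
  df <- read.delim(path, colClasses = "character")
  homolog_map(df[[1]], df[[2]])
}

#' Cross-species overlap of extreme gene sets
#'
#' Genes of species A whose homolog appears in the corresponding extreme set
#' of species B — the candidate conserved expression-connectivity
#' correlates.
#'
#' @param setsA,setsB [extreme_genes()] lists for the two species.
#' @param hmap a [homolog_map()] (column `a` = species A ids).
#' @return List `top` / `bottom` of species-A gene ids whose homolog is in
#'   the matching species-B set; empty (with a warning) for an empty map.
#' @export
overlap_conserved <- function(setsA, setsB, hmap) {
  if (!nrow(hmap)) {
    warning("empty homolog map; overlap is empty")
    return(list(top = character(0), bottom = character(0)))
  }
  pick <- function(sa, sb) {
    partner <- hmap$b[match(sa, hmap$a)]
    sa[!is.na(partner) & partner %in% sb]
  }
  list(top = pick(setsA$top, setsB$top),
       bottom = pick(setsA$bottom, setsB$bottom))
}

#' Distribution shift between two coefficient samples
#'
#' Two-sample Kolmogorov-Smirnov test comparing the distributions of
#' expression-connectivity coefficients of two groups (e.g. genes expressed
#' in excitatory vs inhibitory cell types).
#'
#' @param r_group_a,r_group_b numeric coefficient samples (NA dropped),
#'   each of length >= 2 after removal.
#' @return List with `statistic` (D) and `p_value`.
#' @export
correlation_shift_test <- function(r_group_a, r_group_b) {
  a <- r_group_a[!is.na(r_group_a)]
  b <- r_group_b[!is.na(r_group_b)]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 coefficients per group")
  ks <- suppressWarnings(ks.test(a, b))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Directionality of homolog coefficients
#'
#' One-sample t-test of a coefficient sample against zero (chance level):
#' does the set of human homologs of mouse-extreme genes keep a consistent
#' correlation direction?
#'
#' @param r_values numeric coefficient sample (NA dropped), n >= 2 with
#'   nonzero variance.
#' @return List with `statistic` (t), `p_value`, `mean`, `n`.
#' @export
homolog_direction_test <- function(r_values) {
  x <- r_values[!is.na(r_values)]
  if (length(x) < 2L) stop("need at least 2 coefficients")
  if (stats::sd(x) == 0) stop("zero variance in coefficients")
  tt <- t.test(x, mu = 0)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean = mean(x), n = length(x))
}

#' Inter-dataset rank concordance of cell-type expression
#'
#' For every (cell type A, cell type B) pair, the Spearman correlation over
#' all shared genes between the two datasets' per-cell-type mean expression
#' vectors, plus a one-sided Wilcoxon rank-sum test that matched cell-type
#' pairs correlate higher than unmatched pairs — the check that gene
#' *ranking* is consistent across datasets even when absolute values are
#' not.
#'
#' @param dsA,dsB [expression_dataset()]s with `cell_type` metadata.
#' @param matched_groups data frame / 2-column matrix of matched cell-type
#'   pairs (A name, B name).
#' @param hmap optional [homolog_map()] translating A gene ids to B gene
#'   ids; `NULL` when the datasets share an id universe.
#' @return List with `correlations` (matrix, cell types A x cell types B),
#'   `p_value` (one-sided Wilcoxon), `matched` (logical matrix),
#'   `n_shared_genes`.
#' @export
dataset_concordance <- function(dsA, dsB, matched_groups, hmap = NULL) {
  idsA <- genes(dsA)
  idsB <- if (is.null(hmap)) idsA else hmap$b[match(idsA, hmap$a)]
  shared <- !is.na(idsB) & idsB %in% genes(dsB)
  if (sum(shared) < 3L) stop("fewer than 3 shared genes after matching")
  gA <- idsA[shared]; gB <- idsB[shared]
  mean_by_ct <- function(ds, gene_sel) {
    cts <- sort(unique(ds$meta$cell_type))
    vapply(cts, function(ct)
      rowMeans(ds$mat[gene_sel, ds$meta$cell_type == ct, drop = FALSE]),
      numeric(length(gene_sel)))
  }
  mA <- mean_by_ct(dsA, gA)
  mB <- mean_by_ct(dsB, gB)
  corr <- cor(apply(mA, 2, rank), apply(mB, 2, rank), method = "pearson")
  rownames(corr) <- colnames(mA); colnames(corr) <- colnames(mB)
  matched_groups <- as.data.frame(matched_groups)
  matched <- matrix(FALSE, nrow(corr), ncol(corr),
                    dimnames = dimnames(corr))
  for (i in seq_len(nrow(matched_groups)))
    matched[as.character(matched_groups[i, 1]),
            as.character(matched_groups[i, 2])] <- TRUE
  p <- if (any(matched) && any(!matched))
    wilcox.test(corr[matched], corr[!matched],
                alternative = "greater", exact = FALSE)$p.value
  else NA_real_
  list(correlations = corr, p_value = p, matched = matched,
       n_shared_genes = sum(shared))
}
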