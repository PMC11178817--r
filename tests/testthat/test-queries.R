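test_that("sample selection matches a per-sample full scan", {
  for (seed in c(1, 2, 3)) {
    fx <- random_query_fixture(seed)
    voi <- random_voi(fx$atlas$parc$space, seed + 100)
    cts <- sample(c("exc", "inh", "glia"), 2)
    meta <- list(age = "adult")
    sel <- select_samples(fx$ds, voi, fx$atlas$parc, fx$atlas$ont,
                          cell_types = cts, meta = meta)
    expect_equal(sel$selected,
                 oracle_selection(fx$ds, voi, fx$atlas$parc, fx$atlas$ont,
                                  cell_types = cts, meta = meta))
  }
  fx <- random_query_fixture(4)
  # empty VOI -> empty selection
  empty <- make_voi(array(FALSE, c(4, 4, 4)), fx$atlas$parc$space)
  expect_equal(sum(select_samples(fx$ds, empty, fx$atlas$parc, fx$atlas$ont)$selected), 0)
  expect_error(select_samples(fx$ds, empty, fx$atlas$parc, fx$atlas$ont,
                              meta = list(nonexistent = "x")), "unknown metadata")
})

test_that("a VOI at a coarser level selects all samples annotated below it", {
  # samples annotated at two children; the parent VOI selects all of them
  fx <- random_query_fixture(5)
  parent <- region_voxels(fx$atlas$parc, fx$atlas$ont, 2)  # leaves 4+5
  sel <- select_samples(fx$ds, parent, fx$atlas$parc, fx$atlas$ont)
  expect_true(all(sel$selected[fx$ds$annotation %in% c(4, 5)]))
  expect_false(any(sel$selected[fx$ds$annotation %in% c(6, 7)]))
})

test_that("voxel-backed datasets select by voxel membership", {
  sp <- reference_space(c(4, 4, 4))
  m <- matrix(runif(3 * 10), 3, 10, dimnames = list(paste0("g", 1:3), NULL))
  ds <- expression_dataset(m, annotation = 0:9, voxel_backed = TRUE)
  voi <- make_voi(lin_voxel(c(0, 3, 7, 50), sp), sp)
  sel <- select_samples(ds, voi)
  expect_equal(which(sel$selected), c(1, 4, 8))
})

test_that("the four queries match literal formula evaluation", {
  for (seed in 1:10) {
    fx <- random_query_fixture(seed)
    voi <- random_voi(fx$atlas$parc$space, seed + 200)
    cts <- sample(c("exc", "inh", "glia"), sample(1:2, 1))
    sel <- select_samples(fx$ds, voi, fx$atlas$parc, fx$atlas$ont, cell_types = cts)
    if (!sum(sel$selected)) next
    oq <- oracle_queries(fx$ds, sel$V, sel$C, sel$F)
    expect_equal(mean_expression(fx$ds, sel)$score, oq$mean, tolerance = 1e-12)
    expect_equal(region_specificity(fx$ds, sel)$score, oq$region, tolerance = 1e-12)
    expect_equal(cell_type_specificity(fx$ds, sel)$score, oq$cell, tolerance = 1e-12)
    expect_equal(enrichment(fx$ds, sel)$score, oq$enrich, tolerance = 1e-12)
  }
})

test_that("degenerate query identities hold exactly", {
  fx <- random_query_fixture(20)
  whole <- region_voxels(fx$atlas$parc, fx$atlas$ont, 1)
  # whole-brain VOI: region specificity is exactly 1
  sel <- select_samples(fx$ds, whole, fx$atlas$parc, fx$atlas$ont, cell_types = "exc")
  expect_equal(region_specificity(fx$ds, sel)$score, rep(1, 12))
  # single cell type in the data: cell-type specificity is 1
  one_ct <- fx$ds; one_ct$meta$cell_type <- "exc"
  sel2 <- select_samples(one_ct, whole, fx$atlas$parc, fx$atlas$ont, cell_types = "exc")
  expect_equal(cell_type_specificity(one_ct, sel2)$score, rep(1, 12))
  # no filters at all: enrichment is 1
  sel3 <- select_samples(fx$ds, whole, fx$atlas$parc, fx$atlas$ont)
  expect_equal(enrichment(fx$ds, sel3)$score, rep(1, 12))
  # two samples with values 2 and 4 -> mean 3
  m <- matrix(c(2, 4), 1, 2, dimnames = list("g1", c("a", "b")))
  ds <- expression_dataset(m, annotation = c(0, 1), voxel_backed = TRUE)
  v <- make_voi(lin_voxel(0:1, reference_space(c(2, 1, 1))), reference_space(c(2, 1, 1)))
  expect_equal(mean_expression(ds, select_samples(ds, v))$score, 3)
})

test_that("a gene silent everywhere gets an undefined ratio, not 0 or Inf", {
  fx <- random_query_fixture(21)
  fx$ds$mat[3, ] <- 0
  voi <- region_voxels(fx$atlas$parc, fx$atlas$ont, 4)
  sel <- select_samples(fx$ds, voi, fx$atlas$parc, fx$atlas$ont, cell_types = "exc")
  res <- region_specificity(fx$ds, sel)
  expect_true(is.na(res$score[3]))
  ranked <- gene_ranks(res)
  expect_true(is.na(ranked$rank[3]))
  expect_equal(sort(ranked$rank), sort(rank(-res$score[-3])))
})

test_that("empty selections signal an empty result instead of crashing", {
  fx <- random_query_fixture(22)
  empty <- make_voi(array(FALSE, c(4, 4, 4)), fx$atlas$parc$space)
  sel <- select_samples(fx$ds, empty, fx$atlas$parc, fx$atlas$ont)
  expect_warning(res <- mean_expression(fx$ds, sel), "empty")
  expect_s3_class(res, "empty_result")
  expect_equal(nrow(res), 0L)
})

test_that("gene ranks are descending with average ties", {
  res <- structure(data.frame(gene = c("a", "b", "c"), score = c(5, 2, 9),
                              rank = NA_real_),
                   class = c("query_result", "data.frame"))
  expect_equal(gene_ranks(res)$rank, c(2, 3, 1))
  res$score <- c(4, 4, 1)
  expect_equal(gene_ranks(res)$rank, c(1.5, 1.5, 3))
  # sort-based oracle on random scores
  set.seed(8)
  res$score <- NULL; res <- rbind(res, res, res)[1:9, ]
  res$gene <- paste0("g", 1:9); res$score <- sample(c(runif(7), NA, NA))
  rk <- gene_ranks(res)$rank
  def <- !is.na(res$score)
  expect_equal(rk[def][order(-res$score[def])], seq_len(sum(def)))
  res$score <- rep(NA_real_, 9)
  expect_error(gene_ranks(res), "no defined scores")
})

test_that("query scale invariance: scaling a gene row leaves ratios unchanged", {
  fx <- random_query_fixture(23)
  voi <- region_voxels(fx$atlas$parc, fx$atlas$ont, 4)
  sel <- select_samples(fx$ds, voi, fx$atlas$parc, fx$atlas$ont, cell_types = "inh")
  before <- list(region_specificity(fx$ds, sel)$score,
                 cell_type_specificity(fx$ds, sel)$score,
                 enrichment(fx$ds, sel)$score)
  fx$ds$mat[5, ] <- fx$ds$mat[5, ] * 37.5
  sel2 <- select_samples(fx$ds, voi, fx$atlas$parc, fx$atlas$ont, cell_types = "inh")
  after <- list(region_specificity(fx$ds, sel2)$score,
                cell_type_specificity(fx$ds, sel2)$score,
                enrichment(fx$ds, sel2)$score)
  for (i in 1:3) expect_equal(after[[i]][5], before[[i]][5], tolerance = 1e-12)
})

test_that("coverage table counts selected samples per region and group", {
  fx <- random_query_fixture(24)
  tab <- coverage_table(list(fx$ds), fx$atlas$ont, fx$atlas$parc,
                        regions = c(4:7, 2), group_by = "cell_type")
  # leaf columns: counts equal the generator layout (3 reps x 1 cell type)
  for (r in 4:7) for (ct in c("exc", "inh", "glia")) {
    row <- tab[tab$region == r & tab$group == ct, ]
    expect_equal(row$n_samples,
                 sum(fx$ds$annotation == r & fx$ds$meta$cell_type == ct))
    if (row$n_samples > 0) expect_equal(row$annotations, as.character(r))
  }
  # parent column = sum over its disjoint leaf children
  for (ct in c("exc", "inh", "glia")) {
    expect_equal(tab$n_samples[tab$region == 2 & tab$group == ct],
                 sum(tab$n_samples[tab$region %in% c(4, 5) & tab$group == ct]))
  }
  # a region with no intersecting samples counts zero
  fx2 <- random_query_fixture(25)
  fx2$ds$annotation[] <- 4
  tab2 <- coverage_table(list(fx2$ds), fx2$atlas$ont, fx2$atlas$parc, regions = 7)
  expect_equal(tab2$n_samples, 0L)
})

test_that("query results export as TSV with a descriptive header block", {
  fx <- random_query_fixture(26)
  voi <- region_voxels(fx$atlas$parc, fx$atlas$ont, 4)
  sel <- select_samples(fx$ds, voi, fx$atlas$parc, fx$atlas$ont)
  res <- gene_ranks(mean_expression(fx$ds, sel))
  f <- tempfile(fileext = ".tsv")
  write_query_result(res, f, extra = list(seed = 7))
  lines <- readLines(f)
  expect_true(any(grepl("^# query: mean", lines)))
  expect_true(any(grepl("^# seed: 7", lines)))
  body <- read.delim(f, comment.char = "#")
  expect_equal(body$score, res$score)
})
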