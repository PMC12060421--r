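test_that("QC filtering applies the three thresholds with inclusive bounds", {
  ## five cells: (n_features, pct_mito) = (150,1) (300,1) (7500,1) (500,6)
  ## (1000,4); only cells 2 and 5 survive
  n_genes <- 8000
  counts <- matrix(0L, n_genes, 5,
                   dimnames = list(c(sprintf("G%04d", 1:(n_genes - 100)),
                                     sprintf("mt-G%03d", 1:100)), NULL))
  ## one count per detected gene, with the right share on mt- genes
  fill <- function(j, n_feat, pct_mito) {
    n_mito <- as.integer(round(n_feat * pct_mito / 100))
    counts[seq_len(n_feat - n_mito), j] <<- 1L
    counts[n_genes - 100 + seq_len(n_mito), j] <<- 1L
  }
  fill(1, 150, 1); fill(2, 300, 1); fill(3, 7500, 1); fill(4, 500, 6)
  fill(5, 1000, 4)
  m <- tiny_matrix(counts)
  expect_equal(round(m$cells$n_features), c(150, 300, 7500, 500, 1000))
  filt <- suppressMessages(filter_cells(m))
  expect_equal(filt$cells$cell_id, m$cells$cell_id[c(2, 5)])
  expect_equal(unname(attr(filt, "qc_removed")), c(1, 1, 1))

  ## idempotence, and identity when everything is in bounds
  filt2 <- suppressMessages(filter_cells(filt))
  expect_identical(filt$cells, filt2$cells)
  expect_error(suppressMessages(
    filter_cells(m, qc_thresholds(min_features = 7600,
                                  max_features = 7800))), "all cells")
})

test_that("cells exactly on a QC boundary are retained", {
  counts <- matrix(0L, 400, 2,
                   dimnames = list(c(sprintf("G%03d", 1:380),
                                     sprintf("mt-G%02d", 1:20)), NULL))
  ## cell 1: exactly 200 features, exactly 5% mito (10 mito of 200)
  counts[1:190, 1] <- 1L
  counts[381:390, 1] <- 1L
  counts[1:300, 2] <- 1L
  m <- tiny_matrix(counts)
  expect_equal(m$cells$n_features[1], 200)
  expect_equal(m$cells$pct_mito[1], 5)
  filt <- suppressMessages(filter_cells(m))
  expect_equal(nrow(filt$cells), 2)
})

test_that("normalization is depth-aware and HVG selection finds planted
           high-variance genes", {
  ## two cells with depths d and 2d: same count c gives different
  ## normalized values; count 2c in the deeper cell matches count c in
  ## the shallower
  counts <- matrix(c(5, 10,
                     10, 20,
                     85, 170), nrow = 3, byrow = TRUE)
  rownames(counts) <- c("A", "B", "C")
  m <- tiny_matrix(counts)
  ns <- suppressWarnings(normalize_and_select(m, n_hvg = 3))
  expect_equal(ns$normalized["A", 1], ns$normalized["A", 2])
  expect_equal(ns$normalized["B", 1], ns$normalized["B", 2])

  ## planted high-dispersion genes (same mean as background, much larger
  ## variance) dominate the ranking
  set.seed(1)
  base <- matrix(rpois(50 * 40, 5), 50, 40)
  hot <- sample(50, 5)
  for (g in hot) base[g, ] <- rep(c(0L, 10L), 20)   # mean 5, var ~25
  rownames(base) <- sprintf("G%02d", 1:50)
  m2 <- tiny_matrix(base)
  ns2 <- normalize_and_select(m2, n_hvg = 10)
  expect_true(all(sprintf("G%02d", hot) %in% ns2$hvg))

  ## direct dispersion oracle: variance/mean of the normalized values
  norm <- ns2$normalized
  disp_oracle <- apply(norm, 1, var) / rowMeans(norm)
  expect_equal(ns2$dispersion$dispersion, unname(disp_oracle))

  ## genes constant after normalization are never selected while varying
  ## genes exist (equal-depth construction keeps them exactly constant)
  const <- matrix(5L, 20, 30, dimnames = list(
    c(sprintf("C%02d", 1:18), "HOT", "FILL"), NULL))
  const["HOT", ] <- rep(c(0L, 10L), 15)
  const["FILL", ] <- 10L - const["HOT", ]   # totals stay equal per cell
  ns3 <- normalize_and_select(tiny_matrix(const), n_hvg = 5)
  expect_setequal(ns3$hvg, c("HOT", "FILL"))
})

test_that("PC-count selection implements the relative-change elbow rule", {
  v <- c(30, 20, 10, 5, 4.999, 4.998, 4.997)
  expect_equal(select_pc_count(v), 4)

  geo <- 30 * 0.5^(0:9)   # constant 50% relative change, never below 0.1%
  expect_warning(k <- select_pc_count(geo), "never fired")
  expect_equal(k, 10)

  expect_error(select_pc_count(c(5)), "at least 2")

  ## spectrum built so the rule fires exactly at component 19
  v19 <- 30 * 0.9^(0:18)
  tail_v <- v19[19] * 0.9995^(1:6)
  spec <- c(v19, tail_v)
  expect_equal(select_pc_count(spec), 19)

  ## absolute-change variant
  expect_equal(select_pc_count(c(10, 9.9995, 9.999), mode = "absolute"), 1)
})

test_that("clustering separates well-separated blobs and picks them by
           silhouette", {
  set.seed(2)
  n_per <- 60
  blob <- rbind(matrix(rnorm(n_per * 30), n_per, 30),
                matrix(rnorm(n_per * 30, mean = 10), n_per, 30))
  x <- t(blob)   # genes x cells
  rownames(x) <- sprintf("G%02d", 1:30)
  colnames(x) <- sprintf("c%03d", 1:(2 * n_per))
  cl <- cluster_cells(x, n_pcs = 5)
  expect_equal(length(unique(cl$cluster_id)), 2)
  best <- cl$silhouette_by_resolution
  expect_gt(max(best$mean_silhouette), 0.8)
  expect_equal(cl$selected_resolution,
               best$resolution[which.max(best$mean_silhouette)])

  ## permuting cell order permutes labels but not the partition
  perm <- sample(ncol(x))
  cl2 <- cluster_cells(x[, perm], n_pcs = 5)
  expect_equal(mclust::adjustedRandIndex(cl$cluster_id[perm],
                                         cl2$cluster_id), 1)

  ## identical coordinates degenerate to a single cluster
  flat <- matrix(1, 10, 20,
                 dimnames = list(sprintf("G%02d", 1:10),
                                 sprintf("c%02d", 1:20)))
  expect_warning(cl3 <- cluster_cells(flat, n_pcs = 3), "identical")
  expect_equal(unique(cl3$cluster_id), 0L)
})

test_that("marker weights, voting and the 25% rule drive annotation", {
  ## weight endpoints: unique marker -> 1; shared by all types -> 0
  counts <- matrix(rpois(40 * 30, 5), 40, 30,
                   dimnames = list(sprintf("G%02d", 1:40), NULL))
  m <- tiny_matrix(counts)
  markers <- list(typeA = c("G01", "G05"), typeB = c("G02", "G05"),
                  typeC = c("G03", "G05"))
  ann <- annotate_clusters(m, rep(0L, 30), markers,
                           sensitivity_threshold = 0)
  w <- ann$marker_weights
  expect_equal(unname(w["G01"]), 1)
  expect_equal(unname(w["G05"]), 0)

  ## two-type data with disjoint 8x-elevated markers: both clusters
  ## labeled, no Unknown
  set.seed(3)
  base <- matrix(rpois(60 * 80, 3), 60, 80,
                 dimnames = list(sprintf("G%02d", 1:60), NULL))
  base[1:5, 1:40] <- matrix(rpois(5 * 40, 24), 5, 40)
  base[6:10, 41:80] <- matrix(rpois(5 * 40, 24), 5, 40)
  m2 <- tiny_matrix(base)
  mk <- list(alpha = sprintf("G%02d", 1:5), beta = sprintf("G%02d", 6:10))
  cl <- rep(c(0L, 1L), each = 40)
  ann2 <- annotate_clusters(m2, cl, mk)
  expect_equal(sort(ann2$assignments$cell_type), c("alpha", "beta"))

  ## a cluster expressing no markers stays Unknown
  base2 <- base
  base2[1:10, 41:80] <- 0L
  ann3 <- annotate_clusters(tiny_matrix(base2), cl, mk)
  expect_equal(ann3$assignments$cell_type[ann3$assignments$cluster == 1],
               "Unknown")

  expect_error(annotate_clusters(m2, cl, list()), "empty marker")
})

test_that("full preprocessing chain recovers planted cell types", {
  cfg <- simulation_config(n_genes = 500, n_cells_per_group = 220,
                           n_planted_per_category = 5,
                           cell_types = c("astro", "micro", "oligo", "neuron"),
                           n_markers_per_type = 10, seed = 11)
  sim <- simulate_counts(cfg)
  filt <- suppressMessages(filter_cells(sim$matrix,
                                        qc_thresholds(min_features = 50)))
  ns <- normalize_and_select(filt, n_hvg = 250)
  cl <- cluster_cells(ns$scaled, n_pcs = 10)
  ann <- annotate_clusters(filt, cl$cluster_id, sim$markers)
  truth <- sim$truth_cells$cell_type[match(filt$cells$cell_id,
                                           sim$truth_cells$cell_id)]
  expect_gte(mclust::adjustedRandIndex(ann$cell_type, truth), 0.9)
  expect_setequal(unique(ann$cell_type), c("astro", "micro", "oligo",
                                           "neuron"))
})
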