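#' Cluster cells on a shared-nearest-neighbor graph with silhouette-based
#' resolution selection
#'
#' Runs PCA on the scaled HVG matrix, builds a k-nearest-neighbor graph in
#' PC space (k = 20, each neighborhood including the cell itself) weighted
#' by Jaccard overlap of neighborhoods (SNN), and applies modularity-based
#' Louvain community detection over a grid of resolution parameters. The
#' returned partition is the one maximizing the mean silhouette width
#' (Euclidean distance in PC space); single-cluster solutions are assigned
#' silhouette -1 so they are never selected when an alternative exists.
#'
#' @param scaled_hvg_matrix gene x cell matrix of z-scored normalized
#'   expression (from [normalize_and_select()]).
#' @param n_pcs number of principal components to use.
#' @param resolutions resolution grid; default 15 geometric points in
#'   \[0.001, 1\].
#' @param k neighbors for the kNN graph (reduced with a warning when
#'   there are fewer cells).
#' @param seed seed fixed before each community-detection run.
#' @return a `ClusteringResult`: list with `cluster_id` (integer labels,
#'   contiguous from 0, named by cell), `selected_resolution`,
#'   `silhouette_by_resolution` (data.frame resolution / mean_silhouette /
#'   n_clusters), `n_pcs_used`, and `pc_scores` (cells x PCs).
#' @export
cluster_cells <- function(scaled_hvg_matrix, n_pcs,
                          resolutions = exp(seq(log(0.001), log(1),
                                                length.out = 15)),
                          k = 20, seed = 42L) {
  x <- t(as.matrix(scaled_hvg_matrix))           # cells x genes
  n <- nrow(x)
  if (n < 2) stop("need at least 2 cells to cluster")
  n_pcs <- min(n_pcs, ncol(x), n - 1)
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                           drop = FALSE]
  d <- stats::dist(pcs)
  dm <- as.matrix(d)
  if (max(dm) < 1e-12) {
    warning("all cells have identical coordinates; returning one cluster")
    labels <- stats::setNames(rep(0L, n), rownames(x))
    return(structure(list(cluster_id = labels, selected_resolution = NA_real_,
                          silhouette_by_resolution =
                            data.frame(resolution = NA_real_,
                                       mean_silhouette = -1, n_clusters = 1L),
                          n_pcs_used = n_pcs, pc_scores = pcs),
                     class = "ClusteringResult"))
  }
  if (k >= n) {
    warning("k reduced to n_cells - 1")
    k <- n - 1
  }
  ## kNN neighborhoods including self, then Jaccard (SNN) edge weights
  nn <- lapply(seq_len(n), function(i) {
    others <- setdiff(order(dm[i, ]), i)[seq_len(k)]
    c(i, others)
  })
  ei <- integer(); ej <- integer(); ew <- numeric()
  nnsets <- lapply(nn, sort)
  for (i in seq_len(n)) {
    for (j in nn[[i]]) {
      if (j <= i) next
      inter <- length(intersect(nnsets[[i]], nnsets[[j]]))
      w <- inter / (2 * (k + 1) - inter)
      if (w > 0) { ei <- c(ei, i); ej <- c(ej, j); ew <- c(ew, w) }
    }
  }
  g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- ew
  g <- igraph::simplify(g, edge.attr.comb = "max")

  res_tab <- data.frame(resolution = resolutions, mean_silhouette = NA_real_,
                        n_clusters = NA_integer_)
  labels_by_res <- vector("list", length(resolutions))
  for (r in seq_along(resolutions)) {
    set.seed(as.integer(seed))
    cl <- igraph::cluster_louvain(g, resolution = resolutions[r])
    memb <- igraph::membership(cl)
    k_cl <- length(unique(memb))
    sil <- if (k_cl < 2) -1 else mean(cluster::silhouette(as.integer(memb), d)[, 3])
    res_tab$mean_silhouette[r] <- sil
    res_tab$n_clusters[r] <- k_cl
    labels_by_res[[r]] <- memb
  }
  best <- which.max(res_tab$mean_silhouette)
  memb <- labels_by_res[[best]]
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(labels) <- rownames(x)
  structure(list(cluster_id = labels,
                 selected_resolution = resolutions[best],
                 silhouette_by_resolution = res_tab,
                 n_pcs_used = n_pcs, pc_scores = pcs),
            class = "ClusteringResult")
}

#' Annotate clusters with cell types from marker-score voting
#'
#' Marker specificity weight is `w_g = 1 - (t_g - 1) / (T - 1)` where
#' `t_g` is the number of cell types listing gene `g` and `T` the number
#' of types (a marker unique to one type has weight 1; one shared by all
#' types has weight 0). Markers with weight below `sensitivity_threshold`
#' are discarded. Each cell scores every type as the weighted sum of its
#' markers' z-scored normalized expression and votes for its top-scoring
#' type when that score is positive. A cluster is assigned the type with
#' most votes iff the votes exceed `assign_fraction` of the cluster size;
#' otherwise it is labeled `"Unknown"`.
#'
#' @param matrix a `CellExpressionMatrix`.
#' @param clusters integer cluster labels per cell (e.g.
#'   `ClusteringResult$cluster_id`).
#' @param markers named list: cell type -> character vector of marker
#'   gene ids (markers absent from the matrix are dropped with a warning).
#' @param sensitivity_threshold minimum specificity weight (default 0.5).
#' @param assign_fraction vote fraction required for assignment
#'   (default 0.25).
#' @return an `AnnotationResult`: list with `assignments` (data.frame
#'   cluster / cell_type / votes / cluster_size), `cell_type` (per-cell
#'   label from its cluster's assignment), `scores` (cluster x type vote
#'   matrix), `threshold_fraction`.
#' @export
annotate_clusters <- function(matrix, clusters, markers,
                              sensitivity_threshold = 0.5,
                              assign_fraction = 0.25) {
  stopifnot(inherits(matrix, "CellExpressionMatrix"))
  if (!length(markers)) stop("empty marker set")
  if (length(clusters) != ncol(matrix$counts))
    stop("clusters length != number of cells")
  present <- lapply(markers, intersect, matrix$gene_ids)
  n_drop <- sum(lengths(markers)) - sum(lengths(present))
  if (n_drop > 0) warning(n_drop, " marker genes absent from matrix; dropped")
  markers <- present[lengths(present) > 0]
  if (!length(markers)) stop("no marker genes present in matrix")

  types <- names(markers)
  T_n <- length(types)
  all_m <- unique(unlist(markers))
  t_g <- vapply(all_m, function(g) sum(vapply(markers, function(s) g %in% s,
                                              logical(1))), numeric(1))
  w_g <- if (T_n == 1) stats::setNames(rep(1, length(all_m)), all_m)
         else stats::setNames(1 - (t_g - 1) / (T_n - 1), all_m)
  keep <- names(w_g)[w_g >= sensitivity_threshold]
  markers <- lapply(markers, intersect, keep)

  ## z-scored normalized expression of the retained markers
  counts <- as.matrix(matrix$counts[unique(unlist(markers)), , drop = FALSE])
  depth <- Matrix::colSums(matrix$counts)
  norm <- log1p(sweep(counts, 2, stats::median(depth) / depth, `*`))
  z <- t(scale(t(norm)))
  z[is.na(z)] <- 0

  cell_scores <- sapply(types, function(tt) {
    m <- markers[[tt]]
    if (!length(m)) return(rep(0, ncol(z)))
    colSums(z[m, , drop = FALSE] * w_g[m])
  })
  if (is.null(dim(cell_scores))) cell_scores <- matrix(cell_scores, nrow = 1)
  vote <- ifelse(apply(cell_scores, 1, max) > 0,
                 types[apply(cell_scores, 1, which.max)], NA_character_)

  cl_levels <- sort(unique(clusters))
  votes_mat <- matrix(0L, length(cl_levels), T_n,
                      dimnames = list(as.character(cl_levels), types))
  assignments <- data.frame(cluster = cl_levels, cell_type = "Unknown",
                            votes = 0L, cluster_size = 0L,
                            stringsAsFactors = FALSE)
  for (ci in seq_along(cl_levels)) {
    in_cl <- clusters == cl_levels[ci]
    tab <- table(factor(vote[in_cl], levels = types))
    votes_mat[ci, ] <- as.integer(tab)
    assignments$cluster_size[ci] <- sum(in_cl)
    top <- which.max(tab)
    if (length(tab) && tab[top] > assign_fraction * sum(in_cl)) {
      assignments$cell_type[ci] <- types[top]
      assignments$votes[ci] <- as.integer(tab[top])
    } else {
      assignments$votes[ci] <- if (length(tab)) as.integer(max(tab)) else 0L
    }
  }
  cell_type <- assignments$cell_type[match(clusters, assignments$cluster)]
  structure(list(assignments = assignments, cell_type = cell_type,
                 scores = votes_mat, threshold_fraction = assign_fraction,
                 marker_weights = w_g),
            class = "AnnotationResult")
}
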