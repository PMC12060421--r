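#' Quality-control thresholds for cell filtering
#'
#' Cells with fewer unique detected features than `min_features` (likely
#' empty droplets), more than `max_features` (likely doublets), or more
#' than `max_pct_mito` percent mitochondrial counts (stressed/apoptotic
#' cells) are removed. All boundaries are inclusive on the kept side:
#' "fewer than 200" excludes, so exactly 200 is kept; likewise exactly
#' 7000 features or exactly 5% mitochondrial content is kept.
#'
#' @param min_features minimum number of genes with count > 0 (default 200).
#' @param max_features maximum number of detected genes (default 7000).
#' @param max_pct_mito maximum mitochondrial percentage (default 5).
#' @return a `QCThresholds` object.
#' @export
qc_thresholds <- function(min_features = 200, max_features = 7000,
                          max_pct_mito = 5) {
  stopifnot(min_features < max_features,
            max_pct_mito >= 0, max_pct_mito <= 100)
  structure(list(min_features = min_features, max_features = max_features,
                 max_pct_mito = max_pct_mito), class = "QCThresholds")
}

#' Filter cells on QC metrics
#'
#' Retains cells with `min_features <= n_features <= max_features` and
#' `pct_mito <= max_pct_mito` (inclusive boundaries). Removal counts per
#' criterion are reported via `message()` and attached as the
#' `"qc_removed"` attribute.
#'
#' @param matrix a `CellExpressionMatrix` (QC columns are recomputed).
#' @param thresholds a [qc_thresholds()] object.
#' @return the filtered `CellExpressionMatrix`.
#' @export
filter_cells <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "CellExpressionMatrix"),
            inherits(thresholds, "QCThresholds"))
  matrix <- recompute_qc(matrix)
  md <- matrix$cells
  low <- md$n_features < thresholds$min_features
  high <- md$n_features > thresholds$max_features
  mito <- md$pct_mito > thresholds$max_pct_mito
  keep <- !(low | high | mito)
  if (!any(keep)) stop("all cells removed by QC filtering")
  message(sprintf(
    "QC: removed %d low-feature, %d high-feature, %d high-mito of %d cells",
    sum(low), sum(high), sum(mito), nrow(md)))
  out <- subset_cells(matrix, cells = which(keep))
  attr(out, "qc_removed") <- c(low_features = sum(low),
                               high_features = sum(high),
                               high_mito = sum(mito))
  out
}

#' Depth-normalize counts and select highly variable genes
#'
#' Normalized expression is `log1p(count * median_depth / cell_depth)`
#' (depth = total counts per cell). Highly variable genes (HVGs) are
#' selected by binned dispersion: per-gene dispersion = variance / mean of
#' the normalized values, standardized within 20 quantile bins of the mean
#' so that selection is not driven by the mean-dispersion trend. The
#' scaled matrix is the per-gene z-score of the normalized HVG values,
#' clipped at +/- 10.
#'
#' @param matrix a `CellExpressionMatrix`.
#' @param n_hvg number of variable genes to select (default 2500; capped
#'   at the number of genes with a warning).
#' @return list with `normalized` (dense gene x cell matrix), `hvg`
#'   (character vector, ordered by decreasing standardized dispersion),
#'   `scaled` (HVG x cell z-scored matrix), `dispersion` (per-gene table).
#' @export
normalize_and_select <- function(matrix, n_hvg = 2500) {
  stopifnot(inherits(matrix, "CellExpressionMatrix"), ncol(matrix$counts) > 0)
  counts <- as.matrix(matrix$counts)
  depth <- colSums(counts)
  if (any(depth == 0)) stop("cells with zero total counts; filter first")
  med <- stats::median(depth)
  norm <- log1p(sweep(counts, 2, med / depth, `*`))

  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ## at least ~20 genes per bin so within-bin standardization is stable
  nbins <- min(20L, max(1L, nrow(norm) %/% 20L))
  bins <- if (nbins < 2) rep(1L, nrow(norm))
          else cut(rank(mu, ties.method = "first"), breaks = nbins,
                   labels = FALSE)
  bmu <- tapply(disp, bins, mean)[as.character(bins)]
  bsd <- tapply(disp, bins, stats::sd)[as.character(bins)]
  std_disp <- ifelse(is.na(bsd) | bsd == 0, 0, (disp - bmu) / bsd)
  std_disp[disp == 0] <- -Inf   # constant genes never selected

  if (n_hvg > nrow(norm)) {
    warning("n_hvg exceeds number of genes; using all genes")
    n_hvg <- nrow(norm)
  }
  ord <- order(std_disp, disp, decreasing = TRUE)
  hvg <- rownames(norm)[ord[seq_len(n_hvg)]]
  hvg <- hvg[apply(norm[hvg, , drop = FALSE], 1, stats::sd) > 0]

  scaled <- t(scale(t(norm[hvg, , drop = FALSE])))
  scaled[scaled > 10] <- 10
  scaled[scaled < -10] <- -10
  list(normalized = norm, hvg = hvg, scaled = scaled,
       dispersion = data.frame(gene_id = rownames(norm), mean = mu,
                               variance = v, dispersion = disp,
                               std_dispersion = std_disp,
                               stringsAsFactors = FALSE))
}

#' Choose the number of principal components by the elbow rule
#'
#' Returns the smallest `k` such that the change in variance explained
#' from PC `k` to PC `k+1` falls below `rel_change_threshold`. By default
#' the change is relative, `(v_k - v_{k+1}) / v_k`; `mode = "absolute"`
#' uses the percentage-point difference `v_k - v_{k+1}` instead.
#'
#' @param variance_explained positive, non-increasing vector of percent
#'   variance explained per PC.
#' @param rel_change_threshold threshold on the change (default 0.001,
#'   i.e. 0.1%).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return the selected PC count; if the rule never fires, the full length
#'   with a warning.
#' @export
select_pc_count <- function(variance_explained, rel_change_threshold = 0.001,
                            mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  v <- variance_explained
  if (length(v) < 2) stop("need at least 2 components")
  stopifnot(all(v > 0), all(diff(v) <= 1e-12))
  chg <- if (mode == "relative") (v[-length(v)] - v[-1]) / v[-length(v)]
         else v[-length(v)] - v[-1]
  hit <- which(chg < rel_change_threshold)
  if (!length(hit)) {
    warning("variance-change rule never fired; using all components")
    return(length(v))
  }
  hit[1]
}
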