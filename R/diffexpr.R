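## Per-gene Poisson-regression differential expression.
##
## The two-group Poisson log-linear model with a depth offset,
##   log mu_i = b0 + b1 * group_i + log(depth_i / median depth),
## has closed-form maximum-likelihood estimates: the fitted rate of group j
## is total counts / total offset within the group. All likelihood-ratio
## statistics below use these exact MLEs, vectorized across genes. The
## additive two-factor null of the interaction test has no closed form and
## is fitted by iterative proportional fitting (IPF) on the 2x2 totals.

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

## vectorized 2-group Poisson LRT from group totals
poisson_lrt_totals <- function(Y1, Y0, S1, S0) {
  m1 <- Y1 / S1
  m0 <- Y0 / S0
  m <- (Y1 + Y0) / (S1 + S0)
  lrt <- 2 * (xlogy(Y1, m1 / m) + xlogy(Y0, m0 / m))
  lrt[Y1 + Y0 == 0] <- NA_real_
  list(lrt = lrt, p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       m1 = m1, m0 = m0)
}

capped_log2fc <- function(m1, m0, n_cells, cap = 25) {
  eps <- 1 / n_cells
  lfc <- log2((m1 + eps) / (m0 + eps))
  capped <- abs(lfc) > cap
  lfc[capped] <- sign(lfc[capped]) * cap
  list(log2fc = lfc, capped = capped)
}

#' Fit the two-group Poisson model for a single gene
#'
#' Maximum-likelihood fit of
#' `log mu = b0 + b1 * group + log(depth / median depth)` with a
#' likelihood-ratio test of `b1 = 0` (chi-squared, 1 df). The reported
#' fold change is `log2((m1 + eps) / (m0 + eps))` on the depth-normalized
#' group means, with `eps = 1 / n_cells` stabilizing one-condition-only
#' genes, and is capped at `|log2fc| <= cap` with a flag.
#'
#' @param counts_by_cell integer counts for one gene across cells.
#' @param group_indicator logical/0-1 vector; `TRUE`/1 marks group 1
#'   (e.g. TG), the rest group 0 (e.g. WT). Each group needs >= 2 cells.
#' @param depth_offsets positive per-cell depths (library sizes).
#' @param cap fold-change cap in log2 units (default 25).
#' @return list with `log2fc`, `p_value`, `lrt`, `mean_group1`,
#'   `mean_group0` (depth-normalized), `capped`, `untestable` (both groups
#'   all-zero; excluded from any testing family).
#' @export
fit_gene_poisson <- function(counts_by_cell, group_indicator, depth_offsets,
                             cap = 25) {
  g1 <- as.logical(group_indicator)
  stopifnot(length(counts_by_cell) == length(g1),
            length(depth_offsets) == length(g1),
            all(depth_offsets > 0))
  if (sum(g1) < 2 || sum(!g1) < 2) stop("need >= 2 cells per group")
  s <- depth_offsets / stats::median(depth_offsets)
  r <- poisson_lrt_totals(sum(counts_by_cell[g1]), sum(counts_by_cell[!g1]),
                          sum(s[g1]), sum(s[!g1]))
  lf <- capped_log2fc(r$m1, r$m0, length(g1), cap)
  list(log2fc = lf$log2fc, p_value = unname(r$p), lrt = unname(r$lrt),
       mean_group1 = unname(r$m1), mean_group0 = unname(r$m0),
       capped = unname(lf$capped),
       untestable = sum(counts_by_cell) == 0)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH: p-values sorted in decreasing order are multiplied by
#' `m / rank` and a running minimum enforces monotonicity.
#'
#' @param p_values numeric vector of p-values in \[0,1\] (NAs passed
#'   through).
#' @return FDR values in the original order.
#' @export
adjust_fdr <- function(p_values) {
  p <- p_values
  if (!length(p)) return(numeric(0))
  ok <- !is.na(p)
  stopifnot(all(p[ok] >= 0 & p[ok] <= 1))
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    tmp <- numeric(m)
    tmp[o] <- pmin(1, cummin(m / seq(m, 1) * pv[o]))
    out[ok] <- tmp
  }
  out
}

## Composition-robust recentering of the group-1 size total: when counts
## are normalized by observed library size, genes that truly change drag
## every other gene's apparent fold change in the opposite direction
## (library sizes absorb the shift). Under the standard assumption that
## most genes are unchanged, the median log-ratio across co-expressed
## genes estimates that residual bias; it is absorbed into the group-1
## offset total before testing. Skipped when fewer than `min_genes` genes
## are co-expressed (too few for a stable median).
composition_recenter <- function(Y1, Y0, S1, S0, min_genes = 20) {
  ok <- Y1 > 0 & Y0 > 0
  if (sum(ok) < min_genes) return(S1)
  delta <- stats::median(log((Y1[ok] / S1) / (Y0[ok] / S0)))
  S1 * exp(delta)
}

de_table_totals <- function(Y1, Y0, S1, S0, n1, n0, n_cells, cap = 25,
                            composition_correct = TRUE) {
  if (composition_correct) S1 <- composition_recenter(Y1, Y0, S1, S0)
  r <- poisson_lrt_totals(Y1, Y0, S1, S0)
  lf <- capped_log2fc(r$m1, r$m0, n_cells, cap)
  data.frame(gene_id = names(Y1), log2fc = lf$log2fc, p_value = r$p,
             fdr = adjust_fdr(r$p),
             mean_count_group1 = r$m1, mean_count_group2 = r$m0,
             n_cells_group1 = n1, n_cells_group2 = n0,
             capped_flag = lf$capped, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Stratified TG-vs-WT differential expression
#'
#' For each stratum (every annotated cell type plus all cells pooled as
#' `"pseudobulk"`) and each sex, fits the per-gene Poisson model of
#' [fit_gene_poisson()] to the TG-vs-WT contrast and applies BH adjustment
#' within each (stratum, sex) table. Genes detected (count > 0) in fewer
#' than `min_cells` cells in both genotype groups are pre-filtered from
#' that table; strata with fewer than `min_cells_per_group` cells in
#' either genotype are skipped with a warning.
#'
#' @param matrix a `CellExpressionMatrix`; needs `genotype` ("TG"/"WT")
#'   and `sex` ("M"/"F") metadata; `cell_type` for per-type strata.
#' @param sexes sexes to analyze (default both).
#' @param strata `"auto"` (all annotated cell types + pseudobulk), a
#'   character vector of cell types, or `"pseudobulk"`.
#' @param age_months restrict to one age (default: all cells).
#' @param min_cells detection pre-filter (default 3).
#' @param min_cells_per_group minimum group size per stratum (default 20).
#' @param cap log2 fold-change cap.
#' @param composition_correct recenter the TG size total so the median
#'   log fold change across co-expressed genes is zero before testing
#'   (default TRUE). With library-size offsets, strong expression changes
#'   inflate the affected group's totals and drag every unchanged gene's
#'   apparent fold change the other way; the recentering removes that
#'   bias under the standard assumption that most genes do not change.
#' @return named list of `DETable` data.frames, names `"<stratum>.<sex>"`.
#'   Group 1 is TG, group 2 WT.
#' @export
run_stratified_de <- function(matrix, sexes = c("M", "F"), strata = "auto",
                              age_months = NULL, min_cells = 3,
                              min_cells_per_group = 20, cap = 25,
                              composition_correct = TRUE) {
  stopifnot(inherits(matrix, "CellExpressionMatrix"))
  md <- matrix$cells
  if (!is.null(age_months)) {
    matrix <- subset_cells(matrix, cells = which(md$age_months %in% age_months))
    md <- matrix$cells
  }
  if (identical(strata, "auto")) {
    strata <- character()
    if (!is.null(md$cell_type) && !all(is.na(md$cell_type)))
      strata <- sort(unique(stats::na.omit(md$cell_type)))
    strata <- c(strata, "pseudobulk")
  }
  counts <- matrix$counts
  out <- list()
  for (st in strata) {
    for (sx in sexes) {
      in_st <- if (st == "pseudobulk") rep(TRUE, nrow(md))
               else !is.na(md$cell_type) & md$cell_type == st
      sel <- which(in_st & md$sex == sx)
      if (!length(sel)) next
      geno <- md$genotype[sel]
      n1 <- sum(geno == "TG"); n0 <- sum(geno == "WT")
      if (n1 < min_cells_per_group || n0 < min_cells_per_group) {
        warning(sprintf("stratum %s/%s skipped: %d TG / %d WT cells",
                        st, sx, n1, n0))
        next
      }
      sub <- counts[, sel, drop = FALSE]
      depth <- Matrix::colSums(sub)
      s <- depth / stats::median(depth)
      tg <- geno == "TG"
      det1 <- Matrix::rowSums(sub[, tg, drop = FALSE] > 0)
      det0 <- Matrix::rowSums(sub[, !tg, drop = FALSE] > 0)
      keep <- det1 >= min_cells | det0 >= min_cells
      sub <- sub[keep, , drop = FALSE]
      Y1 <- Matrix::rowSums(sub[, tg, drop = FALSE])
      Y0 <- Matrix::rowSums(sub[, !tg, drop = FALSE])
      tab <- de_table_totals(Y1, Y0, sum(s[tg]), sum(s[!tg]), n1, n0,
                             length(sel), cap, composition_correct)
      tab <- tab[!is.na(tab$p_value), , drop = FALSE]
      rownames(tab) <- NULL
      out[[paste(st, sx, sep = ".")]] <- tab
    }
  }
  out
}

## IPF fit of the additive two-factor Poisson model on 2x2 group totals,
## vectorized across genes. Y: genes x 4 matrix (cells of the design in
## order (1,1),(2,1),(1,2),(2,2) for factors f1 x f2); S: length-4 offsets.
ipf_additive_loglik <- function(Y, S, max_iter = 200, tol = 1e-12) {
  b <- matrix(1, nrow(Y), 2)
  a <- matrix(0, nrow(Y), 2)
  Yrow <- cbind(rowSums(Y[, c(1, 3), drop = FALSE]),
                rowSums(Y[, c(2, 4), drop = FALSE]))
  Ycol <- cbind(rowSums(Y[, c(1, 2), drop = FALSE]),
                rowSums(Y[, c(3, 4), drop = FALSE]))
  Smat <- matrix(S, 2, 2)   # Smat[j,k], j = f1 level, k = f2 level
  for (it in seq_len(max_iter)) {
    denom_a <- cbind(Smat[1, 1] * b[, 1] + Smat[1, 2] * b[, 2],
                     Smat[2, 1] * b[, 1] + Smat[2, 2] * b[, 2])
    a_new <- ifelse(denom_a > 0, Yrow / denom_a, 0)
    denom_b <- cbind(Smat[1, 1] * a_new[, 1] + Smat[2, 1] * a_new[, 2],
                     Smat[1, 2] * a_new[, 1] + Smat[2, 2] * a_new[, 2])
    b_new <- ifelse(denom_b > 0, Ycol / denom_b, 0)
    delta <- max(abs(a_new - a), abs(b_new - b))
    a <- a_new; b <- b_new
    if (delta < tol) break
  }
  mu <- cbind(a[, 1] * b[, 1], a[, 2] * b[, 1],
              a[, 1] * b[, 2], a[, 2] * b[, 2])
  Svec <- c(Smat[1, 1], Smat[2, 1], Smat[1, 2], Smat[2, 2])
  ll <- rowSums(xlogy(Y, mu)) - as.vector(mu %*% Svec)
  ll
}

#' Poisson interaction test for a pair of factors
#'
#' Fits the saturated 2x2 Poisson model
#' `log mu = b0 + b1 f1 + b2 f2 + b3 (f1 f2) + offset` (closed-form group
#' means) against the additive null (`b3 = 0`, fitted by IPF) and reports
#' the likelihood-ratio p-value for the interaction together with the
#' interaction effect on the log2 scale,
#' `[log2 m(f1=2,TG) - log2 m(f1=2,WT)] - [log2 m(f1=1,TG) - log2 m(f1=1,WT)]`
#' with the same `eps` stabilizer and cap as [fit_gene_poisson()].
#'
#' @param matrix a `CellExpressionMatrix`.
#' @param factor_pair `"sex_genotype"` or `"age_genotype"`.
#' @param min_cells detection pre-filter as in [run_stratified_de()].
#' @param cap log2 effect cap.
#' @param subset_cells_idx optional cell index to restrict the analysis
#'   (e.g. one sex for the age x genotype test).
#' @param composition_correct recenter each level's TG size total as in
#'   [run_stratified_de()] (default TRUE), so composition bias cannot
#'   masquerade as an interaction.
#' @return a `DETable` data.frame: `log2fc` holds the interaction effect;
#'   group 1 / group 2 means and cell counts are TG / WT pooled over the
#'   other factor.
#' @export
test_interaction <- function(matrix, factor_pair = c("sex_genotype",
                                                     "age_genotype"),
                             min_cells = 3, cap = 25,
                             subset_cells_idx = NULL,
                             composition_correct = TRUE) {
  factor_pair <- match.arg(factor_pair)
  stopifnot(inherits(matrix, "CellExpressionMatrix"))
  if (!is.null(subset_cells_idx))
    matrix <- subset_cells(matrix, cells = subset_cells_idx)
  md <- matrix$cells
  f1 <- if (factor_pair == "sex_genotype") factor(md$sex, levels = c("M", "F"))
        else factor(md$age_months)
  f2 <- factor(md$genotype, levels = c("WT", "TG"))
  if (nlevels(droplevels(f1)) != 2 || nlevels(droplevels(f2)) != 2)
    stop("both factors need exactly two observed levels")
  f1 <- droplevels(f1)
  cell_of <- interaction(f1, f2, drop = FALSE)
  if (any(table(cell_of) < 2)) stop("empty or near-empty 2x2 design cell")

  counts <- matrix$counts
  depth <- Matrix::colSums(counts)
  s <- depth / stats::median(depth)
  det_tg <- Matrix::rowSums(counts[, f2 == "TG", drop = FALSE] > 0)
  det_wt <- Matrix::rowSums(counts[, f2 == "WT", drop = FALSE] > 0)
  keep <- det_tg >= min_cells | det_wt >= min_cells
  counts <- counts[keep, , drop = FALSE]

  ## group totals in design order (f1=1,WT),(f1=2,WT),(f1=1,TG),(f1=2,TG)
  idx <- list(f1 == levels(f1)[1] & f2 == "WT",
              f1 == levels(f1)[2] & f2 == "WT",
              f1 == levels(f1)[1] & f2 == "TG",
              f1 == levels(f1)[2] & f2 == "TG")
  Y <- sapply(idx, function(i) Matrix::rowSums(counts[, i, drop = FALSE]))
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  S <- vapply(idx, function(i) sum(s[i]), numeric(1))
  if (composition_correct) {
    S[3] <- composition_recenter(Y[, 3], Y[, 1], S[3], S[1])
    S[4] <- composition_recenter(Y[, 4], Y[, 2], S[4], S[2])
  }

  m <- sweep(Y, 2, S, `/`)                       # saturated MLE
  ll_full <- rowSums(xlogy(Y, m)) - rowSums(Y)   # sum S_jk m_jk = sum Y_jk
  ll_add <- ipf_additive_loglik(Y, S)
  lrt <- pmax(0, 2 * (ll_full - ll_add))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  untestable <- rowSums(Y) == 0
  p[untestable] <- NA_real_

  eps <- 1 / ncol(matrix$counts)
  effect <- (log2(m[, 4] + eps) - log2(m[, 2] + eps)) -
            (log2(m[, 3] + eps) - log2(m[, 1] + eps))
  capped <- abs(effect) > cap
  effect[capped] <- sign(effect[capped]) * cap

  m_tg <- rowSums(Y[, 3:4, drop = FALSE]) / (S[3] + S[4])
  m_wt <- rowSums(Y[, 1:2, drop = FALSE]) / (S[1] + S[2])
  tab <- data.frame(gene_id = rownames(counts), log2fc = effect, p_value = p,
                    fdr = adjust_fdr(p),
                    mean_count_group1 = m_tg, mean_count_group2 = m_wt,
                    n_cells_group1 = sum(f2 == "TG"),
                    n_cells_group2 = sum(f2 == "WT"),
                    capped_flag = capped, row.names = NULL,
                    stringsAsFactors = FALSE)
  tab[!is.na(tab$p_value), , drop = FALSE]
}
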