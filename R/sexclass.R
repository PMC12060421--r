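#' Thresholds for sex-dependence classification
#'
#' @param fdr_max significance cutoff on FDR (default 0.05).
#' @param min_abs_log2fc minimum absolute log2 fold change for a
#'   significant call (default 0.5).
#' @param nonsig_nominal_p_min the conservative no-trend gate: a gene may
#'   only be called sex-specific when the opposite sex's nominal p-value
#'   exceeds this (default 0.5), avoiding spurious sex-specificity from
#'   p-values hovering near common thresholds.
#' @param dimorphic_min_delta_log2fc minimum cross-sex difference in log2
#'   fold change for a sex-dimorphic call (default 0.5; with opposite
#'   signs and per-sex effects >= 0.5 this is implied, and is kept as a
#'   redundant guard).
#' @return a `ClassificationThresholds` object.
#' @export
classification_thresholds <- function(fdr_max = 0.05, min_abs_log2fc = 0.5,
                                      nonsig_nominal_p_min = 0.5,
                                      dimorphic_min_delta_log2fc = 0.5) {
  stopifnot(fdr_max > 0, fdr_max <= 1, min_abs_log2fc > 0,
            nonsig_nominal_p_min > 0, nonsig_nominal_p_min <= 1,
            dimorphic_min_delta_log2fc > 0)
  structure(list(fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc,
                 nonsig_nominal_p_min = nonsig_nominal_p_min,
                 dimorphic_min_delta_log2fc = dimorphic_min_delta_log2fc),
            class = "ClassificationThresholds")
}

#' Classify genes as sex-neutral, sex-specific, sex-dimorphic or
#' unclassified
#'
#' Per gene, significance in sex s is `sig_s = (fdr_s < fdr_max AND
#' |log2fc_s| >= min_abs_log2fc)`. The verdict is:
#' \itemize{
#'   \item `sex_neutral`: significant in both sexes, same sign;
#'   \item `sex_dimorphic`: significant in both sexes, opposite signs, and
#'     `|log2fc_M - log2fc_F| >= dimorphic_min_delta_log2fc`;
#'   \item `male_specific` / `female_specific`: significant in exactly
#'     that sex while the other sex shows no nominal trend
#'     (`p > nonsig_nominal_p_min`);
#'   \item `unclassified`: everything else (retained for auditability).
#' }
#' Tables are outer-joined on `gene_id`; a gene absent or untestable in
#' one sex is treated as showing no trend there (its `sig` is FALSE and
#' the nominal-p gate passes), so a gene expressed only in one sex can be
#' called sex-specific.
#'
#' @param male,female `DETable` data.frames for the same stratum.
#' @param thresholds a [classification_thresholds()] object.
#' @param stratum label stored in the output.
#' @return data.frame of `SexCategoryRecord`s: `gene_id`, `stratum`,
#'   `category`, and the supporting `log2fc_m`, `fdr_m`, `p_m`,
#'   `log2fc_f`, `fdr_f`, `p_f`.
#' @export
classify_sex_dependence <- function(male, female,
                                    thresholds = classification_thresholds(),
                                    stratum = "pseudobulk") {
  for (tab in list(male, female)) {
    stopifnot(all(c("gene_id", "log2fc", "p_value", "fdr") %in% colnames(tab)))
    if (anyDuplicated(tab$gene_id)) stop("duplicate gene rows in DE table")
  }
  th <- thresholds
  genes <- union(male$gene_id, female$gene_id)
  im <- match(genes, male$gene_id)
  iff <- match(genes, female$gene_id)
  lfc_m <- male$log2fc[im]; fdr_m <- male$fdr[im]; p_m <- male$p_value[im]
  lfc_f <- female$log2fc[iff]; fdr_f <- female$fdr[iff]; p_f <- female$p_value[iff]

  sig <- function(fdr, lfc) !is.na(fdr) & !is.na(lfc) &
    fdr < th$fdr_max & abs(lfc) >= th$min_abs_log2fc
  notrend <- function(p) is.na(p) | p > th$nonsig_nominal_p_min
  sig_m <- sig(fdr_m, lfc_m)
  sig_f <- sig(fdr_f, lfc_f)

  category <- rep("unclassified", length(genes))
  both <- sig_m & sig_f
  same_sign <- both & sign(lfc_m) == sign(lfc_f)
  opp <- both & sign(lfc_m) != sign(lfc_f) &
    abs(lfc_m - lfc_f) >= th$dimorphic_min_delta_log2fc
  category[same_sign] <- "sex_neutral"
  category[opp] <- "sex_dimorphic"
  category[sig_m & !sig_f & notrend(p_f)] <- "male_specific"
  category[sig_f & !sig_m & notrend(p_m)] <- "female_specific"

  data.frame(gene_id = genes, stratum = stratum, category = category,
             log2fc_m = lfc_m, fdr_m = fdr_m, p_m = p_m,
             log2fc_f = lfc_f, fdr_f = fdr_f, p_f = p_f,
             stringsAsFactors = FALSE)
}

#' Classify age-dependence of the genotype effect per sex
#'
#' Applies the [classify_sex_dependence()] rules to per-sex age x genotype
#' interaction tables. In `age_analysis_mode` (the default) sex-specific
#' calls are reported as `unclassified`, restricting the output to
#' sex-dimorphic / sex-neutral / unclassified: with one interaction test
#' per sex the power for confident sex-specific age calls is limited, so
#' only the two directions supported by significant effects in both sexes
#' are reported.
#'
#' @param male,female per-sex age-interaction `DETable`s.
#' @param thresholds a [classification_thresholds()] object.
#' @param stratum label stored in the output.
#' @param age_analysis_mode collapse sex-specific calls to unclassified
#'   (default TRUE).
#' @return as [classify_sex_dependence()].
#' @export
classify_age_dependence <- function(male, female,
                                    thresholds = classification_thresholds(),
                                    stratum = "pseudobulk",
                                    age_analysis_mode = TRUE) {
  rec <- classify_sex_dependence(male, female, thresholds, stratum)
  if (age_analysis_mode)
    rec$category[rec$category %in% c("male_specific", "female_specific")] <-
      "unclassified"
  rec
}

#' Harmonize gene symbols to a canonical cross-species form
#'
#' Canonical form = trimmed, upper-cased symbol, with an optional alias
#' table applied afterwards (keys matched case-insensitively; values are
#' used verbatim after upper-casing, so the mapping is idempotent).
#'
#' @param symbols character vector of raw gene symbols.
#' @param alias_map optional named character vector `raw -> canonical`
#'   (e.g. `c(Septin4 = "SEPT4")`).
#' @return named character vector mapping each distinct input symbol to
#'   its canonical form; empty strings are dropped with a warning.
#' @export
harmonize_symbols <- function(symbols, alias_map = NULL) {
  stopifnot(is.character(symbols))
  raw <- unique(symbols)
  canon <- toupper(trimws(raw))
  empty <- canon == ""
  if (any(empty)) {
    warning(sum(empty), " empty symbols dropped")
    raw <- raw[!empty]; canon <- canon[!empty]
  }
  if (!is.null(alias_map)) {
    keys <- toupper(trimws(names(alias_map)))
    vals <- toupper(trimws(unname(alias_map)))
    hit <- match(canon, keys)
    canon[!is.na(hit)] <- vals[hit[!is.na(hit)]]
  }
  stats::setNames(canon, raw)
}

#' Read a symbol alias map from a two-column TSV
#'
#' @param path TSV with columns `raw` and `canonical` (header required).
#' @return named character vector usable as `alias_map` in
#'   [harmonize_symbols()].
#' @export
read_alias_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("raw", "canonical") %in% colnames(tab)))
    stop("alias map needs columns 'raw' and 'canonical'")
  stats::setNames(tab$canonical, tab$raw)
}

#' Exact Venn partition of up to four DEG sets
#'
#' Computes every non-empty region of the Venn partition over the given
#' gene sets (each gene assigned to exactly one region by its membership
#' pattern), so region sizes sum to the union size.
#'
#' @param sets named list (2 to 4 elements) of character vectors of
#'   harmonized gene symbols.
#' @return data.frame with one row per non-empty region: `region`
#'   (dataset names joined by `&`), `members` (logical membership pattern
#'   as a compact string like `"1101"`), `size`, `genes`
#'   (comma-separated).
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, length(sets) <= 4,
            !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  memb <- sapply(sets, function(s) universe %in% s)
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(b) paste(as.integer(b), collapse = ""))
  out <- lapply(split(universe, pattern), function(g) g)
  pat <- names(out)
  region <- vapply(pat, function(p) {
    b <- as.logical(as.integer(strsplit(p, "")[[1]]))
    paste(names(sets)[b], collapse = " & ")
  }, character(1))
  res <- data.frame(region = region, members = pat,
                    size = lengths(out),
                    genes = vapply(out, paste, character(1), collapse = ","),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(-nchar(gsub("[^1]", "", res$members)), res$members), ,
      drop = FALSE]
}

#' Cross-dataset overlap for one cell type
#'
#' Convenience wrapper over [overlap_sets()] for dataset collections
#' organized as `dataset -> cell type -> gene set`.
#'
#' @param datasets named list; each element is a named list mapping cell
#'   types to character vectors of harmonized symbols.
#' @param cell_type the cell type to compare (error if absent from any
#'   dataset).
#' @return as [overlap_sets()].
#' @export
overlap_datasets <- function(datasets, cell_type) {
  stopifnot(is.list(datasets), length(datasets) >= 2, !is.null(names(datasets)))
  sets <- lapply(datasets, function(d) {
    if (is.null(d[[cell_type]])) stop("unknown cell type: ", cell_type)
    d[[cell_type]]
  })
  overlap_sets(sets)
}
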