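#' Read a gene-set collection from a GMT file
#'
#' GMT: one set per line, tab-separated fields `name`, `description`,
#' then members. Duplicate members within a set are removed.
#'
#' @param path path to the GMT file.
#' @param namespace optional ontology namespace tag (e.g. "BP" or "MF")
#'   attached to every set.
#' @return a `GeneSetCollection`: named list of character vectors, with a
#'   `namespace` attribute (named character vector per set).
#' @export
read_gmt <- function(path, namespace = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "GeneSetCollection",
                     namespace = character()))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": need name, description, >=1 member")
    if (f[1] %in% names(sets)) stop("duplicate set name at line ", i, ": ", f[1])
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  structure(sets, class = "GeneSetCollection",
            namespace = stats::setNames(rep(namespace, length(sets)),
                                        names(sets)))
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description (default the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis by the hypergeometric test
#'
#' For each gene set, the one-sided tail probability
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' universe size, `K` the set size within the universe, `n` the DEG list
#' size and `k` the overlap — equivalent to a one-sided Fisher exact test
#' on the induced 2x2 table. BH adjustment is applied across the tested
#' sets (per namespace when sets are namespace-tagged).
#'
#' @param deg_list character vector of significant genes (intersected
#'   with the universe).
#' @param universe character vector of all tested genes.
#' @param collection a `GeneSetCollection` or plain named list of sets.
#' @param min_set_size,max_set_size size bounds (after intersection with
#'   the universe); sets outside them are skipped (defaults 3 and 500).
#' @return data.frame sorted by `fdr`: `set`, `namespace`, `k`, `K`, `n`,
#'   `N`, `p_value`, `fdr`, `gene_ratio`, `genes` (overlap,
#'   comma-separated).
#' @export
ora <- function(deg_list, universe, collection, min_set_size = 3,
                max_set_size = 500) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  degs <- unique(intersect(deg_list, universe))
  ns <- attr(collection, "namespace")
  if (is.null(ns)) ns <- stats::setNames(rep(NA_character_,
                                             length(collection)),
                                         names(collection))
  rows <- lapply(names(collection), function(nm) {
    set_u <- intersect(collection[[nm]], universe)
    K <- length(set_u)
    if (K < min_set_size || K > max_set_size) return(NULL)
    ov <- intersect(degs, set_u)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, length(universe) - K, length(degs),
                       lower.tail = FALSE)
    data.frame(set = nm, namespace = ns[[nm]], k = k, K = K,
               n = length(degs), N = length(universe), p_value = p,
               gene_ratio = if (length(degs)) k / length(degs) else 0,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set = character(), namespace = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      gene_ratio = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  res$fdr <- NA_real_
  for (nsp in unique(res$namespace)) {
    sel <- if (is.na(nsp)) is.na(res$namespace) else
      !is.na(res$namespace) & res$namespace == nsp
    res$fdr[sel] <- adjust_fdr(res$p_value[sel])
  }
  res <- res[order(res$fdr, res$p_value),
             c("set", "namespace", "k", "K", "n", "N", "p_value", "fdr",
               "gene_ratio", "genes")]
  rownames(res) <- NULL
  res
}
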