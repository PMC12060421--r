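#' The regulatory interaction categories retained by default
#'
#' Edge-list rows whose `category` falls outside this allow-list are
#' dropped at read time, keeping only interactions with a defined
#' regulatory meaning.
#' @return character vector of category names.
#' @export
regulatory_categories <- function() {
  c("Regulation", "Transcriptional Regulation", "Influence on Expression",
    "Binding", "co-Regulation of Transcription")
}

#' Read a prior-knowledge network from a TSV edge list
#'
#' Expects a header with columns `source`, `target`, `effect` and
#' (optionally) `category`. Effects other than
#' `activation` / `inhibition` are coerced to `"unknown"` with a warning;
#' duplicate rows are removed with a message.
#'
#' @param path TSV path.
#' @param allow_categories categories to keep (default
#'   [regulatory_categories()]); `NULL` keeps everything.
#' @return a `PriorNetwork`.
#' @export
read_network <- function(path, allow_categories = regulatory_categories()) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("source", "target", "effect")
  if (!all(need %in% colnames(tab)))
    stop("network TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$category)) tab$category <- "Regulation"
  if (is.null(tab$provenance)) tab$provenance <- basename(path)
  bad <- !(tab$effect %in% c("activation", "inhibition", "unknown"))
  if (any(bad)) {
    warning(sum(bad), " unrecognized effect values coerced to 'unknown'")
    tab$effect[bad] <- "unknown"
  }
  ndup <- sum(duplicated(tab[, c("source", "target", "effect", "category")]))
  if (ndup > 0) {
    message("removed ", ndup, " duplicate edges")
    tab <- tab[!duplicated(tab[, c("source", "target", "effect", "category")]), ]
  }
  if (!is.null(allow_categories)) {
    drop <- !(tab$category %in% allow_categories)
    if (any(drop)) message("dropped ", sum(drop),
                           " edges outside the regulatory category allow-list")
    tab <- tab[!drop, , drop = FALSE]
  }
  rownames(tab) <- NULL
  new_prior_network(tab)
}

#' Write a network's edge list to TSV
#'
#' @param network a `PriorNetwork` or `RefinedNetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Binary up/down expression profiles from a DE table
#'
#' Genes significant at `fdr < fdr_max` are encoded as 1 (increased in
#' the disease condition, `log2fc > 0`) or 0 (decreased); no effect-size
#' filter is applied, so coordinated small changes are retained. The
#' control profile is the exact complement: a gene up in TG is down in WT
#' relative to TG.
#'
#' @param detable a TG-vs-WT `DETable`.
#' @param fdr_max significance filter (default 0.05).
#' @return list of two `BinaryStateProfile`s: `tg` and `wt`.
#' @export
build_binary_profiles <- function(detable, fdr_max = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% colnames(detable)))
  sig <- !is.na(detable$fdr) & detable$fdr < fdr_max
  zero <- sig & detable$log2fc == 0
  if (any(zero)) {
    warning(sum(zero), " significant genes with log2fc = 0 excluded")
    sig <- sig & detable$log2fc != 0
  }
  states <- stats::setNames(as.integer(detable$log2fc[sig] > 0),
                            detable$gene_id[sig])
  list(tg = new_binary_profile(states, "TG",
                               note = sprintf("FDR < %g, no effect-size filter",
                                              fdr_max)),
       wt = new_binary_profile(1L - states, "WT", note = "complement of TG"))
}

#' Is one signed edge consistent with binary endpoint states?
#'
#' An activation edge is consistent iff source and target share the same
#' state; an inhibition edge iff they differ.
#'
#' @param edge list or one-row data.frame with `source`, `target`,
#'   `effect` (must be resolved: "activation" or "inhibition").
#' @param states named 0/1 vector covering both endpoints.
#' @return logical.
#' @export
edge_consistent <- function(edge, states) {
  eff <- edge$effect
  if (!eff %in% c("activation", "inhibition"))
    stop("edge sign unresolved: ", eff)
  s <- states[c(edge$source, edge$target)]
  if (anyNA(s)) stop("missing endpoint state for ", edge$source, " -> ",
                     edge$target)
  if (eff == "activation") s[[1]] == s[[2]] else s[[1]] != s[[2]]
}

#' Genetic-algorithm parameters for network refinement
#'
#' @param population_size chromosomes per generation (default 200).
#' @param generations number of generations (default 300).
#' @param mutation_rate per-bit flip probability (default 0.02).
#' @param crossover_rate probability a child is produced by uniform
#'   crossover rather than copied (default 0.7).
#' @param elitism_count best chromosomes carried over unchanged
#'   (default 4; with at least 1, best fitness never decreases).
#' @param seed integer seed making the run deterministic.
#' @return a `GAParams` object.
#' @export
ga_params <- function(population_size = 200, generations = 300,
                      mutation_rate = 0.02, crossover_rate = 0.7,
                      elitism_count = 4, seed = 1L) {
  stopifnot(population_size > 0, generations > 0,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            elitism_count >= 0, elitism_count <= population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed)), class = "GAParams")
}

## Problem encoding shared by the GA and the exhaustive oracle.
## Chromosome = (latent state per unmeasured network node) then
## (sign bit per unknown-sign edge; 1 = activation).
refine_problem <- function(prior, profile) {
  stopifnot(inherits(prior, "PriorNetwork"),
            inherits(profile, "BinaryStateProfile"))
  nodes <- prior$nodes
  measured <- intersect(nodes, names(profile$states))
  if (!length(measured)) stop("no network node has a measured state")
  latent <- setdiff(nodes, measured)
  edges <- prior$edges
  unk <- which(edges$effect == "unknown")
  list(edges = edges, latent = latent,
       meas_state = profile$states[measured],
       src_lat = match(edges$source, latent),
       tgt_lat = match(edges$target, latent),
       src_meas = profile$states[edges$source],
       tgt_meas = profile$states[edges$target],
       unk = unk, n_lat = length(latent), n_unk = length(unk),
       n_bits = length(latent) + length(unk))
}

## Fitness of every chromosome in a bits x m population matrix:
## number of edges consistent under the implied states and signs.
refine_fitness <- function(prob, P) {
  m <- ncol(P)
  ne <- nrow(prob$edges)
  S_src <- matrix(prob$src_meas, ne, m)
  S_tgt <- matrix(prob$tgt_meas, ne, m)
  il <- which(!is.na(prob$src_lat))
  if (length(il)) S_src[il, ] <- P[prob$src_lat[il], , drop = FALSE]
  il <- which(!is.na(prob$tgt_lat))
  if (length(il)) S_tgt[il, ] <- P[prob$tgt_lat[il], , drop = FALSE]
  A <- matrix(prob$edges$effect == "activation", ne, m)
  if (prob$n_unk)
    A[prob$unk, ] <- P[prob$n_lat + seq_len(prob$n_unk), , drop = FALSE] == 1
  colSums((S_src == S_tgt) == A)
}

## Decode a chromosome into a RefinedNetwork.
refine_decode <- function(prob, chrom, condition, fitness) {
  states <- c(prob$meas_state,
              stats::setNames(as.integer(chrom[seq_len(prob$n_lat)]),
                              prob$latent))
  edges <- prob$edges
  if (prob$n_unk)
    edges$effect[prob$unk] <- ifelse(
      chrom[prob$n_lat + seq_len(prob$n_unk)] == 1, "activation", "inhibition")
  cons <- (states[edges$source] == states[edges$target]) ==
    (edges$effect == "activation")
  retained <- edges[cons, , drop = FALSE]
  excluded <- edges[!cons, c("source", "target", "effect"), drop = FALSE]
  excluded$reason <- rep("state-conflict", nrow(excluded))
  rownames(retained) <- rownames(excluded) <- NULL
  stopifnot(sum(cons) == fitness)
  new_refined_network(retained, states[prob$latent], fitness, condition,
                      excluded)
}

#' Refine a prior network against a binary profile by genetic algorithm
#'
#' Searches over latent states of unmeasured network nodes and signs of
#' unknown-effect edges for the configuration maximizing the number of
#' sign-consistent edges. Edges inconsistent at the optimum are excluded
#' (reason `"state-conflict"`); unknown signs are resolved from the best
#' chromosome. Tournament selection (size 3), uniform crossover, bit-flip
#' mutation, elitism; a fixed seed makes the run reproducible. When there
#' is nothing to search (no latent nodes, no unknown signs) the problem
#' is solved exactly edge by edge and flagged as such.
#'
#' @param prior a `PriorNetwork`.
#' @param profile a `BinaryStateProfile`.
#' @param params a [ga_params()] object.
#' @return a `RefinedNetwork` with attributes `trajectory` (best fitness
#'   per generation, non-decreasing), `method` ("ga" or "exact") and
#'   `params`.
#' @export
refine_network_ga <- function(prior, profile, params = ga_params()) {
  stopifnot(inherits(params, "GAParams"))
  prob <- refine_problem(prior, profile)
  if (prob$n_bits == 0) {
    fit <- refine_fitness(prob, matrix(integer(), 0, 1))
    out <- refine_decode(prob, integer(), profile$condition, fit)
    attr(out, "method") <- "exact"
    attr(out, "trajectory") <- fit
    attr(out, "params") <- params
    return(out)
  }
  set.seed(params$seed)
  np <- params$population_size
  nb <- prob$n_bits
  P <- matrix(sample(0:1, nb * np, replace = TRUE), nb, np)
  fit <- refine_fitness(prob, P)
  best_chrom <- P[, which.max(fit), drop = TRUE]
  best_fit <- max(fit)
  traj <- numeric(params$generations)
  for (gen in seq_len(params$generations)) {
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(params$elitism_count)]
    ## tournament selection (size 3)
    n_child <- np - params$elitism_count
    pick <- function() {
      cand <- matrix(sample.int(np, 3 * n_child, replace = TRUE), 3, n_child)
      fmat <- matrix(fit[cand], 3, n_child)
      cand[cbind(apply(fmat, 2, which.max), seq_len(n_child))]
    }
    pa <- pick(); pb <- pick()
    cross <- stats::runif(n_child) < params$crossover_rate
    mask <- matrix(stats::runif(nb * n_child) < 0.5, nb, n_child)
    child <- P[, pa, drop = FALSE]
    pbm <- P[, pb, drop = FALSE]
    take_b <- mask & rep(cross, each = nb)
    child[take_b] <- pbm[take_b]
    flip <- matrix(stats::runif(nb * n_child) < params$mutation_rate,
                   nb, n_child)
    child[flip] <- 1L - child[flip]
    P <- cbind(P[, elite_idx, drop = FALSE], child)
    fit <- refine_fitness(prob, P)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_chrom <- P[, which.max(fit), drop = TRUE]
    }
    traj[gen] <- best_fit
  }
  stopifnot(!is.unsorted(traj))   # elitism guarantees monotone best fitness
  out <- refine_decode(prob, best_chrom, profile$condition, best_fit)
  attr(out, "method") <- "ga"
  attr(out, "trajectory") <- traj
  attr(out, "params") <- params
  out
}

#' Exhaustive refinement oracle for small instances
#'
#' Enumerates every configuration of latent states and unknown signs and
#' returns a global optimum; ties are broken by lexicographic chromosome
#' order (all-zero chromosome first).
#'
#' @param prior a `PriorNetwork`.
#' @param profile a `BinaryStateProfile`.
#' @param max_bits refusal threshold on latent + unknown variables
#'   (default 20).
#' @return a `RefinedNetwork` with attribute `method = "exhaustive"`.
#' @export
exhaustive_refine <- function(prior, profile, max_bits = 20) {
  prob <- refine_problem(prior, profile)
  if (prob$n_bits > max_bits)
    stop("instance too large for exhaustive search: ", prob$n_bits,
         " binary variables (latent ", prob$n_lat, " + unknown signs ",
         prob$n_unk, "), limit ", max_bits)
  nb <- prob$n_bits
  if (nb == 0) {
    fit <- refine_fitness(prob, matrix(integer(), 0, 1))
    out <- refine_decode(prob, integer(), profile$condition, fit)
    attr(out, "method") <- "exhaustive"
    return(out)
  }
  best_fit <- -1L
  best_chrom <- NULL
  chunk <- 2^min(nb, 14)
  total <- 2^nb
  ## enumerate with bit 1 as the most significant digit so that integer
  ## order equals lexicographic chromosome order; the first maximum wins
  for (start in seq(0, total - 1, by = chunk)) {
    ids <- start:(min(start + chunk, total) - 1)
    P <- vapply(ids, function(x) {
      as.integer(intToBits(x))[nb:1]
    }, integer(nb))
    if (is.null(dim(P))) P <- matrix(P, nrow = nb)
    fit <- refine_fitness(prob, P)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_chrom <- P[, which.max(fit), drop = TRUE]
    }
  }
  out <- refine_decode(prob, best_chrom, profile$condition, best_fit)
  attr(out, "method") <- "exhaustive"
  out
}
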