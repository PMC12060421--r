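## Synthetic prior-knowledge networks with planted refinement truth.

new_prior_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(edges = edges, nodes = nodes), class = "PriorNetwork")
}

new_binary_profile <- function(states, condition, note = "") {
  stopifnot(all(states %in% c(0L, 1L)), !is.null(names(states)))
  structure(list(condition = condition, states = states, note = note),
            class = "BinaryStateProfile")
}

new_refined_network <- function(edges, latent_states, fitness, condition,
                                excluded) {
  structure(list(edges = edges, latent_states = latent_states,
                 fitness = fitness, condition = condition,
                 excluded = excluded), class = "RefinedNetwork")
}

#' @export
print.PriorNetwork <- function(x, ...) {
  cat("PriorNetwork:", length(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$effect == "unknown"), "unknown-sign )\n")
  invisible(x)
}

#' @export
print.RefinedNetwork <- function(x, ...) {
  cat("RefinedNetwork [", x$condition, "]:", nrow(x$edges),
      "retained edges, fitness", x$fitness, ",", nrow(x$excluded),
      "excluded,", length(x$latent_states), "latent states\n")
  invisible(x)
}

#' Simulate a signed prior network with known refinement ground truth
#'
#' Generates a directed regulatory network together with binary expression
#' states so that the maximal-consistency refinement is known by
#' construction: exactly `floor(frac_inconsistent * n_edges)` edges get a
#' known sign that contradicts their (measured) endpoint states and can
#' never be reconciled; all other edges get the sign consistent with the
#' true states. Unknown-sign flags are placed only on reconcilable edges
#' (an unknown-sign edge between measured endpoints can always be given a
#' consistent sign, so flagging an inconsistent edge would change the
#' planted optimum).
#'
#' @param n_genes number of network nodes.
#' @param n_edges number of directed edges (no self-loops, unique pairs).
#' @param frac_unknown_sign fraction of edges whose effect is reported as
#'   `"unknown"` in the prior (their true sign is kept in the ground truth).
#' @param frac_inconsistent fraction of edges made irreconcilably
#'   inconsistent with the states.
#' @param n_latent number of nodes whose state is withheld from the
#'   profiles (latent; to be inferred during refinement).
#' @param seed integer seed.
#' @return list with elements `prior` (`PriorNetwork`), `truth`
#'   (`RefinedNetwork`: the maximal-consistency refinement),
#'   `profile_tg` / `profile_wt` (`BinaryStateProfile`, complements over
#'   the measured nodes).
#' @export
simulate_prior_network <- function(n_genes, n_edges,
                                   frac_unknown_sign = 0,
                                   frac_inconsistent = 0,
                                   n_latent = 0, seed = 1L) {
  stopifnot(n_genes >= 2, n_edges >= 1,
            frac_unknown_sign >= 0, frac_unknown_sign <= 1,
            frac_inconsistent >= 0, frac_inconsistent <= 1,
            n_latent >= 0, n_latent < n_genes)
  if (n_edges > n_genes * (n_genes - 1))
    stop("n_edges exceeds the number of possible directed edges (",
         n_genes * (n_genes - 1), ")")
  set.seed(as.integer(seed))
  nodes <- sprintf("N%02d", seq_len(n_genes))

  ## sample unique ordered pairs without self-loops
  pair_ids <- sample(n_genes * (n_genes - 1), n_edges)
  src <- (pair_ids - 1L) %/% (n_genes - 1L) + 1L
  off <- (pair_ids - 1L) %% (n_genes - 1L) + 1L
  tgt <- ifelse(off >= src, off + 1L, off)

  state <- stats::rbinom(n_genes, 1, 0.5)
  names(state) <- nodes

  ## plant the inconsistent edges first, then pick latent nodes away from
  ## them, so every planted-inconsistent edge has measured endpoints and
  ## stays irreconcilable under any latent assignment
  n_inc <- floor(frac_inconsistent * n_edges)
  inc_idx <- if (n_inc > 0) sample(n_edges, n_inc) else integer()
  inc_nodes <- unique(c(nodes[src[inc_idx]], nodes[tgt[inc_idx]]))
  latent_pool <- setdiff(nodes, inc_nodes)
  if (length(latent_pool) < n_latent)
    stop("cannot choose ", n_latent, " latent nodes disjoint from planted ",
         "inconsistent edges; lower n_latent or frac_inconsistent")
  latent <- if (n_latent > 0) sample(latent_pool, n_latent) else character()
  measured <- setdiff(nodes, latent)

  same <- state[src] == state[tgt]
  true_sign <- ifelse(same, "activation", "inhibition")   # consistent sign
  effect <- true_sign
  effect[inc_idx] <- ifelse(same[inc_idx], "inhibition", "activation")

  cons_idx <- setdiff(seq_len(n_edges), inc_idx)
  n_unk <- min(floor(frac_unknown_sign * n_edges), length(cons_idx))
  unk_idx <- if (n_unk > 0) sample(cons_idx, n_unk) else integer()
  reported <- effect
  reported[unk_idx] <- "unknown"

  edges <- data.frame(source = nodes[src], target = nodes[tgt],
                      effect = reported, category = "Regulation",
                      provenance = "synthetic", stringsAsFactors = FALSE)
  prior <- new_prior_network(edges, nodes)

  retained <- edges[cons_idx, c("source", "target"), drop = FALSE]
  retained$effect <- true_sign[cons_idx]
  retained$category <- "Regulation"
  rownames(retained) <- NULL
  excluded <- edges[inc_idx, c("source", "target", "effect"), drop = FALSE]
  excluded$reason <- if (n_inc > 0) "state-conflict" else character()
  rownames(excluded) <- NULL
  truth <- new_refined_network(retained, state[latent],
                               fitness = length(cons_idx),
                               condition = "TG", excluded = excluded)

  profile_tg <- new_binary_profile(state[measured], "TG",
                                   note = "synthetic truth states")
  profile_wt <- new_binary_profile(1L - state[measured], "WT",
                                   note = "complement of TG")
  list(prior = prior, truth = truth,
       profile_tg = profile_tg, profile_wt = profile_wt)
}
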