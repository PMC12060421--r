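## Network perturbation: flip a regulator's activity in the disease state
## and propagate the signal through the refined (fully signed) network.

perturb_states <- function(network, disease_profile) {
  stopifnot(inherits(network, "RefinedNetwork"))
  c(disease_profile$states,
    network$latent_states[setdiff(names(network$latent_states),
                                  names(disease_profile$states))])
}

#' Propagate a regulator flip through a signed network
#'
#' Each regulator is seeded with the opposite of its disease state and a
#' breadth-first wavefront spreads the signal: a node is evaluated the
#' first time it is reached; every already-perturbed parent implies a
#' state for it (the parent's state for activation, its complement for
#' inhibition); if all implications agree the node adopts the state and
#' propagates further, if they conflict the node is marked ambiguous and
#' stops propagating. Nodes are finalized at their first wavefront, so
#' cycles cannot re-open them; unreached nodes are untouched.
#' Unperturbed parents impose no constraint: only the perturbation signal
#' travels, modeling deviation from the disease baseline.
#'
#' @param network a `RefinedNetwork` (every edge sign resolved).
#' @param disease_states a `BinaryStateProfile` (disease condition) or
#'   named 0/1 vector; latent nodes take the network's inferred states.
#' @param flipped_regulators character vector of regulator genes (must
#'   have a disease or latent state).
#' @return list with `predicted` (named 0/1 vector over changed nodes,
#'   including the seeded regulators), `status` (named vector over all
#'   network nodes: "changed", "ambiguous" or "untouched"), and `trace`
#'   (data.frame node / wave / implied-by parents).
#' @export
propagate <- function(network, disease_states, flipped_regulators) {
  if (inherits(disease_states, "BinaryStateProfile")) {
    states <- perturb_states(network, disease_states)
  } else states <- disease_states
  edges <- network$edges
  if (any(!edges$effect %in% c("activation", "inhibition")))
    stop("network contains unsigned edges; refine first")
  nodes <- unique(c(edges$source, edges$target, names(states)))
  miss <- setdiff(flipped_regulators, names(states))
  if (length(miss)) stop("no state for regulator(s): ",
                         paste(miss, collapse = ", "))

  status <- stats::setNames(rep("untouched", length(nodes)), nodes)
  predicted <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  predicted[flipped_regulators] <- 1L - states[flipped_regulators]
  status[flipped_regulators] <- "changed"
  trace <- list()
  frontier <- flipped_regulators
  wave <- 0L
  while (length(frontier)) {
    wave <- wave + 1L
    out_e <- edges[edges$source %in% frontier, , drop = FALSE]
    candidates <- setdiff(unique(out_e$target),
                          names(status)[status != "untouched"])
    next_frontier <- character()
    ## evaluate all candidates against the snapshot at the start of the
    ## wave, so results do not depend on iteration order within a wave
    status_snap <- status
    predicted_snap <- predicted
    for (nd in candidates) {
      ## all parents perturbed in earlier waves imply a state
      pe <- edges[edges$target == nd &
                    status_snap[edges$source] == "changed", , drop = FALSE]
      implied <- ifelse(pe$effect == "activation",
                        predicted_snap[pe$source], 1L - predicted_snap[pe$source])
      if (length(unique(implied)) == 1) {
        predicted[nd] <- implied[1]
        status[nd] <- "changed"
        next_frontier <- c(next_frontier, nd)
      } else {
        status[nd] <- "ambiguous"
      }
      trace[[length(trace) + 1L]] <- data.frame(
        node = nd, wave = wave, parents = paste(pe$source, collapse = ","),
        implied = paste(implied, collapse = ","),
        outcome = status[nd], stringsAsFactors = FALSE)
    }
    frontier <- next_frontier
  }
  list(predicted = predicted[status == "changed"], status = status,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(node = character(), wave = integer(),
                               parents = character(), implied = character(),
                               outcome = character()))
}

#' Score a regulator set by downstream DEG reversal
#'
#' Flips the regulators (simultaneously for a pair), propagates through
#' the network, and counts the downstream genes with a measured disease
#' state whose predicted state equals the complement of that disease
#' state (i.e. the control state). Ambiguous and untouched genes never
#' count; the regulators themselves are excluded from the score.
#'
#' @param network a `RefinedNetwork`.
#' @param disease_profile `BinaryStateProfile` of the disease condition.
#' @param regulators character vector (1 or 2 genes, must be network
#'   nodes).
#' @param max_set_size maximum allowed regulator-set size (default 2).
#' @return a `PerturbationResult`: list with `regulators`, `score`,
#'   `reversed` (gene vector), `ambiguous`, `trace`.
#' @export
perturbation_score <- function(network, disease_profile, regulators,
                               max_set_size = 2) {
  stopifnot(length(regulators) >= 1, length(regulators) <= max_set_size)
  net_nodes <- unique(c(network$edges$source, network$edges$target))
  miss <- setdiff(regulators, net_nodes)
  if (length(miss)) stop("regulator(s) absent from network: ",
                         paste(miss, collapse = ", "))
  pr <- propagate(network, disease_profile, regulators)
  measured <- names(disease_profile$states)
  downstream <- setdiff(measured, regulators)
  changed <- intersect(downstream, names(pr$predicted))
  reversed <- changed[pr$predicted[changed] ==
                        1L - disease_profile$states[changed]]
  ambiguous <- intersect(downstream, names(pr$status)[pr$status == "ambiguous"])
  structure(list(regulators = regulators, score = length(reversed),
                 reversed = reversed, ambiguous = ambiguous,
                 trace = pr$trace),
            class = "PerturbationResult")
}

#' @export
print.PerturbationResult <- function(x, ...) {
  cat("PerturbationResult {", paste(x$regulators, collapse = ", "),
      "}: score", x$score, "\n")
  invisible(x)
}

#' Rank single and paired perturbagens
#'
#' Evaluates every single regulator with out-degree > 0, then (when
#' `max_set_size >= 2`) all pairs among the `beam_width` best singles.
#' Results are sorted by decreasing score, ties broken by smaller set
#' size then lexicographic gene order, so the ranking is deterministic
#' and invariant to input edge order.
#'
#' @param network a `RefinedNetwork`.
#' @param disease_profile `BinaryStateProfile` of the disease condition.
#' @param max_set_size 1 or 2 (default 2).
#' @param top_k rows to return (default 20).
#' @param beam_width singles carried into pair evaluation (default 20).
#' @return data.frame `regulator_set` (comma-joined, sorted), `set_size`,
#'   `score`, `n_ambiguous`, `reversed` (comma-joined genes), with the
#'   full `PerturbationResult` list in attribute `"results"`.
#' @export
rank_perturbagens <- function(network, disease_profile, max_set_size = 2,
                              top_k = 20, beam_width = 20) {
  stopifnot(nrow(network$edges) > 0)
  regs <- sort(unique(network$edges$source))
  singles <- lapply(regs, function(r)
    perturbation_score(network, disease_profile, r))
  score1 <- vapply(singles, `[[`, numeric(1), "score")
  ord1 <- order(-score1, regs)
  results <- singles[ord1]
  if (max_set_size >= 2 && length(regs) >= 2) {
    top <- regs[ord1][seq_len(min(beam_width, length(regs)))]
    prs <- utils::combn(sort(top), 2, simplify = FALSE)
    results <- c(results, lapply(prs, function(p)
      perturbation_score(network, disease_profile, p)))
  }
  key_set <- vapply(results, function(r)
    paste(sort(r$regulators), collapse = ","), character(1))
  score <- vapply(results, `[[`, numeric(1), "score")
  size <- vapply(results, function(r) length(r$regulators), integer(1))
  ord <- order(-score, size, key_set)
  results <- results[ord]
  out <- data.frame(
    regulator_set = key_set[ord], set_size = size[ord], score = score[ord],
    n_ambiguous = vapply(results, function(r) length(r$ambiguous), integer(1)),
    reversed = vapply(results, function(r) paste(sort(r$reversed),
                                                 collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- utils::head(out, top_k)
  attr(out, "results") <- utils::head(results, top_k)
  out
}
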