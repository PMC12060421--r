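## Shared fixture builders. Everything is generated in code; no files.

## Tiny CellExpressionMatrix with explicit counts and metadata.
tiny_matrix <- function(counts, sex = NULL, genotype = NULL, age = 17) {
  n <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    sample_id = "s1",
    sex = if (is.null(sex)) rep("M", n) else sex,
    genotype = if (is.null(genotype)) rep("WT", n) else genotype,
    age_months = age, stringsAsFactors = FALSE)
  cell_expression_matrix(counts, cells)
}

## Minimal DE table row-by-row.
de_table <- function(gene_id, log2fc, p_value, fdr = p_value) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, log2fc = log2fc, p_value = p_value,
             fdr = fdr, mean_count_group1 = rep(1, n),
             mean_count_group2 = rep(1, n),
             n_cells_group1 = rep(100L, n), n_cells_group2 = rep(100L, n),
             capped_flag = rep(FALSE, n), stringsAsFactors = FALSE)
}

## Hand-built refined network from an edge table (all nodes measured
## unless latent states are supplied).
refined_net <- function(source, target, effect, latent_states = NULL) {
  edges <- data.frame(source = source, target = target, effect = effect,
                      category = "Regulation", stringsAsFactors = FALSE)
  if (is.null(latent_states))
    latent_states <- stats::setNames(integer(0), character(0))
  scDimorph:::new_refined_network(edges, latent_states,
                                  fitness = nrow(edges), condition = "TG",
                                  excluded = data.frame())
}

binary_profile <- function(states, condition = "TG") {
  scDimorph:::new_binary_profile(states, condition)
}

## Random signed DAG over topologically ordered nodes, all states
## measured. Returns edges + states.
random_dag <- function(n_nodes, p_edge = 0.25, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("D%02d", seq_len(n_nodes))
  src <- character(); tgt <- character()
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < p_edge) {
        src <- c(src, nodes[i]); tgt <- c(tgt, nodes[j])
      }
    }
  }
  list(net = refined_net(src, tgt,
                         sample(c("activation", "inhibition"),
                                length(src), replace = TRUE)),
       states = stats::setNames(stats::rbinom(n_nodes, 1, 0.5), nodes),
       nodes = nodes)
}

## Path-sign enumeration oracle for perturbation propagation on a DAG.
## For every node, enumerates all directed paths from each flipped
## regulator; a path implies state flip(seed) transformed by the product
## of edge signs. Returns per-node implied-state sets; a node is
## "changed" with a definite state when all implications agree,
## "conflict" when they disagree, "untouched" when unreachable.
oracle_path_propagate <- function(net, states, regulators) {
  edges <- net$edges
  sgn <- ifelse(edges$effect == "activation", 1L, -1L)
  implied <- list()
  for (r in regulators) {
    seed_state <- 1L - states[[r]]
    ## DFS over paths
    stack <- list(list(node = r, state = seed_state))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      out_i <- which(edges$source == top$node)
      for (e in out_i) {
        child <- edges$target[e]
        st <- if (sgn[e] == 1L) top$state else 1L - top$state
        implied[[child]] <- union(implied[[child]], st)
        stack[[length(stack) + 1L]] <- list(node = child, state = st)
      }
    }
    implied[[r]] <- union(implied[[r]], seed_state)
  }
  status <- lapply(implied, function(s)
    if (length(s) == 1) c(state = s) else c(state = NA_integer_))
  list(implied = implied,
       changed = names(implied)[vapply(implied, length, 1L) == 1],
       conflicted = names(implied)[vapply(implied, length, 1L) > 1],
       state = vapply(implied, function(s)
         if (length(s) == 1) s else NA_integer_, integer(1)))
}

## Oracle reversal score from the path oracle.
oracle_score <- function(net, states, regulators) {
  o <- oracle_path_propagate(net, states, regulators)
  down <- setdiff(o$changed, regulators)
  sum(o$state[down] == 1L - states[down])
}
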