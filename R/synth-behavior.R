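#' Simulate Y-maze arm-entry sequences with planted alternation propensity
#'
#' Each simulated mouse produces an ordered sequence over the arms A, B, C
#' in which consecutive entries always differ (an "entry" requires changing
#' arms). After the first two entries, the next arm completes a correct
#' alternation (the arm not among the last two) with the group's
#' propensity, and otherwise revisits the arm entered two steps back, so a
#' propensity of 1 yields a pure rotation (100% alternation) and 0 yields
#' strict A-B-A-B revisiting (0%).
#'
#' @param n_mice_per_group mice per (sex, genotype) group.
#' @param alternation_propensity named numeric vector of correct-alternation
#'   probabilities, names `"<sex>_<genotype>"` over
#'   `M_TG`, `M_WT`, `F_TG`, `F_WT` (missing groups are skipped).
#' @param mean_entries Poisson mean of the number of arm entries per mouse
#'   (floored at 3 so an alternation window exists).
#' @param seed integer seed.
#' @return data.frame with columns `mouse_id`, `sex`, `genotype`,
#'   `sequence` (arm labels as a single string, e.g. `"ABCAB"`).
#' @export
simulate_arm_sequences <- function(n_mice_per_group,
                                   alternation_propensity,
                                   mean_entries = 25, seed = 1L) {
  stopifnot(n_mice_per_group >= 1, mean_entries >= 3,
            all(alternation_propensity >= 0), all(alternation_propensity <= 1),
            !is.null(names(alternation_propensity)))
  set.seed(as.integer(seed))
  arms <- c("A", "B", "C")
  rows <- list()
  for (grp in names(alternation_propensity)) {
    p <- alternation_propensity[[grp]]
    parts <- strsplit(grp, "_", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("group name must be '<sex>_<genotype>': ", grp)
    for (i in seq_len(n_mice_per_group)) {
      n <- max(3L, stats::rpois(1, mean_entries))
      seq_arms <- character(n)
      seq_arms[1] <- sample(arms, 1)
      seq_arms[2] <- sample(setdiff(arms, seq_arms[1]), 1)
      for (k in 3:n) {
        alt_arm <- setdiff(arms, seq_arms[c(k - 1, k - 2)])
        seq_arms[k] <- if (stats::runif(1) < p) alt_arm else seq_arms[k - 2]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = sprintf("%s_m%02d", grp, i),
        sex = parts[1], genotype = parts[2],
        sequence = paste(seq_arms, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
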