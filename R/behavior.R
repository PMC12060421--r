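#' Parse an arm-entry sequence, collapsing consecutive duplicates
#'
#' An "entry" requires changing arms, so consecutive repeats of the same
#' arm label are collapsed at ingest; scoring is therefore idempotent.
#'
#' @param sequence character vector of arm labels, or a single string
#'   like `"ABCAB"`.
#' @param arms allowed arm alphabet (default A, B, C).
#' @return character vector of entries.
#' @export
parse_arm_sequence <- function(sequence, arms = c("A", "B", "C")) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(sequence), arms)
  if (length(bad)) stop("invalid arm label(s): ", paste(bad, collapse = ", "))
  if (!length(sequence)) return(character())
  keep <- c(TRUE, sequence[-1] != sequence[-length(sequence)])
  sequence[keep]
}

#' Score spontaneous alternation for one mouse
#'
#' A correct alternation is a window of three consecutive entries visiting
#' three distinct arms. The percentage is
#' `100 * correct / (entries - 2)` (the number of possible alternations);
#' sequences with fewer than 3 entries have an undefined percentage
#' (`NA`) and are flagged.
#'
#' @param sequence arm labels (string or vector; consecutive duplicates
#'   collapsed via [parse_arm_sequence()]).
#' @param mouse_id optional identifier carried into the result.
#' @return data.frame (`AlternationResult`): `mouse_id`, `n_entries`,
#'   `n_correct_alternations`, `n_possible`, `percent_alternation`,
#'   `excluded` (set later by [apply_exclusion()]; `NA` here).
#' @export
score_alternation <- function(sequence, mouse_id = NA_character_) {
  s <- parse_arm_sequence(sequence)
  n <- length(s)
  if (n < 3) {
    return(data.frame(mouse_id = mouse_id, n_entries = n,
                      n_correct_alternations = NA_integer_,
                      n_possible = NA_integer_,
                      percent_alternation = NA_real_,
                      excluded = NA, stringsAsFactors = FALSE))
  }
  wins <- vapply(seq_len(n - 2), function(i)
    length(unique(s[i:(i + 2)])) == 3, logical(1))
  data.frame(mouse_id = mouse_id, n_entries = n,
             n_correct_alternations = sum(wins), n_possible = n - 2L,
             percent_alternation = 100 * sum(wins) / (n - 2),
             excluded = NA, stringsAsFactors = FALSE)
}

#' Score a cohort of arm sequences
#'
#' @param cohort data.frame with columns `mouse_id`, `sex`, `genotype`,
#'   `sequence` (as produced by [simulate_arm_sequences()]).
#' @return data.frame: one [score_alternation()] row per mouse with `sex`
#'   and `genotype` attached.
#' @export
score_cohort <- function(cohort) {
  stopifnot(all(c("mouse_id", "sequence") %in% colnames(cohort)))
  res <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
    score_alternation(cohort$sequence[i], cohort$mouse_id[i])))
  for (col in intersect(c("sex", "genotype"), colnames(cohort)))
    res[[col]] <- cohort[[col]]
  res
}

#' Exclude mice with too few arm entries
#'
#' @param results an alternation results data.frame.
#' @param min_entries exclusion threshold: mice with fewer than this many
#'   entries are excluded (default 10; exactly 10 is retained).
#' @return `results` with the `excluded` flag set.
#' @export
apply_exclusion <- function(results, min_entries = 10) {
  if (!nrow(results)) return(results)
  results$excluded <- results$n_entries < min_entries
  results
}

#' Two-way ANOVA of alternation scores with Sidak post hoc comparisons
#'
#' Fits the fixed-effects linear model `value ~ sex * genotype` and
#' reports Type II sums-of-squares F tests (appropriate for unbalanced
#' group sizes) for the sex and genotype main effects and the
#' interaction. The post hoc table holds the four planned pairwise
#' comparisons (within-sex genotype contrasts and within-genotype sex
#' contrasts) on the model's estimated marginal means, with Sidak
#' adjustment `p_adj = 1 - (1 - p)^4`.
#'
#' @param values numeric response (e.g. percent alternation).
#' @param sex_factor,genotype_factor factors of the same length.
#' @return an `AnovaResult`: list with `effects` (data.frame effect / F /
#'   df1 / df2 / p_value) and `posthoc` (data.frame comparison /
#'   difference / p_value / p_adjusted).
#' @export
two_way_anova <- function(values, sex_factor, genotype_factor) {
  df <- data.frame(y = values, sex = factor(sex_factor),
                   genotype = factor(genotype_factor))
  stopifnot(nrow(df) >= 4, nlevels(df$sex) == 2, nlevels(df$genotype) == 2)
  cells <- table(df$sex, df$genotype)
  if (any(cells == 0))
    stop("empty design cell; interaction untestable: ",
         paste(which(cells == 0), collapse = ","))
  fit <- stats::lm(y ~ sex * genotype, data = df)
  if (sum(stats::residuals(fit)^2) < 1e-16 * max(1, stats::var(df$y)))
    return(anova_zero_residual(df))
  a2 <- car::Anova(fit, type = 2)
  eff_names <- c("sex", "genotype", "sex:genotype")
  rows <- match(eff_names, rownames(a2))
  Fv <- a2[rows, "F value"]
  pv <- a2[rows, "Pr(>F)"]
  ## a constant response gives 0/0 F statistics: report F = 0, p = 1
  degenerate <- !is.finite(Fv) & a2[rows, "Sum Sq"] < 1e-12
  Fv[degenerate] <- 0
  pv[degenerate] <- 1
  effects <- data.frame(effect = eff_names, F = Fv,
                        df1 = a2[rows, "Df"],
                        df2 = a2["Residuals", "Df"],
                        p_value = pv, stringsAsFactors = FALSE)

  emm <- emmeans::emmeans(fit, ~ genotype | sex)
  c1 <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  emm2 <- emmeans::emmeans(fit, ~ sex | genotype)
  c2 <- as.data.frame(emmeans::contrast(emm2, "pairwise", adjust = "none"))
  post <- rbind(
    data.frame(comparison = paste0(c1$contrast, " | sex=", c1$sex),
               difference = c1$estimate, p_value = c1$p.value),
    data.frame(comparison = paste0(c2$contrast, " | genotype=", c2$genotype),
               difference = c2$estimate, p_value = c2$p.value))
  m <- nrow(post)
  post$p_adjusted <- pmin(1, 1 - (1 - post$p_value)^m)
  structure(list(effects = effects, posthoc = post), class = "AnovaResult")
}

## Degenerate design with (numerically) zero residual variance: the
## mean-squared error is 0, so each effect's F is SS/0 — infinite when
## the effect explains anything, and 0/0 (reported F = 0, p = 1) when it
## does not. Type II sums of squares come from explicit projections.
anova_zero_residual <- function(df) {
  rss <- function(X) {
    f <- stats::lm.fit(X, df$y)
    sum(f$residuals^2)
  }
  xs <- as.numeric(df$sex == levels(df$sex)[2])
  xg <- as.numeric(df$genotype == levels(df$genotype)[2])
  X_full <- cbind(1, xs, xg, xs * xg)
  X_add <- cbind(1, xs, xg)
  ss <- c(sex = rss(cbind(1, xg)) - rss(X_add),
          genotype = rss(cbind(1, xs)) - rss(X_add),
          `sex:genotype` = rss(X_add) - rss(X_full))
  tol <- 1e-10 * max(1, sum(df$y^2))
  Fv <- ifelse(ss < tol, 0, Inf)
  effects <- data.frame(effect = names(ss), F = Fv, df1 = 1L,
                        df2 = nrow(df) - 4L,
                        p_value = ifelse(ss < tol, 1, 0),
                        stringsAsFactors = FALSE)
  cm <- tapply(df$y, list(df$sex, df$genotype), mean)
  sx <- levels(df$sex); gt <- levels(df$genotype)
  dd <- c(cm[sx[2], gt[2]] - cm[sx[2], gt[1]],
          cm[sx[1], gt[2]] - cm[sx[1], gt[1]],
          cm[sx[2], gt[2]] - cm[sx[1], gt[2]],
          cm[sx[2], gt[1]] - cm[sx[1], gt[1]])
  comps <- c(paste0(gt[2], " - ", gt[1], " | sex=", sx[2]),
             paste0(gt[2], " - ", gt[1], " | sex=", sx[1]),
             paste0(sx[2], " - ", sx[1], " | genotype=", gt[2]),
             paste0(sx[2], " - ", sx[1], " | genotype=", gt[1]))
  pv <- ifelse(abs(dd) < sqrt(tol), 1, 0)
  posthoc <- data.frame(comparison = comps, difference = dd, p_value = pv,
                        p_adjusted = pmin(1, 1 - (1 - pv)^4),
                        stringsAsFactors = FALSE)
  structure(list(effects = effects, posthoc = posthoc),
            class = "AnovaResult")
}

#' Power of the two-sample t test via the noncentral t distribution
#'
#' Power to detect a standardized effect `d` with `n` per group at level
#' `alpha`: noncentrality `ncp = d * sqrt(n / 2)`, `df = 2n - 2`, and
#' power = P(|T| > t_crit) under the noncentral t.
#'
#' @param effect_size_d Cohen's d (>= 0).
#' @param n_per_group per-group sample size (>= 2).
#' @param alpha type I error probability (default 0.05).
#' @param two_sided two-sided test (default TRUE).
#' @return the power (scalar in \[alpha, 1\]).
#' @export
power_two_sample_t <- function(effect_size_d, n_per_group, alpha = 0.05,
                               two_sided = TRUE) {
  stopifnot(effect_size_d >= 0, n_per_group >= 2, alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- effect_size_d * sqrt(n_per_group / 2)
  if (two_sided) {
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE)
  }
}
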