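test_that("single-gene Poisson LRT matches a profile-likelihood grid oracle", {
  y <- c(0, 1, 2, 4, 5, 6)
  grp <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  fit <- fit_gene_poisson(y, grp, rep(1, 6))

  ## brute-force grid maximization of the Poisson log-likelihood
  loglik <- function(mu, yy) sum(stats::dpois(yy, mu, log = TRUE))
  grid <- seq(0.01, 12, by = 1e-4)
  ll1 <- max(vapply(grid, loglik, numeric(1), yy = y[!grp])) +
         max(vapply(grid, loglik, numeric(1), yy = y[grp]))
  ll0 <- max(vapply(grid, loglik, numeric(1), yy = y))
  lrt_oracle <- 2 * (ll1 - ll0)
  expect_equal(fit$lrt, lrt_oracle, tolerance = 1e-6)
  expect_equal(fit$p_value,
               pchisq(lrt_oracle, 1, lower.tail = FALSE), tolerance = 1e-6)

  ## equal groups, equal depths: no effect, p = 1
  fit0 <- fit_gene_poisson(c(2, 3, 2, 3), c(TRUE, TRUE, FALSE, FALSE),
                           rep(1, 4))
  expect_equal(fit0$log2fc, 0)
  expect_equal(fit0$p_value, 1)

  ## all-zero gene is flagged untestable
  expect_true(fit_gene_poisson(rep(0, 6), grp, rep(1, 6))$untestable)
})

test_that("single-gene fit agrees with glm() and respects offsets", {
  set.seed(10)
  y <- rpois(80, 3)
  grp <- rep(c(TRUE, FALSE), 40)
  depth <- runif(80, 0.5, 2)
  fit <- fit_gene_poisson(y, grp, depth)
  s <- depth / median(depth)
  g <- glm(y ~ grp + offset(log(s)), family = poisson())
  g0 <- glm(y ~ offset(log(s)), family = poisson())
  expect_equal(fit$lrt, g0$deviance - g$deviance, tolerance = 1e-8)

  ## offset correctness: offsets are defined up to a constant, so
  ## rescaling the whole depth vector changes nothing
  fit_resc <- fit_gene_poisson(y, grp, depth * 17)
  expect_equal(fit_resc$lrt, fit$lrt, tolerance = 1e-8)
  expect_equal(fit_resc$mean_group1, fit$mean_group1, tolerance = 1e-8)
  expect_equal(fit_resc$log2fc, fit$log2fc, tolerance = 1e-8)
})

test_that("BH adjustment matches the reference implementation exactly", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_fdr(0.5), 0.5)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_fdr(p), p.adjust(p, "BH"))
  }
})

test_that("stratified DE recovers planted effects and applies the
           detection pre-filter", {
  cfg <- simulation_config(n_genes = 300, n_cells_per_group = 500,
                           n_planted_per_category = c(male_specific = 10),
                           planted_log2fc = 2, seed = 21)
  sim <- simulate_counts(cfg)
  de <- run_stratified_de(sim$matrix, strata = "pseudobulk")
  male <- de[["pseudobulk.M"]]
  ms <- sim$truth_genes$gene_id[sim$truth_genes$category == "male_specific"]
  rows <- male[match(ms, male$gene_id), ]
  expect_true(all(rows$fdr < 0.05))
  expect_true(all(abs(rows$log2fc) >= 0.5))
  ## planted genes rank in the top 5% by p-value in the male table
  expect_true(all(rank(male$p_value)[match(ms, male$gene_id)] <=
                    0.05 * nrow(male)))

  ## a gene detected in only 2 cells is pre-filtered from every table
  m2 <- sim$matrix
  counts <- as.matrix(m2$counts)
  counts[1, ] <- 0L
  counts[1, c(1, 600)] <- 5L
  m3 <- cell_expression_matrix(counts, m2$cells)
  de2 <- run_stratified_de(m3, strata = "pseudobulk")
  expect_false(any(vapply(de2, function(t) "G0001" %in% t$gene_id,
                          logical(1))))

  ## tiny strata are skipped with a warning
  expect_warning(
    run_stratified_de(subset_cells(sim$matrix, cells = c(1:10, 501:530)),
                      strata = "pseudobulk", sexes = "M"),
    "skipped")
})

test_that("male and female tables are exchangeable under sex permutation
           of a null dataset", {
  cfg <- simulation_config(n_genes = 400, n_cells_per_group = 150,
                           n_planted_per_category = 0, seed = 31)
  sim <- simulate_counts(cfg)
  md <- sim$matrix$cells
  set.seed(1)
  md$sex <- sample(md$sex)
  perm <- cell_expression_matrix(sim$matrix$counts, md)
  de <- run_stratified_de(perm, strata = "pseudobulk")
  ks <- suppressWarnings(ks.test(de[["pseudobulk.M"]]$p_value,
                                 de[["pseudobulk.F"]]$p_value))
  expect_gt(ks$p.value, 0.01)
})

test_that("interaction LRT matches glm() and flips sign with level coding", {
  cfg <- simulation_config(n_genes = 60, n_cells_per_group = 100,
                           n_planted_per_category = c(sex_dimorphic = 5),
                           planted_log2fc = 1.5, seed = 41)
  sim <- simulate_counts(cfg)
  it <- test_interaction(sim$matrix, "sex_genotype",
                         composition_correct = FALSE)

  ## glm oracle on a handful of genes
  md <- sim$matrix$cells
  depth <- Matrix::colSums(sim$matrix$counts)
  s <- depth / median(depth)
  f1 <- factor(md$sex, levels = c("M", "F"))
  f2 <- factor(md$genotype, levels = c("WT", "TG"))
  for (g in it$gene_id[1:8]) {
    y <- as.numeric(sim$matrix$counts[g, ])
    full <- glm(y ~ f1 * f2 + offset(log(s)), family = poisson())
    add <- glm(y ~ f1 + f2 + offset(log(s)), family = poisson())
    lrt <- add$deviance - full$deviance
    expect_equal(it$p_value[it$gene_id == g],
                 pchisq(lrt, 1, lower.tail = FALSE), tolerance = 1e-6)
  }

  ## swapping the sex coding flips the effect sign, p unchanged
  md2 <- md
  md2$sex <- ifelse(md$sex == "M", "F", "M")
  it2 <- test_interaction(cell_expression_matrix(sim$matrix$counts, md2),
                          "sex_genotype", composition_correct = FALSE)
  expect_equal(it2$p_value, it$p_value, tolerance = 1e-8)
  expect_equal(it2$log2fc, -it$log2fc, tolerance = 1e-6)
})

test_that("interaction test detects magnitude-only sex differences", {
  cfg <- simulation_config(n_genes = 300, n_cells_per_group = 500,
                           n_planted_per_category =
                             c(interaction_magnitude = 10),
                           planted_log2fc = 2, seed = 51)
  sim <- simulate_counts(cfg)
  it <- test_interaction(sim$matrix, "sex_genotype")
  planted <- sim$truth_genes$gene_id[sim$truth_genes$category ==
                                       "interaction_magnitude"]
  expect_true(all(it$fdr[match(planted, it$gene_id)] < 0.05))
})

test_that("power is monotone in effect size", {
  sizes <- c(0.5, 1, 2)
  rates <- vapply(sizes, function(e) {
    cfg <- simulation_config(n_genes = 400, n_cells_per_group = 150,
                             n_planted_per_category = c(sex_neutral = 80),
                             planted_log2fc = e, seed = 61)
    sim <- simulate_counts(cfg)
    de <- run_stratified_de(sim$matrix, strata = "pseudobulk", sexes = "M")
    tab <- de[["pseudobulk.M"]]
    planted <- sim$truth_genes$gene_id[sim$truth_genes$category ==
                                         "sex_neutral"]
    mean(tab$fdr[match(planted, tab$gene_id)] < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.95)
})
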