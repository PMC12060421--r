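test_that("classification reproduces the published decision patterns", {
  male <- de_table(
    gene_id = c("Hsp90aa1", "Cst3", "Fth1", "Edge1"),
    log2fc  = c(0.01,       1.2,    0.9,    0.6),
    p_value = c(0.9,        1e-280, 1e-270, 0.02),
    fdr     = c(1,          1e-274, 1e-270, 0.04))
  female <- de_table(
    gene_id = c("Hsp90aa1", "Cst3", "Fth1", "Edge1"),
    log2fc  = c(0.65,       -0.8,   0.7,    0.1),
    p_value = c(0.001,      1e-46,  1e-10,  0.2),
    fdr     = c(0.0053,     1.37e-44, 1.97e-09, 0.6))
  rec <- classify_sex_dependence(male, female)
  got <- setNames(rec$category, rec$gene_id)
  expect_equal(unname(got["Hsp90aa1"]), "female_specific")
  expect_equal(unname(got["Cst3"]), "sex_dimorphic")
  expect_equal(unname(got["Fth1"]), "sex_neutral")
  ## significant in males but the other sex shows a nominal trend
  expect_equal(unname(got["Edge1"]), "unclassified")
})

test_that("categories partition the gene universe and duplicates error", {
  set.seed(12)
  n <- 400
  male <- de_table(sprintf("g%03d", 1:n), rnorm(n), runif(n), runif(n))
  female <- de_table(sprintf("g%03d", 1:n), rnorm(n), runif(n), runif(n))
  rec <- classify_sex_dependence(male, female)
  expect_equal(nrow(rec), n)
  expect_true(all(rec$category %in% c("male_specific", "female_specific",
                                      "sex_dimorphic", "sex_neutral",
                                      "unclassified")))
  expect_error(classify_sex_dependence(rbind(male, male[1, ]), female),
               "duplicate")
})

test_that("raising fdr_max never removes a gene from the classified union", {
  set.seed(13)
  n <- 500
  male <- de_table(sprintf("g%03d", 1:n), rnorm(n, sd = 1),
                   runif(n)^2, runif(n)^2)
  female <- de_table(sprintf("g%03d", 1:n), rnorm(n, sd = 1),
                     runif(n)^2, runif(n)^2)
  classified <- function(fdr_max) {
    rec <- classify_sex_dependence(male, female,
      classification_thresholds(fdr_max = fdr_max))
    rec$gene_id[rec$category != "unclassified"]
  }
  lo <- classified(0.01)
  hi <- classified(0.2)
  expect_true(all(lo %in% hi))
})

test_that("a gene absent from one table can still be sex-specific", {
  male <- de_table("only_m", 2, 1e-8, 1e-6)
  female <- de_table(character(0), numeric(0), numeric(0), numeric(0))
  rec <- classify_sex_dependence(male, female)
  expect_equal(rec$category, "male_specific")
})

test_that("age-dependence classification restricts to dimorphic/neutral", {
  male <- de_table(c("a", "b", "c"), c(1.5, 1.2, 1.1),
                   c(1e-6, 1e-6, 1e-6), c(1e-5, 1e-5, 1e-5))
  female <- de_table(c("a", "b", "c"), c(-1.5, 1.2, 0),
                     c(1e-6, 1e-6, 0.9), c(1e-5, 1e-5, 1))
  rec <- classify_age_dependence(male, female)
  got <- setNames(rec$category, rec$gene_id)
  expect_equal(unname(got["a"]), "sex_dimorphic")
  expect_equal(unname(got["b"]), "sex_neutral")
  expect_equal(unname(got["c"]), "unclassified")  # would be male_specific
  rec2 <- classify_age_dependence(male, female, age_analysis_mode = FALSE)
  expect_equal(rec2$category[rec2$gene_id == "c"], "male_specific")
})

test_that("a planted age-dimorphic effect is recovered end to end", {
  groups <- expand.grid(sex = c("M", "F"), genotype = c("TG", "WT"),
                        age_months = c(7, 17), stringsAsFactors = FALSE)
  cfg <- simulation_config(n_genes = 200, n_cells_per_group = 500,
                           groups = groups,
                           n_planted_per_category = c(sex_dimorphic = 5),
                           planted_log2fc = 1.5, effect_ages = 17, seed = 71)
  sim <- simulate_counts(cfg)
  md <- sim$matrix$cells
  tabs <- lapply(c("M", "F"), function(sx)
    test_interaction(sim$matrix, "age_genotype",
                     subset_cells_idx = which(md$sex == sx)))
  rec <- classify_age_dependence(tabs[[1]], tabs[[2]])
  planted <- sim$truth_genes$gene_id[sim$truth_genes$category ==
                                       "sex_dimorphic"]
  expect_true(all(rec$category[match(planted, rec$gene_id)] ==
                    "sex_dimorphic"))
})

test_that("symbol harmonization is case-folding, alias-aware, idempotent", {
  h <- harmonize_symbols(c("Malat1", "MALAT1", " Mbp "))
  expect_equal(unname(h["Malat1"]), "MALAT1")
  expect_equal(unname(h["MALAT1"]), "MALAT1")
  expect_equal(unname(h[" Mbp "]), "MBP")

  am <- c(Septin4 = "SEPT4")
  h2 <- harmonize_symbols(c("Septin4", "sePtin4", "Other"), alias_map = am)
  expect_equal(unname(h2["Septin4"]), "SEPT4")
  expect_equal(unname(h2["sePtin4"]), "SEPT4")

  once <- unname(h2)
  twice <- unname(harmonize_symbols(once, alias_map = am)[once])
  expect_equal(twice, once)

  expect_warning(h3 <- harmonize_symbols(c("A", "")), "empty")
  expect_equal(unname(h3), "A")

  tf <- tempfile(fileext = ".tsv")
  writeLines("raw\tcanonical\nSeptin4\tSEPT4", tf)
  expect_equal(read_alias_map(tf), c(Septin4 = "SEPT4"))
})

test_that("Venn partition regions are exact", {
  sets <- list(d1 = c("MALAT1", "MBP", "X"), d2 = c("MALAT1", "MBP"),
               d3 = c("MALAT1", "MBP", "Y"), d4 = c("MALAT1", "MBP"))
  ov <- overlap_sets(sets)
  core <- ov[ov$members == "1111", ]
  expect_equal(core$size, 2)
  expect_setequal(strsplit(core$genes, ",")[[1]], c("MALAT1", "MBP"))
  expect_equal(sum(ov$size), length(unique(unlist(sets))))

  ## disjoint sets: no multi-set regions; union = sum of sizes
  dis <- list(a = c("p", "q"), b = c("r"), c = c("s", "t", "u"))
  ovd <- overlap_sets(dis)
  expect_true(all(sapply(strsplit(ovd$members, ""),
                         function(b) sum(b == "1")) == 1))
  expect_equal(sum(ovd$size), 6)

  ## bitmask oracle on random sets
  set.seed(14)
  sym <- sprintf("S%03d", 1:100)
  rsets <- list(A = sample(sym, 40), B = sample(sym, 40),
                C = sample(sym, 40), D = sample(sym, 40))
  ov2 <- overlap_sets(rsets)
  uni <- sort(unique(unlist(rsets)))
  mask <- sapply(rsets, function(s) uni %in% s)
  key <- apply(mask, 1, function(b) paste(as.integer(b), collapse = ""))
  oracle <- table(key)
  got <- setNames(as.integer(ov2$size), ov2$members)
  expect_setequal(names(got), names(oracle))
  expect_equal(unname(got[names(oracle)]), as.integer(oracle))

  ## dataset wrapper checks cell types
  ds <- list(x = list(micro = c("A")), y = list(micro = c("A", "B")))
  expect_equal(sum(overlap_datasets(ds, "micro")$size), 2)
  expect_error(overlap_datasets(ds, "astro"), "unknown cell type")
})
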