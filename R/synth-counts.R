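#' Configuration for the synthetic single-cell count generator
#'
#' Defines the simulated study design: sex x genotype (x age) groups with
#' several mice (samples) per group, log-normal library sizes with
#' per-sample shifts, gamma-distributed baseline gene means, and planted
#' genotype effects per sex category. Effects are applied in transgenic
#' (TG) cells only, so TG-vs-WT contrasts recover them.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_group cells per (sex, genotype, age) group.
#' @param groups data.frame with columns `sex` ("M"/"F"), `genotype`
#'   ("TG"/"WT"), `age_months`; defaults to the 2x2 design at 17 months.
#' @param n_samples_per_group mice per group; cells are split evenly.
#' @param depth_lognormal_mu,depth_lognormal_sigma log-normal parameters of
#'   per-cell library-size factors (mu on the log scale).
#' @param sample_depth_sd standard deviation of per-sample shifts added to
#'   `depth_lognormal_mu`, so the depth offset in the GLM is exercised.
#' @param baseline_mean_gamma_shape,baseline_mean_gamma_rate gamma
#'   distribution of baseline expected counts per median-depth cell.
#' @param planted_log2fc effect magnitude; either one number used for every
#'   category or a named vector over categories
#'   (`male_specific`, `female_specific`, `sex_dimorphic`, `sex_neutral`,
#'   `interaction_magnitude`).
#' @param n_planted_per_category genes per category; one number or a named
#'   vector as above. Categories with 0 genes are simply absent.
#' @param interaction_female_scale for `interaction_magnitude` genes the
#'   female effect is `planted_log2fc * interaction_female_scale` with the
#'   same sign as the male effect (magnitude-only sex difference).
#' @param effect_ages ages (months) at which planted effects are active;
#'   default all ages in `groups`. Restricting to one age plants
#'   age-dependent effects.
#' @param dispersion negative-binomial overdispersion; 0 gives Poisson.
#' @param n_mito_genes number of genes flagged mitochondrial (renamed with
#'   the mouse `mt-` prefix).
#' @param mito_fraction_range interval in \[0,1\]: each cell's expected
#'   mitochondrial count fraction is drawn uniformly from it.
#' @param cell_types character vector of cell-type names; empty for an
#'   unstructured population.
#' @param n_markers_per_type markers per cell type (disjoint across types,
#'   never overlapping planted or mitochondrial genes).
#' @param marker_fold_range fold-elevation range of a marker in its type.
#' @param planted_genes optional named list of explicit gene indices per
#'   category (must be disjoint); default assignment is automatic.
#' @param seed integer seed fixing all randomness.
#' @return a `SimulationConfig` object (validated list).
#' @export
simulation_config <- function(n_genes = 1000,
                              n_cells_per_group = 500,
                              groups = expand.grid(sex = c("M", "F"),
                                                   genotype = c("TG", "WT"),
                                                   age_months = 17,
                                                   stringsAsFactors = FALSE),
                              n_samples_per_group = 4,
                              depth_lognormal_mu = log(2000),
                              depth_lognormal_sigma = 0.35,
                              sample_depth_sd = 0.15,
                              baseline_mean_gamma_shape = 2,
                              baseline_mean_gamma_rate = 2,
                              planted_log2fc = 1.5,
                              n_planted_per_category = 0,
                              interaction_female_scale = 0.25,
                              effect_ages = NULL,
                              dispersion = 0,
                              n_mito_genes = 10,
                              mito_fraction_range = c(0.005, 0.03),
                              cell_types = character(),
                              n_markers_per_type = 10,
                              marker_fold_range = c(2, 8),
                              planted_genes = NULL,
                              seed = 1L) {
  cats <- c("male_specific", "female_specific", "sex_dimorphic",
            "sex_neutral", "interaction_magnitude")
  expand_named <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, 5), cats)
    if (!all(names(x) %in% cats)) stop("unknown category in ", what)
    out <- stats::setNames(rep(0, 5), cats)
    out[names(x)] <- x
    out
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_cells_per_group = as.integer(n_cells_per_group),
    groups = as.data.frame(groups),
    n_samples_per_group = as.integer(n_samples_per_group),
    depth_lognormal_mu = depth_lognormal_mu,
    depth_lognormal_sigma = depth_lognormal_sigma,
    sample_depth_sd = sample_depth_sd,
    baseline_mean_gamma_shape = baseline_mean_gamma_shape,
    baseline_mean_gamma_rate = baseline_mean_gamma_rate,
    planted_log2fc = expand_named(planted_log2fc, "planted_log2fc"),
    n_planted_per_category = expand_named(n_planted_per_category,
                                          "n_planted_per_category"),
    interaction_female_scale = interaction_female_scale,
    effect_ages = effect_ages,
    dispersion = dispersion,
    n_mito_genes = as.integer(n_mito_genes),
    mito_fraction_range = mito_fraction_range,
    cell_types = as.character(cell_types),
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_fold_range = marker_fold_range,
    planted_genes = planted_genes,
    seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_cells_per_group > 0,
            cfg$n_samples_per_group > 0, cfg$dispersion >= 0,
            cfg$depth_lognormal_sigma >= 0,
            cfg$baseline_mean_gamma_shape > 0,
            cfg$baseline_mean_gamma_rate > 0)
  stopifnot(all(c("sex", "genotype", "age_months") %in% colnames(cfg$groups)),
            all(cfg$groups$sex %in% c("M", "F")),
            all(cfg$groups$genotype %in% c("TG", "WT")))
  r <- cfg$mito_fraction_range
  stopifnot(length(r) == 2, r[1] >= 0, r[2] <= 1, r[1] <= r[2])
  if (!is.null(cfg$planted_genes)) {
    idx <- unlist(cfg$planted_genes)
    if (anyDuplicated(idx))
      stop("planted gene sets must be disjoint across categories")
    stopifnot(all(idx >= 1), all(idx <= cfg$n_genes))
  }
  n_special <- sum(cfg$n_planted_per_category) + cfg$n_mito_genes +
    length(cfg$cell_types) * cfg$n_markers_per_type
  if (n_special > cfg$n_genes)
    stop("n_genes too small for planted + mito + marker genes (need >= ",
         n_special, ")")
  invisible(cfg)
}

#' Simulate a single-cell count matrix with planted ground truth
#'
#' Counts are drawn gene-wise from a Poisson distribution (negative
#' binomial when `dispersion > 0`) with mean
#' `baseline * 2^log2fc(sex, genotype, age) * depth / median(depth)`.
#' Planted effects act only in TG cells (and only at `effect_ages`).
#' Cell-type identity is expressed solely through fold-elevation of that
#' type's marker genes; mitochondrial content is controlled by scaling the
#' `mt-` flagged genes to a per-cell target fraction.
#'
#' @param config a [simulation_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{matrix}{a `CellExpressionMatrix` (QC columns populated)}
#'     \item{truth_genes}{data.frame `gene_id`, `category`, `log2fc_male`,
#'       `log2fc_female` (`null` category has both effects 0)}
#'     \item{truth_cells}{data.frame `cell_id`, `cell_type` (true labels)}
#'     \item{markers}{named list cell_type -> marker gene ids (a MarkerSet)}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(cfg$seed)
  cats <- names(cfg$n_planted_per_category)

  ## --- gene roles -------------------------------------------------------
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (is.null(cfg$planted_genes)) {
    pool <- seq_len(cfg$n_genes)
    planted <- list(); used <- integer()
    for (ct in cats) {
      k <- cfg$n_planted_per_category[[ct]]
      take <- setdiff(pool, used)[seq_len(k)]
      planted[[ct]] <- take
      used <- c(used, take)
    }
  } else {
    planted <- lapply(stats::setNames(cats, cats), function(ct) {
      idx <- cfg$planted_genes[[ct]]
      if (is.null(idx)) integer() else as.integer(idx)
    })
    used <- unlist(planted)
  }
  rest <- setdiff(seq_len(cfg$n_genes), used)
  mito_idx <- rest[seq_len(min(cfg$n_mito_genes, length(rest)))]
  rest <- setdiff(rest, mito_idx)
  gene_ids[mito_idx] <- sub("^G", "mt-G", gene_ids[mito_idx])

  markers <- list()
  if (length(cfg$cell_types)) {
    for (ct in cfg$cell_types) {
      take <- rest[seq_len(cfg$n_markers_per_type)]
      rest <- setdiff(rest, take)
      markers[[ct]] <- gene_ids[take]
    }
  }

  ## --- per-gene effects -------------------------------------------------
  lfc_m <- lfc_f <- numeric(cfg$n_genes)
  category <- rep("null", cfg$n_genes)
  rnd_sign <- function(n) sample(c(-1, 1), n, replace = TRUE)
  for (ct in cats) {
    idx <- planted[[ct]]
    if (!length(idx)) next
    e <- cfg$planted_log2fc[[ct]]
    s <- rnd_sign(length(idx))
    category[idx] <- ct
    switch(ct,
      male_specific = { lfc_m[idx] <- s * e },
      female_specific = { lfc_f[idx] <- s * e },
      sex_dimorphic = { lfc_m[idx] <- s * e; lfc_f[idx] <- -s * e },
      sex_neutral = { lfc_m[idx] <- s * e; lfc_f[idx] <- s * e },
      interaction_magnitude = {
        lfc_m[idx] <- s * e
        lfc_f[idx] <- s * e * cfg$interaction_female_scale
      })
  }

  baseline <- stats::rgamma(cfg$n_genes, shape = cfg$baseline_mean_gamma_shape,
                            rate = cfg$baseline_mean_gamma_rate)
  baseline <- pmax(baseline, 1e-4)

  marker_fold <- matrix(1, cfg$n_genes, max(1L, length(cfg$cell_types)))
  colnames(marker_fold) <- if (length(cfg$cell_types)) cfg$cell_types else "all"
  for (ct in names(markers)) {
    gi <- match(markers[[ct]], gene_ids)
    marker_fold[gi, ct] <- stats::runif(length(gi), cfg$marker_fold_range[1],
                                        cfg$marker_fold_range[2])
  }

  ## --- cells ------------------------------------------------------------
  effect_ages <- if (is.null(cfg$effect_ages)) unique(cfg$groups$age_months)
                 else cfg$effect_ages
  grp <- cfg$groups
  n_grp <- nrow(grp)
  n_cells <- cfg$n_cells_per_group * n_grp
  meta_list <- vector("list", n_grp)
  count_cols <- vector("list", n_grp)
  depth_list <- vector("list", n_grp)
  types <- if (length(cfg$cell_types)) cfg$cell_types else "all"
  mito_local <- which(is_mito_gene(gene_ids))

  for (g in seq_len(n_grp)) {
    nc <- cfg$n_cells_per_group
    gname <- paste(grp$sex[g], grp$genotype[g], grp$age_months[g], sep = "_")
    sample_of <- rep(seq_len(cfg$n_samples_per_group), length.out = nc)
    sample_shift <- stats::rnorm(cfg$n_samples_per_group, 0, cfg$sample_depth_sd)
    depth <- stats::rlnorm(nc, cfg$depth_lognormal_mu + sample_shift[sample_of],
                           cfg$depth_lognormal_sigma)
    type_of <- sample(rep(types, length.out = nc))

    active <- grp$genotype[g] == "TG" && grp$age_months[g] %in% effect_ages
    lfc <- if (!active) numeric(cfg$n_genes)
           else if (grp$sex[g] == "M") lfc_m else lfc_f
    base_g <- baseline * 2^lfc

    lam <- matrix(0, cfg$n_genes, nc)
    for (tt in types) {
      j <- which(type_of == tt)
      if (!length(j)) next
      lam[, j] <- (base_g * marker_fold[, tt]) %o% rep(1, length(j))
    }
    ## mitochondrial content: rescale mt- genes to a per-cell target fraction
    f_target <- stats::runif(nc, cfg$mito_fraction_range[1],
                             cfg$mito_fraction_range[2])
    s_mito <- colSums(lam[mito_local, , drop = FALSE])
    s_rest <- colSums(lam) - s_mito
    alpha <- ifelse(s_mito > 0, f_target * s_rest / ((1 - f_target) * s_mito), 1)
    lam[mito_local, ] <- sweep(lam[mito_local, , drop = FALSE], 2, alpha, `*`)

    lam <- sweep(lam, 2, depth, `*`)   # depth factor, normalized below
    count_cols[[g]] <- lam
    depth_list[[g]] <- depth
    meta_list[[g]] <- data.frame(
      cell_id = sprintf("%s_c%04d", gname, seq_len(nc)),
      sample_id = sprintf("%s_s%d", gname, sample_of),
      sex = grp$sex[g], genotype = grp$genotype[g],
      age_months = grp$age_months[g], cell_type = type_of,
      stringsAsFactors = FALSE)
  }

  lam_all <- do.call(cbind, count_cols)
  ## lam currently = per-gene rate x depth; divide by the median drawn depth
  ## so a median-depth cell has expected counts equal to its baseline rates
  lam_all <- lam_all / stats::median(unlist(depth_list))
  counts <- if (cfg$dispersion > 0) {
    matrix(stats::rnbinom(length(lam_all), size = 1 / cfg$dispersion,
                          mu = lam_all), nrow = cfg$n_genes)
  } else {
    matrix(stats::rpois(length(lam_all), lam_all), nrow = cfg$n_genes)
  }
  rownames(counts) <- gene_ids

  meta <- do.call(rbind, meta_list)
  mat <- cell_expression_matrix(counts, meta, gene_ids = gene_ids)
  list(matrix = mat,
       truth_genes = data.frame(gene_id = gene_ids, category = category,
                                log2fc_male = lfc_m, log2fc_female = lfc_f,
                                stringsAsFactors = FALSE),
       truth_cells = data.frame(cell_id = meta$cell_id,
                                cell_type = meta$cell_type,
                                stringsAsFactors = FALSE),
       markers = markers)
}
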