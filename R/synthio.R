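#' Simulation configuration for synthetic expression cohorts
#'
#' Describes a cohort with the statistical structure the downstream analysis
#' assumes: a bimodal log2 intensity distribution with a low-expression mode,
#' gene-wise variance heterogeneity, a 2-phenotype x 2-condition design, and
#' planted differential expression with a ground-truth table. Defaults emulate
#' an aged-rat induction study: 16 unimpaired arrays (8 spatial, 8 non-spatial)
#' and 15 impaired arrays (8 spatial, 7 non-spatial).
#'
#' Gene SDs are drawn from a scaled inverse-chi-square-like family:
#' `sd_i = base_sd * sqrt(shape / rchisq(shape))`, so smaller `gene_sd_shape`
#' means heavier variance heterogeneity (and a non-trivial s0 selection).
#'
#' @param n_genes number of probesets.
#' @param group_sizes named integer vector, group label -> array count. Labels
#'   of the form `PHENOTYPE-CONDITION` (e.g. "AU-S") are parsed into the
#'   sample sheet's phenotype and condition columns.
#' @param frac_low_expressed fraction of genes in the low-intensity mode.
#' @param low_mode_mean,high_mode_mean centers of the two modes (log2 scale).
#' @param mode_sd spread of gene-level means around their mode (log2).
#' @param base_sd,gene_sd_shape scale and shape of the gene-SD distribution.
#' @param n_de number of planted differentially expressed genes; planted only
#'   among high-mode genes since low-mode genes are filtered before testing.
#' @param effect_size log2 shift for planted genes (scalar or length `n_de`).
#' @param effect_size_unit "log2" (absolute shift) or "gene_sd" (shift is
#'   `effect_size` times each planted gene's own SD).
#' @param de_up_fraction fraction of planted effects that are positive in the
#'   DE groups.
#' @param de_groups group labels receiving the planted shift.
#' @param array_effect_sd SD of per-array additive offsets (log2).
#' @param cross_dataset_share fraction of planted effects shared (same genes,
#'   same signs) between the two datasets of [generate_paired_datasets()].
#' @param seed integer RNG seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       group_sizes = c("AU-S" = 8, "AU-NS" = 8,
                                       "AI-S" = 8, "AI-NS" = 7),
                       frac_low_expressed = 0.4,
                       low_mode_mean = 2.0,
                       high_mode_mean = 8.0,
                       mode_sd = 0.8,
                       base_sd = 0.3,
                       gene_sd_shape = 5,
                       n_de = 300,
                       effect_size = 0.6,
                       effect_size_unit = c("log2", "gene_sd"),
                       de_up_fraction = 0.5,
                       de_groups = c("AU-S", "AU-NS"),
                       array_effect_sd = 0.1,
                       cross_dataset_share = 0.5,
                       seed = 1L) {
  effect_size_unit <- match.arg(effect_size_unit)
  cfg <- list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
              frac_low_expressed = frac_low_expressed,
              low_mode_mean = low_mode_mean, high_mode_mean = high_mode_mean,
              mode_sd = mode_sd, base_sd = base_sd,
              gene_sd_shape = gene_sd_shape, n_de = as.integer(n_de),
              effect_size = effect_size, effect_size_unit = effect_size_unit,
              de_up_fraction = de_up_fraction, de_groups = de_groups,
              array_effect_sd = array_effect_sd,
              cross_dataset_share = cross_dataset_share,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stop("config error: n_genes must be positive")
  if (is.null(names(cfg$group_sizes)) || any(names(cfg$group_sizes) == ""))
    stop("config error: group_sizes must be a named vector")
  if (any(cfg$group_sizes < 2))
    stop("config error: every group needs at least 2 arrays")
  for (f in c("frac_low_expressed", "de_up_fraction", "cross_dataset_share")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("config error: ", f, " must lie in [0,1]")
  }
  if (cfg$n_de > cfg$n_genes) stop("config error: n_de exceeds n_genes")
  if (cfg$gene_sd_shape <= 0 || cfg$base_sd <= 0)
    stop("config error: gene SD parameters must be positive")
  if (!all(cfg$de_groups %in% names(cfg$group_sizes)))
    stop("config error: de_groups not among group_sizes labels")
  if (!length(cfg$effect_size) %in% c(1L, cfg$n_de))
    stop("config error: effect_size must be scalar or length n_de")
  invisible(cfg)
}

# Deterministic sub-seed for dataset `index` within a paired run; keeps the
# derived seed inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

#' Generate one synthetic cohort with ground truth
#'
#' Each gene is assigned to the low or high intensity mode, given a mean around
#' its mode center and a gene-specific SD. Planted DE genes (high-mode only)
#' are shifted by the configured effect in the designated groups; per-array
#' additive offsets model residual technical variation. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param de_ids optional character vector overriding the random choice of
#'   planted genes (used internally for paired datasets).
#' @param de_signs optional +1/-1 vector matching `de_ids`.
#' @return a list with elements `matrix` (an annotated [expression_matrix()])
#'   and `truth` (data.frame: probeset_id, true_effect, is_de, is_low,
#'   gene_sd).
#' @export
generate_cohort <- function(config, de_ids = NULL, de_signs = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("ps_%05d", seq_len(n))

  is_low <- stats::runif(n) < config$frac_low_expressed
  mode_center <- ifelse(is_low, config$low_mode_mean, config$high_mode_mean)
  mu <- stats::rnorm(n, mode_center, config$mode_sd)
  gene_sd <- config$base_sd *
    sqrt(config$gene_sd_shape / stats::rchisq(n, df = config$gene_sd_shape))

  # planted effects live on high-mode genes only
  true_effect <- numeric(n)
  if (config$n_de > 0) {
    high_ids <- ids[!is_low]
    if (is.null(de_ids)) {
      if (config$n_de > length(high_ids))
        stop("config error: n_de exceeds the number of high-mode genes")
      de_ids <- sample(high_ids, config$n_de)
      de_signs <- ifelse(stats::runif(config$n_de) < config$de_up_fraction, 1, -1)
    }
    idx <- match(de_ids, ids)
    if (anyNA(idx)) stop("unknown planted gene IDs")
    eff <- rep_len(config$effect_size, length(idx))
    if (config$effect_size_unit == "gene_sd") eff <- eff * gene_sd[idx]
    true_effect[idx] <- de_signs * eff
  }

  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n_samp <- length(groups)
  sample_ids <- sprintf("%s_%02d", groups, stats::ave(seq_len(n_samp), groups,
                                                      FUN = seq_along))
  in_de_group <- groups %in% config$de_groups
  array_offset <- stats::rnorm(n_samp, 0, config$array_effect_sd)

  vals <- mu + matrix(stats::rnorm(n * n_samp, 0, gene_sd), n, n_samp)
  vals <- vals + outer(true_effect, as.numeric(in_de_group)) +
    matrix(array_offset, n, n_samp, byrow = TRUE)
  dimnames(vals) <- list(ids, sample_ids)

  parts <- strsplit(groups, "-", fixed = TRUE)
  samples <- data.frame(
    sample_id = sample_ids,
    phenotype = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
    group = groups,
    stringsAsFactors = FALSE)
  # learning index: a proximity-style score; impaired phenotypes sit above the
  # conventional 240 cutoff, unimpaired below
  samples$learning_index <- round(ifelse(grepl("I$", samples$phenotype),
                                         stats::rnorm(n_samp, 280, 20),
                                         stats::rnorm(n_samp, 210, 20)), 1)

  truth <- data.frame(probeset_id = ids, true_effect = true_effect,
                      is_de = true_effect != 0, is_low = is_low,
                      gene_sd = gene_sd, stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals, samples), truth = truth)
}

#' Generate two cohorts sharing a controlled fraction of planted effects
#'
#' The two truths share exactly `round(cross_dataset_share * n_de)` planted
#' genes with equal-signed effects; the remaining planted genes are drawn
#' disjointly across the pair, so the shared count is exact by construction
#' (at share 0 the planted sets are fully dataset-specific). This is the
#' device for testing cross-dataset d-statistic concordance.
#'
#' @param config a [sim_config()] with `cross_dataset_share` set.
#' @return a list of two `generate_cohort()`-style lists, named `a` and `b`.
#' @export
generate_paired_datasets <- function(config) {
  validate_sim_config(config)
  share <- config$cross_dataset_share
  n_shared <- round(share * config$n_de)

  set.seed(config$seed)
  # the mode assignment must match what each cohort will draw from its own
  # stream, so regenerate it per-dataset seed and take the intersection of
  # high-mode genes for the shared core
  ids <- sprintf("ps_%05d", seq_len(config$n_genes))
  low_a <- local({set.seed(derive_seed(config$seed, 1L))
    stats::runif(config$n_genes) < config$frac_low_expressed})
  low_b <- local({set.seed(derive_seed(config$seed, 2L))
    stats::runif(config$n_genes) < config$frac_low_expressed})
  high_both <- ids[!low_a & !low_b]
  if (config$n_de > 0 && length(high_both) < config$n_de)
    stop("config error: too few jointly high-mode genes for n_de")

  set.seed(derive_seed(config$seed, 3L))
  shared_ids <- if (n_shared > 0) sample(high_both, n_shared) else character(0)
  shared_signs <- ifelse(stats::runif(n_shared) < config$de_up_fraction, 1, -1)

  # dataset-specific planted genes are kept disjoint across the pair, so the
  # two truths share exactly the forced core
  n_own <- config$n_de - n_shared
  set.seed(derive_seed(config$seed, 11L))
  pool_a <- setdiff(ids[!low_a], shared_ids)
  own_a <- if (n_own > 0) sample(pool_a, n_own) else character(0)
  signs_a <- ifelse(stats::runif(n_own) < config$de_up_fraction, 1, -1)
  set.seed(derive_seed(config$seed, 12L))
  pool_b <- setdiff(ids[!low_b], c(shared_ids, own_a))
  if (n_own > length(pool_b))
    stop("config error: too few high-mode genes for disjoint planted sets")
  own_b <- if (n_own > 0) sample(pool_b, n_own) else character(0)
  signs_b <- ifelse(stats::runif(n_own) < config$de_up_fraction, 1, -1)

  gen_one <- function(index, own_ids, own_signs) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, index)
    generate_cohort(cfg, de_ids = c(shared_ids, own_ids),
                    de_signs = c(shared_signs, own_signs))
  }
  list(a = gen_one(1L, own_a, signs_a), b = gen_one(2L, own_b, signs_b))
}

#' Write / read a ground-truth table
#'
#' Tab-delimited with header, one row per probeset, fixed column order:
#' probeset_id, true_effect, is_de, is_low, gene_sd.
#'
#' @param truth a truth data.frame from [generate_cohort()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  cols <- c("probeset_id", "true_effect", "is_de", "is_low", "gene_sd")
  if (!all(cols %in% names(truth))) stop("truth table missing columns")
  utils::write.table(truth[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
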