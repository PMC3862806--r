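#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end driver: generate a cohort from a [sim_config()], quantile
#' normalize, QC for outlier arrays, detect and apply the low-expression
#' cutoff, run the moderated d-statistic analysis with permutation FDR on the
#' phenotype contrast, embed samples by correlation-distance MDS, and write
#' every artifact as tab-delimited text plus a JSON run summary. Byte-identical
#' outputs for identical config and seed.
#'
#' @param config a [sim_config()]; its seed drives data generation.
#' @param out_dir output directory (created if needed).
#' @param contrast character(2) phenotype labels (default the two phenotypes
#'   in the config's group labels, first vs second).
#' @param fdr target FDR levels for significance calls.
#' @param B number of permutations.
#' @param seed RNG seed for the permutation null.
#' @param cutoff "auto" or a numeric log2 cutoff.
#' @return (invisibly) a list with the sam_result, qc report, embedding, and
#'   the paths written.
#' @export
run_pipeline <- function(config, out_dir, contrast = NULL,
                         fdr = c(0.05, 0.1), B = 200, seed = 1,
                         cutoff = "auto") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  x <- quantile_normalize(cohort$matrix)
  qc <- detect_outlier_arrays(x)
  if (length(qc$flagged_outliers))
    x <- subset_matrix(x, samples = setdiff(colnames(x$values),
                                            qc$flagged_outliers))
  cut <- if (identical(cutoff, "auto")) detect_low_cutoff(x) else cutoff
  filtered <- filter_low_expression(x, cut)

  if (is.null(contrast)) contrast <- unique(x$samples$phenotype)[1:2]
  design <- sam_design(filtered, contrast, by = "phenotype")
  res <- sam(filtered, design, fdr = fdr, B = B, seed = seed)

  emb <- classical_mds(correlation_distance(filtered), k = 2)

  paths <- c(
    matrix = file.path(out_dir, "expression_matrix.tsv"),
    samples = file.path(out_dir, "sample_sheet.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    genes = file.path(out_dir, "sam_genes.tsv"),
    delta = file.path(out_dir, "delta_table.tsv"),
    mds = file.path(out_dir, "mds_coordinates.tsv"),
    summary = file.path(out_dir, "run_summary.json"))
  write_matrix(x, paths["matrix"])
  write_sample_sheet(x, paths["samples"])
  write_truth(cohort$truth, paths["truth"])

  genes <- res$genes
  for (f in names(res$calls)) {
    cl <- res$calls[[f]]
    col <- paste0("call_fdr_", f)
    genes[[col]] <- "ns"
    hit <- match(cl$calls$probeset_id, genes$probeset_id)
    genes[[col]][hit] <- cl$calls$direction
  }
  utils::write.table(format(genes, digits = 10, trim = TRUE), paths["genes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(res$delta_table, digits = 10, trim = TRUE),
                     paths["delta"], sep = "\t", quote = FALSE, row.names = FALSE)
  coords <- data.frame(sample_id = rownames(emb$points),
                       dim1 = emb$points[, 1], dim2 = emb$points[, 2],
                       phenotype = filtered$samples$phenotype,
                       condition = filtered$samples$condition,
                       stringsAsFactors = FALSE)
  utils::write.table(format(coords, digits = 10, trim = TRUE), paths["mds"],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    n_genes_input = config$n_genes,
    n_genes_retained = nrow(filtered$values),
    cutoff_used = as.numeric(cut),
    cutoff_source = if (identical(cutoff, "auto"))
      attr(cut, "source") else "user",
    flagged_outliers = qc$flagged_outliers,
    contrast = contrast, s0 = res$s0, n_permutations = res$B,
    calls = lapply(res$calls, function(cl)
      list(target_fdr = cl$target_fdr, delta = cl$delta,
           n_called = cl$n_called, estimated_fdr = cl$fdr)),
    seed = seed)
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null")

  invisible(list(sam = res, qc = qc, embedding = emb, cutoff = cut,
                 truth = cohort$truth, filtered = filtered, paths = paths))
}
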