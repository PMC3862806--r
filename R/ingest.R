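#' Quantile-normalize an expression matrix
#'
#' Forces every sample onto the common distribution given by the across-sample
#' mean of sorted values (the standard microarray quantile normalization,
#' delegated to limma). Idempotent: a second application changes nothing
#' beyond numerical tolerance.
#'
#' @param x an `expr_matrix`.
#' @return the normalized `expr_matrix`.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x$values) < 2) {
    warning("single sample: quantile normalization is a no-op")
    return(x)
  }
  v <- limma::normalizeQuantiles(x$values)
  dimnames(v) <- dimnames(x$values)
  x$values <- v
  x
}

#' Detect the low-expression intensity cutoff
#'
#' Affymetrix-style data background-corrected with gcRMA shows a bimodal log2
#' intensity distribution; differential-expression statistics behave badly in
#' the low mode, so genes below the inter-mode dip are excluded. The dip is
#' located as the minimum of a kernel density of per-gene mean intensities
#' between the two highest density peaks. When no second mode is found the
#' conventional default of 4.0 log2 units is returned.
#'
#' @param x an `expr_matrix`.
#' @param default fallback cutoff when the density is not bimodal.
#' @return the cutoff (log2 scale), with attribute `source` = "dip" or
#'   "default".
#' @export
detect_low_cutoff <- function(x, default = 4.0) {
  means <- rowMeans(x$values)
  dens <- stats::density(means, bw = "SJ", n = 512)
  y <- dens$y
  # interior local maxima; discard bumps under 5% of the main peak
  peak <- which(diff(sign(diff(y))) == -2) + 1L
  peak <- peak[y[peak] >= 0.05 * max(y)]
  if (length(peak) >= 2) {
    top2 <- sort(peak[order(y[peak], decreasing = TRUE)][1:2])
    between <- seq(top2[1], top2[2])
    dip <- between[which.min(y[between])]
    # a real dip separates the modes clearly
    if (y[dip] < 0.5 * min(y[top2]))
      return(structure(dens$x[dip], source = "dip"))
  }
  message("no bimodality detected; using default cutoff ", default)
  structure(default, source = "default")
}

#' Filter genes below a low-expression cutoff
#'
#' Removes whole genes whose mean intensity across all samples falls strictly
#' below the cutoff (DE statistics need complete per-gene vectors, so
#' filtering is per-gene, not per-value).
#'
#' @param x an `expr_matrix`.
#' @param cutoff log2 intensity limit (finite).
#' @return the filtered `expr_matrix` with attribute `n_removed`.
#' @export
filter_low_expression <- function(x, cutoff) {
  if (!(is.finite(cutoff) || identical(cutoff, -Inf)))
    stop("cutoff must be finite (or -Inf for no filtering)")
  keep <- rowMeans(x$values) >= cutoff
  if (!any(keep)) stop("low-expression filter removed every gene")
  out <- subset_matrix(x, probesets = keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Flag outlier arrays by inter-array correlation
#'
#' Computes each sample's median Pearson correlation to all other samples and
#' flags samples falling strictly below Q1 - 1.5*IQR of those medians (a
#' reproducible stand-in for visual MDS/pseudoimage inspection). At most 20%
#' of samples are ever flagged; with fewer than 4 samples the report is empty.
#'
#' @param x an `expr_matrix`.
#' @return a list of class `qc_report`: `median_correlation` (named vector),
#'   `flagged_outliers`, `threshold`.
#' @export
detect_outlier_arrays <- function(x) {
  n <- ncol(x$values)
  if (n < 4) {
    warning("need at least 4 samples for outlier detection")
    return(structure(list(median_correlation = stats::setNames(numeric(0), character(0)),
                          flagged_outliers = character(0), threshold = NA_real_),
                     class = "qc_report"))
  }
  cc <- stats::cor(x$values)
  diag(cc) <- NA
  med <- apply(cc, 2, stats::median, na.rm = TRUE)
  q <- stats::quantile(med, c(0.25, 0.75), names = FALSE)
  thr <- q[1] - 1.5 * (q[2] - q[1])
  flagged <- names(med)[med < thr]
  cap <- floor(0.2 * n)
  if (length(flagged) > cap)
    flagged <- names(sort(med[flagged]))[seq_len(cap)]
  structure(list(median_correlation = med, flagged_outliers = flagged,
                 threshold = thr), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d flagged (threshold %.4f)\n",
              length(x$median_correlation), length(x$flagged_outliers),
              x$threshold))
  if (length(x$flagged_outliers))
    cat("flagged:", paste(x$flagged_outliers, collapse = ", "), "\n")
  invisible(x)
}
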