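#' Correlation distance between samples
#'
#' Pairwise sample distance defined as 1 - Pearson r over the retained genes:
#' identical profiles sit at distance 0, perfectly anti-correlated ones at 2.
#'
#' @param x an `expr_matrix`.
#' @return symmetric numeric matrix of class `dist_cor` with zero diagonal.
#' @export
correlation_distance <- function(x) {
  v <- x$values
  if (ncol(v) < 2) stop("need at least 2 samples")
  if (nrow(v) < 3) stop("need at least 3 genes")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ", paste(colnames(v)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  structure(d, class = c("dist_cor", "matrix"))
}

# fix reflection: within each dimension the largest-magnitude coordinate is
# made positive, so embeddings are reproducible across platforms
fix_signs <- function(pts) {
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  pts
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds samples in `k` dimensions from a distance matrix via the
#' double-centered Gram eigendecomposition, so that inter-point distances
#' approximate the input distances. Deterministic up to reflection, which is
#' fixed by a sign convention.
#'
#' @param dist a symmetric distance matrix (e.g. [correlation_distance()]).
#' @param k embedding dimension (default 2).
#' @return list of class `embedding`: `points` (samples x k), `eig`
#'   (eigenvalues, non-increasing), `var_explained` (share of the positive
#'   eigenvalue mass carried by the k axes).
#' @export
classical_mds <- function(dist, k = 2) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (k >= n) stop("k must be smaller than the number of samples")
  fit <- stats::cmdscale(stats::as.dist(dist), k = k, eig = TRUE)
  neg <- fit$eig[fit$eig < 0]
  if (length(neg) && min(neg) < -1e-8)
    message("negative eigenvalues truncated (largest magnitude ",
            format(max(abs(neg)), digits = 3), ")")
  pts <- fix_signs(fit$points)
  rownames(pts) <- rownames(dist)
  pos <- sum(fit$eig[fit$eig > 0])
  structure(list(points = pts,
                 eig = sort(fit$eig, decreasing = TRUE),
                 var_explained = if (pos > 0) sum(pmax(fit$eig[seq_len(k)], 0)) / pos
                                 else NA_real_),
            class = "embedding")
}

#' Principal-component scores of samples
#'
#' Gene-centered PCA of the samples (covariance eigendecomposition), with the
#' same reflection convention as [classical_mds()].
#'
#' @param x an `expr_matrix`.
#' @param k number of components.
#' @return an `embedding` (see [classical_mds()]).
#' @export
pca_scores <- function(x, k = 2) {
  n <- ncol(x$values)
  if (k >= n) stop("k must be smaller than the number of samples")
  fit <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE)
  pts <- fix_signs(fit$x[, seq_len(k), drop = FALSE])
  rownames(pts) <- colnames(x$values)
  ev <- fit$sdev^2
  structure(list(points = pts, eig = ev,
                 var_explained = sum(ev[seq_len(k)]) / sum(ev)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d samples in %d dimensions (%.1f%% of variance)\n",
              nrow(x$points), ncol(x$points), 100 * x$var_explained))
  invisible(x)
}
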