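#' Define a two-group contrast
#'
#' Builds the design for a moderated d-statistic comparison: an ordered pair
#' of group labels plus the sample-to-group map. Positive d means increased
#' expression in the first group of `contrast`. Condition labels are combined
#' simply by choosing the annotation column that ignores them: `by =
#' "phenotype"` pools spatial and non-spatial arrays within each cognitive
#' group (e.g. AU-act = AU-S + AU-NS), `by = "group"` keeps the full
#' phenotype-condition label, and `by = "condition"` with `subset` supports
#' within-phenotype comparisons.
#'
#' @param x an annotated `expr_matrix`, or a named character vector mapping
#'   sample_id -> group label.
#' @param contrast character(2): group labels, first minus second.
#' @param by annotation column providing the group label (ignored when `x` is
#'   already a named vector).
#' @param subset optional logical/character selector of samples considered.
#' @return a list of class `sam_design` with `contrast` and `sample_groups`.
#' @export
sam_design <- function(x, contrast, by = "phenotype", subset = NULL) {
  if (length(contrast) != 2 || contrast[1] == contrast[2])
    stop("design error: contrast must be two distinct group labels")
  if (inherits(x, "expr_matrix")) {
    if (is.null(x$samples)) stop("design error: matrix has no sample annotations")
    if (!by %in% names(x$samples)) stop("design error: no annotation column '", by, "'")
    groups <- stats::setNames(as.character(x$samples[[by]]), x$samples$sample_id)
  } else if (is.character(x) && !is.null(names(x))) {
    groups <- x
  } else stop("design error: x must be an annotated expr_matrix or a named vector")
  if (!is.null(subset)) groups <- groups[subset]
  groups <- groups[groups %in% contrast]
  n1 <- sum(groups == contrast[1]); n2 <- sum(groups == contrast[2])
  if (n1 < 2 || n2 < 2)
    stop("design error: each contrast group needs at least 2 samples (got ",
         n1, " and ", n2, ")")
  structure(list(contrast = contrast, sample_groups = groups),
            class = "sam_design")
}

# indices of the two groups inside the columns of `vals`
design_indices <- function(vals, design) {
  ids <- names(design$sample_groups)
  missing <- setdiff(ids, colnames(vals))
  if (length(missing))
    stop("design error: samples absent from matrix: ", paste(missing, collapse = ", "))
  cols <- match(ids, colnames(vals))
  list(idx1 = cols[design$sample_groups == design$contrast[1]],
       idx2 = cols[design$sample_groups == design$contrast[2]])
}

# vectorized core: mean difference, pooled gene scatter and d for one split
d_core <- function(vals, idx1, idx2, s0) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- vals[, idx1, drop = FALSE]; x2 <- vals[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  r <- m1 - m2
  d <- r / (s + s0)
  if (s0 == 0 && any(s == 0)) {
    warning("zero within-group variance with s0 = 0: infinite d reported")
    d[s == 0] <- sign(r[s == 0]) * Inf
  }
  list(r = r, s = s, d = d)
}

#' Per-gene moderated d-statistics
#'
#' For each gene, `d = r / (s + s0)` where `r` is the difference of group
#' means (group1 - group2, log2 scale) and `s` is the pooled two-sample
#' standard error of `r`. The additive constant `s0` (the "fudge factor")
#' damps the statistic of low-variance genes; with `s0 = 0`, `d` is exactly
#' the classical pooled two-sample t-statistic.
#'
#' @param x an `expr_matrix` (already low-expression filtered).
#' @param design a [sam_design()].
#' @param s0 non-negative additive constant in the denominator.
#' @return data.frame: probeset_id, r, s, d.
#' @export
compute_d <- function(x, design, s0 = 0) {
  ix <- design_indices(x$values, design)
  core <- d_core(x$values, ix$idx1, ix$idx2, s0)
  data.frame(probeset_id = rownames(x$values), r = core$r, s = core$s,
             d = core$d, row.names = NULL, stringsAsFactors = FALSE)
}

#' Choose the fudge factor s0
#'
#' Grid search over candidate s0 values (percentiles of the gene scatter s).
#' For each candidate, genes are partitioned into quantile windows of s and
#' the median absolute deviation of d is computed per window; the candidate
#' minimizing the coefficient of variation of those MADs is chosen, so that
#' the spread of d is decoupled from gene-wise variance (the device that
#' keeps low-variance genes from dominating the significant list). Ties go to
#' the smaller s0.
#'
#' @param r,s per-gene mean differences and scatters (from [compute_d()]).
#' @param candidate_percentiles percentiles of `s` to try, in \[0, 100\].
#' @param n_windows number of quantile windows of s.
#' @return the selected s0, with attributes `percentile` and `cv_table`.
#' @export
choose_s0 <- function(r, s, candidate_percentiles = seq(0, 100, by = 5),
                      n_windows = 100) {
  stopifnot(length(r) == length(s))
  n <- length(s)
  if (stats::sd(s) == 0) {
    warning("degenerate gene scatter (all equal): s0 = 0")
    return(structure(0, percentile = 0, cv_table = NULL))
  }
  cand <- stats::quantile(s, candidate_percentiles / 100, names = FALSE)
  nw <- max(2L, min(as.integer(n_windows), floor(n / 5)))
  win <- ceiling(rank(s, ties.method = "first") * nw / n)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    mads <- tapply(d, win, stats::mad)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  best <- which(cv == min(cv))[1]  # ties -> smaller s0 (grid is ascending)
  structure(cand[best], percentile = candidate_percentiles[best],
            cv_table = data.frame(percentile = candidate_percentiles,
                                  s0 = cand, cv = cv))
}

#' Permutation null for the d-statistic
#'
#' Recomputes d under permuted group labels. All distinct assignments of
#' samples to group1 are enumerated when their number fits within `B`
#' (`method = "auto"`); otherwise `B` distinct assignments are sampled.
#' `method = "sample"` forces plain Monte-Carlo draws with replacement,
#' `method = "enumerate"` forces full enumeration. Expected order statistics
#' `dbar[i]` are the across-permutation means of the i-th smallest permuted d.
#'
#' @param x an `expr_matrix`.
#' @param design a [sam_design()].
#' @param B number of permutations (>= 1).
#' @param seed RNG seed; identical seeds give identical nulls.
#' @param s0 fudge factor (fixed at the observed-data value).
#' @param method assignment strategy, see above.
#' @return list of class `sam_null`: `d_sorted` (genes x B matrix, each column
#'   sorted ascending), `dbar`, `B`, `method`.
#' @export
permute_null <- function(x, design, B = 1000, seed = 1, s0 = 0,
                         method = c("auto", "enumerate", "sample")) {
  method <- match.arg(method)
  if (B < 1) stop("B must be at least 1")
  ix <- design_indices(x$values, design)
  all_idx <- c(ix$idx1, ix$idx2)
  n <- length(all_idx); n1 <- length(ix$idx1)
  total <- choose(n, n1)

  set.seed(seed)
  if (method == "enumerate" || (method == "auto" && total <= B)) {
    assign1 <- utils::combn(n, n1, simplify = FALSE)
  } else if (method == "sample") {
    assign1 <- replicate(B, sort(sample.int(n, n1)), simplify = FALSE)
  } else {
    seen <- new.env(hash = TRUE)
    assign1 <- vector("list", B); k <- 0L
    while (k < B) {
      a <- sort(sample.int(n, n1))
      key <- paste(a, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE; k <- k + 1L; assign1[[k]] <- a
      }
    }
  }
  d_sorted <- vapply(assign1, function(a) {
    sort(d_core(x$values, all_idx[a], all_idx[-a], s0)$d)
  }, numeric(nrow(x$values)))
  structure(list(d_sorted = d_sorted, dbar = rowMeans(d_sorted),
                 B = length(assign1), method = method), class = "sam_null")
}

#' Delta table: symmetric-offset cutoffs and estimated FDR
#'
#' For each offset delta, genes are called increased where the i-th observed
#' order statistic exceeds its permutation expectation by more than delta
#' (the up cutoff is the smallest such d) and decreased symmetrically (the
#' low cutoff is the largest such d). The estimated FDR at each delta is the
#' median, over permutations, of the number of permuted d-values falling
#' beyond the cutoffs, divided by the number of genes called, optionally
#' scaled by pi0 and capped at 1. The `fdr` column is monotonized to be
#' non-increasing in delta (raw medians kept as `fdr_raw`).
#'
#' @param d_obs observed per-gene d (order follows the input matrix).
#' @param null a `sam_null` from [permute_null()].
#' @param deltas offsets to tabulate; default: quantile grid of the absolute
#'   deviations between observed and expected order statistics.
#' @param pi0 multiplier for the estimated proportion of true nulls.
#' @return data.frame: delta, cut_low, cut_up, n_called, n_false_median,
#'   fdr_raw, fdr.
#' @export
estimate_fdr_table <- function(d_obs, null, deltas = NULL, pi0 = 1) {
  ord <- order(d_obs)            # stable: ties keep probeset order
  d_sorted <- d_obs[ord]
  dbar <- null$dbar
  if (length(dbar) != length(d_obs))
    stop("null and observed statistics differ in length")
  dev <- d_sorted - dbar
  if (is.null(deltas)) {
    # quantile grid over the bulk plus single-step resolution in the tail,
    # where each delta increment changes the call list by a few genes
    a <- abs(dev)
    bulk <- stats::quantile(a, seq(0, 1, length.out = 101), names = FALSE)
    tail_vals <- sort(a, decreasing = TRUE)[seq_len(min(500L, length(a)))]
    deltas <- sort(unique(c(0, bulk, tail_vals)))
  }
  n <- length(d_obs)
  # cutoff searches are restricted to their own tails (positive d for the up
  # cutoff, negative for the down cutoff); otherwise permutation expectations
  # exceeding the observed extremes would drag a cutoff across the origin and
  # call most of the distribution
  cut_up <- vapply(deltas, function(delta) {
    up <- dev > delta & d_sorted > 0
    if (any(up)) min(d_sorted[up]) else Inf
  }, numeric(1))
  cut_low <- vapply(deltas, function(delta) {
    lo <- -dev > delta & d_sorted < 0
    if (any(lo)) max(d_sorted[lo]) else -Inf
  }, numeric(1))
  # call counts: genes at or beyond the cutoffs, via the sorted observed d
  n_up <- n - findInterval(cut_up, d_sorted, left.open = TRUE)
  n_lo <- findInterval(cut_low, d_sorted)
  n_called <- n_up + n_lo
  # per-permutation counts of null d beyond the cutoffs (columns are sorted,
  # so each is two binary searches vectorized over the delta grid)
  counts <- vapply(seq_len(ncol(null$d_sorted)), function(j) {
    col <- null$d_sorted[, j]
    (n - findInterval(cut_up, col, left.open = TRUE)) + findInterval(cut_low, col)
  }, numeric(length(deltas)))
  if (length(deltas) == 1L) counts <- matrix(counts, nrow = 1L)
  n_false <- apply(counts, 1, stats::median)
  fdr_raw <- ifelse(n_called > 0, pmin(1, pi0 * n_false / n_called), NA_real_)
  tab <- data.frame(delta = deltas, cut_low = cut_low, cut_up = cut_up,
                    n_called = as.integer(n_called), n_false_median = n_false,
                    fdr_raw = fdr_raw)
  v <- tab$fdr_raw
  v[is.na(v)] <- -Inf
  v <- rev(cummax(rev(v)))       # enforce non-increasing FDR in delta
  v[v == -Inf] <- NA_real_
  tab$fdr <- v
  tab
}

#' Call significant genes at a target FDR
#'
#' Selects the smallest delta whose (monotonized) estimated FDR is at or
#' below the target, then flags genes beyond that delta's cutoffs with their
#' direction (increased/decreased in the first contrast group).
#'
#' @param delta_table from [estimate_fdr_table()].
#' @param d_obs per-gene observed d, named or accompanied by `probeset_ids`.
#' @param target_fdr the FDR level (e.g. 0.05 or 0.1).
#' @param probeset_ids gene identifiers matching `d_obs`.
#' @return list of class `sam_calls`: `target_fdr`, `delta`, `cut_low`,
#'   `cut_up`, `fdr`, `n_called`, and `calls` (data.frame probeset_id, d,
#'   direction).
#' @export
call_significant <- function(delta_table, d_obs, target_fdr,
                             probeset_ids = names(d_obs)) {
  if (!nrow(delta_table)) stop("empty delta table")
  if (is.null(probeset_ids)) probeset_ids <- as.character(seq_along(d_obs))
  ok <- which(!is.na(delta_table$fdr) & delta_table$fdr <= target_fdr)
  if (!length(ok)) {
    message("no delta meets target FDR ", target_fdr, ": zero calls")
    return(structure(list(target_fdr = target_fdr, delta = NA_real_,
                          cut_low = -Inf, cut_up = Inf, fdr = NA_real_,
                          n_called = 0L,
                          calls = data.frame(probeset_id = character(0),
                                             d = numeric(0),
                                             direction = character(0))),
                     class = "sam_calls"))
  }
  row <- delta_table[ok[1], ]
  up <- d_obs >= row$cut_up
  lo <- d_obs <= row$cut_low
  calls <- data.frame(probeset_id = probeset_ids[up | lo],
                      d = d_obs[up | lo],
                      direction = ifelse(d_obs[up | lo] >= row$cut_up,
                                         "increased", "decreased"),
                      stringsAsFactors = FALSE)
  structure(list(target_fdr = target_fdr, delta = row$delta,
                 cut_low = row$cut_low, cut_up = row$cut_up, fdr = row$fdr,
                 n_called = nrow(calls), calls = calls),
            class = "sam_calls")
}

#' @export
print.sam_calls <- function(x, ...) {
  cat(sprintf("sam_calls: %d genes at target FDR %.3g (delta %.4g, est. FDR %.3g)\n",
              x$n_called, x$target_fdr, x$delta, x$fdr))
  if (x$n_called) {
    tb <- table(x$calls$direction)
    cat(paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full SAM-style analysis of one contrast
#'
#' Runs the whole moderated-d workflow: gene scatters, s0 selection,
#' observed d, permutation null with expected order statistics, delta table,
#' and significance calls at the requested FDR levels.
#'
#' @param x a filtered `expr_matrix`.
#' @param design a [sam_design()].
#' @param fdr numeric vector of target FDR levels.
#' @param B number of permutations.
#' @param seed RNG seed for the permutation null.
#' @param s0 either "auto" (choose via [choose_s0()]) or a number.
#' @param pi0 true-null proportion multiplier for FDR estimates.
#' @return list of class `sam_result`: per-gene table (`genes`: probeset_id,
#'   r, s, d), `s0`, `B`, `dbar`, `delta_table`, `calls` (one `sam_calls` per
#'   FDR level, named by level), `design`.
#' @export
sam <- function(x, design, fdr = c(0.05, 0.1), B = 1000, seed = 1,
                s0 = "auto", pi0 = 1) {
  base <- compute_d(x, design, s0 = 0)
  if (identical(s0, "auto")) s0 <- as.numeric(choose_s0(base$r, base$s))
  genes <- compute_d(x, design, s0 = s0)
  null <- permute_null(x, design, B = B, seed = seed, s0 = s0)
  tab <- estimate_fdr_table(genes$d, null, pi0 = pi0)
  calls <- lapply(fdr, function(f)
    call_significant(tab, genes$d, f, probeset_ids = genes$probeset_id))
  names(calls) <- as.character(fdr)
  structure(list(genes = genes, s0 = s0, B = null$B, dbar = null$dbar,
                 delta_table = tab, calls = calls, design = design),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("sam_result: %d genes, contrast %s vs %s, s0 = %.4g, B = %d\n",
              nrow(x$genes), x$design$contrast[1], x$design$contrast[2],
              x$s0, x$B))
  for (f in names(x$calls))
    cat(sprintf("  FDR %s: %d called\n", f, x$calls[[f]]$n_called))
  invisible(x)
}

#' Density summary of observed vs expected d (the density-plot device)
#'
#' Kernel densities of the observed d-statistics and of the pooled permuted
#' null d, evaluated on a common grid, for the classic observed-vs-expected
#' density figure with FDR-shaded tails.
#'
#' @param result a `sam_result`.
#' @param n_grid grid size.
#' @return data.frame: d, observed, expected (both densities integrate to 1).
#' @export
d_density_summary <- function(result, n_grid = 512) {
  d <- result$genes$d
  expected <- result$dbar
  rng <- range(c(d, expected))
  pad <- 0.1 * diff(rng)
  from <- rng[1] - pad; to <- rng[2] + pad
  obs <- stats::density(d, from = from, to = to, n = n_grid)
  exp_ <- stats::density(expected, from = from, to = to, n = n_grid)
  data.frame(d = obs$x, observed = obs$y, expected = exp_$y)
}
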