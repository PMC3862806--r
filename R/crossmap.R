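#' Pair two d-statistic results by probeset identifier
#'
#' Inner join of two per-gene tables on probeset ID (identifiers, not gene
#' annotations, are the join key, so platform subsets pair at the smaller
#' set's size). Order follows the first result; unmatched IDs are counted.
#'
#' @param a,b `sam_result` objects or data.frames with `probeset_id` and `d`.
#' @return data.frame of class `paired_d`: probeset_id, d_a, d_b; attributes
#'   `n_unmatched_a`, `n_unmatched_b`.
#' @export
align_by_id <- function(a, b) {
  ga <- if (inherits(a, "sam_result")) a$genes else a
  gb <- if (inherits(b, "sam_result")) b$genes else b
  common <- intersect(ga$probeset_id, gb$probeset_id)
  if (!length(common)) stop("no probeset IDs in common")
  n_a <- length(unique(ga$probeset_id)); n_b <- length(unique(gb$probeset_id))
  ga <- ga[ga$probeset_id %in% common, ]
  out <- data.frame(probeset_id = ga$probeset_id, d_a = ga$d,
                    d_b = gb$d[match(ga$probeset_id, gb$probeset_id)],
                    stringsAsFactors = FALSE)
  attr(out, "n_unmatched_a") <- n_a - length(common)
  attr(out, "n_unmatched_b") <- n_b - length(common)
  class(out) <- c("paired_d", "data.frame")
  out
}

#' Cross-dataset d-statistic concordance
#'
#' Pearson correlation between the paired d-statistics of two comparisons
#' (e.g. the same phenotype contrast computed in two induction conditions or
#' two experiments). A positive r indicates similar direction and magnitude
#' of group differences across datasets.
#'
#' @param paired a `paired_d` from [align_by_id()].
#' @return list of class `concordance`: `n_paired`, `r`, `p_value` (floored
#'   at 1e-300), `p_label` (e.g. "<1e-300" below the floor).
#' @export
dstat_concordance <- function(paired) {
  if (nrow(paired) < 10) stop("need at least 10 paired probesets")
  if (stats::sd(paired$d_a) == 0 || stats::sd(paired$d_b) == 0)
    stop("zero variance in a d-statistic vector")
  ct <- stats::cor.test(paired$d_a, paired$d_b, method = "pearson")
  p <- ct$p.value
  floored <- p < 1e-300
  structure(list(n_paired = nrow(paired), r = unname(ct$estimate),
                 p_value = max(p, 1e-300),
                 p_label = if (floored) "<1e-300" else format(p, digits = 3)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance: r = %.3f over %d paired probesets (p %s)\n",
              x$r, x$n_paired, if (startsWith(x$p_label, "<")) x$p_label
                               else paste("=", x$p_label)))
  invisible(x)
}

#' Gene-set distribution-shift test
#'
#' Tests whether the d-statistics of a named gene set are shifted relative to
#' the background of all tested genes — the device behind density plots of a
#' set's d distribution against all genes. Default is the two-sided Wilcoxon
#' rank-sum of set members versus non-members (rank-based, robust to the
#' d-statistic's heavy tails); alternatives are the two-sample
#' Kolmogorov-Smirnov test and a permutation null built from random sets of
#' the same size. Direction is the sign of (median d of set - median d of
#' background).
#'
#' @param result a `sam_result`, or a data.frame with probeset_id and d.
#' @param set character vector of probeset IDs (one GMT entry).
#' @param method "ranksum" (default), "ks" or "perm".
#' @param background "exclude" (default: set members are removed from the
#'   background) or "include".
#' @param n_perm permutation draws for `method = "perm"`.
#' @param seed RNG seed for the permutation method.
#' @param set_name label carried into the result.
#' @return list of class `shift_result`: `set_name`, `n_set`, `direction`,
#'   `statistic`, `p_value`, `median_set`, `median_background`, `method`.
#' @export
geneset_shift_test <- function(result, set, method = c("ranksum", "ks", "perm"),
                               background = c("exclude", "include"),
                               n_perm = 10000, seed = 1, set_name = "set") {
  method <- match.arg(method)
  background <- match.arg(background)
  genes <- if (inherits(result, "sam_result")) result$genes else result
  in_set <- genes$probeset_id %in% set
  n_set <- sum(in_set)
  if (n_set < 5) stop("fewer than 5 set members present in the background")
  d_set <- genes$d[in_set]
  if (all(in_set)) {
    # degenerate: the set is the whole background
    if (method == "perm") {
      med <- stats::median(d_set)
      return(structure(list(set_name = set_name, n_set = n_set,
                            direction = "increased", statistic = 0, p_value = 1,
                            median_set = med, median_background = med,
                            method = method), class = "shift_result"))
    }
    stop("set covers the entire background; no complement to compare against")
  }
  d_bg <- if (background == "exclude") genes$d[!in_set] else genes$d
  med_set <- stats::median(d_set)
  med_bg <- stats::median(d_bg)
  direction <- if (med_set >= med_bg) "increased" else "decreased"

  if (method == "ranksum") {
    d_comp <- genes$d[!in_set]
    ht <- stats::wilcox.test(d_set, d_comp, alternative = "two.sided",
                             exact = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (method == "ks") {
    d_comp <- genes$d[!in_set]
    ht <- suppressWarnings(stats::ks.test(d_set, d_comp,
                                          alternative = "two.sided"))
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    set.seed(seed)
    obs <- stats::median(d_set) - stats::median(genes$d[!in_set])
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(genes$d), n_set)
      stats::median(genes$d[idx]) - stats::median(genes$d[-idx])
    }, numeric(1))
    stat <- obs
    p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  }
  structure(list(set_name = set_name, n_set = n_set, direction = direction,
                 statistic = stat, p_value = max(p, 1e-300),
                 median_set = med_set, median_background = med_bg,
                 method = method), class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  p_lab <- if (x$p_value <= 1e-300) "<1e-300" else format(x$p_value, digits = 3)
  cat(sprintf("shift_result [%s]: %s (N=%d) %s, p %s\n", x$method, x$set_name,
              x$n_set, x$direction,
              if (startsWith(p_lab, "<")) p_lab else paste("=", p_lab)))
  invisible(x)
}

#' Density curves of d for gene sets against the all-gene background
#'
#' Kernel densities of the d-statistic evaluated on a common grid for each
#' gene set and for all genes, each integrating to 1 (the data behind
#' set-vs-background density figures).
#'
#' @param result a `sam_result` or per-gene data.frame.
#' @param sets named list of probeset-ID vectors (e.g. from [read_gmt()]).
#' @param n_grid grid size.
#' @return data.frame: d, all_genes, then one density column per set.
#' @export
shift_density_summary <- function(result, sets, n_grid = 512) {
  genes <- if (inherits(result, "sam_result")) result$genes else result
  if (n_grid < 2) stop("empty grid")
  d <- genes$d
  rng <- range(d); pad <- 0.15 * diff(rng)
  from <- rng[1] - pad; to <- rng[2] + pad
  out <- data.frame(d = stats::density(d, from = from, to = to, n = n_grid)$x)
  out$all_genes <- stats::density(d, from = from, to = to, n = n_grid)$y
  for (nm in names(sets)) {
    dm <- d[genes$probeset_id %in% sets[[nm]]]
    if (length(dm) < 2) stop("set '", nm, "' has fewer than 2 members present")
    out[[nm]] <- stats::density(dm, from = from, to = to, n = n_grid)$y
  }
  out
}

#' Overlap of two significant-gene lists
#'
#' Counts and fractions of shared calls plus a hypergeometric enrichment
#' p-value against a shared identifier universe (the "X% of list A was also
#' significant in B" computation).
#'
#' @param calls_a,calls_b character vectors of called probeset IDs (or
#'   `sam_calls` objects).
#' @param universe character vector: all IDs both analyses tested.
#' @return list: `n_a`, `n_b`, `n_overlap`, `frac_a_in_b`, `frac_b_in_a`,
#'   `p_hyper` (upper tail, includes the observed overlap).
#' @export
list_overlap <- function(calls_a, calls_b, universe) {
  if (inherits(calls_a, "sam_calls")) calls_a <- calls_a$calls$probeset_id
  if (inherits(calls_b, "sam_calls")) calls_b <- calls_b$calls$probeset_id
  if (!length(universe)) stop("empty universe")
  a <- intersect(unique(calls_a), universe)
  b <- intersect(unique(calls_b), universe)
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), length(universe) - length(a),
                     length(b), lower.tail = FALSE)
  list(n_a = length(a), n_b = length(b), n_overlap = k,
       frac_a_in_b = if (length(a)) k / length(a) else NA_real_,
       frac_b_in_a = if (length(b)) k / length(b) else NA_real_,
       p_hyper = p)
}
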