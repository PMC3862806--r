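#' Read / write gene sets in GMT format
#'
#' GMT: one set per line — name, description, then tab-separated member IDs.
#' Reading is delegated to fgsea.
#'
#' @param path file path.
#' @return named list of character vectors of probeset IDs.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be named")
  fgsea::writeGmtPathways(sets, path)
  invisible(path)
}

#' Over-representation analysis with Bonferroni correction
#'
#' For each functional group, tests whether the query list contains more group
#' members than expected by chance from the universe, using the upper-tail
#' hypergeometric probability (including the observed overlap). The universe
#' should be the set of probesets actually tested (those surviving the
#' low-expression filter), not the whole platform. Bonferroni correction is
#' over the groups with non-zero universe overlap; groups are flagged at
#' corrected p < 0.05.
#'
#' @param query character vector of called probeset IDs (must lie within the
#'   universe).
#' @param groups named list of probeset-ID vectors (functional groups).
#' @param universe character vector: all tested probeset IDs.
#' @return data.frame of class `enrichment_result`, sorted by corrected p:
#'   group, k (overlap), m (group size in universe), n (query size),
#'   universe_size, p_hyper, p_bonferroni, significant.
#' @export
ora_test <- function(query, groups, universe) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query)) stop("empty query")
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe))
    stop("query contains IDs outside the universe")
  sizes <- vapply(groups, function(g) length(intersect(g, universe)), integer(1))
  tested <- names(groups)[sizes > 0]
  n_tests <- length(tested)
  if (!n_tests) stop("no group overlaps the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(tested, function(nm) {
    members <- intersect(groups[[nm]], universe)
    m <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(group = nm, k = k, m = m, n = n, universe_size = N,
               p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_hyper * n_tests)
  out$significant <- out$p_bonferroni < 0.05
  out <- out[order(out$p_bonferroni, out$p_hyper, out$group), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Split significance calls by direction
#'
#' Partitions a call set into increased and decreased queries so each can be
#' tested for over-representation separately.
#'
#' @param calls a `sam_calls` object or a data.frame with `probeset_id` and
#'   `direction`.
#' @return list with character vectors `increased` and `decreased`.
#' @export
split_by_direction <- function(calls) {
  df <- if (inherits(calls, "sam_calls")) calls$calls else calls
  list(increased = df$probeset_id[df$direction == "increased"],
       decreased = df$probeset_id[df$direction == "decreased"])
}
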