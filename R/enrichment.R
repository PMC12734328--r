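#' Read a GMT annotation map
#'
#' Standard GMT: one term per line, tab-separated
#' \code{term<TAB>description<TAB>gene1<TAB>gene2...}. Term gene sets are
#' intersected with the supplied universe (the analyzed gene space, e.g.
#' the genes surviving the zero-count filter).
#'
#' @param file GMT path.
#' @param universe character vector of analyzed genes.
#' @return an \code{annotation_map}: list with \code{sets} (named list of
#'   gene vectors), \code{descriptions}, \code{universe}.
#' @export
read_annotation_map <- function(file, universe) {
  sets <- fgsea::gmtPathways(file)
  # gmtPathways drops the description column; recover it
  fields <- strsplit(readLines(file), "\t", fixed = TRUE)
  desc <- stats::setNames(vapply(fields, function(f)
    if (length(f) >= 2) f[2] else "", ""),
    vapply(fields, `[[`, "", 1L))
  annotation_map(sets, universe, desc[names(sets)])
}

#' Build an annotation map from a named list of gene sets
#'
#' @param sets named list of character vectors (term -> genes).
#' @param universe analyzed gene universe; term sets are clipped to it and
#'   emptied terms dropped.
#' @param descriptions optional named character vector of term descriptions.
#' @return an \code{annotation_map} list.
#' @export
annotation_map <- function(sets, universe, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            !anyDuplicated(names(sets)))
  universe <- unique(universe)
  sets <- lapply(sets, function(g) intersect(unique(g), universe))
  sets <- sets[lengths(sets) > 0]
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions[names(sets)]),
            class = "annotation_map")
}

#' Hypergeometric upper-tail probability
#'
#' p = P(X >= k) for X ~ hypergeometric(N, K, n): the chance of drawing at
#' least \code{k} annotated genes when \code{n} genes are sampled without
#' replacement from a universe of \code{N} genes of which \code{K} carry
#' the annotation. Inclusive tail: k = 0 gives p = 1.
#'
#' @param k observed overlap.
#' @param n query size.
#' @param K term size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(k < 0) || any(k > pmin(n, K)) || any(pmax(n, K) > N))
    stop("inconsistent sizes: need 0 <= k <= min(n, K) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation test of a query gene set against an annotation map
#'
#' One hypergeometric upper-tail test per term; Benjamini-Hochberg
#' adjustment across all terms of the map; rows with zero overlap are
#' dropped from the report. Query genes outside the universe are discarded
#' and counted in the \code{n_dropped} attribute.
#'
#' @param query character vector of genes.
#' @param ann an [annotation_map()].
#' @return data frame sorted by p: \code{term}, \code{description},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{p}, \code{q},
#'   \code{genes} (comma-separated overlap).
#' @export
enrich <- function(query, ann) {
  stopifnot(inherits(ann, "annotation_map"))
  query <- unique(query)
  dropped <- setdiff(query, ann$universe)
  query <- intersect(query, ann$universe)
  if (length(query) == 0 || length(ann$sets) == 0) {
    if (length(ann$sets) == 0) warning("annotation map has no terms")
    else warning("empty query after universe restriction")
    res <- data.frame(term = character(), description = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      genes = character())
    attr(res, "n_dropped") <- length(dropped)
    return(res)
  }
  N <- length(ann$universe)
  n <- length(query)
  terms <- names(ann$sets)
  k <- vapply(ann$sets, function(g) length(intersect(query, g)), 0L)
  K <- lengths(ann$sets)
  p <- hypergeom_test(k, n, K, N)
  q <- stats::p.adjust(p, method = "BH")
  genes <- vapply(ann$sets, function(g)
    paste(sort(intersect(query, g)), collapse = ","), "")
  res <- data.frame(term = terms,
                    description = unname(ann$descriptions[terms]),
                    k = k, n = n, K = K, N = N, p = p, q = q,
                    genes = genes, row.names = NULL)
  res <- res[res$k >= 1, , drop = FALSE]
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- length(dropped)
  res
}
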