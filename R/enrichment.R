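# Over-representation analysis: hypergeometric upper-tail test, rich
# factor, Benjamini-Hochberg correction and multi-set shared/unique
# comparison of enriched-term sets.

#' Hypergeometric term over-representation
#'
#' For each term with at least one study hit, tests whether the study set
#' contains more of the term's genes than expected under random sampling
#' from the background: `p = P[X >= k]` with
#' `X ~ Hypergeometric(N, n, m)` (background size N, term size n, study
#' size m, hits k). Benjamini-Hochberg q-values are computed across the
#' tested terms (terms with k = 0 are not tested and do not enter the BH
#' denominator). Background defaults to all annotated genes.
#'
#' @param study character vector of study gene ids (must be a subset of the
#'   background).
#' @param assignments data.frame with `gene_id`, `term_id` and optionally
#'   `term_name`, `namespace`.
#' @param background character vector of background gene ids; default all
#'   genes in `assignments`.
#' @param qMax significance threshold on q (default 0.05).
#' @return data.frame sorted by q then p: `term_id`, `term_name`,
#'   `namespace`, `k`, `n`, `m`, `N`, `p`, `q`, `rich_factor`,
#'   `significant`.
#' @export
hypergeomEnrich <- function(study, assignments, background = NULL,
                            qMax = 0.05) {
  stopifnot(all(c("gene_id", "term_id") %in% names(assignments)))
  if (is.null(background)) background <- unique(assignments$gene_id)
  background <- unique(as.character(background))
  study <- unique(as.character(study))
  offenders <- setdiff(study, background)
  if (length(offenders)) {
    stop("study gene(s) absent from background: ",
         paste(utils::head(offenders, 10), collapse = ", "), call. = FALSE)
  }
  ann <- assignments[assignments$gene_id %in% background, , drop = FALSE]
  ann <- ann[!duplicated(ann[c("gene_id", "term_id")]), , drop = FALSE]
  N <- length(background)
  m <- length(study)
  termGenes <- split(ann$gene_id, ann$term_id)
  k <- vapply(termGenes, function(g) sum(g %in% study), 0L)
  n <- lengths(termGenes)
  tested <- k >= 1L
  if (!any(tested)) {
    return(emptyEnrichFrame())
  }
  k <- k[tested]; n <- n[tested]; terms <- names(termGenes)[tested]
  p <- stats::phyper(k - 1L, n, N - n, m, lower.tail = FALSE)
  q <- bhAdjust(p)
  meta <- ann[!duplicated(ann$term_id), , drop = FALSE]
  nameOf <- if ("term_name" %in% names(meta)) {
    stats::setNames(meta$term_name, meta$term_id)
  } else stats::setNames(rep(NA_character_, nrow(meta)), meta$term_id)
  nsOf <- if ("namespace" %in% names(meta)) {
    stats::setNames(meta$namespace, meta$term_id)
  } else stats::setNames(rep(NA_character_, nrow(meta)), meta$term_id)
  out <- data.frame(
    term_id = terms,
    term_name = unname(nameOf[terms]),
    namespace = unname(nsOf[terms]),
    k = as.integer(k), n = as.integer(n), m = m, N = N,
    p = p, q = q,
    rich_factor = richFactor(k, n),
    significant = q <= qMax,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyEnrichFrame <- function() {
  data.frame(term_id = character(), term_name = character(),
             namespace = character(), k = integer(), n = integer(),
             m = integer(), N = integer(), p = numeric(), q = numeric(),
             rich_factor = numeric(), significant = logical())
}

#' Rich factor
#'
#' Ratio of study genes annotated to a term to all genes annotated to that
#' term — an effect-size companion to the enrichment p-value.
#'
#' @param k study genes in the term (0 <= k <= n).
#' @param n all genes in the term (>= 1).
#' @return `k / n`.
#' @examples
#' richFactor(3, 4) # 0.75
#' @export
richFactor <- function(k, n) {
  if (any(n < 1)) stop("term size n must be >= 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n", call. = FALSE)
  k / n
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control with monotonicity enforcement, preserving input
#' order (delegates to [stats::p.adjust()] after validation).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Shared/unique partition of named term sets
#'
#' Venn-style comparison: every term in the union is assigned to exactly
#' one region keyed by the subset of set names that contain it.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list with `regions` (named list of term vectors, keys like
#'   "A&B") and `sizes` (named integer vector).
#' @export
setComparison <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  keyOf <- vapply(universe, function(tm) {
    paste(names(sets)[vapply(sets, function(s) tm %in% s, TRUE)],
          collapse = "&")
  }, "")
  regions <- split(universe, keyOf)
  list(regions = regions, sizes = lengths(regions))
}
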