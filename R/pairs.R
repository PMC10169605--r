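# Canonical pair identifier: the lexicographically smaller gene id is A.
# Returns ids "A|B"; inputs may be in either orientation.
canonical_pair_id <- function(gene_a, gene_b) {
  swap <- gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  paste(a, b, sep = "|")
}

split_pair_ids <- function(pair_ids) {
  parts <- strsplit(pair_ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed pair id(s): ", paste(pair_ids[bad], collapse = ", "),
         call. = FALSE)
  list(a = vapply(parts, `[[`, "", 1L), b = vapply(parts, `[[`, "", 2L))
}

#' Build the binary pair-indicator matrix
#'
#' For every unordered pair of candidate genes, one row `"A|B"` in canonical
#' orientation (lexicographically smaller gene first): the indicator is 1 when
#' `expr[A, s] > expr[B, s]` and 0 otherwise — ties score 0. With m candidate
#' genes the matrix has choose(m, 2) rows. Because only the within-sample
#' ordering of the two genes matters, the indicators are invariant under any
#' strictly increasing per-sample transform of expression.
#'
#' @param expr an [expression_matrix()] (any scale) restricted, via
#'   `candidates`, to the candidate genes.
#' @param candidates character vector of >= 2 gene ids; default all genes of
#'   `expr`.
#' @return matrix of 0/1 values, pair ids as rownames, class `pair_matrix`
#'   with attribute `source_gene_ids`.
#' @export
build_pair_matrix <- function(expr, candidates = rownames(expr)) {
  missing <- setdiff(candidates, rownames(expr))
  if (length(missing))
    stop("candidate gene(s) missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- length(candidates)
  if (m < 2) stop("need >= 2 candidate genes to form pairs", call. = FALSE)
  candidates <- sort(candidates)           # canonical orientation by sort
  x <- unclass(expr)[candidates, , drop = FALSE]
  idx <- utils::combn(m, 2)
  out <- (x[idx[1L, ], , drop = FALSE] >
          x[idx[2L, ], , drop = FALSE]) * 1L
  rownames(out) <- paste(candidates[idx[1L, ]], candidates[idx[2L, ]],
                         sep = "|")
  structure(out, source_gene_ids = candidates,
            class = c("pair_matrix", class(out)))
}

#' Prevalence (validity) filter for pair indicators
#'
#' A pair that is almost always 0 or almost always 1 carries no information;
#' the filter keeps pairs whose minority indicator frequency exceeds
#' `min_minor_frac`, i.e. `min_minor_frac < mean(indicator) <
#' 1 - min_minor_frac`, strictly at both boundaries. Row order is preserved.
#'
#' @param pairs a `pair_matrix` from [build_pair_matrix()].
#' @param min_minor_frac in (0, 0.5); default 0.2 — the ">20%" validity rule.
#' @return the filtered `pair_matrix` (possibly zero rows).
#' @export
filter_pairs_by_prevalence <- function(pairs, min_minor_frac = 0.2) {
  stopifnot(min_minor_frac > 0, min_minor_frac < 0.5)
  if (nrow(pairs) == 0) return(pairs)
  prev <- rowMeans(pairs)
  keep <- prev > min_minor_frac & prev < 1 - min_minor_frac
  out <- unclass(pairs)[keep, , drop = FALSE]
  structure(out, source_gene_ids = attr(pairs, "source_gene_ids"),
            class = c("pair_matrix", class(out)))
}

#' Compute fixed-pair indicators on a new cohort
#'
#' Applies the A-greater-than-B rule for a fixed list of pair ids on another
#' expression matrix (e.g. a validation cohort, where the model's pairs are
#' re-derived from that cohort's own expression). No prevalence filter is
#' applied: model pairs are fixed. Pair ids are honored verbatim — the genes
#' are taken in the order written, which is what lets a published signature
#' keep its original (possibly non-canonical) orientation.
#'
#' @param pair_ids character vector of `"A|B"` ids.
#' @param expr an [expression_matrix()] containing every gene of every pair.
#' @return 0/1 matrix, one row per requested pair, in the requested order.
#' @export
score_pairs_on_cohort <- function(pair_ids, expr) {
  g <- split_pair_ids(pair_ids)
  absent <- setdiff(unique(c(g$a, g$b)), rownames(expr))
  if (length(absent))
    stop("gene(s) absent from cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  x <- unclass(expr)
  out <- (x[g$a, , drop = FALSE] > x[g$b, , drop = FALSE]) * 1L
  rownames(out) <- pair_ids
  structure(out, source_gene_ids = sort(unique(c(g$a, g$b))),
            class = c("pair_matrix", class(out)))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples (from %d genes)\n",
              nrow(x), ncol(x), length(attr(x, "source_gene_ids"))))
  invisible(x)
}

#' @export
`[.pair_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, source_gene_ids = attr(x, "source_gene_ids"),
                     class = class(x))
  out
}
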