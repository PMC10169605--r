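#' Construct an expression matrix
#'
#' A thin wrapper around a numeric gene-by-sample matrix that carries a
#' `scale_tag` recording where the values sit on the normalization ladder:
#' `"counts"` (raw, nonnegative integers or expected counts), `"normalized"`
#' (positive linear-scale values) or `"log_normalized"` (log2 scale; the only
#' scale on which differential expression and pairing operate in the
#' pipeline). Guards against the classic double-log mistake: the tag is set
#' once and checked by every consumer.
#'
#' @param values numeric matrix, genes as rows, samples as columns; rownames
#'   and colnames are required and must be unique.
#' @param scale_tag one of `"counts"`, `"normalized"`, `"log_normalized"`.
#' @return the matrix with class `expr_matrix` and attribute `scale_tag`.
#' @export
expression_matrix <- function(values,
                              scale_tag = c("counts", "normalized",
                                            "log_normalized")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (anyNA(values)) stop("expression values contain NA", call. = FALSE)
  if (scale_tag != "log_normalized" && any(values < 0))
    stop("negative values are not allowed on scale '", scale_tag, "'",
         call. = FALSE)
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", class(values)))
}

expr_scale <- function(x) attr(x, "scale_tag") %||% "normalized"

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

# subsetting keeps the class and scale tag (drop is forced off for matrices)
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale_tag = attr(x, "scale_tag"), class = class(x))
  out
}

# Put an arbitrary expression matrix on the log2 scale the downstream stages
# expect. counts -> log-CPM; normalized -> log2(x + pseudocount).
as_log_expression <- function(expr, pseudocount = 1) {
  switch(expr_scale(expr),
    counts = normalize_log_cpm(expr, pseudocount = pseudocount),
    normalized = expression_matrix(log2(unclass(expr) + pseudocount),
                                   scale_tag = "log_normalized"),
    log_normalized = expr)
}
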