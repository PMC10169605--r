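#' Library-size normalization to log2 counts per million
#'
#' `log2(1e6 * count / library_size + pseudocount)` per cell, where the
#' library size is the sample's column sum. Before the log, per-sample CPM
#' sums to exactly 1e6.
#'
#' @param expr an [expression_matrix()] on the `"counts"` scale.
#' @param pseudocount added inside the log; default 1.
#' @return an [expression_matrix()] tagged `"log_normalized"`.
#' @export
normalize_log_cpm <- function(expr, pseudocount = 1) {
  if (expr_scale(expr) != "counts")
    stop("normalize_log_cpm expects scale_tag 'counts', got '",
         expr_scale(expr), "'", call. = FALSE)
  lib <- colSums(expr)
  if (any(lib <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(expr)[lib <= 0], collapse = ", "), call. = FALSE)
  vals <- log2(sweep(unclass(expr), 2, lib, "/") * 1e6 + pseudocount)
  expression_matrix(vals, "log_normalized")
}

# Tie-corrected normal-approximation Wilcoxon rank-sum test on two numeric
# vectors. Returns the standardized statistic z (for group x against y) and a
# two-sided p. Completely tied data (zero rank variance) -> z = 0, p = 1.
ranksum_test <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(stat = 0, p = 1))
  z <- (w - mu) / sqrt(sigma2)
  list(stat = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Differential expression by rank-sum screen
#'
#' Per gene: `logFC = mean(group_a) - mean(group_b)` on the (log2) expression
#' scale and a two-sided Wilcoxon rank-sum p-value (tie-corrected normal
#' approximation). This is a deliberately self-contained, rank-robust screen;
#' it does not reproduce a count-model (edgeR/DESeq2-style) analysis.
#'
#' @param expr log-scale [expression_matrix()] (tag `"log_normalized"`).
#' @param group_a,group_b disjoint character vectors of sample ids, each with
#'   at least 2 samples; logFC is a-minus-b.
#' @param adjust `"none"` (default, raw p) or `"BH"` for
#'   Benjamini-Hochberg-adjusted p-values.
#' @return data.frame with columns `gene_id`, `logFC`, `p_value`.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (expr_scale(expr) != "log_normalized")
    stop("differential_expression expects log-normalized expression",
         call. = FALSE)
  unknown <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(unknown))
    stop("unknown sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap", call. = FALSE)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  xa <- unclass(expr)[, group_a, drop = FALSE]
  xb <- unclass(expr)[, group_b, drop = FALSE]
  logfc <- rowMeans(xa) - rowMeans(xb)
  p <- vapply(seq_len(nrow(expr)),
              function(i) ranksum_test(xa[i, ], xb[i, ])$p, 0.0)
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  data.frame(gene_id = rownames(expr), logFC = logfc, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold a differential-expression table
#'
#' Keeps genes with `|logFC| >= min_abs_logfc` (inclusive) and
#' `p < max_p` (strict), the boundary conventions of the screening rules
#' "|logFC| >= 1.3 and p < 0.0001" / "|logFC| >= 1.0 and p < 0.05".
#'
#' @param records data.frame from [differential_expression()].
#' @param min_abs_logfc,max_p positive thresholds.
#' @return sorted character vector of passing gene ids.
#' @export
apply_thresholds <- function(records, min_abs_logfc, max_p) {
  stopifnot(min_abs_logfc > 0, max_p > 0)
  keep <- abs(records$logFC) >= min_abs_logfc & records$p_value < max_p
  sort(records$gene_id[keep])
}

#' Intersect per-contrast gene sets
#' @param sets list of >= 2 character vectors of gene ids.
#' @return sorted character vector, the common genes.
#' @export
intersect_contrasts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sort(Reduce(intersect, sets))
}

#' Annotate a DE table with pass flags and write it as TSV
#' @param records data.frame from [differential_expression()].
#' @param min_abs_logfc,max_p thresholds, see [apply_thresholds()].
#' @param path output TSV.
#' @export
write_deg_table <- function(records, min_abs_logfc, max_p, path) {
  records$passes <- abs(records$logFC) >= min_abs_logfc &
    records$p_value < max_p
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
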