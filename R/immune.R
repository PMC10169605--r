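#' Single-sample GSEA enrichment score
#'
#' Barbie-style running-sum ssGSEA. Per sample, genes are ordered by
#' expression, descending, ties broken by their (stable) order in the matrix.
#' Walking down that ordering, the in-set cumulative mass uses weights
#' `rank^alpha` (rank = number of genes at or below the position, so the top
#' gene carries rank G), normalized by the total in-set weight; the out-set
#' cumulative mass steps by `1/(G - |set|)`. The score is the sum over all G
#' positions of (in-set mass - out-set mass). It depends only on within-sample
#' ranks, so it is invariant under any strictly monotone per-sample transform.
#'
#' @param expr an [expression_matrix()] (any scale; only ranks are used).
#' @param gene_set character vector; its intersection with the matrix genes
#'   must be non-empty and must not cover all genes.
#' @param alpha rank-weight exponent, >= 0; 0.25 is the conventional default.
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(alpha >= 0)
  genes <- rownames(expr)
  inset <- genes %in% gene_set
  if (!any(inset)) stop("gene set has no genes in the matrix", call. = FALSE)
  if (all(inset))
    stop("gene set covers every gene; out-set is empty", call. = FALSE)
  x <- unclass(expr)
  G <- nrow(x); m <- sum(inset)
  scores <- numeric(ncol(x))
  for (s in seq_len(ncol(x))) {
    ord <- order(-x[, s], seq_len(G))    # descending, stable in gene order
    rnk <- numeric(G)
    rnk[ord] <- G - seq_len(G) + 1       # top gene -> G, bottom -> 1
    w <- rnk^alpha
    # sum over positions of cumulative masses telescopes: a gene entering at
    # position i contributes to positions i..G, i.e. rnk[g] of them
    in_mass <- sum(w[inset] * rnk[inset]) / sum(w[inset])
    out_mass <- sum(rnk[!inset]) / (G - m)
    scores[s] <- in_mass - out_mass
  }
  stats::setNames(scores, colnames(x))
}

#' Score a gene-set collection across all samples
#' @param expr an [expression_matrix()].
#' @param collection named list of gene-id vectors.
#' @param alpha see [ssgsea_score()].
#' @return numeric matrix, sets as rows, samples as columns.
#' @export
score_collection <- function(expr, collection, alpha = 0.25) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  out <- matrix(NA_real_, length(collection), ncol(expr),
                dimnames = list(names(collection), colnames(expr)))
  for (nm in names(collection)) {
    out[nm, ] <- tryCatch(ssgsea_score(expr, collection[[nm]], alpha),
                          error = function(e)
                            stop("set '", nm, "': ", conditionMessage(e),
                                 call. = FALSE))
  }
  out
}

#' Immune and stromal summary scores
#'
#' Per sample, the mean of the named immune-set scores and the mean of the
#' named stromal-set scores. Which sets count as immune vs stromal is
#' configuration: no proprietary signature lists are bundled.
#'
#' @param score_matrix set-by-sample matrix from [score_collection()].
#' @param immune_set_names,stromal_set_names row names of `score_matrix`.
#' @return data.frame with `sample_id`, `immune_score`, `stromal_score`.
#' @export
immune_stromal_scores <- function(score_matrix, immune_set_names,
                                  stromal_set_names) {
  unknown <- setdiff(c(immune_set_names, stromal_set_names),
                     rownames(score_matrix))
  if (length(unknown))
    stop("unknown set name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  data.frame(
    sample_id = colnames(score_matrix),
    immune_score = colMeans(score_matrix[immune_set_names, , drop = FALSE]),
    stromal_score = colMeans(score_matrix[stromal_set_names, , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster samples into high/medium/low immune-infiltration groups
#'
#' Ward hierarchical clustering (`ward.D2`, Euclidean distance) on the
#' standardized (immune_score, stromal_score) pairs, tree cut at `k`; clusters
#' are relabeled by descending mean immune score, so `"high"` always has the
#' largest mean.
#'
#' @param immune_score,stromal_score per-sample numeric vectors (finite).
#' @param k number of groups; default 3 (`high`, `medium`, `low`).
#' @return factor of group labels, levels `high > medium > low` (for k = 3;
#'   otherwise `grp1 ... grpk` by descending mean immune score), named by the
#'   names of `immune_score` when present.
#' @export
cluster_immune_groups <- function(immune_score, stromal_score, k = 3) {
  n <- length(immune_score)
  stopifnot(length(stromal_score) == n)
  if (!all(is.finite(immune_score)) || !all(is.finite(stromal_score)))
    stop("scores must be finite", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  feats <- cbind(immune_score, stromal_score)
  sds <- apply(feats, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate clustering: all samples identical",
                          call. = FALSE)
  feats <- sweep(feats, 2, colMeans(feats), "-")
  feats[, sds > 0] <- sweep(feats[, sds > 0, drop = FALSE], 2,
                            sds[sds > 0], "/")
  hc <- stats::hclust(stats::dist(feats), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  means <- tapply(immune_score, cl, mean)
  ord <- order(means, decreasing = TRUE)       # cluster ids, high first
  labels <- if (k == 3) c("high", "medium", "low")
            else sprintf("grp%d", seq_len(k))
  lab <- labels[match(cl, ord)]
  stats::setNames(factor(lab, levels = labels), names(immune_score))
}
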