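#' Pipeline configuration
#'
#' Either a `simulate` block ([sim_config()]) or input paths (`expression`,
#' `clinical`, `gene_sets`) must be supplied — not neither. Threshold defaults
#' are the published screening rules: tumor contrast |logFC| >= 1.3 with
#' p < 1e-4, the metastasis and immune contrasts |logFC| >= 1.0 with p < 0.05,
#' pair prevalence > 20%, univariate screen alpha 0.05; ROC horizons 1, 3 and
#' 6 years with the cutoff taken from the longest horizon.
#'
#' @param simulate a [sim_config()], or `NULL` when reading files.
#' @param expression,clinical,gene_sets input paths (see [read_expression()],
#'   [read_clinical()], [read_gmt()]); ignored when `simulate` is given.
#' @param expression_scale scale tag of the expression file.
#' @param thresholds named list; any of `tumor_lfc`, `tumor_p`, `other_lfc`,
#'   `other_p`, `prevalence`, `screen_alpha` override the defaults.
#' @param roc_times ROC horizons in the cohort's time units.
#' @param ssgsea_alpha rank-weight exponent for ssGSEA.
#' @param stromal_sets set names treated as stromal for the summary score;
#'   `NULL` = names starting with "Stromal".
#' @param seed governs fold assignment (and simulation when `simulate` lacks
#'   its own seed).
#' @param out_dir directory for intermediate artifacts; `NULL` = in-memory
#'   only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, expression = NULL,
                            clinical = NULL, gene_sets = NULL,
                            expression_scale = "normalized",
                            thresholds = list(), roc_times = c(1, 3, 6),
                            ssgsea_alpha = 0.25, stromal_sets = NULL,
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulate) &&
      (is.null(expression) || is.null(clinical) || is.null(gene_sets)))
    stop("pipeline_config: supply either a simulate block or all of ",
         "expression, clinical and gene_sets paths", call. = FALSE)
  th <- list(tumor_lfc = 1.3, tumor_p = 1e-4, other_lfc = 1.0,
             other_p = 0.05, prevalence = 0.2, screen_alpha = 0.05)
  bad <- setdiff(names(thresholds), names(th))
  if (length(bad))
    stop("unknown threshold(s): ", paste(bad, collapse = ", "), call. = FALSE)
  th[names(thresholds)] <- thresholds
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  structure(list(simulate = simulate, expression = expression,
                 clinical = clinical, gene_sets = gene_sets,
                 expression_scale = expression_scale, thresholds = th,
                 roc_times = roc_times, ssgsea_alpha = ssgsea_alpha,
                 stromal_sets = stromal_sets, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[pairsig] %-16s %6.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full gene-pair signature pipeline
#'
#' Stages: load or simulate the cohort; log-normalize; ssGSEA immune profiling
#' and high/medium/low clustering (tumor samples); differential expression for
#' the tumor/normal, metastatic/non-metastatic and high-/low-immune contrasts;
#' intersection; pair construction with prevalence filter; univariate Cox
#' screen; LASSO-Cox selection; unpenalized refit; time-dependent ROC with
#' Youden cutoff at the longest horizon; risk grouping, Kaplan-Meier/log-rank
#' and association tests. Every intermediate is written under
#' `config$out_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @return `run_report`: list with `counts` (genes per contrast, intersected,
#'   pairs built/filtered/screened/selected), `model` (`signature_model`),
#'   `scores`, `groups`, `roc` (per horizon), `km`, `associations`,
#'   `infiltration`, `immune_groups`, `seeds`, `artifacts`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  artifacts <- character(0)
  od <- config$out_dir
  if (!is.null(od)) dir.create(od, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) {
    if (is.null(od)) return(invisible(NULL))
    path <- file.path(od, name)
    writer(path)
    artifacts[[name]] <<- path
  }

  # --- inputs ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- pipeline_stage("simulate", generate_cohort(config$simulate))
    expr <- cohort$expression
    clinical <- cohort$annotations
    sets <- cohort$gene_sets
    if (!is.null(od)) write_cohort(cohort, file.path(od, "cohort"))
  } else {
    cohort <- NULL
    expr <- pipeline_stage("read",
      read_expression(config$expression, config$expression_scale))
    clinical <- read_clinical(config$clinical)
    sets <- read_gmt(config$gene_sets)
  }
  if (!all(colnames(expr) %in% clinical$sample_id))
    stop("samples in expression missing from clinical table", call. = FALSE)
  clinical <- clinical[match(colnames(expr), clinical$sample_id), ]
  logx <- as_log_expression(expr)
  is_tumor <- clinical$tissue == "tumor"
  tumor_ids <- clinical$sample_id[is_tumor]
  surv_t <- data.frame(time = clinical$time[is_tumor],
                       event = clinical$event[is_tumor])

  # --- immune profiling ------------------------------------------------
  scores_mat <- pipeline_stage("ssgsea",
    score_collection(logx, sets, alpha = config$ssgsea_alpha))
  stromal_nm <- config$stromal_sets %||%
    grep("^Stromal", rownames(scores_mat), value = TRUE)
  immune_nm <- setdiff(rownames(scores_mat), stromal_nm)
  if (!length(stromal_nm)) stromal_nm <- immune_nm  # no stromal sets supplied
  iss <- immune_stromal_scores(scores_mat, immune_nm, stromal_nm)
  imm_groups <- cluster_immune_groups(
    stats::setNames(iss$immune_score, iss$sample_id)[tumor_ids],
    stats::setNames(iss$stromal_score, iss$sample_id)[tumor_ids])
  emit("immune_scores.tsv", function(p) utils::write.table(
    data.frame(iss, group = as.character(imm_groups[iss$sample_id])),
    p, sep = "\t", quote = FALSE, row.names = FALSE))

  # --- differential expression (three contrasts) -----------------------
  deg <- pipeline_stage("deg_screen", {
    de_tumor <- differential_expression(
      logx, clinical$sample_id[is_tumor], clinical$sample_id[!is_tumor])
    de_met <- differential_expression(
      logx, clinical$sample_id[is_tumor & clinical$metastatic %in% TRUE],
      clinical$sample_id[is_tumor & clinical$metastatic %in% FALSE])
    de_imm <- differential_expression(
      logx, names(imm_groups)[imm_groups == "high"],
      names(imm_groups)[imm_groups == "low"])
    list(tumor = de_tumor, metastasis = de_met, immune = de_imm)
  })
  genes_tumor <- apply_thresholds(deg$tumor, th$tumor_lfc, th$tumor_p)
  genes_met <- apply_thresholds(deg$metastasis, th$other_lfc, th$other_p)
  genes_imm <- apply_thresholds(deg$immune, th$other_lfc, th$other_p)
  candidates <- intersect_contrasts(list(genes_tumor, genes_met, genes_imm))
  emit("deg_tumor.tsv", function(p)
    write_deg_table(deg$tumor, th$tumor_lfc, th$tumor_p, p))
  emit("deg_metastasis.tsv", function(p)
    write_deg_table(deg$metastasis, th$other_lfc, th$other_p, p))
  emit("deg_immune.tsv", function(p)
    write_deg_table(deg$immune, th$other_lfc, th$other_p, p))
  emit("candidate_genes.txt", function(p) writeLines(candidates, p))
  if (length(candidates) < 2)
    stop("pipeline stage 'intersect' failed: fewer than 2 candidate genes ",
         "survive the three contrasts", call. = FALSE)

  # --- pairs, screen, selection, refit (tumor samples) ------------------
  pairs_all <- pipeline_stage("pairs",
    build_pair_matrix(logx[, tumor_ids], candidates))
  pairs_valid <- filter_pairs_by_prevalence(pairs_all, th$prevalence)
  screen <- pipeline_stage("screen",
    screen_pairs(pairs_valid, surv_t, alpha = th$screen_alpha))
  if (length(screen$selected) < 2)
    stop("pipeline stage 'screen' failed: fewer than 2 pairs at p < ",
         th$screen_alpha, call. = FALSE)
  sel <- pipeline_stage("lasso",
    lasso_cox_select(pairs_valid[screen$selected, ], surv_t,
                     seed = config$seed))
  if (!length(sel$selected))
    stop("pipeline stage 'lasso' failed: empty selection at lambda.min",
         call. = FALSE)
  model <- pipeline_stage("refit",
    fit_final_model(pairs_valid, surv_t, sel$selected))
  emit("univariate_cox.tsv", function(p) utils::write.table(
    screen$table, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # --- evaluation ------------------------------------------------------
  scores <- risk_score(model, pairs_valid)
  roc <- pipeline_stage("roc",
    time_dependent_roc(scores, surv_t, config$roc_times))
  cutoff_roc <- roc[[as.character(max(config$roc_times))]]
  model$cutoff <- optimal_cutoff(cutoff_roc)
  groups <- assign_risk_groups(scores, model$cutoff)
  km <- km_logrank(surv_t, groups)
  assoc_fields <- intersect(c("metastatic", "stage", "T", "N", "M", "age",
                              "gender"), names(clinical))
  assoc <- association_tests(groups, clinical[is_tumor, , drop = FALSE],
                             fields = assoc_fields)
  infl <- infiltration_by_risk(scores_mat[, tumor_ids, drop = FALSE],
                               groups, scores)
  emit("model.json", function(p) write_model_json(model, p))
  emit("risk_scores.tsv", function(p) utils::write.table(
    data.frame(sample_id = tumor_ids, score = scores,
               group = as.character(groups)),
    p, sep = "\t", quote = FALSE, row.names = FALSE))

  report <- structure(list(
    counts = list(
      genes_tumor = length(genes_tumor), genes_metastasis = length(genes_met),
      genes_immune = length(genes_imm), genes_intersected = length(candidates),
      pairs_built = nrow(pairs_all), pairs_prevalent = nrow(pairs_valid),
      pairs_screened = length(screen$selected),
      pairs_selected = length(sel$selected)),
    model = model, lambda = sel$lambda, scores = scores, groups = groups,
    roc = roc, auc = vapply(roc, `[[`, 0.0, "auc"), km = km,
    associations = assoc, infiltration = infl,
    immune_groups = imm_groups, deg = deg, univariate = screen$table,
    cohort = cohort,
    seeds = list(pipeline = config$seed,
                 simulate = if (!is.null(config$simulate))
                   config$simulate$seed else NULL),
    artifacts = artifacts), class = "run_report")
  if (!is.null(od)) {
    manifest <- list(counts = report$counts, auc = as.list(report$auc),
                     cutoff = model$cutoff, logrank_p = km$logrank_p,
                     seeds = report$seeds, artifacts = as.list(artifacts))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  c <- x$counts
  cat("gene-pair signature run\n")
  cat(sprintf("  DEGs: tumor %d | metastasis %d | immune %d -> intersected %d\n",
              c$genes_tumor, c$genes_metastasis, c$genes_immune,
              c$genes_intersected))
  cat(sprintf("  pairs: built %d -> prevalent %d -> screened %d -> selected %d\n",
              c$pairs_built, c$pairs_prevalent, c$pairs_screened,
              c$pairs_selected))
  cat(sprintf("  model: %s (cutoff %.4f)\n",
              paste(x$model$pairs, collapse = ", "), x$model$cutoff))
  cat(sprintf("  AUC: %s\n",
              paste(sprintf("%s y = %.3f", names(x$auc), x$auc),
                    collapse = ", ")))
  cat(sprintf("  log-rank p (high vs low risk): %.4g\n", x$km$logrank_p))
  invisible(x)
}

#' Score an independent cohort with a fitted or published signature
#'
#' Recomputes the model's pair indicators from the new cohort's own
#' expression (rank-based, so no cross-platform normalization is needed),
#' applies the risk score, dichotomizes either at the model's stored cutoff
#' (`reuse_cutoff = TRUE`) or at a cutoff re-derived on this cohort from the
#' ROC at `roc_time`, and evaluates with Kaplan-Meier/log-rank.
#'
#' @param model a `signature_model`.
#' @param expr the cohort's [expression_matrix()].
#' @param surv aligned data.frame with `time` and `event` (one row per
#'   expression column).
#' @param reuse_cutoff reuse `model$cutoff` (default) or recompute.
#' @param roc_time horizon for cutoff recomputation and the reported ROC.
#' @return list with `scores`, `groups`, `cutoff`, `km`, `roc`.
#' @export
score_cohort <- function(model, expr, surv, reuse_cutoff = TRUE,
                         roc_time = 6) {
  stopifnot(inherits(model, "signature_model"), nrow(surv) == ncol(expr))
  pairs <- score_pairs_on_cohort(model$pairs, expr)
  scores <- risk_score(model, pairs)
  roc <- time_dependent_roc(scores, surv, roc_time)[[1]]
  cutoff <- if (reuse_cutoff) {
    if (!is.finite(model$cutoff))
      stop("model carries no cutoff; use reuse_cutoff = FALSE", call. = FALSE)
    model$cutoff
  } else optimal_cutoff(roc)
  groups <- assign_risk_groups(scores, cutoff)
  if (nlevels(droplevels(groups)) < 2)
    stop("all samples fall in one risk group at cutoff ", cutoff,
         call. = FALSE)
  list(scores = scores, groups = groups, cutoff = cutoff,
       km = km_logrank(surv, groups), roc = roc)
}
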