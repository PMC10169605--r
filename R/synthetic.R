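#' Configuration for the synthetic-cohort generator
#'
#' Describes a cohort with the statistical structure the pair-signature
#' analysis assumes: a tumor/normal contrast, a metastatic/non-metastatic
#' contrast among tumors, a latent immune-infiltration axis that drives the
#' expression of immune gene-set members, and survival whose hazard depends on
#' planted gene-pair indicators. Genes are laid out in disjoint blocks —
#' immune-set members, stromal-set members, tumor-only DE, metastasis-only DE,
#' an "overlap" block that is differential in all three contrasts (planted
#' pairs draw their genes from it, so they can survive the set intersection),
#' and null background genes.
#'
#' Within a planted pair both genes receive identical contrast shifts and the
#' same immune coupling, so the indicator `I(A > B)` depends only on the two
#' baselines and the log-scale noise; its tumor-sample prevalence is forced
#' into the open interval (0.2, 0.8) by resampling the pair's baselines
#' (bounded retries), matching the prevalence validity filter downstream.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param frac_normal fraction of samples that are adjacent-normal tissue, in
#'   \[0, 1).
#' @param frac_metastatic fraction of tumor samples with metastasis, in
#'   \[0, 1).
#' @param n_immune_sets,genes_per_set immune cell-type gene sets (29 sets is
#'   the conventional immune-cell panel size).
#' @param n_stromal_sets stromal gene sets used for the stromal summary score.
#' @param immune_effect log2-scale expression shift per unit of the latent
#'   (standard-normal) immune score for genes in immune/stromal sets.
#' @param tumor_de_genes,tumor_effect genes shifted (alternating sign) between
#'   tumor and normal, in log2 units.
#' @param metastasis_de_genes,metastasis_effect same for the metastatic
#'   contrast (tumors only).
#' @param n_overlap_genes genes differential in all three contrasts; must be
#'   at least twice the number of planted pairs.
#' @param planted_pairs data.frame with columns `gene_a`, `gene_b`, `beta`
#'   (log-hazard per unit indicator) naming genes in the overlap block, or
#'   `NULL` to derive `n_planted_pairs` pairs with `planted_betas` from the
#'   first overlap genes. Zero-row data.frame plants no pairs (null cohort).
#' @param n_planted_pairs,planted_betas used when `planted_pairs` is `NULL`.
#' @param baseline_hazard event rate per unit time (years) at indicator zero.
#' @param censor_rate independent exponential censoring rate per unit time.
#' @param max_followup administrative censoring cap, years.
#' @param noise_sd log2-scale residual standard deviation.
#' @param counts if `TRUE`, emit Poisson counts around the linear-scale means
#'   (scale tag `"counts"`); otherwise positive linear-scale values
#'   (`"normalized"`).
#' @param seed integer; one seed governs every random draw.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1200, n_samples = 444,
                       frac_normal = 0.1, frac_metastatic = 0.16,
                       n_immune_sets = 29, genes_per_set = 10,
                       n_stromal_sets = 2, immune_effect = 1,
                       tumor_de_genes = 100, tumor_effect = 2,
                       metastasis_de_genes = 60, metastasis_effect = 1.5,
                       n_overlap_genes = 12,
                       planted_pairs = NULL, n_planted_pairs = 3,
                       planted_betas = c(0.9, -0.8, 0.7),
                       baseline_hazard = 0.12, censor_rate = 0.035,
                       max_followup = 12, noise_sd = 1,
                       counts = FALSE, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples,
              frac_normal = frac_normal, frac_metastatic = frac_metastatic,
              n_immune_sets = n_immune_sets, genes_per_set = genes_per_set,
              n_stromal_sets = n_stromal_sets, immune_effect = immune_effect,
              tumor_de_genes = tumor_de_genes, tumor_effect = tumor_effect,
              metastasis_de_genes = metastasis_de_genes,
              metastasis_effect = metastasis_effect,
              n_overlap_genes = n_overlap_genes,
              planted_pairs = planted_pairs,
              n_planted_pairs = n_planted_pairs,
              planted_betas = planted_betas,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              max_followup = max_followup, noise_sd = noise_sd,
              counts = counts, seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 &&
    x == round(x)
  for (f in c("n_genes", "n_samples", "n_immune_sets", "genes_per_set",
              "n_stromal_sets"))
    if (!pos_count(cfg[[f]]))
      stop("sim_config: '", f, "' must be a positive count", call. = FALSE)
  for (f in c("frac_normal", "frac_metastatic"))
    if (!(is.finite(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] < 1))
      stop("sim_config: '", f, "' must lie in [0, 1)", call. = FALSE)
  if (!(is.finite(cfg$baseline_hazard) && cfg$baseline_hazard > 0))
    stop("sim_config: 'baseline_hazard' must be > 0", call. = FALSE)
  if (!(is.finite(cfg$censor_rate) && cfg$censor_rate >= 0))
    stop("sim_config: 'censor_rate' must be >= 0", call. = FALSE)
  if (!(cfg$max_followup > 0))
    stop("sim_config: 'max_followup' must be > 0", call. = FALSE)
  if (!(is.finite(cfg$noise_sd) && cfg$noise_sd > 0))
    stop("sim_config: 'noise_sd' must be > 0", call. = FALSE)

  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  n_setgenes <- (cfg$n_immune_sets + cfg$n_stromal_sets) * cfg$genes_per_set
  used <- n_setgenes + cfg$tumor_de_genes + cfg$metastasis_de_genes +
    cfg$n_overlap_genes
  if (used > cfg$n_genes)
    stop("sim_config: gene blocks need ", used, " genes but n_genes = ",
         cfg$n_genes, call. = FALSE)

  ov_start <- n_setgenes + cfg$tumor_de_genes + cfg$metastasis_de_genes
  overlap_ids <- gene_ids[ov_start + seq_len(cfg$n_overlap_genes)]

  pp <- cfg$planted_pairs
  if (is.null(pp)) {
    k <- cfg$n_planted_pairs
    if (length(cfg$planted_betas) != k)
      stop("sim_config: planted_betas must have length n_planted_pairs",
           call. = FALSE)
    if (k > 0 && 2 * k > cfg$n_overlap_genes)
      stop("sim_config: n_overlap_genes too small for ", k, " planted pairs",
           call. = FALSE)
    pp <- data.frame(
      gene_a = overlap_ids[seq_len(k) * 2 - 1],
      gene_b = overlap_ids[seq_len(k) * 2],
      beta = as.numeric(cfg$planted_betas),
      stringsAsFactors = FALSE)
    if (k == 0) pp <- pp[0, ]
  } else {
    if (!is.data.frame(pp) ||
        !all(c("gene_a", "gene_b", "beta") %in% names(pp)))
      stop("sim_config: planted_pairs needs columns gene_a, gene_b, beta",
           call. = FALSE)
    missing <- setdiff(c(pp$gene_a, pp$gene_b), gene_ids)
    if (length(missing))
      stop("sim_config: planted-pair genes not in cohort: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (any(pp$gene_a == pp$gene_b))
      stop("sim_config: a pair cannot use one gene twice", call. = FALSE)
  }
  cfg$planted_pairs <- pp
  cfg$gene_ids <- gene_ids
  cfg$overlap_ids <- overlap_ids
  structure(cfg, class = "sim_config")
}

#' Simulate proportional-hazards survival data
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(linear_predictor)`; observed time is the minimum of
#' the event time, an independent exponential censoring time (rate
#' `censor_rate`; none when 0) and the administrative cap `max_followup`. The
#' event flag is 1 iff the event time is the smallest.
#'
#' @param linear_predictor per-sample log relative hazard (finite).
#' @param baseline_hazard rate per unit time, > 0.
#' @param censor_rate censoring rate per unit time, >= 0.
#' @param max_followup administrative cap (may be `Inf`).
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return data.frame with columns `time` (> 0) and `event` (0/1).
#' @export
simulate_survival <- function(linear_predictor, baseline_hazard,
                              censor_rate = 0, max_followup = Inf,
                              seed = NULL) {
  if (!is.numeric(linear_predictor) || !all(is.finite(linear_predictor)))
    stop("linear_predictor must be finite numeric", call. = FALSE)
  if (!(baseline_hazard > 0)) stop("baseline_hazard must be > 0")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  n <- length(linear_predictor)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = baseline_hazard * exp(linear_predictor))
    t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate)
              else rep(Inf, n)
    time <- pmin(t_event, t_cens, max_followup)
    data.frame(time = time,
               event = as.integer(t_event <= pmin(t_cens, max_followup)))
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Expression is log2-normal around gene baselines: for gene g and sample s,
#' `log2 x = baseline_g + tumor-shift + metastasis-shift +
#' immune_effect * z_s * [g in an immune/stromal set] + noise`, exponentiated
#' to positive values (optionally Poisson-rounded to counts). `z_s` is the
#' latent immune score, standard normal. Survival follows
#' [simulate_survival()] with linear predictor `sum(beta_p * indicator_p)`
#' over the planted pairs, evaluated on the generated expression itself.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `expression`
#'   ([expression_matrix()]), `annotations` (sample_id, tissue, metastatic),
#'   `survival` (sample_id, time, event), `gene_sets` (named list; stromal
#'   sets are named `Stromal..`), and `ground_truth` (per-contrast DE gene
#'   sets, planted pairs with canonical ids and true betas, latent immune
#'   score, block assignments).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  g <- cfg$n_genes
  gene_ids <- cfg$gene_ids
  sample_ids <- sprintf("s%04d", seq_len(n))

  n_normal <- round(cfg$frac_normal * n)
  tissue <- rep(c("normal", "tumor"), c(n_normal, n - n_normal))
  is_tumor <- tissue == "tumor"
  metastatic <- rep(NA, n)
  n_met <- round(cfg$frac_metastatic * sum(is_tumor))
  met_pick <- sample(which(is_tumor), n_met)
  metastatic[is_tumor] <- FALSE
  metastatic[met_pick] <- TRUE

  # gene blocks
  gps <- cfg$genes_per_set
  imm_idx <- seq_len(cfg$n_immune_sets * gps)
  str_idx <- max(imm_idx) + seq_len(cfg$n_stromal_sets * gps)
  tum_idx <- max(str_idx) + seq_len(cfg$tumor_de_genes)
  met_idx <- max(tum_idx) + seq_len(cfg$metastasis_de_genes)
  ov_idx <- max(met_idx) + seq_len(cfg$n_overlap_genes)

  gene_sets <- c(
    split(gene_ids[imm_idx],
          rep(sprintf("ImmCell%02d", seq_len(cfg$n_immune_sets)), each = gps)),
    split(gene_ids[str_idx],
          rep(sprintf("Stromal%02d", seq_len(cfg$n_stromal_sets)), each = gps)))
  gene_sets <- gene_sets[order(names(gene_sets))]
  # overlap genes join immune sets round-robin so they differ between the
  # high- and low-immune groups downstream
  for (k in seq_along(ov_idx)) {
    s <- sprintf("ImmCell%02d", (k - 1L) %% cfg$n_immune_sets + 1L)
    gene_sets[[s]] <- c(gene_sets[[s]], gene_ids[ov_idx[k]])
  }

  in_set <- logical(g)
  in_set[c(imm_idx, str_idx, ov_idx)] <- TRUE

  # per-gene contrast shifts (log2); signs alternate, and within a planted
  # pair both genes share all shifts so the indicator ignores them
  tumor_shift <- numeric(g)
  tumor_shift[tum_idx] <- cfg$tumor_effect *
    rep_len(c(1, -1), length(tum_idx))
  met_shift <- numeric(g)
  met_shift[met_idx] <- cfg$metastasis_effect *
    rep_len(c(1, -1), length(met_idx))
  if (length(ov_idx)) {
    ov_pair_block <- (seq_along(ov_idx) + 1L) %/% 2L  # 1 1 2 2 3 3 ...
    nb <- max(ov_pair_block)
    tumor_shift[ov_idx] <- cfg$tumor_effect * rep_len(c(1, -1), nb)[ov_pair_block]
    met_shift[ov_idx] <- cfg$metastasis_effect * rep_len(c(-1, 1), nb)[ov_pair_block]
  }

  baseline <- stats::runif(g, 4, 12)
  latent <- stats::rnorm(n)
  noise <- matrix(stats::rnorm(g * n, sd = cfg$noise_sd), g, n)

  met_num <- as.numeric(!is.na(metastatic) & metastatic)
  make_rows <- function(idx, base) {
    base + tumor_shift[idx] %o% as.numeric(is_tumor) +
      met_shift[idx] %o% met_num +
      (cfg$immune_effect * in_set[idx]) %o% latent +
      noise[idx, , drop = FALSE]
  }
  log2x <- make_rows(seq_len(g), baseline)

  # force each planted pair's tumor prevalence into (0.2, 0.8) by resampling
  # the two baselines (noise redrawn with them); bounded retries
  pp <- cfg$planted_pairs
  tum_cols <- which(is_tumor)
  if (nrow(pp) > 0) {
    ridx <- match(c(pp$gene_a, pp$gene_b), gene_ids)
    if (anyNA(ridx)) stop("planted-pair gene missing from cohort")
    for (p in seq_len(nrow(pp))) {
      ia <- match(pp$gene_a[p], gene_ids)
      ib <- match(pp$gene_b[p], gene_ids)
      prev <- mean(log2x[ia, tum_cols] > log2x[ib, tum_cols])
      tries <- 0L
      while ((prev <= 0.2 || prev >= 0.8) && tries < 100L) {
        baseline[c(ia, ib)] <- stats::runif(2, 4, 12)
        noise[c(ia, ib), ] <- stats::rnorm(2 * n, sd = cfg$noise_sd)
        log2x[c(ia, ib), ] <- make_rows(c(ia, ib), baseline[c(ia, ib)])
        prev <- mean(log2x[ia, tum_cols] > log2x[ib, tum_cols])
        tries <- tries + 1L
      }
      if (prev <= 0.2 || prev >= 0.8)
        stop("generate_cohort: could not place pair ", pp$gene_a[p], "|",
             pp$gene_b[p], " at prevalence in (0.2, 0.8) within 100 retries",
             call. = FALSE)
    }
  }

  linear <- 2^log2x
  dimnames(linear) <- list(gene_ids, sample_ids)
  if (cfg$counts) {
    vals <- matrix(stats::rpois(g * n, lambda = linear), g, n,
                   dimnames = dimnames(linear))
    expr <- expression_matrix(vals, "counts")
  } else {
    expr <- expression_matrix(linear, "normalized")
  }

  # survival: hazard driven by the planted indicators on the realized data
  lp <- numeric(n)
  pair_ids <- character(0)
  if (nrow(pp) > 0) {
    for (p in seq_len(nrow(pp))) {
      ind <- as.numeric(linear[pp$gene_a[p], ] > linear[pp$gene_b[p], ])
      lp <- lp + pp$beta[p] * ind
    }
    pair_ids <- canonical_pair_id(pp$gene_a, pp$gene_b)
  }
  surv <- simulate_survival(lp, cfg$baseline_hazard, cfg$censor_rate,
                            cfg$max_followup, seed = NULL)
  surv <- data.frame(sample_id = sample_ids, surv, stringsAsFactors = FALSE)

  annotations <- data.frame(
    sample_id = sample_ids, tissue = tissue, metastatic = metastatic,
    time = surv$time, event = surv$event, stringsAsFactors = FALSE)

  # ground-truth pairs are reported in canonical orientation; when
  # canonicalization flips a pair, its indicator complements, so the
  # equivalent hazard effect flips sign
  gt_pp <- pp
  if (nrow(gt_pp) > 0) {
    gt_pp$pair_id <- pair_ids
    flipped <- gt_pp$gene_a > gt_pp$gene_b
    gt_pp$beta[flipped] <- -gt_pp$beta[flipped]
    ga <- gt_pp$gene_a
    gt_pp$gene_a[flipped] <- gt_pp$gene_b[flipped]
    gt_pp$gene_b[flipped] <- ga[flipped]
  }
  ground_truth <- list(
    de_gene_sets = list(
      tumor = gene_ids[c(tum_idx, ov_idx)],
      metastasis = gene_ids[c(met_idx, ov_idx)],
      immune = gene_ids[c(imm_idx, ov_idx)]),
    immune_gene_sets = gene_sets,
    planted_pairs = gt_pp,
    latent_immune_score = stats::setNames(latent, sample_ids),
    overlap_genes = gene_ids[ov_idx],
    linear_predictor = stats::setNames(lp, sample_ids))

  structure(list(expression = expr, annotations = annotations,
                 survival = surv, gene_sets = gene_sets,
                 ground_truth = ground_truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  a <- x$annotations
  cat(sprintf(
    "sim_cohort: %d genes x %d samples (%d tumor / %d normal, %d metastatic)\n",
    nrow(x$expression), ncol(x$expression), sum(a$tissue == "tumor"),
    sum(a$tissue == "normal"), sum(a$metastatic %in% TRUE)))
  cat(sprintf("  planted pairs: %s\n",
              if (nrow(x$ground_truth$planted_pairs)) paste(
                x$ground_truth$planted_pairs$pair_id, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Write a synthetic cohort to standard formats
#'
#' Emits expression as TSV (genes as rows), clinical annotations as TSV, gene
#' sets as GMT and the ground truth as a JSON sidecar.
#' @param cohort a `sim_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_expression(cohort$expression, paths["expression"])
  write_clinical(cohort$annotations, paths["clinical"])
  write_gmt(cohort$gene_sets, paths["gene_sets"])
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(de_gene_sets = gt$de_gene_sets,
         planted_pairs = gt$planted_pairs,
         latent_immune_score = as.list(gt$latent_immune_score),
         overlap_genes = gt$overlap_genes,
         scale_tag = expr_scale(cohort$expression)),
    paths["ground_truth"], auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(paths)
}
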