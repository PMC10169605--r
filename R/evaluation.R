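# Product-limit (Kaplan-Meier) survival probability at a single time t.
km_surv_at <- function(time, event, t) {
  evt <- sort(time[event == 1 & time <= t])
  if (!length(evt)) return(1)
  ut <- unique(evt)
  d <- diff(c(0L, findInterval(ut, evt)))                  # deaths per time
  n_risk <- length(time) - findInterval(ut, sort(time), left.open = TRUE)
  prod(1 - d / n_risk)
}

#' Time-dependent ROC (cumulative/dynamic, KM-weighted)
#'
#' Heagerty-Lumley-Pepe estimator at each evaluation horizon t: cases are
#' subjects with an event by t, controls are survivors past t, and censoring
#' is handled through Kaplan-Meier estimates — S(t) on the whole cohort and,
#' per score threshold c, S(t | score > c) on the subset above the threshold:
#' `sens(c) = (1 - S_c(t)) P(X > c) / (1 - S(t))`,
#' `1 - spec(c) = S_c(t) P(X > c) / S(t)`. AUC is the trapezoidal area over
#' the empirical thresholds. Without censoring before t this reduces exactly
#' to the empirical ROC of the dichotomized outcome (Mann-Whitney AUC).
#'
#' @param scores per-sample risk scores (higher = riskier).
#' @param surv aligned data.frame with `time`, `event`.
#' @param eval_times horizons (same units as `time`); each must have at least
#'   one event at or before it.
#' @return list of `time_roc` objects (fields `eval_time`, `thresholds`,
#'   `sensitivity`, `specificity`, `auc`), one per horizon, named by horizon.
#' @export
time_dependent_roc <- function(scores, surv, eval_times) {
  stopifnot(length(scores) == nrow(surv))
  out <- lapply(eval_times, function(t) {
    if (!any(surv$time <= t & surv$event == 1))
      stop("no events at or before t = ", t, call. = FALSE)
    St <- km_surv_at(surv$time, surv$event, t)
    cuts <- sort(unique(scores))
    sens <- spec <- numeric(length(cuts))
    for (i in seq_along(cuts)) {
      above <- scores > cuts[i]
      p <- mean(above)
      Sc <- if (any(above))
        km_surv_at(surv$time[above], surv$event[above], t) else 1
      tp <- if (St < 1) (1 - Sc) * p / (1 - St) else 0
      fp <- if (St > 0) Sc * p / St else 0
      sens[i] <- min(max(tp, 0), 1)
      spec[i] <- min(max(1 - fp, 0), 1)
    }
    # traverse thresholds from the highest (0, 0) down to below the minimum
    # (1, 1); this is the ROC path itself, immune to floating ties in FPR
    fpr <- c(rev(1 - spec), 1)
    tpr <- c(rev(sens), 1)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    structure(list(eval_time = t, thresholds = cuts, sensitivity = sens,
                   specificity = spec, auc = auc),
              class = "time_roc")
  })
  stats::setNames(out, as.character(eval_times))
}

#' @export
print.time_roc <- function(x, ...) {
  cat(sprintf("time_roc at t = %s: AUC = %.4f (%d thresholds)\n",
              format(x$eval_time), x$auc, length(x$thresholds)))
  invisible(x)
}

#' Optimal cutoff by Youden's J
#'
#' The threshold maximizing `J = sensitivity + specificity - 1` on a
#' [time_dependent_roc()] curve; ties are broken toward the smaller
#' threshold.
#'
#' @param roc a `time_roc`.
#' @return the cutoff (a score value).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "time_roc"))
  if (length(roc$thresholds) < 2)
    stop("degenerate ROC: all scores equal", call. = FALSE)
  j <- roc$sensitivity + roc$specificity - 1
  roc$thresholds[which.max(j)]   # which.max takes the first (smallest) tie
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit estimator per group plus the (k-1)-df log-rank chi-square.
#'
#' @param surv data.frame with `time`, `event`.
#' @param groups factor/character of group labels aligned with `surv`; at
#'   least two non-empty groups.
#' @return `km_result`: list with `curves` (per group: time, n_risk, n_event,
#'   surv), `logrank_stat`, `df`, `logrank_p`.
#' @export
km_logrank <- function(surv, groups) {
  stopifnot(length(groups) == nrow(surv))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2)
    stop("log-rank needs >= 2 non-empty groups", call. = FALSE)
  y <- survival::Surv(surv$time, surv$event)
  fit <- survival::survfit(y ~ groups)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  curves <- lapply(levels(groups), function(g) {
    sel <- strata == paste0("groups=", g)
    data.frame(time = fit$time[sel], n_risk = fit$n.risk[sel],
               n_event = fit$n.event[sel], surv = fit$surv[sel])
  })
  names(curves) <- levels(groups)
  sd <- survival::survdiff(y ~ groups, rho = 0)
  df <- nlevels(groups) - 1L
  structure(list(curves = curves, logrank_stat = sd$chisq, df = df,
                 logrank_p = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("km_result: %d groups, log-rank chisq = %.4f (df %d), p = %.4g\n",
              length(x$curves), x$logrank_stat, x$df, x$logrank_p))
  invisible(x)
}

#' Association between risk groups and clinical annotations
#'
#' Categorical fields vs the risk grouping: Pearson chi-square without
#' continuity correction (zero-margin rows/columns are dropped with a
#' warning). Numeric fields: two-sided Mann-Whitney rank test between the two
#' risk groups (tie-corrected normal approximation).
#'
#' @param groups risk labels (two levels) aligned with `annotations` rows.
#' @param annotations data.frame of clinical fields; `NA`s dropped per field.
#' @param fields which columns to test; default all except `sample_id`.
#' @return data.frame: `field`, `test` ("chisq" or "ranksum"), `statistic`,
#'   `p`.
#' @export
association_tests <- function(groups, annotations,
                              fields = setdiff(names(annotations),
                                               "sample_id")) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) >= 2, length(groups) == nrow(annotations))
  rows <- lapply(fields, function(f) {
    v <- annotations[[f]]
    ok <- !is.na(v) & !is.na(groups)
    v <- v[ok]; g <- droplevels(groups[ok])
    if (length(unique(v)) < 2 || nlevels(g) < 2)
      return(data.frame(field = f, test = NA_character_,
                        statistic = NA_real_, p = NA_real_))
    if (is.numeric(v) && length(unique(v)) > 5) {
      lv <- levels(g)
      r <- ranksum_test(v[g == lv[1]], v[g == lv[2]])
      data.frame(field = f, test = "ranksum", statistic = r$stat, p = r$p)
    } else {
      tab <- table(g, v)
      drop_r <- rowSums(tab) == 0; drop_c <- colSums(tab) == 0
      if (any(drop_r) || any(drop_c)) {
        warning("dropping zero-margin levels for field '", f, "'")
        tab <- tab[!drop_r, !drop_c, drop = FALSE]
      }
      if (sum(tab) == 0 || any(dim(tab) < 2))
        stop("degenerate contingency table for field '", f, "'",
             call. = FALSE)
      ct <- stats::chisq.test(tab, correct = FALSE)
      data.frame(field = f, test = "chisq",
                 statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
  do.call(rbind, rows)
}

#' Immune-infiltration differences between risk groups
#'
#' Per gene set: a Mann-Whitney rank test of the set's ssGSEA scores between
#' high- and low-risk samples, the direction of the difference, and the
#' Spearman correlation of the set score with the continuous risk score. A
#' set whose score is constant across samples has no defined correlation and
#' is flagged.
#'
#' @param score_matrix set-by-sample matrix from [score_collection()].
#' @param groups risk labels (`high`/`low`) aligned with columns.
#' @param risk_scores continuous per-sample risk scores.
#' @return data.frame: `set`, `direction` ("up_in_high"/"down_in_high"),
#'   `p_ranksum`, `spearman_rho`, `defined`.
#' @export
infiltration_by_risk <- function(score_matrix, groups, risk_scores) {
  groups <- droplevels(as.factor(groups))
  stopifnot(ncol(score_matrix) == length(groups),
            length(risk_scores) == length(groups))
  hi <- groups == "high"; lo <- groups == "low"
  if (!any(hi) || !any(lo)) stop("both risk groups must be non-empty",
                                 call. = FALSE)
  rows <- lapply(rownames(score_matrix), function(s) {
    v <- score_matrix[s, ]
    if (stats::sd(v) == 0)
      return(data.frame(set = s, direction = NA_character_,
                        p_ranksum = NA_real_, spearman_rho = NA_real_,
                        defined = FALSE))
    r <- ranksum_test(v[hi], v[lo])
    data.frame(
      set = s,
      direction = if (mean(v[hi]) >= mean(v[lo])) "up_in_high"
                  else "down_in_high",
      p_ranksum = r$p,
      spearman_rho = stats::cor(v, risk_scores, method = "spearman"),
      defined = TRUE)
  })
  do.call(rbind, rows)
}
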