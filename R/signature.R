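Z975 <- stats::qnorm(0.975)  # 1.959964

new_signature_model <- function(pairs, coefficients, table, cutoff,
                                provenance) {
  stopifnot(length(pairs) == length(coefficients))
  structure(list(pairs = pairs, coefficients = coefficients, table = table,
                 cutoff = cutoff, provenance = provenance),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model (%s): %d pair(s), cutoff %s\n", x$provenance,
              length(x$pairs),
              if (is.na(x$cutoff)) "unset" else format(x$cutoff)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

unicox_record <- function(pair_id, coef, se) {
  data.frame(pair_id = pair_id, coef = coef, se = se,
             hr = exp(coef),
             ci_low = exp(coef - Z975 * se),
             ci_high = exp(coef + Z975 * se),
             p = 2 * stats::pnorm(-abs(coef / se)),
             estimable = TRUE, stringsAsFactors = FALSE)
}

#' Univariate Cox regression for one pair indicator
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for a single
#' binary covariate; the standard error comes from the observed information
#' and the p-value is the two-sided Wald test. Hazard-ratio confidence bounds
#' are `exp(coef -+ 1.959964 * se)`, so `sqrt(ci_low * ci_high) == hr`.
#'
#' @param indicator 0/1 vector, one value per sample.
#' @param surv data.frame with `time` (> 0) and `event` (0/1) aligned with
#'   `indicator`.
#' @return one-row data.frame: `pair_id` (NA here; filled by callers), `coef`,
#'   `se`, `hr`, `ci_low`, `ci_high`, `p`, `estimable`. A constant indicator
#'   is returned flagged `estimable = FALSE` rather than raising.
#' @export
univariate_cox <- function(indicator, surv) {
  stopifnot(length(indicator) == nrow(surv))
  if (sum(surv$event) < 1) stop("no events in the cohort", call. = FALSE)
  if (length(unique(indicator)) < 2) {
    out <- unicox_record(NA_character_, NA_real_, NA_real_)
    out$estimable <- FALSE
    return(out)
  }
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ indicator,
                         ties = "efron")
  unicox_record(NA_character_, unname(stats::coef(fit)),
                sqrt(unname(stats::vcov(fit)[1, 1])))
}

#' Univariate screen of pair indicators
#'
#' Fits [univariate_cox()] per pair and keeps those with Wald `p < alpha`, in
#' input order. Non-estimable (constant) pairs are dropped silently.
#'
#' @param pairs a `pair_matrix`.
#' @param surv survival data.frame aligned with the pair-matrix columns.
#' @param alpha significance threshold; default 0.05.
#' @return list with `selected` (pair ids) and `table` (all univariate
#'   records).
#' @export
screen_pairs <- function(pairs, surv, alpha = 0.05) {
  recs <- lapply(rownames(pairs), function(pid) {
    r <- univariate_cox(unclass(pairs)[pid, ], surv)
    r$pair_id <- pid
    r
  })
  tab <- do.call(rbind, recs)
  selected <- tab$pair_id[tab$estimable & tab$p < alpha]
  list(selected = selected, table = tab)
}

#' LASSO-penalized Cox selection
#'
#' L1-penalized Cox path over the screened pairs; lambda is chosen by k-fold
#' cross-validated partial-likelihood deviance at its minimum, with folds
#' stratified by event status and assigned from `seed` (the caller's RNG
#' state is untouched). Returns the pairs with nonzero coefficients at the
#' chosen lambda.
#'
#' @param pairs a `pair_matrix` restricted to screened pairs (>= 2 rows).
#' @param surv aligned survival data.frame.
#' @param n_folds cross-validation folds; default 10.
#' @param seed fold-assignment seed.
#' @param lambda optional fixed lambda overriding cross-validation (used for
#'   path diagnostics/limits).
#' @return list with `selected` pair ids, `lambda`, and `path` (lambda grid
#'   with number of nonzero coefficients).
#' @export
lasso_cox_select <- function(pairs, surv, n_folds = 10, seed = 1L,
                             lambda = NULL) {
  if (nrow(pairs) == 0) stop("no candidate pairs", call. = FALSE)
  if (nrow(pairs) < 2)
    stop("LASSO selection needs >= 2 screened pairs", call. = FALSE)
  x <- t(unclass(pairs))
  y <- survival::Surv(surv$time, surv$event)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1)
    cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y))
    return(list(selected = rownames(cf)[cf[, 1] != 0], lambda = lambda,
                path = NULL))
  }
  if (sum(surv$event) < n_folds)
    stop("need at least ", n_folds, " events for ", n_folds, "-fold CV",
         call. = FALSE)
  foldid <- integer(nrow(x))
  with_seed(seed, {
    for (grp in list(which(surv$event == 1), which(surv$event == 0))) {
      if (length(grp))
        foldid[grp] <- sample(rep_len(seq_len(n_folds), length(grp)))
    }
  })
  cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  list(selected = rownames(cf)[cf[, 1] != 0],
       lambda = cv$lambda.min,
       path = data.frame(lambda = cv$lambda, nonzero = cv$nzero,
                         cvm = cv$cvm, row.names = NULL))
}

#' Unpenalized multivariable Cox refit of the selected pairs
#'
#' The final signature: an ordinary Cox model (Efron ties) over the selected
#' pair indicators, reporting per-pair HR, 95% CI and Wald p.
#'
#' @param pairs a `pair_matrix` containing (at least) the selected pairs.
#' @param surv aligned survival data.frame.
#' @param selected pair ids to refit; default all rows of `pairs`.
#' @param cutoff optional risk-score cutoff to store (e.g. from
#'   [optimal_cutoff()] on the training ROC); `NA` leaves it unset.
#' @return a `signature_model` with provenance `"fitted"`.
#' @export
fit_final_model <- function(pairs, surv, selected = rownames(pairs),
                            cutoff = NA_real_) {
  if (length(selected) < 1) stop("no selected pairs to refit", call. = FALSE)
  missing <- setdiff(selected, rownames(pairs))
  if (length(missing))
    stop("selected pair(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- t(unclass(pairs)[selected, , drop = FALSE])
  if (qr(cbind(1, x))$rank < ncol(x) + 1)
    stop("collinear pair indicators among: ",
         paste(selected, collapse = ", "), call. = FALSE)
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ x,
                         ties = "efron")
  cf <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  if (anyNA(cf))
    stop("collinear pair indicators among: ",
         paste(selected[is.na(cf)], collapse = ", "), call. = FALSE)
  tab <- unicox_record(selected, cf, unname(se))
  new_signature_model(selected, cf, tab, cutoff, "fitted")
}

#' The published three-pair colorectal-cancer signature
#'
#' The fixed model `risk = 0.39691 x C6orf15|PCSK1 - 0.74874 x CTSW|FABP4 +
#' 0.67854 x SPRR1B|PCSK1` with cutoff 0.703, hazard ratios, 95% CIs and
#' p-values attached verbatim as published. Pair orientations are honored as
#' written (they predate this package's canonical-orientation convention).
#' At construction the internal-consistency identities are checked:
#' `hr = exp(coef)` and `sqrt(ci_low * ci_high) = hr` (symmetric log-scale
#' interval) to 1e-3 relative.
#'
#' @return a `signature_model` with provenance `"published"`.
#' @export
published_signature <- function() {
  tab <- data.frame(
    pair_id = c("C6orf15|PCSK1", "CTSW|FABP4", "SPRR1B|PCSK1"),
    coef = c(0.39691, -0.74874, 0.67854),
    se = NA_real_,
    hr = c(1.48722, 0.47296, 1.97099),
    ci_low = c(0.93941, 0.29779, 1.24667),
    ci_high = c(2.35448, 0.75117, 3.11618),
    p = c(0.09039, 0.00151, 0.00369),
    estimable = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(abs(exp(tab$coef) / tab$hr - 1) < 1e-3),
            all(abs(sqrt(tab$ci_low * tab$ci_high) / tab$hr - 1) < 1e-3))
  new_signature_model(tab$pair_id, tab$coef, tab, cutoff = 0.703,
                      provenance = "published")
}

#' Risk score of a signature on pair indicators
#'
#' `score(sample) = sum_i coefficient_i * indicator_i(sample)`.
#'
#' @param model a `signature_model`.
#' @param pairs matrix with one row per model pair (extra rows allowed).
#' @return named numeric vector of per-sample scores.
#' @export
risk_score <- function(model, pairs) {
  missing <- setdiff(model$pairs, rownames(pairs))
  if (length(missing))
    stop("pair row(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  drop(model$coefficients %*% unclass(pairs)[model$pairs, , drop = FALSE])
}

#' Dichotomize risk scores at a cutoff
#'
#' `score > cutoff` is `"high"`; a score exactly at the cutoff is `"low"`
#' (deterministic boundary convention).
#'
#' @param scores numeric vector.
#' @param cutoff finite threshold.
#' @return factor with levels `high`, `low`, named like `scores`.
#' @export
assign_risk_groups <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  stats::setNames(factor(ifelse(scores > cutoff, "high", "low"),
                         levels = c("high", "low")), names(scores))
}
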