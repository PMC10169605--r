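tiefree_surv <- function(n, seed, lp = rep(0, n)) {
  simulate_survival(lp, baseline_hazard = 0.3, censor_rate = 0.1,
                    max_followup = Inf, seed = seed)
}

test_that("univariate Cox matches the partial-likelihood grid oracle", {
  # 6-sample tie-free toy
  surv <- data.frame(time = c(1.1, 2.3, 3.0, 4.2, 5.9, 7.5),
                     event = c(1, 1, 0, 1, 1, 0))
  ind <- c(1, 0, 1, 0, 1, 0)
  fit <- univariate_cox(ind, surv)
  oracle <- cox_coef_oracle(surv$time, surv$event, ind)
  expect_lt(abs(fit$coef - oracle), 1e-3)
  # and on random tie-free data up to 8 samples; datasets with a monotone
  # partial likelihood (separation) have no interior maximum and are skipped
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:8, 1)
    s <- tiefree_surv(n, seed + 50)
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2 || sum(s$event) == 0) next
    f <- suppressWarnings(univariate_cox(x, s))
    if (abs(f$coef) > 3) next
    expect_lt(abs(f$coef - cox_coef_oracle(s$time, s$event, x)), 1e-3)
  }
})

test_that("univariate Cox record satisfies the HR/CI identities", {
  set.seed(60)
  s <- tiefree_surv(80, 60)
  x <- rbinom(80, 1, 0.4)
  r <- univariate_cox(x, s)
  expect_equal(r$hr, exp(r$coef))
  expect_equal(r$ci_low, exp(r$coef - qnorm(0.975) * r$se))
  expect_equal(r$ci_high, exp(r$coef + qnorm(0.975) * r$se))
  expect_lt(abs(sqrt(r$ci_low * r$ci_high) / r$hr - 1), 1e-10)
  # null case: balanced exponential data -> hr near 1
  s0 <- tiefree_surv(4000, 61)
  x0 <- rep(0:1, 2000)
  expect_lt(abs(univariate_cox(x0, s0)$hr - 1), 0.15)
  # constant indicator flagged, zero events error
  expect_false(univariate_cox(rep(1, 80), s)$estimable)
  expect_error(univariate_cox(x, data.frame(time = s$time,
                                            event = rep(0, 80))), "events")
})

test_that("screen keeps pairs at p < alpha, in order; alpha = 1 keeps all", {
  set.seed(62)
  n <- 300
  ind1 <- rbinom(n, 1, 0.5)                       # prognostic
  s <- simulate_survival(1.2 * ind1, 0.3, 0.05, Inf, seed = 63)
  pm <- rbind(good = ind1, noise1 = rbinom(n, 1, 0.5),
              noise2 = rbinom(n, 1, 0.5), flat = rep(1, n))
  colnames(pm) <- paste0("s", 1:n)
  class(pm) <- c("pair_matrix", class(pm))
  res <- screen_pairs(pm, s, alpha = 0.05)
  expect_true("good" %in% res$selected)
  expect_identical(res$selected, res$table$pair_id[res$table$estimable &
                                                   res$table$p < 0.05])
  all_est <- screen_pairs(pm, s, alpha = 1)
  expect_identical(all_est$selected, c("good", "noise1", "noise2"))  # flat dropped
})

test_that("LASSO limits: full shrinkage empty, no shrinkage keeps both", {
  set.seed(64)
  n <- 200
  p1 <- rbinom(n, 1, 0.5); p2 <- rbinom(n, 1, 0.5)
  s <- simulate_survival(0.9 * p1 - 0.7 * p2, 0.3, 0.05, Inf, seed = 65)
  pm <- rbind(p1 = p1, p2 = p2)
  colnames(pm) <- paste0("s", 1:n)
  big <- lasso_cox_select(pm, s, lambda = 1e3)
  expect_length(big$selected, 0)
  none <- lasso_cox_select(pm, s, lambda = 1e-8)
  expect_setequal(none$selected, c("p1", "p2"))
  # path consistency spot-check: selection at mid lambda nested in lambda -> 0
  mid <- lasso_cox_select(pm, s, lambda = 0.05)
  expect_true(all(mid$selected %in% none$selected))
  expect_error(lasso_cox_select(pm[0, ], s), "no candidate")
})

test_that("cross-validated LASSO keeps a dominant planted pair, deterministically", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed + 70)
    n <- 500
    planted <- rbinom(n, 1, 0.5)
    pm <- rbind(planted = planted,
                matrix(rbinom(9 * n, 1, 0.5), 9, n,
                       dimnames = list(paste0("null", 1:9), NULL)))
    colnames(pm) <- paste0("s", 1:n)
    s <- simulate_survival(1.0 * planted, 0.3, 0.05, Inf, seed = seed + 80)
    sel <- lasso_cox_select(pm, s, seed = 99)
    if ("planted" %in% sel$selected) hits <- hits + 1
    if (seed == 1) {
      again <- lasso_cox_select(pm, s, seed = 99)
      expect_identical(sel$selected, again$selected)
      expect_equal(sel$lambda, again$lambda)
    }
  }
  expect_gte(hits, 4)
})

test_that("final refit: single pair equals univariate fit; collinearity errors", {
  set.seed(90)
  n <- 150
  p1 <- rbinom(n, 1, 0.5)
  s <- simulate_survival(0.8 * p1, 0.3, 0.05, Inf, seed = 91)
  pm <- rbind(p1 = p1)
  colnames(pm) <- paste0("s", 1:n)
  m <- fit_final_model(pm, s)
  u <- univariate_cox(p1, s)
  expect_equal(m$coefficients, u$coef, tolerance = 1e-8)
  expect_equal(m$table$hr, u$hr, tolerance = 1e-8)
  expect_identical(m$provenance, "fitted")
  # duplicated indicator is collinear
  pm2 <- rbind(p1 = p1, p1copy = p1)
  colnames(pm2) <- paste0("s", 1:n)
  expect_error(fit_final_model(pm2, s), "collinear")
  expect_error(fit_final_model(pm, s, selected = character(0)), "no selected")
  expect_error(fit_final_model(pm, s, selected = "zz"), "zz")
})

test_that("refit hazard ratios obey the CI identities on multi-pair models", {
  set.seed(92)
  n <- 400
  pm <- rbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.5),
              c = rbinom(n, 1, 0.6))
  colnames(pm) <- paste0("s", 1:n)
  s <- simulate_survival(0.7 * pm["a", ] - 0.6 * pm["b", ], 0.3, 0.05, Inf,
                         seed = 93)
  m <- fit_final_model(pm, s)
  expect_equal(m$table$hr, exp(m$table$coef))
  expect_true(all(abs(sqrt(m$table$ci_low * m$table$ci_high) /
                      m$table$hr - 1) < 1e-4))
})

test_that("published signature carries the fixed pairs, coefficients and cutoff", {
  m <- published_signature()
  expect_identical(m$pairs, c("C6orf15|PCSK1", "CTSW|FABP4", "SPRR1B|PCSK1"))
  expect_equal(m$coefficients, c(0.39691, -0.74874, 0.67854))
  expect_equal(m$cutoff, 0.703)
  expect_identical(m$provenance, "published")
  expect_equal(m$table$hr[m$table$pair_id == "CTSW|FABP4"], 0.47296)
  expect_lt(abs(sqrt(0.29779 * 0.75117) - 0.47296), 1e-4)
})

test_that("risk scoring is the stated linear form and groups split at the cutoff", {
  m <- published_signature()
  ind <- matrix(c(0, 0, 0,  1, 1, 1,  0, 1, 0), 3, 3,
                dimnames = list(m$pairs, c("zero", "ones", "mid")))
  sc <- risk_score(m, ind)
  expect_equal(unname(sc), c(0, 0.39691 - 0.74874 + 0.67854, -0.74874))
  # additivity over a partition of the coefficient vector
  m1 <- m; m1$pairs <- m$pairs[1]; m1$coefficients <- m$coefficients[1]
  m2 <- m; m2$pairs <- m$pairs[2:3]; m2$coefficients <- m$coefficients[2:3]
  expect_equal(risk_score(m1, ind) + risk_score(m2, ind), sc)
  expect_error(risk_score(m, ind[1:2, ]), "missing")

  g <- assign_risk_groups(c(a = 0.71, b = 0.703, c = 0.1), 0.703)
  expect_identical(as.character(g), c("high", "low", "low"))
  expect_error(assign_risk_groups(1:3, NA_real_), "finite")
})

test_that("model JSON round-trips through serialization", {
  m <- published_signature()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$pairs, m$pairs)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$cutoff, m$cutoff)
  expect_equal(m2$table$hr, m$table$hr)
  ones <- matrix(1, 3, 1, dimnames = list(m$pairs, "s"))
  expect_equal(risk_score(m2, ones), risk_score(m, ones))
})
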