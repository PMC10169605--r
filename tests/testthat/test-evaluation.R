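test_that("td-ROC equals the Mann-Whitney AUC when nothing is censored before t", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    sc <- round(rnorm(n), 1)                      # ties in scores
    time <- rexp(n, 0.2)
    surv <- data.frame(time = time, event = rep(1, n))
    t0 <- stats::median(time)
    roc <- time_dependent_roc(sc, surv, t0)[[1]]
    want <- mw_auc_oracle(sc[time <= t0], sc[time > t0])
    expect_equal(roc$auc, want, tolerance = 1e-12)
    # monotone staircase in the uncensored case
    expect_true(all(diff(roc$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$specificity) >= -1e-12))
    expect_true(roc$auc >= 0 && roc$auc <= 1)
  }
})

test_that("td-ROC: perfect separation gives AUC 1; transforms leave AUC alone", {
  time <- c(1, 2, 3, 10, 11, 12, 13)
  surv <- data.frame(time = time, event = rep(1, 7))
  sc <- c(9, 8, 7, 1, 2, 0.5, 1.5)               # events by t=5 score highest
  roc <- time_dependent_roc(sc, surv, 5)[[1]]
  expect_equal(roc$auc, 1)
  roc2 <- time_dependent_roc(exp(sc), surv, 5)[[1]]
  expect_equal(roc2$auc, roc$auc)
  expect_error(time_dependent_roc(sc, surv, 0.5), "no events")
})

test_that("td-ROC handles censoring via Kaplan-Meier weighting", {
  # strongly prognostic score with moderate censoring: AUC well above 0.5
  set.seed(8)
  n <- 400
  sc <- rnorm(n)
  surv <- simulate_survival(1.5 * sc, 0.2, censor_rate = 0.1,
                            max_followup = 8, seed = 9)
  roc <- time_dependent_roc(sc, surv, 4)[[1]]
  expect_gt(roc$auc, 0.75)
})

test_that("optimal cutoff maximizes Youden's J with smallest-threshold ties", {
  # hand-built 6-point score set; exhaustive J search as oracle
  sc <- c(0.1, 0.2, 0.35, 0.5, 0.7, 0.9)
  surv <- data.frame(time = c(9, 8, 10, 2, 1.5, 1), event = rep(1, 6))
  roc <- time_dependent_roc(sc, surv, 5)[[1]]
  j <- roc$sensitivity + roc$specificity - 1
  brute <- roc$thresholds[which(j == max(j))]
  expect_equal(optimal_cutoff(roc), min(brute))
  expect_equal(optimal_cutoff(roc), 0.35)   # separates events from survivors
  expect_equal(max(j), 1)
  # all-equal scores refuse a cutoff
  const_roc <- structure(list(thresholds = 1, sensitivity = 1,
                              specificity = 0, eval_time = 1, auc = 0.5),
                         class = "time_roc")
  expect_error(optimal_cutoff(const_roc), "degenerate")
})

test_that("log-rank matches the hand O-E/V oracle and survfit step values", {
  # 8-sample tie-free worked toy
  surv <- data.frame(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                     event = c(1, 1, 0, 1, 1, 0, 1, 1))
  grp <- c("a", "b", "a", "b", "a", "b", "a", "b")
  res <- km_logrank(surv, grp)
  expect_equal(res$logrank_stat, logrank_oracle(surv$time, surv$event, grp),
               tolerance = 1e-12)
  expect_equal(res$logrank_p,
               pchisq(res$logrank_stat, 1, lower.tail = FALSE))
  # product-limit hand check for group a: events at t=1 (n=4), 5 (2), 7 (1)
  expect_equal(res$curves$a$surv[res$curves$a$time == 1], 3 / 4)
  expect_equal(res$curves$a$surv[res$curves$a$time == 5], 3 / 4 * 1 / 2)
  expect_equal(res$curves$a$surv[res$curves$a$time == 7], 0)
  expect_true(all(vapply(res$curves, function(cv)
    all(diff(cv$surv) <= 1e-12) && all(cv$surv <= 1), TRUE)))

  # identical data relabeled into two identical groups: stat 0, p 1
  dbl <- data.frame(time = rep(surv$time, 2), event = rep(surv$event, 2))
  res0 <- km_logrank(dbl, rep(c("x", "y"), each = 8))
  expect_equal(res0$logrank_stat, 0, tolerance = 1e-12)
  expect_equal(res0$logrank_p, 1)
  expect_error(km_logrank(surv, rep("one", 8)), ">= 2")
})

test_that("log-rank separates an early-event group from a censored group", {
  set.seed(40)
  s1 <- simulate_survival(rep(1.5, 150), 0.4, 0, Inf, seed = 41)  # early events
  s2 <- data.frame(time = runif(150, 5, 10), event = 0)           # all censored
  surv <- rbind(s1, s2)
  res <- km_logrank(surv, rep(c("early", "censored"), each = 150))
  expect_lt(res$logrank_p, 0.01)
})

test_that("KM tracks the closed-form exponential survival curve", {
  s <- simulate_survival(rep(0, 2000), baseline_hazard = 0.5,
                         censor_rate = 0.2, max_followup = Inf, seed = 42)
  res <- km_logrank(rbind(s, s), rep(c("g1", "g2"), each = 2000))
  cv <- res$curves$g1
  at <- cv$time <= 4
  expect_lt(max(abs(cv$surv[at] - exp(-0.5 * cv$time[at]))), 0.05)
})

test_that("association tests: chi-square by hand, rank test on ties", {
  # 2x2 table [[20,10],[10,20]] -> chi-square 6.6667 without correction
  groups <- rep(c("high", "low"), each = 30)
  flag <- c(rep(c(TRUE, FALSE), c(20, 10)), rep(c(TRUE, FALSE), c(10, 20)))
  tab <- association_tests(groups, data.frame(metastatic = flag))
  expect_identical(tab$test, "chisq")
  expect_equal(tab$statistic, 20 / 3, tolerance = 1e-6)
  expect_equal(tab$p, pchisq(20 / 3, 1, lower.tail = FALSE), tolerance = 1e-6)

  # identical per-group value multisets -> rank test z = 0, p = 1 exactly
  vals <- c(50, 60, 70, 55, 65, 52, 62, 72, 57, 67)
  same <- data.frame(age = rep(vals, 2))
  tab2 <- association_tests(rep(c("high", "low"), each = 10), same)
  expect_identical(tab2$test, "ranksum")
  expect_equal(tab2$p, 1)
  one <- association_tests(rep(c("high", "low"), each = 4),
                           data.frame(v = rep(7.5, 8)))
  expect_true(is.na(one$p))   # constant field: no test possible

  # planted enrichment of metastasis in the high-risk group is detected
  set.seed(43)
  g <- rep(c("high", "low"), each = 200)
  met <- c(rbinom(200, 1, 0.35), rbinom(200, 1, 0.15)) == 1
  tab3 <- association_tests(g, data.frame(metastatic = met))
  expect_lt(tab3$p, 0.05)
})

test_that("infiltration-by-risk reports direction, rank p and Spearman rho", {
  set.seed(44)
  n <- 80
  risk <- rnorm(n)
  groups <- ifelse(risk > 0, "high", "low")
  sm <- rbind(coupled = risk * 2 + rnorm(n, sd = 0.3),
              anti = -risk + rnorm(n, sd = 0.3),
              flat = rep(1, n))
  colnames(sm) <- paste0("s", 1:n)
  res <- infiltration_by_risk(sm, groups, risk)
  expect_identical(res$direction[res$set == "coupled"], "up_in_high")
  expect_identical(res$direction[res$set == "anti"], "down_in_high")
  expect_gt(res$spearman_rho[res$set == "coupled"], 0.5)
  expect_lt(res$spearman_rho[res$set == "anti"], -0.5)
  expect_false(res$defined[res$set == "flat"])
  expect_true(all(res$p_ranksum[res$defined] < 0.01))
})
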