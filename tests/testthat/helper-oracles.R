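# Independent oracles used across the suite. Each is a direct transcription
# of the defining formula, kept free of any package internals.

# Cox log partial likelihood for a single covariate, tie-free data
# (Breslow = Efron = exact when no event times coincide).
cox_loglik_oracle <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

cox_coef_oracle <- function(time, event, x, interval = c(-6, 6)) {
  stats::optimize(cox_loglik_oracle, interval, time = time, event = event,
                  x = x, maximum = TRUE)$maximum
}

# ssGSEA score by position-by-position enumeration of the running sum.
ssgsea_oracle <- function(values, gene_ids, set, alpha) {
  G <- length(values)
  ord <- order(-values, seq_len(G))      # descending, stable
  inset <- gene_ids[ord] %in% set
  m <- sum(inset)
  rnk <- G - seq_len(G) + 1              # rank value at each position
  w_total <- sum(rnk[inset]^alpha)
  p_in <- p_out <- score <- 0
  for (i in seq_len(G)) {
    if (inset[i]) p_in <- p_in + rnk[i]^alpha / w_total
    else p_out <- p_out + 1 / (G - m)
    score <- score + p_in - p_out
  }
  score
}

# Two-group log-rank chi-square from the observed-minus-expected /
# hypergeometric-variance tables.
logrank_oracle <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  ut <- sort(unique(time[event == 1]))
  o_e <- v <- 0
  for (u in ut) {
    at <- time >= u
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & g1)
    o_e <- o_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_e^2 / v
}

# Mann-Whitney AUC with ties counted half.
mw_auc_oracle <- function(case_scores, control_scores) {
  cmp <- outer(case_scores, control_scores, ">") +
    0.5 * outer(case_scores, control_scores, "==")
  mean(cmp)
}

# A small, fast cohort configuration for module tests.
test_config <- function(...) {
  args <- list(n_genes = 300, n_samples = 200, frac_normal = 0.12,
               frac_metastatic = 0.2, n_immune_sets = 8, genes_per_set = 8,
               n_stromal_sets = 2, tumor_de_genes = 40,
               metastasis_de_genes = 30, n_overlap_genes = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
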