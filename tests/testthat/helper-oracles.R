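# Independent brute-force oracles used to cross-check the package's
# statistical engines. These deliberately re-derive each statistic from
# its definition (enumeration, hand loops) rather than calling the code
# paths they verify.

# Benjamini-Hochberg step-up q-values from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) q[i] <- min(sorted[i:m] * m / (i:m))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
# (no ties assumed); U counted for the first group
mw_exact_bruteforce <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(ix) {
    a <- all_v[ix]; b <- all_v[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  center <- n1 * n2 / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-12)
}

# Kaplan-Meier product-limit by hand
km_bruteforce <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- as.logical(events[ord])
  ut <- unique(times)
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# one-degree-of-freedom log-rank chi-square by the O/E/V table
logrank_bruteforce <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[as.logical(e1)], t2[as.logical(e2)])))
  o1 <- ex1 <- v <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & as.logical(e1)); d2 <- sum(t2 == tt & as.logical(e2))
    d <- d1 + d2
    o1 <- o1 + d1
    ex1 <- ex1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - ex1)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# GSEA running-sum enrichment score recomputed with an explicit O(N*|S|)
# loop over positions
es_bruteforce <- function(metric, in_set, weight_exponent = 1) {
  n <- length(metric)
  nh <- sum(in_set)
  nr <- sum(abs(metric[in_set])^weight_exponent)
  best <- 0
  p_hit <- p_miss <- 0
  run <- numeric(n)
  for (i in seq_len(n)) {
    if (in_set[i]) {
      p_hit <- p_hit + if (nr > 0) abs(metric[i])^weight_exponent / nr else 1 / nh
    } else {
      p_miss <- p_miss + 1 / (n - nh)
    }
    run[i] <- p_hit - p_miss
    if (abs(run[i]) > abs(best)) best <- run[i]
  }
  list(es = best, running_sum = run)
}

# four-parameter logistic curve
fourpl_curve <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

# small deterministic cohort for unit tests
tiny_cohort <- function(seed = 1, n = 120, genes = 60, clusters = 2,
                        de = 8, fc = 2, beta = NULL) {
  cfg <- synth_config(n_samples = n, n_genes = genes, n_clusters = clusters,
                      de_genes_per_cluster = de, de_log2fc = fc,
                      prognostic_genes = beta, seed = seed)
  generate_cohort(cfg)
}
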