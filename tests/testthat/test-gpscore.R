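test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  km1 <- km_estimate(5, FALSE)
  expect_equal(km1$surv, 1)
  # 5 subjects, one censored at 2.5: S(1)=4/5, S(2)=3/5, S(3)=2/5 * ... by hand
  t5 <- c(1, 2, 2.5, 3, 4); e5 <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  km5 <- km_estimate(t5, e5)
  expect_equal(km5$surv[km5$time == 1], 4/5)
  expect_equal(km5$surv[km5$time == 2], 4/5 * 3/4)
  expect_equal(km5$surv[km5$time == 3], 4/5 * 3/4 * 1/2)
  expect_equal(km5$surv[km5$time == 4], 0)
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("KM and log-rank agree with brute-force oracles on random inputs", {
  set.seed(67)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    t1 <- sample(1:12, n, replace = FALSE)
    e1 <- runif(n) < 0.7
    km <- km_estimate(t1, e1)
    oracle <- km_bruteforce(t1, e1)
    expect_equal(km$surv[match(oracle$time, km$time)], oracle$surv,
                 tolerance = 1e-12)
    m <- sample(3:10, 1)
    t2 <- sample(1:12, m, replace = FALSE) + 0.5
    e2 <- runif(m) < 0.7
    if (sum(e1) + sum(e2) == 0) next
    lr <- logrank_test(t1, e1, t2, e2)
    lo <- logrank_bruteforce(t1, e1, t2, e2)
    expect_equal(lr$chi2, lo$chi2, tolerance = 1e-9)
    expect_equal(lr$p, lo$p, tolerance = 1e-9)
  }
})

test_that("log-rank behaves at the extremes", {
  t1 <- c(1, 2, 3, 4); e1 <- c(TRUE, TRUE, FALSE, TRUE)
  lr_same <- logrank_test(t1, e1, t1 + 1e-9, e1)
  expect_lt(lr_same$chi2, 1e-6)
  expect_gt(lr_same$p, 0.99)
  # disjoint supports: all A events precede all B events
  ta <- 1:20; tb <- 101:120
  lr <- logrank_test(ta, rep(TRUE, 20), tb, rep(TRUE, 20))
  expect_lt(lr$p, 0.01)
  expect_error(logrank_test(1:3, rep(FALSE, 3), 4:6, rep(FALSE, 3)),
               "no observed events")
  # six-subject O/E hand check: A = {1,3,5} all events, B = {2,4,6} all events
  lr6 <- logrank_test(c(1, 3, 5), rep(TRUE, 3), c(2, 4, 6), rep(TRUE, 3))
  lo6 <- logrank_bruteforce(c(1, 3, 5), rep(TRUE, 3), c(2, 4, 6), rep(TRUE, 3))
  expect_equal(lr6$chi2, lo6$chi2, tolerance = 1e-9)
  expect_equal(unname(lr6$observed), c(3, 3))
})

test_that("gene prognosis direction follows the planted hazard sign", {
  beta <- c(G0001 = 1.5, G0002 = -1.5)
  coh <- tiny_cohort(seed = 71, n = 300, genes = 40, clusters = 1, de = 0,
                     beta = beta)
  bad <- gene_prognosis(coh$expr, coh$clinical, "G0001", n_tests = 40)
  expect_identical(bad$direction, "unfavorable")
  good <- gene_prognosis(coh$expr, coh$clinical, "G0002", n_tests = 40)
  expect_identical(good$direction, "favorable")
  # a constant gene cannot be scanned
  v <- coh$expr$values; v["G0003", ] <- 5
  m2 <- expression_matrix(v)
  expect_warning(ns <- gene_prognosis(m2, coh$clinical, "G0003"), "constant")
  expect_identical(ns$direction, "ns")
  # scan mode pays an extra Bonferroni factor for its cutoffs
  sc <- gene_prognosis(coh$expr, coh$clinical, "G0001", n_tests = 40,
                       cutoff = "scan")
  expect_lte(sc$p, bad$p + 1e-12)
  expect_identical(sc$direction, "unfavorable")
})

test_that("null genes are rarely significant under Bonferroni correction", {
  frac <- vapply(1:10, function(s) {
    coh <- tiny_cohort(seed = 600 + s, n = 80, genes = 40, clusters = 1, de = 0)
    pr <- gene_prognosis_all(coh$expr, coh$clinical)
    mean(pr$direction != "ns")
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("GPScore is the unfavorable fraction and flips with directions", {
  pr <- data.frame(gene = c("A", "B", "C", "D", "E"),
                   direction = c("unfavorable", "unfavorable", "unfavorable",
                                 "favorable", "ns"))
  g <- gpscore(c("A", "B", "C", "D", "E"), pr)
  expect_equal(g$score, 0.75)
  expect_equal(g$n_unfavorable, 3)
  expect_equal(g$n_favorable, 1)
  expect_equal(gpscore(c("A", "B"), pr)$score, 1.0)
  expect_equal(gpscore(c("A", "D"), pr)$score, 0.5)
  ns_only <- gpscore("E", pr)
  expect_true(ns_only$no_prognostic_genes)
  expect_true(is.na(ns_only$score))
  # direction flip complements the score
  pr_flip <- pr
  pr_flip$direction <- c("favorable", "favorable", "favorable",
                         "unfavorable", "ns")
  expect_equal(gpscore(pr$gene, pr_flip)$score,
               1 - gpscore(pr$gene, pr)$score)
})

test_that("random-set null matches the global unfavorable fraction", {
  set.seed(73)
  dirs <- sample(c("unfavorable", "favorable", "ns"), 400, TRUE,
                 prob = c(0.3, 0.2, 0.5))
  pr <- data.frame(gene = sprintf("g%03d", 1:400), direction = dirs)
  global <- sum(dirs == "unfavorable") /
    sum(dirs %in% c("unfavorable", "favorable"))
  nc <- null_calibration(pr, n_random = 50, size_range = c(50, 300), seed = 5)
  se <- nc$sd / sqrt(length(nc$scores))
  expect_lt(abs(nc$mean - global), 3 * se + 0.02)
  # same seed, same sets
  nc2 <- null_calibration(pr, n_random = 50, size_range = c(50, 300), seed = 5)
  expect_identical(nc$scores, nc2$scores)
  # degenerate all-unfavorable universe
  pr_u <- data.frame(gene = pr$gene, direction = "unfavorable")
  nc_u <- null_calibration(pr_u, n_random = 10, size_range = c(50, 100), seed = 1)
  expect_equal(nc_u$mean, 1); expect_equal(nc_u$sd, 0)
  expect_error(null_calibration(pr, size_range = c(50, 1000)), "universe")
})

test_that("cross-dataset score significance separates planted from null sets", {
  scores <- rbind(planted = c(0.95, 0.92, 0.97),
                  at_null = c(0.50, 0.52, 0.49))
  nulls <- c(0.50, 0.51, 0.50)
  res <- score_significance(scores, nulls)
  expect_lt(res$p[res$set == "planted"], 0.01)
  expect_gt(res$p[res$set == "at_null"], 0.5)
  # exactly-at-null scores give p = 1
  res2 <- score_significance(rbind(s = nulls), nulls)
  expect_equal(res2$p, 1)
  expect_error(score_significance(scores[, 1, drop = FALSE], nulls[1]),
               ">= 2 datasets")
})

test_that("shared-set counting matches brute-force intersections", {
  enr <- list(g1 = c("A", "B", "C"), g2 = c("A", "C"), g3 = c("A", "D"))
  out <- shared_sets(enr, k_min = 2)
  expect_identical(out$shared$set[1], "A")
  expect_equal(out$shared$n_genes[out$shared$set == "A"], 3)
  expect_equal(out$shared$n_genes[out$shared$set == "C"], 2)
  expect_false("B" %in% out$shared$set)
  pw <- out$pairwise
  expect_equal(pw$n_shared[pw$gene_a == "g1" & pw$gene_b == "g2"],
               length(intersect(enr$g1, enr$g2)))
  expect_equal(pw$n_shared[pw$gene_a == "g2" & pw$gene_b == "g3"], 1)
  # disjoint enrichments share nothing
  out2 <- shared_sets(list(a = "X", b = "Y"), k_min = 2)
  expect_equal(nrow(out2$shared), 0)
})

test_that("sample set scores are mean squared expression with Q1 highest", {
  v <- rbind(A = c(2, 1, 0.5, 1), B = c(0, 1, 0.5, 1))
  colnames(v) <- paste0("s", 1:4)
  v <- v / rowMeans(v)
  m <- expression_matrix(v, "fold_from_mean")
  sc <- sample_set_score(m, c("A", "B"))
  expect_equal(sc$score, colMeans(v^2), ignore_attr = TRUE)
  expect_identical(as.character(sc$quartile[which.max(sc$score)]), "Q1")
  expect_error(sample_set_score(m, "ZZ"), "no set gene")
  # constant scores degrade gracefully
  vc <- matrix(1, 2, 4, dimnames = list(c("A", "B"), paste0("s", 1:4)))
  mc <- expression_matrix(vc, "fold_from_mean")
  expect_warning(scc <- sample_set_score(mc, c("A", "B")), "degenerate")
  expect_true(all(is.na(scc$quartile)))
})

test_that("hazard-linked set scores stratify survival by quartile", {
  beta <- setNames(rep(1.2, 10), sprintf("G%04d", 1:10))
  coh <- tiny_cohort(seed = 79, n = 400, genes = 60, clusters = 1, de = 0,
                     beta = beta)
  fm <- normalize_fold_from_mean(coh$expr)
  sc <- sample_set_score(fm, names(beta))
  q1 <- sc$quartile == "Q1"; q4 <- sc$quartile == "Q4"
  lr <- logrank_test(coh$clinical$os_time[q1], coh$clinical$os_event[q1],
                     coh$clinical$os_time[q4], coh$clinical$os_event[q4])
  expect_lt(lr$p, 0.01)
  # Q1 (highest burden) has more deaths than expected
  expect_gt(lr$observed[1], lr$expected[1])
})
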