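test_that("landmark labels classify deaths, survivors and early censoring", {
  cl <- clinical_table(data.frame(
    sample_id = c("a", "b", "c", "d"),
    os_time = c(2000, 1000, 1000, 1825),
    os_event = c(FALSE, TRUE, FALSE, TRUE)))
  y <- landmark_labels(cl, landmark = 1825)
  expect_identical(unname(y), c(1L, 0L, NA_integer_, 1L))
})

test_that("candidate panel is the order-stable union of stratum DEGs", {
  expect_identical(select_model_genes(list(c("A", "B"), c("B", "C"))),
                   c("A", "B", "C"))
  expect_identical(select_model_genes(list(c("A", "B"), c("A", "B"))),
                   c("A", "B"))
  expect_error(select_model_genes(list(character(0), character(0))), "empty")
})

test_that("logistic prediction obeys closed-form limits", {
  mod <- structure(list(
    strata = list(
      amplified = list(y0 = 0, weights = c(G1 = 1), panel = "G1"),
      non_amplified = list(y0 = 0, weights = c(G1 = 0), panel = "G1")),
    panel = "G1", landmark = 1825, normalization = "fold_from_mean"),
    class = "survival_model")
  v <- matrix(c(1e-9, 1, 50), 1, dimnames = list("G1", c("s1", "s2", "s3")))
  m <- structure(list(values = v, norm_state = "fold_from_mean", dataset = NULL),
                 class = "expr_matrix")
  p <- predict_survival(mod, m, rep("amplified", 3))
  expect_equal(unname(p[1]), 0.5, tolerance = 1e-6)   # exp -> 0 gives p -> 0.5
  expect_equal(unname(p[2]), stats::plogis(1))
  expect_gt(unname(p[3]), 0.999)                      # exp -> Inf gives p -> 1
  # zero-weight stratum: p = 0.5 everywhere; unknown MYCN uses it
  p_unk <- predict_survival(mod, m, rep("unknown", 3))
  expect_equal(unname(p_unk), rep(0.5, 3))
  p_non <- predict_survival(mod, m, rep("non_amplified", 3))
  expect_identical(p_unk, p_non)
  # missing panel genes are named
  m2 <- m; rownames(m2$values) <- "G9"
  expect_error(predict_survival(mod, m2, rep("amplified", 3)), "G1")
})

test_that("risk bins partition [0,1] with the contiguous boundary convention", {
  expect_identical(as.character(stratify_risk(0.97)), ">95%")
  expect_identical(as.character(stratify_risk(0.50)), "40-60%")
  expect_identical(as.character(stratify_risk(0.82)), "60-80%")
  expect_identical(as.character(stratify_risk(c(0, 0.399, 0.4, 0.6, 0.85, 0.95, 1))),
                   c("<40%", "<40%", "40-60%", "60-80%", "85-95%", ">95%", ">95%"))
  expect_error(stratify_risk(1.2), "\\[0, 1\\]")
  expect_false(anyNA(stratify_risk(seq(0, 1, by = 0.001))))
})

test_that("rank-statistic AUC equals brute-force pair counting", {
  ev <- evaluate_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(ev$roc_auc, 1.0)
  set.seed(23)
  for (i in 1:10) {
    s <- runif(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- outer(s[y == 1], s[y == 0], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(evaluate_predictions(s, y)$roc_auc, mean(pairs))
  }
  set.seed(31)
  s <- runif(2000); y <- rbinom(2000, 1, 0.5)
  auc <- evaluate_predictions(s, y)$roc_auc
  expect_gt(auc, 0.45); expect_lt(auc, 0.55)
  expect_error(evaluate_predictions(runif(5), rep(1, 5)), "single class")
})

test_that("two-round training recovers planted prognostic genes", {
  genes <- sprintf("G%04d", 1:150)
  beta <- setNames(c(rep(2, 5), rep(-2, 5)), sprintf("G%04d", 101:110))
  cfg <- synth_config(n_samples = 500, n_genes = 150, prognostic_genes = beta,
                      seed = 11)
  coh <- generate_cohort(cfg)
  fm <- normalize_fold_from_mean(coh$expr)
  mod <- train_two_round(fm, coh$clinical, genes, seed = 11)
  expect_gte(length(intersect(names(beta), mod$panel)), 8)
  # round-2 panels are subsets of the candidates, never larger
  for (s in c("amplified", "non_amplified")) {
    expect_true(all(mod$strata[[s]]$panel %in% genes))
    expect_lte(length(mod$strata[[s]]$panel), length(genes))
    expect_true(all(mod$strata[[s]]$panel %in%
                      names(mod$strata[[s]]$round1_weights)))
  }
  # deterministic given the seed
  mod2 <- train_two_round(fm, coh$clinical, genes, seed = 11)
  expect_identical(mod$panel, mod2$panel)
  expect_equal(mod$strata$amplified$weights, mod2$strata$amplified$weights)

  # monotonicity: raising a positive-weight gene's expression never lowers p
  w <- mod$strata$non_amplified$weights
  gpos <- names(w)[which.max(w)]
  if (w[gpos] > 0) {
    m1 <- fm$values[mod$strata$non_amplified$panel, 1, drop = FALSE]
    base <- stats::plogis(mod$strata$non_amplified$y0 +
                            sum(w * m1[names(w), 1]))
    m1[gpos, 1] <- m1[gpos, 1] * 2
    up <- stats::plogis(mod$strata$non_amplified$y0 + sum(w * m1[names(w), 1]))
    expect_gte(up, base)
  }

  # JSON round trip preserves predictions
  f <- withr::local_tempfile(fileext = ".json")
  write_survival_model(mod, f)
  back <- read_survival_model(f)
  p1 <- predict_survival(mod, fm, coh$clinical$mycn)
  p2 <- predict_survival(back, fm, coh$clinical$mycn)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("training validates stratum sizes and outcome classes", {
  coh <- tiny_cohort(seed = 3, n = 40, genes = 20, clusters = 1, de = 0)
  fm <- normalize_fold_from_mean(coh$expr)
  cl <- coh$clinical
  cl$mycn <- rep("non_amplified", nrow(cl))  # empty amplified stratum
  expect_error(train_two_round(fm, cl, gene_ids(fm), seed = 1), "< 20")
})
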