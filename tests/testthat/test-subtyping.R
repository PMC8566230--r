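# --- HDBSCAN engine -------------------------------------------------------

make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(x = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("hdbscan separates well-spaced Gaussian blobs", {
  b <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), 60, sd = 0.4, seed = 2)
  cl <- hdbscan_cluster(dist(b$x), min_samples = 10, min_cluster_size = 20)
  expect_equal(cl$n_clusters, 3)
  expect_gt(adjusted_rand_index(cl$labels, b$labels), 0.95)
})

test_that("hdbscan never splits a single tight blob", {
  b <- make_blobs(rbind(c(0, 0)), 100, sd = 0.3, seed = 5)
  cl <- hdbscan_cluster(dist(b$x), min_samples = 10, min_cluster_size = 20)
  expect_lte(cl$n_clusters, 1)
  cl1 <- hdbscan_cluster(dist(b$x), min_samples = 10, min_cluster_size = 20,
                         allow_single_cluster = TRUE)
  expect_equal(cl1$n_clusters, 1)
})

test_that("hdbscan labels genuine outliers as noise", {
  b <- make_blobs(rbind(c(0, 0), c(8, 0)), 50, sd = 0.3, seed = 3)
  x <- rbind(b$x, c(4, 30))  # far outlier
  cl <- hdbscan_cluster(dist(x), min_samples = 5, min_cluster_size = 15)
  expect_equal(cl$n_clusters, 2)
  expect_identical(cl$labels[101], -1L)
})

# --- embedding + clustering ----------------------------------------------

test_that("embedding recovers planted clusters and tolerates permutation", {
  coh <- tiny_cohort(seed = 7, n = 240, genes = 80, clusters = 3, de = 12, fc = 2)
  fm <- normalize_fold_from_mean(coh$expr)
  cm <- embed_and_cluster(fm, n_neighbors = 20, min_samples = 15,
                          min_cluster_size = "auto", seed = 7)
  expect_gte(adjusted_rand_index(cm$labels, coh$truth$cluster), 0.9)

  # gene order must not change the result at all
  perm <- sample(nrow(fm$values))
  fm_g <- fm; fm_g$values <- fm$values[perm, , drop = FALSE]
  cm_g <- embed_and_cluster(fm_g, n_neighbors = 20, min_samples = 15,
                            min_cluster_size = "auto", seed = 7)
  expect_identical(cm$labels, cm_g$labels)

  # sample order: partition equivalent up to relabeling
  sperm <- sample(ncol(fm$values))
  fm_s <- fm; fm_s$values <- fm$values[, sperm, drop = FALSE]
  cm_s <- embed_and_cluster(fm_s, n_neighbors = 20, min_samples = 15,
                            min_cluster_size = "auto", seed = 7)
  expect_equal(adjusted_rand_index(cm_s$labels, cm$labels[sperm]), 1)
})

test_that("embedding refuses cohorts smaller than the minimum cluster size", {
  coh <- tiny_cohort(seed = 1, n = 30, genes = 20, clusters = 1, de = 0)
  fm <- normalize_fold_from_mean(coh$expr)
  expect_error(embed_and_cluster(fm, min_cluster_size = 100), "min_cluster_size")
  expect_error(embed_and_cluster(coh$expr), "fold-from-mean")
})

# --- cluster DEGs ---------------------------------------------------------

test_that("Mann-Whitney DEG engine matches the exact enumeration oracle", {
  # fully separated toy groups: U = 0, exact two-sided p = 0.1
  expect_equal(stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(mw_exact_bruteforce(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(11)
  for (i in 1:8) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(stats::wilcox.test(x, y)$p.value, mw_exact_bruteforce(x, y),
                 tolerance = 1e-12)
  }
})

test_that("DEG table reproduces a direct Mann-Whitney + BH computation", {
  coh <- tiny_cohort(seed = 13, n = 24, genes = 15, clusters = 2, de = 4, fc = 2)
  fm <- normalize_fold_from_mean(coh$expr)
  labels <- coh$truth$cluster
  degs <- call_cluster_degs(fm, labels)
  # independent recomputation
  v <- fm$values
  ps <- c()
  for (cl in 1:2) for (g in rownames(v)) {
    ps <- c(ps, stats::wilcox.test(v[g, labels == cl], v[g, labels != cl])$p.value)
  }
  expect_equal(degs$p, ps, tolerance = 1e-12)
  expect_equal(degs$q, bh_bruteforce(ps), tolerance = 1e-12)
  expect_true(all(degs$q >= degs$p - 1e-12))
  expect_identical(degs$direction, ifelse(degs$log2fc > 0, "up", "down"))
})

test_that("planted DEGs are recovered with calibrated effect sizes", {
  coh <- tiny_cohort(seed = 17, n = 600, genes = 60, clusters = 3, de = 6, fc = 2)
  fm <- normalize_fold_from_mean(coh$expr)
  degs <- call_cluster_degs(fm, coh$truth$cluster)
  planted <- coh$truth$de_genes[["1"]]
  hit <- degs[degs$cluster == 1 & degs$gene %in% planted, ]
  expect_true(all(hit$q < 0.05))
  # against the all-samples mean, a +2 log2 shift in a third of the cohort
  # appears as log2(4b / ((4b + b + b)/3)) = 1 exactly
  expect_true(all(hit$log2fc > 0.6 & hit$log2fc < 1.4))
})

test_that("DEG calling validates its inputs", {
  coh <- tiny_cohort(seed = 2, n = 30, genes = 10, clusters = 1, de = 0)
  fm <- normalize_fold_from_mean(coh$expr)
  expect_error(call_cluster_degs(fm, rep(1L, 30)), ">= 2 clusters")
  lab <- c(rep(1L, 28), 2L, 2L)
  expect_error(call_cluster_degs(fm, lab), "< 3 samples")
})

# --- cell-line cluster score ----------------------------------------------

test_that("cluster score is the signed sum of log2 expression", {
  degs <- data.frame(cluster = c(1, 1, 2), gene = c("A", "B", "C"),
                     log2fc = c(1, -1, 1), p = 0.001, q = 0.001,
                     direction = c("up", "down", "up"))
  s <- assign_cluster(c(A = 2, B = 1, C = 1), degs)
  expect_equal(unname(s$scores["1"]), 1)   # log2(2)*1 + log2(1)*(-1)
  s2 <- assign_cluster(c(A = 1, B = 4, C = 1), degs)
  expect_equal(unname(s2$scores["1"]), -2) # down gene, exp 4 -> -2
  # additivity over genes
  s3 <- assign_cluster(c(A = 2, B = 4, C = 1), degs)
  expect_equal(unname(s3$scores["1"]), 1 - 2)
  # antisymmetry under flipping all directions
  flipped <- degs
  flipped$direction <- ifelse(degs$direction == "up", "down", "up")
  ex <- c(A = 2, B = 4, C = 3)
  expect_equal(unname(assign_cluster(ex, flipped)$scores),
               -unname(assign_cluster(ex, degs)$scores))
  expect_error(assign_cluster(c(A = 0, B = 1, C = 1), degs), "> 0")
})

test_that("cell lines over-expressing one cluster's up-genes join it", {
  coh <- tiny_cohort(seed = 19, n = 300, genes = 60, clusters = 3, de = 6, fc = 2)
  fm <- normalize_fold_from_mean(coh$expr)
  degs <- call_cluster_degs(fm, coh$truth$cluster)
  up1 <- coh$truth$de_genes[["1"]]
  cell <- setNames(rep(1, nrow(fm$values)), rownames(fm$values))
  cell[up1] <- 4
  res <- assign_cluster(cell, degs)
  expect_identical(res$assigned, "1")
  # exact tie across clusters is reported as ambiguous
  res_tie <- assign_cluster(setNames(rep(1, nrow(fm$values)), rownames(fm$values)),
                            degs)
  expect_identical(res_tie$assigned, "ambiguous")
})
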