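#' Embed and cluster tumors on growth-factor gene expression
#'
#' UMAP embedding (correlation metric) of fold-from-mean expression passed
#' on the log2 scale, followed by HDBSCAN density clustering of the 2-D
#' embedding. Defaults mirror a cohort of ~1200 tumors (n_neighbors 50,
#' min_dist 0, min_samples 50, min_cluster_size 100); for smaller cohorts
#' `min_cluster_size = "auto"` scales as `max(10, n/12)`.
#'
#' @param m an [expression_matrix()] with `norm_state = "fold_from_mean"`.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param min_samples,min_cluster_size HDBSCAN parameters;
#'   `min_cluster_size = "auto"` uses `max(10, round(n/12))`.
#' @param seed RNG seed controlling the embedding.
#' @param log2_input take log2 of the fold values before embedding
#'   (default TRUE; raw fold ratios are right-skewed).
#' @return A `cluster_model`: list with `embedding` (n x 2), `labels`
#'   (integer per sample, `-1` = no cluster), and `params`.
#' @export
embed_and_cluster <- function(m, n_neighbors = 50, min_dist = 0,
                              min_samples = 50, min_cluster_size = 100,
                              seed = 42, log2_input = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$norm_state != "fold_from_mean")
    stop("embedding expects fold-from-mean normalized expression")
  n <- ncol(m$values)
  if (identical(min_cluster_size, "auto"))
    min_cluster_size <- max(10, round(n / 12))
  if (n < min_cluster_size)
    stop("fewer samples (", n, ") than min_cluster_size (", min_cluster_size, ")")
  x <- t(m$values)
  if (log2_input) {
    if (any(x <= 0)) stop("log2 input requires strictly positive fold values")
    x <- log2(x)
  }
  n_neighbors <- min(n_neighbors, n - 1)
  min_samples <- min(min_samples, n)
  # precomputed correlation distances keep the embedding invariant to gene order
  cd <- stats::as.dist(1 - stats::cor(t(x)))
  set.seed(seed)
  emb <- uwot::umap(cd, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_threads = 1, n_sgd_threads = 1)
  rownames(emb) <- sample_ids(m)
  cl <- hdbscan_cluster(stats::dist(emb), min_samples = min_samples,
                        min_cluster_size = min_cluster_size)
  structure(list(embedding = emb,
                 labels = setNames(cl$labels, sample_ids(m)),
                 params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                               metric = "correlation",
                               min_samples = min_samples,
                               min_cluster_size = min_cluster_size,
                               seed = seed, log2_input = log2_input)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  k <- length(setdiff(unique(x$labels), -1L))
  cat(sprintf("cluster_model: %d samples, %d cluster(s), %d noise\n",
              length(x$labels), k, sum(x$labels == -1L)))
  invisible(x)
}

#' Call per-cluster differentially expressed genes
#'
#' Each gene is tested cluster-vs-rest by a two-sided Mann-Whitney test
#' over the clustered samples (noise excluded); Benjamini-Hochberg
#' correction is applied over all (cluster, gene) tests. The log2 fold
#' change is computed against the mean over all clustered samples.
#'
#' @param m an [expression_matrix()] with `norm_state = "fold_from_mean"`.
#' @param labels integer labels per sample (`-1` = noise), as produced by
#'   [embed_and_cluster()].
#' @return A `deg_table` data.frame with columns `cluster`, `gene`,
#'   `log2fc`, `p`, `q`, `direction`.
#' @export
call_cluster_degs <- function(m, labels) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$norm_state != "fold_from_mean")
    stop("DEG calling expects fold-from-mean normalized expression")
  stopifnot(length(labels) == ncol(m$values))
  keep <- labels != -1L
  v <- m$values[, keep, drop = FALSE]
  lab <- labels[keep]
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) stop("need >= 2 clusters for DEG calling")
  sizes <- table(lab)
  if (any(sizes < 3))
    stop("cluster(s) with < 3 samples: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  overall_mean <- rowMeans(v)
  rows <- list()
  for (cl in clusters) {
    inc <- lab == cl
    pvals <- apply(v, 1, function(g)
      stats::wilcox.test(g[inc], g[!inc])$p.value)
    l2fc <- log2(rowMeans(v[, inc, drop = FALSE]) / overall_mean)
    rows[[as.character(cl)]] <- data.frame(
      cluster = cl, gene = rownames(v), log2fc = l2fc, p = pvals,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out$q <- adjust_pvalues(out$p, "bh_fdr")
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

# significant DEGs of one cluster, optionally capped at the top_n smallest q
significant_degs <- function(degs, cluster, q_max = 0.05, top_n = NULL) {
  d <- degs[degs$cluster == cluster & degs$q < q_max, , drop = FALSE]
  d <- d[order(d$q, d$p), , drop = FALSE]
  if (!is.null(top_n)) d <- utils::head(d, top_n)
  d
}

#' Assign a cell line to a tumor cluster by DEG score
#'
#' Score for cluster k: `S = sum(log2(exp_i) * c_i)` over cluster k's
#' significant DEGs, with `c_i = +1` for up-regulated and `-1` for
#' down-regulated genes; expression must be fold-from-mean normalized
#' against a reference panel. The cell line is assigned to the
#' highest-scoring cluster; exact ties are reported as `"ambiguous"`.
#'
#' @param cell_expr named numeric vector of normalized (fold-from-mean)
#'   expression for one sample; values must be > 0.
#' @param degs a `deg_table` from [call_cluster_degs()].
#' @param q_max significance cutoff defining each cluster's DEG list.
#' @param top_n optional cap on DEGs per cluster (smallest q first).
#' @return List with `scores` (named by cluster) and `assigned` (cluster
#'   label as character, or `"ambiguous"`).
#' @export
assign_cluster <- function(cell_expr, degs, q_max = 0.05, top_n = NULL) {
  stopifnot(is.numeric(cell_expr), !is.null(names(cell_expr)))
  clusters <- sort(unique(degs$cluster))
  scores <- setNames(numeric(length(clusters)), clusters)
  for (cl in clusters) {
    d <- significant_degs(degs, cl, q_max = q_max, top_n = top_n)
    if (nrow(d) == 0) { scores[as.character(cl)] <- NA_real_; next }
    missing <- setdiff(d$gene, names(cell_expr))
    if (length(missing))
      stop("DEG gene(s) absent from cell expression: ",
           paste(utils::head(missing, 5), collapse = ", "))
    ex <- cell_expr[d$gene]
    if (any(ex <= 0)) stop("expression must be > 0 to take log2")
    ci <- ifelse(d$direction == "up", 1, -1)
    scores[as.character(cl)] <- sum(log2(ex) * ci)
  }
  ok <- !is.na(scores)
  if (!any(ok)) stop("no cluster has significant DEGs to score against")
  best <- max(scores[ok])
  top <- names(scores)[ok & scores == best]
  list(scores = scores,
       assigned = if (length(top) == 1) top else "ambiguous",
       tied = top)
}
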