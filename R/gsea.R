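#' Rank genes by correlation with a target gene
#'
#' Pearson correlation of every other gene's expression with the target
#' gene across samples, sorted descending; ties broken lexicographically
#' by gene id for determinism. Zero-variance genes get metric 0 with a
#' warning.
#'
#' @param m an [expression_matrix()].
#' @param target_gene gene id present in the matrix.
#' @return A `ranked_list` data.frame with columns `gene`, `metric`.
#' @export
rank_by_correlation <- function(m, target_gene) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!target_gene %in% gene_ids(m)) stop("target gene not in matrix: ", target_gene)
  if (ncol(m$values) < 10) stop("need >= 10 samples for correlation ranking")
  target <- m$values[target_gene, ]
  others <- m$values[setdiff(gene_ids(m), target_gene), , drop = FALSE]
  r <- suppressWarnings(as.numeric(stats::cor(t(others), target)))
  if (anyNA(r)) {
    warning(sum(is.na(r)), " zero-variance gene(s) assigned metric 0")
    r[is.na(r)] <- 0
  }
  out <- data.frame(gene = rownames(others), metric = r,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted enrichment score of a gene set in a ranked list
#'
#' The weighted Kolmogorov-Smirnov-style running-sum statistic: walking
#' down the ranking, hits increment by `|metric|^w / sum(|metric|^w over
#' hits)` and misses decrement by `1 / (N - N_hits)`; ES is the running
#' sum's extremum by absolute value.
#'
#' @param ranked a `ranked_list` ([rank_by_correlation()]) or a
#'   data.frame with `gene` and `metric` ordered by decreasing metric.
#' @param gene_set character vector of gene ids.
#' @param weight_exponent metric weighting exponent (1 = the classic
#'   "weighted" scheme; 0 = unweighted KS).
#' @return List with `es` and `running_sum` (length N).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) stop("no gene-set member present in the ranking")
  es_running(ranked$metric, hit, weight_exponent)
}

# core running-sum computation on a hit indicator
es_running <- function(metric, hit, weight_exponent = 1) {
  n <- length(hit)
  n_hit <- sum(hit)
  if (n_hit == n) return(list(es = 1, running_sum = cumsum(rep(1 / n, n))))
  w <- abs(metric)^weight_exponent
  w_hit <- sum(w[hit])
  if (w_hit == 0) {          # all hit metrics zero: fall back to equal steps
    inc <- ifelse(hit, 1 / n_hit, 0)
  } else {
    inc <- ifelse(hit, w / w_hit, 0)
  }
  dec <- ifelse(hit, 0, 1 / (n - n_hit))
  run <- cumsum(inc - dec)
  list(es = run[which.max(abs(run))], running_sum = run)
}

#' Pre-ranked gene set enrichment with a gene-set permutation null
#'
#' For each set, the enrichment score is compared against `n_perm` random
#' same-size gene sets drawn from the ranking. NES divides ES by the mean
#' absolute null ES of the same sign; nominal p is the same-sign
#' empirical tail probability (with +1 smoothing); FDR q follows the
#' sign-stratified GSEA procedure over pooled normalized null scores,
#' made monotone within each sign class. Sets passing nominal p and FDR
#' thresholds are flagged and the top `top_n` by NES returned separately.
#'
#' @param ranked a `ranked_list`.
#' @param collection a [gene_set_collection()].
#' @param n_perm permutations per set size (>= 100).
#' @param seed RNG seed.
#' @param p_cut,fdr_cut significance thresholds (defaults 0.05 / 0.25).
#' @param top_n number of passing sets to return (by decreasing NES).
#' @param weight_exponent see [enrichment_score()].
#' @return List with `results` (all sets: `set`, `size`, `es`, `nes`,
#'   `p`, `fdr`, `leading_edge`, `selected`) and `top` (the filtered,
#'   NES-sorted head).
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, seed = 1,
                           p_cut = 0.05, fdr_cut = 0.25, top_n = 100,
                           weight_exponent = 1) {
  stopifnot(n_perm >= 100)
  n <- nrow(ranked)
  metric <- ranked$metric
  present <- lapply(collection, function(g) which(ranked$gene %in% g))
  sizes <- lengths(present)
  usable <- sizes >= 1 & sizes < n
  if (any(!usable))
    warning("skipping ", sum(!usable),
            " set(s) with no overlap or spanning the whole ranking")
  present <- present[usable]
  if (length(present) == 0) stop("no usable gene sets")

  es_at <- function(idx) {
    hit <- logical(n); hit[idx] <- TRUE
    es_running(metric, hit, weight_exponent)$es
  }
  obs <- vapply(present, es_at, numeric(1))
  lead <- vapply(seq_along(present), function(i) {
    hit <- logical(n); hit[present[[i]]] <- TRUE
    run <- es_running(metric, hit, weight_exponent)$running_sum
    pk <- which.max(abs(run))
    if (run[pk] >= 0) sum(hit[seq_len(pk)]) else sum(hit[pk:n])
  }, numeric(1))

  set.seed(seed)
  size_classes <- sort(unique(lengths(present)))
  null_by_size <- lapply(setNames(size_classes, size_classes), function(k)
    vapply(seq_len(n_perm), function(i) es_at(sample(n, k)), numeric(1)))

  nes <- numeric(length(obs)); pval <- numeric(length(obs))
  null_nes <- numeric(0)
  for (i in seq_along(obs)) {
    nul <- null_by_size[[as.character(length(present[[i]]))]]
    same <- if (obs[i] >= 0) nul[nul >= 0] else -nul[nul < 0]
    if (length(same) == 0) { nes[i] <- NA; pval[i] <- 1 / (1 + n_perm); next }
    denom <- mean(same)
    nes[i] <- obs[i] / denom
    pval[i] <- (1 + sum(same >= abs(obs[i]))) / (1 + length(same))
  }
  # pooled normalized null (each null ES scaled by its size class's
  # same-sign mean), for the sign-stratified FDR
  for (k in names(null_by_size)) {
    nul <- null_by_size[[k]]
    mp <- mean(nul[nul >= 0]); mn <- mean(-nul[nul < 0])
    scaled <- ifelse(nul >= 0, nul / mp, nul / mn)
    null_nes <- c(null_nes, scaled[is.finite(scaled)])
  }
  fdr <- vapply(seq_along(obs), function(i) {
    if (is.na(nes[i])) return(1)
    if (nes[i] >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes[i])
      den <- mean(nes[!is.na(nes) & nes >= 0] >= nes[i])
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes[i])
      den <- mean(nes[!is.na(nes) & nes < 0] <= nes[i])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  # enforce monotone FDR within each sign class: a stronger NES can never
  # have a larger q than a weaker one
  for (pos in c(TRUE, FALSE)) {
    idx <- which(!is.na(nes) & if (pos) nes >= 0 else nes < 0)
    if (length(idx) > 1) {
      ord <- idx[order(-abs(nes[idx]))]
      fdr[ord] <- rev(cummin(rev(fdr[ord])))  # step-up: strong sets never exceed weak
    }
  }

  res <- data.frame(set = names(present), size = lengths(present),
                    es = obs, nes = nes, p = pval, fdr = fdr,
                    leading_edge = lead,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$selected <- !is.na(res$nes) & res$p < p_cut & res$fdr < fdr_cut
  res <- res[order(-res$nes), , drop = FALSE]
  rownames(res) <- NULL
  list(results = res, top = utils::head(res[res$selected, , drop = FALSE], top_n))
}
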