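#' Kaplan-Meier product-limit survival estimate
#'
#' Product-limit curve for one group; censored observations leave the
#' risk set without producing a step. Backed by [survival::survfit()].
#'
#' @param times event/censoring times (>= 0).
#' @param events logical/0-1, TRUE when the death was observed.
#' @return A `km_curve` data.frame: `time`, `n_risk`, `n_event`, `surv`
#'   (one row per distinct observed time).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic via
#' [survival::survdiff()].
#'
#' @param time_a,event_a survival data of group A.
#' @param time_b,event_b survival data of group B.
#' @return List with `chi2`, `p`, and observed/expected event counts per
#'   group.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0)
    stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0)
    stop("no observed events in either group")
  time <- c(time_a, time_b)
  event <- as.integer(c(event_a, event_b))
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Prognostic direction of one gene
#'
#' Samples are split at the gene's median expression (or, in `"scan"`
#' mode, at the expression quantile 0.1-0.9 giving the smallest log-rank
#' p, with an extra Bonferroni factor for the number of cutoffs tried);
#' the high- and low-expression halves are compared by log-rank.
#' Direction is `"unfavorable"` when the high-expression group has worse
#' survival (more observed than expected deaths), `"favorable"` when
#' better, and `"ns"` when the Bonferroni-corrected p (factor `n_tests`)
#' is >= 0.05.
#'
#' @param m an [expression_matrix()].
#' @param clinical a [clinical_table()] covering the samples.
#' @param gene gene id.
#' @param n_tests Bonferroni correction factor (number of genes tested in
#'   the scan this call belongs to).
#' @param cutoff `"median"` (default) or `"scan"`.
#' @return A one-row data.frame: `gene`, `direction`, `p`, `p_adj`,
#'   `cutoff_quantile`.
#' @export
gene_prognosis <- function(m, clinical, gene, n_tests = 1,
                           cutoff = c("median", "scan")) {
  cutoff <- match.arg(cutoff)
  stopifnot(inherits(m, "expr_matrix"))
  cl <- align_clinical(m, clinical)
  if (nrow(cl) < 20) stop("need >= 20 samples for prognosis scanning")
  if (!gene %in% gene_ids(m)) stop("gene not in matrix: ", gene)
  x <- m$values[gene, ]
  ns_row <- function(msg) {
    warning("gene ", gene, ": ", msg)
    data.frame(gene = gene, direction = "ns", p = NA_real_, p_adj = NA_real_,
               cutoff_quantile = NA_real_, stringsAsFactors = FALSE)
  }
  if (stats::sd(x) == 0) return(ns_row("constant expression"))
  qs <- if (cutoff == "median") 0.5 else seq(0.1, 0.9, by = 0.1)
  best <- NULL
  for (qq in qs) {
    thr <- stats::quantile(x, qq)
    high <- x > thr
    if (sum(high) < 2 || sum(!high) < 2) next
    if (sum(cl$os_event) == 0) return(ns_row("no events"))
    lr <- logrank_test(cl$os_time[high], cl$os_event[high],
                       cl$os_time[!high], cl$os_event[!high])
    if (is.null(best) || lr$p < best$p)
      best <- list(p = lr$p, q = qq,
                   worse_high = lr$observed[1] > lr$expected[1])
  }
  if (is.null(best)) return(ns_row("degenerate expression split"))
  m_corr <- if (cutoff == "median") n_tests else n_tests * length(qs)
  p_adj <- min(1, best$p * m_corr)
  dir <- if (p_adj >= 0.05) "ns" else if (best$worse_high) "unfavorable" else "favorable"
  data.frame(gene = gene, direction = dir, p = best$p, p_adj = p_adj,
             cutoff_quantile = best$q, stringsAsFactors = FALSE)
}

#' Prognostic directions for a panel of genes
#'
#' Runs [gene_prognosis()] for every gene with Bonferroni factor equal to
#' the number of genes tested.
#'
#' @inheritParams gene_prognosis
#' @param genes gene ids (default: all genes of the matrix).
#' @return data.frame, one row per gene.
#' @export
gene_prognosis_all <- function(m, clinical, genes = gene_ids(m),
                               cutoff = "median") {
  out <- do.call(rbind, lapply(genes, function(g)
    suppressWarnings(gene_prognosis(m, clinical, g, n_tests = length(genes),
                                    cutoff = cutoff))))
  rownames(out) <- NULL
  out
}

#' Gene-set prognostic score (GPScore)
#'
#' `GPScore = Nu / (Nu + Nf)`: among a set's members with a significant
#' prognostic direction, the fraction whose high expression associates
#' with unfavorable survival. Sets with no prognostic members are flagged
#' and carry an NA score.
#'
#' @param set_genes character vector of member gene ids.
#' @param prognoses data.frame from [gene_prognosis_all()].
#' @return List with `n_unfavorable`, `n_favorable`, `score`, and
#'   `no_prognostic_genes` flag.
#' @export
gpscore <- function(set_genes, prognoses) {
  d <- prognoses[prognoses$gene %in% set_genes, , drop = FALSE]
  nu <- sum(d$direction == "unfavorable")
  nf <- sum(d$direction == "favorable")
  list(n_unfavorable = nu, n_favorable = nf,
       score = if (nu + nf > 0) nu / (nu + nf) else NA_real_,
       no_prognostic_genes = nu + nf == 0)
}

#' Random-gene-set null calibration for GPScore
#'
#' Scores `n_random` gene sets drawn uniformly without replacement from
#' the measured gene universe, with sizes uniform on `size_range`, and
#' summarizes their GPScores by mean, SD and the mean +/- 3 SD interval.
#' Sets without prognostic members are excluded from the summary.
#'
#' @param prognoses data.frame from [gene_prognosis_all()] over the full
#'   gene universe.
#' @param n_random number of random sets (default 20).
#' @param size_range integer range of set sizes (default 50-1000).
#' @param seed RNG seed.
#' @return List with `scores`, `mean`, `sd`, `interval` (mean +/- 3 SD).
#' @export
null_calibration <- function(prognoses, n_random = 20,
                             size_range = c(50, 1000), seed = 1) {
  universe <- prognoses$gene
  if (size_range[2] > length(universe))
    stop("size_range exceeds the gene universe (", length(universe), " genes)")
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_random, replace = TRUE)
  scores <- vapply(sizes, function(k)
    gpscore(sample(universe, k), prognoses)$score, numeric(1))
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no random set had prognostic members")
  mu <- mean(scores); sdv <- stats::sd(scores)
  if (length(scores) == 1) sdv <- 0
  list(scores = scores, mean = mu, sd = sdv,
       interval = c(lower = mu - 3 * sdv, upper = mu + 3 * sdv))
}

#' Cross-dataset significance of gene-set prognostic scores
#'
#' Each set's per-dataset GPScores are compared with the per-dataset
#' random-set mean scores by a two-sided one-sample t-test on the paired
#' differences, then BH-corrected across sets; significant at q < 0.01.
#'
#' @param score_matrix numeric matrix, sets x datasets, of GPScores.
#' @param null_means numeric vector of per-dataset random-set mean scores.
#' @return data.frame with `set`, `mean_score`, `mean_null`, `p`, `q`,
#'   `significant`.
#' @export
score_significance <- function(score_matrix, null_means) {
  stopifnot(is.matrix(score_matrix))
  if (ncol(score_matrix) < 2) stop("need >= 2 datasets per set")
  if (length(null_means) != ncol(score_matrix))
    stop("one null mean per dataset required")
  p <- apply(score_matrix, 1, function(s) {
    d <- s - null_means
    if (anyNA(d)) return(NA_real_)
    if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    stats::t.test(d)$p.value
  })
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- adjust_pvalues(p[ok], "bh_fdr")
  data.frame(set = rownames(score_matrix),
             mean_score = rowMeans(score_matrix),
             mean_null = mean(null_means),
             p = p, q = q, significant = !is.na(q) & q < 0.01,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene sets shared across per-gene enrichment results
#'
#' Annotates every enriched set with the number of query genes sharing
#' it, filters at `k_min`, and emits pairwise shared-set counts for
#' ribbon (Circos-style) plotting.
#'
#' @param per_gene_enriched named list: query gene -> character vector of
#'   enriched set names.
#' @param k_min minimum number of genes sharing a set (default 2).
#' @return List with `shared` (data.frame `set`, `n_genes`, `genes`) and
#'   `pairwise` (data.frame `gene_a`, `gene_b`, `n_shared`).
#' @export
shared_sets <- function(per_gene_enriched, k_min = 2) {
  stopifnot(is.list(per_gene_enriched), length(per_gene_enriched) >= 2)
  genes <- names(per_gene_enriched)
  all_sets <- unique(unlist(per_gene_enriched, use.names = FALSE))
  counts <- vapply(all_sets, function(s)
    sum(vapply(per_gene_enriched, function(e) s %in% e, logical(1))), integer(1))
  members <- vapply(all_sets, function(s)
    paste(genes[vapply(per_gene_enriched, function(e) s %in% e, logical(1))],
          collapse = ","), character(1))
  shared <- data.frame(set = all_sets, n_genes = counts, genes = members,
                       row.names = NULL, stringsAsFactors = FALSE)
  shared <- shared[shared$n_genes >= k_min, , drop = FALSE]
  shared <- shared[order(-shared$n_genes, shared$set), , drop = FALSE]
  pairs <- utils::combn(genes, 2)
  pairwise <- data.frame(
    gene_a = pairs[1, ], gene_b = pairs[2, ],
    n_shared = apply(pairs, 2, function(gp)
      length(intersect(per_gene_enriched[[gp[1]]], per_gene_enriched[[gp[2]]]))),
    stringsAsFactors = FALSE)
  list(shared = shared, pairwise = pairwise)
}

#' Per-sample gene-set score and quartile labels
#'
#' Score of a sample = mean over the set's genes of the squared
#' fold-from-mean expression value; the cohort is split into quartiles
#' Q1 (highest scores) to Q4 (lowest).
#'
#' @param m an [expression_matrix()] with `norm_state = "fold_from_mean"`.
#' @param set_genes member gene ids (>= 1 present in the matrix).
#' @return data.frame with `sample_id`, `score`, `quartile` (factor
#'   Q1-Q4; all-NA with a warning when scores are constant).
#' @export
sample_set_score <- function(m, set_genes) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$norm_state != "fold_from_mean")
    stop("set scoring expects fold-from-mean normalized expression")
  genes <- intersect(set_genes, gene_ids(m))
  if (length(genes) == 0) stop("no set gene present in the matrix")
  sc <- colMeans(m$values[genes, , drop = FALSE]^2)
  if (stats::sd(sc) == 0) {
    warning("all samples score identically; quartile split degenerate")
    qt <- factor(rep(NA, length(sc)), levels = c("Q1", "Q2", "Q3", "Q4"))
  } else {
    br <- stats::quantile(sc, c(0, 0.25, 0.5, 0.75, 1))
    qt <- cut(sc, breaks = unique(br), include.lowest = TRUE)
    # highest scores are Q1
    levels(qt) <- paste0("Q", rev(seq_along(levels(qt))))
    qt <- factor(as.character(qt), levels = c("Q1", "Q2", "Q3", "Q4"))
  }
  data.frame(sample_id = sample_ids(m), score = sc, quartile = qt,
             row.names = NULL, stringsAsFactors = FALSE)
}
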