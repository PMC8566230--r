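#' Pathway definition with activator/repressor roles
#'
#' A named pathway whose member genes carry an activator/repressor role
#' ARR in \{-1, -0.5, 0, 0.5, 1\}: positive for signal activators,
#' negative for repressors, 0 for ambivalent/neutral members. Membership
#' itself plays the role of the 0/1 pathway-assignment index. A pathway
#' whose members are all ambivalent cannot be scored and is flagged
#' unusable with a warning.
#'
#' @param name pathway name.
#' @param genes member gene ids (unique).
#' @param arr numeric roles, one per gene, in \{-1, -0.5, 0, 0.5, 1\}.
#' @return A `pathway_def`.
#' @export
pathway_def <- function(name, genes, arr) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("pathway ", name, ": duplicate member genes")
  if (length(arr) != length(genes)) stop("one ARR per gene required")
  if (!all(arr %in% c(-1, -0.5, 0, 0.5, 1)))
    stop("ARR values must be in {-1, -0.5, 0, 0.5, 1}")
  usable <- any(arr != 0)
  if (!usable)
    warning("pathway ", name, " has only ambivalent (ARR = 0) members; unusable")
  structure(list(name = name, genes = genes, arr = setNames(arr, genes),
                 usable = usable),
            class = "pathway_def")
}

#' Read pathway definitions from a 3-column TSV
#'
#' Columns: pathway name, gene, ARR. One row per pathway member.
#'
#' @param path file path (with header).
#' @return Named list of [pathway_def()] objects.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("pathway file needs columns: pathway, gene, arr")
  names(df)[1:3] <- c("pathway", "gene", "arr")
  out <- lapply(split(df, df$pathway), function(d)
    pathway_def(d$pathway[1], d$gene, as.numeric(d$arr)))
  out[unique(df$pathway)]
}

#' Case-to-normal expression ratios
#'
#' Per gene, the case sample's value divided by the mean over the control
#' group; a pseudocount of 1e-6 on both numerator and denominator keeps
#' ratios finite for zero expression.
#'
#' @param case_expr named numeric vector, one case sample's (quantile-
#'   normalized) expression.
#' @param control_expr numeric matrix genes x control samples (>= 3).
#' @param eps pseudocount (default 1e-6).
#' @return Named vector of positive ratios.
#' @export
compute_cnr <- function(case_expr, control_expr, eps = 1e-6) {
  if (is.null(dim(control_expr)) || ncol(control_expr) == 0)
    stop("empty control group")
  if (ncol(control_expr) < 3) stop("control group needs >= 3 samples")
  common <- intersect(names(case_expr), rownames(control_expr))
  if (length(common) == 0) stop("no genes shared between case and controls")
  (case_expr[common] + eps) / (rowMeans(control_expr[common, , drop = FALSE]) + eps)
}

#' Pathway activation level of one sample
#'
#' `PAL = sum(ARR_n * log2(CNR_n)) / sum(|ARR_n|)` over the pathway's
#' member genes: a role-weighted mean of log2 case-to-normal ratios.
#' Positive PAL means the pathway is activated in the case sample
#' relative to the control group.
#'
#' @param cnr named vector of case-to-normal ratios ([compute_cnr()]).
#' @param pw a [pathway_def()].
#' @return Numeric scalar.
#' @export
compute_pal <- function(cnr, pw) {
  stopifnot(inherits(pw, "pathway_def"))
  missing <- setdiff(pw$genes, names(cnr))
  if (length(missing))
    stop("pathway ", pw$name, ": gene(s) missing from CNR: ",
         paste(utils::head(missing, 5), collapse = ", "))
  denom <- sum(abs(pw$arr))
  if (denom == 0) stop("ambivalent-only pathway: ", pw$name)
  sum(pw$arr * log2(cnr[pw$genes])) / denom
}

#' Differential pathway activation between two phenotype groups
#'
#' Genes are prefiltered by a two-sided t-test (p < `prefilter_p`) between
#' the groups; PAL is then computed for every sample against the reference
#' group's mean over the surviving member genes, and the two groups'
#' PAL distributions are compared with an unpaired t-test, BH-corrected
#' across pathways. Positive differences mean activation in the case
#' group.
#'
#' @param m an [expression_matrix()] (quantile-normalized recommended).
#' @param case logical vector per sample; `TRUE` = case phenotype (poor
#'   response / metastatic), `FALSE` = reference (good response /
#'   localized).
#' @param pathways list of [pathway_def()] objects.
#' @param prefilter_p per-gene differential-expression threshold.
#' @return A `pal_result` data.frame: `pathway`, `pal_diff`, `t`, `p`,
#'   `q`, `n_genes_used`. Pathways with no usable genes after the
#'   prefilter carry NA statistics.
#' @export
differential_pal <- function(m, case, pathways, prefilter_p = 0.05) {
  stopifnot(inherits(m, "expr_matrix"), is.logical(case),
            length(case) == ncol(m$values))
  if (sum(case) < 3 || sum(!case) < 3) stop("both groups need >= 3 samples")
  v <- m$values
  tt <- row_welch_t(v[, case, drop = FALSE], v[, !case, drop = FALSE])
  surviving <- rownames(v)[tt$p < prefilter_p]
  if (length(surviving) == 0) {
    warning("no genes survive the differential-expression prefilter")
    return(structure(data.frame(pathway = character(0), pal_diff = numeric(0),
                                t = numeric(0), p = numeric(0), q = numeric(0),
                                n_genes_used = integer(0)),
                     class = c("pal_result", "data.frame")))
  }
  ref_mean <- rowMeans(v[, !case, drop = FALSE])
  rows <- lapply(pathways, function(pw) {
    keep <- pw$genes %in% surviving & pw$arr != 0
    if (!any(keep))
      return(data.frame(pathway = pw$name, pal_diff = NA_real_, t = NA_real_,
                        p = NA_real_, n_genes_used = 0L))
    g <- pw$genes[keep]; arr <- pw$arr[keep]
    logcnr <- log2((v[g, , drop = FALSE] + 1e-6) / (ref_mean[g] + 1e-6))
    pal <- as.numeric(crossprod(logcnr, arr)) / sum(abs(arr))
    tt2 <- stats::t.test(pal[case], pal[!case])
    data.frame(pathway = pw$name,
               pal_diff = mean(pal[case]) - mean(pal[!case]),
               t = unname(tt2$statistic), p = tt2$p.value,
               n_genes_used = length(g))
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- adjust_pvalues(out$p[ok], "bh_fdr")
  rownames(out) <- NULL
  class(out) <- c("pal_result", "data.frame")
  out
}

#' Two-contrast pathway association table
#'
#' Pairs each pathway's activation difference in the therapy-response
#' contrast with its difference in the metastasis contrast, sorted by
#' joint magnitude; the scatter of these pairs reproduces the usual
#' response-vs-metastasis pathway plot.
#'
#' @param contrast_response,contrast_metastasis `pal_result` tables over
#'   the same pathway universe.
#' @return data.frame with `pathway`, `pal_response`, `pal_metastasis`,
#'   `q_response`, `q_metastasis`, sorted by decreasing joint magnitude.
#' @export
association_table <- function(contrast_response, contrast_metastasis) {
  a <- contrast_response; b <- contrast_metastasis
  if (length(intersect(a$pathway, b$pathway)) == 0)
    stop("contrasts share no pathways")
  only <- c(setdiff(a$pathway, b$pathway), setdiff(b$pathway, a$pathway))
  if (length(only))
    stop("pathway(s) absent from one contrast: ",
         paste(utils::head(only, 5), collapse = ", "))
  i <- match(a$pathway, b$pathway)
  out <- data.frame(pathway = a$pathway,
                    pal_response = a$pal_diff,
                    pal_metastasis = b$pal_diff[i],
                    q_response = a$q, q_metastasis = b$q[i])
  out[order(-(out$pal_response^2 + out$pal_metastasis^2)), , drop = FALSE]
}
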