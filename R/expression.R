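#' Expression matrix container
#'
#' Holds a genes x samples matrix of non-negative, linear-scale expression
#' values (microarray intensities, TPM-like quantities) together with a
#' normalization-state flag and an optional per-sample dataset-of-origin
#' label used for per-dataset normalization of merged cohorts.
#'
#' @param values numeric matrix, genes as rows and samples as columns, with
#'   unique row and column names. All values must be finite and >= 0.
#' @param norm_state one of `"raw"`, `"fold_from_mean"`, `"quantile"`.
#' @param dataset optional character vector of dataset labels, one per
#'   sample. Required when samples from more than one source are merged.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, norm_state = c("raw", "fold_from_mean", "quantile"),
                              dataset = NULL) {
  norm_state <- match.arg(norm_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene (row) and sample (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (!is.null(dataset)) {
    if (length(dataset) != ncol(values))
      stop("`dataset` must have one label per sample")
    dataset <- as.character(dataset)
  }
  if (norm_state == "fold_from_mean") {
    gm <- if (is.null(dataset)) rowMeans(values) else NULL
    if (!is.null(gm) && any(abs(gm - 1) > 1e-9))
      stop("fold_from_mean state requires every gene mean to equal 1")
  }
  structure(list(values = values, norm_state = norm_state, dataset = dataset),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$norm_state))
  if (!is.null(x$dataset))
    cat("datasets:", paste(unique(x$dataset), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param m an `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Read an expression matrix from a tab-delimited file
#'
#' Expects genes as rows and samples as columns; the first column holds the
#' gene identifier.
#'
#' @param path file path.
#' @param norm_state normalization state of the stored values.
#' @param dataset optional single dataset label applied to all samples.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, norm_state = "raw", dataset = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  if (!is.null(dataset) && length(dataset) == 1)
    dataset <- rep(dataset, ncol(vals))
  expression_matrix(vals, norm_state = norm_state, dataset = dataset)
}

#' Write an expression matrix to a tab-delimited file
#' @param m an `expr_matrix`.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = gene_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize expression as fold change from the per-gene mean
#'
#' Each gene's values are divided by that gene's mean over all samples of
#' its dataset, so that after normalization every gene has mean 1 within a
#' dataset. This is the normalization used upstream of tumor subtyping and
#' the survival model.
#'
#' @param m an `expr_matrix` with `norm_state = "raw"`.
#' @return An `expr_matrix` with `norm_state = "fold_from_mean"`.
#' @export
normalize_fold_from_mean <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$norm_state != "raw")
    stop("fold-from-mean normalization expects raw input, got ", m$norm_state)
  v <- m$values
  groups <- if (is.null(m$dataset)) rep("all", ncol(v)) else m$dataset
  for (g in unique(groups)) {
    idx <- groups == g
    gm <- rowMeans(v[, idx, drop = FALSE])
    zero <- gm <= 0
    if (any(zero))
      stop("zero mean expression for gene(s): ",
           paste(utils::head(rownames(v)[zero], 5), collapse = ", "))
    v[, idx] <- v[, idx, drop = FALSE] / gm
  }
  out <- m
  out$values <- v
  out$norm_state <- "fold_from_mean"
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same empirical distribution,
#' the mean of the sorted columns; ties within a column receive the average
#' of the tied target values. Applied per dataset when a dataset label is
#' present. Delegates to [limma::normalizeQuantiles()].
#'
#' @param m an `expr_matrix` with `norm_state = "raw"`.
#' @return An `expr_matrix` with `norm_state = "quantile"`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$norm_state != "raw")
    stop("quantile normalization expects raw input, got ", m$norm_state)
  v <- m$values
  groups <- if (is.null(m$dataset)) rep("all", ncol(v)) else m$dataset
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) < 2) stop("quantile normalization needs >= 2 samples")
    v[, idx] <- limma::normalizeQuantiles(v[, idx, drop = FALSE], ties = TRUE)
  }
  out <- m
  out$values <- v
  out$norm_state <- "quantile"
  out
}

#' Merge expression datasets on their common genes
#'
#' Genes absent from any dataset are dropped (intersection semantics) and
#' the dropped count is reported; sample identifiers must be unique across
#' datasets. Normalization is intentionally not performed here: normalize
#' each dataset first (per-dataset semantics), then merge.
#'
#' @param mats named list of `expr_matrix` objects sharing a `norm_state`.
#' @return A single `expr_matrix` whose `dataset` field records the origin
#'   of each sample.
#' @export
merge_expression <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1)
  if (is.null(names(mats)) || any(names(mats) == ""))
    stop("`mats` must be a named list (dataset identifiers)")
  states <- unique(vapply(mats, function(m) m$norm_state, character(1)))
  if (length(states) != 1)
    stop("all datasets must share one norm_state, got: ",
         paste(states, collapse = ", "))
  common <- Reduce(intersect, lapply(mats, gene_ids))
  if (length(common) == 0) stop("no genes common to all datasets")
  n_all <- length(unique(unlist(lapply(mats, gene_ids))))
  if (n_all > length(common))
    message(sprintf("dropping %d gene(s) absent from some dataset; %d kept",
                    n_all - length(common), length(common)))
  vals <- do.call(cbind, lapply(mats, function(m) m$values[common, , drop = FALSE]))
  ds <- rep(names(mats), vapply(mats, function(m) ncol(m$values), integer(1)))
  if (anyDuplicated(colnames(vals))) stop("duplicate sample ids across datasets")
  expression_matrix(vals, norm_state = states, dataset = ds)
}
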