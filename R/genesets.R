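#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per tab-delimited line — set name,
#' description, then member genes. Duplicate genes within a set are
#' collapsed, order preserved.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: a named list of character vectors with
#'   a `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(f)))
    name <- f[1]
    if (name %in% names(sets)) stop("duplicate gene-set name: ", name)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop(sprintf("GMT line %d has no genes", i))
    sets[[name]] <- genes
    desc[name] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (unique set names, non-empty
#'   gene lists; duplicates within a set are collapsed).
#' @param descriptions optional named character vector of descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  sets <- lapply(sets, function(g) {
    g <- unique(as.character(g))
    if (length(g) == 0) stop("empty gene set")
    g
  })
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions[names(sets)],
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param gsc a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  desc <- attr(gsc, "descriptions")
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, if (is.null(desc)) "" else desc[[nm]], gsc[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s), sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}
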