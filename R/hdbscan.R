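#' HDBSCAN density-based hierarchical clustering
#'
#' Hierarchical DBSCAN over a distance matrix: per-point core distances
#' (distance to the `min_samples`-th nearest neighbour, counting the point
#' itself), mutual-reachability distances, a single-linkage hierarchy on
#' mutual reachability (equivalent to the minimum-spanning-tree hierarchy),
#' condensation of the dendrogram at `min_cluster_size`, and excess-of-mass
#' cluster selection by stability. Points never captured by a selected
#' cluster are labelled `-1` (noise).
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param min_samples neighbourhood size defining core distances.
#' @param min_cluster_size smallest cluster retained in the condensed tree.
#' @param allow_single_cluster permit the hierarchy root to be selected
#'   (default FALSE, matching the reference implementation).
#' @return List with `labels` (integer per point, `-1` = noise, clusters
#'   numbered by decreasing size), `n_clusters`, and `cluster_stability`.
#' @export
hdbscan_cluster <- function(d, min_samples = 5, min_cluster_size = 5,
                            allow_single_cluster = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need >= 2 points")
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
  if (min_samples > n) stop("min_samples exceeds number of points")

  core <- apply(dm, 1, function(r) sort(r, partial = min_samples)[min_samples])
  mreach <- pmax(dm, outer(core, core, pmax))
  diag(mreach) <- 0
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")

  # binary tree: leaves 1..n, internal node for merge row r is n + r
  n_int <- n - 1
  left <- integer(n_int); right <- integer(n_int)
  for (r in seq_len(n_int)) {
    m1 <- hc$merge[r, 1]; m2 <- hc$merge[r, 2]
    left[r] <- if (m1 < 0) -m1 else n + m1
    right[r] <- if (m2 < 0) -m2 else n + m2
  }
  size <- c(rep(1L, n), integer(n_int))
  for (r in seq_len(n_int)) size[n + r] <- size[left[r]] + size[right[r]]
  lambda_node <- 1 / pmax(hc$height, 1e-12)

  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (nd <= n) out <- c(out, nd)
      else stack <- c(stack, left[nd - n], right[nd - n])
    }
    out
  }

  # condensed tree: walk top-down; children >= min_cluster_size on both
  # sides open two new condensed clusters, smaller side falls out as
  # individual points at the split level
  root <- n + n_int
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_stab <- numeric(0)
  point_cluster <- rep(0L, n)   # condensed cluster each point fell out of
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1] <<- parent
    cl_birth[length(cl_birth) + 1] <<- birth
    cl_stab[length(cl_stab) + 1] <<- 0
    length(cl_parent)
  }
  root_cl <- new_cluster(0L, 0)
  stack_node <- root; stack_cl <- root_cl
  while (length(stack_node)) {
    i <- length(stack_node)
    node <- stack_node[i]; cl <- stack_cl[i]
    stack_node <- stack_node[-i]; stack_cl <- stack_cl[-i]
    if (node <= n) next
    r <- node - n
    lam <- lambda_node[r]
    ch <- c(left[r], right[r])
    big <- size[ch] >= min_cluster_size
    if (all(big)) {
      cl_stab[cl] <- cl_stab[cl] + sum(size[ch]) * (lam - cl_birth[cl])
      for (c2 in ch) {
        id <- new_cluster(cl, lam)
        stack_node <- c(stack_node, c2); stack_cl <- c(stack_cl, id)
      }
    } else {
      for (j in 1:2) {
        if (big[j]) {
          stack_node <- c(stack_node, ch[j]); stack_cl <- c(stack_cl, cl)
        } else {
          pts <- leaves_under(ch[j])
          point_cluster[pts] <- cl
          cl_stab[cl] <- cl_stab[cl] + length(pts) * (lam - cl_birth[cl])
        }
      }
    }
  }

  n_cl <- length(cl_parent)
  children <- split(seq_len(n_cl), factor(cl_parent, levels = seq_len(n_cl)))
  # excess-of-mass selection, bottom-up (clusters created parent-first)
  selected <- rep(FALSE, n_cl)
  subtree_stab <- numeric(n_cl)
  for (cl in rev(seq_len(n_cl))) {
    kids <- children[[cl]]
    child_sum <- if (length(kids)) sum(subtree_stab[kids]) else 0
    if ((cl != root_cl || allow_single_cluster) &&
        (length(kids) == 0 || cl_stab[cl] >= child_sum)) {
      selected[cl] <- TRUE
      subtree_stab[cl] <- cl_stab[cl]
    } else {
      subtree_stab[cl] <- max(cl_stab[cl], child_sum)
    }
  }
  # a selected ancestor absorbs its descendants
  final <- rep(FALSE, n_cl)
  anc_sel <- rep(0L, n_cl)  # nearest selected ancestor-or-self
  for (cl in seq_len(n_cl)) {
    par <- cl_parent[cl]
    up <- if (par > 0) anc_sel[par] else 0L
    if (up > 0) anc_sel[cl] <- up
    else if (selected[cl]) { anc_sel[cl] <- cl; final[cl] <- TRUE }
  }

  labels <- rep(-1L, n)
  mapped <- ifelse(point_cluster > 0, anc_sel[pmax(point_cluster, 1L)], 0L)
  keep <- mapped > 0
  labels[keep] <- mapped[keep]
  # renumber selected clusters 1..K by decreasing size
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
    ord <- ids[order(-sizes)]
    labels <- ifelse(labels > 0, match(labels, ord), -1L)
  }
  list(labels = labels,
       n_clusters = length(ids),
       cluster_stability = if (length(ids)) cl_stab[ord] else numeric(0))
}
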