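#' Configuration for synthetic neuroblastoma-like cohorts
#'
#' Defines the generating conditions for a cohort with planted expression
#' clusters, MYCN strata, prognostic genes and (optionally) pathway shifts.
#' Expression is multiplicative log-normal around per-gene baselines;
#' cluster-specific genes are shifted by `de_log2fc` log2 units; survival
#' follows a Weibull proportional-hazards model whose log hazard is shifted
#' by `sum(beta * log2 fold expression)` over the prognostic genes, with
#' independent uniform censoring.
#'
#' @param n_samples number of tumors.
#' @param n_genes number of genes.
#' @param n_clusters number of planted expression clusters.
#' @param frac_mycn_amp per-cluster probability of MYCN amplification.
#' @param de_genes_per_cluster genes up-shifted in each cluster.
#' @param de_log2fc planted cluster shift, log2 units.
#' @param prognostic_genes named numeric vector: gene -> log hazard ratio
#'   per unit of centered log2 expression. Names may be indices into the
#'   gene panel (`"G0005"` style ids are assigned as `sprintf("G%04d", i)`).
#' @param weibull_shape Weibull shape parameter (> 0).
#' @param baseline_scale Weibull scale at zero linear predictor, days.
#' @param censor_time_max upper bound of the uniform censoring time, days.
#' @param noise_sd_log2 SD of the per-measurement log2 noise.
#' @param gene_modules optional list of co-expression modules, each a list
#'   with `genes` (member ids) and `rho` (within-module correlation in
#'   \[0, 1\]): members share a latent per-sample "process activity" so
#'   that genes of one biological process rise and fall together.
#' @param base_mean_log2,base_sd_log2 distribution of per-gene baseline
#'   log2 expression levels.
#' @param seed RNG seed; identical configurations generate identical cohorts.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_samples = 600, n_genes = 300, n_clusters = 3,
                         frac_mycn_amp = NULL,
                         de_genes_per_cluster = 20, de_log2fc = 2,
                         prognostic_genes = NULL,
                         weibull_shape = 1.5, baseline_scale = 3000,
                         censor_time_max = 6000, noise_sd_log2 = 0.5,
                         gene_modules = NULL,
                         base_mean_log2 = 7, base_sd_log2 = 1.5,
                         seed = 1) {
  if (n_clusters < 1) stop("need >= 1 cluster")
  if (is.null(frac_mycn_amp))  # cluster 1 MYCN-enriched, last depleted
    frac_mycn_amp <- rep_len(c(0.48, 0.10, 0.01), n_clusters)
  if (length(frac_mycn_amp) == 1) frac_mycn_amp <- rep(frac_mycn_amp, n_clusters)
  if (length(frac_mycn_amp) != n_clusters)
    stop("frac_mycn_amp must have one value per cluster")
  if (any(frac_mycn_amp < 0 | frac_mycn_amp > 1))
    stop("frac_mycn_amp must lie in [0, 1]")
  if (de_genes_per_cluster * n_clusters > n_genes)
    stop("de_genes_per_cluster * n_clusters exceeds n_genes")
  if (weibull_shape <= 0) stop("weibull_shape must be > 0")
  if (!is.null(prognostic_genes)) {
    if (is.null(names(prognostic_genes)) || !is.numeric(prognostic_genes))
      stop("prognostic_genes must be a named numeric vector (gene -> beta)")
  }
  if (!is.null(gene_modules)) {
    for (md in gene_modules) {
      if (is.null(md$genes) || is.null(md$rho) || md$rho < 0 || md$rho > 1)
        stop("each gene module needs `genes` and `rho` in [0, 1]")
    }
  }
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_clusters = n_clusters, frac_mycn_amp = frac_mycn_amp,
                 de_genes_per_cluster = de_genes_per_cluster,
                 de_log2fc = de_log2fc, prognostic_genes = prognostic_genes,
                 weibull_shape = weibull_shape, baseline_scale = baseline_scale,
                 censor_time_max = censor_time_max,
                 noise_sd_log2 = noise_sd_log2, gene_modules = gene_modules,
                 base_mean_log2 = base_mean_log2, base_sd_log2 = base_sd_log2,
                 seed = seed),
            class = "synth_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param cfg a [synth_config()].
#' @return List with `expr` (raw-scale [expression_matrix()]), `clinical`
#'   (a [clinical_table()]), and `truth` (cluster labels, per-cluster DE
#'   genes, prognostic betas, seed).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; p <- cfg$n_genes; k <- cfg$n_clusters
  genes <- sprintf("G%04d", seq_len(p))
  samples <- sprintf("S%04d", seq_len(n))
  cluster <- sample(rep(seq_len(k), length.out = n))

  base <- stats::rnorm(p, cfg$base_mean_log2, cfg$base_sd_log2)
  log2x <- matrix(stats::rnorm(p * n, 0, cfg$noise_sd_log2), p, n) + base
  dimnames(log2x) <- list(genes, samples)
  # co-expression modules: members share a latent per-sample activity
  if (!is.null(cfg$gene_modules)) {
    for (md in cfg$gene_modules) {
      missing <- setdiff(md$genes, genes)
      if (length(missing))
        stop("module gene(s) outside panel: ", paste(missing, collapse = ", "))
      latent <- stats::rnorm(n, 0, cfg$noise_sd_log2)
      idx <- match(md$genes, genes)
      noise <- matrix(stats::rnorm(length(idx) * n, 0, cfg$noise_sd_log2),
                      length(idx), n)
      log2x[idx, ] <- base[idx] +
        sqrt(md$rho) * rep(latent, each = length(idx)) +
        sqrt(1 - md$rho) * noise
    }
  }
  if (cfg$de_genes_per_cluster > 0) {
    de_genes <- split(genes[seq_len(k * cfg$de_genes_per_cluster)],
                      rep(seq_len(k), each = cfg$de_genes_per_cluster))
    for (cl in seq_len(k)) {
      idx <- match(de_genes[[cl]], genes)
      log2x[idx, cluster == cl] <- log2x[idx, cluster == cl] + cfg$de_log2fc
    }
  } else de_genes <- list()
  vals <- 2^log2x

  # survival: Weibull PH, log hazard shifted by beta * centered log2 expression
  lp <- rep(0, n)
  if (!is.null(cfg$prognostic_genes)) {
    pg <- names(cfg$prognostic_genes)
    missing <- setdiff(pg, genes)
    if (length(missing))
      stop("prognostic gene(s) outside panel: ", paste(missing, collapse = ", "))
    x <- log2x[pg, , drop = FALSE]
    x <- x - rowMeans(x)
    lp <- as.numeric(crossprod(x, cfg$prognostic_genes))
  }
  t_event <- cfg$baseline_scale *
    (stats::rexp(n) / exp(lp))^(1 / cfg$weibull_shape)
  t_cens <- stats::runif(n, 0, cfg$censor_time_max)
  os_time <- pmin(t_event, t_cens)
  os_event <- t_event <= t_cens

  mycn <- ifelse(stats::runif(n) < cfg$frac_mycn_amp[cluster],
                 "amplified", "non_amplified")
  # descriptive-only clinical covariates, loosely tied to cluster identity
  met_prob <- seq(0.7, 0.3, length.out = k)[cluster]
  metastasis <- stats::runif(n) < met_prob
  poor_prob <- seq(0.45, 0.10, length.out = k)[cluster]
  response <- ifelse(stats::runif(n) < poor_prob, "poor", "good")
  stage_pool <- c("1", "2", "3", "4", "4S")
  inss <- vapply(cluster, function(cl) {
    w <- if (cl == 1) c(.05, .1, .2, .55, .1) else c(.25, .2, .2, .2, .15)
    sample(stage_pool, 1, prob = w)
  }, character(1))

  clinical <- clinical_table(data.frame(
    sample_id = samples, os_time = os_time, os_event = os_event,
    mycn = mycn, inss_stage = inss, metastasis = metastasis,
    response = response, stringsAsFactors = FALSE))

  list(expr = expression_matrix(vals, "raw"),
       clinical = clinical,
       truth = list(cluster = setNames(cluster, samples),
                    de_genes = de_genes,
                    prognostic_genes = cfg$prognostic_genes,
                    seed = cfg$seed))
}

#' Plant pathway activation shifts into a cohort
#'
#' Splits the samples into two phenotype groups and multiplies each pathway
#' member's expression in the shifted group by `2^(shift * ARR)`, so that
#' activators rise and repressors fall in proportion to their role weight.
#' Stands in for a curated activator/repressor pathway database.
#'
#' @param pathway_specs list of specs, each a list with `name`, `members`
#'   (data.frame with columns `gene`, `arr`), and `shift` (log2 units
#'   applied to the shifted group).
#' @param expr an [expression_matrix()] (raw scale).
#' @param groups optional logical vector per sample (`TRUE` = shifted
#'   group); drawn half/half at random when omitted.
#' @param seed RNG seed for the group draw.
#' @return List with `pathways` (list of [pathway_def()]), `groups`
#'   (logical per sample), and `expr` (shifted matrix).
#' @export
generate_pathway_db <- function(pathway_specs, expr, groups = NULL, seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"), length(pathway_specs) >= 1)
  n <- ncol(expr$values)
  if (is.null(groups)) {
    set.seed(seed)
    groups <- seq_len(n) %in% sample(n, floor(n / 2))
  }
  stopifnot(length(groups) == n, is.logical(groups))
  v <- expr$values
  pathways <- vector("list", length(pathway_specs))
  for (i in seq_along(pathway_specs)) {
    sp <- pathway_specs[[i]]
    missing <- setdiff(sp$members$gene, rownames(v))
    if (length(missing))
      stop("pathway ", sp$name, ": member gene(s) not in cohort: ",
           paste(missing, collapse = ", "))
    pathways[[i]] <- pathway_def(sp$name, sp$members$gene, sp$members$arr)
    if (sp$shift != 0) {
      fac <- 2^(sp$shift * sp$members$arr)
      v[sp$members$gene, groups] <- v[sp$members$gene, groups, drop = FALSE] * fac
    }
  }
  out <- expr
  out$values <- v
  list(pathways = pathways, groups = groups, expr = out)
}

#' Generate a Bliss-consistent dose-response viability grid
#'
#' Single-agent fractional inhibitions follow a four-parameter logistic
#' (top 1, bottom 0); combination inhibition equals the Bliss independence
#' expectation plus a constant planted excess and Gaussian noise, clipped
#' to \[0, 1\]. Default concentration series span up to each drug's IC50 so
#' the planted excess survives clipping.
#'
#' @param ic50_a,hill_a,ic50_b,hill_b single-agent curve parameters.
#' @param bliss_excess planted excess inhibition over independence in
#'   combination wells (fraction scale).
#' @param noise_sd Gaussian noise SD on inhibition fractions.
#' @param seed RNG seed.
#' @param conc_a,conc_b concentration series including 0; defaults
#'   `c(0, ic50/8, ic50/4, ic50/2, ic50)`.
#' @param n_replicates replicate grids.
#' @return A `dose_response_grid`: list with `conc_a`, `conc_b`, and
#'   `viability` array `[length(conc_a), length(conc_b), n_replicates]`.
#' @export
generate_dose_response <- function(ic50_a, hill_a, ic50_b, hill_b,
                                   bliss_excess = 0, noise_sd = 0, seed = 1,
                                   conc_a = NULL, conc_b = NULL,
                                   n_replicates = 1) {
  stopifnot(ic50_a > 0, ic50_b > 0, hill_a > 0, hill_b > 0)
  if (is.null(conc_a)) conc_a <- c(0, ic50_a / c(8, 4, 2, 1))
  if (is.null(conc_b)) conc_b <- c(0, ic50_b / c(8, 4, 2, 1))
  if (conc_a[1] != 0 || conc_b[1] != 0) stop("concentration series must include 0")
  if (is.unsorted(conc_a, strictly = TRUE) || is.unsorted(conc_b, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  set.seed(seed)
  f1 <- function(c, ic50, h) ifelse(c == 0, 0, c^h / (c^h + ic50^h))
  fa <- f1(conc_a, ic50_a, hill_a)
  fb <- f1(conc_b, ic50_b, hill_b)
  expected <- outer(fa, fb, function(x, y) x + y - x * y)
  viab <- array(NA_real_, c(length(conc_a), length(conc_b), n_replicates))
  for (r in seq_len(n_replicates)) {
    f <- expected
    combo <- outer(conc_a > 0, conc_b > 0, `&`)
    f[combo] <- f[combo] + bliss_excess
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    f <- pmin(pmax(f, 0), 1)
    f[1, 1] <- 0  # untreated control defines 100% viability
    viab[, , r] <- 1 - f
  }
  structure(list(conc_a = conc_a, conc_b = conc_b, viability = viab),
            class = "dose_response_grid")
}
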