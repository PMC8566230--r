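#' Landmark survival labels for model training
#'
#' The model predicts the probability of surviving past a landmark time:
#' `y = 1` for samples alive at or beyond the landmark (death afterwards
#' still counts as surviving the landmark), `y = 0` for deaths before it,
#' and `NA` for samples censored before the landmark (unusable for a
#' binary label; they are excluded from training and evaluation).
#'
#' @param clinical a [clinical_table()].
#' @param landmark landmark time in days (default 1825, i.e. 5 years).
#' @return Named integer vector (1, 0 or NA) keyed by sample id.
#' @export
landmark_labels <- function(clinical, landmark = 1825) {
  y <- ifelse(clinical$os_time >= landmark, 1L,
              ifelse(clinical$os_event, 0L, NA_integer_))
  setNames(y, clinical$sample_id)
}

#' Union of stratum-specific cluster DEGs as model candidates
#'
#' @param degs_by_stratum list of `deg_table`s (or character vectors of
#'   gene ids), one per MYCN stratum.
#' @param q_max significance cutoff when `deg_table`s are supplied.
#' @return Deduplicated, order-stable character vector of genes.
#' @export
select_model_genes <- function(degs_by_stratum, q_max = 0.05) {
  pull <- function(d) {
    if (is.character(d)) return(d)
    d$gene[d$q < q_max]
  }
  genes <- unique(unlist(lapply(degs_by_stratum, pull), use.names = FALSE))
  if (length(genes) == 0) stop("empty candidate gene union")
  genes
}

# one elastic-net logistic CV fit: mixing over l1_grid, strength over
# lambda_grid, joint minimum of 5-fold CV deviance; returns intercept,
# weights, and the chosen penalties (paper's alpha = glmnet's lambda,
# paper's l1 = glmnet's alpha)
fit_enet_cv <- function(x, y, l1_grid, lambda_grid, foldid) {
  best <- NULL
  for (mix in l1_grid) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = mix,
                            lambda = lambda_grid, foldid = foldid,
                            standardize = TRUE)
    i <- which.min(cv$cvm)
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      co <- as.numeric(stats::coef(cv$glmnet.fit, s = cv$lambda[i]))
      best <- list(cvm = cv$cvm[i], l1 = mix, alpha = cv$lambda[i],
                   y0 = co[1],
                   weights = setNames(co[-1], colnames(x)))
    }
  }
  best
}

f1_score <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the two-round MYCN-stratified elastic-net survival model
#'
#' Per MYCN stratum: samples are split 70/30 into train/test; round 1 fits
#' an elastic-net logistic model on all candidate genes with penalties
#' chosen by fivefold cross-validation on the training split; round 2
#' refits on the top-fraction of genes by absolute weight, the fraction
#' (10-50%) chosen to maximize F1 on the held-out 30%.
#'
#' @param expr an [expression_matrix()] with `norm_state =
#'   "fold_from_mean"` (expression enters the linear predictor on this
#'   linear fold scale).
#' @param clinical a [clinical_table()] covering the expression samples.
#' @param genes candidate gene panel (see [select_model_genes()]).
#' @param landmark landmark time defining the binary outcome, days.
#' @param test_fraction held-out fraction (default 0.3).
#' @param keep_fractions round-2 candidate fractions of genes kept.
#' @param l1_grid elastic-net mixing values tried.
#' @param lambda_grid penalty-strength values tried (log grid).
#' @param seed seed fixing the split and CV folds.
#' @return A `survival_model`: per-stratum intercept `y0`, named weights,
#'   penalties, kept fraction and panel, plus the merged panel, landmark
#'   and training metadata.
#' @export
train_two_round <- function(expr, clinical, genes, landmark = 1825,
                            test_fraction = 0.3,
                            keep_fractions = seq(0.1, 0.5, by = 0.1),
                            l1_grid = seq(0.1, 0.9, by = 0.1),
                            lambda_grid = 10^seq(-4, 0, length.out = 7),
                            seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$norm_state != "fold_from_mean")
    stop("model training expects fold-from-mean normalized expression")
  missing <- setdiff(genes, gene_ids(expr))
  if (length(missing))
    stop("candidate gene(s) missing from expression: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cl <- align_clinical(expr, clinical)
  y_all <- landmark_labels(cl, landmark)
  x_all <- t(expr$values[genes, , drop = FALSE])

  set.seed(seed)
  strata <- c("amplified", "non_amplified")
  models <- list()
  for (s in strata) {
    use <- cl$mycn == s & !is.na(y_all)
    if (sum(use) < 20)
      stop("stratum ", s, " has ", sum(use), " usable samples (< 20)")
    y <- y_all[use]
    if (length(unique(y)) < 2)
      stop("stratum ", s, " has a single outcome class")
    x <- x_all[use, , drop = FALSE]
    n <- length(y)
    # class-stratified 70/30 split so both splits see both outcomes
    test_idx <- unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, max(1, round(length(ix) * test_fraction)))))
    tr <- setdiff(seq_len(n), test_idx)
    foldid <- stats::ave(seq_along(tr), y[tr],
                         FUN = function(ix) sample(rep_len(1:5, length(ix))))
    r1 <- fit_enet_cv(x[tr, , drop = FALSE], y[tr], l1_grid, lambda_grid, foldid)
    ranked <- names(sort(abs(r1$weights), decreasing = TRUE))

    best <- NULL
    for (f in keep_fractions) {
      k <- min(length(genes), max(2, floor(f * length(genes))))
      panel <- ranked[seq_len(k)]
      r2 <- fit_enet_cv(x[tr, panel, drop = FALSE], y[tr],
                        l1_grid, lambda_grid, foldid)
      p_test <- stats::plogis(r2$y0 +
        as.numeric(x[test_idx, panel, drop = FALSE] %*% r2$weights))
      f1 <- f1_score(y[test_idx], as.integer(p_test >= 0.5))
      if (is.null(best) || f1 > best$f1) {
        best <- list(f1 = f1, fraction = f, panel = panel, fit = r2)
      }
    }
    models[[s]] <- list(y0 = best$fit$y0, weights = best$fit$weights,
                        alpha = best$fit$alpha, l1 = best$fit$l1,
                        panel = best$panel, keep_fraction = best$fraction,
                        test_f1 = best$f1, round1_weights = r1$weights,
                        n_train = length(tr), n_test = length(test_idx))
  }
  structure(list(strata = models,
                 panel = unique(c(models$amplified$panel,
                                  models$non_amplified$panel)),
                 candidate_genes = genes, landmark = landmark,
                 normalization = "fold_from_mean",
                 seed = seed, test_fraction = test_fraction),
            class = "survival_model")
}

#' @export
print.survival_model <- function(x, ...) {
  cat(sprintf("survival_model: %d-gene merged panel (amp %d, non-amp %d), landmark %d d\n",
              length(x$panel), length(x$strata$amplified$panel),
              length(x$strata$non_amplified$panel), x$landmark))
  invisible(x)
}

#' Predict survival probability from the stratified model
#'
#' `p = 1 / (1 + exp(-(y0 + sum(w_i * exp_i))))` with the parameters of
#' the sample's MYCN stratum; samples with unknown MYCN status use the
#' non-amplified parameters.
#'
#' @param model a `survival_model`.
#' @param expr an [expression_matrix()] normalized as in training.
#' @param mycn character vector per sample (`"amplified"`,
#'   `"non_amplified"` or `"unknown"`).
#' @return Named numeric vector of survival probabilities.
#' @export
predict_survival <- function(model, expr, mycn) {
  stopifnot(inherits(model, "survival_model"), inherits(expr, "expr_matrix"))
  if (expr$norm_state != model$normalization)
    stop("expression normalization (", expr$norm_state,
         ") differs from training (", model$normalization, ")")
  stopifnot(length(mycn) == ncol(expr$values))
  missing <- setdiff(model$panel, gene_ids(expr))
  if (length(missing))
    stop("panel gene(s) missing from expression: ",
         paste(missing, collapse = ", "))
  stratum <- ifelse(mycn == "amplified", "amplified", "non_amplified")
  p <- numeric(ncol(expr$values))
  for (s in unique(stratum)) {
    idx <- stratum == s
    fit <- model$strata[[s]]
    x <- t(expr$values[fit$panel, idx, drop = FALSE])
    p[idx] <- stats::plogis(fit$y0 + as.numeric(x %*% fit$weights))
  }
  setNames(p, sample_ids(expr))
}

#' Bin predicted survival probabilities into risk groups
#'
#' Contiguous bins `[0, 0.40) -> "<40%"`, `[0.40, 0.60) -> "40-60%"`,
#' `[0.60, 0.85) -> "60-80%"`, `[0.85, 0.95) -> "85-95%"`,
#' `[0.95, 1] -> ">95%"`.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return Factor of risk-group labels, ordered worst to best.
#' @export
stratify_risk <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  cut(p, breaks = c(-Inf, 0.40, 0.60, 0.85, 0.95, Inf), right = FALSE,
      labels = c("<40%", "40-60%", "60-80%", "85-95%", ">95%"))
}

#' Evaluate survival predictions against binary labels
#'
#' ROC AUC is computed by the rank (Mann-Whitney) statistic,
#' `U / (n1 * n0)`; the precision-recall curve sweeps every observed
#' score threshold; F1 is reported at the 0.5 threshold.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcomes (0/1), same length.
#' @return List with `roc_auc`, `pr_curve` (data.frame threshold,
#'   precision, recall), and `f1`.
#' @export
evaluate_predictions <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(labels) & !is.na(scores)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  pr <- do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    data.frame(threshold = t,
               precision = if (sum(pred) == 0) 1 else tp / sum(pred),
               recall = tp / n1)
  }))
  list(roc_auc = auc, pr_curve = pr,
       f1 = f1_score(labels, as.integer(scores >= 0.5)))
}

#' Serialize a survival model to JSON
#' @param model a `survival_model`.
#' @param path output path.
#' @export
write_survival_model <- function(model, path) {
  obj <- list(landmark = model$landmark, normalization = model$normalization,
              panel = model$panel,
              strata = lapply(model$strata, function(s)
                list(y0 = s$y0, weights = as.list(s$weights[s$panel]),
                     alpha = s$alpha, l1 = s$l1,
                     keep_fraction = s$keep_fraction)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a survival model from JSON
#' @param path JSON path written by [write_survival_model()].
#' @return A `survival_model` (prediction fields only).
#' @export
read_survival_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  strata <- lapply(obj$strata, function(s) {
    w <- unlist(s$weights)
    list(y0 = s$y0, weights = w, alpha = s$alpha, l1 = s$l1,
         panel = names(w), keep_fraction = s$keep_fraction)
  })
  structure(list(strata = strata, panel = unlist(obj$panel),
                 landmark = obj$landmark, normalization = obj$normalization),
            class = "survival_model")
}
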