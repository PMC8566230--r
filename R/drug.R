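#' Normalize raw viability signals to fractions
#'
#' `(raw - mean(blank)) / (mean(control) - mean(blank))`, where blank
#' wells hold growth medium without cells and control wells mock-treated
#' (DMSO) cells defining 100% viability. Values are clipped to
#' \[0, 1.5\]; clipping above 1 tolerates growth stimulation.
#'
#' @param raw_signals numeric vector/matrix of treated-well signals.
#' @param blank_signals blank-well signals.
#' @param control_signals mock-treated control signals.
#' @return Viability fractions with the shape of `raw_signals`.
#' @export
normalize_viability <- function(raw_signals, blank_signals, control_signals) {
  b <- mean(blank_signals); ctr <- mean(control_signals)
  if (ctr <= b) stop("control signal must exceed blank signal")
  v <- (raw_signals - b) / (ctr - b)
  if (any(v < 0)) warning(sum(v < 0), " signal(s) below blank clipped to 0")
  pmin(pmax(v, 0), 1.5)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' `v(c) = bottom + (top - bottom) / (1 + (c/IC50)^hill)`, fitted on
#' log-concentration. A least-squares fit ([minpack.lm::nlsLM()])
#' initializes a robust refit minimizing the soft-L1 (pseudo-Huber) loss,
#' which bounds the influence of outlying wells. Zero-dose wells are
#' excluded from the fit.
#'
#' @param conc concentrations (>= 5 positive values spanning the
#'   transition).
#' @param viability viability fractions, same length.
#' @param robust use the soft-L1 loss (default TRUE); FALSE gives the
#'   plain least-squares fit.
#' @param delta soft-L1 scale in viability units (default 0.05).
#' @return A `fourpl_fit`: `top`, `bottom`, `ic50`, `hill`, `fitted`,
#'   `residuals`, `converged`.
#' @export
fit_ic50 <- function(conc, viability, robust = TRUE, delta = 0.05) {
  stopifnot(length(conc) == length(viability))
  keep <- conc > 0
  conc <- conc[keep]; viability <- viability[keep]
  if (length(unique(conc)) < 5)
    stop("need >= 5 distinct positive concentrations")
  lc <- log(conc)
  # parameters: top, span = top - bottom (>= 0), log_ic50, hill (> 0)
  mid <- (max(viability) + min(viability)) / 2
  start <- c(top = max(viability), span = max(viability) - min(viability),
             log_ic50 = lc[which.min(abs(viability - mid))], hill = 1)
  ls_fit <- tryCatch(
    minpack.lm::nlsLM(
      viability ~ (top - span) + span / (1 + exp(hill * (lc - log_ic50))),
      start = as.list(start),
      lower = c(top = -0.5, span = 0, log_ic50 = min(lc) - 5, hill = 0.05),
      upper = c(top = 2, span = 2.5, log_ic50 = max(lc) + 5, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  par0 <- if (!is.null(ls_fit)) stats::coef(ls_fit) else start
  predict_par <- function(par, x)
    (par[1] - par[2]) + par[2] / (1 + exp(par[4] * (x - par[3])))
  if (robust) {
    obj <- function(par) {
      r <- viability - predict_par(par, lc)
      sum(2 * delta^2 * (sqrt(1 + (r / delta)^2) - 1))
    }
    opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                        lower = c(-0.5, 0, min(lc) - 5, 0.05),
                        upper = c(2, 2.5, max(lc) + 5, 20),
                        control = list(maxit = 500))
    if (opt$convergence != 0 && is.null(ls_fit))
      stop("4PL fit did not converge: optim code ", opt$convergence,
           " (", opt$message, ")")
    par <- opt$par
  } else {
    if (is.null(ls_fit)) stop("4PL least-squares fit did not converge")
    par <- par0
  }
  fitted <- predict_par(par, lc)
  structure(list(top = unname(par[1]), bottom = unname(par[1] - par[2]),
                 ic50 = exp(unname(par[3])), hill = unname(par[4]),
                 fitted = fitted, residuals = viability - fitted,
                 conc = conc, robust = robust,
                 converged = if (robust) TRUE else !is.null(ls_fit)),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g (%s)\n",
              x$ic50, x$hill, x$top, x$bottom,
              if (x$robust) "soft-L1" else "least squares"))
  invisible(x)
}

#' Predicted viability of a fitted 4PL curve
#' @param object a `fourpl_fit`.
#' @param newconc concentrations.
#' @param ... unused.
#' @return Predicted viability fractions.
#' @export
predict.fourpl_fit <- function(object, newconc, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (newconc / object$ic50)^object$hill)
}

#' Bliss synergy score of a dose-response grid
#'
#' With fractional inhibition `f = 1 - viability`, Bliss independence
#' expects `f_ab = f_a + f_b - f_a*f_b` for the drug combination; the
#' synergy score is `100 * mean(observed - expected)` over the
#' combination wells (both doses > 0). Replicates are averaged first.
#'
#' @param grid a `dose_response_grid` (see [generate_dose_response()]):
#'   list with `conc_a`, `conc_b` (each including 0) and `viability`
#'   (matrix or 3-d array with replicates).
#' @return List with `excess` (matrix, NA on single-agent margins),
#'   `mean_score` (x100 scale), and `max_excess`.
#' @export
bliss_synergy <- function(grid) {
  v <- grid$viability
  if (length(dim(v)) == 3) v <- apply(v, c(1, 2), mean)
  if (grid$conc_a[1] != 0 || grid$conc_b[1] != 0)
    stop("single-agent rows/columns (dose 0) are required")
  f <- 1 - v
  fa <- f[, 1]; fb <- f[1, ]
  expected <- outer(fa, fb, function(x, y) x + y - x * y)
  excess <- f - expected
  combo <- outer(grid$conc_a > 0, grid$conc_b > 0, `&`)
  excess[!combo] <- NA
  list(excess = excess,
       mean_score = 100 * mean(excess[combo]),
       max_excess = 100 * max(excess[combo]))
}

#' Growth-factor protection against drug treatment
#'
#' Per cell line, the viability fold change conferred by a growth factor
#' under drug treatment, `viab(drug+GF) / viab(drug)`, compared with the
#' corresponding DMSO fold change `viab(DMSO+GF) / viab(DMSO)` across
#' cell lines by a Friedman test (blocks = cell lines, treatments =
#' drug-fold vs DMSO-fold).
#'
#' @param viab data.frame with one row per cell line and columns
#'   `cell_line`, `drug_gf`, `drug`, `dmso_gf`, `dmso` (mean viabilities).
#' @return List with `folds` (data.frame `cell_line`, `fold_drug`,
#'   `fold_dmso`), `statistic`, `p`.
#' @export
gf_protection <- function(viab) {
  need <- c("cell_line", "drug_gf", "drug", "dmso_gf", "dmso")
  miss <- setdiff(need, names(viab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(viab) < 3) stop("need >= 3 cell lines")
  if (anyNA(viab[need])) stop("missing measurements (check the DMSO arm)")
  folds <- data.frame(cell_line = viab$cell_line,
                      fold_drug = viab$drug_gf / viab$drug,
                      fold_dmso = viab$dmso_gf / viab$dmso)
  ft <- stats::friedman.test(as.matrix(folds[, c("fold_drug", "fold_dmso")]))
  list(folds = folds, statistic = unname(ft$statistic), p = ft$p.value)
}
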