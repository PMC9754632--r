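#' Evaluate the four-parameter Hill inhibition model
#'
#' \deqn{Y(X) = Bottom + \frac{Top - Bottom}{1 + (IC_{50}/X)^{HillSlope}}.}
#' The printed form is undefined at `X = 0`; the analytic limit is used
#' there (`Top` for negative slopes, `Bottom` for positive slopes), so
#' zero-dose controls participate in fits.
#'
#' @param X Concentration(s), uM, `>= 0`.
#' @param params List or `dose_response_fit` with `Top`, `Bottom`, `IC50`,
#'   `HillSlope` (`IC50 > 0`, `HillSlope != 0`).
#' @return Response value(s).
#' @examples
#' hill_eval(30, list(Top = 22, Bottom = 2, IC50 = 10, HillSlope = 1))  # 17
#' @export
hill_eval <- function(X, params) {
  p <- params
  if (!all(c("Top", "Bottom", "IC50", "HillSlope") %in% names(p)))
    stop("params must supply Top, Bottom, IC50, HillSlope")
  if (p$HillSlope == 0) stop("degenerate Hill model: HillSlope must be nonzero")
  if (p$IC50 <= 0) stop("IC50 must be positive")
  if (any(X < 0)) stop("concentrations must be >= 0")
  out <- numeric(length(X))
  zero <- X == 0
  out[zero] <- if (p$HillSlope < 0) p$Top else p$Bottom
  xs <- X[!zero]
  out[!zero] <- p$Bottom + (p$Top - p$Bottom) /
    (1 + exp(p$HillSlope * (log(p$IC50) - log(xs))))
  out
}

#' Fit the unconstrained four-parameter Hill model
#'
#' Unconstrained nonlinear least squares of the Hill inhibition curve on
#' (dose, response) pairs: all four parameters `Top`, `Bottom`, `IC50`,
#' `HillSlope` are free. Fitting is on linear concentration as the model is
#' written; starting values come from the data (plateaus from extreme-dose
#' means, IC50 from the dose bracketing the half response, slope sign from
#' the response direction). The gauge freedom
#' `(Top, Bottom, HillSlope) <-> (Bottom, Top, -HillSlope)` is resolved by
#' canonicalizing to `Top >= Bottom`.
#'
#' @param doses Numeric vector of concentrations (uM), `>= 0`; at least 4
#'   distinct values (the model has 4 free parameters).
#' @param responses Numeric vector of responses, same length.
#' @param n_boot Number of nonparametric bootstrap replicates (resampling
#'   responses within each dose) for an IC50 percentile interval; 0 (the
#'   default) skips the bootstrap. Needs replicated doses to be informative.
#' @return Object of class `dose_response_fit` with `Top`, `Bottom`, `IC50`,
#'   `HillSlope`, `se` (named vector of standard errors from the Jacobian at
#'   the optimum), `covariance`, `rss`, `fitted`, `converged`, and when
#'   `n_boot > 0` an `IC50_ci` (2.5/97.5 bootstrap percentiles).
#' @examples
#' truth <- list(Top = 21, Bottom = 2, IC50 = 10, HillSlope = -1)
#' d <- rep(c(0.5, 1, 3, 10, 30, 80, 160), each = 2)
#' fit_hill(d, hill_eval(d, truth))
#' @export
fit_hill <- function(doses, responses, n_boot = 0L) {
  if (!is.numeric(doses) || !is.numeric(responses) ||
      length(doses) != length(responses))
    stop("doses and responses must be numeric vectors of equal length")
  if (any(!is.finite(responses)) || any(!is.finite(doses)) || any(doses < 0))
    stop("doses must be finite and >= 0; responses finite")
  if (length(unique(doses)) < 4L)
    stop("under-determined fit: need at least 4 distinct doses for 4 free parameters")
  if (stats::var(responses) < 1e-12 * max(1, mean(responses)^2))
    stop("unidentifiable IC50: responses carry no variance")

  ord <- order(doses)
  d <- doses[ord]; y <- responses[ord]
  du <- unique(d)
  mlow <- mean(y[d == du[1L]])
  mhigh <- mean(y[d == du[length(du)]])
  decreasing <- mlow > mhigh
  # Y(0) = Top needs HillSlope < 0; Y(0) = Bottom needs HillSlope > 0
  p0 <- if (decreasing) c(Top = mlow, Bottom = mhigh, HillSlope = -1)
        else c(Top = mhigh, Bottom = mlow, HillSlope = 1)
  half <- (p0[["Top"]] + p0[["Bottom"]]) / 2
  per_dose <- vapply(du, function(dd) mean(y[d == dd]), numeric(1))
  pos <- du[du > 0]
  if (!length(pos)) stop("at least one nonzero dose is required")
  ic0 <- pos[which.min(abs(per_dose[du > 0] - half))]
  if (ic0 <= 0) ic0 <- stats::median(pos)

  model <- function(par, X) {
    if (par[3] <= 0) return(rep(1e6, length(X)))  # IC50 must stay positive
    hill_eval(X, list(Top = par[1], Bottom = par[2], IC50 = par[3],
                      HillSlope = par[4]))
  }
  par0 <- c(p0[["Top"]], p0[["Bottom"]], ic0, p0[["HillSlope"]])
  res <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) y - model(par, d),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (res$info %in% c(0, 9))
    stop("Hill fit did not converge; last residual sum of squares ",
         sum(res$fvec^2))
  par <- res$par

  # canonical gauge: Top >= Bottom
  if (par[1] < par[2]) {
    par <- c(par[2], par[1], par[3], -par[4])
  }
  names(par) <- c("Top", "Bottom", "IC50", "HillSlope")

  # covariance from a numerical Jacobian at the optimum
  n <- length(y)
  rss <- sum((y - model(par, d))^2)
  J <- .num_jacobian(function(p) model(p, d), par)
  covmat <- tryCatch({
    s2 <- rss / max(n - 4L, 1L)
    s2 * solve(crossprod(J))
  }, error = function(e) matrix(NA_real_, 4, 4))
  dimnames(covmat) <- list(names(par), names(par))
  se <- sqrt(pmax(diag(covmat), 0))

  out <- structure(list(
    Top = par[["Top"]], Bottom = par[["Bottom"]], IC50 = par[["IC50"]],
    HillSlope = par[["HillSlope"]],
    se = se, covariance = covmat, rss = rss,
    fitted = model(par, d), doses = d, responses = y,
    converged = !(res$info %in% c(0, 5, 9))
  ), class = "dose_response_fit")

  if (n_boot > 0L) {
    boot <- vapply(seq_len(n_boot), function(k) {
      yb <- unlist(lapply(unique(d), function(dd) {
        yi <- y[d == dd]
        sample(yi, length(yi), replace = TRUE)
      }))
      db <- unlist(lapply(unique(d), function(dd) d[d == dd]))
      tryCatch(fit_hill(db, yb)$IC50, error = function(e) NA_real_)
    }, numeric(1))
    out$IC50_boot <- boot
    out$IC50_ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE,
                                   names = FALSE)
  }
  out
}

.num_jacobian <- function(f, par, eps = 1e-6) {
  f0 <- f(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}

#' Convert a racemic IC50 to the active-enantiomer IC50
#'
#' A racemic inhibitor containing a fraction `active_fraction` of the active
#' enantiomer has an effective active-compound IC50 of
#' `ic50_racemic * active_fraction` (e.g. racemic blebbistatin at ~50-60%
#' active (-) form).
#'
#' @param ic50_racemic Racemic IC50 (uM), `> 0`.
#' @param active_fraction Fraction of active enantiomer, in `(0, 1]`.
#' @return Active-enantiomer IC50 in uM.
#' @examples
#' active_ic50(10, 0.6)  # 6 uM
#' @export
active_ic50 <- function(ic50_racemic, active_fraction) {
  if (!is.numeric(ic50_racemic) || length(ic50_racemic) != 1L ||
      !is.finite(ic50_racemic) || ic50_racemic <= 0)
    stop("ic50_racemic must be a single finite positive concentration (uM)")
  if (!is.numeric(active_fraction) || length(active_fraction) != 1L ||
      !is.finite(active_fraction) ||
      active_fraction <= 0 || active_fraction > 1)
    stop("active_fraction must lie in (0, 1]")
  ic50_racemic * active_fraction
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: Top = %.3g, Bottom = %.3g, IC50 = %.3g uM (se %.2g), HillSlope = %.3g\n",
    x$Top, x$Bottom, x$IC50, x$se[["IC50"]], x$HillSlope))
  invisible(x)
}
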