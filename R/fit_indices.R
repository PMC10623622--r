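#' Model chi-square
#'
#' For complete-data ML fits, \eqn{\chi^2 = N \cdot F_{ML}(\hat\theta)} (or
#' \eqn{(N-1) F_{ML}} with \code{scale = "N-1"}).  For FIML fits on
#' incomplete data the chi-square is the likelihood ratio against the
#' saturated (unstructured) multivariate-normal model, whose ML solution is
#' obtained by EM.
#'
#' @param fitted An \code{\link{lst_fit}}.
#' @param scale Chi-square multiplier, \code{"N"} (common software default)
#'   or \code{"N-1"}.
#' @return List with \code{chi2}, \code{df}, \code{p_value}.
#' @export
chi_square <- function(fitted, scale = c("N", "N-1")) {
  stopifnot(inherits(fitted, "lst_fit"))
  scale <- match.arg(scale)
  df <- fitted$df
  if (!is.null(fitted$sample)) {
    parts <- nat_parts(fitted$msp, fitted$estimates)
    Fml <- fml_discrepancy(list(mu = parts$mu, Sigma = parts$Sigma),
                           fitted$sample)
    mult <- if (scale == "N") fitted$N_used else fitted$N_used - 1
    chi2 <- mult * Fml
  } else {
    ll_sat <- em_saturated(fitted$data_used)$loglik
    chi2 <- max(2 * (ll_sat - fitted$loglik), 0)
  }
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Root mean square error of approximation
#'
#' \eqn{RMSEA = \sqrt{\max(\chi^2 - df, 0) / (df (N-1))}}; the 90% confidence
#' interval inverts the noncentral chi-square distribution for the
#' noncentrality parameter at the 5% and 95% points.
#'
#' @param chi2 Model chi-square.
#' @param df Model degrees of freedom.
#' @param N Sample size.
#' @return \code{rmsea} returns the point value; \code{rmsea_ci90} a vector
#'   \code{c(lower, upper)}.
#' @export
rmsea <- function(chi2, df, N) {
  stopifnot(df > 0, N > 1)
  sqrt(max(chi2 - df, 0) / (df * (N - 1)))
}

#' @rdname rmsea
#' @export
rmsea_ci90 <- function(chi2, df, N) {
  stopifnot(df > 0, N > 1)
  lo <- ncp_solve(chi2, df, 0.95)
  hi <- ncp_solve(chi2, df, 0.05)
  c(lower = sqrt(lo / (df * (N - 1))), upper = sqrt(hi / (df * (N - 1))))
}

# Solve P(chisq_{df, ncp} <= chi2) = prob for the noncentrality parameter by
# bisection on [0, 10 * chi2]; P is decreasing in ncp.
ncp_solve <- function(chi2, df, prob, tol = 1e-8) {
  if (stats::pchisq(chi2, df, ncp = 0) <= prob) return(0)
  lo <- 0; hi <- max(10 * chi2, 1)
  if (stats::pchisq(chi2, df, ncp = hi) > prob)
    hi <- hi * 10  # extreme misfit; widen once
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (stats::pchisq(chi2, df, ncp = mid) > prob) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Baseline (independence) model fit
#'
#' The null model for the incremental fit indices: free means and variances,
#' all covariances zero, giving \code{df_b = p(p-1)/2}.  Closed form on
#' complete data; per-variable univariate ML against the EM saturated
#' log-likelihood on incomplete data.
#'
#' @param fitted An \code{\link{lst_fit}}.
#' @inheritParams chi_square
#' @return List with \code{chi2} and \code{df}.
#' @export
baseline_fit <- function(fitted, scale = c("N", "N-1")) {
  stopifnot(inherits(fitted, "lst_fit"))
  scale <- match.arg(scale)
  p <- fitted$msp$p
  df_b <- p * (p - 1) / 2
  if (!is.null(fitted$sample)) {
    S <- fitted$sample$S
    ld <- determinant(S, logarithm = TRUE)
    Fb <- sum(log(diag(S))) - as.numeric(ld$modulus)
    mult <- if (scale == "N") fitted$N_used else fitted$N_used - 1
    chi2_b <- mult * max(Fb, 0)
  } else {
    Y <- fitted$data_used
    ll_b <- 0
    for (j in seq_len(ncol(Y))) {
      x <- Y[, j]; x <- x[!is.na(x)]
      v <- mean((x - mean(x))^2)
      ll_b <- ll_b + sum(stats::dnorm(x, mean(x), sqrt(v), log = TRUE))
    }
    ll_sat <- em_saturated(Y)$loglik
    chi2_b <- max(2 * (ll_sat - ll_b), 0)
  }
  list(chi2 = chi2_b, df = df_b)
}

#' Incremental fit indices
#'
#' \eqn{CFI = 1 - \max(\chi^2-df, 0) / \max(\chi^2_b-df_b, \chi^2-df, 0)} and
#' \eqn{TLI = (\chi^2_b/df_b - \chi^2/df) / (\chi^2_b/df_b - 1)}.
#'
#' @param chi2,df Target model chi-square and degrees of freedom.
#' @param chi2_b,df_b Baseline model chi-square and degrees of freedom.
#' @return Scalar index.
#' @export
cfi <- function(chi2, df, chi2_b, df_b) {
  stopifnot(df_b > 0)
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' @rdname cfi
#' @export
tli <- function(chi2, df, chi2_b, df_b) {
  stopifnot(df_b > 0)
  if (df == 0) stop("TLI undefined for a saturated model (df = 0)")
  rb <- chi2_b / df_b
  (rb - chi2 / df) / (rb - 1)
}

#' Standardized root mean square residual
#'
#' Root mean square of the standardized covariance residuals
#' \eqn{(s_{ij} - \hat\sigma_{ij}) / \sqrt{s_{ii} s_{jj}}} over the
#' \eqn{p(p+1)/2} lower-triangle cells (covariance residuals only; the mean
#' structure is not included).
#'
#' @param Sigma_hat Model-implied covariance matrix.
#' @param S Sample covariance matrix.
#' @return Scalar SRMR.
#' @export
srmr <- function(Sigma_hat, S) {
  p <- nrow(S)
  stopifnot(all(dim(Sigma_hat) == p))
  if (any(diag(S) <= 0)) stop("zero sample variance: SRMR undefined")
  sds <- sqrt(diag(S))
  Rres <- (S - Sigma_hat) / tcrossprod(sds)
  sqrt(mean(Rres[lower.tri(Rres, diag = TRUE)]^2))
}

#' Information criteria
#'
#' \eqn{AIC = -2\ell + 2q} and \eqn{BIC = -2\ell + q\ln N}.
#'
#' @param fitted An \code{\link{lst_fit}}.
#' @return List with \code{aic} and \code{bic}.
#' @export
information_criteria <- function(fitted) {
  stopifnot(inherits(fitted, "lst_fit"))
  list(aic = -2 * fitted$loglik + 2 * fitted$n_free,
       bic = -2 * fitted$loglik + fitted$n_free * log(fitted$N_used))
}

#' Log-likelihood difference test
#'
#' Likelihood-ratio statistic \eqn{2(\ell_{full} - \ell_{nested})} with
#' degrees of freedom equal to the difference in free-parameter counts.  Both
#' fits must use the same data; the nesting of the two specifications is the
#' caller's assertion (a negative statistic is flagged).
#'
#' @param fit_nested,fit_full Two \code{\link{lst_fit}} objects on the same
#'   data with \code{fit_full} having more free parameters.
#' @return List with \code{stat}, \code{ddf}, \code{p_value}.
#' @export
lr_test <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "lst_fit"), inherits(fit_full, "lst_fit"))
  if (fit_nested$N_used != fit_full$N_used)
    stop("fits use different sample sizes; the test requires the same data")
  ddf <- fit_full$n_free - fit_nested$n_free
  if (ddf < 0)
    stop("fit_full must have at least as many free parameters as fit_nested")
  stat <- 2 * (fit_full$loglik - fit_nested$loglik)
  if (stat < -1e-6)
    warning("negative likelihood-ratio statistic: models are not nested ",
            "or a fit did not converge")
  stat <- max(stat, 0)
  list(stat = stat, ddf = ddf,
       p_value = if (ddf > 0) stats::pchisq(stat, ddf, lower.tail = FALSE)
                 else NA_real_)
}

#' Full fit-index report
#'
#' Computes the chi-square test, RMSEA with 90% CI, SRMR, CFI, TLI, AIC and
#' BIC for a fitted model, plus threshold labels per index ("good" at
#' CFI/TLI >= .97, RMSEA <= .05, SRMR <= .05; "acceptable" at .95/.95/.08/.10).
#'
#' @inheritParams chi_square
#' @return Object of class \code{lst_fit_indices}.
#' @examples
#' sim <- simulate_panel(sim_config(N = 500, seed = 7))
#' f <- lst_fit(lst_spec("item_effects", 3), sim, se = FALSE)
#' fit_indices(f)
#' @export
fit_indices <- function(fitted, scale = c("N", "N-1")) {
  scale <- match.arg(scale)
  cs <- chi_square(fitted, scale)
  bl <- baseline_fit(fitted, scale)
  N <- fitted$N_used
  parts <- nat_parts(fitted$msp, fitted$estimates)
  S <- if (!is.null(fitted$sample)) fitted$sample$S
       else em_saturated(fitted$data_used)$Sigma
  out <- list(
    chi2 = cs$chi2, df = cs$df, p_value = cs$p_value,
    rmsea = rmsea(cs$chi2, cs$df, N),
    rmsea_ci90 = rmsea_ci90(cs$chi2, cs$df, N),
    srmr = srmr(parts$Sigma, S),
    cfi = cfi(cs$chi2, cs$df, bl$chi2, bl$df),
    tli = tli(cs$chi2, cs$df, bl$chi2, bl$df),
    aic = information_criteria(fitted)$aic,
    bic = information_criteria(fitted)$bic,
    baseline_chi2 = bl$chi2, baseline_df = bl$df,
    N = N, scale = scale)
  out$classification <- classify_fit(out$cfi, out$tli, out$rmsea, out$srmr)
  structure(out, class = "lst_fit_indices")
}

#' Threshold classification of fit indices
#'
#' @param cfi,tli,rmsea,srmr Index values.
#' @return Named character vector with a label per index and an
#'   \code{overall} label ("good" only if every index is good, "acceptable"
#'   if every index is at least acceptable).
#' @export
classify_fit <- function(cfi, tli, rmsea, srmr) {
  lab <- function(x, good, acc, higher_better) {
    ok_good <- if (higher_better) x >= good else x <= good
    ok_acc <- if (higher_better) x >= acc else x <= acc
    if (ok_good) "good" else if (ok_acc) "acceptable" else "poor"
  }
  v <- c(cfi = lab(cfi, .97, .95, TRUE),
         tli = lab(tli, .97, .95, TRUE),
         rmsea = lab(rmsea, .05, .08, FALSE),
         srmr = lab(srmr, .05, .10, FALSE))
  overall <- if (all(v == "good")) "good"
             else if (all(v %in% c("good", "acceptable"))) "acceptable"
             else "poor"
  c(v, overall = overall)
}

#' @export
print.lst_fit_indices <- function(x, digits = 3, ...) {
  cat(sprintf("chi2(%d) = %.1f, p %s\n", x$df, x$chi2,
              format.pval(x$p_value, digits = 3)))
  cat(sprintf("RMSEA = %.3f [%.3f, %.3f]  SRMR = %.3f\n",
              x$rmsea, x$rmsea_ci90["lower"], x$rmsea_ci90["upper"],
              x$srmr))
  cat(sprintf("CFI = %.3f  TLI = %.3f  AIC = %.0f  BIC = %.0f\n",
              x$cfi, x$tli, x$aic, x$bic))
  cat("classification:", x$classification[["overall"]], "\n")
  invisible(x)
}

#' Fit comparison table for a set of fitted models
#'
#' @param fits Named list of \code{\link{lst_fit}} objects on the same data.
#' @inheritParams chi_square
#' @return Data frame, one row per model, with chi-square(df), RMSEA and its
#'   90% CI, SRMR, CFI, TLI, AIC, BIC.
#' @export
fit_index_table <- function(fits, scale = c("N", "N-1")) {
  scale <- match.arg(scale)
  rows <- lapply(names(fits), function(nm) {
    ix <- fit_indices(fits[[nm]], scale)
    data.frame(model = nm,
               chi2 = ix$chi2, df = ix$df,
               rmsea = ix$rmsea,
               rmsea_lo = ix$rmsea_ci90[["lower"]],
               rmsea_hi = ix$rmsea_ci90[["upper"]],
               srmr = ix$srmr, cfi = ix$cfi, tli = ix$tli,
               aic = ix$aic, bic = ix$bic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
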