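#' Model-implied moments
#'
#' Computes the model-implied mean vector \eqn{\mu(\theta) = \tilde\alpha +
#' \Lambda\kappa} and covariance matrix \eqn{\Sigma(\theta) = \Lambda \Phi
#' \Lambda' + \mathrm{diag}(\theta)} of the \code{p = I * T} observed
#' variables.
#'
#' @param spec An \code{\link{lst_spec}}.
#' @param params An \code{\link{lst_parameters}} for that spec.
#' @return List of class \code{lst_moments} with elements \code{mu} (length
#'   \code{p}) and \code{Sigma} (\code{p x p} symmetric, positive definite
#'   whenever \code{Phi} is PD and all residual variances are positive).
#' @export
implied_moments <- function(spec, params) {
  stopifnot(inherits(spec, "lst_spec"), inherits(params, "lst_parameters"))
  msp <- build_msp(spec)
  parts <- nat_parts(msp, params_to_nat(msp, params))
  structure(list(mu = stats::setNames(parts$mu, msp$obs_names),
                 Sigma = structure(parts$Sigma,
                                   dimnames = list(msp$obs_names,
                                                   msp$obs_names))),
            class = "lst_moments")
}

#' Sample moments of complete data
#'
#' Mean vector and covariance matrix (maximum-likelihood divisor \code{N})
#' of a complete-case data matrix.
#'
#' @param data Data frame or matrix of numeric columns without missing
#'   values.
#' @return List of class \code{lst_sample} with \code{ybar}, \code{S}
#'   (divisor \code{N}) and \code{N}.
#' @export
sample_moments <- function(data) {
  Y <- as.matrix(data)
  if (anyNA(Y))
    stop("data contain missing values; use estimator = \"fiml\" or ",
         "\"listwise\" in lst_fit()")
  storage.mode(Y) <- "double"
  N <- nrow(Y)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  S <- crossprod(Yc) / N
  structure(list(ybar = ybar, S = (S + t(S)) / 2, N = N),
            class = "lst_sample")
}

#' Normal-theory maximum-likelihood discrepancy
#'
#' The ML fitting function between model-implied moments \eqn{(\mu,\Sigma)}
#' and sample moments \eqn{(\bar y, S)}:
#' \deqn{F_{ML} = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p +
#'   (\bar y-\mu)'\Sigma^{-1}(\bar y-\mu).}
#' \eqn{F \ge 0} with equality iff \eqn{\Sigma = S} and \eqn{\mu = \bar y};
#' \eqn{N \cdot F_{ML}} evaluated at the estimate is the model chi-square.
#'
#' @param implied An \code{lst_moments} (or list with \code{mu},
#'   \code{Sigma}).
#' @param sample An \code{lst_sample} (or list with \code{ybar}, \code{S},
#'   \code{N}).
#' @return Scalar discrepancy.
#' @export
fml_discrepancy <- function(implied, sample) {
  Sigma <- implied$Sigma; mu <- implied$mu
  S <- sample$S; ybar <- sample$ybar
  p <- length(mu)
  stopifnot(length(ybar) == p, all(dim(S) == p), all(dim(Sigma) == p))
  R <- chol_or_null(Sigma)
  if (is.null(R)) stop("model-implied covariance is singular / not PD")
  Sinv <- chol2inv(R)
  ldet_sigma <- 2 * sum(log(diag(R)))
  ldet_s <- determinant(S, logarithm = TRUE)
  if (ldet_s$sign <= 0) stop("sample covariance is singular")
  d <- ybar - mu
  as.numeric(ldet_sigma + sum(Sinv * S) - as.numeric(ldet_s$modulus) - p +
               d %*% Sinv %*% d)
}
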