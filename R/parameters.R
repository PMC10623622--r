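#' Parameter vector of a multi-state measurement model
#'
#' Bundles all model parameters in their natural (constrained) form: latent
#' means \code{kappa}, latent covariance \code{Phi} (symmetric positive
#' definite), per-item loadings \code{lambda} and intercepts \code{alpha}
#' (the reference item is fixed at 1 and 0; under the item-effects variant
#' every loading is 1 and every intercept 0), and residual variances
#' \code{theta}, one per item-occasion combination.
#'
#' @param spec An \code{\link{lst_spec}}.
#' @param kappa Numeric vector of latent means, length \code{m}.
#' @param Phi Symmetric positive-definite \code{m x m} latent covariance.
#' @param lambda Numeric vector of item loadings, length \code{I}.
#' @param alpha Numeric vector of item intercepts, length \code{I}.
#' @param theta Strictly positive residual variances, length \code{p}, in
#'   observed-variable order.
#' @return An object of class \code{lst_parameters}.
#' @export
lst_parameters <- function(spec, kappa, Phi, lambda = NULL, alpha = NULL,
                           theta) {
  stopifnot(inherits(spec, "lst_spec"))
  I <- spec$design$n_items
  if (is.null(lambda)) lambda <- rep(1, I)
  if (is.null(alpha)) alpha <- rep(0, I)
  kappa <- as.numeric(kappa); theta <- as.numeric(theta)
  stopifnot(length(kappa) == spec$m,
            all(dim(Phi) == spec$m),
            length(lambda) == I, length(alpha) == I,
            length(theta) == spec$p)
  if (max(abs(Phi - t(Phi))) > 1e-8) stop("Phi must be symmetric")
  Phi <- (Phi + t(Phi)) / 2
  if (is.null(chol_or_null(Phi)))
    stop("Phi must be positive definite")
  if (any(theta <= 0)) stop("residual variances theta must be > 0")
  r <- spec$reference_item
  if (abs(lambda[r] - 1) > 1e-12 || abs(alpha[r]) > 1e-12)
    stop("the reference item's loading and intercept are fixed to 1 and 0")
  if (spec$variant == "item_effects" &&
      (any(abs(lambda - 1) > 1e-12) || any(abs(alpha) > 1e-12)))
    stop("under the item-effects variant all loadings are fixed to 1 and ",
         "all intercepts to 0")
  names(kappa) <- spec$latent_labels
  dimnames(Phi) <- list(spec$latent_labels, spec$latent_labels)
  names(theta) <- observed_names(spec$design)
  structure(list(spec = spec, kappa = kappa, Phi = Phi, lambda = lambda,
                 alpha = alpha, theta = theta),
            class = "lst_parameters")
}

#' @export
print.lst_parameters <- function(x, ...) {
  cat("Parameters for", x$spec$variant, "model (reference item",
      x$spec$reference_item, ")\n")
  cat("latent means:\n"); print(round(x$kappa, 3))
  cat("latent SDs:\n"); print(round(sqrt(diag(x$Phi)), 3))
  if (x$spec$variant == "states_only") {
    cat("loadings:", round(x$lambda, 3), "\n")
    cat("intercepts:", round(x$alpha, 3), "\n")
  }
  cat("residual variances: ")
  cat(round(x$theta, 3), sep = ", "); cat("\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Free-vector layouts.
#
# Natural layout:      [kappa, vech(Phi), lam_free, alpha_free, theta]
# Transformed layout:  [kappa, vech(L) with log diagonal, lam_free,
#                       alpha_free, log(theta)]
# where Phi = L L' (lower-triangular Cholesky).  The transformed layout keeps
# every optimizer iterate admissible (Phi PD, theta > 0).

msp_idx <- function(msp) {
  m <- msp$m
  nphi <- m * (m + 1) / 2
  k <- 0L
  idx <- list(kappa = k + seq_len(m)); k <- k + m
  idx$phi <- k + seq_len(nphi); k <- k + nphi
  idx$lam <- if (msp$n_lam > 0) k + seq_len(msp$n_lam) else integer(0)
  k <- k + msp$n_lam
  idx$alpha <- if (msp$n_alpha > 0) k + seq_len(msp$n_alpha) else integer(0)
  k <- k + msp$n_alpha
  idx$theta <- k + seq_len(msp$p)
  idx$q <- k + msp$p
  idx
}

msp_par_names <- function(msp) {
  c(msp$kappa_names, msp$phi_names, msp$lam_names, msp$alpha_names,
    msp$theta_names)
}

# diag positions within vech ordering (column-major lower triangle)
vech_diag_pos <- function(m) {
  pos <- integer(m); k <- 0L
  for (j in seq_len(m)) { pos[j] <- k + 1L; k <- k + (m - j + 1L) }
  pos
}

nat_to_trans <- function(msp, v) {
  idx <- msp_idx(msp)
  Phi <- unvech(v[idx$phi], msp$m)
  ch <- chol_or_null(Phi)
  if (is.null(ch)) stop("Phi must be positive definite")
  L <- t(ch)
  lv <- vech(L)
  dp <- vech_diag_pos(msp$m)
  lv[dp] <- log(lv[dp])
  x <- v
  x[idx$phi] <- lv
  x[idx$theta] <- log(v[idx$theta])
  x
}

trans_to_nat <- function(msp, x) {
  idx <- msp_idx(msp)
  lv <- x[idx$phi]
  dp <- vech_diag_pos(msp$m)
  lv[dp] <- exp(lv[dp])
  L <- matrix(0, msp$m, msp$m)
  L[lower.tri(L, diag = TRUE)] <- lv
  Phi <- tcrossprod(L)
  v <- x
  v[idx$phi] <- vech(Phi)
  v[idx$theta] <- exp(x[idx$theta])
  v
}

# Unpack a NATURAL free vector into model matrices.
nat_parts <- function(msp, v) {
  idx <- msp_idx(msp)
  kappa <- v[idx$kappa]
  Phi <- unvech(v[idx$phi], msp$m)
  lam <- v[idx$lam]
  alf <- v[idx$alpha]
  theta <- v[idx$theta]
  Lambda <- msp_Lambda(msp, lam)
  alpha_t <- msp_alpha(msp, alf)
  mu <- as.numeric(alpha_t + Lambda %*% kappa)
  Sigma <- Lambda %*% Phi %*% t(Lambda)
  diag(Sigma) <- diag(Sigma) + theta
  Sigma <- (Sigma + t(Sigma)) / 2
  list(kappa = kappa, Phi = Phi, lam = lam, alpha = alf, theta = theta,
       Lambda = Lambda, mu = mu, Sigma = Sigma)
}

params_to_nat <- function(msp, params) {
  spec <- params$spec
  free_items <- setdiff(seq_len(spec$design$n_items), spec$reference_item)
  c(params$kappa, vech(params$Phi),
    if (msp$n_lam > 0) params$lambda[free_items] else numeric(0),
    if (msp$n_alpha > 0) params$alpha[free_items] else numeric(0),
    params$theta)
}

nat_to_params <- function(spec, msp, v) {
  idx <- msp_idx(msp)
  I <- spec$design$n_items
  lambda <- rep(1, I); alpha <- rep(0, I)
  if (msp$n_lam > 0) {
    free_items <- setdiff(seq_len(I), spec$reference_item)
    lambda[free_items] <- v[idx$lam]
    alpha[free_items] <- v[idx$alpha]
  }
  lst_parameters(spec,
                 kappa = v[idx$kappa],
                 Phi = unvech(v[idx$phi], msp$m),
                 lambda = lambda, alpha = alpha,
                 theta = v[idx$theta])
}
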