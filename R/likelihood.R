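# Likelihood engine.
#
# Both complete-data ML and FIML reduce to the same computation: the data are
# partitioned into groups of rows sharing one missingness pattern, each group
# is summarized by (index set, N_g, mean, covariance with divisor N_g), and
# the log-likelihood is the sum of multivariate-normal group contributions
# evaluated on the corresponding submatrix of (mu, Sigma).  Complete data are
# the single-group special case, which makes the FIML = ML reduction on
# complete data an identity of the code path, not just of the algebra.
# Gradients with respect to (mu, Sigma) are accumulated per group and chained
# analytically through the moment structure.

complete_groups <- function(Y) {
  sm <- sample_moments(Y)
  list(list(idx = seq_along(sm$ybar), N = sm$N, ybar = sm$ybar, S = sm$S))
}

fiml_groups <- function(Y) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0))
    stop("rows with no observed entries cannot contribute to the ",
         "likelihood; remove them first")
  pat <- apply(obs, 1L, paste, collapse = "")
  lapply(split(seq_len(nrow(Y)), pat), function(rows) {
    idx <- which(obs[rows[1L], ])
    Yg <- Y[rows, idx, drop = FALSE]
    Ng <- nrow(Yg)
    ybar <- colMeans(Yg)
    Yc <- sweep(Yg, 2, ybar)
    S <- crossprod(Yc) / Ng
    list(idx = idx, N = Ng, ybar = ybar, S = (S + t(S)) / 2)
  })
}

# Observed-data log-likelihood of arbitrary (mu, Sigma) over pattern groups,
# with optional gradient in (mu, Sigma).
groups_loglik_musigma <- function(mu, Sigma, groups, want_grad = FALSE) {
  p <- length(mu)
  ll <- 0
  g_mu <- if (want_grad) numeric(p) else NULL
  G <- if (want_grad) matrix(0, p, p) else NULL
  for (g in groups) {
    o <- g$idx
    So <- Sigma[o, o, drop = FALSE]
    R <- chol_or_null(So)
    if (is.null(R)) return(list(loglik = -Inf, g_mu = g_mu, G = G))
    Sinv <- chol2inv(R)
    ldet <- 2 * sum(log(diag(R)))
    d <- g$ybar - mu[o]
    Sd <- as.numeric(Sinv %*% d)
    ll <- ll - g$N / 2 *
      (length(o) * log(2 * pi) + ldet + sum(Sinv * g$S) + sum(d * Sd))
    if (want_grad) {
      g_mu[o] <- g_mu[o] + g$N * Sd
      A <- Sinv %*% (g$S + tcrossprod(d)) %*% Sinv
      G[o, o] <- G[o, o] - g$N / 2 * (Sinv - (A + t(A)) / 2)
    }
  }
  list(loglik = ll, g_mu = g_mu, G = G)
}

# Chain the (mu, Sigma) gradient through the moment structure to the natural
# free parameters [kappa, vech(Phi), lam, alpha, theta].
chain_gradient_nat <- function(msp, parts, g_mu, G) {
  idx <- msp_idx(msp)
  grad <- numeric(idx$q)
  Lambda <- parts$Lambda
  grad[idx$kappa] <- as.numeric(crossprod(Lambda, g_mu))
  Gphi <- crossprod(Lambda, G %*% Lambda)
  Gphi <- (Gphi + t(Gphi)) / 2
  gp <- 2 * Gphi
  diag(gp) <- diag(Gphi)
  grad[idx$phi] <- vech(gp)
  if (msp$n_lam > 0) {
    dLam <- 2 * (G %*% Lambda %*% parts$Phi) +
      tcrossprod(g_mu, parts$kappa)
    for (k in seq_len(msp$n_lam))
      grad[idx$lam[k]] <- sum(dLam[msp$lam_map == k])
  }
  if (msp$n_alpha > 0)
    for (k in seq_len(msp$n_alpha))
      grad[idx$alpha[k]] <- sum(g_mu[msp$alpha_map == k])
  grad[idx$theta] <- diag(G)
  grad
}

# Log-likelihood (and gradient) at a natural free vector.
loglik_nat <- function(msp, v, groups, want_grad = FALSE) {
  parts <- nat_parts(msp, v)
  ls <- groups_loglik_musigma(parts$mu, parts$Sigma, groups, want_grad)
  if (!want_grad || !is.finite(ls$loglik))
    return(list(loglik = ls$loglik, grad = NULL))
  list(loglik = ls$loglik,
       grad = chain_gradient_nat(msp, parts, ls$g_mu, ls$G))
}

# Log-likelihood (and gradient) at a transformed free vector
# (log-Cholesky Phi, log theta): every iterate is admissible.
loglik_trans <- function(msp, x, groups, want_grad = FALSE) {
  idx <- msp_idx(msp)
  v <- trans_to_nat(msp, x)
  res <- loglik_nat(msp, v, groups, want_grad)
  if (!want_grad || is.null(res$grad)) return(res)
  grad <- res$grad
  # Phi block: dl/dL = 2 * Gphi * L with log-diagonal scaling
  m <- msp$m
  lv <- x[idx$phi]
  dp <- vech_diag_pos(m)
  lv[dp] <- exp(lv[dp])
  L <- matrix(0, m, m)
  L[lower.tri(L, diag = TRUE)] <- lv
  # vech gradient has off-diagonals doubled; recover the full-matrix
  # convention dl/dPhi_ij before chaining through Phi = L L'
  gp <- unvech(grad[idx$phi], m)
  diag_full <- diag(gp)
  Gphi <- gp / 2
  diag(Gphi) <- diag_full
  dL <- 2 * Gphi %*% L
  dLv <- vech(dL)
  dLv[dp] <- dLv[dp] * diag(L)
  grad[idx$phi] <- dLv
  # theta block: log scale
  grad[idx$theta] <- grad[idx$theta] * v[idx$theta]
  list(loglik = res$loglik, grad = grad)
}

#' Full-information maximum-likelihood log-likelihood
#'
#' Casewise (pattern-wise) observed-data log-likelihood of a parameter
#' vector: each respondent contributes the multivariate-normal log-density of
#' their observed subvector under the corresponding submatrix of the
#' model-implied moments.  On complete data this equals the complete-data ML
#' log-likelihood exactly.
#'
#' @param spec An \code{\link{lst_spec}}.
#' @param params An \code{\link{lst_parameters}}.
#' @param data Data frame with the model's observed columns; missing cells
#'   \code{NA}.  Every row must have at least one observed entry.
#' @return Scalar log-likelihood.
#' @export
fiml_loglik <- function(spec, params, data) {
  msp <- build_msp(spec)
  Y <- as.matrix(data[, msp$obs_names, drop = FALSE])
  groups <- fiml_groups(Y)
  v <- params_to_nat(msp, params)
  loglik_nat(msp, v, groups)$loglik
}

# ---------------------------------------------------------------------------
# Saturated (unstructured) multivariate-normal ML with missing data, via EM.
# Needed for the FIML chi-square: chi2 = 2 * (loglik_saturated - loglik_model).
em_saturated <- function(Y, max_iter = 500, tol = 1e-9) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  p <- ncol(Y)
  groups <- fiml_groups(Y)
  N <- nrow(Y)
  mu <- vapply(seq_len(p), function(j) mean(Y[, j], na.rm = TRUE), 0)
  v0 <- vapply(seq_len(p), function(j) {
    x <- Y[, j]; x <- x[!is.na(x)]; mean((x - mean(x))^2)
  }, 0)
  Sigma <- diag(v0, p)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (g in groups) {
      o <- g$idx
      mi <- setdiff(seq_len(p), o)
      Soo_inv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
      Eo <- g$ybar
      So_full <- g$S + tcrossprod(g$ybar)          # E[y_o y_o'] (divisor N_g)
      T1[o] <- T1[o] + g$N * Eo
      T2[o, o] <- T2[o, o] + g$N * So_full
      if (length(mi)) {
        B <- Sigma[mi, o, drop = FALSE] %*% Soo_inv
        Em <- mu[mi] + as.numeric(B %*% (g$ybar - mu[o]))
        C <- Sigma[mi, mi, drop = FALSE] -
          B %*% Sigma[o, mi, drop = FALSE]
        # E[y_m y_o'] = mu_m ybar_o' + B * (S + centered cross moments)
        Cov_mo <- B %*% g$S
        Emo <- tcrossprod(Em, g$ybar) + Cov_mo
        Emm <- tcrossprod(Em) + B %*% g$S %*% t(B) + C
        T1[mi] <- T1[mi] + g$N * Em
        T2[mi, o] <- T2[mi, o] + g$N * Emo
        T2[o, mi] <- T2[o, mi] + g$N * t(Emo)
        T2[mi, mi] <- T2[mi, mi] + g$N * Emm
      }
    }
    mu <- T1 / N
    Sigma <- T2 / N - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- groups_loglik_musigma(mu, Sigma, groups)$loglik
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, iterations = iter)
}
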