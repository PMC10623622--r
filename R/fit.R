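#' Fit a multi-state measurement model by maximum likelihood
#'
#' Maximizes the normal-theory likelihood of an \code{\link{lst_spec}} over
#' its free parameters.  The latent covariance is parameterized through its
#' log-Cholesky factor and residual variances on the log scale, so every
#' optimizer iterate is admissible (Phi positive definite, theta > 0); fixed
#' entries of the loading/intercept pattern never move.  Optimization uses a
#' deterministic quasi-Newton method (\code{\link[stats]{nlminb}}) with
#' analytic gradients from method-of-moments starting values, so fits are
#' reproducible without a seed.
#'
#' @param spec An \code{\link{lst_spec}}.
#' @param data Data frame containing the observed columns named
#'   \code{<item_label>_w<occasion>}.
#' @param estimator \code{"ml"} (complete data required), \code{"listwise"}
#'   (drop rows with any missing model column, mirroring a complete-case
#'   analysis), or \code{"fiml"} (full-information ML over missingness
#'   patterns, valid under MAR).
#' @param start Optional starting values as an \code{\link{lst_parameters}}.
#' @param se Compute the observed-information covariance matrix of the free
#'   parameters (default \code{TRUE}).
#' @param control List overriding optimizer control: \code{rel.tol}
#'   (default \code{1e-14}), \code{iter.max} (1000), \code{eval.max} (4000).
#' @return An object of class \code{lst_fit} with the parameter estimates
#'   (\code{$params}), log-likelihood, free-parameter count, convergence
#'   diagnostics, and (if requested) \code{$vcov}, the inverse observed
#'   information of the natural free parameters.  Non-convergence is flagged
#'   in \code{$converged}, not raised as an error; boundary solutions
#'   (residual variances near zero) are recorded in \code{$warnings}.
#' @examples
#' sim <- simulate_panel(sim_config(N = 300, seed = 1))
#' f <- lst_fit(lst_spec("item_effects", 3), sim, se = FALSE)
#' logLik(f)
#' @export
lst_fit <- function(spec, data, estimator = c("ml", "listwise", "fiml"),
                    start = NULL, se = TRUE, control = list()) {
  stopifnot(inherits(spec, "lst_spec") || inherits(spec, "lst_structural_spec"))
  estimator <- match.arg(estimator)
  msp <- msp_of(spec)
  missing_cols <- setdiff(msp$obs_names, names(data))
  if (length(missing_cols))
    stop("data lack required columns: ", paste(missing_cols, collapse = ", "))
  Y <- as.matrix(data[, msp$obs_names, drop = FALSE])
  storage.mode(Y) <- "double"
  if (estimator == "ml" && anyNA(Y))
    stop("missing values present with estimator = \"ml\"; ",
         "use \"fiml\" or \"listwise\"")
  if (estimator == "listwise") {
    Y <- Y[stats::complete.cases(Y), , drop = FALSE]
    if (nrow(Y) <= msp$p)
      stop("fewer complete rows than observed variables + 1")
  }
  groups <- if (estimator == "fiml" && anyNA(Y)) fiml_groups(Y)
            else complete_groups(Y)
  N <- sum(vapply(groups, `[[`, 0, "N"))

  # moment summary used for starts (EM-pooled when patterns are incomplete)
  if (length(groups) == 1L) {
    mom <- list(mu = groups[[1L]]$ybar, Sigma = groups[[1L]]$S)
  } else {
    em <- em_saturated(Y)
    mom <- list(mu = em$mu, Sigma = em$Sigma)
  }

  v0 <- if (!is.null(start)) {
    if (inherits(start, "lst_parameters")) params_to_nat(msp, start)
    else as.numeric(start)
  } else {
    start_values_nat(spec, msp, mom)
  }
  x0 <- nat_to_trans(msp, v0)

  # tight default: reference-switch equivalence checks compare optima to
  # ~1e-6 relative, which needs the optimizer run essentially to the floor
  ctl <- utils::modifyList(
    list(rel.tol = 1e-14, iter.max = 1000L, eval.max = 4000L), control)
  fn <- function(x) {
    ll <- loglik_trans(msp, x, groups)$loglik
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  gr <- function(x) {
    res <- loglik_trans(msp, x, groups, want_grad = TRUE)
    if (is.null(res$grad)) return(rep(0, length(x)))
    -res$grad
  }
  opt <- stats::nlminb(x0, fn, gr, control = ctl)
  vhat <- trans_to_nat(msp, opt$par)
  names(vhat) <- msp_par_names(msp)
  final <- loglik_nat(msp, vhat, groups, want_grad = TRUE)
  grad_inf <- max(abs(final$grad))
  converged <- opt$convergence == 0 || grad_inf / max(1, N) < 1e-6

  warnings_out <- character(0)
  idx <- msp_idx(msp)
  theta_hat <- vhat[idx$theta]
  scale_ref <- mean(diag(mom$Sigma))
  if (any(theta_hat < 1e-4 * scale_ref))
    warnings_out <- c(warnings_out,
      paste("residual variance at boundary (near zero):",
            paste(names(theta_hat)[theta_hat < 1e-4 * scale_ref],
                  collapse = ", ")))

  vc <- NULL
  if (se) {
    H <- nat_hessian(msp, vhat, groups)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vc)) {
      warnings_out <- c(warnings_out, singular_information_message(H, msp))
    } else {
      dimnames(vc) <- list(names(vhat), names(vhat))
    }
  }

  fit <- structure(
    list(spec = spec, msp = msp,
         estimates = vhat,
         params = if (inherits(spec, "lst_spec"))
           nat_to_params(spec, msp, vhat) else NULL,
         loglik = final$loglik,
         n_free = length(vhat),
         df = msp$p * (msp$p + 3) / 2 - length(vhat),
         converged = converged,
         iterations = opt$iterations,
         grad_inf = grad_inf,
         optim_message = opt$message,
         vcov = vc,
         N_used = N,
         estimator = estimator,
         sample = if (length(groups) == 1L)
           structure(list(ybar = groups[[1L]]$ybar, S = groups[[1L]]$S,
                          N = N), class = "lst_sample") else NULL,
         data_used = Y,
         warnings = warnings_out),
    class = "lst_fit")
  fit
}

# Method-of-moments starting values from a pooled moment summary.
start_values_nat <- function(spec, msp, mom) {
  if (inherits(spec, "lst_structural_spec"))
    return(start_values_structural(spec, msp, mom))
  d <- spec$design
  I <- d$n_items; T_ <- d$n_occasions; r <- spec$reference_item
  mu <- mom$mu; S <- mom$Sigma
  ridx <- vapply(seq_len(T_), function(t) obs_index(d, r, t), 0L)
  kappa_eta <- mu[ridx]
  # state covariances from the reference item across occasions (its residual
  # does not repeat over time, so cross-wave covariances are error-free)
  Phi <- matrix(0, spec$m, spec$m)
  for (t in seq_len(T_)) for (u in seq_len(T_)) {
    if (t != u) Phi[t, u] <- S[ridx[t], ridx[u]]
  }
  for (t in seq_len(T_)) {
    off <- Phi[t, seq_len(T_)][-t]
    Phi[t, t] <- max(mean(off), 0.05)
  }
  kappa <- kappa_eta
  if (spec$variant == "item_effects") {
    others <- setdiff(seq_len(I), r)
    for (k in seq_along(others)) {
      i <- others[k]
      col <- T_ + k
      iidx <- vapply(seq_len(T_), function(t) obs_index(d, i, t), 0L)
      kappa <- c(kappa, mean(mu[iidx] - mu[ridx]))
      # Var(delta_i) from cross-wave covariances of the difference scores
      dv <- c()
      for (t in seq_len(T_)) for (u in seq_len(T_)) if (t < u) {
        dv <- c(dv, S[iidx[t], iidx[u]] - S[iidx[t], ridx[u]] -
                  S[ridx[t], iidx[u]] + S[ridx[t], ridx[u]])
      }
      Phi[col, col] <- max(mean(dv), 0.05)
      for (t in seq_len(T_)) {
        cv <- c()
        for (u in seq_len(T_)) if (u != t)
          cv <- c(cv, S[ridx[t], iidx[u]] - S[ridx[t], ridx[u]])
        Phi[col, t] <- Phi[t, col] <- mean(cv)
      }
    }
    # delta-delta covariances
    for (k in seq_along(others)) for (l in seq_along(others)) if (k < l) {
      i <- others[k]; j <- others[l]
      iidx <- vapply(seq_len(T_), function(t) obs_index(d, i, t), 0L)
      jidx <- vapply(seq_len(T_), function(t) obs_index(d, j, t), 0L)
      cv <- c()
      for (t in seq_len(T_)) for (u in seq_len(T_)) if (t != u) {
        cv <- c(cv, S[iidx[t], jidx[u]] - S[iidx[t], ridx[u]] -
                  S[ridx[t], jidx[u]] + S[ridx[t], ridx[u]])
      }
      Phi[T_ + k, T_ + l] <- Phi[T_ + l, T_ + k] <- mean(cv)
    }
  }
  Phi <- pd_floor(Phi)
  lam <- alf <- numeric(0)
  if (msp$n_lam > 0) {
    others <- setdiff(seq_len(I), r)
    sdev <- sqrt(diag(S))
    lam <- vapply(others, function(i) {
      mean(vapply(seq_len(T_), function(t)
        sdev[obs_index(d, i, t)] / sdev[ridx[t]], 0))
    }, 0)
    alf <- vapply(seq_along(others), function(k) {
      i <- others[k]
      mean(vapply(seq_len(T_), function(t)
        mu[obs_index(d, i, t)] - lam[k] * mu[ridx[t]], 0))
    }, 0)
  }
  theta <- pmax(diag(S) / 2, 1e-3)
  c(kappa, vech(Phi), lam, alf, theta)
}

# Nudge a symmetric matrix to be safely positive definite.
pd_floor <- function(M, eps = 1e-3) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps * max(abs(e$values), 1))
  V <- e$vectors %*% (vals * t(e$vectors))
  (V + t(V)) / 2
}

# Observed information: central differences of the analytic gradient.
nat_hessian <- function(msp, v, groups, h_scale = 1e-5) {
  q <- length(v)
  H <- matrix(0, q, q)
  for (i in seq_len(q)) {
    h <- h_scale * max(1, abs(v[i]))
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    gp <- loglik_nat(msp, vp, groups, want_grad = TRUE)$grad
    gm <- loglik_nat(msp, vm, groups, want_grad = TRUE)$grad
    if (is.null(gp) || is.null(gm))
      stop("information matrix not computable: non-PD neighborhood")
    H[i, ] <- -(gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

singular_information_message <- function(H, msp) {
  e <- eigen(H, symmetric = TRUE)
  v <- e$vectors[, which.min(e$values)]
  nm <- msp_par_names(msp)
  top <- order(abs(v), decreasing = TRUE)[seq_len(min(3, length(v)))]
  paste0("observed information is singular; non-identified direction loads ",
         "on: ", paste(nm[top], collapse = ", "))
}

#' Standard errors of the free parameters
#'
#' @param fitted An \code{\link{lst_fit}}.
#' @return Named vector of standard errors (square roots of the diagonal of
#'   the inverse observed information).  Fixed parameters do not appear.
#' @export
standard_errors <- function(fitted) {
  stopifnot(inherits(fitted, "lst_fit"))
  if (is.null(fitted$vcov))
    stop("no parameter covariance available: ",
         paste(fitted$warnings, collapse = "; "))
  sqrt(pmax(diag(fitted$vcov), 0))
}

# Delta-method estimate and SE of g(natural free vector).
delta_method <- function(fitted, gfun, h_scale = 1e-6) {
  v <- fitted$estimates
  est <- gfun(v)
  k <- length(est)
  J <- matrix(0, k, length(v))
  for (i in seq_along(v)) {
    h <- h_scale * max(1, abs(v[i]))
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    J[, i] <- (gfun(vp) - gfun(vm)) / (2 * h)
  }
  V <- J %*% fitted$vcov %*% t(J)
  list(est = est, se = sqrt(pmax(diag(V), 0)), vcov = V)
}

#' @export
logLik.lst_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$N_used,
            class = "logLik")
}

#' @export
coef.lst_fit <- function(object, ...) object$estimates

#' @export
vcov.lst_fit <- function(object, ...) object$vcov

#' @export
print.lst_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit (%s), N = %d\n",
              x$estimator, x$N_used))
  cat(sprintf("  log-likelihood %.3f on %d free parameters (df = %d)\n",
              x$loglik, x$n_free, x$df))
  cat(sprintf("  converged: %s (iterations %d, max |gradient| %.2e)\n",
              x$converged, x$iterations, x$grad_inf))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
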