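#' Structural model: outcome regression on the latent variables
#'
#' Declares a linear regression of a single manifest outcome composite
#' \eqn{Z} on the latent variables of an item-effects measurement model,
#' estimated simultaneously with the measurement part in one ML fit:
#' \eqn{Z = \nu + \sum_j \gamma_j \zeta_j + \epsilon_Z} with free intercept,
#' coefficients and residual variance.  The predictor set is either the
#' latent states alone or states plus all item-effect variables (the
#' reference item's effect variable does not exist and is marked "ref" in
#' reports).
#'
#' @param base An item-effects \code{\link{lst_spec}}.
#' @param outcome_label Column name of the outcome in the data.
#' @param predictor_set \code{"states"} (aliases \code{"states_only"}) or
#'   \code{"full"} (alias \code{"states_plus_item_effects"}).
#' @return Object of class \code{lst_structural_spec}.
#' @export
structural_spec <- function(base, outcome_label,
                            predictor_set = c("states", "full",
                                              "states_only",
                                              "states_plus_item_effects")) {
  stopifnot(inherits(base, "lst_spec"))
  if (base$variant != "item_effects")
    stop("the structural model extends the item-effects measurement model")
  predictor_set <- match.arg(predictor_set)
  predictor_set <- switch(predictor_set,
                          states_only = "states",
                          states_plus_item_effects = "full",
                          predictor_set)
  stopifnot(is.character(outcome_label), length(outcome_label) == 1L,
            nzchar(outcome_label))
  structure(list(base = base, outcome_label = outcome_label,
                 predictor_set = predictor_set),
            class = "lst_structural_spec")
}

build_structural_msp <- function(sspec) {
  base <- build_msp(sspec$base)
  T_ <- sspec$base$design$n_occasions
  p <- base$p + 1L
  m <- base$m
  obs <- c(base$obs_names, sspec$outcome_label)
  Lambda0 <- rbind(base$Lambda0, 0)
  lam_map <- rbind(base$lam_map, 0L)
  pred_cols <- if (sspec$predictor_set == "states") seq_len(T_)
               else seq_len(m)
  lam_map[p, pred_cols] <- seq_along(pred_cols)
  lam_names <- paste0("gamma_", base$latent_labels[pred_cols])
  alpha0 <- c(base$alpha0, 0)
  names(alpha0) <- obs
  alpha_map <- c(base$alpha_map, 1L)
  list(p = p, m = m,
       obs_names = obs,
       latent_labels = base$latent_labels,
       Lambda0 = Lambda0, lam_map = lam_map, n_lam = length(pred_cols),
       alpha0 = alpha0, alpha_map = alpha_map, n_alpha = 1L,
       lam_names = lam_names,
       alpha_names = paste0("nu_", sspec$outcome_label),
       theta_names = paste0("theta_", obs),
       kappa_names = paste0("kappa_", base$latent_labels),
       phi_names = paste0("phi_", vech_names(base$latent_labels)),
       pred_cols = pred_cols)
}

start_values_structural <- function(sspec, msp, mom) {
  base_msp <- build_msp(sspec$base)
  pb <- base_msp$p
  mom_base <- list(mu = mom$mu[seq_len(pb)],
                   Sigma = mom$Sigma[seq_len(pb), seq_len(pb), drop = FALSE])
  v_base <- start_values_nat(sspec$base, base_msp, mom_base)
  ib <- msp_idx(base_msp)
  mu_z <- mom$mu[pb + 1L]
  var_z <- mom$Sigma[pb + 1L, pb + 1L]
  c(v_base[ib$kappa], v_base[ib$phi],
    rep(0, msp$n_lam),              # gamma
    mu_z,                           # nu
    v_base[ib$theta], max(var_z, 1e-3))
}

#' Fit the structural outcome-regression model
#'
#' Simultaneous ML (or FIML) fit of the item-effects measurement model and
#' the latent regression of the outcome.  The explained variance is
#' model-implied, \eqn{R^2 = \gamma'\Phi\gamma / (\gamma'\Phi\gamma +
#' \mathrm{var}(\epsilon_Z))}, and standardized coefficients use the
#' model-implied outcome SD: \eqn{\beta_j = \gamma_j \,
#' \mathrm{SD}(\zeta_j) / \mathrm{SD}(Z)}.
#'
#' @param sspec An \code{\link{structural_spec}}.
#' @param data Data frame with the measurement columns and the outcome
#'   column.
#' @param ... Passed to \code{\link{lst_fit}} (estimator, se, control).
#' @return Object of class \code{lst_structural_result} with standardized
#'   coefficients \code{$betas_std}, \code{$r2}, raw \code{$gamma},
#'   \code{$nu}, \code{$var_ez}, and the underlying \code{$fit}.
#'   Standardized coefficients with absolute value above 1 (possible under
#'   predictor collininearity) are flagged in \code{$collinearity}.
#' @export
fit_structural <- function(sspec, data, ...) {
  stopifnot(inherits(sspec, "lst_structural_spec"))
  if (!sspec$outcome_label %in% names(data))
    stop("outcome column not present in data: ", sspec$outcome_label)
  z <- data[[sspec$outcome_label]]
  if (stats::var(z, na.rm = TRUE) < 1e-12)
    stop("outcome is constant; the regression is undefined")
  fit <- lst_fit(sspec, data, ...)
  msp <- fit$msp
  idx <- msp_idx(msp)
  v <- fit$estimates
  Phi <- unvech(v[idx$phi], msp$m)
  gamma_full <- numeric(msp$m)
  gamma_full[msp$pred_cols] <- v[idx$lam]
  explained <- as.numeric(gamma_full %*% Phi %*% gamma_full)
  var_ez <- unname(v[idx$theta][msp$p])
  var_z <- explained + var_ez
  r2 <- explained / var_z
  sds <- sqrt(diag(Phi))
  betas <- gamma_full[msp$pred_cols] * sds[msp$pred_cols] / sqrt(var_z)
  names(betas) <- msp$latent_labels[msp$pred_cols]
  structure(list(sspec = sspec, fit = fit,
                 outcome = sspec$outcome_label,
                 predictor_set = sspec$predictor_set,
                 betas_std = betas,
                 gamma = stats::setNames(gamma_full[msp$pred_cols],
                                         msp$latent_labels[msp$pred_cols]),
                 nu = unname(v[idx$alpha]),
                 var_ez = var_ez,
                 sd_z = sqrt(var_z),
                 r2 = r2,
                 loglik = fit$loglik,
                 n_free = fit$n_free,
                 converged = fit$converged,
                 collinearity = any(abs(betas) > 1)),
            class = "lst_structural_result")
}

#' Incremental variance explained by the item-effect variables
#'
#' \eqn{\Delta R^2 = R^2_{full} - R^2_{reduced}} between the states-only and
#' the states-plus-item-effects predictor sets for the same outcome on the
#' same data, together with the likelihood-ratio test between the two
#' structural models.
#'
#' @param res_reduced,res_full \code{lst_structural_result} objects sharing
#'   outcome, data and measurement base, with nested predictor sets.
#' @return List with \code{delta_r2}, \code{r2_reduced}, \code{r2_full} and
#'   the \code{lr} test (\code{stat}, \code{ddf}, \code{p_value}).
#' @export
compare_increment <- function(res_reduced, res_full) {
  stopifnot(inherits(res_reduced, "lst_structural_result"),
            inherits(res_full, "lst_structural_result"))
  if (res_reduced$outcome != res_full$outcome)
    stop("results refer to different outcomes")
  if (res_reduced$fit$N_used != res_full$fit$N_used)
    stop("results were fitted on different samples")
  nested <- (res_reduced$predictor_set == "states" &&
             res_full$predictor_set == "full") ||
            res_reduced$predictor_set == res_full$predictor_set
  if (!nested)
    stop("predictor sets are not nested (expected states within full)")
  list(delta_r2 = res_full$r2 - res_reduced$r2,
       r2_reduced = res_reduced$r2,
       r2_full = res_full$r2,
       lr = if (res_full$n_free > res_reduced$n_free)
         lr_test(res_reduced$fit, res_full$fit)
       else list(stat = 0, ddf = 0, p_value = 1))
}

#' Outcome composite from item columns
#'
#' Scores an index as the mean of the available item responses per row
#' (rows with no available response get \code{NA}).
#'
#' @param data Data frame.
#' @param columns Names of the item columns to average.
#' @return Numeric vector of composite scores.
#' @export
build_composite <- function(data, columns) {
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols))
    stop("composite columns not in data: ",
         paste(missing_cols, collapse = ", "))
  rowMeans(as.matrix(data[, columns, drop = FALSE]), na.rm = TRUE)
}

#' @export
print.lst_structural_result <- function(x, digits = 3, ...) {
  cat(sprintf("Latent regression of '%s' on %s predictors\n",
              x$outcome,
              if (x$predictor_set == "states") "state"
              else "state + item-effect"))
  tab <- data.frame(predictor = names(x$betas_std),
                    beta_std = round(x$betas_std, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("R2 = %.3f (model-implied outcome SD %.3f)\n", x$r2, x$sd_z))
  if (x$collinearity)
    cat("note: |standardized coefficient| > 1 (predictor collinearity)\n")
  invisible(x)
}
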