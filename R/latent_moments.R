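#' Latent moment table
#'
#' Container for the latent-variable summary of a multi-state model with
#' item-effect variables: means, standard deviations and correlations of the
#' latent states \eqn{\eta_t} and item-effect variables \eqn{\delta_i},
#' with optional significance flags (two-sided, alpha = .05).
#'
#' @param labels Latent labels, \code{eta1..etaT} followed by
#'   \code{delta<i>} for the non-reference items in ascending item order.
#' @param means,sds Numeric vectors (sds > 0).
#' @param corr Correlation matrix (unit diagonal, entries in [-1, 1]).
#' @param reference_item Index of the reference item.
#' @param n Sample size behind the estimates (optional).
#' @param sig_means,sig_sds Logical vectors: significantly different from
#'   zero at p < .05 (NA when unknown).
#' @param sig_corr Logical matrix for the correlations (NA when unknown).
#' @return Object of class \code{latent_moment_table}.
#' @export
latent_moment_table <- function(labels, means, sds, corr, reference_item,
                                n = NA_integer_,
                                sig_means = NULL, sig_sds = NULL,
                                sig_corr = NULL) {
  m <- length(labels)
  stopifnot(length(means) == m, length(sds) == m, all(dim(corr) == m))
  if (any(sds <= 0)) stop("latent standard deviations must be positive")
  if (max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-8)
    stop("corr must be symmetric with unit diagonal")
  if (max(abs(corr)) > 1 + 1e-8) stop("correlations must lie in [-1, 1]")
  corr <- (corr + t(corr)) / 2
  dimnames(corr) <- list(labels, labels)
  structure(list(labels = labels,
                 means = stats::setNames(as.numeric(means), labels),
                 sds = stats::setNames(as.numeric(sds), labels),
                 corr = corr,
                 reference_item = as.integer(reference_item),
                 n = n,
                 sig_means = sig_means %||% rep(NA, m),
                 sig_sds = sig_sds %||% rep(NA, m),
                 sig_corr = sig_corr %||%
                   matrix(NA, m, m, dimnames = list(labels, labels))),
            class = "latent_moment_table")
}

lmt_cov <- function(table) cor_to_cov(table$corr, table$sds)

#' Extract latent means, SDs and correlations from a fitted model
#'
#' Returns the estimated latent moments \eqn{\hat\kappa},
#' \eqn{\sqrt{\mathrm{diag}(\hat\Phi)}} and the correlation matrix derived
#' from \eqn{\hat\Phi}, with Wald-type significance flags: means tested
#' directly, variances on the log scale, correlations through the Fisher-z
#' transform (delta method).
#'
#' @param fitted A converged \code{\link{lst_fit}} of a measurement model.
#' @return A \code{\link{latent_moment_table}}.
#' @export
extract_latent_moments <- function(fitted) {
  stopifnot(inherits(fitted, "lst_fit"), inherits(fitted$spec, "lst_spec"))
  spec <- fitted$spec
  msp <- fitted$msp
  idx <- msp_idx(msp)
  v <- fitted$estimates
  kappa <- v[idx$kappa]
  Phi <- unvech(v[idx$phi], msp$m)
  if (is.null(chol_or_null(Phi)))
    stop("estimated latent covariance is not positive definite")
  sds <- sqrt(diag(Phi))
  corr <- cov_to_cor(Phi)
  sig_means <- sig_sds <- rep(NA, msp$m)
  sig_corr <- matrix(NA, msp$m, msp$m)
  if (!is.null(fitted$vcov)) {
    sig_means <- wald_flags(fitted, "means")
    sig_sds <- wald_flags(fitted, "sds")
    sig_corr <- wald_flags(fitted, "correlations")
  }
  latent_moment_table(spec$latent_labels, kappa, sds, corr,
                      reference_item = spec$reference_item,
                      n = fitted$N_used,
                      sig_means = sig_means, sig_sds = sig_sds,
                      sig_corr = sig_corr)
}

#' Wald significance flags for latent moments
#'
#' Two-sided z tests at alpha = .05: latent means against zero; latent
#' variances against zero on the log scale (so the flag marks SD
#' significantly different from zero); correlations against zero via the
#' Fisher-z transform with delta-method standard errors.
#'
#' @param fitted An \code{\link{lst_fit}} with an available \code{vcov}.
#' @param quantity One of \code{"means"}, \code{"sds"},
#'   \code{"correlations"}.
#' @param alpha Test level (default .05).
#' @return Logical vector (means, sds) or matrix (correlations).
#' @export
wald_flags <- function(fitted, quantity = c("means", "sds", "correlations"),
                       alpha = 0.05) {
  quantity <- match.arg(quantity)
  if (is.null(fitted$vcov))
    stop("wald_flags requires the parameter covariance; refit with se = TRUE")
  msp <- fitted$msp
  idx <- msp_idx(msp)
  zcrit <- stats::qnorm(1 - alpha / 2)
  m <- msp$m
  if (quantity == "means") {
    est <- fitted$estimates[idx$kappa]
    se <- sqrt(pmax(diag(fitted$vcov)[idx$kappa], 0))
    return(stats::setNames(abs(est / se) > zcrit, msp$latent_labels))
  }
  if (quantity == "sds") {
    # Wald z of the variance against zero; an SD differs from zero iff its
    # variance does
    dm <- delta_method(fitted, function(v) diag(unvech(v[idx$phi], m)))
    return(stats::setNames(abs(dm$est / dm$se) > zcrit, msp$latent_labels))
  }
  low <- lower.tri(matrix(0, m, m))
  dm <- delta_method(fitted, function(v) {
    R <- cov_to_cor(unvech(v[idx$phi], m))
    atanh(pmin(pmax(R[low], -1 + 1e-12), 1 - 1e-12))
  })
  flags <- matrix(NA, m, m)
  flags[low] <- abs(dm$est / dm$se) > zcrit
  flags[upper.tri(flags)] <- t(flags)[upper.tri(flags)]
  dimnames(flags) <- list(msp$latent_labels, msp$latent_labels)
  flags
}

# Linear map taking the latent vector under reference r to the latent vector
# under reference s: eta'_t = eta_t + delta_s; delta'_i = delta_i - delta_s
# (i != r, s); delta'_r = -delta_s.  Returns the matrix and the new labels.
reference_switch_map <- function(labels, r, s) {
  etas <- grep("^eta", labels, value = TRUE)
  T_ <- length(etas)
  old_items <- as.integer(sub("^delta", "", grep("^delta", labels,
                                                 value = TRUE)))
  if (!(s %in% old_items))
    stop(sprintf("item %d has no item-effect variable in this table", s))
  new_items <- sort(c(setdiff(old_items, s), r))
  new_labels <- c(etas, paste0("delta", new_items))
  m <- length(labels)
  A <- matrix(0, m, m, dimnames = list(new_labels, labels))
  ds <- paste0("delta", s)
  for (t in seq_len(T_)) {
    A[etas[t], etas[t]] <- 1
    A[etas[t], ds] <- 1
  }
  for (i in new_items) {
    nl <- paste0("delta", i)
    if (i == r) {
      A[nl, ds] <- -1
    } else {
      A[nl, nl] <- 1
      A[nl, ds] <- -1
    }
  }
  list(A = A, labels = new_labels)
}

#' Re-express latent moments under a different reference item
#'
#' Applies the exact linear reparameterization between reference items to a
#' latent moment table: with old reference \eqn{r} and new reference
#' \eqn{s}, \eqn{\eta'_t = \eta_t + \delta_s}, \eqn{\delta'_i = \delta_i -
#' \delta_s} for \eqn{i \notin \{r, s\}}, and \eqn{\delta'_r = -\delta_s}.
#' The implied observed-variable moments are unchanged; only the meaning
#' (and hence the means, SDs and correlations) of the latent variables
#' changes.
#'
#' @param table A \code{\link{latent_moment_table}} from an item-effects
#'   model.
#' @param new_reference Item index \eqn{s}; must have an item-effect
#'   variable in \code{table}.  \code{s = r} returns the table unchanged.
#' @return A \code{\link{latent_moment_table}} under the new reference.
#'   Significance flags are not propagated (they require re-estimation).
#' @examples
#' t3 <- published_latent_moments("2008-2010")
#' t4 <- reference_switch(t3, 5)
#' round(t4$means["delta3"], 3)
#' @export
reference_switch <- function(table, new_reference) {
  stopifnot(inherits(table, "latent_moment_table"))
  s <- as.integer(new_reference)
  r <- table$reference_item
  if (s == r) return(table)
  sw <- reference_switch_map(table$labels, r, s)
  mu <- as.numeric(sw$A %*% table$means)
  C <- sw$A %*% lmt_cov(table) %*% t(sw$A)
  sds <- sqrt(diag(C))
  latent_moment_table(sw$labels, mu, sds, cov_to_cor(C),
                      reference_item = s, n = table$n)
}

#' Re-parameterize a fitted/true parameter vector under a new reference item
#'
#' The parameter-level counterpart of \code{\link{reference_switch}}: maps an
#' item-effects \code{\link{lst_parameters}} with reference \eqn{r} to the
#' equivalent parameters under reference \eqn{s}.  The implied mean vector
#' and covariance matrix of the observed variables are identical, which is
#' why model fit does not depend on the reference item.
#'
#' @param params An \code{\link{lst_parameters}} of an item-effects spec.
#' @param new_reference New reference item index.
#' @return An \code{\link{lst_parameters}} for the reference-\code{s} spec.
#' @export
switch_parameters <- function(params, new_reference) {
  stopifnot(inherits(params, "lst_parameters"))
  spec <- params$spec
  if (spec$variant != "item_effects")
    stop("reference switching applies to the item-effects variant")
  s <- as.integer(new_reference)
  if (s == spec$reference_item) return(params)
  sw <- reference_switch_map(spec$latent_labels, spec$reference_item, s)
  new_spec <- lst_spec("item_effects", s, spec$design)
  # rows of A are ordered as new_spec$latent_labels by construction
  stopifnot(identical(rownames(sw$A), new_spec$latent_labels))
  lst_parameters(new_spec,
                 kappa = as.numeric(sw$A %*% params$kappa),
                 Phi = sw$A %*% params$Phi %*% t(sw$A),
                 theta = params$theta)
}

#' @export
print.latent_moment_table <- function(x, digits = 3, ...) {
  cat(sprintf("Latent moments (reference item %d%s)\n", x$reference_item,
              if (is.na(x$n)) "" else sprintf(", N = %d", x$n)))
  df <- as.data.frame.latent_moment_table(x, digits = digits)
  print(df, row.names = FALSE)
  if (any(!is.na(x$sig_corr)) && any(!x$sig_corr, na.rm = TRUE))
    cat("(correlations marked n.s. are not significant at p < .05)\n")
  invisible(x)
}

#' @export
as.data.frame.latent_moment_table <- function(x, row.names = NULL,
                                              optional = FALSE, digits = 3,
                                              ...) {
  m <- length(x$labels)
  R <- matrix("", m, m, dimnames = list(x$labels, x$labels))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j < i) next
    val <- formatC(x$corr[i, j], digits = digits, format = "f")
    if (isFALSE(x$sig_corr[i, j]) && i != j) val <- paste0(val, " n.s.")
    R[i, j] <- val
  }
  data.frame(variable = x$labels,
             mean = round(x$means, digits),
             sd = round(x$sds, digits),
             R, check.names = FALSE, stringsAsFactors = FALSE)
}
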