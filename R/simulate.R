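#' Default generating parameters for the synthetic panel
#'
#' An admissible item-effects parameter vector whose latent moments equal the
#' published reference-item-3 estimates (see
#' \code{\link{published_latent_moments}}): state means around 5.5 with SDs
#' near 1.0 and correlations .70-.79, item-effect means between -0.28 and
#' -0.99 with SDs 0.39-0.89, and cross-block correlations below |.20| in
#' absolute value.  Residual variances are 0.5 on every item-occasion, which
#' places all implied observed-item SDs inside the reported 1.08-1.63 range.
#'
#' @param design A \code{\link{panel_design}} (5 items x 3 occasions).
#' @param period Which measurement period's published moments to use.
#' @return An \code{\link{lst_parameters}} for the reference-item-3
#'   item-effects spec.
#' @export
default_true_parameters <- function(design = panel_design(),
                                    period = "2008-2010") {
  if (design$n_items != 5 || design$n_occasions != 3)
    stop("default generating parameters are defined for the 5 x 3 design")
  tab <- published_latent_moments(period)
  spec <- lst_spec("item_effects", 3L, design)
  lst_parameters(spec,
                 kappa = tab$means,
                 Phi = lmt_cov(tab),
                 theta = rep(0.5, spec$p))
}

#' Outcome specification for the generator
#'
#' Describes one outcome composite generated from the latent variables: a
#' linear index with target standardized coefficients, rescaled to a target
#' mean and SD, with an optional monotone right-skew transform
#' (\eqn{\exp(s\,z)} applied to the standardized linear index, then
#' re-standardized) emulating the skewed distribution of health composites
#' in a non-clinical population.
#'
#' @param label Column name for the outcome.
#' @param beta_std Named numeric vector of standardized regression
#'   coefficients on (a subset of) the latent variables.
#' @param mean,sd Target sample-scale mean and SD.
#' @param skew Skew-transform strength \code{s >= 0}; 0 disables the
#'   transform and makes the outcome exactly linear-normal in the latents.
#' @return Object of class \code{lst_outcome_spec}.
#' @export
outcome_spec <- function(label, beta_std, mean, sd, skew = 0) {
  stopifnot(is.character(label), length(label) == 1L,
            !is.null(names(beta_std)), sd > 0, skew >= 0)
  structure(list(label = label, beta_std = beta_std, mean = mean, sd = sd,
                 skew = skew),
            class = "lst_outcome_spec")
}

#' Default outcome specifications
#'
#' Two health composites linked to the latent variables with standardized
#' coefficients of the magnitudes reported for the reference-item-3
#' full-predictor regressions (2008-2010): a psychological-distress index
#' ("mhi", mean 2.20, SD 0.82, explaining ~29% latent variance) and a
#' physical mobility-problem index ("phi_index", mean 1.20, SD 0.34, ~19%).
#' Both use the right-skew transform (strength 0.5), matching the reported
#' right-skewed composite distributions.
#'
#' @return List of \code{\link{outcome_spec}} objects.
#' @export
default_outcome_specs <- function() {
  list(
    outcome_spec("mhi",
                 beta_std = c(eta1 = -0.063, eta2 = -0.196, eta3 = -0.292,
                              delta1 = 0.022, delta2 = -0.083,
                              delta4 = 0.084, delta5 = -0.058),
                 mean = 2.20, sd = 0.82, skew = 0.5),
    outcome_spec("phi_index",
                 beta_std = c(eta1 = -0.120, eta2 = -0.100, eta3 = -0.101,
                              delta1 = 0.158, delta2 = -0.359,
                              delta4 = 0.108, delta5 = -0.062),
                 mean = 1.20, sd = 0.34, skew = 0.5))
}

#' Simulation configuration
#'
#' @param design A \code{\link{panel_design}}.
#' @param theta_true Generating \code{\link{lst_parameters}} (item-effects
#'   variant).
#' @param N Number of respondents (default 2543, the complete-case sample
#'   size the generator emulates).
#' @param outcome_specs List of \code{\link{outcome_spec}} objects (possibly
#'   empty).
#' @param missing_rate Per-wave unit-nonresponse probability in [0, 1):
#'   whole occasions are removed per respondent, never all of them.
#' @param discretize Round and clip responses to the 1..7 scale (off by
#'   default: the analysis model is linear-normal; discretization is a
#'   deliberate model-mismatch mode for robustness experiments).
#' @param seed Integer seed; the generator is deterministic given the seed
#'   (R's default Mersenne-Twister RNG).
#' @return Object of class \code{lst_sim_config}.
#' @export
sim_config <- function(design = panel_design(),
                       theta_true = default_true_parameters(design),
                       N = 2543L,
                       outcome_specs = list(),
                       missing_rate = 0,
                       discretize = FALSE,
                       seed = NULL) {
  stopifnot(inherits(design, "panel_design"),
            inherits(theta_true, "lst_parameters"),
            is_count(N), N >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (theta_true$spec$variant != "item_effects")
    stop("the generator draws from the item-effects model")
  structure(list(design = design, theta_true = theta_true, N = as.integer(N),
                 outcome_specs = outcome_specs,
                 missing_rate = missing_rate,
                 discretize = isTRUE(discretize), seed = seed),
            class = "lst_sim_config")
}

# Multivariate normal draws via Cholesky (deterministic given the RNG state).
rmvn <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * length(mu)), n, length(mu))
  sweep(Z %*% L, 2, mu, `+`)
}

#' Simulate a panel dataset from the item-effects model
#'
#' Draws latent vectors \eqn{\zeta \sim N(\kappa, \Phi)} and residuals
#' \eqn{\epsilon \sim N(0, \Theta)}, composes \eqn{Y = \tilde\alpha +
#' \Lambda\zeta + \epsilon}, generates the configured outcome composites from
#' the same latent draws, and finally injects wave-level unit nonresponse.
#'
#' @param config An \code{\link{sim_config}}.
#' @return Data frame with the observed item columns
#'   (\code{<item>_w<occasion>}) and one column per outcome.  The latent
#'   draws are attached as attribute \code{"latents"}; the seed used as
#'   attribute \code{"seed"}.
#' @examples
#' d <- simulate_panel(sim_config(N = 100, seed = 42))
#' dim(d)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "lst_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  params <- config$theta_true
  spec <- params$spec
  msp <- build_msp(spec)
  N <- config$N
  Z <- rmvn(N, params$kappa, params$Phi)
  colnames(Z) <- spec$latent_labels
  E <- matrix(stats::rnorm(N * spec$p, sd = rep(sqrt(params$theta),
                                                each = N)),
              N, spec$p)
  Lambda <- msp_Lambda(msp, numeric(0))
  Y <- Z %*% t(Lambda) + E
  Y <- sweep(Y, 2, msp$alpha0, `+`)
  colnames(Y) <- msp$obs_names
  if (config$discretize)
    Y <- pmin(pmax(round(Y), 1), 7)
  out <- as.data.frame(Y)
  for (os in config$outcome_specs)
    out[[os$label]] <- simulate_outcome(Z, os)
  if (config$missing_rate > 0)
    out <- inject_missingness(out, config$missing_rate, config$design)
  attr(out, "latents") <- Z
  attr(out, "seed") <- config$seed
  out
}

#' Generate one outcome composite from latent draws
#'
#' Builds the standardized linear index \eqn{u = \sum_j \beta_j \zeta^*_j +
#' \epsilon} with \eqn{\mathrm{var}(u) = 1} (residual variance
#' \eqn{1 - \beta'R\beta}), optionally applies the monotone skew transform
#' \eqn{\exp(s\,u)}, and rescales to the target mean and SD.  With
#' \code{skew = 0} the standardized latent regression coefficients of the
#' generated outcome equal \code{beta_std} exactly in the population.
#'
#' @param latents Matrix of latent draws (columns named by latent labels).
#' @param ospec An \code{\link{outcome_spec}}.
#' @param seed Optional seed (set only if given; normally the caller's RNG
#'   stream is used so that one panel seed fixes everything).
#' @return Numeric vector of outcome values.
#' @export
simulate_outcome <- function(latents, ospec, seed = NULL) {
  stopifnot(inherits(ospec, "lst_outcome_spec"))
  if (!is.null(seed)) set.seed(seed)
  miss <- setdiff(names(ospec$beta_std), colnames(latents))
  if (length(miss))
    stop("outcome coefficients refer to unknown latents: ",
         paste(miss, collapse = ", "))
  Zs <- scale(latents[, names(ospec$beta_std), drop = FALSE])
  b <- ospec$beta_std
  R <- stats::cor(latents[, names(b), drop = FALSE])
  expl <- as.numeric(b %*% R %*% b)
  if (expl >= 1)
    stop("standardized coefficients imply explained variance >= 1")
  u <- as.numeric(Zs %*% b) +
    stats::rnorm(nrow(latents), sd = sqrt(1 - expl))
  if (ospec$skew > 0) {
    u <- exp(ospec$skew * (u - mean(u)) / stats::sd(u))
    u <- (u - mean(u)) / stats::sd(u)
  }
  ospec$mean + ospec$sd * (u - mean(u)) / stats::sd(u)
}

#' Inject wave-level unit nonresponse
#'
#' Removes whole measurement occasions per respondent completely at random
#' (MCAR): each wave is dropped independently with probability \code{rate},
#' except that every respondent keeps at least one wave (a respondent drawn
#' to lose all waves keeps one uniformly chosen wave).  Item columns of a
#' dropped wave are set to \code{NA}; outcome columns are untouched.
#'
#' @param data Data frame from \code{\link{simulate_panel}} (or any data
#'   with the design's item columns).
#' @param rate Per-wave nonresponse probability in [0, 1).
#' @param design The \code{\link{panel_design}}.
#' @param seed Optional seed.
#' @return The data with missing waves set to \code{NA}.
#' @export
inject_missingness <- function(data, rate, design = panel_design(),
                               seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(data)
  N <- nrow(data)
  T_ <- design$n_occasions
  drop <- matrix(stats::runif(N * T_) < rate, N, T_)
  all_gone <- rowSums(drop) == T_
  if (any(all_gone)) {
    keep <- sample.int(T_, sum(all_gone), replace = TRUE)
    drop[cbind(which(all_gone), keep)] <- FALSE
  }
  for (t in seq_len(T_)) {
    cols <- paste0(design$item_labels, "_w", design$occasion_labels[t])
    data[drop[, t], cols] <- NA_real_
  }
  data
}
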