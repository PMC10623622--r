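#' Specify a longitudinal multi-state measurement model
#'
#' Declares one of the two measurement-model variants for an \code{I} item by
#' \code{T} occasion panel:
#' \describe{
#'   \item{\code{"states_only"}}{A congeneric multi-state model under strong
#'     (scalar) measurement invariance: \eqn{Y_{it} = \alpha_i + \lambda_i
#'     \eta_t + \epsilon_{it}} with time-invariant loadings and intercepts,
#'     identified by fixing \eqn{\lambda_r = 1,\ \alpha_r = 0} for the
#'     reference item \eqn{r}.}
#'   \item{\code{"item_effects"}}{The extension with person-specific
#'     item-effect variables: \eqn{Y_{it} = \eta_t + \delta_i +
#'     \epsilon_{it}} with all loadings fixed to 1 and all intercepts fixed
#'     to 0.  \eqn{\delta_i} is the stable latent difference between item
#'     \eqn{i}'s true score and the reference item's true score;
#'     \eqn{\delta_r \equiv 0}.}
#' }
#' Latent variables are ordered \eqn{\eta_1, \ldots, \eta_T} followed (for
#' \code{"item_effects"}) by \eqn{\delta_i} for every non-reference item in
#' ascending item order, so the latent dimension is \code{m = T} or
#' \code{m = T + I - 1}.
#'
#' @param variant \code{"item_effects"} or \code{"states_only"}.
#' @param reference_item Index \code{r} in \code{1..I} of the reference item
#'   whose true score defines the latent states.
#' @param design A \code{\link{panel_design}}.
#' @return An object of class \code{lst_spec}.
#' @examples
#' sp <- lst_spec("item_effects", reference_item = 3)
#' sp$latent_labels
#' count_df(sp)
#' @export
lst_spec <- function(variant = c("item_effects", "states_only"),
                     reference_item = 3L,
                     design = panel_design()) {
  variant <- match.arg(variant)
  stopifnot(inherits(design, "panel_design"))
  if (!is_count(reference_item) ||
      reference_item < 1 || reference_item > design$n_items)
    stop(sprintf("reference_item must be an item index in 1..%d",
                 design$n_items))
  r <- as.integer(reference_item)
  T_ <- design$n_occasions
  I <- design$n_items
  eta <- paste0("eta", seq_len(T_))
  latent <- eta
  if (variant == "item_effects")
    latent <- c(eta, paste0("delta", setdiff(seq_len(I), r)))
  spec <- structure(
    list(design = design, variant = variant, reference_item = r,
         invariance = "strong",
         latent_labels = latent,
         m = length(latent),
         p = I * T_),
    class = "lst_spec")
  spec
}

# ---------------------------------------------------------------------------
# Internal moment-structure problem (msp): a generic linear moment structure
#   mu    = alpha0 + (free alphas scattered by alpha_map) + Lambda kappa
#   Sigma = Lambda Phi Lambda' + diag(theta)
# with entry-level tie maps so that time-invariant loadings/intercepts and
# structural regression rows are all instances of one engine.
build_msp <- function(spec) {
  d <- spec$design
  I <- d$n_items; T_ <- d$n_occasions
  p <- spec$p; m <- spec$m; r <- spec$reference_item
  obs <- observed_names(d)
  Lambda0 <- matrix(0, p, m, dimnames = list(obs, spec$latent_labels))
  lam_map <- matrix(0L, p, m)
  alpha0 <- stats::setNames(numeric(p), obs)
  alpha_map <- integer(p)
  lam_names <- character(0)
  alpha_names <- character(0)
  if (spec$variant == "item_effects") {
    for (t in seq_len(T_)) {
      for (i in seq_len(I)) {
        row <- obs_index(d, i, t)
        Lambda0[row, t] <- 1
        if (i != r)
          Lambda0[row, paste0("delta", i)] <- 1
      }
    }
  } else {
    free_items <- setdiff(seq_len(I), r)
    lam_idx <- stats::setNames(seq_along(free_items), free_items)
    for (t in seq_len(T_)) {
      for (i in seq_len(I)) {
        row <- obs_index(d, i, t)
        if (i == r) {
          Lambda0[row, t] <- 1
        } else {
          lam_map[row, t] <- lam_idx[[as.character(i)]]
          alpha_map[row] <- lam_idx[[as.character(i)]]
        }
      }
    }
    lam_names <- paste0("lambda_", d$item_labels[free_items])
    alpha_names <- paste0("alpha_", d$item_labels[free_items])
  }
  list(p = p, m = m,
       obs_names = obs,
       latent_labels = spec$latent_labels,
       Lambda0 = Lambda0, lam_map = lam_map, n_lam = length(lam_names),
       alpha0 = alpha0, alpha_map = alpha_map, n_alpha = length(alpha_names),
       lam_names = lam_names, alpha_names = alpha_names,
       theta_names = paste0("theta_", obs),
       kappa_names = paste0("kappa_", spec$latent_labels),
       phi_names = paste0("phi_", vech_names(spec$latent_labels)))
}

msp_of <- function(spec) {
  if (inherits(spec, "lst_structural_spec")) build_structural_msp(spec)
  else build_msp(spec)
}

# number of free parameters of an msp
msp_q <- function(msp)
  msp$m + msp$m * (msp$m + 1) / 2 + msp$n_lam + msp$n_alpha + msp$p

#' Loading matrix of a model specification
#'
#' Returns the \code{p x m} factor-loading matrix implied by a specification
#' and (for the congeneric \code{"states_only"} variant) a vector of item
#' loadings.  Under \code{"item_effects"} all loadings are fixed at 1 by
#' construction, so no loading values are needed.
#'
#' @param spec An \code{\link{lst_spec}}.
#' @param lambda Optional numeric vector of length \code{I} of item loadings
#'   (the reference item's entry must be 1).  Defaults to all ones.
#' @return Matrix with rows in observed-variable order and columns in latent
#'   order.
#' @export
loading_matrix <- function(spec, lambda = NULL) {
  stopifnot(inherits(spec, "lst_spec"))
  msp <- build_msp(spec)
  I <- spec$design$n_items
  if (is.null(lambda)) lambda <- rep(1, I)
  stopifnot(length(lambda) == I)
  if (abs(lambda[spec$reference_item] - 1) > 1e-12)
    stop("the reference item's loading is fixed to 1")
  lam_free <- lambda[setdiff(seq_len(I), spec$reference_item)]
  msp_Lambda(msp, lam_free)
}

msp_Lambda <- function(msp, lam_free) {
  L <- msp$Lambda0
  if (msp$n_lam > 0 && any(msp$lam_map > 0)) {
    nz <- which(msp$lam_map > 0)
    L[nz] <- lam_free[msp$lam_map[nz]]
  }
  L
}

msp_alpha <- function(msp, alpha_free) {
  a <- msp$alpha0
  if (msp$n_alpha > 0 && any(msp$alpha_map > 0)) {
    nz <- which(msp$alpha_map > 0)
    a[nz] <- a[nz] + alpha_free[msp$alpha_map[nz]]
  }
  a
}

#' Count free parameters and model degrees of freedom
#'
#' The saturated mean-and-covariance structure of \code{p} observed variables
#' has \code{p(p+3)/2} moments; the model's degrees of freedom are that count
#' minus the number of free parameters \code{q}.  For the default 5 item x 3
#' occasion design this gives \code{q = 32, df = 103} (states only) and
#' \code{q = 50, df = 85} (with item effects).
#'
#' @param spec An \code{\link{lst_spec}} (or structural specification).
#' @return Integer count.
#' @export
count_free_parameters <- function(spec) {
  as.integer(msp_q(msp_of(spec)))
}

#' @rdname count_free_parameters
#' @export
count_df <- function(spec) {
  msp <- msp_of(spec)
  as.integer(msp$p * (msp$p + 3) / 2 - msp_q(msp))
}

#' @export
print.lst_spec <- function(x, ...) {
  cat(sprintf("Multi-state measurement model (%s), reference item %d (%s)\n",
              x$variant, x$reference_item,
              x$design$item_labels[x$reference_item]))
  cat(sprintf("  %d items x %d occasions; latent variables: %s\n",
              x$design$n_items, x$design$n_occasions,
              paste(x$latent_labels, collapse = ", ")))
  cat(sprintf("  free parameters: %d; df: %d\n",
              count_free_parameters(x), count_df(x)))
  invisible(x)
}

#' Write / read a model specification as a plain-text config
#'
#' Serializes the declarative part of an \code{\link{lst_spec}} as simple
#' \code{key: value} lines (a YAML subset) and reads it back.
#'
#' @param spec An \code{\link{lst_spec}}.
#' @param path File path.
#' @return \code{read_lst_spec} returns an \code{\link{lst_spec}}.
#' @export
write_lst_spec <- function(spec, path) {
  stopifnot(inherits(spec, "lst_spec"))
  d <- spec$design
  lines <- c(
    paste0("variant: ", spec$variant),
    paste0("reference_item: ", spec$reference_item),
    paste0("n_items: ", d$n_items),
    paste0("n_occasions: ", d$n_occasions),
    paste0("item_labels: ", paste(d$item_labels, collapse = ",")),
    paste0("occasion_labels: ", paste(d$occasion_labels, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lst_spec
#' @export
read_lst_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  get <- function(k) {
    if (!k %in% keys) stop("missing key in spec config: ", k)
    vals[match(k, keys)]
  }
  design <- panel_design(
    n_items = as.integer(get("n_items")),
    n_occasions = as.integer(get("n_occasions")),
    item_labels = strsplit(get("item_labels"), ",")[[1]],
    occasion_labels = strsplit(get("occasion_labels"), ",")[[1]])
  lst_spec(get("variant"), as.integer(get("reference_item")), design)
}
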