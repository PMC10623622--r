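#' Published latent moments of the five-item life-satisfaction scale
#'
#' Latent means, standard deviations and correlations of the multi-state
#' model with person-specific item-effect variables under reference item 3
#' ("I am satisfied with my life"), as estimated on the complete sample
#' (N = 2,543) of a large Dutch household panel for two three-wave
#' measurement periods (2008-2010 and 2011-2013).  These printed estimates
#' serve as inputs for the reference-switch reparameterization and as the
#' magnitudes behind \code{\link{default_true_parameters}}; the underlying
#' raw panel data are access-restricted and are not part of this package.
#'
#' Flags mark cells reported as significantly different from zero at
#' p < .05 (all means and SDs were; a few state/item-effect correlations
#' were not).
#'
#' @param period \code{"2008-2010"} or \code{"2011-2013"}.
#' @return A \code{\link{latent_moment_table}} with reference item 3.
#' @examples
#' published_latent_moments("2008-2010")
#' @export
published_latent_moments <- function(period = c("2008-2010", "2011-2013")) {
  period <- match.arg(period)
  labels <- c("eta1", "eta2", "eta3", "delta1", "delta2", "delta4", "delta5")
  if (period == "2008-2010") {
    means <- c(5.565, 5.548, 5.516, -0.461, -0.330, -0.277, -0.990)
    sds <- c(0.977, 0.977, 0.997, 0.389, 0.400, 0.562, 0.889)
    upper <- c(
      .754, .698, .021, .066, -.135, .002,
            .785, .030, .035, -.199, -.018,
                  .069, .085, -.200, -.014,
                        .626, .317, .316,
                              .227, .111,
                                    .457)
    nonsig <- rbind(c("eta1", "delta1"), c("eta1", "delta5"),
                    c("eta2", "delta1"), c("eta2", "delta2"),
                    c("eta2", "delta5"), c("eta3", "delta5"))
  } else {
    means <- c(5.505, 5.500, 5.484, -0.460, -0.320, -0.214, -0.898)
    sds <- c(0.997, 0.998, 1.032, 0.436, 0.406, 0.532, 0.902)
    upper <- c(
      .763, .737, .062, .082, -.161, .005,
            .786, .078, .103, -.156, .015,
                  .041, .103, -.191, .008,
                        .691, .254, .331,
                              .131, .143,
                                    .431)
    nonsig <- rbind(c("eta1", "delta1"), c("eta1", "delta5"),
                    c("eta2", "delta5"), c("eta3", "delta1"),
                    c("eta3", "delta5"))
  }
  m <- length(labels)
  R <- diag(m)
  # `upper` lists the printed upper triangle row-wise, which matches the
  # column-major order of the lower triangle
  R[lower.tri(R)] <- upper
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  sig_corr <- matrix(TRUE, m, m, dimnames = list(labels, labels))
  for (k in seq_len(nrow(nonsig))) {
    sig_corr[nonsig[k, 1], nonsig[k, 2]] <- FALSE
    sig_corr[nonsig[k, 2], nonsig[k, 1]] <- FALSE
  }
  latent_moment_table(labels, means, sds, R, reference_item = 3L,
                      n = 2543L,
                      sig_means = rep(TRUE, m), sig_sds = rep(TRUE, m),
                      sig_corr = sig_corr)
}
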