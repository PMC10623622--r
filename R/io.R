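#' Read a wide panel CSV
#'
#' Reads a wide-format panel file (one row per respondent, columns
#' \code{<item>_w<occasion>}, empty cells for missing) and validates it
#' against a design: required columns present, numeric content, optional
#' response-scale bounds.  A per-column missingness report is attached as
#' attribute \code{"missingness"}.
#'
#' @param path CSV file path.
#' @param design A \code{\link{panel_design}}.
#' @param bounds Optional numeric \code{c(lower, upper)} response bounds for
#'   the item columns (e.g. \code{c(1, 7)}); out-of-range values raise a
#'   descriptive error.  \code{NULL} (default) skips the check, which is
#'   appropriate for continuous synthetic responses.
#' @return Data frame with all file columns.
#' @export
read_panel_csv <- function(path, design = panel_design(), bounds = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- observed_names(design)
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("malformed header: missing columns ",
         paste(missing_cols, collapse = ", "))
  for (cn in need) {
    if (!is.numeric(d[[cn]])) {
      suppressWarnings(x <- as.numeric(d[[cn]]))
      bad <- which(!is.na(d[[cn]]) & d[[cn]] != "" & is.na(x))
      if (length(bad))
        stop(sprintf("non-numeric cell(s) in column '%s', e.g. row %d: '%s'",
                     cn, bad[1], d[[cn]][bad[1]]))
      d[[cn]] <- x
    }
  }
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2L)
    for (cn in need) {
      x <- d[[cn]]
      bad <- which(!is.na(x) & (x < bounds[1] | x > bounds[2]))
      if (length(bad))
        stop(sprintf(
          "response out of bounds [%g, %g] in column '%s', row %d: %g",
          bounds[1], bounds[2], cn, bad[1], x[bad[1]]))
    }
  }
  attr(d, "missingness") <-
    vapply(d[need], function(x) sum(is.na(x)), 0L)
  d
}

#' @rdname read_panel_csv
#' @param data Data frame to write.
#' @export
write_panel_csv <- function(data, path) {
  out <- data
  for (cn in names(out))
    if (is.double(out[[cn]]))
      # 17 significant digits: doubles survive the round trip bit-exactly
      out[[cn]] <- ifelse(is.na(out[[cn]]), "",
                          sprintf("%.17g", out[[cn]]))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Configuration for the two-period analysis pipeline
#'
#' @param periods Named list of datasets (data frames, or CSV paths read via
#'   \code{\link{read_panel_csv}}), one per measurement period.  All periods
#'   must share the design.
#' @param design A \code{\link{panel_design}}.
#' @param references Reference items to report (first entry is used for the
#'   states-only model).
#' @param outcomes Character vector of outcome column names (possibly
#'   empty).
#' @param estimator Passed to \code{\link{lst_fit}}.
#' @param chi2_scale Chi-square multiplier option, \code{"N"} or
#'   \code{"N-1"}.
#' @param seed Recorded in the provenance header (the fits themselves are
#'   deterministic).
#' @return Object of class \code{lst_run_config}.
#' @export
run_config <- function(periods, design = panel_design(),
                       references = c(3L, 5L), outcomes = character(0),
                       estimator = "ml", chi2_scale = "N", seed = NULL) {
  stopifnot(is.list(periods), length(periods) >= 1)
  if (is.null(names(periods)) || any(!nzchar(names(periods))))
    stop("periods must be a named list")
  structure(list(periods = periods, design = design,
                 references = as.integer(references),
                 outcomes = outcomes, estimator = estimator,
                 chi2_scale = chi2_scale, seed = seed),
            class = "lst_run_config")
}

#' Run the full analysis pipeline over measurement periods
#'
#' For every period: fits the states-only and the item-effects measurement
#' model, assembles the fit-comparison table (including the log-likelihood
#' difference test and information criteria), extracts latent moments under
#' every requested reference item, and—per outcome—fits the states-only and
#' full structural regressions and their incremental-variance comparison.
#' Running two periods realizes the cross-validation design of repeating the
#' identical analysis on the same respondents in different periods.  A stage
#' failure is captured in \code{$failures} instead of aborting the bundle.
#'
#' @param config An \code{\link{run_config}}.
#' @return A report bundle (class \code{lst_report_bundle}): per period the
#'   fitted models, fit table, moment tables and structural results, plus a
#'   provenance record (package version, seed, estimator).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lst_run_config"))
  bundle <- list(provenance = list(
    package = as.character(utils::packageVersion("lstitem")),
    seed = config$seed,
    estimator = config$estimator,
    chi2_scale = config$chi2_scale,
    references = config$references),
    periods = list(), failures = list())
  for (pname in names(config$periods)) {
    res <- list()
    fail <- character(0)
    dat <- config$periods[[pname]]
    if (is.character(dat))
      dat <- read_panel_csv(dat, config$design)
    step <- function(label, expr) {
      tryCatch(expr, error = function(e) {
        fail <<- c(fail, paste0(label, ": ", conditionMessage(e)))
        NULL
      })
    }
    r1 <- config$references[1]
    fits <- list()
    fits[["states_only"]] <- step("fit states_only", lst_fit(
      lst_spec("states_only", r1, config$design), dat,
      estimator = config$estimator, se = FALSE))
    for (r in config$references)
      fits[[paste0("item_effects_ref", r)]] <- step(
        paste0("fit item_effects ref ", r),
        lst_fit(lst_spec("item_effects", r, config$design), dat,
                estimator = config$estimator))
    res$fits <- fits
    ok <- !vapply(fits, is.null, TRUE)
    res$fit_table <- step("fit table",
                          fit_index_table(fits[ok], config$chi2_scale))
    f0 <- fits[["states_only"]]
    f1 <- fits[[paste0("item_effects_ref", r1)]]
    if (!is.null(f0) && !is.null(f1))
      res$lr_states_vs_item_effects <- step("lr test", lr_test(f0, f1))
    res$moments <- list()
    for (r in config$references) {
      fr <- fits[[paste0("item_effects_ref", r)]]
      if (!is.null(fr))
        res$moments[[as.character(r)]] <-
          step(paste0("moments ref ", r), extract_latent_moments(fr))
    }
    res$structural <- list()
    for (oc in config$outcomes) {
      for (r in config$references) {
        base <- lst_spec("item_effects", r, config$design)
        red <- step(paste(oc, "ref", r, "states"), fit_structural(
          structural_spec(base, oc, "states"), dat,
          estimator = config$estimator, se = FALSE))
        ful <- step(paste(oc, "ref", r, "full"), fit_structural(
          structural_spec(base, oc, "full"), dat,
          estimator = config$estimator, se = FALSE))
        key <- paste0(oc, "_ref", r)
        res$structural[[key]] <- list(
          reduced = red, full = ful,
          increment = if (!is.null(red) && !is.null(ful))
            step(paste(key, "increment"), compare_increment(red, ful)))
      }
    }
    bundle$periods[[pname]] <- res
    if (length(fail)) bundle$failures[[pname]] <- fail
  }
  class(bundle) <- "lst_report_bundle"
  bundle
}

#' Structural-results table (outcome regressions)
#'
#' Formats the structural results of one outcome under one reference item
#' as a long table: one row per latent predictor (the reference item's
#' effect variable marked \code{"ref"}), followed by R-squared and the
#' incremental R-squared.
#'
#' @param entry One element of \code{run_pipeline()$periods[[i]]$structural}.
#' @param design The \code{\link{panel_design}}.
#' @param reference_item Reference item of the entry.
#' @return Data frame with columns \code{predictor}, \code{reduced},
#'   \code{full}.
#' @export
structural_table <- function(entry, design = panel_design(),
                             reference_item = 3L) {
  T_ <- design$n_occasions
  preds <- c(paste0("eta", seq_len(T_)),
             paste0("delta", seq_len(design$n_items)))
  fmt <- function(res, pr) {
    if (is.null(res)) return(NA_character_)
    if (pr == paste0("delta", reference_item) &&
        res$predictor_set == "full") return("ref")
    if (!pr %in% names(res$betas_std)) return("")
    formatC(res$betas_std[[pr]], digits = 3, format = "f")
  }
  rows <- data.frame(
    predictor = preds,
    reduced = vapply(preds, function(pr) fmt(entry$reduced, pr), ""),
    full = vapply(preds, function(pr) fmt(entry$full, pr), ""),
    stringsAsFactors = FALSE)
  r2 <- data.frame(
    predictor = c("R2", "delta_R2"),
    reduced = c(formatC(entry$reduced$r2, digits = 3, format = "f"), ""),
    full = c(formatC(entry$full$r2, digits = 3, format = "f"),
             formatC(entry$increment$delta_r2, digits = 3, format = "f")),
    stringsAsFactors = FALSE)
  rbind(rows, r2)
}

#' Write a report bundle as TSV files
#'
#' Emits, per period, the fit-comparison table, the latent-moment tables per
#' reference (with a flag column marking non-significant correlations), and
#' the structural tables, plus a provenance manifest.  Identical
#' configuration and seed yield byte-identical files.
#'
#' @param bundle From \code{\link{run_pipeline}}.
#' @param dir Output directory (created if needed).
#' @param design The \code{\link{panel_design}} used.
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir, design = panel_design()) {
  stopifnot(inherits(bundle, "lst_report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (pname in names(bundle$periods)) {
    per <- bundle$periods[[pname]]
    if (!is.null(per$fit_table))
      wtsv(per$fit_table, paste0("fit_", pname, ".tsv"))
    for (r in names(per$moments)) {
      tab <- per$moments[[r]]
      if (!is.null(tab))
        wtsv(as.data.frame(tab),
             paste0("moments_", pname, "_ref", r, ".tsv"))
    }
    for (key in names(per$structural)) {
      entry <- per$structural[[key]]
      if (!is.null(entry$reduced) && !is.null(entry$full)) {
        r <- entry$reduced$sspec$base$reference_item
        wtsv(structural_table(entry, design, r),
             paste0("structural_", pname, "_", key, ".tsv"))
      }
    }
  }
  prov <- bundle$provenance
  manifest <- c(
    paste0("package_version\t", prov$package),
    paste0("seed\t", prov$seed %||% "none"),
    paste0("estimator\t", prov$estimator),
    paste0("chi2_scale\t", prov$chi2_scale),
    paste0("references\t", paste(prov$references, collapse = ",")),
    if (length(bundle$failures))
      paste0("failures\t", paste(names(bundle$failures), collapse = ","))
    else "failures\tnone")
  manifest_path <- file.path(dir, "manifest.tsv")
  writeLines(manifest, manifest_path)
  invisible(c(paths, manifest_path))
}

#' @export
print.lst_report_bundle <- function(x, ...) {
  cat("Analysis bundle over", length(x$periods), "period(s):",
      paste(names(x$periods), collapse = ", "), "\n")
  for (pname in names(x$periods)) {
    cat("\n==", pname, "==\n")
    ft <- x$periods[[pname]]$fit_table
    if (!is.null(ft)) print(ft, digits = 4, row.names = FALSE)
  }
  if (length(x$failures)) {
    cat("\nfailures:\n")
    for (pname in names(x$failures))
      cat(" ", pname, ":", paste(x$failures[[pname]], collapse = "; "), "\n")
  }
  invisible(x)
}
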