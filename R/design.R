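#' Panel design for a repeated multi-item measurement
#'
#' Describes the observation layout: \code{I} items administered at \code{T}
#' measurement occasions, giving \code{p = I * T} observed variables per
#' respondent.  Observed variables are ordered item-major within occasion
#' blocks with occasions ascending, i.e. item 1 .. item I at occasion 1, then
#' item 1 .. item I at occasion 2, and so on.  Column names follow the
#' \code{<item_label>_w<occasion>} convention.
#'
#' @param n_items Number of items \code{I} (at least 2).
#' @param n_occasions Number of measurement occasions \code{T}.  At least 3
#'   occasions are required: stable person-specific item effects are only
#'   identified longitudinally with three or more waves.
#' @param item_labels Character vector of item identifiers.
#' @param occasion_labels Vector of occasion identifiers (used in column
#'   names as \code{_w<label>}).
#' @return An object of class \code{panel_design}.
#' @examples
#' d <- panel_design()
#' observed_names(d)
#' @export
panel_design <- function(n_items = 5, n_occasions = 3,
                         item_labels = paste0("item", seq_len(n_items)),
                         occasion_labels = seq_len(n_occasions)) {
  stopifnot(is_count(n_items), is_count(n_occasions))
  if (n_items < 2)
    stop("at least two items are required (n_items >= 2)")
  if (n_occasions < 3)
    stop("at least three occasions are required: person-specific item ",
         "effects are identified longitudinally only with T >= 3 waves")
  if (length(item_labels) != n_items)
    stop("item_labels must have length n_items")
  if (length(occasion_labels) != n_occasions)
    stop("occasion_labels must have length n_occasions")
  if (anyDuplicated(item_labels) || anyDuplicated(occasion_labels))
    stop("item and occasion labels must be unique")
  structure(
    list(n_items = as.integer(n_items),
         n_occasions = as.integer(n_occasions),
         item_labels = as.character(item_labels),
         occasion_labels = as.character(occasion_labels)),
    class = "panel_design")
}

#' Observed-variable names of a panel design
#'
#' @param design A \code{panel_design}.
#' @return Character vector of length \code{I * T}, item-major within
#'   ascending occasion blocks.
#' @export
observed_names <- function(design) {
  stopifnot(inherits(design, "panel_design"))
  as.vector(vapply(design$occasion_labels, function(w)
    paste0(design$item_labels, "_w", w),
    character(design$n_items)))
}

# row index of item i at occasion t under the fixed ordering
obs_index <- function(design, i, t) (t - 1L) * design$n_items + i

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("Panel design: %d items x %d occasions (%d observed variables)\n",
              x$n_items, x$n_occasions, x$n_items * x$n_occasions))
  cat("  items:    ", paste(x$item_labels, collapse = ", "), "\n")
  cat("  occasions:", paste(x$occasion_labels, collapse = ", "), "\n")
  invisible(x)
}
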