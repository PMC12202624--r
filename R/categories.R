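#' Benthic category labels
#'
#' The six benthic categories scored in every annotation protocol supported by
#' the package: four coral morphology categories (branching *Acropora*, plating
#' *Acropora*, massive-form coral, all other coral), hard reef substrate, and a
#' catch-all for water, sand and shadow (regions where the substrate cannot be
#' identified).
#'
#' @return Character vector of the six category labels, in canonical order.
#'   Mask rasters index categories 0--5 in this order.
#' @seealso [coral_categories()], [colonisable_categories()]
#' @export
#' @examples
#' benthic_categories()
benthic_categories <- function() {
  c("branching", "plating", "massive", "other_coral",
    "reef_substrate", "water_sand_shadow")
}

#' @describeIn benthic_categories The four coral morphology categories.
#' @export
coral_categories <- function() {
  benthic_categories()[1:4]
}

#' @describeIn benthic_categories Categories remaining on the colonisable
#'   basis, i.e. all categories except `water_sand_shadow`.
#' @export
colonisable_categories <- function() {
  benthic_categories()[1:5]
}

# Residual label for image area covered by no polygon (includes "I don't
# know" labels from the detailed protocol).
unannotated_label <- function() "unannotated"

#' Assign covers to 10 percentage-point reef-state bins
#'
#' Bins percent-cover values into the ten reef-state intervals
#' `[0,10), [10,20), ..., [80,90), [90,100]`. Bins are left-closed and
#' right-open except the last, which is closed at 100.
#'
#' @param x Numeric vector of percent covers in `[0, 100]`.
#' @return Factor with the ten interval labels as levels.
#' @export
#' @examples
#' cover_bin(c(0, 9.99, 10, 95, 100))
cover_bin <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0 | x > 100, na.rm = TRUE)) {
    stop("cover values must lie in [0, 100]", call. = FALSE)
  }
  idx <- pmin(floor(x / 10), 9L)
  labs <- cover_bin_levels()
  factor(labs[idx + 1L], levels = labs)
}

cover_bin_levels <- function() {
  lo <- seq(0L, 90L, 10L)
  labs <- sprintf("[%d,%d)", lo, lo + 10L)
  labs[10L] <- "[90,100]"
  labs
}
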