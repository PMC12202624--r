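#' Cover tables
#'
#' A cover table is the common currency of the pipeline: one row per
#' (image, method, analyst, category) holding a percent-cover value. Columns:
#'
#' * `image_id`, `site_id`, `reef_id` -- identifiers (character).
#' * `method` -- one of `"expert_detailed"`, `"expert_visual"`, `"ai"`,
#'   `"citizen"`, `"best"`.
#' * `analyst_id` -- analyst identifier, or the aggregate marker `"mean"` for
#'   analyst-averaged records.
#' * `basis` -- `"total_image"` (percent of the whole image) or
#'   `"colonisable"` (percent of colonisable substrate, i.e. excluding
#'   water/sand/shadow).
#' * `category`, `cover_pct` -- category label and percent cover in `[0, 100]`.
#'
#' `as_cover_table()` validates a data frame and stamps the `cover_table`
#' class; all pipeline functions accept plain data frames with these columns
#' and validate on entry.
#'
#' @param x A data frame with the columns listed above.
#' @return A `cover_table` tibble.
#' @export
as_cover_table <- function(x) {
  required <- c("image_id", "site_id", "reef_id", "method", "analyst_id",
                "basis", "category", "cover_pct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("cover table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  bad_method <- setdiff(unique(x$method), cover_methods())
  if (length(bad_method) > 0) {
    stop("unknown method(s): ", paste(bad_method, collapse = ", "),
         call. = FALSE)
  }
  bad_basis <- setdiff(unique(x$basis), c("total_image", "colonisable"))
  if (length(bad_basis) > 0) {
    stop("unknown basis value(s): ", paste(bad_basis, collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(x$category),
                     c(benthic_categories(), unannotated_label()))
  if (length(bad_cat) > 0) {
    stop("unknown category label(s): ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$cover_pct)) ||
      any(x$cover_pct < -1e-9 | x$cover_pct > 100 + 1e-9)) {
    stop("cover_pct values must be finite and in [0, 100]", call. = FALSE)
  }
  if (any(x$basis == "colonisable" & x$category == "water_sand_shadow")) {
    stop("colonisable-basis records must not contain water_sand_shadow",
         call. = FALSE)
  }
  class(x) <- unique(c("cover_table", class(x)))
  x
}

cover_methods <- function() {
  c("expert_detailed", "expert_visual", "ai", "citizen", "best")
}

#' @rdname as_cover_table
#' @param path Path to a `covers.csv` file (UTF-8, header row) with the cover
#'   table columns.
#' @export
read_cover_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         image_id = readr::col_character(),
                         site_id = readr::col_character(),
                         reef_id = readr::col_character(),
                         method = readr::col_character(),
                         analyst_id = readr::col_character(),
                         basis = readr::col_character(),
                         category = readr::col_character(),
                         cover_pct = readr::col_double()
                       ))
  as_cover_table(x)
}

#' @rdname as_cover_table
#' @param digits Number of decimal places for serialized percentages.
#' @export
write_cover_table <- function(x, path, digits = 4) {
  x <- as_cover_table(x)
  x$cover_pct <- round(x$cover_pct, digits)
  readr::write_csv(x, path)
  invisible(path)
}

# Turn a named per-category cover vector into cover-table rows.
cover_record <- function(cover, image_id, site_id = NA_character_,
                         reef_id = NA_character_, method, analyst_id,
                         basis) {
  tibble::tibble(
    image_id = as.character(image_id),
    site_id = as.character(site_id),
    reef_id = as.character(reef_id),
    method = method,
    analyst_id = as.character(analyst_id),
    basis = basis,
    category = names(cover),
    cover_pct = unname(cover)
  )
}
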