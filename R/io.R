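#' Read and write plain-text category masks
#'
#' Masks are stored as plain text: one row of space-separated category
#' indices (0--5, in [benthic_categories()] order) per pixel row, with 255
#' marking missing pixels.
#'
#' @param path File path.
#' @return `read_mask()`: an integer matrix with `NA` for missing pixels.
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
  if (length(unique(lengths(rows))) != 1) {
    stop("mask rows have unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  m[m == 255L] <- NA_integer_
  if (any(!is.na(m) & (m < 0 | m > 5))) {
    stop("mask values must be category indices 0..5 or 255", call. = FALSE)
  }
  m
}

#' @rdname read_mask
#' @param mask Integer matrix (values 0--5 or `NA`).
#' @export
write_mask <- function(mask, path) {
  m <- mask
  m[is.na(m)] <- 255L
  writeLines(apply(m, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Read grid or polygon annotation tables
#'
#' `read_grid_annotations()` reads `annotations_grid.csv`
#' (columns `image_id`, `site_id`, `reef_id`, `analyst_id`, `method`,
#' `cell_index`, `category`, `value_pct`); `read_polygon_annotations()`
#' reads `annotations_polygons.csv` (columns `image_id`, `site_id`,
#' `reef_id`, `analyst_id`, `method`, `polygon_id`, `category`, `area`,
#' `image_area`). Both are UTF-8 CSV with a header row.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_grid_annotations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    image_id = readr::col_character(),
                    site_id = readr::col_character(),
                    reef_id = readr::col_character(),
                    analyst_id = readr::col_character(),
                    method = readr::col_character(),
                    cell_index = readr::col_integer(),
                    category = readr::col_character(),
                    value_pct = readr::col_double()))
}

#' @rdname read_grid_annotations
#' @export
read_polygon_annotations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    image_id = readr::col_character(),
                    site_id = readr::col_character(),
                    reef_id = readr::col_character(),
                    analyst_id = readr::col_character(),
                    method = readr::col_character(),
                    polygon_id = readr::col_character(),
                    category = readr::col_character(),
                    area = readr::col_double(),
                    image_area = readr::col_double()))
}
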