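#' Validate a cover table (or covers.csv file)
#'
#' Checks schema, value bounds and key uniqueness of a cover table and
#' returns a report rather than failing on first problem. Fatal problems
#' (missing columns, out-of-range covers, duplicated
#' (image, method, analyst, category) keys, unknown labels) are reported
#' with severity `"error"`; suspicious but workable ones (colonisable
#' compositions of full-composition methods not summing to 100) with
#' severity `"warning"`.
#'
#' @param x A data frame, or a path to a `covers.csv` file.
#' @return Tibble with columns `severity`, `check`, `message`; zero rows
#'   means a clean table.
#' @export
validate_tables <- function(x) {
  if (is.character(x)) {
    x <- readr::read_csv(x, show_col_types = FALSE)
  }
  issues <- list()
  note <- function(severity, check, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = severity, check = check, message = message)
  }
  required <- c("image_id", "site_id", "reef_id", "method", "analyst_id",
                "basis", "category", "cover_pct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    note("error", "schema",
         paste("missing column(s):", paste(missing_cols, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  bad <- setdiff(unique(x$method), cover_methods())
  if (length(bad) > 0) {
    note("error", "method",
         paste("unknown method(s):", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(x$category),
                 c(benthic_categories(), unannotated_label()))
  if (length(bad) > 0) {
    note("error", "category",
         paste("unknown category label(s):", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(x$basis), c("total_image", "colonisable"))
  if (length(bad) > 0) {
    note("error", "basis",
         paste("unknown basis value(s):", paste(bad, collapse = ", ")))
  }
  out_of_range <- !is.finite(x$cover_pct) | x$cover_pct < 0 |
    x$cover_pct > 100
  if (any(out_of_range)) {
    note("error", "bounds",
         sprintf("%d cover_pct value(s) outside [0, 100]",
                 sum(out_of_range)))
  }
  key <- paste(x$image_id, x$method, x$analyst_id, x$category, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- x[which(dup)[1], ]
    note("error", "duplicate",
         sprintf("%d duplicated key row(s); first: image %s, method %s, analyst %s, category %s",
                 sum(dup), first$image_id, first$method, first$analyst_id,
                 first$category))
  }
  # full-composition records on the colonisable basis should sum to 100
  comp <- x[x$basis == "colonisable" &
              x$method %in% c("expert_visual", "expert_detailed") &
              x$category %in% colonisable_categories(), ]
  if (nrow(comp) > 0) {
    sums <- tapply(comp$cover_pct,
                   paste(comp$image_id, comp$analyst_id, sep = "\r"), sum)
    off <- sum(abs(sums - 100) > 0.01)
    if (off > 0) {
      note("warning", "composition",
           sprintf("%d expert colonisable composition(s) do not sum to 100",
                   off))
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(severity = character(), check = character(),
                          message = character()))
  }
  dplyr::bind_rows(issues)
}
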