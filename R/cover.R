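#' Percent cover from a segmentation mask
#'
#' Computes per-category percent cover of the whole image from a per-pixel
#' category raster: the pixel count of each category divided by the image's
#' total (non-missing) pixel count.
#'
#' @param mask Integer matrix; each entry is a category index 0--5 in the
#'   order of [benthic_categories()], or `NA` for missing pixels.
#' @return Named numeric vector of percent covers over the six categories,
#'   summing to 100 (basis: total image).
#' @export
#' @examples
#' m <- matrix(c(0, 0, 5, 5), 2, 2)
#' cover_from_mask(m)
cover_from_mask <- function(mask) {
  if (!is.matrix(mask) || length(mask) == 0) {
    stop("mask must be a non-empty matrix", call. = FALSE)
  }
  vals <- mask[!is.na(mask)]
  if (length(vals) == 0) {
    stop("all pixels are missing: cover is undefined", call. = FALSE)
  }
  cats <- benthic_categories()
  if (any(vals != trunc(vals)) || any(vals < 0) || any(vals >= length(cats))) {
    stop("mask values must be category indices in 0..", length(cats) - 1,
         call. = FALSE)
  }
  counts <- tabulate(as.integer(vals) + 1L, nbins = length(cats))
  stats::setNames(100 * counts / length(vals), cats)
}

#' Percent cover from polygon annotations
#'
#' Computes per-category percent cover of the whole image from labelled
#' polygon areas (the detailed expert protocol): the summed polygon area of
#' each category divided by the image area. Area covered by no polygon -- and
#' area labelled "I don't know" -- is reported as an explicit `unannotated`
#' residual rather than silently merged into `reef_substrate`; set
#' `exhaustive = TRUE` when the annotation protocol labelled all substrate
#' exhaustively, in which case the residual is folded into `reef_substrate`.
#'
#' Overlaps are assumed already resolved into disjoint areas (each image
#' region counted once, owned by the later-drawn polygon); see
#' [rasterize_rectangles()] for the z-order rule applied when rasterizing
#' geometric annotations.
#'
#' @param polygons Data frame with columns `category` (a benthic category or
#'   `"i_dont_know"`) and `area` (non-negative, same units as `image_area`).
#'   May have zero rows.
#' @param image_area Total image area (> 0), in the same units as `area`.
#' @param exhaustive If `TRUE`, fold the unannotated residual into
#'   `reef_substrate`.
#' @param tol Tolerance, as a fraction of `image_area`, by which summed areas
#'   may exceed the image area before an error is raised.
#' @return Named numeric vector over the six categories plus `unannotated`,
#'   summing to 100 (basis: total image).
#' @export
#' @examples
#' cover_from_polygons(data.frame(category = "plating", area = 25),
#'                     image_area = 100)
cover_from_polygons <- function(polygons, image_area, exhaustive = FALSE,
                                tol = 1e-6) {
  if (!is.finite(image_area) || image_area <= 0) {
    stop("image_area must be positive", call. = FALSE)
  }
  cats <- benthic_categories()
  if (nrow(polygons) > 0) {
    bad <- setdiff(unique(polygons$category), c(cats, "i_dont_know"))
    if (length(bad) > 0) {
      stop("unknown polygon categories: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(polygons$area)) || any(polygons$area < 0)) {
      stop("polygon areas must be finite and non-negative", call. = FALSE)
    }
    if (sum(polygons$area) > image_area * (1 + tol)) {
      stop("summed polygon areas exceed the image area", call. = FALSE)
    }
  }
  out <- stats::setNames(numeric(length(cats)), cats)
  if (nrow(polygons) > 0) {
    # "I don't know" polygons contribute to the unannotated residual only
    keep <- polygons$category != "i_dont_know"
    agg <- tapply(polygons$area[keep], polygons$category[keep], sum)
    out[names(agg)] <- 100 * agg / image_area
  }
  residual <- max(0, 100 - sum(out))
  if (exhaustive) {
    out["reef_substrate"] <- out["reef_substrate"] + residual
    residual <- 0
  }
  c(out, stats::setNames(residual, unannotated_label()))
}

#' Percent cover from a 3x3 visual grid assessment
#'
#' The visual expert protocol scores each cell of a 3x3 overlay with the
#' percentage of the cell occupied by each category. Each cell represents an
#' equal ninth of the image, so the image-level cover of a category is the
#' mean of its nine cell values (equivalently, the sum of cell values each
#' weighted by exactly 1/9; the weight is not rounded to 0.111, so nine full
#' cells give exactly 100).
#'
#' @param cells Data frame with columns `cell_index` (each of 1--9 exactly
#'   once per category present), `category` and `value_pct` in `[0, 100]`.
#'   Categories absent from the table score 0 in every cell.
#' @param cell_sum_tol Per-cell category sums may exceed 100 by at most this
#'   many percentage points (data-entry slack); larger sums are an error.
#' @return Named numeric vector of percent covers over the six categories
#'   (basis: total image). Does not necessarily sum to 100: cells may contain
#'   unscored area.
#' @export
#' @examples
#' cells <- expand.grid(cell_index = 1:9, category = "branching")
#' cells$value_pct <- 100
#' cover_from_grid(cells)  # a fully branching image
cover_from_grid <- function(cells, cell_sum_tol = 0.5) {
  cats <- benthic_categories()
  bad <- setdiff(unique(cells$category), cats)
  if (length(bad) > 0) {
    stop("unknown grid categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(cells$value_pct)) ||
      any(cells$value_pct < 0 | cells$value_pct > 100)) {
    stop("grid cell values must lie in [0, 100]", call. = FALSE)
  }
  for (cat in unique(cells$category)) {
    idx <- sort(cells$cell_index[cells$category == cat])
    if (!identical(as.integer(idx), 1:9)) {
      stop("category ", cat, " must have exactly one value per cell 1..9",
           call. = FALSE)
    }
  }
  cell_sums <- tapply(cells$value_pct, cells$cell_index, sum)
  if (any(cell_sums > 100 + cell_sum_tol)) {
    stop("per-cell category percentages sum to more than 100", call. = FALSE)
  }
  out <- stats::setNames(numeric(length(cats)), cats)
  agg <- tapply(cells$value_pct, cells$category, sum) / 9
  out[names(agg)] <- agg
  out
}

#' Renormalize covers to the colonisable-substrate basis
#'
#' Converts a total-image cover composition to percent of colonisable reef
#' substrate by excluding `water_sand_shadow` and rescaling the remaining
#' categories to sum to 100. Images that are (almost) entirely water, sand or
#' shadow have no colonisable substrate to score: these raise a
#' `reefcover_non_colonisable` error so that callers can exclude them
#' explicitly rather than propagate meaningless values.
#'
#' @param cover Named numeric vector including `water_sand_shadow`, on the
#'   total-image basis.
#' @param eps Minimum colonisable percentage of the image; below this the
#'   image is flagged non-colonisable.
#' @return Named numeric vector over the remaining categories, summing to 100.
#' @export
#' @examples
#' normalize_to_colonisable(
#'   c(branching = 20, plating = 0, massive = 0, other_coral = 0,
#'     reef_substrate = 30, water_sand_shadow = 50))
normalize_to_colonisable <- function(cover, eps = 0.01) {
  if (!"water_sand_shadow" %in% names(cover)) {
    stop("cover must contain water_sand_shadow on the total-image basis",
         call. = FALSE)
  }
  w <- cover[["water_sand_shadow"]]
  if (w >= 100 - eps) {
    stop(structure(
      class = c("reefcover_non_colonisable", "error", "condition"),
      list(message = "image is (almost) entirely water/sand/shadow: no colonisable substrate",
           call = NULL)))
  }
  rest <- cover[setdiff(names(cover), "water_sand_shadow")]
  100 * rest / (100 - w)
}

#' @describeIn normalize_to_colonisable Table version: renormalizes every
#'   (image, method, analyst) record of a total-image cover table. Records
#'   flagged non-colonisable are dropped from the result and returned in the
#'   `non_colonisable` attribute (a tibble of their identifiers) so that the
#'   exclusion is signalled, never silent.
#' @param covers A cover table (see [as_cover_table()]) on the
#'   `total_image` basis.
#' @export
normalize_cover_table <- function(covers, eps = 0.01) {
  covers <- as_cover_table(covers)
  if (any(covers$basis != "total_image")) {
    stop("normalize_cover_table expects basis = total_image", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(covers,
                             id_cols = c("image_id", "site_id", "reef_id",
                                         "method", "analyst_id"),
                             names_from = "category",
                             values_from = "cover_pct",
                             values_fill = 0)
  if (!"water_sand_shadow" %in% names(wide)) {
    wide$water_sand_shadow <- 0
  }
  flagged <- wide$water_sand_shadow >= 100 - eps
  excluded <- wide[flagged, c("image_id", "site_id", "reef_id", "method",
                              "analyst_id")]
  kept <- wide[!flagged, , drop = FALSE]
  cat_cols <- intersect(names(kept),
                        c(colonisable_categories(), unannotated_label()))
  scale <- 100 / (100 - kept$water_sand_shadow)
  for (cc in cat_cols) kept[[cc]] <- kept[[cc]] * scale
  long <- tidyr::pivot_longer(
    kept[, c("image_id", "site_id", "reef_id", "method", "analyst_id",
             cat_cols)],
    cols = tidyr::all_of(cat_cols),
    names_to = "category", values_to = "cover_pct")
  long$basis <- "colonisable"
  out <- as_cover_table(long[, c("image_id", "site_id", "reef_id", "method",
                                 "analyst_id", "basis", "category",
                                 "cover_pct")])
  attr(out, "non_colonisable") <- tibble::as_tibble(excluded)
  out
}

#' Average repeated analyses of the same image
#'
#' When several analysts (experts or citizen scientists) analysed the same
#' image with the same method, the per-category covers are averaged with equal
#' weight per analyst. The aggregated record carries `analyst_id = "mean"` and
#' an `n_analysts` column with the number of contributing analyses.
#'
#' @param covers A cover table; all rows must share one `basis`.
#' @return A cover table with one record per (image, method, category) and an
#'   added `n_analysts` column.
#' @export
aggregate_analysts <- function(covers) {
  covers <- as_cover_table(covers)
  if (nrow(covers) == 0) {
    stop("no records to aggregate", call. = FALSE)
  }
  if (length(unique(covers$basis)) > 1) {
    stop("cannot aggregate across bases", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(covers, .data$image_id, .data$site_id, .data$reef_id,
                    .data$method, .data$basis, .data$category),
    n_analysts = dplyr::n_distinct(.data$analyst_id),
    cover_pct = mean(.data$cover_pct),
    .groups = "drop")
  out$analyst_id <- "mean"
  as_cover_table(out[, c("image_id", "site_id", "reef_id", "method",
                         "analyst_id", "basis", "category", "cover_pct",
                         "n_analysts")])
}

#' Train/validation split arithmetic
#'
#' Splits an annotation pool into training and validation counts at a given
#' ratio; the training count is the floor of `pool_size * ratio` and the
#' validation set receives the remainder.
#'
#' @param pool_size Number of annotated images (>= 1).
#' @param ratio Training fraction, strictly between 0 and 1 (default 0.8 for
#'   an 80:20 split).
#' @return Named list with integer `train` and `val` counts.
#' @export
#' @examples
#' train_val_split(7505, 0.8)
train_val_split <- function(pool_size, ratio = 0.8) {
  stopifnot(length(pool_size) == 1, length(ratio) == 1)
  if (!is.finite(pool_size) || pool_size < 1 || pool_size != trunc(pool_size)) {
    stop("pool_size must be a positive integer", call. = FALSE)
  }
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1) {
    stop("ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  train <- floor(pool_size * ratio)
  list(train = as.integer(train), val = as.integer(pool_size - train))
}

#' Rasterize rectangular polygon annotations onto a pixel grid
#'
#' Paints axis-aligned rectangles onto a category raster in input order, so
#' that overlapping area is counted once and owned by the later-drawn
#' rectangle (a deterministic z-order). Used to cross-check area-based polygon
#' cover against pixel-counted mask cover.
#'
#' @param rects Data frame with columns `category` and integer pixel bounds
#'   `x0`, `x1`, `y0`, `y1` (inclusive, 1-based, within the image).
#' @param height,width Image dimensions in pixels.
#' @param background Category index (0--5) painted where no rectangle lands,
#'   or `NA` to leave unpainted pixels missing.
#' @return Integer matrix usable with [cover_from_mask()].
#' @export
rasterize_rectangles <- function(rects, height, width,
                                 background = NA_integer_) {
  cats <- benthic_categories()
  mask <- matrix(background, nrow = height, ncol = width)
  if (nrow(rects) > 0) {
    idx <- match(rects$category, cats) - 1L
    if (anyNA(idx)) stop("unknown rectangle category", call. = FALSE)
    for (i in seq_len(nrow(rects))) {
      mask[rects$y0[i]:rects$y1[i], rects$x0[i]:rects$x1[i]] <- idx[i]
    }
  }
  mask
}
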