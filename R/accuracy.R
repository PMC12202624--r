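#' Per-image signed accuracy of a method against expert values
#'
#' For every image analysed by both the method and the experts, computes the
#' signed difference (method minus expert, in percentage points of cover) for
#' each coral category. Positive values mean the method overestimates the
#' expert value. Both tables must be on the colonisable basis and hold one
#' record per (image, category) -- i.e. analyst-aggregated values (see
#' [aggregate_analysts()]).
#'
#' @param method_covers Cover table of the method under evaluation (`"ai"`,
#'   `"citizen"` or `"best"`). A `n_analysts` column, if present, is carried
#'   through as `n_citizen_analyses` (0 for `"ai"`).
#' @param expert_covers Cover table of expert values, analyst-aggregated.
#' @param categories Categories to score (default: the four coral
#'   categories).
#' @return An accuracy table: tibble with columns `image_id`, `site_id`,
#'   `method`, `category`, `diff_pct`, `n_citizen_analyses`.
#' @export
per_image_accuracy <- function(method_covers, expert_covers,
                               categories = coral_categories()) {
  method_covers <- as_cover_table(method_covers)
  expert_covers <- as_cover_table(expert_covers)
  if (any(method_covers$basis != "colonisable") ||
      any(expert_covers$basis != "colonisable")) {
    stop("accuracy requires both tables on the colonisable basis",
         call. = FALSE)
  }
  method <- unique(method_covers$method)
  if (length(method) != 1) {
    stop("method_covers must hold exactly one method", call. = FALSE)
  }
  m <- method_covers[method_covers$category %in% categories, ]
  e <- expert_covers[expert_covers$category %in% categories,
                     c("image_id", "category", "cover_pct")]
  names(e)[names(e) == "cover_pct"] <- "expert_pct"
  if (!"n_analysts" %in% names(m)) m$n_analysts <- 1L
  joined <- dplyr::inner_join(m, e, by = c("image_id", "category"))
  if (nrow(joined) == 0) {
    warning("no images shared between method and expert tables",
            call. = FALSE)
  }
  n_cit <- if (method == "ai") 0L else as.integer(joined$n_analysts)
  tibble::tibble(
    image_id = joined$image_id,
    site_id = joined$site_id,
    method = method,
    category = joined$category,
    diff_pct = joined$cover_pct - joined$expert_pct,
    n_citizen_analyses = n_cit
  )
}

#' Summarize a method's accuracy over all images
#'
#' Per-category mean signed difference from expert, with its standard error
#' and image count, plus a `total_coral` row: the mean over images of the sum
#' of the coral-category differences (i.e. the accuracy of total coral
#' cover). The total uses only images scored in every coral category.
#'
#' @param acc Accuracy table from [per_image_accuracy()].
#' @return Tibble with columns `method`, `category` (including
#'   `"total_coral"`), `mean_diff`, `se`, `n_images`.
#' @export
summarize_method <- function(acc) {
  if (nrow(acc) == 0) stop("empty accuracy table", call. = FALSE)
  per_cat <- dplyr::summarise(
    dplyr::group_by(acc, .data$method, .data$category),
    mean_diff = mean(.data$diff_pct),
    se = stats::sd(.data$diff_pct) / sqrt(dplyr::n()),
    n_images = dplyr::n(),
    .groups = "drop")
  per_cat$se[per_cat$n_images == 1] <- 0
  wide <- tidyr::pivot_wider(acc, id_cols = c("image_id", "method"),
                             names_from = "category",
                             values_from = "diff_pct")
  coral_cols <- intersect(coral_categories(), names(wide))
  total <- rowSums(wide[, coral_cols, drop = FALSE])
  total <- total[stats::complete.cases(wide[, coral_cols, drop = FALSE])]
  total_row <- tibble::tibble(
    method = wide$method[1],
    category = "total_coral",
    mean_diff = mean(total),
    se = if (length(total) > 1) stats::sd(total) / sqrt(length(total)) else 0,
    n_images = length(total))
  dplyr::bind_rows(per_cat, total_row)
}

#' Choose the more accurate method per coral category
#'
#' Compares the mean signed difference of two method summaries category by
#' category and selects, for each coral category, the method whose mean is
#' closer to zero. Ties go to `"ai"`, which needs no analysts and so is the
#' cheaper choice.
#'
#' @param ai_summary,citizen_summary Summaries from [summarize_method()]
#'   covering every coral category.
#' @return Named character vector mapping each coral category to `"ai"` or
#'   `"citizen"`.
#' @export
select_best_method <- function(ai_summary, citizen_summary) {
  cats <- coral_categories()
  pick <- function(s, cat) {
    row <- s[s$category == cat, ]
    if (nrow(row) != 1) {
      stop("summary is missing category ", cat, call. = FALSE)
    }
    row$mean_diff
  }
  out <- vapply(cats, function(cat) {
    a <- abs(pick(ai_summary, cat))
    c_ <- abs(pick(citizen_summary, cat))
    if (c_ < a) "citizen" else "ai"
  }, character(1))
  stats::setNames(out, cats)
}

#' Apply a best-method map to per-image accuracies
#'
#' Builds the fused "best" accuracy table: for each coral category, the rows
#' of whichever method the map selects. Images lacking the mapped method's
#' value for a category are simply absent (their count is reported in the
#' `n_missing` attribute), which is why the fused table can have a different
#' image count per category than either source.
#'
#' @param ai_acc,citizen_acc Accuracy tables from [per_image_accuracy()].
#' @param best_map Named map from [select_best_method()].
#' @return Accuracy table with `method = "best"`.
#' @export
apply_best <- function(ai_acc, citizen_acc, best_map) {
  cats <- coral_categories()
  if (!all(cats %in% names(best_map))) {
    stop("best_map must cover every coral category", call. = FALSE)
  }
  all_images <- union(ai_acc$image_id, citizen_acc$image_id)
  pieces <- lapply(cats, function(cat) {
    src <- if (best_map[[cat]] == "ai") ai_acc else citizen_acc
    src[src$category == cat, ]
  })
  out <- dplyr::bind_rows(pieces)
  n_missing <- vapply(cats, function(cat) {
    length(all_images) - sum(out$category == cat)
  }, integer(1))
  out$method <- "best"
  attr(out, "n_missing") <- n_missing
  out
}

#' Accuracy by reef-state bin
#'
#' Stratifies per-image accuracies by the expert-assessed cover of each
#' category: for every coral category independently, each image is assigned
#' to the 10 percentage-point bin containing its expert cover of that
#' category (see [cover_bin()]), and the mean signed difference, its standard
#' error and the image count are reported per bin. Only bins with at least
#' `min_bin_images` images are returned; the complete partition (no size
#' filter) is available via `min_bin_images = 0`.
#'
#' @param acc Accuracy table (typically the fused "best" table).
#' @param expert_covers Analyst-aggregated expert cover table (colonisable
#'   basis).
#' @param min_bin_images Minimum images for a bin to be reported
#'   (default 80).
#' @return Tibble with columns `category`, `bin`, `n_images`, `mean_diff`,
#'   `se`.
#' @export
bin_by_reef_state <- function(acc, expert_covers, min_bin_images = 80) {
  expert_covers <- as_cover_table(expert_covers)
  e <- expert_covers[, c("image_id", "category", "cover_pct")]
  names(e)[names(e) == "cover_pct"] <- "expert_pct"
  joined <- dplyr::inner_join(acc, e, by = c("image_id", "category"))
  joined$bin <- cover_bin(joined$expert_pct)
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$category, .data$bin),
    n_images = dplyr::n(),
    mean_diff = mean(.data$diff_pct),
    se = if (dplyr::n() > 1) {
      stats::sd(.data$diff_pct) / sqrt(dplyr::n())
    } else 0,
    .groups = "drop")
  out[out$n_images >= min_bin_images, ]
}

#' Correct covers with constant per-category offsets
#'
#' Subtracts a known mean bias (e.g. a method's mean difference from expert)
#' from each cover value, clamping the result to `[0, 100]`. The number of
#' clamped values is reported in the `n_clamped` attribute.
#'
#' @param covers A cover table.
#' @param offsets Named numeric vector of offsets in percentage points;
#'   categories not named get offset 0.
#' @return The corrected cover table.
#' @export
correct_with_offset <- function(covers, offsets) {
  covers <- as_cover_table(covers)
  if (any(!is.finite(offsets))) stop("offsets must be finite", call. = FALSE)
  off <- unname(offsets[covers$category])
  off[is.na(off)] <- 0
  corrected <- covers$cover_pct - off
  clamped <- corrected < 0 | corrected > 100
  covers$cover_pct <- pmin(pmax(corrected, 0), 100)
  attr(covers, "n_clamped") <- sum(clamped)
  covers
}

#' Paired comparison of two annotation protocols
#'
#' Compares total coral cover (the sum of the four coral categories) between
#' two cover tables over the images present in both, using a two-sided
#' Wilcoxon signed-rank test on the paired differences.
#'
#' @param a,b Cover tables, e.g. the detailed and visual expert protocols,
#'   analyst-aggregated, on a common basis.
#' @return List with `n` (paired images), `mean_difference` (mean of a minus
#'   b), `statistic` and `p_value`.
#' @export
compare_annotation_methods <- function(a, b) {
  total <- function(x) {
    x <- as_cover_table(x)
    x <- x[x$category %in% coral_categories(), ]
    dplyr::summarise(dplyr::group_by(x, .data$image_id),
                     total = sum(.data$cover_pct), .groups = "drop")
  }
  ta <- total(a)
  tb <- total(b)
  names(tb)[2] <- "total_b"
  joined <- dplyr::inner_join(ta, tb, by = "image_id")
  if (nrow(joined) < 2) {
    stop("need at least two paired images", call. = FALSE)
  }
  d <- joined$total - joined$total_b
  wt <- stats::wilcox.test(joined$total, joined$total_b, paired = TRUE,
                           exact = FALSE)
  list(n = nrow(joined), mean_difference = mean(d),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}
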