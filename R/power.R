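#' Power analysis settings
#'
#' Defaults target detection of a 10 percentage-point absolute difference in
#' cover between two sites with power 0.8 at alpha 0.05, using a two-sided,
#' equal-n, pooled-variance two-sample t test, discarding sites with fewer
#' than 10 analysed images.
#'
#' @param effect Detectable absolute difference in percent cover
#'   (percentage points).
#' @param power Required power.
#' @param alpha Significance level.
#' @param sides `"two"` or `"one"`.
#' @param min_images_per_site Sites with fewer images are discarded.
#' @return A `power_config` list.
#' @export
power_config <- function(effect = 10, power = 0.8, alpha = 0.05,
                         sides = c("two", "one"), min_images_per_site = 10) {
  sides <- match.arg(sides)
  stopifnot(effect > 0, power > 0, power < 1, alpha > 0, alpha < 1,
            min_images_per_site >= 1)
  structure(list(effect = effect, power = power, alpha = alpha,
                 sides = sides,
                 min_images_per_site = as.integer(min_images_per_site)),
            class = "power_config")
}

#' Power of the two-sample t test at a given group size
#'
#' Exact power of the pooled-variance two-sample t test with equal group
#' sizes, computed from the noncentral t distribution: with effect size
#' `d = effect / sd` (Cohen's d), the test statistic under the alternative is
#' noncentral t with `2n - 2` degrees of freedom and noncentrality
#' `d * sqrt(n / 2)`.
#'
#' @param n Images per group (>= 2); vectorized.
#' @param sd Within-site standard deviation of cover (percentage points,
#'   > 0).
#' @param effect Absolute difference in cover to detect.
#' @param alpha Significance level.
#' @param sides `"two"` (default) or `"one"`.
#' @return Achieved power in `[0, 1]`, same length as `n`.
#' @export
#' @examples
#' power_of_n(17, sd = 10, effect = 10)  # d = 1
power_of_n <- function(n, sd, effect = 10, alpha = 0.05,
                       sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(all(n >= 2), sd > 0, effect > 0, alpha > 0, alpha < 1)
  d <- effect / sd
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (sides == "two") {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  }
}

#' Images per site required to detect a cover difference
#'
#' Smallest integer group size `n` at which the two-sample t test of
#' [power_of_n()] reaches the required power: the exact integer solution of
#' the noncentral-t power equation (no continuous approximation, no
#' rounding-up of a fractional solve). A degenerate `sd <= 0` returns the
#' search floor of 2 with a `degenerate` attribute set.
#'
#' @inheritParams power_of_n
#' @param power Required power.
#' @param n_max Search cap; `NA` is returned (with a warning) if the target
#'   power is not reached by `n_max`.
#' @return Integer images per group.
#' @export
#' @examples
#' required_n(sd = 10, effect = 10)  # d = 1 -> 17 per group
required_n <- function(sd, effect = 10, power = 0.8, alpha = 0.05,
                       sides = c("two", "one"), n_max = 1e6) {
  sides <- match.arg(sides)
  stopifnot(effect > 0, power > 0, power < 1)
  if (!is.finite(sd) || sd <= 0) {
    out <- 2L
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d <- effect / sd
  # normal-approximation starting point, then exact integer search
  za <- stats::qnorm(1 - alpha / ifelse(sides == "two", 2, 1))
  zb <- stats::qnorm(power)
  n <- max(2, floor(2 * ((za + zb) / d)^2) - 2)
  while (n <= n_max && power_of_n(n, sd, effect, alpha, sides) < power) {
    n <- n + 1
  }
  if (n > n_max) {
    warning("required n exceeds n_max; returning NA", call. = FALSE)
    return(NA_integer_)
  }
  while (n > 2 && power_of_n(n - 1, sd, effect, alpha, sides) >= power) {
    n <- n - 1
  }
  as.integer(n)
}

#' Per-site cover variability
#'
#' Groups best-method covers by survey site and computes, per site and coral
#' category, the number of images, the mean cover and the sample standard
#' deviation (n - 1 denominator) of cover across the site's images -- the
#' within-site heterogeneity a survey must overcome. Each site is assigned to
#' a reef-state bin from the *expert* mean cover at that site. Sites with
#' fewer than `min_images_per_site` images are discarded; their count is
#' reported in the `n_dropped_sites` attribute. Images are never mixed
#' across sites.
#'
#' @param best_covers Cover table of best-method covers (one record per
#'   image and category).
#' @param expert_covers Analyst-aggregated expert cover table used for
#'   binning.
#' @param config A [power_config()].
#' @return Tibble with columns `site_id`, `category`, `n_images`,
#'   `site_mean_cover`, `site_sd`, `bin`.
#' @export
site_sd_table <- function(best_covers, expert_covers,
                          config = power_config()) {
  best_covers <- as_cover_table(best_covers)
  expert_covers <- as_cover_table(expert_covers)
  if (any(is.na(best_covers$site_id))) {
    stop("every image must carry a site_id", call. = FALSE)
  }
  b <- best_covers[best_covers$category %in% coral_categories(), ]
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(b, .data$site_id, .data$category),
    n_images = dplyr::n(),
    site_mean_cover = mean(.data$cover_pct),
    site_sd = stats::sd(.data$cover_pct),
    .groups = "drop")
  e <- expert_covers[expert_covers$category %in% coral_categories(), ]
  site_expert <- dplyr::summarise(
    dplyr::group_by(e, .data$site_id, .data$category),
    expert_site_mean = mean(.data$cover_pct), .groups = "drop")
  stats_tbl <- dplyr::inner_join(stats_tbl, site_expert,
                                 by = c("site_id", "category"))
  keep <- stats_tbl$n_images >= config$min_images_per_site
  dropped <- length(unique(stats_tbl$site_id[!keep]))
  out <- stats_tbl[keep, ]
  if (nrow(out) == 0) stop("no sites meet the image minimum", call. = FALSE)
  out$bin <- cover_bin(out$expert_site_mean)
  out$expert_site_mean <- NULL
  attr(out, "n_dropped_sites") <- dropped
  out
}

#' Mean within-site variability per reef-state bin
#'
#' Averages the per-site standard deviations of [site_sd_table()] within each
#' coral category and reef-state bin (unweighted across sites), with the
#' standard error of that mean. Bins with a single site report `se = 0` and
#' are flagged low-confidence.
#'
#' @param site_stats Output of [site_sd_table()].
#' @return Tibble with columns `category`, `bin`, `n_sites`, `mean_site_sd`,
#'   `se_of_sd`, `low_confidence`.
#' @export
bin_mean_sd <- function(site_stats) {
  if (nrow(site_stats) == 0) stop("empty site table", call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(site_stats, .data$category, .data$bin),
    n_sites = dplyr::n(),
    mean_site_sd = mean(.data$site_sd),
    se_of_sd = if (dplyr::n() > 1) {
      stats::sd(.data$site_sd) / sqrt(dplyr::n())
    } else 0,
    .groups = "drop")
  out$low_confidence <- out$n_sites == 1
  out
}

#' Images per site needed to detect a cover difference, by reef state
#'
#' The full power analysis: per-site SDs ([site_sd_table()]), their bin means
#' ([bin_mean_sd()]), and for each (category, bin) the images per site
#' required to detect the configured absolute difference in cover
#' ([required_n()] at the bin's mean site SD).
#'
#' @inheritParams site_sd_table
#' @return Tibble with columns `category`, `bin`, `n_sites`, `mean_site_sd`,
#'   `se_of_sd`, `required_n_per_site`, `low_confidence`. The site-level
#'   table is attached as the `site_stats` attribute.
#' @export
power_analysis <- function(best_covers, expert_covers,
                           config = power_config()) {
  site_stats <- site_sd_table(best_covers, expert_covers, config)
  bins <- bin_mean_sd(site_stats)
  bins$required_n_per_site <- vapply(
    bins$mean_site_sd,
    function(s) as.integer(required_n(s, effect = config$effect,
                                      power = config$power,
                                      alpha = config$alpha,
                                      sides = config$sides)),
    integer(1))
  bins <- bins[, c("category", "bin", "n_sites", "mean_site_sd", "se_of_sd",
                   "required_n_per_site", "low_confidence")]
  attr(bins, "site_stats") <- site_stats
  bins
}
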