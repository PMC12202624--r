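#' Simulation settings for the images-per-site analysis
#'
#' Bundles the Monte-Carlo settings used when asking how many images per site
#' (`n`), analysed by how many citizen scientists each (`m`), deliver a site
#' mean within the accuracy target. Defaults follow the standard design:
#' 10,000 runs per (n, m) combination, n from 1 to 120, m from 1 to 6, a
#' +/-5 percentage-point accuracy target met in 95% of runs.
#'
#' @param n_values Image counts per site to simulate.
#' @param m_values Citizen analyses per image to simulate.
#' @param runs Simulation runs per combination.
#' @param threshold Accuracy target in percentage points (a run counts as
#'   accurate when the absolute run mean is at most this).
#' @param target_fraction Required fraction of runs within the threshold.
#' @param replace_images Sample images with replacement within a run? The
#'   default samples without replacement, mimicking `n` distinct photographs
#'   of a site.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_values = 1:120, m_values = 1:6, runs = 10000,
                       threshold = 5, target_fraction = 0.95,
                       replace_images = FALSE) {
  stopifnot(runs >= 1, threshold > 0,
            target_fraction > 0, target_fraction < 1,
            all(n_values >= 1), all(m_values >= 1))
  structure(list(n_values = as.integer(sort(unique(n_values))),
                 m_values = as.integer(sort(unique(m_values))),
                 runs = as.integer(runs), threshold = threshold,
                 target_fraction = target_fraction,
                 replace_images = isTRUE(replace_images)),
            class = "sim_config")
}

# Deterministic per-(n, m) substream seed derived from the master seed, so
# the grid is reproducible under partial recomputation. Kept within the
# 32-bit integer range set.seed() accepts.
substream_seed <- function(seed, n, m = 1L, stream = 0L) {
  as.integer(((as.double(seed) %% 65011 + 1) * 30011 +
                n * 6151 + m * 769 + stream * 97) %% 2147483629)
}

#' Simulate site-mean accuracy for n images per site
#'
#' Each run samples `n` per-image accuracies (signed differences from expert,
#' in percentage points) from the image pool and records their mean -- the
#' accuracy of the site estimate a survey of `n` images would deliver. Images
#' are sampled without replacement within a run unless `replace_images` is
#' set.
#'
#' @param pool Numeric vector of per-image accuracies (the image library).
#' @param n Images sampled per run; at most `length(pool)` when sampling
#'   without replacement.
#' @param runs Number of simulation runs.
#' @param seed Optional integer seed for reproducibility.
#' @param replace_images Sample images with replacement?
#' @return Numeric vector of `runs` run means.
#' @export
simulate_site_accuracy <- function(pool, n, runs = 10000, seed = NULL,
                                   replace_images = FALSE) {
  stopifnot(is.numeric(pool), length(pool) >= 1, n >= 1, runs >= 1)
  if (!replace_images && n > length(pool)) {
    stop("n exceeds the image pool size (sampling without replacement)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (replace_images) {
    draws <- matrix(pool[sample.int(length(pool), n * runs, replace = TRUE)],
                    nrow = n)
  } else {
    idx <- vapply(seq_len(runs), function(i) sample.int(length(pool), n),
                  integer(n))
    draws <- matrix(pool[idx], nrow = n)
  }
  .colMeans(draws, n, runs)
}

#' Simulate site-mean accuracy with analyst resampling
#'
#' As [simulate_site_accuracy()], but each image carries the accuracies of
#' its individual citizen analyses: per run, `n` images are sampled without
#' replacement and, for each sampled image, `m` analyses are drawn with
#' replacement from that image's analyses and averaged. The run value is the
#' mean over the `n` image means -- the site estimate when every image is
#' analysed by `m` citizens.
#'
#' @param pools List of numeric vectors: per image, the accuracies of its
#'   individual analyses (all non-empty).
#' @param n Images sampled per run.
#' @param m Analyses drawn (with replacement) per image.
#' @inheritParams simulate_site_accuracy
#' @return Numeric vector of `runs` run means.
#' @export
simulate_with_analyst_resampling <- function(pools, n, m, runs = 10000,
                                             seed = NULL,
                                             replace_images = FALSE) {
  stopifnot(is.list(pools), length(pools) >= 1, n >= 1, m >= 1, runs >= 1)
  len <- lengths(pools)
  if (any(len == 0)) {
    stop("every image must have at least one analysis", call. = FALSE)
  }
  if (!replace_images && n > length(pools)) {
    stop("n exceeds the image pool size (sampling without replacement)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  vals <- unlist(pools, use.names = FALSE)
  offset <- cumsum(len) - len
  if (replace_images) {
    img <- sample.int(length(pools), n * runs, replace = TRUE)
  } else {
    img <- as.vector(vapply(seq_len(runs),
                            function(i) sample.int(length(pools), n),
                            integer(n)))
  }
  li <- len[img]                      # analyses available per sampled image
  # m draws with replacement per sampled image, vectorized over all runs
  u <- stats::runif(length(img) * m)
  pick <- pmin(pmax(ceiling(u * rep(li, m)), 1L), rep(li, m))
  analysis_vals <- vals[rep(offset[img], m) + pick]
  img_means <- .rowMeans(matrix(analysis_vals, ncol = m), length(img), m)
  .colMeans(matrix(img_means, nrow = n), n, runs)
}

#' Fraction of runs within the accuracy threshold
#'
#' @param run_means Numeric vector of simulated run means.
#' @param threshold Accuracy target in percentage points; the comparison is
#'   inclusive (`|mean| <= threshold`).
#' @return Proportion of runs within the threshold.
#' @export
fraction_within <- function(run_means, threshold = 5) {
  stopifnot(length(run_means) >= 1, threshold > 0)
  mean(abs(run_means) <= threshold)
}

#' Simulate the full (n, m) accuracy grid for one category
#'
#' Runs [simulate_site_accuracy()] (or, when analyst-level accuracies are
#' supplied, [simulate_with_analyst_resampling()]) for every combination in
#' the configuration and summarizes each: mean of the run means, the central
#' 95% band (2.5 and 97.5 percentiles) and the fraction of runs within the
#' threshold. With a fixed seed the grid is reproducible; every (n, m) cell
#' uses its own deterministic substream so partial grids agree with full
#' ones.
#'
#' @param pool Numeric vector of per-image accuracies, or a list of
#'   per-image analysis vectors for analyst resampling.
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return Tibble with columns `n`, `m`, `runs`, `mean_of_means`, `p2_5`,
#'   `p97_5`, `fraction_within`.
#' @export
simulate_accuracy_grid <- function(pool, config = sim_config(), seed = 1) {
  analyst_level <- is.list(pool)
  m_values <- if (analyst_level) config$m_values else 1L
  n_values <- config$n_values
  pool_size <- if (analyst_level) length(pool) else length(pool)
  if (!config$replace_images) {
    n_values <- n_values[n_values <= pool_size]
  }
  rows <- vector("list", length(n_values) * length(m_values))
  k <- 0
  for (m in m_values) {
    for (n in n_values) {
      means <- if (analyst_level) {
        simulate_with_analyst_resampling(
          pool, n, m, config$runs,
          seed = substream_seed(seed, n, m),
          replace_images = config$replace_images)
      } else {
        simulate_site_accuracy(
          pool, n, config$runs,
          seed = substream_seed(seed, n, m),
          replace_images = config$replace_images)
      }
      q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        n = n, m = m, runs = config$runs,
        mean_of_means = mean(means), p2_5 = q[1], p97_5 = q[2],
        fraction_within = fraction_within(means, config$threshold))
    }
  }
  dplyr::bind_rows(rows[seq_len(k)])
}

#' Minimum images per site to meet the accuracy target
#'
#' Reads a simulated accuracy grid and reports, for each analysis count `m`,
#' the smallest simulated `n` whose fraction of runs within the threshold
#' reaches the target fraction -- or `NA` ("not reached") when no simulated
#' `n` qualifies, as happens for categories whose per-image accuracy
#' distribution is too biased or too dispersed. No smoothing is applied: with
#' finitely many runs the reported minimum carries Monte-Carlo noise of about
#' one image near the crossing.
#'
#' @param grid Output of [simulate_accuracy_grid()] (a `category` column, if
#'   present, is honoured).
#' @param target_fraction Required fraction of runs within the threshold.
#' @return Tibble with one row per (category,) m: `n_required` (integer or
#'   `NA`).
#' @export
min_images_required <- function(grid, target_fraction = 0.95) {
  group_cols <- intersect(c("category", "m"), names(grid))
  dplyr::summarise(
    dplyr::group_by(grid, dplyr::across(dplyr::all_of(group_cols))),
    n_required = {
      ok <- .data$n[.data$fraction_within >= target_fraction]
      if (length(ok) == 0) NA_integer_ else as.integer(min(ok))
    },
    .groups = "drop")
}
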