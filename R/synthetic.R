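#' Configuration of the synthetic reef-survey generator
#'
#' Describes a hierarchical survey: reefs contain sites, sites contribute
#' images, and each image is analysed by experts, by the automated (AI)
#' method, and by one or more citizen scientists. Site and image covers are
#' drawn on the logit scale around the configured population means, so covers
#' stay inside their bounds; systematic method biases and per-analysis noise
#' are then added on the percent-cover scale.
#'
#' Defaults emulate the structure of a large citizen-science reef survey:
#' 1,500 sites (50 reefs x 30 sites) of 30 images each, six benthic
#' categories, within-site SDs in the mid-single digits to low teens, 1-6
#' citizen analyses per image, and per-category method biases of a few
#' percentage points (automated analysis underestimating plating coral and
#' overestimating other coral; citizen analysis overestimating branching
#' coral). The defaults describe plausible magnitudes for such a survey; they
#' are a simulation setting, not an estimate of any real survey.
#'
#' @param n_reefs,sites_per_reef,images_per_site Survey dimensions.
#' @param category_mean_cover Named population mean covers (percent of total
#'   image, all six categories, summing to 100).
#' @param between_site_sd,within_site_sd Site-to-site and image-to-image
#'   variability (percentage points of cover).
#' @param expert_noise_sd Per-category noise of an expert analysis.
#' @param ai_bias,citizen_bias Named per-coral-category systematic biases
#'   (percentage points; method minus truth). `reef_substrate` may also be
#'   named.
#' @param ai_bias_slope,citizen_bias_slope Optional named per-category slopes
#'   making bias depend on the true cover: the bias applied to an image is
#'   `bias + slope * (true_cover - bias_reference)`. Default all zero
#'   (constant bias).
#' @param bias_reference Cover (percentage points, colonisable basis) at
#'   which the sloped bias equals the configured constant bias.
#' @param ai_noise_sd,citizen_noise_sd Per-category noise of a single AI /
#'   citizen analysis.
#' @param analyst_effect_sd SD of a per-analyst offset added to every
#'   category of that analyst's analysis.
#' @param analyses_per_image Integer vector of admissible citizen analysis
#'   counts; each image draws its count uniformly from this set.
#' @param cell_noise_sd Cell-to-cell noise used by
#'   [generate_grid_annotations()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_reefs = 50, sites_per_reef = 30,
                             images_per_site = 30,
                             category_mean_cover = c(
                               branching = 8, plating = 6, massive = 7,
                               other_coral = 9, reef_substrate = 45,
                               water_sand_shadow = 25),
                             between_site_sd = 10, within_site_sd = 8,
                             expert_noise_sd = 2,
                             ai_bias = c(branching = -1.1, plating = -9.1,
                                         massive = -2, other_coral = 6.9),
                             citizen_bias = c(branching = 9.5,
                                              plating = -0.99,
                                              massive = -0.1,
                                              other_coral = 4.5),
                             ai_bias_slope = NULL, citizen_bias_slope = NULL,
                             bias_reference = 20,
                             ai_noise_sd = 8, citizen_noise_sd = 10,
                             analyst_effect_sd = 3,
                             analyses_per_image = 1:6,
                             cell_noise_sd = 5) {
  cats <- benthic_categories()
  stopifnot(n_reefs >= 1, sites_per_reef >= 1, images_per_site >= 1,
            between_site_sd >= 0, within_site_sd >= 0, expert_noise_sd >= 0,
            ai_noise_sd >= 0, citizen_noise_sd >= 0, analyst_effect_sd >= 0,
            cell_noise_sd >= 0, all(analyses_per_image >= 1))
  if (!setequal(names(category_mean_cover), cats)) {
    stop("category_mean_cover must name all six benthic categories",
         call. = FALSE)
  }
  category_mean_cover <- category_mean_cover[cats]
  if (any(category_mean_cover < 0) ||
      abs(sum(category_mean_cover) - 100) > 0.01) {
    stop("category mean covers must be non-negative and sum to 100",
         call. = FALSE)
  }
  full_bias <- function(b) {
    out <- stats::setNames(numeric(length(colonisable_categories())),
                           colonisable_categories())
    if (!is.null(b)) {
      bad <- setdiff(names(b), colonisable_categories())
      if (length(bad) > 0) {
        stop("bias names must be colonisable categories", call. = FALSE)
      }
      out[names(b)] <- b
    }
    out
  }
  structure(list(
    n_reefs = as.integer(n_reefs),
    sites_per_reef = as.integer(sites_per_reef),
    images_per_site = as.integer(images_per_site),
    category_mean_cover = category_mean_cover,
    between_site_sd = between_site_sd, within_site_sd = within_site_sd,
    expert_noise_sd = expert_noise_sd,
    ai_bias = full_bias(ai_bias), citizen_bias = full_bias(citizen_bias),
    ai_bias_slope = full_bias(ai_bias_slope),
    citizen_bias_slope = full_bias(citizen_bias_slope),
    bias_reference = bias_reference,
    ai_noise_sd = ai_noise_sd, citizen_noise_sd = citizen_noise_sd,
    analyst_effect_sd = analyst_effect_sd,
    analyses_per_image = as.integer(analyses_per_image),
    cell_noise_sd = cell_noise_sd), class = "generator_config")
}

# Draw a logit-normal value around mean p (proportion) with a target SD on
# the proportion scale, via the delta method; the logit-scale SD is capped so
# extreme means stay numerically sane. Vectorized over p.
rlogitnorm <- function(n, p, sd_prop, cap = 3) {
  sd_logit <- pmin(sd_prop / pmax(p * (1 - p), 1e-6), cap)
  stats::plogis(stats::qlogis(p) + stats::rnorm(n, 0, sd_logit))
}

#' Generate latent true covers for a synthetic survey
#'
#' Draws the survey hierarchy: per-site mean covers around the population
#' means (logit-normal, SD `between_site_sd`), then per-image covers around
#' the site means (logit-normal, SD `within_site_sd`). Coral categories and
#' water/sand/shadow are drawn independently; `reef_substrate` absorbs the
#' remainder so each image composition sums to exactly 100 (if the drawn
#' categories exceed 100 they are scaled back proportionally first). This
#' keeps the realized SD of each drawn category at its configured value away
#' from the cover bounds; near 0 or 100 the logit transform shrinks it.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the same seed reproduces the same truth.
#' @return A `synthetic_truth` list with elements `images` (tibble:
#'   `image_id`, `site_id`, `reef_id`, `water_sand_shadow` -- the total-image
#'   percentage -- and one column per colonisable category holding true
#'   covers on the **colonisable** basis, summing to 100) and `config`.
#' @export
generate_truth <- function(config = generator_config(), seed = 1) {
  set.seed(seed)
  cats <- benthic_categories()
  drawn_cats <- setdiff(cats, "reef_substrate")
  n_sites <- config$n_reefs * config$sites_per_reef
  n_images <- n_sites * config$images_per_site
  site_id <- sprintf("S%04d", seq_len(n_sites))
  reef_id <- sprintf("R%03d", rep(seq_len(config$n_reefs),
                                  each = config$sites_per_reef))
  img_site <- rep(seq_len(n_sites), each = config$images_per_site)
  image_id <- sprintf("I%06d", seq_len(n_images))

  total <- matrix(0, n_images, length(cats), dimnames = list(NULL, cats))
  for (cat in drawn_cats) {
    p0 <- config$category_mean_cover[[cat]] / 100
    if (p0 <= 0) next
    site_p <- rlogitnorm(n_sites, rep(p0, n_sites),
                         config$between_site_sd / 100)
    img_p <- rlogitnorm(n_images, site_p[img_site],
                        config$within_site_sd / 100)
    total[, cat] <- 100 * img_p
  }
  drawn_sum <- rowSums(total)
  over <- drawn_sum > 100
  if (any(over)) {
    total[over, ] <- total[over, ] * (100 / drawn_sum[over])
    drawn_sum[over] <- 100
  }
  total[, "reef_substrate"] <- 100 - drawn_sum

  w <- total[, "water_sand_shadow"]
  colon <- total[, colonisable_categories(), drop = FALSE] *
    (100 / (100 - w))
  images <- tibble::tibble(
    image_id = image_id,
    site_id = site_id[img_site],
    reef_id = reef_id[img_site],
    water_sand_shadow = w)
  for (cat in colonisable_categories()) images[[cat]] <- colon[, cat]
  structure(list(images = images, config = config),
            class = "synthetic_truth")
}

#' @describeIn generate_truth Long-format cover table of the true covers on
#'   the colonisable basis (`method = "expert_visual"` is *not* implied;
#'   records carry `analyst_id = "truth"` and `method` as given).
#' @param truth A `synthetic_truth` object.
#' @param method Method label for the emitted records.
#' @export
truth_to_cover_table <- function(truth, method = "expert_visual") {
  long <- tidyr::pivot_longer(
    truth$images,
    cols = tidyr::all_of(colonisable_categories()),
    names_to = "category", values_to = "cover_pct")
  long$method <- method
  long$analyst_id <- "truth"
  long$basis <- "colonisable"
  as_cover_table(long[, c("image_id", "site_id", "reef_id", "method",
                          "analyst_id", "basis", "category", "cover_pct")])
}

# truth matrix on the colonisable basis (images x categories)
truth_matrix <- function(truth) {
  as.matrix(truth$images[, colonisable_categories()])
}

#' Generate observed method covers from a synthetic truth
#'
#' Produces a cover table of what each analysis method would report for every
#' image of the truth, on the colonisable basis:
#'
#' * `expert_visual`: truth plus per-category noise
#'   (`expert_noise_sd`), clamped at 0 and renormalized to sum 100 -- an
#'   expert scores a full composition.
#' * `ai`: truth plus the configured per-category bias (plus any
#'   cover-dependent slope term) plus noise (`ai_noise_sd`), clamped to
#'   `[0, 100]`. Method estimates carry measurement error per category and
#'   are deliberately **not** renormalized, so the configured biases survive
#'   to the accuracy stage unchanged.
#' * `citizen`: one record per analysis; each analysis adds the citizen bias,
#'   a per-analyst offset (`analyst_effect_sd`) shared across categories,
#'   and per-category noise (`citizen_noise_sd`), clamped to `[0, 100]`. The
#'   number of analyses per image is drawn uniformly from
#'   `analyses_per_image`.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param seed Integer seed for the observation noise (independent of the
#'   truth seed).
#' @return A cover table with methods `expert_visual`, `ai` and `citizen`.
#' @export
generate_method_observations <- function(truth, seed = 1) {
  set.seed(seed)
  cfg <- truth$config
  tm <- truth_matrix(truth)
  n_images <- nrow(tm)
  cats <- colonisable_categories()
  ids <- truth$images[, c("image_id", "site_id", "reef_id")]

  obs_rows <- function(mat, method, analyst_id) {
    rec <- ids
    rec$method <- method
    rec$analyst_id <- analyst_id
    for (cat in cats) rec[[cat]] <- mat[, cat]
    rec
  }

  # expert: noisy full composition, clamped then renormalized to 100
  expert <- tm + matrix(stats::rnorm(n_images * length(cats),
                                     0, cfg$expert_noise_sd),
                        n_images, length(cats))
  expert <- pmax(expert, 0)
  expert <- expert * (100 / rowSums(expert))
  colnames(expert) <- cats

  biased <- function(bias, slope) {
    b <- matrix(rep(bias[cats], each = n_images), n_images, length(cats))
    s <- matrix(rep(slope[cats], each = n_images), n_images, length(cats))
    b + s * (tm - cfg$bias_reference)
  }
  ai <- tm + biased(cfg$ai_bias, cfg$ai_bias_slope) +
    matrix(stats::rnorm(n_images * length(cats), 0, cfg$ai_noise_sd),
           n_images, length(cats))
  ai <- pmin(pmax(ai, 0), 100)
  colnames(ai) <- cats

  n_analyses <- cfg$analyses_per_image[
    sample.int(length(cfg$analyses_per_image), n_images, replace = TRUE)]
  img_idx <- rep(seq_len(n_images), n_analyses)
  n_rows <- length(img_idx)
  analyst_offset <- stats::rnorm(n_rows, 0, cfg$analyst_effect_sd)
  cit <- tm[img_idx, , drop = FALSE] +
    biased(cfg$citizen_bias, cfg$citizen_bias_slope)[img_idx, ,
                                                     drop = FALSE] +
    analyst_offset +
    matrix(stats::rnorm(n_rows * length(cats), 0, cfg$citizen_noise_sd),
           n_rows, length(cats))
  cit <- pmin(pmax(cit, 0), 100)
  colnames(cit) <- cats
  analysis_no <- sequence(n_analyses)
  cit_ids <- ids[img_idx, ]
  cit_rec <- cit_ids
  cit_rec$method <- "citizen"
  cit_rec$analyst_id <- sprintf("C_%s_%d", cit_ids$image_id, analysis_no)
  for (cat in cats) cit_rec[[cat]] <- cit[, cat]

  wide <- dplyr::bind_rows(
    obs_rows(expert, "expert_visual", "E1"),
    obs_rows(ai, "ai", "ai"),
    cit_rec)
  long <- tidyr::pivot_longer(wide, cols = tidyr::all_of(cats),
                              names_to = "category",
                              values_to = "cover_pct")
  long$basis <- "colonisable"
  as_cover_table(long[, c("image_id", "site_id", "reef_id", "method",
                          "analyst_id", "basis", "category", "cover_pct")])
}

# Largest-remainder apportionment of `total` units to targets proportional
# to `weights` (deterministic; ties broken by category order).
largest_remainder <- function(weights, total) {
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    out[1] <- total
    return(out)
  }
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate segmentation masks realizing the true covers
#'
#' Builds, for each image of the truth, a category raster whose pixel counts
#' match the image's true total-image composition as closely as an integer
#' pixel grid allows (largest-remainder rounding, deterministic). Pixels are
#' laid out as contiguous category blocks and then shuffled when `shuffle` is
#' set; [cover_from_mask()] recovers the intended covers to within one pixel
#' quantum, `100 / (height * width)`, per category.
#'
#' @param truth A `synthetic_truth`.
#' @param height,width Mask dimensions in pixels (`height * width >= 100`).
#' @param shuffle Randomly permute pixel positions (cover is unaffected).
#' @param seed Seed for the shuffle.
#' @return Named list of integer matrices, one per image.
#' @export
generate_masks <- function(truth, height = 32, width = 32, shuffle = TRUE,
                           seed = 1) {
  stopifnot(height * width >= 100)
  set.seed(seed)
  cats <- benthic_categories()
  w <- truth$images$water_sand_shadow
  colon <- truth_matrix(truth)
  total_basis <- cbind(colon * (100 - w) / 100, water_sand_shadow = w)
  colnames(total_basis) <- c(colonisable_categories(), "water_sand_shadow")
  total_basis <- total_basis[, cats, drop = FALSE]
  n_px <- height * width
  masks <- lapply(seq_len(nrow(total_basis)), function(i) {
    counts <- largest_remainder(total_basis[i, ], n_px)
    vals <- rep.int(seq_along(cats) - 1L, counts)
    if (shuffle) vals <- vals[sample.int(n_px)]
    matrix(vals, nrow = height, ncol = width)
  })
  stats::setNames(masks, truth$images$image_id)
}

#' Generate 3x3 visual-grid annotations realizing the true covers
#'
#' Emulates the visual expert protocol on the synthetic truth: each of the
#' nine grid cells scores every category at the image's total-image cover
#' plus cell-level noise (`cell_noise_sd`), clamped to `[0, 100]`. Noise is
#' added to the drawn categories only; `reef_substrate` absorbs the cell
#' remainder so each cell composition sums to exactly 100 (scaled back
#' proportionally if the noisy categories exceed 100). With zero cell noise,
#' [cover_from_grid()] returns the true total-image covers exactly; a
#' category whose true cover is 0 scores 0 in every cell.
#'
#' @param truth A `synthetic_truth`.
#' @param analyst_id Analyst label for the emitted annotations.
#' @param seed Integer seed.
#' @return Tibble with columns `image_id`, `site_id`, `reef_id`,
#'   `analyst_id`, `method`, `cell_index`, `category`, `value_pct`.
#' @export
generate_grid_annotations <- function(truth, analyst_id = "E1", seed = 1) {
  set.seed(seed)
  cfg <- truth$config
  cats <- benthic_categories()
  drawn_cats <- setdiff(cats, "reef_substrate")
  w <- truth$images$water_sand_shadow
  colon <- truth_matrix(truth)
  total_basis <- cbind(colon * (100 - w) / 100, water_sand_shadow = w)
  colnames(total_basis) <- c(colonisable_categories(), "water_sand_shadow")
  n_images <- nrow(total_basis)
  n_cells <- 9L

  rows <- vector("list", length(drawn_cats))
  cell_mat <- matrix(0, n_images * n_cells, length(cats),
                     dimnames = list(NULL, cats))
  for (cat in drawn_cats) {
    base <- rep(total_basis[, cat], each = n_cells)
    noise <- ifelse(base > 0,
                    stats::rnorm(n_images * n_cells, 0, cfg$cell_noise_sd),
                    0)
    cell_mat[, cat] <- pmin(pmax(base + noise, 0), 100)
  }
  drawn_sum <- rowSums(cell_mat[, drawn_cats, drop = FALSE])
  over <- drawn_sum > 100
  if (any(over)) {
    cell_mat[over, drawn_cats] <- cell_mat[over, drawn_cats] *
      (100 / drawn_sum[over])
    drawn_sum[over] <- 100
  }
  cell_mat[, "reef_substrate"] <- 100 - drawn_sum

  out <- tibble::tibble(
    image_id = rep(truth$images$image_id, each = n_cells),
    site_id = rep(truth$images$site_id, each = n_cells),
    reef_id = rep(truth$images$reef_id, each = n_cells),
    analyst_id = analyst_id,
    method = "expert_visual",
    cell_index = rep(seq_len(n_cells), n_images))
  long <- tidyr::pivot_longer(
    cbind(out, tibble::as_tibble(cell_mat)),
    cols = tidyr::all_of(cats),
    names_to = "category", values_to = "value_pct")
  tibble::as_tibble(long)
}

#' Convert grid annotations to a cover table
#'
#' Applies [cover_from_grid()] to every (image, analyst) group of a grid
#' annotation table (long format, as produced by
#' [generate_grid_annotations()] or read from `annotations_grid.csv`).
#'
#' @param grid_annotations Tibble with columns `image_id`, `site_id`,
#'   `reef_id`, `analyst_id`, `method`, `cell_index`, `category`,
#'   `value_pct`.
#' @return A cover table on the total-image basis.
#' @export
grid_annotations_to_covers <- function(grid_annotations) {
  groups <- dplyr::group_split(
    dplyr::group_by(grid_annotations, .data$image_id, .data$analyst_id))
  recs <- lapply(groups, function(g) {
    cover <- cover_from_grid(g[, c("cell_index", "category", "value_pct")])
    cover_record(cover, image_id = g$image_id[1], site_id = g$site_id[1],
                 reef_id = g$reef_id[1], method = g$method[1],
                 analyst_id = g$analyst_id[1], basis = "total_image")
  })
  as_cover_table(dplyr::bind_rows(recs))
}
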