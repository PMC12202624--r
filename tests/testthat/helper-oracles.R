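# Shared test fixtures and independent oracles.

# Build a cover table from a wide data frame of per-category covers.
make_cover_table <- function(wide, method, analyst_id = "mean",
                             basis = "colonisable") {
  cats <- setdiff(names(wide), c("image_id", "site_id", "reef_id"))
  long <- tidyr::pivot_longer(wide, cols = tidyr::all_of(cats),
                              names_to = "category",
                              values_to = "cover_pct")
  long$site_id <- if ("site_id" %in% names(wide)) long$site_id else "S1"
  long$reef_id <- if ("reef_id" %in% names(wide)) long$reef_id else "R1"
  long$method <- method
  long$analyst_id <- analyst_id
  long$basis <- basis
  as_cover_table(long[, c("image_id", "site_id", "reef_id", "method",
                          "analyst_id", "basis", "category", "cover_pct")])
}

# Random colonisable-basis covers for n images (compositions summing to 100).
random_cover_wide <- function(n, site_id = NULL, prefix = "I") {
  cats <- colonisable_categories()
  raw <- matrix(stats::rexp(n * length(cats)), n)
  comp <- 100 * raw / rowSums(raw)
  colnames(comp) <- cats
  out <- tibble::tibble(image_id = sprintf("%s%04d", prefix, seq_len(n)))
  if (!is.null(site_id)) out$site_id <- site_id
  cbind(out, tibble::as_tibble(comp))
}

# Monte-Carlo power of the equal-n two-sample pooled t test, vectorized
# over replicates. Independent of the noncentral-t implementation.
mc_power <- function(n, d, reps = 5000, alpha = 0.05) {
  x <- matrix(stats::rnorm(n * reps, mean = d), n)
  y <- matrix(stats::rnorm(n * reps), n)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- (colSums(x^2) - n * mx^2) / (n - 1)
  vy <- (colSums(y^2) - n * my^2) / (n - 1)
  tstat <- (mx - my) / sqrt((vx + vy) / n)
  mean(abs(tstat) > stats::qt(1 - alpha / 2, 2 * n - 2))
}

# A tiny noiseless truth whose every image equals the configured means.
deterministic_truth <- function(means = c(branching = 25, plating = 10,
                                          massive = 5, other_coral = 10,
                                          reef_substrate = 30,
                                          water_sand_shadow = 20),
                                images_per_site = 4) {
  cfg <- generator_config(n_reefs = 1, sites_per_reef = 1,
                          images_per_site = images_per_site,
                          category_mean_cover = means,
                          between_site_sd = 0, within_site_sd = 0,
                          expert_noise_sd = 0,
                          ai_bias = NULL, citizen_bias = NULL,
                          ai_noise_sd = 0, citizen_noise_sd = 0,
                          analyst_effect_sd = 0, analyses_per_image = 2,
                          cell_noise_sd = 0)
  generate_truth(cfg, seed = 1)
}
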