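#' Pipeline configuration
#'
#' Gathers every stage's settings. When `covers_path` is `NULL` the pipeline
#' generates a synthetic survey from `generator` instead of reading observed
#' covers, so the whole chain runs self-contained.
#'
#' @param covers_path Optional path to a `covers.csv` of per-analysis covers
#'   (colonisable basis); `NULL` to simulate.
#' @param expert_method Which expert protocol provides the reference values.
#' @param min_bin_images Minimum images for a reef-state bin to be reported.
#' @param generator A [generator_config()].
#' @param sim A [sim_config()].
#' @param power A [power_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(covers_path = NULL,
                            expert_method = "expert_visual",
                            min_bin_images = 80,
                            generator = generator_config(),
                            sim = sim_config(),
                            power = power_config()) {
  stopifnot(expert_method %in% c("expert_visual", "expert_detailed"),
            min_bin_images >= 0)
  structure(list(covers_path = covers_path, expert_method = expert_method,
                 min_bin_images = min_bin_images, generator = generator,
                 sim = sim, power = power),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- covers (read or simulate), analyst
#' aggregation, per-image accuracy of the AI and citizen methods, method
#' summaries, best-method fusion, reef-state bin summaries, images-per-site
#' simulation grid, and the power analysis -- and writes each stage's table
#' as CSV into `out_dir`, plus a `manifest.json` recording the seed, a
#' configuration hash and per-stage row counts. Identical configuration and
#' seed produce byte-identical outputs. Progress is logged to stderr;
#' results never are.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed for every stochastic stage.
#' @return Invisibly, a named list of the stage tables and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name) {
    message(sprintf("[reefcover] %s (%.1fs elapsed)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  stage("covers")
  if (is.null(config$covers_path)) {
    truth <- generate_truth(config$generator, seed = seed)
    covers <- generate_method_observations(truth, seed = seed + 1L)
  } else {
    covers <- read_cover_table(config$covers_path)
  }

  stage("aggregate analysts")
  agg <- aggregate_analysts(covers)
  expert <- agg[agg$method == config$expert_method, ]
  if (nrow(expert) == 0) {
    stop("pipeline stage 'aggregate analysts' failed: no expert records for method ",
         config$expert_method, call. = FALSE)
  }

  stage("accuracy")
  ai_acc <- per_image_accuracy(agg[agg$method == "ai", ], expert)
  cit_acc <- per_image_accuracy(agg[agg$method == "citizen", ], expert)
  ai_sum <- summarize_method(ai_acc)
  cit_sum <- summarize_method(cit_acc)

  stage("best-method fusion")
  best_map <- select_best_method(ai_sum, cit_sum)
  best_acc <- apply_best(ai_acc, cit_acc, best_map)
  best_sum <- summarize_method(best_acc)
  summaries <- dplyr::bind_rows(ai_sum, cit_sum, best_sum)

  stage("reef-state bins")
  bins <- bin_by_reef_state(best_acc, expert,
                            min_bin_images = config$min_bin_images)

  stage("site simulation")
  sim_rows <- lapply(coral_categories(), function(cat) {
    cat_acc <- best_acc[best_acc$category == cat, ]
    pool <- if (best_map[[cat]] == "citizen") {
      # resample individual citizen analyses within each image
      per_analysis <- per_image_accuracy(
        covers[covers$method == "citizen", ], expert)
      per_analysis <- per_analysis[per_analysis$category == cat, ]
      split(per_analysis$diff_pct, per_analysis$image_id)
    } else {
      cat_acc$diff_pct
    }
    g <- simulate_accuracy_grid(pool, config$sim,
                                seed = substream_seed(seed, 0L, 0L,
                                                      stream = match(
                                                        cat,
                                                        coral_categories())))
    g$category <- cat
    g[, c("category", setdiff(names(g), "category"))]
  })
  simgrid <- dplyr::bind_rows(sim_rows)
  min_images <- min_images_required(simgrid, config$sim$target_fraction)

  stage("power analysis")
  best_covers <- best_method_covers(agg, best_map)
  power_bins <- power_analysis(best_covers, expert, config$power)
  site_stats <- attr(power_bins, "site_stats")

  stage("write outputs")
  outputs <- list(covers = covers, accuracy = dplyr::bind_rows(
    ai_acc, cit_acc, best_acc),
    summaries = summaries,
    best_map = tibble::tibble(category = names(best_map),
                              method = unname(best_map)),
    bins = bins, simgrid = simgrid, min_images = min_images,
    site_stats = site_stats, power = power_bins)
  paths <- character(0)
  for (name in names(outputs)) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    tab <- outputs[[name]]
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], round, digits = 4)
    readr::write_csv(tab, path)
    paths[name] <- path
  }
  manifest <- list(
    package = "reefcover",
    version = as.character(utils::packageVersion("reefcover")),
    seed = seed,
    config_hash = rlang::hash(config),
    n_rows = lapply(outputs, nrow),
    best_map = as.list(best_map))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage("done")
  invisible(c(outputs, list(manifest = manifest, paths = paths)))
}

# Per-image best-method cover values (not differences): for each category,
# the analyst-aggregated covers of the mapped method.
best_method_covers <- function(agg_covers, best_map) {
  pieces <- lapply(coral_categories(), function(cat) {
    src <- agg_covers[agg_covers$method == best_map[[cat]] &
                        agg_covers$category == cat, ]
    src$method <- "best"
    src
  })
  as_cover_table(dplyr::bind_rows(pieces))
}
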