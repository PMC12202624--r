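test_that("per-image accuracy is method minus expert per coral category", {
  expert <- make_cover_table(
    tibble::tibble(image_id = "i1", branching = 10, reef_substrate = 90),
    method = "expert_visual")
  ai <- make_cover_table(
    tibble::tibble(image_id = "i1", branching = 5, reef_substrate = 95),
    method = "ai")
  acc <- per_image_accuracy(ai, expert)
  expect_equal(acc$diff_pct[acc$category == "branching"], -5)
  expect_true(all(acc$n_citizen_analyses == 0))

  # a method compared with itself is identically zero
  w <- random_cover_wide(6)
  tbl <- make_cover_table(w, method = "ai")
  self <- per_image_accuracy(tbl, make_cover_table(w, "expert_visual"))
  expect_true(all(self$diff_pct == 0))
})

test_that("per-image accuracy matches a direct subtraction oracle", {
  set.seed(61)
  wm <- random_cover_wide(8)
  we <- random_cover_wide(8)
  acc <- per_image_accuracy(make_cover_table(wm, "citizen"),
                            make_cover_table(we, "expert_visual"))
  for (cat in coral_categories()) {
    expect_equal(acc$diff_pct[acc$category == cat],
                 wm[[cat]] - we[[cat]])
  }
  expect_true(all(acc$n_citizen_analyses == 1))
})

test_that("per-image accuracy validates bases and warns on disjoint images", {
  e <- make_cover_table(random_cover_wide(3), "expert_visual")
  m_total <- make_cover_table(random_cover_wide(3), "ai",
                              basis = "total_image")
  expect_error(per_image_accuracy(m_total, e), "colonisable")

  m_other <- make_cover_table(random_cover_wide(3, prefix = "J"), "ai")
  expect_warning(acc <- per_image_accuracy(m_other, e), "no images")
  expect_equal(nrow(acc), 0)
})

test_that("method summaries report per-category means, SEs and total coral", {
  acc <- tibble::tibble(
    image_id = "i1", site_id = "s1", method = "ai",
    category = coral_categories(),
    diff_pct = c(-5, 5, 0, 0), n_citizen_analyses = 0L)
  s <- summarize_method(acc)
  expect_equal(s$mean_diff[match(coral_categories(), s$category)],
               c(-5, 5, 0, 0))
  expect_equal(s$mean_diff[s$category == "total_coral"], 0)

  # two images with opposite differences cancel
  acc2 <- dplyr::bind_rows(acc, dplyr::mutate(acc, image_id = "i2",
                                              diff_pct = -diff_pct))
  s2 <- summarize_method(acc2)
  expect_true(all(s2$mean_diff == 0))

  # random table vs direct mean/SE oracle
  set.seed(71)
  n <- 40
  accr <- tidyr::expand_grid(image_id = sprintf("i%02d", 1:n),
                             category = coral_categories())
  accr$site_id <- "s1"
  accr$method <- "best"
  accr$diff_pct <- stats::rnorm(nrow(accr), 0, 6)
  accr$n_citizen_analyses <- 1L
  s3 <- summarize_method(accr)
  for (cat in coral_categories()) {
    d <- accr$diff_pct[accr$category == cat]
    row <- s3[s3$category == cat, ]
    expect_equal(row$mean_diff, mean(d))
    expect_equal(row$se, stats::sd(d) / sqrt(n))
    expect_equal(row$n_images, n)
  }
  totals <- tapply(accr$diff_pct, accr$image_id, sum)
  expect_equal(s3$mean_diff[s3$category == "total_coral"],
               mean(totals))
})

test_that("summaries are translation-equivariant", {
  set.seed(72)
  acc <- tidyr::expand_grid(image_id = sprintf("i%02d", 1:15),
                            category = coral_categories())
  acc$site_id <- "s1"; acc$method <- "ai"
  acc$diff_pct <- stats::rnorm(nrow(acc))
  acc$n_citizen_analyses <- 0L
  s <- summarize_method(acc)
  shifted <- acc
  shifted$diff_pct[shifted$category == "plating"] <-
    shifted$diff_pct[shifted$category == "plating"] + 3
  s2 <- summarize_method(shifted)
  expect_equal(s2$mean_diff[s2$category == "plating"],
               s$mean_diff[s$category == "plating"] + 3)
  expect_equal(s2$se, s$se)
})

test_that("best-method selection takes the smaller absolute mean, ties to ai", {
  mk <- function(method, means) {
    tibble::tibble(method = method, category = coral_categories(),
                   mean_diff = means, se = 1, n_images = 100)
  }
  ai <- mk("ai", c(-1.1, -9.1, -2, 6.9))
  cit <- mk("citizen", c(9.5, -0.99, -0.1, 4.5))
  map <- select_best_method(ai, cit)
  expect_equal(unname(map["branching"]), "ai")
  expect_equal(unname(map["plating"]), "citizen")

  tie <- select_best_method(mk("ai", c(2, -2, 2, -2)),
                            mk("citizen", c(-2, 2, -2, 2)))
  expect_true(all(tie == "ai"))

  set.seed(81)
  for (rep in 1:10) {
    a <- stats::rnorm(4); b <- stats::rnorm(4)
    map <- select_best_method(mk("ai", a), mk("citizen", b))
    expect_equal(unname(map), ifelse(abs(b) < abs(a), "citizen", "ai"))
  }
})

test_that("applying a best map merges tables cell-wise", {
  set.seed(91)
  ai <- per_image_accuracy(make_cover_table(random_cover_wide(6), "ai"),
                           make_cover_table(random_cover_wide(6),
                                            "expert_visual"))
  cit <- per_image_accuracy(
    make_cover_table(random_cover_wide(6), "citizen"),
    make_cover_table(random_cover_wide(6), "expert_visual"))

  all_ai <- apply_best(ai, cit, stats::setNames(rep("ai", 4),
                                                coral_categories()))
  expect_equal(dplyr::arrange(tibble::as_tibble(all_ai), image_id,
                              category)[, c("image_id", "category",
                                            "diff_pct")],
               dplyr::arrange(ai, image_id, category)[, c("image_id",
                                                          "category",
                                                          "diff_pct")],
               ignore_attr = TRUE)
  expect_true(all(all_ai$method == "best"))

  map <- c(branching = "ai", plating = "citizen", massive = "citizen",
           other_coral = "ai")
  best <- apply_best(ai, cit, map)
  for (cat in coral_categories()) {
    src <- if (map[[cat]] == "ai") ai else cit
    expect_equal(sort(best$diff_pct[best$category == cat]),
                 sort(src$diff_pct[src$category == cat]))
  }

  # disjoint coverage leaves missing cells, counted not invented
  cit_partial <- cit[cit$image_id != cit$image_id[1], ]
  best2 <- apply_best(ai, cit_partial, map)
  expect_equal(sum(best2$category == "plating"), 5)
  expect_equal(unname(attr(best2, "n_missing")["plating"]), 1L)
  expect_error(apply_best(ai, cit, map[1:3]), "every coral category")
})

test_that("reef-state binning follows expert covers with [lo, hi) edges", {
  expert <- make_cover_table(
    tibble::tibble(image_id = c("a", "b"), branching = c(9.99, 10),
                   reef_substrate = c(90.01, 90)),
    "expert_visual")
  acc <- tibble::tibble(image_id = c("a", "b"), site_id = "s",
                        method = "best", category = "branching",
                        diff_pct = c(1, 2), n_citizen_analyses = 0L)
  bins <- bin_by_reef_state(acc, expert, min_bin_images = 0)
  expect_setequal(as.character(bins$bin), c("[0,10)", "[10,20)"))
  expect_equal(as.character(cover_bin(100)), "[90,100]")
})

test_that("bins below the image minimum are absent and counts partition", {
  set.seed(101)
  n <- 200
  w <- random_cover_wide(n)
  expert <- make_cover_table(w, "expert_visual")
  acc <- tidyr::expand_grid(image_id = w$image_id,
                            category = coral_categories())
  acc$site_id <- "s"; acc$method <- "best"
  acc$diff_pct <- stats::rnorm(nrow(acc))
  acc$n_citizen_analyses <- 1L

  all_bins <- bin_by_reef_state(acc, expert, min_bin_images = 0)
  counts <- tapply(all_bins$n_images, all_bins$category, sum)
  expect_true(all(counts == n))  # binning partitions the images

  filtered <- bin_by_reef_state(acc, expert, min_bin_images = 80)
  expect_true(all(filtered$n_images >= 80))
  kept <- all_bins[all_bins$n_images >= 80, ]
  expect_equal(nrow(filtered), nrow(kept))

  just_under <- bin_by_reef_state(acc, expert,
                                  min_bin_images = max(all_bins$n_images) + 1)
  expect_equal(nrow(just_under), 0)
})

test_that("offset correction subtracts, clamps and counts clamps", {
  tbl <- make_cover_table(
    tibble::tibble(image_id = "i", branching = 3, plating = 50,
                   reef_substrate = 47),
    "ai")
  same <- correct_with_offset(tbl, c(branching = 0))
  expect_equal(same$cover_pct, tbl$cover_pct)
  expect_equal(attr(same, "n_clamped"), 0L)

  corr <- correct_with_offset(tbl, c(branching = 5, plating = -10))
  expect_equal(corr$cover_pct[corr$category == "branching"], 0)
  expect_equal(corr$cover_pct[corr$category == "plating"], 60)
  expect_equal(attr(corr, "n_clamped"), 1L)

  set.seed(111)
  w <- random_cover_wide(10)
  tbl <- make_cover_table(w, "ai")
  off <- stats::setNames(stats::rnorm(5, 0, 10), colonisable_categories())
  corr <- correct_with_offset(tbl, off)
  expect_equal(corr$cover_pct,
               pmin(pmax(tbl$cover_pct - off[tbl$category], 0), 100),
               ignore_attr = TRUE)
})

test_that("annotation-protocol comparison runs a paired signed-rank test", {
  set.seed(115)
  w <- random_cover_wide(30)
  a <- make_cover_table(w, "expert_detailed")
  expect_equal(compare_annotation_methods(a, a)$mean_difference, 0)

  shifted <- w
  for (cat in coral_categories()) shifted[[cat]] <- shifted[[cat]] + 0.5
  b <- make_cover_table(shifted, "expert_visual")
  res <- compare_annotation_methods(a, b)
  expect_equal(res$mean_difference, -2)  # four coral categories shifted
  expect_lt(res$p_value, 0.01)
  expect_equal(res$n, 30)
})

test_that("the signed-rank comparison holds its type-I error under the null", {
  set.seed(121)
  n_img <- 40
  reps <- 400
  rejections <- 0
  for (r in seq_len(reps)) {
    ta <- stats::rnorm(n_img, 20, 5)
    tb <- stats::rnorm(n_img, 20, 5)
    wa <- tibble::tibble(image_id = sprintf("i%02d", 1:n_img),
                         branching = ta, reef_substrate = 100 - ta)
    wb <- tibble::tibble(image_id = sprintf("i%02d", 1:n_img),
                         branching = tb, reef_substrate = 100 - tb)
    p <- compare_annotation_methods(make_cover_table(wa, "expert_detailed"),
                                    make_cover_table(wb, "expert_visual"))
    if (p$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / reps, 0.015)
  expect_lt(rejections / reps, 0.095)
})
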