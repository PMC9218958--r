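test_that("recovery proportions are plain counting", {
  m <- synth_match(10, 10, 1, seed = 1)
  expect_equal(found_proportion(m), 100)
  m$match_status[1:30] <- "missed"
  expect_equal(found_proportion(m), 70)
  m$match_status[31:40] <- "split"
  expect_equal(found_proportion(m), 70) # split still found
  expect_equal(split_proportion(m), 10)
  expect_error(found_proportion(m[0, ]), class = "irbench_assess_error")
  attr(m, "stage") <- "post"
  expect_error(split_proportion(m), class = "irbench_assess_error")
})

test_that("IR recovery compares NFD bias to benchmark bias plus margin", {
  fx <- clean_fixture()
  mp <- match_unaligned(fx$bm, fx$scene$unaligned)
  expect_equal(as.numeric(ir_accuracy(mp)), 100)
  # inflate one LAIT well beyond its benchmark bias + 20 points
  i <- which(mp$status == "accepted_lait")[1]
  mp$matched_abundance[i] <- mp$matched_abundance[i] * 2
  n_l <- sum(mp$status == "accepted_lait")
  expect_equal(as.numeric(ir_accuracy(mp)), 100 * (n_l - 1) / n_l)
  # a generous margin re-admits it: accuracy is monotone in the margin
  expect_equal(as.numeric(ir_accuracy(mp, margin = 150)), 100)
  # nothing assessable -> NA, never zero
  mp$matched_abundance[mp$status == "accepted_lait"] <- NA
  out <- ir_accuracy(mp)
  expect_true(is.na(out))
  expect_equal(attr(out, "n"), 0L)
})

test_that("metrics are invariant under duplicating the whole input", {
  m <- synth_match(20, 3, 0.7, seed = 2)
  m2 <- dplyr::bind_rows(m, dplyr::mutate(m, molecule_id = paste0(molecule_id, "bis")))
  m2 <- structure(m2, stage = "pre",
                  class = c("match_result", class(tibble::tibble())))
  expect_equal(found_proportion(m2), found_proportion(m))
})

test_that("the bootstrap is molecule-wise, deterministic, and degenerate-safe", {
  m <- synth_match(30, 3, 0.8, seed = 4)
  ci1 <- bootstrap_ci(found_proportion, m, R = 200, seed = 9)
  ci2 <- bootstrap_ci(found_proportion, m, R = 200, seed = 9)
  expect_identical(ci1, ci2)
  p <- found_proportion(m)
  expect_lte(ci1[["lower"]], p)
  expect_gte(ci1[["upper"]], p)
  # a metric constant across molecules collapses the interval
  mc <- synth_match(30, 3, 1, seed = 5)
  cic <- bootstrap_ci(found_proportion, mc, R = 100, seed = 1)
  expect_equal(unname(cic), c(100, 100), ignore_attr = TRUE)
  # single molecule: degenerate with a warning
  ms <- synth_match(1, 5, 0.8, seed = 6)
  expect_warning(cis <- bootstrap_ci(found_proportion, ms, R = 50, seed = 1),
                 "single")
  expect_equal(unname(cis[1]), unname(cis[2]))
})

test_that("CV metrics reproduce hand-computed values and rules", {
  ab <- rbind(F1 = c(100, 100, 160),  # cv 28.87 -> passes
              F2 = c(100, 100, 200),  # cv 43.3  -> fails
              F3 = c(50, NA, 60),     # missing value -> fails
              F4 = c(0, 0, 0),        # zero mean -> fails
              F5 = c(80, 80, 80))     # cv 0 -> passes
  ft <- make_features(ab, files = c("r1", "r2", "r3"))
  expect_message(cv <- cv_metrics(ft, c("r1", "r2", "r3")), "zero mean")
  expect_equal(cv$nCV30, 2L)
  expect_equal(cv$pCV30, 40)
  d <- cv$detail
  expect_equal(d$cv[d$feature_id == "F1"], 100 * sd(c(100, 100, 160)) / 120)
  expect_true(is.na(d$cv[d$feature_id == "F3"]))
  # pass count is monotone in the threshold
  cv2 <- cv_metrics(ft, c("r1", "r2", "r3"), cv_threshold = 50)
  expect_gte(cv2$nCV30, cv$nCV30)
  expect_error(cv_metrics(ft, "r1"), class = "irbench_assess_error")
})

test_that("label filtering retains exactly the features with enough good peaks", {
  ab <- matrix(100, nrow = 6, ncol = 3,
               dimnames = list(paste0("F", 1:6), NULL))
  lab <- matrix("high_quality", 6, 3)
  lab[1, ] <- "low_quality"          # 0 good
  lab[2, 1:2] <- "low_quality"       # 1 good
  lab[3, 1] <- "low_quality"         # 2 good
  ft <- make_features(ab, files = c("r1", "r2", "r3"), labels = lab)
  counts <- vapply(0:3, function(k) {
    evaluate_feature_filter(ft, min_good = k)$n_retained
  }, integer(1))
  expect_equal(counts, c(6L, 5L, 4L, 3L))
  # monotone non-increasing in min_good; errors on impossible requests
  expect_true(all(diff(counts) <= 0))
  expect_error(evaluate_feature_filter(ft, min_good = 4),
               class = "irbench_assess_error")
  ft$label[1] <- NA
  expect_error(evaluate_feature_filter(ft, min_good = 1),
               class = "irbench_assess_error")
})

test_that("assess() bundles matching, metrics, and intervals", {
  fx <- clean_fixture()
  rep <- assess(fx$bm, unaligned = fx$scene$unaligned,
                aligned = fx$scene$aligned, R = 100, seed = 2)
  g <- glance(rep)
  expect_equal(g$found_pre, 100)
  expect_equal(g$found_post, 100)
  expect_equal(g$split_pre, 0)
  expect_equal(g$ir_accuracy_pre, 100)
  m <- rep$metrics
  expect_true(all(m$ci_lower <= m$value, na.rm = TRUE))
  expect_true(all(m$ci_upper >= m$value, na.rm = TRUE))
  td <- tidy(rep)
  expect_equal(td$value[td$metric == "missed_pre"],
               100 - g$found_pre)
  expect_error(assess(fx$bm), class = "irbench_assess_error")
})
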