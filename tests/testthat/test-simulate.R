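test_that("simulation is deterministic under a fixed seed", {
  roster <- sim_molecules(n = 4, seed = 21)
  cfg <- sim_config(roster, mz_jitter_ppm = 3, noise_cv = 0.05, seed = 21)
  s1 <- simulate_run(cfg, tempfile(fileext = ".mzML"))
  s2 <- simulate_run(cfg, tempfile(fileext = ".mzML"))
  expect_identical(s1$truth, s2$truth)
  r1 <- read_run(s1$path)
  r2 <- read_run(s2$path)
  expect_equal(r1$flat$mz, r2$flat$mz)
  expect_equal(r1$flat$intensity, r2$flat$intensity)
  # a different seed moves the noise
  cfg2 <- sim_config(roster, mz_jitter_ppm = 3, noise_cv = 0.05, seed = 22)
  s3 <- simulate_run(cfg2, tempfile(fileext = ".mzML"))
  r3 <- read_run(s3$path)
  expect_false(identical(r1$flat$intensity, r3$flat$intensity))
})

test_that("written runs reproduce the planted apexes and areas", {
  fx <- clean_fixture()
  cfg <- fx$scene$config
  for (i in c(1, 5, nrow(fx$scene$truth))) {
    tr <- fx$scene$truth[i, ]
    eic <- extract_eic(fx$run, tr$mz, rt_window = c(tr$rt_min, tr$rt_max))
    m <- measure_peak(eic, c(tr$rt_min, tr$rt_max))
    expect_equal(m$rt_apex, tr$rt_apex, tolerance = cfg$scan_interval)
    expect_equal(m$area, tr$area, tolerance = 0.01 * tr$area)
  }
})

test_that("planted heights realize the configured dynamic range", {
  roster <- sim_molecules(n = 12, height_range = c(1e3, 1e7), seed = 2)
  expect_equal(log10(max(roster$height) / min(roster$height)), 4)
  cfg <- sim_config(roster, seed = 2)
  scene <- simulate_run(cfg, tempfile(fileext = ".mzML"))
  mait <- scene$truth[scene$truth$ir == 1, ]
  expect_equal(log10(max(mait$height) / min(mait$height)), 4)
})

test_that("the saturation ceiling clips apexes and flags the right traces", {
  roster <- sim_molecules(n = 5, height_range = c(1e4, 1e5), seed = 9)
  roster$height[3] <- 2e6
  cfg <- sim_config(roster, saturation = 1e6, seed = 9)
  scene <- simulate_run(cfg, tempfile(fileext = ".mzML"))
  tr <- scene$truth
  expect_setequal(tr$molecule_id[tr$saturated], roster$molecule_id[3])
  expect_equal(max(tr$height[tr$molecule_id == roster$molecule_id[3]]), 1e6)
  run <- read_run(scene$path)
  expect_lte(max(run$flat$intensity), 1e6)
})

test_that("identical (m/z, rt) duplicates are rejected", {
  roster <- sim_molecules(n = 2, seed = 1)
  roster$formula <- c("C6H12O6", "C6H12O6")
  roster$rt_apex <- c(100, 100)
  expect_error(simulate_run(sim_config(roster)),
               class = "irbench_sim_error")
})

test_that("corruption plans are validated", {
  fx <- clean_fixture()
  expect_error(corruption_plan(split = tibble::tibble(peak_id = "x", at = 1.2)),
               class = "irbench_sim_error")
  expect_error(corruption_plan(drop = "p1",
                               split = tibble::tibble(peak_id = "p1", at = 0.5)),
               "disjoint", class = "irbench_sim_error")
  expect_error(corrupt_tables(fx$scene, corruption_plan(drop = "nonexistent")),
               class = "irbench_sim_error")
  expect_error(
    corrupt_tables(fx$scene, corruption_plan(
      blank = tibble::tibble(feature_id = "nope", file = fx$scene$run_id))),
    class = "irbench_sim_error")
})

test_that("an empty plan leaves the tables untouched and all metrics perfect", {
  fx <- clean_fixture()
  ct <- corrupt_tables(fx$scene, corruption_plan())
  cols <- c("file", "mz", "rt", "rt_min", "rt_max", "area", "height", "peak_id")
  expect_equal(dplyr::arrange(tibble::as_tibble(ct$unaligned[cols]), mz),
               dplyr::arrange(tibble::as_tibble(fx$scene$unaligned[cols]), mz),
               ignore_attr = TRUE)
  ex <- expected_metrics(fx$scene, corruption_plan())
  expect_equal(ex$found_pre, 100)
  expect_equal(ex$split_pre, 0)
  expect_equal(ex$ir_accuracy_pre, 100)
})

test_that("assessment metrics close the ledger exactly for a by-list plan", {
  fx <- clean_fixture()
  tr <- fx$scene$truth
  lait_ids <- tr$peak_id[tr$ir < 1]
  plan <- corruption_plan(
    drop = tr$peak_id[c(2, 6)],
    split = tibble::tibble(peak_id = tr$peak_id[9], at = 0.5),
    misintegrate = tibble::tibble(peak_id = setdiff(lait_ids,
                                                    tr$peak_id[c(2, 6, 9)])[1],
                                  factor = 2))
  ct <- corrupt_tables(fx$scene, plan)
  ex <- expected_metrics(fx$scene, plan)
  mp <- match_unaligned(fx$bm, ct$unaligned)
  expect_equal(found_proportion(mp), ex$found_pre)
  expect_equal(split_proportion(mp), ex$split_pre)
  expect_equal(as.numeric(ir_accuracy(mp)), ex$ir_accuracy_pre)
  ma <- match_aligned(fx$bm, ct$aligned)
  expect_equal(found_proportion(ma), ex$found_post)
})
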