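test_that("IR bias is the relative deviation in percent", {
  expect_equal(ir_bias(0.010, 0.010), 0)
  expect_equal(ir_bias(0.012, 0.010), 20)
  expect_equal(ir_bias(0.008, 0.010), 20)
  expect_error(ir_bias(0.01, 0), class = "irbench_bm_error")
})

test_that("acceptance filters are strict and report the first failure", {
  th <- bm_thresholds()
  expect_true(validate_isotopologue(0.99, 5, 5, th)$accepted)
  # boundary values are rejections, not acceptances
  expect_equal(validate_isotopologue(0.85, 5, 5, th)$reason, "pcc")
  expect_equal(validate_isotopologue(0.99, 35, 5, th)$reason, "bias_area")
  expect_equal(validate_isotopologue(0.99, 5, 30, th)$reason, "bias_height")
  expect_equal(validate_isotopologue(0.99, 5, 34.99, th)$reason, "bias_height")
  expect_equal(validate_isotopologue(0.99, 34.5, 4, th)$reason, "bias_diff")
  # first failed filter wins when several fail
  expect_equal(validate_isotopologue(0.2, 99, 99, th)$reason, "pcc")
  expect_equal(validate_isotopologue(NA, 1, 1, th)$reason, "undefined PCC")
})

test_that("a clean scene is accepted in full", {
  fx <- clean_fixture()
  bm <- fx$bm
  expect_equal(nrow(bm), nrow(fx$scene$truth))
  expect_true(all(bm$status != "rejected"))
  expect_equal(sum(bm$status == "accepted_mait"),
               nrow(fx$scene$config$molecules))
  # one MAIT per group, no duplicate keys
  per_group <- dplyr::count(tibble::as_tibble(bm),
                            molecule_id, file, adduct,
                            wt = (status == "accepted_mait"))
  expect_true(all(per_group$n == 1))
})

test_that("observed IRs of a noise-free scene match the planted ratios", {
  fx <- clean_fixture()
  lait <- fx$bm[fx$bm$status == "accepted_lait", ]
  expect_true(all(lait$bias_area < 0.5))
  expect_true(all(lait$bias_height < 2))
  expect_true(all(lait$pcc > 0.999))
})

test_that("the traditional comparator is the MAIT-[M+H]+ subset", {
  fx <- clean_fixture()
  runs <- stats::setNames(list(fx$run), fx$scene$run_id)
  bm_mh <- build_benchmark(runs, sim_targets(fx$scene), mode = "mait_only_mh")
  expect_equal(nrow(bm_mh), nrow(fx$scene$config$molecules))
  expect_true(all(bm_mh$isotopologue == "M+0"))
  key <- function(b) paste(b$molecule_id, b$file, b$adduct, b$isotopologue)
  expect_true(all(key(bm_mh) %in% key(fx$bm)))
})

test_that("tightening any threshold never admits more peaks", {
  fx <- two_iso_fixture()
  n_acc <- function(th) sum(revalidate_benchmark(fx$bm, th)$status != "rejected")
  base <- n_acc(bm_thresholds())
  for (th in list(bm_thresholds(pcc = 0.95), bm_thresholds(bias_area = 10),
                  bm_thresholds(bias_height = 5), bm_thresholds(bias_diff = 1),
                  bm_thresholds(0.99, 5, 3, 1))) {
    expect_lte(n_acc(th), base)
  }
  # and loosening everything fully re-admits every measurable candidate
  loose <- n_acc(bm_thresholds(pcc = 0, bias_area = Inf, bias_height = Inf,
                               bias_diff = Inf))
  expect_gte(loose, base)
})

test_that("groups with an unmeasurable MAIT are dropped with a reason", {
  fx <- clean_fixture()
  tg <- sim_targets(fx$scene)
  # boundaries placed where nothing elutes (the gap after the first peak)
  tg$rt_start[1] <- tg$rt_end[1] + 5
  tg$rt_end[1] <- tg$rt_start[1] + 15
  runs <- stats::setNames(list(fx$run), fx$scene$run_id)
  bm <- build_benchmark(runs, tg)
  expect_false(tg$molecule_id[1] %in% bm$molecule_id)
  dropped <- attr(bm, "dropped")
  expect_equal(dropped$molecule_id, tg$molecule_id[1])
  expect_match(dropped$reason, "MAIT")
})

test_that("benchmark summaries report counts and dynamic range", {
  fx <- clean_fixture()
  s <- benchmark_summary(fx$bm)
  expect_equal(sum(s$counts$n), nrow(fx$bm))
  dr <- s$dynamic_range
  expect_gte(dr$log10_span[dr$set == "with_laits"],
             dr$log10_span[dr$set == "mait_only"])
  expect_error(benchmark_summary(fx$bm[0, ]), class = "irbench_bm_error")
})

test_that("benchmark export writes the table and a metadata sidecar", {
  fx <- clean_fixture()
  path <- tempfile(fileext = ".csv")
  write_benchmark(fx$bm, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(fx$bm))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$thresholds$pcc, 0.85)
  expect_equal(meta$mode, "full")
  expect_true(nzchar(meta$provenance$targets_hash))
})

test_that("target lists round-trip with multi-adduct rows expanded", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("molecule_id,formula,adduct,file,rt_start,rt_end",
               "glc,C6H12O6,[M+H]+;[M+Na]+,run1,100,130",
               "ala,C3H7NO2,[M+H]+,run1,210,240"), p)
  tg <- read_targets(p)
  expect_equal(nrow(tg), 3L)
  expect_setequal(tg$adduct[tg$molecule_id == "glc"], c("[M+H]+", "[M+Na]+"))
  writeLines(c("molecule_id,formula,file,rt_start,rt_end",
               "glc,C6H12O6,run1,100,130"), p)
  expect_error(read_targets(p), "adduct", class = "irbench_io_error")
})
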