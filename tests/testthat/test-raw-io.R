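test_that("simulated mzML files round-trip through the reader", {
  fx <- clean_fixture()
  run <- fx$run
  n_scans <- length(seq(fx$scene$config$rt_span[1], fx$scene$config$rt_span[2],
                        by = fx$scene$config$scan_interval))
  expect_s3_class(run, "centroid_run")
  expect_length(run$rt, n_scans)
  expect_true(all(diff(run$rt) > 0))
  expect_true(all(vapply(run$spectra,
                         function(p) !is.unsorted(p[, 1]), logical(1))))
})

test_that("profile-mode and MS1-free files are refused", {
  hdr <- data.frame(
    seqNum = 1:3, acquisitionNum = 1:3, msLevel = 1L, polarity = 1L,
    peaksCount = 1L, totIonCurrent = 1, retentionTime = 1:3,
    basePeakMZ = 100, basePeakIntensity = 1, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 100, highMZ = 100,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", 1:3), centroided = FALSE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  pks <- lapply(1:3, function(i) cbind(mz = 100, intensity = 10))
  prof <- tempfile(fileext = ".mzML")
  mzR::writeMSData(pks, file = prof, header = hdr, outformat = "mzml")
  expect_error(read_run(prof), "centroid", class = "irbench_io_error")

  hdr$centroided <- TRUE
  hdr$msLevel <- 2L
  ms2 <- tempfile(fileext = ".mzML")
  mzR::writeMSData(pks, file = ms2, header = hdr, outformat = "mzml")
  expect_error(read_run(ms2), "MS1", class = "irbench_io_error")

  expect_error(read_run(tempfile(fileext = ".mzML")),
               class = "irbench_io_error")
})

test_that("EIC extraction recovers planted traces and zero-fills gaps", {
  fx <- clean_fixture()
  tr <- fx$scene$truth[1, ]
  eic <- extract_eic(fx$run, tr$mz, tol_ppm = 5,
                     rt_window = c(tr$rt_min, tr$rt_max))
  expect_equal(eic$rt[which.max(eic$intensity)], tr$rt_apex,
               tolerance = fx$scene$config$scan_interval)
  expect_equal(nrow(eic), sum(fx$run$rt >= tr$rt_min & fx$run$rt <= tr$rt_max))
  # a window with no centroids is all zero, one point per spectrum
  far <- extract_eic(fx$run, 999.9, tol_ppm = 5,
                     rt_window = c(tr$rt_min, tr$rt_max))
  expect_true(all(far$intensity == 0))
  expect_true(all(is.na(far$mz)))
  expect_error(extract_eic(fx$run, 200, rt_window = c(10, 10)),
               class = "irbench_io_error")
})

test_that("in-tolerance centroids of one spectrum are summed", {
  run <- structure(list(
    run_id = "toy", rt = c(1, 2),
    spectra = list(cbind(mz = c(200.0000, 200.0005), intensity = c(10, 5)),
                   cbind(mz = 200.0000, intensity = 7)),
    flat = tibble::tibble(scan = c(1L, 1L, 2L),
                          rt = c(1, 1, 2),
                          mz = c(200.0000, 200.0005, 200.0000),
                          intensity = c(10, 5, 7))),
    class = "centroid_run")
  eic <- extract_eic(run, 200.0, tol_ppm = 5, rt_window = c(0.5, 2.5))
  expect_equal(eic$intensity, c(15, 7))
  # matched m/z is the intensity-weighted mean
  expect_equal(eic$mz[1], (200.0000 * 10 + 200.0005 * 5) / 15)
})

test_that("peak metrics recover closed-form shape properties", {
  # dense Gaussian: FWHM converges to 2.3548 sigma
  sigma <- 2
  rt <- seq(0, 40, by = 0.1)
  g <- make_eic(rt, 1000 * exp(-(rt - 20)^2 / (2 * sigma^2)))
  m <- measure_peak(g, c(10, 30))
  expect_equal(m$fwhm, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.02)
  expect_equal(m$rt_apex, 20)
  expect_equal(m$height, 1000, tolerance = 1e-6)
  # symmetric triangle: trapezoid integrates to h*b/2
  rt2 <- seq(0, 10, by = 0.5)
  tri <- make_eic(rt2, pmax(0, 100 * (1 - abs(rt2 - 5) / 3)))
  m2 <- measure_peak(tri, c(0, 10))
  expect_equal(m2$area, 100 * 6 / 2, tolerance = 1e-9)
})

test_that("the zigzag index responds to alternating noise", {
  rt <- seq(0, 40, by = 0.5)
  smooth <- 1000 * exp(-(rt - 20)^2 / 8)
  noisy <- smooth * (1 + 0.2 * rep_len(c(1, -1), length(rt)))
  mz_s <- measure_peak(make_eic(rt, smooth), c(10, 30))
  mz_n <- measure_peak(make_eic(rt, noisy), c(10, 30))
  expect_gt(mz_n$zigzag, mz_s$zigzag)
  expect_gt(mz_n$zigzag, 5 * mz_s$zigzag)
})

test_that("intensity scaling and zero padding behave as invariants", {
  rt <- seq(0, 40, by = 0.5)
  y <- 1000 * exp(-(rt - 20)^2 / 8)
  base <- measure_peak(make_eic(rt, y), c(10, 30))
  scaled <- measure_peak(make_eic(rt, 7 * y), c(10, 30))
  expect_equal(scaled$area, 7 * base$area)
  expect_equal(scaled$height, 7 * base$height)
  expect_equal(scaled$fwhm, base$fwhm)
  expect_equal(scaled$zigzag, base$zigzag)
  expect_equal(scaled$sharpness, base$sharpness)
  # points outside the bounds never matter
  rt_pad <- c(seq(-5, -1), rt, seq(41, 45))
  y_pad <- c(rep(0, 5), y, rep(0, 5))
  padded <- measure_peak(make_eic(rt_pad, y_pad), c(10, 30))
  expect_equal(padded, base)
})

test_that("unmeasurable candidates yield NULL, not an error", {
  expect_null(measure_peak(make_eic(1:10, rep(0, 10)), c(1, 10)))
  expect_null(measure_peak(make_eic(1:10, c(1, 2, 1, rep(0, 7))), c(1, 10)))
})
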