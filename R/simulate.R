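#' Draw a molecule roster for simulation
#'
#' Samples a roster of known molecules with apex retention times spread over
#' `rt_range` and peak heights drawn log-uniformly over `height_range`. The
#' roster's first and last molecules are pinned to the extremes of the
#' height range so the configured dynamic range is realized exactly. The
#' built-in formula pool covers common polar metabolites (sugars, amino
#' acids, organic acids, nucleotides).
#'
#' @param n Number of molecules (default 20).
#' @param formulas Character vector to sample from (with replacement when
#'   `n` exceeds the pool).
#' @param adduct Adduct applied to every molecule (default `"[M+H]+"`).
#' @param rt_range Apex retention-time range in seconds.
#' @param height_range MAIT apex height range in counts; the default spans
#'   just over four orders of magnitude, typical of what a validated
#'   benchmark covers.
#' @param seed Integer seed.
#' @return A tibble with `molecule_id`, `formula`, `adduct`, `rt_apex`,
#'   `height`.
#' @export
sim_molecules <- function(n = 20,
                          formulas = c("C6H12O6", "C5H10O5", "C12H22O11",
                                       "C3H7NO2", "C5H9NO4", "C6H14N4O2",
                                       "C9H11NO2", "C4H6O4", "C6H8O7",
                                       "C5H5N5", "C10H13N5O4", "C4H6O5",
                                       "C3H4O3", "C5H11NO2", "C6H13NO2",
                                       "C10H16N2O3S", "C7H6O2", "C8H10N4O2",
                                       "C11H12N2O2", "C6H6O6"),
                          adduct = "[M+H]+", rt_range = c(60, 540),
                          height_range = c(1e3, 2e7), seed = 1) {
  withr::with_seed(seed, {
    fs <- if (n <= length(formulas)) sample(formulas, n)
          else sample(formulas, n, replace = TRUE)
    lh <- runif(n, log10(height_range[1]), log10(height_range[2]))
    lh[1] <- log10(height_range[1])
    lh[n] <- log10(height_range[2])
    rts <- seq(rt_range[1], rt_range[2], length.out = n) +
      runif(n, -2, 2)
    tibble::tibble(
      molecule_id = sprintf("M%03d", seq_len(n)),
      formula = fs, adduct = adduct,
      rt_apex = rts, height = 10^lh
    )
  })
}

#' Simulation configuration
#'
#' Bundles everything [simulate_run()] needs: the molecule roster, the
#' chromatographic peak shape, the scan grid, the noise model and the
#' detector model. Defaults emulate a well-behaved high-resolution MS1 run:
#' Gaussian peaks of 6 s FWHM sampled every 0.5 s, no noise, no saturation.
#'
#' @param molecules Roster tibble (see [sim_molecules()]).
#' @param shape `"gaussian"` or `"emg"` (exponentially modified Gaussian,
#'   for tailing peaks).
#' @param fwhm Peak full width at half maximum in seconds; must exceed two
#'   scan intervals.
#' @param tau EMG tailing constant in seconds (ignored for Gaussian).
#' @param scan_interval Time between MS1 spectra in seconds.
#' @param rt_span `c(start, end)` of the run in seconds; `NULL` covers all
#'   apexes with margin.
#' @param mz_jitter_ppm Per-centroid m/z jitter standard deviation in ppm.
#' @param noise_floor Additive noise scale in counts (half-normal draw added
#'   to every emitted centroid).
#' @param noise_cv Multiplicative noise coefficient of variation (fraction).
#' @param saturation Detector ceiling in counts; intensities are clipped
#'   there and affected isotopologues flagged.
#' @param abundance_floor Minimum predicted ratio for an isotopologue to be
#'   planted.
#' @param run_id Identifier written into the ground truth tables.
#' @param seed Integer seed controlling all randomness of the run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(molecules = sim_molecules(),
                       shape = c("gaussian", "emg"),
                       fwhm = 6, tau = 2, scan_interval = 0.5,
                       rt_span = NULL, mz_jitter_ppm = 0,
                       noise_floor = 0, noise_cv = 0, saturation = Inf,
                       abundance_floor = 0.01, run_id = "sim_run",
                       seed = 1) {
  shape <- match.arg(shape)
  stopifnot(scan_interval > 0, fwhm > 2 * scan_interval,
            all(molecules$height > 0), nrow(molecules) > 0)
  if (is.null(rt_span)) {
    rt_span <- c(max(0, min(molecules$rt_apex) - 6 * fwhm),
                 max(molecules$rt_apex) + 6 * fwhm + (shape == "emg") * 6 * tau)
  }
  structure(list(molecules = molecules, shape = shape, fwhm = fwhm, tau = tau,
                 scan_interval = scan_interval, rt_span = rt_span,
                 mz_jitter_ppm = mz_jitter_ppm, noise_floor = noise_floor,
                 noise_cv = noise_cv, saturation = saturation,
                 abundance_floor = abundance_floor, run_id = run_id,
                 seed = seed),
            class = "sim_config")
}

# peak shape normalized to unit apex; erfc via pnorm
.shape_values <- function(t, apex, sigma, shape, tau) {
  if (shape == "gaussian") {
    exp(-(t - apex)^2 / (2 * sigma^2))
  } else {
    z <- sigma / tau - (t - apex) / sigma
    v <- (sigma / tau) * sqrt(pi / 2) *
      exp(0.5 * (sigma / tau)^2 - (t - apex) / tau) *
      2 * stats::pnorm(-z / sqrt(2) * sqrt(2))
    v[!is.finite(v)] <- 0
    v / max(v)
  }
}

#' Simulate a centroided mzML run with exact ground truth
#'
#' Writes a centroided MS1 mzML file in which every molecule of the roster
#' contributes one co-eluting trace per predicted isotopologue above the
#' abundance floor, with the configured peak shape, m/z jitter, additive and
#' multiplicative noise and detector saturation. Returns the file path
#' together with a ground-truth ledger (one row per planted peak, with its
#' true bounds, apex, height, trapezoidal area and isotopologue ratio) and
#' the derived true unaligned peak list and aligned feature table, ready to
#' be corrupted by [corrupt_tables()] or matched directly.
#'
#' All randomness is governed by `cfg$seed`: the same configuration always
#' produces identical spectra and ground truth. Two roster entries landing
#' on the same m/z and apex are rejected.
#'
#' @param cfg A [sim_config()].
#' @param path Output mzML path.
#' @return A list of class `sim_scene` with `path`, `run_id`, `config`,
#'   `truth` (ground-truth tibble incl. `saturated` flags), `unaligned`
#'   (`nfd_peaks`) and `aligned` (`nfd_features`).
#' @export
simulate_run <- function(cfg, path = tempfile(fileext = ".mzML")) {
  stopifnot(inherits(cfg, "sim_config"))
  sigma <- cfg$fwhm / (2 * sqrt(2 * log(2)))
  scans <- seq(cfg$rt_span[1], cfg$rt_span[2], by = cfg$scan_interval)

  # plant every isotopologue above the floor for every molecule
  plant <- purrr::pmap_dfr(cfg$molecules, function(molecule_id, formula,
                                                   adduct, rt_apex, height) {
    pat <- predict_pattern(formula, adduct = adduct,
                           abundance_floor = cfg$abundance_floor)
    tibble::tibble(molecule_id = molecule_id, adduct = adduct,
                   isotopologue = pat$label, mz = pat$mz, ratio = pat$ratio,
                   rt_apex = rt_apex, height = height * pat$ratio)
  })
  if (anyDuplicated(paste(round(plant$mz, 6), round(plant$rt_apex, 3)))) {
    rlang::abort("Two planted traces share identical (m/z, apex rt).",
                 class = "irbench_sim_error")
  }

  tail_ext <- if (cfg$shape == "emg") 4 * cfg$tau else 0
  withr::with_seed(cfg$seed, {
    pieces <- vector("list", nrow(plant))
    truth <- vector("list", nrow(plant))
    for (i in seq_len(nrow(plant))) {
      p <- plant[i, ]
      lo <- p$rt_apex - 4 * sigma
      hi <- p$rt_apex + 4 * sigma + tail_ext
      t <- scans[scans >= lo & scans <= hi]
      s <- .shape_values(t, p$rt_apex, sigma, cfg$shape, cfg$tau)
      keep <- s >= 1e-5
      t <- t[keep]; s <- s[keep]
      base <- p$height * s
      saturated <- any(base > cfg$saturation)
      clean <- pmin(base, cfg$saturation)
      int <- clean
      if (cfg$noise_cv > 0) int <- int * (1 + rnorm(length(int), 0, cfg$noise_cv))
      if (cfg$noise_floor > 0) int <- int + abs(rnorm(length(int), 0, cfg$noise_floor))
      int <- pmin(pmax(int, 0), cfg$saturation)
      mzv <- if (cfg$mz_jitter_ppm > 0) {
        p$mz * (1 + rnorm(length(t), 0, cfg$mz_jitter_ppm) / 1e6)
      } else rep(p$mz, length(t))
      pieces[[i]] <- tibble::tibble(rt = t, mz = mzv, intensity = int)
      area <- sum(diff(t) * (utils::head(clean, -1) + utils::tail(clean, -1)) / 2)
      truth[[i]] <- tibble::tibble(
        molecule_id = p$molecule_id, adduct = p$adduct,
        isotopologue = p$isotopologue, file = cfg$run_id,
        mz = p$mz, rt_apex = p$rt_apex, rt_min = lo, rt_max = hi,
        height = min(p$height, cfg$saturation), area = area,
        ir = p$ratio, saturated = saturated,
        peak_id = paste(p$molecule_id, p$adduct, p$isotopologue, sep = "|"))
    }
  })
  truth <- dplyr::bind_rows(truth)
  cents <- dplyr::bind_rows(pieces)
  cents <- cents[cents$intensity > 0, ]

  spectra <- vector("list", length(scans))
  idx <- split(seq_len(nrow(cents)), factor(match(cents$rt, scans),
                                            levels = seq_along(scans)))
  for (k in seq_along(scans)) {
    rows <- idx[[k]]
    if (length(rows)) {
      m <- cbind(mz = cents$mz[rows], intensity = cents$intensity[rows])
      spectra[[k]] <- m[order(m[, 1]), , drop = FALSE]
    } else {
      spectra[[k]] <- matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("mz", "intensity")))
    }
  }
  .write_mzml(spectra, scans, path)

  unaligned <- structure(
    tibble::tibble(file = truth$file, mz = truth$mz, rt = truth$rt_apex,
                   rt_min = truth$rt_min, rt_max = truth$rt_max,
                   area = truth$area, height = truth$height,
                   source_row = seq_len(nrow(truth)),
                   peak_id = truth$peak_id),
    class = c("nfd_peaks", class(tibble::tibble())))
  aligned <- structure(
    tibble::tibble(feature_id = truth$peak_id, mz = truth$mz,
                   rt = truth$rt_apex, file = truth$file,
                   abundance = truth$area, gap_filled = FALSE,
                   label = "high_quality"),
    class = c("nfd_features", class(tibble::tibble())))

  structure(list(path = path, run_id = cfg$run_id, config = cfg,
                 truth = truth, unaligned = unaligned, aligned = aligned),
            class = "sim_scene")
}

# minimal centroided MS1 mzML writer on top of mzR
.write_mzml <- function(spectra, rts, path) {
  n <- length(spectra)
  npk <- vapply(spectra, nrow, integer(1))
  tic <- vapply(spectra, function(p) sum(p[, 2]), numeric(1))
  bpi <- vapply(spectra, function(p) if (nrow(p)) max(p[, 2]) else 0, numeric(1))
  bpm <- vapply(spectra, function(p) if (nrow(p)) p[which.max(p[, 2]), 1] else 0,
                numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk, totIonCurrent = tic,
    retentionTime = rts, basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(p) if (nrow(p)) min(p[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(spectra, function(p) if (nrow(p)) max(p[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(spectra, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Build the target list implied by a simulated scene
#'
#' @param scene A `sim_scene`.
#' @return A target tibble usable with [build_benchmark()], one row per
#'   molecule x adduct with the true retention-time boundaries of the MAIT.
#' @export
sim_targets <- function(scene) {
  cfg <- scene$config
  mait <- scene$truth[scene$truth$ir == 1, ]
  tibble::tibble(
    molecule_id = mait$molecule_id,
    formula = cfg$molecules$formula[match(mait$molecule_id,
                                          cfg$molecules$molecule_id)],
    adduct = mait$adduct, file = mait$file,
    rt_start = mait$rt_min, rt_end = mait$rt_max)
}

#' Declare a controlled corruption plan
#'
#' Corruptions are applied by explicit list, never by rate, so the plan
#' itself is the ledger of expected metric values. `drop`, `split` and
#' `misintegrate` must be disjoint.
#'
#' @param drop Character vector of peak ids to delete from the unaligned
#'   table.
#' @param split Tibble `peak_id`, `at` (cut position as a fraction of peak
#'   duration, in (0, 1)): the peak is replaced by two adjacent halves.
#' @param misintegrate Tibble `peak_id`, `factor`: area (and aligned
#'   abundance) multiplied by `factor`.
#' @param blank Tibble `feature_id`, `file`: aligned abundance set missing.
#' @param gap_fill Tibble `feature_id`, `file`: aligned entry flagged as
#'   gap-filled.
#' @param relabel Tibble `feature_id`, `file`, `label`: quality label
#'   replaced.
#' @param rt_shift Tibble `file`, `shift`: seconds added to every unaligned
#'   retention-time column of that file.
#' @return A list of class `corruption_plan`.
#' @export
corruption_plan <- function(drop = character(), split = NULL,
                            misintegrate = NULL, blank = NULL,
                            gap_fill = NULL, relabel = NULL,
                            rt_shift = NULL) {
  if (!is.null(split) && (any(split$at <= 0) || any(split$at >= 1))) {
    rlang::abort("Split fractions must lie in (0, 1).",
                 class = "irbench_sim_error")
  }
  ids <- c(drop, if (!is.null(split)) split$peak_id,
           if (!is.null(misintegrate)) misintegrate$peak_id)
  if (anyDuplicated(ids)) {
    rlang::abort("drop / split / misintegrate lists must be disjoint.",
                 class = "irbench_sim_error")
  }
  structure(list(drop = drop, split = split, misintegrate = misintegrate,
                 blank = blank, gap_fill = gap_fill, relabel = relabel,
                 rt_shift = rt_shift),
            class = "corruption_plan")
}

#' Apply a corruption plan to ground-truth tables
#'
#' Deterministically derives corrupted unaligned and aligned nontargeted
#' tables from a simulated scene, per the plan. Referencing a peak or
#' feature absent from the ground truth is an error.
#'
#' @param scene A `sim_scene`.
#' @param plan A [corruption_plan()].
#' @return A list with `unaligned` (`nfd_peaks`) and `aligned`
#'   (`nfd_features`).
#' @export
corrupt_tables <- function(scene, plan) {
  stopifnot(inherits(scene, "sim_scene"), inherits(plan, "corruption_plan"))
  un <- scene$unaligned
  al <- scene$aligned
  refs <- c(plan$drop,
            if (!is.null(plan$split)) plan$split$peak_id,
            if (!is.null(plan$misintegrate)) plan$misintegrate$peak_id)
  bad <- setdiff(refs, un$peak_id)
  if (length(bad)) {
    rlang::abort(sprintf("Plan references unknown peak id(s): %s",
                         paste(utils::head(bad, 5), collapse = ", ")),
                 class = "irbench_sim_error")
  }
  for (nm in c("blank", "gap_fill")) {
    p <- plan[[nm]]
    if (!is.null(p)) {
      bad <- setdiff(p$feature_id, al$feature_id)
      if (length(bad)) {
        rlang::abort(sprintf("Plan references unknown feature id(s): %s",
                             paste(utils::head(bad, 5), collapse = ", ")),
                     class = "irbench_sim_error")
      }
    }
  }

  un <- un[!un$peak_id %in% plan$drop, ]
  if (!is.null(plan$misintegrate)) {
    i <- match(plan$misintegrate$peak_id, un$peak_id)
    un$area[i] <- un$area[i] * plan$misintegrate$factor
    j <- match(plan$misintegrate$peak_id, al$feature_id)
    al$abundance[j] <- al$abundance[j] * plan$misintegrate$factor
  }
  if (!is.null(plan$split)) {
    for (k in seq_len(nrow(plan$split))) {
      i <- which(un$peak_id == plan$split$peak_id[k])
      row <- un[i, ]
      cut <- row$rt_min + plan$split$at[k] * (row$rt_max - row$rt_min)
      a <- row; b <- row
      a$rt_max <- cut; a$rt <- (row$rt_min + cut) / 2
      a$area <- row$area * plan$split$at[k]
      a$peak_id <- paste0(row$peak_id, "#a")
      b$rt_min <- cut; b$rt <- (cut + row$rt_max) / 2
      b$area <- row$area * (1 - plan$split$at[k])
      b$peak_id <- paste0(row$peak_id, "#b")
      un <- dplyr::bind_rows(un[-i, ], a, b)
    }
  }
  if (!is.null(plan$rt_shift)) {
    for (k in seq_len(nrow(plan$rt_shift))) {
      i <- un$file == plan$rt_shift$file[k]
      s <- plan$rt_shift$shift[k]
      un$rt[i] <- un$rt[i] + s
      un$rt_min[i] <- un$rt_min[i] + s
      un$rt_max[i] <- un$rt_max[i] + s
    }
  }
  un <- un[order(un$file, un$mz, un$rt), ]
  un$source_row <- seq_len(nrow(un))

  if (!is.null(plan$blank)) {
    i <- match(paste(plan$blank$feature_id, plan$blank$file),
               paste(al$feature_id, al$file))
    al$abundance[i] <- NA_real_
  }
  if (!is.null(plan$gap_fill)) {
    i <- match(paste(plan$gap_fill$feature_id, plan$gap_fill$file),
               paste(al$feature_id, al$file))
    al$gap_filled[i] <- TRUE
  }
  if (!is.null(plan$relabel)) {
    i <- match(paste(plan$relabel$feature_id, plan$relabel$file),
               paste(al$feature_id, al$file))
    al$label[i] <- plan$relabel$label
  }
  list(unaligned = un, aligned = al)
}

#' Expected metric values implied by a corruption plan
#'
#' Computes, from the plan alone, the exact values every assessment metric
#' must take on the corrupted tables of a clean scene (all planted peaks
#' accepted into the benchmark): the ledger-closure property.
#'
#' @param scene A `sim_scene`.
#' @param plan A [corruption_plan()].
#' @param margin IR recovery margin used in the assessment (default 20).
#' @return A list with `found_pre`, `split_pre`, `found_post`,
#'   `ir_accuracy_pre` expected percentages.
#' @export
expected_metrics <- function(scene, plan, margin = 20) {
  tr <- scene$truth
  N <- nrow(tr)
  n_drop <- length(plan$drop)
  n_split <- if (is.null(plan$split)) 0L else nrow(plan$split)
  n_blank <- if (is.null(plan$blank)) 0L else nrow(plan$blank)

  # effective matched-area factor per surviving peak: misintegration scales
  # by its factor; a split peak's best match is its larger half
  fac <- stats::setNames(rep(1, N), tr$peak_id)
  if (!is.null(plan$misintegrate)) {
    fac[plan$misintegrate$peak_id] <- plan$misintegrate$factor
  }
  if (!is.null(plan$split)) {
    fac[plan$split$peak_id] <- pmax(plan$split$at, 1 - plan$split$at)
  }

  # pre-alignment IR accuracy: assessable LAITs are those whose own peak and
  # whose MAIT peak both survive (dropped peaks are unmatched); recovery
  # fails iff the corrupted NFD bias reaches the benchmark bias + margin
  lait <- tr[tr$ir < 1, ]
  mait_id <- paste(lait$molecule_id, lait$adduct, "M+0", sep = "|")
  present <- function(id) !id %in% plan$drop
  assessable <- present(lait$peak_id) & present(mait_id)
  fails <- 0L
  for (i in which(assessable)) {
    a_m <- tr$area[match(mait_id[i], tr$peak_id)]
    bias0 <- ir_bias(lait$area[i] / a_m, lait$ir[i])
    bias1 <- ir_bias(fac[[lait$peak_id[i]]] * lait$area[i] /
                       (fac[[mait_id[i]]] * a_m), lait$ir[i])
    if (!(bias1 < bias0 + margin)) fails <- fails + 1L
  }
  list(
    found_pre = 100 * (N - n_drop) / N,
    split_pre = 100 * n_split / N,
    found_post = 100 * (N - n_blank) / N,
    ir_accuracy_pre = if (sum(assessable) == 0) NA_real_
                      else 100 * (sum(assessable) - fails) / sum(assessable)
  )
}

#' Write a scene's tables as generic_csv files
#'
#' @param scene A `sim_scene` (or the list returned by [corrupt_tables()]).
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths.
#' @export
write_sim_tables <- function(scene, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  up <- file.path(dir, paste0(prefix, "_unaligned.csv"))
  utils::write.csv(as.data.frame(scene$unaligned), up, row.names = FALSE)
  al <- scene$aligned
  wide <- tidyr::pivot_wider(
    al[, c("feature_id", "mz", "rt", "file", "abundance")],
    names_from = "file", values_from = "abundance")
  ap <- file.path(dir, paste0(prefix, "_aligned.csv"))
  utils::write.csv(as.data.frame(wide), ap, row.names = FALSE)
  c(unaligned = up, aligned = ap)
}
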