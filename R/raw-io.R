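#' Read a centroided mzML run
#'
#' Loads all MS1 centroided spectra from an mzML file via `mzR`. Retention
#' times are in seconds regardless of how the source file recorded them
#' (the mzML reader normalizes units). Profile-mode MS1 spectra are refused:
#' the package operates on centroided data only.
#'
#' @param path Path to an mzML file.
#' @param run_id Identifier for the run; defaults to the file name without
#'   extension.
#' @return A `centroid_run` object: a list with `run_id`, `rt` (seconds,
#'   strictly increasing), `spectra` (list of two-column matrices `mz`,
#'   `intensity`, m/z sorted) and `flat` (a tibble of all centroids with
#'   columns `scan`, `rt`, `mz`, `intensity`, used for fast EIC extraction).
#' @export
read_run <- function(path, run_id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("mzML file not found: %s", path),
                 class = "irbench_io_error")
  }
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) {
                   rlang::abort(sprintf("Cannot parse mzML file '%s': %s",
                                        path, conditionMessage(e)),
                                class = "irbench_io_error")
                 })
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) {
    rlang::abort("No MS1 spectra in file.", class = "irbench_io_error")
  }
  cent <- hdr$centroided[ms1]
  if (any(!is.na(cent) & !cent)) {
    rlang::abort(
      "Profile-mode MS1 spectra found; centroid the data (e.g. with msConvert) before import.",
      class = "irbench_io_error"
    )
  }
  rt <- hdr$retentionTime[ms1]
  ord <- order(rt)
  ms1 <- ms1[ord]; rt <- rt[ord]
  spectra <- lapply(ms1, function(i) {
    p <- mzR::peaks(ms, i)
    p <- p[p[, 2] > 0, , drop = FALSE]
    p[order(p[, 1]), , drop = FALSE]
  })
  npk <- vapply(spectra, nrow, integer(1))
  flat <- tibble::tibble(
    scan = rep.int(seq_along(spectra), npk),
    rt = rep.int(rt, npk),
    mz = unlist(lapply(spectra, function(p) p[, 1]), use.names = FALSE),
    intensity = unlist(lapply(spectra, function(p) p[, 2]), use.names = FALSE)
  )
  structure(
    list(
      run_id = run_id %||% sub("\\.[^.]*$", "", basename(path)),
      rt = rt,
      spectra = spectra,
      flat = flat
    ),
    class = "centroid_run"
  )
}

#' @export
print.centroid_run <- function(x, ...) {
  cat(sprintf("<centroid_run> %s: %d MS1 spectra, rt %.1f-%.1f s, %d centroids\n",
              x$run_id, length(x$rt), min(x$rt), max(x$rt), nrow(x$flat)))
  invisible(x)
}

#' Extract an ion chromatogram
#'
#' For every spectrum in the retention-time window, sums the intensities of
#' all centroids within `tol_ppm` of the target m/z. Spectra with no matching
#' centroid contribute a zero-intensity point, so the EIC always has one
#' point per spectrum in the window.
#'
#' @param run A `centroid_run`.
#' @param mz Target m/z (Th).
#' @param tol_ppm m/z tolerance in ppm (default 5).
#' @param rt_window Optional `c(start, end)` in seconds; `NULL` uses the full
#'   run.
#' @return A tibble of class `eic` with columns `rt`, `intensity` and `mz`
#'   (intensity-weighted mean of matched centroids, `NA` where none matched),
#'   plus attributes `target_mz` and `tol_ppm`.
#' @export
extract_eic <- function(run, mz, tol_ppm = 5, rt_window = NULL) {
  stopifnot(inherits(run, "centroid_run"), tol_ppm > 0)
  if (is.null(rt_window)) rt_window <- range(run$rt)
  if (rt_window[2] <= rt_window[1]) {
    rlang::abort("Empty retention-time window.", class = "irbench_io_error")
  }
  scans <- which(run$rt >= rt_window[1] & run$rt <= rt_window[2])
  if (length(scans) == 0L) {
    rlang::abort("No spectra inside the retention-time window.",
                 class = "irbench_io_error")
  }
  halfw <- tol_ppm * mz / 1e6
  fl <- run$flat
  sel <- fl$scan %in% scans & fl$mz >= mz - halfw & fl$mz <= mz + halfw
  hit <- fl[sel, ]
  ints <- numeric(length(scans))
  mzs <- rep(NA_real_, length(scans))
  if (nrow(hit) > 0L) {
    idx <- match(hit$scan, scans)
    ints_sum <- rowsum(hit$intensity, idx)
    wmz <- rowsum(hit$intensity * hit$mz, idx)
    at <- as.integer(rownames(ints_sum))
    ints[at] <- ints_sum[, 1]
    mzs[at] <- wmz[, 1] / ints_sum[, 1]
  }
  out <- tibble::tibble(rt = run$rt[scans], intensity = ints, mz = mzs)
  structure(out, target_mz = mz, tol_ppm = tol_ppm,
            class = c("eic", class(out)))
}

#' Characterize a chromatographic peak in an EIC
#'
#' Computes height, trapezoidal area, full width at half maximum, zigzag
#' index, sharpness and m/z statistics for the points of an EIC within the
#' given retention-time bounds. A candidate with fewer than 4 non-zero
#' points is not a measurable peak and yields `NULL` (callers treat this as
#' an exclusion, not an error).
#'
#' The zigzag index is
#' \deqn{\sum_{i=2}^{N-1} (2 I_i - I_{i-1} - I_{i+1})^2 / (N I_{max}^2)}
#' and sharpness is the sum of relative successive increases on the rising
#' flank plus relative successive decreases on the falling flank, both
#' computed on raw (unsmoothed) positive-intensity points.
#'
#' @param eic An `eic` tibble.
#' @param bounds `c(start, end)` retention-time bounds in seconds.
#' @return A one-row tibble with columns `rt_start`, `rt_end`, `rt_apex`,
#'   `height`, `area`, `fwhm`, `zigzag`, `sharpness`, `n_points`, `mz_mean`,
#'   `mz_min`, `mz_max`, or `NULL` for an unmeasurable candidate.
#' @export
measure_peak <- function(eic, bounds) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  inb <- eic$rt >= bounds[1] & eic$rt <= bounds[2]
  rt <- eic$rt[inb]
  ii <- eic$intensity[inb]
  mzv <- eic$mz[inb]
  pos <- ii > 0
  if (sum(pos) < 4L) return(NULL)

  apex_i <- which.max(ii)
  height <- ii[apex_i]
  area <- sum(diff(rt) * (utils::head(ii, -1) + utils::tail(ii, -1)) / 2)

  half <- height / 2
  # left flank: last upward crossing of half height before the apex
  left <- rt[1]
  if (apex_i > 1L) {
    below <- which(ii[seq_len(apex_i - 1L)] <= half)
    if (length(below) > 0L) {
      j <- max(below)
      left <- rt[j] + (half - ii[j]) * (rt[j + 1L] - rt[j]) / (ii[j + 1L] - ii[j])
    }
  }
  right <- rt[length(rt)]
  if (apex_i < length(ii)) {
    below <- which(ii[seq(apex_i + 1L, length(ii))] <= half) + apex_i
    if (length(below) > 0L) {
      j <- min(below)
      right <- rt[j - 1L] + (ii[j - 1L] - half) * (rt[j] - rt[j - 1L]) / (ii[j - 1L] - ii[j])
    }
  }
  fwhm <- right - left

  n <- length(ii)
  zig <- if (n >= 3L) {
    d2 <- 2 * ii[2:(n - 1)] - ii[1:(n - 2)] - ii[3:n]
    sum(d2^2) / (n * height^2)
  } else NA_real_

  ip <- ii[pos]
  ap <- which.max(ip)
  sharp <- 0
  if (ap > 1L) {
    sharp <- sharp + sum((ip[2:ap] - ip[1:(ap - 1L)]) / ip[1:(ap - 1L)])
  }
  if (ap < length(ip)) {
    sharp <- sharp + sum((ip[ap:(length(ip) - 1L)] - ip[(ap + 1L):length(ip)]) /
                           ip[(ap + 1L):length(ip)])
  }

  mzm <- mzv[!is.na(mzv) & pos]
  tibble::tibble(
    rt_start = rt[1], rt_end = rt[length(rt)], rt_apex = rt[apex_i],
    height = height, area = area, fwhm = fwhm,
    zigzag = zig, sharpness = sharp, n_points = sum(pos),
    mz_mean = if (length(mzm)) mean(mzm) else NA_real_,
    mz_min = if (length(mzm)) min(mzm) else NA_real_,
    mz_max = if (length(mzm)) max(mzm) else NA_real_
  )
}

#' Export an EIC as delimited text
#'
#' @param eic An `eic` tibble.
#' @param path Output path (CSV with columns rt, intensity, mz).
#' @export
write_eic <- function(eic, path) {
  utils::write.csv(as.data.frame(eic), path, row.names = FALSE)
  invisible(path)
}
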