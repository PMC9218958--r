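#' Match a benchmark against an unaligned peak list
#'
#' Classifies every accepted benchmark peak as `found`, `missed` or `split`
#' against a per-file nontargeted peak list. A benchmark peak is found if at
#' least one NFD peak agrees in m/z within `mz_tol_ppm` and overlaps the
#' benchmark peak's retention-time interval by at least `min_overlap` of the
#' benchmark peak's duration. If two or more such peaks exist and at least
#' one border between adjacent matched peaks lies within the benchmark
#' peak's FWHM window around the apex, the peak is split. The best single
#' match (largest overlap, ties broken by closest m/z, then by source row)
#' supplies the matched area and height.
#'
#' One NFD peak may match several benchmark peaks (isobaric coelution);
#' such matches are flagged `ambiguous` but counted once per benchmark peak.
#'
#' @param bm A `benchmark`; only accepted rows are matched.
#' @param peaks An `nfd_peaks` tibble (see [read_unaligned()]).
#' @param mz_tol_ppm m/z tolerance in ppm (default 10).
#' @param min_overlap Minimum retention-time overlap as a fraction of the
#'   benchmark peak duration (default 0.2).
#' @return A tibble of class `match_result` (attribute `stage = "pre"`),
#'   one row per accepted benchmark peak, with `match_status`, `n_matches`,
#'   `matched_abundance` (area of the best match), `matched_height`,
#'   `matched_rows` (list of source rows), `ambiguous`, plus the benchmark
#'   keys, `status`, `predicted_ir` and `bm_bias_area` needed downstream.
#' @export
match_unaligned <- function(bm, peaks, mz_tol_ppm = 10, min_overlap = 0.2) {
  acc <- bm[bm$status != "rejected", ]
  if (nrow(acc) == 0L) {
    rlang::abort("Empty benchmark: nothing to match.",
                 class = "irbench_match_error")
  }
  n <- nrow(acc)
  mstat <- character(n); nm <- integer(n)
  m_area <- rep(NA_real_, n); m_height <- rep(NA_real_, n)
  m_rows <- vector("list", n)
  bm_mz <- ifelse(is.na(acc$mz_mean), acc$mz, acc$mz_mean)

  for (i in seq_len(n)) {
    cand <- peaks[peaks$file == acc$file[i], ]
    tol <- mz_tol_ppm * bm_mz[i] / 1e6
    cand <- cand[abs(cand$mz - bm_mz[i]) <= tol, ]
    if (nrow(cand) > 0L) {
      ov <- pmin(cand$rt_max, acc$rt_end[i]) - pmax(cand$rt_min, acc$rt_start[i])
      frac <- ov / (acc$rt_end[i] - acc$rt_start[i])
      cand <- cand[frac >= min_overlap, ]
      frac <- frac[frac >= min_overlap]
    }
    if (nrow(cand) == 0L) {
      mstat[i] <- "missed"; nm[i] <- 0L
      next
    }
    # best single match: largest overlap, then closest m/z, then source row
    ord <- order(-frac, abs(cand$mz - bm_mz[i]), cand$source_row)
    best <- cand[ord[1L], ]
    m_area[i] <- best$area
    m_height[i] <- best$height
    m_rows[[i]] <- sort(cand$source_row)
    nm[i] <- nrow(cand)
    if (nrow(cand) >= 2L) {
      cs <- cand[order(cand$rt_min, cand$rt_max), ]
      borders <- (utils::head(cs$rt_max, -1) + utils::tail(cs$rt_min, -1)) / 2
      win <- c(acc$rt_apex[i] - acc$fwhm[i] / 2, acc$rt_apex[i] + acc$fwhm[i] / 2)
      if (any(borders >= win[1] & borders <= win[2])) {
        mstat[i] <- "split"
        next
      }
    }
    mstat[i] <- "found"
  }

  all_rows <- unlist(m_rows, use.names = FALSE)
  dup <- unique(all_rows[duplicated(all_rows)])
  out <- tibble::tibble(
    molecule_id = acc$molecule_id, file = acc$file, adduct = acc$adduct,
    isotopologue = acc$isotopologue, status = acc$status,
    predicted_ir = acc$predicted_ir, bm_bias_area = acc$bias_area,
    match_status = mstat, n_matches = nm,
    matched_abundance = m_area, matched_height = m_height,
    matched_rows = m_rows,
    gap_filled = FALSE,
    ambiguous = vapply(m_rows, function(r) any(r %in% dup), logical(1))
  )
  structure(out, stage = "pre",
            mz_tol_ppm = mz_tol_ppm, min_overlap = min_overlap,
            class = c("match_result", class(out)))
}

#' Match a benchmark against an aligned feature table
#'
#' A benchmark peak is found post-alignment if a feature matches its m/z
#' within `mz_tol_ppm` and its apex retention time within `rt_tol`, and that
#' feature has a non-missing abundance in the benchmark peak's file.
#' Gap-filled abundances count as found and are flagged. The matched
#' abundance feeds the post-alignment isotopologue ratios.
#'
#' @param bm A `benchmark`.
#' @param features An `nfd_features` tibble (see [read_aligned()]).
#' @param mz_tol_ppm m/z tolerance in ppm (default 10).
#' @param rt_tol Retention-time tolerance in seconds; `NULL` (default) uses
#'   half the benchmark peak's FWHM.
#' @param sample_map Optional named character vector renaming feature file
#'   ids to benchmark file ids (`c(feature_file = bm_file)`).
#' @return A tibble of class `match_result` (attribute `stage = "post"`)
#'   with `match_status` (`found`/`missed`), `matched_abundance`,
#'   `gap_filled`, `label` and `feature_id`.
#' @export
match_aligned <- function(bm, features, mz_tol_ppm = 10, rt_tol = NULL,
                          sample_map = NULL) {
  acc <- bm[bm$status != "rejected", ]
  if (nrow(acc) == 0L) {
    rlang::abort("Empty benchmark: nothing to match.",
                 class = "irbench_match_error")
  }
  if (!is.null(sample_map)) {
    hit <- features$file %in% names(sample_map)
    features$file[hit] <- sample_map[features$file[hit]]
  }
  unmapped <- setdiff(unique(acc$file), unique(features$file))
  if (length(unmapped)) {
    rlang::abort(sprintf("No sample column mapped to file(s): %s",
                         paste(unmapped, collapse = ", ")),
                 class = "irbench_match_error")
  }
  n <- nrow(acc)
  mstat <- character(n)
  m_ab <- rep(NA_real_, n); gapf <- rep(FALSE, n)
  labl <- rep(NA_character_, n); fid <- rep(NA_character_, n)
  bm_mz <- ifelse(is.na(acc$mz_mean), acc$mz, acc$mz_mean)

  for (i in seq_len(n)) {
    rtt <- if (is.null(rt_tol)) acc$fwhm[i] / 2 else rt_tol
    tol <- mz_tol_ppm * bm_mz[i] / 1e6
    cand <- features[features$file == acc$file[i] &
                       abs(features$mz - bm_mz[i]) <= tol &
                       abs(features$rt - acc$rt_apex[i]) <= rtt, ]
    cand <- cand[!is.na(cand$abundance), ]
    if (nrow(cand) == 0L) {
      mstat[i] <- "missed"
      next
    }
    ord <- order(abs(cand$mz - bm_mz[i]), abs(cand$rt - acc$rt_apex[i]),
                 cand$feature_id)
    best <- cand[ord[1L], ]
    mstat[i] <- "found"
    m_ab[i] <- best$abundance
    gapf[i] <- isTRUE(best$gap_filled)
    labl[i] <- best$label
    fid[i] <- best$feature_id
  }

  out <- tibble::tibble(
    molecule_id = acc$molecule_id, file = acc$file, adduct = acc$adduct,
    isotopologue = acc$isotopologue, status = acc$status,
    predicted_ir = acc$predicted_ir, bm_bias_area = acc$bias_area,
    match_status = mstat, n_matches = as.integer(mstat == "found"),
    matched_abundance = m_ab, gap_filled = gapf, label = labl,
    feature_id = fid
  )
  structure(out, stage = "post", mz_tol_ppm = mz_tol_ppm, rt_tol = rt_tol,
            class = c("match_result", class(out)))
}
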