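#' Benchmark acceptance thresholds
#'
#' The four quantitative-quality filters applied to every lower-abundance
#' isotopologue (LAIT) before it enters the benchmark: Pearson correlation
#' with the MAIT trace strictly above `pcc`, isotopologue-ratio bias from
#' peak areas strictly below `bias_area` percent, ratio bias from peak
#' heights strictly below `bias_height` percent, and the absolute difference
#' between the two biases strictly below `bias_diff` percentage points.
#'
#' @param pcc Pearson correlation threshold (default 0.85).
#' @param bias_area Area-based IR bias threshold in percent (default 35).
#' @param bias_height Height-based IR bias threshold in percent (default 30).
#' @param bias_diff Height-vs-area bias difference threshold in percentage
#'   points (default 30).
#' @return A named list of thresholds.
#' @export
bm_thresholds <- function(pcc = 0.85, bias_area = 35, bias_height = 30,
                          bias_diff = 30) {
  stopifnot(pcc >= 0, pcc <= 1, bias_area >= 0, bias_height >= 0,
            bias_diff >= 0)
  list(pcc = pcc, bias_area = bias_area, bias_height = bias_height,
       bias_diff = bias_diff)
}

#' Isotopologue ratio bias
#'
#' Relative deviation, in percent, of an observed isotopologue ratio from
#' the ratio predicted from the molecular formula:
#' `100 * |observed - predicted| / predicted`.
#'
#' @param observed,predicted Ratios (vectorized). `predicted` must be > 0.
#' @return Bias in percent.
#' @export
#' @examples
#' ir_bias(0.012, 0.010) # 20
ir_bias <- function(observed, predicted) {
  if (any(predicted <= 0)) {
    rlang::abort("Predicted IR must be > 0 to compute a bias.",
                 class = "irbench_bm_error")
  }
  100 * abs(observed - predicted) / predicted
}

#' Validate a LAIT candidate against the benchmark filters
#'
#' Applies the four acceptance filters to the quantities already measured for
#' a candidate lower-abundance isotopologue. All comparisons are strict. The
#' reason records the first failed filter, in the order PCC, area bias,
#' height bias, bias difference. An undefined correlation (constant trace)
#' rejects the candidate.
#'
#' @param pcc Pearson correlation between the candidate and MAIT EICs
#'   (`NA` if undefined).
#' @param bias_area,bias_height Observed IR biases in percent.
#' @param thresholds A [bm_thresholds()] list.
#' @return A one-row tibble with `accepted` (logical) and `reason`
#'   (`NA` when accepted).
#' @export
validate_isotopologue <- function(pcc, bias_area, bias_height,
                                  thresholds = bm_thresholds()) {
  if (is.na(pcc)) {
    return(tibble::tibble(accepted = FALSE, reason = "undefined PCC"))
  }
  if (is.na(bias_area) || is.na(bias_height)) {
    return(tibble::tibble(accepted = FALSE, reason = "unmeasurable peak"))
  }
  reason <- NA_character_
  if (!(pcc > thresholds$pcc)) {
    reason <- "pcc"
  } else if (!(bias_area < thresholds$bias_area)) {
    reason <- "bias_area"
  } else if (!(bias_height < thresholds$bias_height)) {
    reason <- "bias_height"
  } else if (!(abs(bias_height - bias_area) < thresholds$bias_diff)) {
    reason <- "bias_diff"
  }
  tibble::tibble(accepted = is.na(reason), reason = reason)
}

#' Read a molecule target list
#'
#' The target list is the output of an upstream targeted evaluation: one row
#' per molecule, adduct and raw file, with the neutral molecular formula and
#' manually set retention-time boundaries in seconds. Multiple adducts may be
#' given in one row separated by semicolons.
#'
#' @param path Delimited text file with columns `molecule_id`, `formula`,
#'   `adduct`, `file`, `rt_start`, `rt_end`.
#' @param sep Field separator (default `,`).
#' @return A tibble with one row per molecule x adduct x file.
#' @export
read_targets <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("molecule_id", "formula", "adduct", "file", "rt_start", "rt_end")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    rlang::abort(sprintf("Target list is missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 class = "irbench_io_error")
  }
  out <- tibble::as_tibble(df[req]) |>
    tidyr::separate_rows("adduct", sep = ";") |>
    dplyr::mutate(adduct = trimws(.data$adduct))
  if (any(out$rt_start >= out$rt_end)) {
    rlang::abort("Every target needs rt_start < rt_end.",
                 class = "irbench_io_error")
  }
  out
}

#' Build a validated benchmark from raw runs and known molecules
#'
#' For every molecule x file x adduct, extracts the EIC of the most abundant
#' isotopologue (MAIT) inside the target's retention-time boundaries and
#' measures its peak; then extracts and measures every predictable
#' lower-abundance isotopologue (LAIT) whose predicted ratio exceeds
#' `abundance_floor`, and accepts only LAITs passing all four
#' [bm_thresholds()] filters. Groups whose MAIT peak is unmeasurable are
#' dropped entirely (recorded in the `dropped` attribute).
#'
#' `mode = "mait_only_mh"` builds the traditional comparator benchmark:
#' only the monoisotopic peak of the `[M+H]+` adduct.
#'
#' @param runs Named list of `centroid_run` objects or mzML paths; names (or
#'   run ids) must cover every file referenced in `targets`.
#' @param targets Target tibble as from [read_targets()].
#' @param mode `"full"` or `"mait_only_mh"`.
#' @param tol_ppm EIC extraction tolerance in ppm (default 5).
#' @param abundance_floor Minimum predicted ratio-to-MAIT for a LAIT to be
#'   extracted (default 0.01).
#' @param thresholds A [bm_thresholds()] list.
#' @param merge_tol Isotopologue merge tolerance passed to
#'   [predict_pattern()].
#' @return A tibble of class `benchmark`, one row per benchmark peak
#'   (accepted MAITs and accepted/rejected LAITs) with peak metrics,
#'   predicted and observed IRs, biases, PCC, `status`
#'   (`accepted_mait` / `accepted_lait` / `rejected`) and `reason`.
#'   Attributes: `thresholds`, `mode`, `tol_ppm`, `abundance_floor`,
#'   `dropped` (tibble of dropped groups) and `provenance` (input hashes).
#' @export
build_benchmark <- function(runs, targets, mode = c("full", "mait_only_mh"),
                            tol_ppm = 5, abundance_floor = 0.01,
                            thresholds = bm_thresholds(), merge_tol = 1e-4) {
  mode <- match.arg(mode)
  if (is.character(runs)) runs <- lapply(runs, read_run)
  if (!is.data.frame(targets) || nrow(targets) == 0L) {
    rlang::abort("`targets` must be a non-empty data frame.",
                 class = "irbench_bm_error")
  }
  ids <- vapply(runs, function(r) r$run_id, character(1))
  if (is.null(names(runs)) || any(!nzchar(names(runs)))) names(runs) <- ids
  missing_files <- setdiff(unique(targets$file), names(runs))
  if (length(missing_files)) {
    rlang::abort(sprintf("No run supplied for file(s): %s",
                         paste(missing_files, collapse = ", ")),
                 class = "irbench_bm_error")
  }
  if (mode == "mait_only_mh") {
    targets <- dplyr::filter(targets, .data$adduct == "[M+H]+")
  }

  rows <- list()
  dropped <- list()
  groups <- dplyr::group_split(dplyr::group_by(
    targets, .data$molecule_id, .data$file, .data$adduct))

  for (g in groups) {
    g <- g[1, ]
    run <- runs[[g$file]]
    bounds <- c(g$rt_start, g$rt_end)
    pat <- predict_pattern(g$formula, adduct = g$adduct,
                           abundance_floor = abundance_floor,
                           merge_tol = merge_tol)
    mait_lab <- attr(pat, "mait")
    if (mode == "mait_only_mh") pat <- pat[pat$label == mait_lab, ]

    eics <- lapply(pat$mz, function(mz) {
      tryCatch(extract_eic(run, mz, tol_ppm = tol_ppm, rt_window = bounds),
               irbench_io_error = function(e) NULL)
    })
    mets <- lapply(eics, function(e) if (is.null(e)) NULL
                                     else measure_peak(e, bounds))
    names(eics) <- names(mets) <- pat$label

    mm <- mets[[mait_lab]]
    if (is.null(mm)) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        molecule_id = g$molecule_id, file = g$file, adduct = g$adduct,
        reason = "MAIT peak unmeasurable (< 4 points)")
      next
    }
    me <- eics[[mait_lab]]

    for (k in seq_len(nrow(pat))) {
      lab <- pat$label[k]
      pred <- pat$ratio[k]
      pm <- mets[[lab]]
      base <- tibble::tibble(
        molecule_id = g$molecule_id, file = g$file, adduct = g$adduct,
        isotopologue = lab, mz = pat$mz[k], predicted_ir = pred)
      if (lab == mait_lab) {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          base, mm,
          tibble::tibble(observed_ir_area = 1, observed_ir_height = 1,
                         bias_area = 0, bias_height = 0, pcc = 1,
                         status = "accepted_mait", reason = NA_character_))
        next
      }
      if (is.null(pm)) {
        empty <- mm[0, ][1, ] # one all-NA metrics row with the right columns
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          base, empty,
          tibble::tibble(observed_ir_area = NA_real_,
                         observed_ir_height = NA_real_,
                         bias_area = NA_real_, bias_height = NA_real_,
                         pcc = NA_real_, status = "rejected",
                         reason = "unmeasurable peak"))
        next
      }
      obs_a <- pm$area / mm$area
      obs_h <- pm$height / mm$height
      b_a <- ir_bias(obs_a, pred)
      b_h <- ir_bias(obs_h, pred)
      le <- eics[[lab]]
      pcc <- if (stats::sd(le$intensity) == 0 || stats::sd(me$intensity) == 0) {
        NA_real_
      } else {
        stats::cor(le$intensity, me$intensity)
      }
      v <- validate_isotopologue(pcc, b_a, b_h, thresholds)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        base, pm,
        tibble::tibble(observed_ir_area = obs_a, observed_ir_height = obs_h,
                       bias_area = b_a, bias_height = b_h, pcc = pcc,
                       status = if (v$accepted) "accepted_lait" else "rejected",
                       reason = v$reason))
    }
  }

  bm <- dplyr::bind_rows(rows)
  if (nrow(bm) > 0L) {
    key <- paste(bm$molecule_id, bm$file, bm$adduct, bm$isotopologue)
    if (anyDuplicated(key)) {
      rlang::abort("Duplicate (molecule, file, adduct, isotopologue) in benchmark.",
                   class = "irbench_bm_error")
    }
  }
  structure(
    bm,
    thresholds = thresholds, mode = mode, tol_ppm = tol_ppm,
    abundance_floor = abundance_floor,
    dropped = dplyr::bind_rows(dropped),
    provenance = list(targets_hash = rlang::hash(targets),
                      runs = unname(vapply(runs, function(r) r$run_id,
                                           character(1)))),
    class = c("benchmark", class(bm))
  )
}

#' Accepted peaks of a benchmark
#'
#' @param bm A `benchmark` tibble.
#' @return The accepted rows (MAITs and validated LAITs).
#' @export
accepted_peaks <- function(bm) {
  out <- bm[bm$status != "rejected", ]
  attributes(out) <- c(attributes(out)[c("names", "row.names", "class")],
                       attributes(bm)[c("thresholds", "mode", "tol_ppm",
                                        "abundance_floor", "provenance")])
  out
}

#' Re-apply acceptance filters with different thresholds
#'
#' Revalidates every LAIT of a benchmark from its stored PCC and biases,
#' without re-reading raw data. MAIT rows and unmeasurable candidates are
#' unchanged.
#'
#' @param bm A `benchmark` tibble.
#' @param thresholds New [bm_thresholds()].
#' @return The benchmark with updated `status` and `reason`.
#' @export
revalidate_benchmark <- function(bm, thresholds = bm_thresholds()) {
  lait <- bm$status != "accepted_mait" & bm$reason %in%
    c(NA, "pcc", "bias_area", "bias_height", "bias_diff") &
    !is.na(bm$pcc)
  if (any(lait)) {
    v <- purrr::pmap_dfr(
      list(bm$pcc[lait], bm$bias_area[lait], bm$bias_height[lait]),
      function(p, a, h) validate_isotopologue(p, a, h, thresholds))
    bm$status[lait] <- ifelse(v$accepted, "accepted_lait", "rejected")
    bm$reason[lait] <- v$reason
  }
  attr(bm, "thresholds") <- thresholds
  bm
}

#' Summarize a benchmark
#'
#' Counts peaks by validation status, reports the covered dynamic range with
#' and without LAITs, and summarizes the distributions of the peak-shape
#' metrics of the accepted peaks.
#'
#' @param bm A non-empty `benchmark`.
#' @return A list of class `benchmark_summary` with elements `counts`
#'   (tibble status/n), `reject_reasons` (tibble), `dynamic_range`
#'   (log10 span of accepted peak heights, `mait_only` vs `with_laits`) and
#'   `shape` (quantile tibble for fwhm, m/z range, zigzag, sharpness).
#' @export
benchmark_summary <- function(bm) {
  if (!is.data.frame(bm) || nrow(bm) == 0L) {
    rlang::abort("Empty benchmark.", class = "irbench_bm_error")
  }
  acc <- bm[bm$status != "rejected", ]
  counts <- dplyr::count(dplyr::as_tibble(bm), .data$status, name = "n")
  reasons <- dplyr::count(dplyr::as_tibble(bm[bm$status == "rejected", ]),
                          .data$reason, name = "n")
  span <- function(h) if (length(h) && all(h > 0)) log10(max(h) / min(h)) else NA_real_
  dr <- tibble::tibble(
    set = c("mait_only", "with_laits"),
    log10_span = c(span(acc$height[acc$status == "accepted_mait"]),
                   span(acc$height))
  )
  qtab <- function(x, nm) {
    x <- x[!is.na(x)]
    tibble::tibble(metric = nm,
                   q25 = quantile(x, 0.25, names = FALSE),
                   median = median(x),
                   q75 = quantile(x, 0.75, names = FALSE))
  }
  shape <- dplyr::bind_rows(
    qtab(acc$fwhm, "fwhm_s"),
    qtab(acc$mz_max - acc$mz_min, "mz_range_th"),
    qtab(acc$zigzag, "zigzag"),
    qtab(acc$sharpness, "sharpness")
  )
  structure(list(counts = counts, reject_reasons = reasons,
                 dynamic_range = dr, shape = shape),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("Benchmark summary\n")
  cat("  peaks by status:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat(sprintf("  dynamic range (log10 height span): MAIT-only %.2f, with LAITs %.2f\n",
              x$dynamic_range$log10_span[1], x$dynamic_range$log10_span[2]))
  invisible(x)
}

#' Export a benchmark with a metadata sidecar
#'
#' Writes the benchmark table as CSV and a JSON sidecar (`<path>.meta.json`)
#' with the thresholds, mode, tolerances and input hashes needed to
#' reproduce it.
#'
#' @param bm A `benchmark`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bm, path) {
  utils::write.csv(as.data.frame(bm), path, row.names = FALSE)
  meta <- list(
    tool = "irbench", version = as.character(utils::packageVersion("irbench")),
    mode = attr(bm, "mode"), tol_ppm = attr(bm, "tol_ppm"),
    abundance_floor = attr(bm, "abundance_floor"),
    thresholds = attr(bm, "thresholds"),
    provenance = attr(bm, "provenance"),
    table_md5 = unname(tools::md5sum(path))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
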