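#' Proportion of benchmark peaks found
#'
#' Percentage of accepted benchmark peaks recovered by the nontargeted
#' output at the given stage. Pre-alignment, split peaks count as found for
#' this metric (they are reported separately by [split_proportion()]).
#'
#' @param match A `match_result`.
#' @return Percentage in `[0, 100]`.
#' @export
found_proportion <- function(match) {
  if (nrow(match) == 0L) {
    rlang::abort("Empty match result.", class = "irbench_assess_error")
  }
  100 * mean(match$match_status %in% c("found", "split"))
}

#' Proportion of split benchmark peaks (pre-alignment)
#'
#' @param match A `match_result` with stage `"pre"`.
#' @return Percentage in `[0, 100]`.
#' @export
split_proportion <- function(match) {
  if (nrow(match) == 0L) {
    rlang::abort("Empty match result.", class = "irbench_assess_error")
  }
  if (!identical(attr(match, "stage"), "pre")) {
    rlang::abort("Split peaks are only defined before alignment.",
                 class = "irbench_assess_error")
  }
  100 * mean(match$match_status == "split")
}

#' Isotopologue-ratio accuracy of the nontargeted output
#'
#' For every accepted LAIT whose own peak and whose MAIT peak both carry a
#' matched abundance at this stage, computes the NFD isotopologue ratio
#' (LAIT abundance / MAIT abundance) and its bias against the predicted
#' ratio. The ratio is recovered if the NFD bias is less than `margin`
#' percentage points above the benchmark's own area-based bias for that
#' LAIT. Returns the percentage recovered among assessable ratios, or `NA`
#' (with attribute `n = 0`) when nothing is assessable.
#'
#' @param match A `match_result`.
#' @param margin Recovery margin in percentage points (default 20).
#' @return Percentage recovered, with attribute `n` (assessable count);
#'   `NA` when no ratio is assessable.
#' @export
ir_accuracy <- function(match, margin = 20) {
  mait <- match[match$status == "accepted_mait", ]
  lait <- match[match$status == "accepted_lait", ]
  key <- function(d) paste(d$molecule_id, d$file, d$adduct)
  idx <- match(key(lait), key(mait))
  mait_ab <- mait$matched_abundance[idx]
  assessable <- !is.na(lait$matched_abundance) & !is.na(mait_ab) & mait_ab > 0
  if (!any(assessable)) {
    return(structure(NA_real_, n = 0L))
  }
  l <- lait[assessable, ]
  nfd_ir <- l$matched_abundance / mait_ab[assessable]
  nfd_bias <- ir_bias(nfd_ir, l$predicted_ir)
  recovered <- nfd_bias < l$bm_bias_area + margin
  structure(100 * mean(recovered), n = sum(assessable))
}

#' Percentile bootstrap confidence interval by benchmark molecule
#'
#' Resamples benchmark molecules (not individual peaks) with replacement
#' `R` times, recomputes the metric on each resample, and returns the
#' percentile interval at level `level`. Deterministic under a fixed seed.
#' A single-molecule benchmark yields a degenerate interval equal to the
#' point estimate, with a warning.
#'
#' @param metric A function taking a `match_result` subset and returning a
#'   single number (e.g. [found_proportion()]).
#' @param match A `match_result`.
#' @param R Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.99).
#' @param seed Optional integer seed.
#' @return Named numeric `c(lower, upper)`, with attributes `point` (the
#'   full-sample metric) and `R`.
#' @export
bootstrap_ci <- function(metric, match, R = 1000, level = 0.99, seed = NULL) {
  stopifnot(R >= 1, level > 0, level < 1)
  point <- metric(match)
  mols <- unique(match$molecule_id)
  if (length(mols) < 2L) {
    warning("Benchmark has a single molecule; CI is degenerate.")
    return(structure(c(lower = point, upper = point), point = point, R = R))
  }
  idx_by_mol <- split(seq_len(nrow(match)), match$molecule_id)
  draw <- function() {
    sampled <- sample.int(length(idx_by_mol), replace = TRUE)
    rows <- unlist(idx_by_mol[sampled], use.names = FALSE)
    metric(dplyr::slice(match, rows))
  }
  reps <- if (is.null(seed)) {
    vapply(seq_len(R), function(r) draw(), numeric(1))
  } else {
    withr::with_seed(seed, vapply(seq_len(R), function(r) draw(), numeric(1)))
  }
  alpha <- (1 - level) / 2
  ci <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  structure(c(lower = ci[1], upper = ci[2]), point = point, R = R)
}

#' Replicate-precision metrics of an aligned feature table
#'
#' Computes, per feature, the coefficient of variation (sample standard
#' deviation over mean, in percent) across the given replicate files. A
#' feature fails if any replicate abundance is missing or its mean is zero.
#' `nCV30` is the number of features with CV strictly below the threshold;
#' `pCV30` is that count as a percentage of all features in the table.
#'
#' @param features An `nfd_features` tibble.
#' @param replicate_files Character vector of at least two file ids forming
#'   the replicate group.
#' @param cv_threshold CV threshold in percent (default 30).
#' @return A list with `nCV30`, `pCV30` and `detail` (per-feature tibble
#'   with `cv` and `pass`).
#' @export
cv_metrics <- function(features, replicate_files, cv_threshold = 30) {
  if (length(replicate_files) < 2L) {
    rlang::abort("Need at least two replicate files.",
                 class = "irbench_assess_error")
  }
  all_ids <- unique(features$feature_id)
  sub <- features[features$file %in% replicate_files, ]
  detail <- sub |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      n_obs = sum(!is.na(.data$abundance)),
      m = mean(.data$abundance),
      s = sd(.data$abundance),
      .groups = "drop"
    ) |>
    dplyr::right_join(tibble::tibble(feature_id = all_ids), by = "feature_id") |>
    dplyr::mutate(
      complete = !is.na(.data$n_obs) & .data$n_obs == length(replicate_files),
      zero_mean = .data$complete & .data$m == 0,
      cv = dplyr::if_else(.data$complete & !.data$zero_mean,
                          100 * .data$s / .data$m, NA_real_),
      pass = dplyr::coalesce(.data$complete & !.data$zero_mean &
                               .data$cv < cv_threshold, FALSE)
    )
  if (any(detail$zero_mean)) {
    message(sprintf("%d feature(s) with zero mean failed.",
                    sum(detail$zero_mean)))
  }
  detail <- dplyr::select(detail, "feature_id", "cv", "pass")
  list(nCV30 = sum(detail$pass), pCV30 = 100 * sum(detail$pass) / length(all_ids),
       detail = detail)
}

#' Filter features by per-file peak quality labels
#'
#' Retains a feature only if it contains at least `min_good` peaks carrying
#' the good-quality label among its non-missing abundances (the generic form
#' of requiring a minimum number of high-quality peaks per feature). If a
#' benchmark is supplied, the post-alignment recovery and IR-accuracy
#' metrics are recomputed on the retained features.
#'
#' @param features An `nfd_features` tibble with a populated `label` column
#'   for every non-missing abundance.
#' @param min_good Minimum number of good-labelled peaks (0 retains all).
#' @param good_label The label value counting as good (default
#'   `"high_quality"`).
#' @param bm Optional `benchmark`; when given, `report` is populated.
#' @param ... Passed to [match_aligned()] when `bm` is given.
#' @return A list with `features` (retained rows), `n_retained`,
#'   `n_total`, and `report` (`NULL`, or a list with `found_post` and
#'   `ir_accuracy_post`).
#' @export
evaluate_feature_filter <- function(features, min_good,
                                    good_label = "high_quality",
                                    bm = NULL, ...) {
  n_samples <- length(unique(features$file))
  if (min_good > n_samples) {
    rlang::abort(sprintf("min_good (%d) exceeds the sample count (%d).",
                         min_good, n_samples),
                 class = "irbench_assess_error")
  }
  has_ab <- !is.na(features$abundance)
  if (any(has_ab & is.na(features$label))) {
    rlang::abort("Every non-missing abundance needs a quality label.",
                 class = "irbench_assess_error")
  }
  good <- features |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      n_good = sum(!is.na(.data$abundance) & .data$label == good_label),
      .groups = "drop")
  keep_ids <- good$feature_id[good$n_good >= min_good]
  retained <- features[features$feature_id %in% keep_ids, ]
  report <- NULL
  if (!is.null(bm)) {
    if (nrow(retained) > 0L) {
      m <- match_aligned(bm, retained, ...)
      report <- list(found_post = found_proportion(m),
                     ir_accuracy_post = as.numeric(ir_accuracy(m)))
    } else {
      report <- list(found_post = 0, ir_accuracy_post = NA_real_)
    }
  }
  list(features = retained, n_retained = length(keep_ids),
       n_total = length(unique(features$feature_id)), report = report)
}

#' Assess a nontargeted output against a benchmark
#'
#' Runs the full scoring: matches the unaligned peak list and/or aligned
#' feature table against the benchmark, computes recovery, split and
#' isotopologue-ratio accuracy metrics, and attaches percentile bootstrap
#' confidence intervals obtained by resampling benchmark molecules.
#'
#' @param bm A `benchmark`.
#' @param unaligned Optional `nfd_peaks` tibble.
#' @param aligned Optional `nfd_features` tibble.
#' @param mz_tol_ppm,min_overlap,rt_tol Matching tolerances (see
#'   [match_unaligned()], [match_aligned()]).
#' @param ir_margin IR recovery margin in percentage points (default 20).
#' @param R,level,seed Bootstrap settings (defaults 1000 resamples at level
#'   0.99).
#' @param sample_map Optional sample-to-file mapping for [match_aligned()].
#' @return An `assessment_report`: list with `metrics` (tibble of metric,
#'   value, ci_lower, ci_upper, n), `matches` (the underlying
#'   `match_result`s) and `settings`.
#' @export
assess <- function(bm, unaligned = NULL, aligned = NULL,
                   mz_tol_ppm = 10, min_overlap = 0.2, rt_tol = NULL,
                   ir_margin = 20, R = 1000, level = 0.99, seed = NULL,
                   sample_map = NULL) {
  if (is.null(unaligned) && is.null(aligned)) {
    rlang::abort("Supply an unaligned peak list and/or an aligned feature table.",
                 class = "irbench_assess_error")
  }
  rows <- list(); matches <- list()
  add <- function(name, metric_fn, match, n) {
    ci <- bootstrap_ci(metric_fn, match, R = R, level = level, seed = seed)
    val <- attr(ci, "point")
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      metric = name, value = as.numeric(val),
      ci_lower = unname(ci[1]), ci_upper = unname(ci[2]), n = n)
  }
  if (!is.null(unaligned)) {
    mp <- match_unaligned(bm, unaligned, mz_tol_ppm = mz_tol_ppm,
                          min_overlap = min_overlap)
    matches$pre <- mp
    add("found_pre", found_proportion, mp, nrow(mp))
    add("split_pre", split_proportion, mp, nrow(mp))
    ir <- ir_accuracy(mp, margin = ir_margin)
    if (!is.na(ir)) {
      add("ir_accuracy_pre", function(m) ir_accuracy(m, margin = ir_margin),
          mp, attr(ir, "n"))
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = "ir_accuracy_pre", value = NA_real_,
        ci_lower = NA_real_, ci_upper = NA_real_, n = 0L)
    }
  }
  if (!is.null(aligned)) {
    ma <- match_aligned(bm, aligned, mz_tol_ppm = mz_tol_ppm, rt_tol = rt_tol,
                        sample_map = sample_map)
    matches$post <- ma
    add("found_post", found_proportion, ma, nrow(ma))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      metric = "found_post_gap_filled",
      value = 100 * mean(ma$gap_filled[ma$match_status == "found"]),
      ci_lower = NA_real_, ci_upper = NA_real_,
      n = sum(ma$match_status == "found"))
    ir <- ir_accuracy(ma, margin = ir_margin)
    if (!is.na(ir)) {
      add("ir_accuracy_post", function(m) ir_accuracy(m, margin = ir_margin),
          ma, attr(ir, "n"))
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = "ir_accuracy_post", value = NA_real_,
        ci_lower = NA_real_, ci_upper = NA_real_, n = 0L)
    }
  }
  structure(
    list(
      metrics = dplyr::bind_rows(rows),
      matches = matches,
      settings = list(mz_tol_ppm = mz_tol_ppm, min_overlap = min_overlap,
                      rt_tol = rt_tol, ir_margin = ir_margin, R = R,
                      level = level, seed = seed,
                      thresholds = attr(bm, "thresholds"),
                      bm_mode = attr(bm, "mode"),
                      bm_provenance = attr(bm, "provenance"))
    ),
    class = "assessment_report"
  )
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Nontargeted feature detection assessment\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$value[i])) {
      cat(sprintf("  %-22s not applicable (n = %d)\n", m$metric[i], m$n[i]))
    } else if (is.na(m$ci_lower[i])) {
      cat(sprintf("  %-22s %6.1f %%            (n = %d)\n",
                  m$metric[i], m$value[i], m$n[i]))
    } else {
      cat(sprintf("  %-22s %6.1f %% [%5.1f, %5.1f] (n = %d)\n",
                  m$metric[i], m$value[i], m$ci_lower[i], m$ci_upper[i], m$n[i]))
    }
  }
  invisible(x)
}

#' Tidy an assessment report
#'
#' Returns one row per metric, in both orientations (e.g. `found_pre` and
#' its complement `missed_pre`) so no sign confusion is possible.
#'
#' @param x An `assessment_report`.
#' @param ... Unused.
#' @return A tibble with `metric`, `value`, `ci_lower`, `ci_upper`, `n`.
#' @export
tidy.assessment_report <- function(x, ...) {
  m <- x$metrics
  comp <- m[m$metric %in% c("found_pre", "found_post", "ir_accuracy_pre",
                            "ir_accuracy_post"), ]
  if (nrow(comp)) {
    comp <- dplyr::mutate(
      comp,
      metric = sub("^found", "missed", sub("^ir_accuracy", "ir_inaccuracy",
                                           .data$metric)),
      value = 100 - .data$value,
      ci_lower2 = 100 - .data$ci_upper,
      ci_upper = 100 - .data$ci_lower,
      ci_lower = .data$ci_lower2
    ) |> dplyr::select(-"ci_lower2")
  }
  dplyr::bind_rows(m, comp)
}

#' One-row summary of an assessment report
#'
#' @param x An `assessment_report`.
#' @param ... Unused.
#' @return A one-row tibble, metrics as columns.
#' @export
glance.assessment_report <- function(x, ...) {
  tidyr::pivot_wider(x$metrics[, c("metric", "value")],
                     names_from = "metric", values_from = "value")
}

#' Export an assessment report
#'
#' Writes the metric table as CSV and the full report (metrics, CIs,
#' settings, tool version) as JSON next to it.
#'
#' @param report An `assessment_report`.
#' @param path CSV output path; the JSON goes to `<path>.json`.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(tidy(report)), path, row.names = FALSE)
  doc <- list(
    tool = "irbench",
    version = as.character(utils::packageVersion("irbench")),
    metrics = report$metrics,
    settings = report$settings
  )
  jsonlite::write_json(doc, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}
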