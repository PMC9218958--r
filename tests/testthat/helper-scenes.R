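# shared simulated fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

# clean scene: zero noise, no saturation, every planted isotopologue must be
# accepted into the benchmark
clean_fixture <- function() {
  if (is.null(.fixtures$clean)) {
    roster <- sim_molecules(n = 8, seed = 7)
    cfg <- sim_config(roster, seed = 7)
    scene <- simulate_run(cfg, tempfile(fileext = ".mzML"))
    run <- read_run(scene$path, run_id = cfg$run_id)
    bm <- build_benchmark(stats::setNames(list(run), cfg$run_id),
                          sim_targets(scene))
    .fixtures$clean <- list(scene = scene, run = run, bm = bm)
  }
  .fixtures$clean
}

# formulas whose [M+H]+ pattern holds exactly two isotopologues above a
# ratio floor of 0.05 (checked at build time), so a roster of n molecules
# plants exactly 2n peaks
two_iso_formulas <- function() {
  f <- c("C6H12O6", "C5H10O5", "C5H9NO4", "C9H11NO2", "C5H5N5",
         "C5H11NO2", "C6H13NO2", "C7H6O2", "C8H10N4O2", "C11H12N2O2",
         "C6H6O6", "C6H14N4O2", "C12H22O11", "C10H13N5O4")
  for (x in f) {
    stopifnot(nrow(predict_pattern(x, adduct = "[M+H]+",
                                   abundance_floor = 0.05)) == 2L)
  }
  f
}

# scene with exactly two isotopologues per molecule (2n planted peaks)
two_iso_scene <- function(n_mol = 50, seed = 3, ...) {
  fs <- rep_len(two_iso_formulas(), n_mol)
  roster <- sim_molecules(n = n_mol, formulas = fs, seed = seed,
                          rt_range = c(60, 60 + 22 * n_mol))
  roster$formula <- fs # keep the cycle order, not a sample
  cfg <- sim_config(roster, abundance_floor = 0.05, seed = seed, ...)
  simulate_run(cfg, tempfile(fileext = ".mzML"))
}

two_iso_fixture <- function() {
  if (is.null(.fixtures$two_iso)) {
    scene <- two_iso_scene(n_mol = 50, seed = 3)
    run <- read_run(scene$path, run_id = scene$run_id)
    bm <- build_benchmark(stats::setNames(list(run), scene$run_id),
                          sim_targets(scene), abundance_floor = 0.05)
    .fixtures$two_iso <- list(scene = scene, run = run, bm = bm)
  }
  .fixtures$two_iso
}

# build an EIC tibble directly (for peak-metric unit tests)
make_eic <- function(rt, intensity, mz = NA_real_, target_mz = 200,
                     tol_ppm = 5) {
  out <- tibble::tibble(rt = rt, intensity = intensity,
                        mz = rep_len(mz, length(rt)))
  structure(out, target_mz = target_mz, tol_ppm = tol_ppm,
            class = c("eic", class(out)))
}

# synthetic match result at the table level (for bootstrap behaviour tests):
# each peak is found with probability p_found, independently
synth_match <- function(n_mol, peaks_per_mol, p_found, seed) {
  m <- withr::with_seed(seed, {
    n <- n_mol * peaks_per_mol
    tibble::tibble(
      molecule_id = rep(sprintf("M%03d", seq_len(n_mol)),
                        each = peaks_per_mol),
      match_status = ifelse(stats::runif(n) < p_found, "found", "missed")
    )
  })
  structure(m, stage = "pre", class = c("match_result", class(m)))
}

# minimal aligned feature table in long form
make_features <- function(abund, files = colnames(abund),
                          labels = NULL, gap = NULL) {
  rows <- lapply(seq_along(files), function(j) {
    tibble::tibble(
      feature_id = rownames(abund), mz = 100 + seq_len(nrow(abund)),
      rt = 10 * seq_len(nrow(abund)), file = files[j],
      abundance = abund[, j],
      gap_filled = if (is.null(gap)) FALSE else gap[, j],
      label = if (is.null(labels)) "high_quality" else labels[, j]
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("nfd_features", class(out)))
}
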