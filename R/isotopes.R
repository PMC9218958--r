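#' Embedded isotope table
#'
#' Monoisotopic masses (u) and natural abundances of stable isotopes for the
#' elements the package supports. Values are a frozen snapshot of the
#' IUPAC/CIAAW recommended values (2021 revision, representative abundances),
#' embedded so that predicted isotopologue patterns are reproducible across
#' installations. The snapshot version is recorded in the `"version"`
#' attribute.
#'
#' @return A tibble with columns `element`, `mass` (u), `abundance`
#'   (fraction, summing to 1 per element).
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  out <- .iso_table
  attr(out, "version") <- "CIAAW-2021 snapshot, irbench embedded v1"
  out
}

# masses in u; abundances are representative terrestrial fractions
.iso_table <- tibble::tribble(
  ~element, ~mass,         ~abundance,
  "H",      1.0078250319,  0.999885,
  "H",      2.0141017779,  0.000115,
  "C",      12.0000000000, 0.9893,
  "C",      13.0033548378, 0.0107,
  "N",      14.0030740052, 0.99636,
  "N",      15.0001088984, 0.00364,
  "O",      15.9949146221, 0.99757,
  "O",      16.9991315000, 0.00038,
  "O",      17.9991604000, 0.00205,
  "F",      18.9984031630, 1.0,
  "Na",     22.9897692820, 1.0,
  "Mg",     23.9850417000, 0.7899,
  "Mg",     24.9858369200, 0.1000,
  "Mg",     25.9825929300, 0.1101,
  "Si",     27.9769265300, 0.92223,
  "Si",     28.9764946600, 0.04685,
  "Si",     29.9737701700, 0.03092,
  "P",      30.9737616300, 1.0,
  "S",      31.9720711700, 0.9499,
  "S",      32.9714589100, 0.0075,
  "S",      33.9678670000, 0.0425,
  "S",      35.9670807600, 0.0001,
  "Cl",     34.9688526800, 0.7576,
  "Cl",     36.9659025900, 0.2424,
  "K",      38.9637066800, 0.932581,
  "K",      39.9639984800, 0.000117,
  "K",      40.9618257600, 0.067302,
  "Ca",     39.9625909800, 0.96941,
  "Ca",     41.9586180100, 0.00647,
  "Ca",     42.9587666000, 0.00135,
  "Ca",     43.9554818000, 0.02086,
  "Ca",     45.9536926000, 0.00004,
  "Ca",     47.9525340000, 0.00187,
  "Fe",     53.9396105000, 0.05845,
  "Fe",     55.9349375000, 0.91754,
  "Fe",     56.9353940000, 0.02119,
  "Fe",     57.9332756000, 0.00282,
  "Br",     78.9183371000, 0.5069,
  "Br",     80.9162906000, 0.4931,
  "I",      126.9044730000, 1.0
)

# electron rest mass in u (CODATA)
.electron_mass <- 0.000548579909

#' Parse a molecular formula
#'
#' Parses a Hill-notation-like molecular formula ("C6H12O6", "H2O",
#' "C9H11NO2") into element counts. Repeated element tokens are summed, so
#' "CH3COOH" parses to the same counts as "C2H4O2".
#'
#' @param text A single formula string.
#' @return A named integer vector of element counts (every count >= 1).
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    rlang::abort("`text` must be a single non-empty formula string.",
                 class = "irbench_parse_error")
  }
  pat <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  # anything not consumed by element/count tokens is malformed
  consumed <- paste(toks, collapse = "")
  if (!identical(consumed, text)) {
    bad <- substr(text, nchar(consumed) + 1L, nchar(text))
    rlang::abort(
      sprintf("Malformed formula '%s': cannot parse at '%s'.", text, bad),
      class = "irbench_parse_error"
    )
  }
  known <- unique(.iso_table$element)
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    nstr <- sub("^[A-Z][a-z]?", "", tok)
    if (!el %in% known) {
      rlang::abort(sprintf("Unknown element symbol '%s' in '%s'.", el, text),
                   class = "irbench_parse_error")
    }
    n <- if (nzchar(nstr)) suppressWarnings(as.integer(nstr)) else 1L
    if (is.na(n) || n <= 0L) {
      rlang::abort(sprintf("Invalid count for element '%s' in '%s'.", el, text),
                   class = "irbench_parse_error")
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts[counts >= 1L]
}

#' Serialize element counts back to Hill notation
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return A formula string (C first, then H, then other elements
#'   alphabetically).
#' @export
format_formula <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- counts[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' Built-in adduct registry
#'
#' The registry holds the electrospray adducts the package knows about.
#' Each adduct is described by its element deltas relative to the neutral
#' molecule and its charge. Users can pass their own adduct as a list
#' `list(name =, deltas =, charge =)` anywhere an adduct name is accepted.
#'
#' @return A tibble with columns `name`, `deltas` (list of named integer
#'   vectors) and `charge`.
#' @export
#' @examples
#' adduct_registry()
adduct_registry <- function() {
  tibble::tibble(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[M+2H]2+",
             "[M-H]-", "[M+Cl]-"),
    deltas = list(
      c(H = 1L), c(Na = 1L), c(K = 1L), c(N = 1L, H = 4L), c(H = 2L),
      c(H = -1L), c(Cl = 1L)
    ),
    charge = c(1L, 1L, 1L, 1L, 2L, -1L, -1L)
  )
}

.resolve_adduct <- function(adduct) {
  if (is.list(adduct) && !is.data.frame(adduct)) {
    stopifnot(all(c("name", "deltas", "charge") %in% names(adduct)))
    if (adduct$charge == 0L) {
      rlang::abort("Adduct charge must be non-zero.", class = "irbench_adduct_error")
    }
    return(adduct)
  }
  reg <- adduct_registry()
  i <- match(adduct, reg$name)
  if (is.na(i)) {
    rlang::abort(
      sprintf("Unknown adduct '%s'; see adduct_registry() or supply a list(name, deltas, charge).",
              adduct),
      class = "irbench_adduct_error"
    )
  }
  list(name = reg$name[[i]], deltas = reg$deltas[[i]], charge = reg$charge[[i]])
}

#' Apply an adduct to a neutral formula
#'
#' @param neutral Named integer vector of element counts of the neutral
#'   molecule.
#' @param adduct Adduct name from [adduct_registry()] or a
#'   `list(name, deltas, charge)`.
#' @return A list with `counts` (element counts of the charged species) and
#'   `charge`.
#' @export
#' @examples
#' apply_adduct(parse_formula("C6H12O6"), "[M+H]+")
apply_adduct <- function(neutral, adduct) {
  ad <- .resolve_adduct(adduct)
  counts <- neutral
  for (el in names(ad$deltas)) {
    cur <- if (el %in% names(counts)) counts[[el]] else 0L
    new <- cur + ad$deltas[[el]]
    if (new < 0L) {
      rlang::abort(
        sprintf("Adduct %s not applicable: would give %d atoms of %s.",
                ad$name, new, el),
        class = "irbench_adduct_error"
      )
    }
    counts[el] <- new
  }
  counts <- counts[counts > 0L]
  list(counts = counts, charge = ad$charge)
}

# isotopologue distribution of n atoms of one element: exact multinomial
# expansion over isotope compositions, pruned at `prune` relative abundance
.element_distribution <- function(element, n, prune = 1e-18) {
  iso <- .iso_table[.iso_table$element == element, ]
  k <- nrow(iso)
  if (k == 1L) {
    return(list(mass = iso$mass * n, ab = 1))
  }
  comps <- .compositions(n, k)
  la <- log(iso$abundance)
  logp <- lgamma(n + 1) - rowSums(lgamma(comps + 1)) + drop(comps %*% la)
  ab <- exp(logp)
  mass <- drop(comps %*% iso$mass)
  keep <- ab >= prune * max(ab)
  list(mass = mass[keep], ab = ab[keep])
}

# all k-vectors of non-negative integers summing to n, as a matrix
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- vector("list", n + 1L)
  for (i in 0:n) {
    sub <- .compositions(n - i, k - 1L)
    out[[i + 1L]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

# convolve two (mass, ab) term lists, pruning and merging identical masses
.convolve_terms <- function(a, b, prune = 1e-18) {
  mass <- outer(a$mass, b$mass, "+")
  ab <- outer(a$ab, b$ab, "*")
  mass <- as.vector(mass); ab <- as.vector(ab)
  keep <- ab >= prune * max(ab)
  mass <- mass[keep]; ab <- ab[keep]
  key <- round(mass, 9)
  agg <- rowsum(cbind(ab, ab * mass), group = key, reorder = TRUE)
  list(mass = agg[, 2] / agg[, 1], ab = agg[, 1])
}

#' Predict the isotopologue pattern of a charged species
#'
#' Computes isotopologue m/z values and abundance ratios relative to the most
#' abundant isotopologue (MAIT) for a molecular formula, optionally after
#' applying an adduct. Abundances come from an exact multinomial expansion
#' over isotope combinations per element, convolved across elements with
#' pruning of negligible terms; isotopologues are aggregated by nominal mass
#' shift (abundance-weighted m/z), which is what centroided MS1 data can
#' resolve, and any aggregated entries still closer than `merge_tol` are
#' merged. m/z accounts for the electron mass per unit charge.
#'
#' @param x Formula string or named element-count vector (the neutral
#'   molecule if `adduct` is given, otherwise the charged species itself).
#' @param adduct Adduct name or spec (see [adduct_registry()]); `NULL` to
#'   treat `x` as the already-charged species and use `charge`.
#' @param charge Signed integer charge, used only when `adduct` is `NULL`.
#' @param abundance_floor Entries with ratio-to-MAIT at or below this floor
#'   are discarded. Must be in (0, 1).
#' @param merge_tol m/z tolerance (Th) for merging aggregated isotopologues.
#' @param prune Per-element and joint pruning threshold (relative abundance)
#'   of the exact expansion; the default keeps retained ratios accurate to
#'   well below 1e-9 relative.
#' @return A tibble of class `iso_pattern` with columns `label` ("M+0",
#'   "M+1", ...), `mz` (Th) and `ratio` (ratio-to-MAIT in (0, 1]), sorted by
#'   m/z, with attributes `species`, `charge`, `mait` (label of the most
#'   abundant isotopologue), `abundance_floor` and `merge_tol`.
#' @export
#' @examples
#' predict_pattern("C6H12O6", adduct = "[M+H]+")
predict_pattern <- function(x, adduct = NULL, charge = NULL,
                            abundance_floor = 1e-4, merge_tol = 1e-4,
                            prune = 1e-18) {
  if (is.character(x)) x <- parse_formula(x)
  if (!is.null(adduct)) {
    sp <- apply_adduct(x, adduct)
    counts <- sp$counts
    charge <- sp$charge
  } else {
    counts <- x
    if (is.null(charge) || charge == 0L) {
      rlang::abort("Supply a non-zero `charge` when no adduct is given.",
                   class = "irbench_pattern_error")
    }
  }
  if (length(counts) == 0L) {
    rlang::abort("Empty species: no atoms.", class = "irbench_pattern_error")
  }
  if (!is.numeric(abundance_floor) || abundance_floor <= 0 || abundance_floor >= 1) {
    rlang::abort("`abundance_floor` must be in (0, 1).",
                 class = "irbench_pattern_error")
  }

  terms <- list(mass = 0, ab = 1)
  mono <- 0
  for (el in names(counts)) {
    n <- counts[[el]]
    terms <- .convolve_terms(terms, .element_distribution(el, n, prune), prune)
    iso <- .iso_table[.iso_table$element == el, ]
    mono <- mono + n * iso$mass[which.max(iso$abundance)]
  }

  # aggregate by nominal shift from the principal-isotope mass
  shift <- round(terms$mass - mono)
  agg <- rowsum(cbind(terms$ab, terms$ab * terms$mass), group = shift,
                reorder = TRUE)
  shift <- as.integer(rownames(agg))
  ab <- agg[, 1]
  mass <- agg[, 2] / agg[, 1]

  mz <- (mass - charge * .electron_mass) / abs(charge)
  ord <- order(mz)
  mz <- mz[ord]; ab <- ab[ord]; shift <- shift[ord]

  # fine-merge aggregated entries closer than merge_tol (rare; high charge)
  i <- 1L
  while (i < length(mz)) {
    if (mz[i + 1L] - mz[i] < merge_tol) {
      w <- ab[i] + ab[i + 1L]
      mz[i] <- (mz[i] * ab[i] + mz[i + 1L] * ab[i + 1L]) / w
      ab[i] <- w
      shift[i] <- shift[i]
      mz <- mz[-(i + 1L)]; ab <- ab[-(i + 1L)]; shift <- shift[-(i + 1L)]
    } else {
      i <- i + 1L
    }
  }

  ratio <- ab / max(ab)
  keep <- ratio > abundance_floor
  label <- sprintf("M%+d", shift)
  out <- tibble::tibble(label = label[keep], mz = unname(mz[keep]),
                        ratio = unname(ratio[keep]))
  out <- out[order(out$mz), ]
  structure(
    out,
    species = counts,
    charge = charge,
    mait = out$label[which.max(out$ratio)],
    abundance_floor = abundance_floor,
    merge_tol = merge_tol,
    class = c("iso_pattern", class(out))
  )
}

#' Predicted isotopologue ratio for a label
#'
#' @param pattern An `iso_pattern` from [predict_pattern()].
#' @param label Isotopologue label, e.g. `"M+1"`.
#' @return The predicted ratio-to-MAIT (1 for the MAIT itself).
#' @export
predicted_ir <- function(pattern, label) {
  i <- match(label, pattern$label)
  if (is.na(i)) {
    rlang::abort(sprintf("Isotopologue '%s' not in pattern (have: %s).",
                         label, paste(pattern$label, collapse = ", ")),
                 class = "irbench_pattern_error")
  }
  pattern$ratio[[i]]
}
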