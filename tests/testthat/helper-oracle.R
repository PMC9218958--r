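# independent isotope-pattern oracle: convolves one atom at a time over the
# full isotope choice tree (no multinomial shortcut, no pruning), then
# aggregates by nominal mass shift exactly like a centroided instrument
oracle_pattern <- function(counts, charge, floor = 1e-4) {
  iso <- as.data.frame(isotope_table())
  emass <- 0.000548579909
  terms <- list(mass = 0, ab = 1)
  mono <- 0
  for (el in names(counts)) {
    it <- iso[iso$element == el, ]
    mono <- mono + counts[[el]] * it$mass[which.max(it$abundance)]
    for (a in seq_len(counts[[el]])) {
      mass <- as.vector(outer(terms$mass, it$mass, "+"))
      ab <- as.vector(outer(terms$ab, it$abundance, "*"))
      key <- round(mass, 9)
      s1 <- rowsum(ab, key)
      s2 <- rowsum(ab * mass, key)
      terms <- list(mass = s2[, 1] / s1[, 1], ab = s1[, 1])
    }
  }
  shift <- round(terms$mass - mono)
  s1 <- rowsum(terms$ab, shift)
  s2 <- rowsum(terms$ab * terms$mass, shift)
  mz <- (s2[, 1] / s1[, 1] - charge * emass) / abs(charge)
  ratio <- s1[, 1] / max(s1[, 1])
  out <- data.frame(label = sprintf("M%+d", as.integer(rownames(s1))),
                    mz = mz, ratio = ratio)
  out[out$ratio > floor, ]
}

# random formula over the CHNOSPCl alphabet with at most `max_atoms` atoms
random_formula <- function(max_atoms = 25) {
  els <- c("C", "H", "N", "O", "S", "P", "Cl")
  k <- sample(2:5, 1)
  e <- sample(els, k)
  n <- as.integer(stats::rmultinom(1, sample(k:max_atoms, 1) - k, rep(1, k))) + 1L
  stats::setNames(n, e)
}
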