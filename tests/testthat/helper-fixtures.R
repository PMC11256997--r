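# shared fixtures and independent brute-force oracles

# small, fast spectra config for unit tests (coarser grid, few cells)
quick_spectra_config <- function(seed = 1, n_cells = 4, n_labelled = 2, ...) {
  sim_spectra_config(seed = seed, n_cells = n_cells, n_labelled = n_labelled,
                     ...)
}

pv_profile <- function(x, centre, fwhm) {
  u <- (x - centre) / fwhm
  0.5 * exp(-4 * log(2) * u^2) + 0.5 / (1 + 4 * u^2)
}

# build a bare spectrum from a function of the wavenumber grid
make_spectrum <- function(f, w = 600:1800, cell_id = "cell", treatment = "13C") {
  raman_spectrum(cell_id, treatment, w, f(w))
}

# taxon mass per fraction reconstructed from the emitted outputs:
# relative abundance x fraction total mass (copies / copies_total)
reconstruct_masses <- function(sim, treatment, copies_total = 1e9) {
  run <- if (treatment == "13C") sim$run_13C else sim$run_12C
  keys <- paste(treatment, run$fraction_number, sep = "_")
  rel <- sim$asv_table$abundance[, keys, drop = FALSE]
  sweep(rel, 2, run$copies_16S / copies_total, "*")
}

# abundance-weighted mean BD per taxon from emitted outputs
weighted_mean_bd <- function(sim, treatment) {
  mass <- reconstruct_masses(sim, treatment)
  run <- if (treatment == "13C") sim$run_13C else sim$run_12C
  drop(mass %*% run$buoyant_density) / rowSums(mass)
}

# brute-force window aggregation: explicit loops, no matrix ops
oracle_aggregate <- function(table, windows, fractions) {
  asvs <- rownames(table$abundance)
  out <- data.frame(asv_id = asvs, A13_heavy = NA_real_, A13_light = NA_real_,
                    A12_heavy = NA_real_, A12_light = NA_real_)
  for (tr in c("13C", "12C")) {
    for (win in c("heavy", "light")) {
      vals <- numeric(length(asvs))
      for (i in seq_along(asvs)) {
        acc <- c()
        for (j in seq_len(nrow(fractions))) {
          if (fractions$treatment[j] != tr) next
          bd <- fractions$buoyant_density[j]
          lo <- if (win == "light") windows$light_lo else windows$heavy_lo
          hi <- if (win == "light") windows$light_hi else windows$heavy_hi
          if (bd >= lo && bd <= hi) {
            key <- paste(tr, fractions$fraction_number[j], sep = "_")
            acc <- c(acc, table$abundance[asvs[i], key])
          }
        }
        vals[i] <- mean(acc)
      }
      out[[paste0("A", sub("C", "", tr), "_", win)]] <- vals
    }
  }
  out
}

# exhaustive search over all contiguous fraction blocks satisfying the
# heavy-window rule; returns indices of the winning block
oracle_heavy_block <- function(bd13, n12, n13, bd_split = 1.72,
                               ratio_min = 1.5) {
  ok <- bd13 > bd_split & n13 >= ratio_min * n12
  best <- integer(0)
  best_sum <- -Inf
  n <- length(ok)
  for (a in seq_len(n)) {
    for (b in a:n) {
      idx <- a:b
      if (!all(ok[idx])) next
      # maximal blocks only: not extendable either way
      if (a > 1 && ok[a - 1]) next
      if (b < n && ok[b + 1]) next
      if (length(idx) > length(best) ||
          (length(idx) == length(best) && sum(n13[idx]) > best_sum)) {
        best <- idx
        best_sum <- sum(n13[idx])
      }
    }
  }
  best
}

# exhaustive local-maxima scan (independent of find_peaks internals)
oracle_local_maxima <- function(y) {
  idx <- integer(0)
  for (i in 2:(length(y) - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) idx <- c(idx, i)
  }
  idx
}
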