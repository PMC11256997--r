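#' Construct a single-cell Raman spectrum
#'
#' @param cell_id Cell identifier.
#' @param treatment Treatment tag (e.g. `"12C"`, `"13C"`).
#' @param wavenumber Strictly ascending wavenumber grid (1/cm).
#' @param intensity Finite intensities (a.u.), same length as `wavenumber`.
#' @param state Character vector of preprocessing flags already applied.
#' @param meta List of metadata (e.g. simulator ground truth); never consumed
#'   by the classifiers.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(cell_id, treatment, wavenumber, intensity,
                           state = character(), meta = list()) {
  assert_that(length(wavenumber) == length(intensity),
              "wavenumber and intensity lengths differ for cell %s", cell_id)
  assert_that(all(diff(wavenumber) > 0),
              "wavenumber grid must be strictly ascending (cell %s)", cell_id)
  assert_that(all(is.finite(intensity)),
              "intensities must be finite (cell %s)", cell_id)
  structure(list(cell_id = as.character(cell_id),
                 treatment = as.character(treatment),
                 wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 state = state,
                 meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("raman_spectrum %s [%s]: %d points, %.0f-%.0f 1/cm%s\n",
              x$cell_id, x$treatment, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber),
              if (length(x$state)) paste0(" (", paste(x$state, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth fluorescence baseline by iteratively reweighted
#' penalised least squares (points above the running baseline get weight `p`,
#' points below `1 - p`) and subtracts it. Negative residual dips are
#' permitted.
#'
#' @param s A [raman_spectrum()].
#' @param lam Smoothness penalty (default 1e5).
#' @param p Asymmetry weight in (0, 1) (default 0.01).
#' @param n_iter Reweighting iterations (default 10).
#' @return The spectrum with the baseline subtracted and state flag
#'   `"baseline_corrected"` appended.
#' @export
baseline_correct <- function(s, lam = 1e5, p = 0.01, n_iter = 10L) {
  assert_that(inherits(s, "raman_spectrum"), "s must be a raman_spectrum")
  z <- als_baseline_cpp(s$intensity, lam, p, as.integer(n_iter))
  s$intensity <- s$intensity - z
  s$state <- union(s$state, "baseline_corrected")
  s
}

#' Vector (unit Euclidean norm) normalisation
#'
#' Scales the trace so that its intensity vector has Euclidean norm 1, making
#' band intensities comparable across cells regardless of acquisition gain.
#'
#' @param s A [raman_spectrum()].
#' @return The normalised spectrum with state flag `"vector_normalized"`.
#' @export
vector_normalize <- function(s) {
  assert_that(inherits(s, "raman_spectrum"), "s must be a raman_spectrum")
  nrm <- sqrt(sum(s$intensity^2))
  assert_that(nrm > 0, "cannot normalise an all-zero trace (cell %s)", s$cell_id)
  s$intensity <- s$intensity / nrm
  s$state <- union(s$state, "vector_normalized")
  s
}

#' Standard preprocessing chain
#'
#' Fixed order: baseline correction, then vector normalisation.
#'
#' @inheritParams baseline_correct
#' @return The preprocessed spectrum.
#' @export
preprocess_spectrum <- function(s, lam = 1e5, p = 0.01, n_iter = 10L) {
  vector_normalize(baseline_correct(s, lam = lam, p = p, n_iter = n_iter))
}

#' Find local maxima and their prominences
#'
#' A point is a peak when it is strictly greater than both neighbours. The
#' prominence of a peak is its height minus the higher of the two valley
#' minima encountered walking left and right until a taller point (or the
#' grid edge) is reached.
#'
#' @param s A [raman_spectrum()].
#' @return Data frame with columns `position` (1/cm), `height`, `prominence`.
#' @export
find_peaks <- function(s) {
  y <- s$intensity
  n <- length(y)
  if (n < 3) {
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  idx <- which(y[-c(1, 2)] < y[-c(1, n)] & y[-c(n - 1, n)] < y[-c(1, n)]) + 1L
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      if (y[j] < left_min) left_min <- y[j]
      j <- j - 1L
    }
    right_min <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) {
      if (y[j] < right_min) right_min <- y[j]
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
  data.frame(position = s$wavenumber[idx], height = y[idx], prominence = prom)
}

# robust noise scale from first differences in a band-free region
estimate_noise_mad <- function(s, region = c(1500, 1700)) {
  sel <- s$wavenumber >= region[1] & s$wavenumber <= region[2]
  y <- s$intensity[sel]
  if (length(y) < 3) return(0)
  stats::mad(diff(y)) / sqrt(2)
}

#' Detect the phenylalanine band in the labelled and unlabelled windows
#'
#' Searches for the highest-prominence local maximum inside the labelled
#' window (default 955-980 1/cm, bracketing both the reported 968 1/cm
#' position and a -37 1/cm redshift) and the unlabelled window (default
#' 990-1010 1/cm around the 1001-1003 1/cm biomarker). A peak is retained only
#' when its prominence reaches `k` times the noise scale (MAD of first
#' differences in the band-free `noise_region`).
#'
#' @param s A preprocessed [raman_spectrum()].
#' @param labelled_window,unlabelled_window Search windows (1/cm).
#' @param k Prominence threshold in noise-MAD units (default 3).
#' @param noise_region Band-free region for noise estimation (1/cm).
#' @return List with elements `labelled` and `unlabelled`, each either `NULL`
#'   or a one-row data frame (`position`, `height`, `prominence`).
#' @export
detect_phenylalanine_band <- function(s,
                                      labelled_window = c(955, 980),
                                      unlabelled_window = c(990, 1010),
                                      k = 3,
                                      noise_region = c(1500, 1700)) {
  peaks <- find_peaks(s)
  thr <- k * estimate_noise_mad(s, noise_region)
  pick <- function(win) {
    cand <- peaks[peaks$position >= win[1] & peaks$position <= win[2] &
                    peaks$prominence >= thr, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand[which.max(cand$prominence), , drop = FALSE]
  }
  list(labelled = pick(labelled_window), unlabelled = pick(unlabelled_window))
}

#' Classify one cell as 13C-labelled or not
#'
#' A cell is called labelled when a phenylalanine band is present in the
#' labelled (redshifted) window and is taller than any band in the unlabelled
#' window (or no unlabelled-window band exists). The reported shift is the
#' detected band position minus the 1001 1/cm unlabelled reference.
#'
#' @param s A preprocessed [raman_spectrum()].
#' @param detection Optional result of [detect_phenylalanine_band()]; computed
#'   from `s` when omitted.
#' @param reference Unlabelled reference position for the shift (1/cm).
#' @param band_labelled,band_unlabelled Positions (1/cm) at which the two
#'   reported band intensities are read off the grid.
#' @param ... Passed to [detect_phenylalanine_band()].
#' @return One-row data frame: `cell_id`, `treatment`, `labelled`,
#'   `band_position`, `intensity_968`, `intensity_1001`, `shift_cm1`.
#' @export
classify_label <- function(s, detection = NULL, reference = 1001,
                           band_labelled = 968, band_unlabelled = 1001, ...) {
  if (is.null(detection)) detection <- detect_phenylalanine_band(s, ...)
  lab <- detection$labelled
  unlab <- detection$unlabelled
  labelled <- !is.null(lab) && (is.null(unlab) || lab$height > unlab$height)
  at <- function(pos) s$intensity[which.min(abs(s$wavenumber - pos))]
  data.frame(cell_id = s$cell_id,
             treatment = s$treatment,
             labelled = labelled,
             band_position = if (labelled) lab$position else
               if (!is.null(unlab)) unlab$position else NA_real_,
             intensity_968 = at(band_labelled),
             intensity_1001 = at(band_unlabelled),
             shift_cm1 = if (labelled) lab$position - reference else NA_real_,
             row.names = NULL)
}

#' Preprocess and classify a set of cells
#'
#' Applies the fixed chain (baseline correction, vector normalisation, band
#' detection, labelling decision) to every spectrum.
#'
#' @param spectra List of [raman_spectrum()] objects.
#' @param lam,p,n_iter Baseline parameters, see [baseline_correct()].
#' @param ... Passed to [detect_phenylalanine_band()] /
#'   [classify_label()].
#' @return Data frame of label calls, one row per cell.
#' @examples
#' sp <- simulate_spectra(sim_spectra_config(n_cells = 5, n_labelled = 2))
#' classify_cells(sp)
#' @export
classify_cells <- function(spectra, lam = 1e5, p = 0.01, n_iter = 10L, ...) {
  assert_that(length(spectra) > 0, "no spectra supplied")
  rows <- lapply(spectra, function(s) {
    classify_label(preprocess_spectrum(s, lam = lam, p = p, n_iter = n_iter),
                   ...)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA of band intensities across cell groups
#'
#' Compares the (preprocessed) intensities at the 968 and 1001 1/cm bands
#' across cell groups (typically labelled 13C cells, unlabelled 13C cells and
#' 12C control cells).
#'
#' @param calls Data frame with columns `intensity_968` and `intensity_1001`
#'   (e.g. from [classify_cells()]).
#' @param group Factor or character vector assigning each row to a group;
#'   every group needs at least 2 cells.
#' @return Data frame with columns `band`, `F`, `p`, `df_between`, `df_within`.
#' @export
compare_band_intensities <- function(calls, group) {
  assert_that(nrow(calls) == length(group),
              "group must have one entry per call")
  group <- factor(group)
  assert_that(nlevels(group) >= 2, "need at least 2 groups")
  counts <- table(group)
  assert_that(all(counts >= 2),
              "every group needs >= 2 cells (got: %s)",
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  one <- function(y) {
    fit <- stats::lm(y ~ group)
    a <- stats::anova(fit)
    data.frame(F = a$`F value`[1], p = a$`Pr(>F)`[1],
               df_between = a$Df[1], df_within = a$Df[2])
  }
  out <- rbind(cbind(band = "968", one(calls$intensity_968)),
               cbind(band = "1001", one(calls$intensity_1001)))
  rownames(out) <- NULL
  out
}

#' Build the cell-sorting manifest
#'
#' Lists the cells called 13C-labelled, ordered by cell id, with their band
#' positions and shifts — the set a Raman-activated cell sorter would eject.
#'
#' @param calls Data frame of label calls from [classify_cells()].
#' @return List with `cells` (data frame: `cell_id`, `band_position`,
#'   `shift_cm1`) and `n` (number of cells to sort).
#' @export
build_sorting_manifest <- function(calls) {
  assert_that(!anyDuplicated(calls$cell_id), "duplicate cell ids in calls")
  sel <- calls[calls$labelled, c("cell_id", "band_position", "shift_cm1"),
               drop = FALSE]
  sel <- sel[order(sel$cell_id), , drop = FALSE]
  rownames(sel) <- NULL
  list(cells = sel, n = nrow(sel))
}
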