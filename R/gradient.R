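#' Construct a gradient run
#'
#' One treatment's ordered set of density-gradient fractions with buoyant
#' density (BD) and total 16S rRNA gene copies.
#'
#' @param treatment `"12C"` or `"13C"`.
#' @param fraction_number 1-based fraction indices (unique).
#' @param buoyant_density BD in g/ml; must lie in (1.60, 1.85).
#' @param copies_16S Non-negative 16S copy totals per fraction.
#' @return A data frame of class `gradient_run`.
#' @export
gradient_run <- function(treatment, fraction_number, buoyant_density,
                         copies_16S) {
  treatment <- as.character(treatment)
  assert_that(all(treatment %in% c("12C", "13C")),
              "treatment must be '12C' or '13C'")
  n <- length(fraction_number)
  assert_that(length(buoyant_density) == n && length(copies_16S) == n,
              "fraction_number, buoyant_density and copies_16S lengths differ")
  assert_that(all(fraction_number >= 1 & fraction_number == floor(fraction_number)),
              "fraction_number must be 1-based integers")
  assert_that(!anyDuplicated(fraction_number),
              "fraction numbers must be unique within a run")
  assert_that(all(buoyant_density > 1.60 & buoyant_density < 1.85),
              "buoyant_density must lie in (1.60, 1.85) g/ml")
  assert_that(all(copies_16S >= 0), "copies_16S must be non-negative")

  out <- data.frame(treatment = rep_len(treatment, n),
                    fraction_number = as.integer(fraction_number),
                    buoyant_density = as.numeric(buoyant_density),
                    copies_16S = as.numeric(copies_16S))
  out <- out[order(out$fraction_number), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gradient_run", "data.frame")
  out
}

#' Light/heavy buoyant-density windows
#'
#' Closed BD intervals delimiting the light (unlabelled) and heavy (labelled)
#' DNA fractions. The packaged defaults are the windows used to stratify the
#' motivating SIP experiment: light 1.7042-1.7089 g/ml, heavy 1.7342-1.7411
#' g/ml.
#'
#' @param light_lo,light_hi,heavy_lo,heavy_hi Window bounds in g/ml; must
#'   satisfy `light_lo <= light_hi < heavy_lo <= heavy_hi` (a window may
#'   degenerate to a single density when it spans one fraction).
#' @param fallback Logical flag set by [identify_windows()] when detection
#'   failed and the packaged defaults were returned.
#' @return An object of class `fraction_windows`.
#' @export
fraction_windows <- function(light_lo = 1.7042, light_hi = 1.7089,
                             heavy_lo = 1.7342, heavy_hi = 1.7411,
                             fallback = FALSE) {
  assert_that(light_lo <= light_hi && light_hi < heavy_lo && heavy_lo <= heavy_hi,
              "windows must satisfy light_lo <= light_hi < heavy_lo <= heavy_hi")
  structure(list(light_lo = light_lo, light_hi = light_hi,
                 heavy_lo = heavy_lo, heavy_hi = heavy_hi,
                 fallback = isTRUE(fallback)),
            class = "fraction_windows")
}

#' @export
print.fraction_windows <- function(x, ...) {
  cat(sprintf("fraction windows (g/ml): light [%.4f, %.4f], heavy [%.4f, %.4f]%s\n",
              x$light_lo, x$light_hi, x$heavy_lo, x$heavy_hi,
              if (x$fallback) " (fallback defaults)" else ""))
  invisible(x)
}

#' Fit the buoyant-density vs fraction-number relationship
#'
#' Ordinary least squares of BD on fraction number, the standard check that a
#' gradient formed linearly, with the Pearson correlation as the quality
#' statistic.
#'
#' @param run A [gradient_run()] with at least 3 fractions.
#' @return A list with `slope`, `intercept`, `r` (Pearson correlation, `NA`
#'   when BD is constant) and `degenerate` (TRUE when BD has zero variance).
#' @export
fit_bd_vs_fraction <- function(run) {
  assert_that(inherits(run, "gradient_run") || is.data.frame(run),
              "run must be a gradient_run")
  assert_that(nrow(run) >= 3, "at least 3 fractions are required for the fit")
  x <- run$fraction_number
  y <- run$buoyant_density
  if (stats::sd(y) == 0) {
    return(list(slope = 0, intercept = y[1], r = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y),
       degenerate = FALSE)
}

# longest TRUE run in a logical vector; ties broken by largest `weight` sum.
# Returns integer indices of the winning block, or integer(0).
longest_true_block <- function(flag, weight = rep(1, length(flag))) {
  if (!any(flag)) return(integer(0))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  len <- r$lengths[cand]
  best <- cand[len == max(len)]
  if (length(best) > 1L) {
    sums <- vapply(best, function(j) sum(weight[starts[j]:ends[j]]), numeric(1))
    best <- best[which.max(sums)]
  }
  seq.int(starts[best], ends[best])
}

#' Identify light and heavy DNA windows from paired gradient runs
#'
#' Compares total-copy-normalised 16S abundance between the 13C and 12C runs
#' across matched fraction numbers. The heavy window is the BD span of the
#' longest contiguous block of fractions above `bd_split` in which the
#' normalised 13C copies exceed the 12C copies by at least `ratio_min`
#' (ties broken by total 13C copies). The light window is the BD span of the
#' contiguous block of fractions below `bd_split` containing the 12C copy peak
#' and extending while copies stay above `light_rel` of the peak. When no
#' qualifying heavy block exists (e.g. an unlabelled experiment) the packaged
#' default windows are returned with `fallback = TRUE`.
#'
#' @param run12,run13 [gradient_run()]s for the 12C and 13C treatments with
#'   matching fraction numbers.
#' @param bd_split BD (g/ml) separating the light and heavy search regions.
#' @param ratio_min Minimum normalised 13C/12C copy ratio for a heavy fraction.
#' @param light_rel Fraction of the sub-split copy peak a fraction must reach
#'   to join the light block.
#' @return A [fraction_windows()] object.
#' @export
identify_windows <- function(run12, run13, bd_split = 1.72, ratio_min = 1.5,
                             light_rel = 0.5) {
  assert_that(nrow(run12) > 0 && nrow(run13) > 0, "runs must be non-empty")
  m <- merge(as.data.frame(run12), as.data.frame(run13),
             by = "fraction_number", suffixes = c("_12", "_13"))
  assert_that(nrow(m) > 0, "runs share no fraction numbers")
  m <- m[order(m$fraction_number), ]
  assert_that(sum(m$copies_16S_12) > 0 && sum(m$copies_16S_13) > 0,
              "a run has zero total copies")
  n12 <- m$copies_16S_12 / sum(m$copies_16S_12)
  n13 <- m$copies_16S_13 / sum(m$copies_16S_13)

  heavy_flag <- m$buoyant_density_13 > bd_split & n13 >= ratio_min * n12
  heavy_idx <- longest_true_block(heavy_flag, n13)

  light_region <- m$buoyant_density_12 < bd_split
  light_idx <- integer(0)
  if (any(light_region)) {
    peak <- which(light_region)[which.max(n12[light_region])]
    ok <- light_region & n12 >= light_rel * n12[peak]
    # contiguous block containing the peak
    blocks <- rle(ok)
    ends <- cumsum(blocks$lengths)
    starts <- ends - blocks$lengths + 1L
    j <- which(starts <= peak & ends >= peak & blocks$values)
    if (length(j)) light_idx <- seq.int(starts[j], ends[j])
  }

  if (!length(heavy_idx) || !length(light_idx)) {
    return(fraction_windows(fallback = TRUE))
  }
  w <- tryCatch(
    fraction_windows(light_lo = min(m$buoyant_density_12[light_idx]),
                     light_hi = max(m$buoyant_density_12[light_idx]),
                     heavy_lo = min(m$buoyant_density_13[heavy_idx]),
                     heavy_hi = max(m$buoyant_density_13[heavy_idx]),
                     fallback = FALSE),
    error = function(e) fraction_windows(fallback = TRUE))
  w
}

#' Classify a buoyant density into light/heavy/neither
#'
#' Windows are closed intervals: densities equal to a bound are inside.
#'
#' @param bd Buoyant density (g/ml); vectorised.
#' @param windows A [fraction_windows()].
#' @return Character vector of `"light"`, `"heavy"` or `"neither"`.
#' @examples
#' classify_fraction(c(1.7060, 1.7375, 1.7200), fraction_windows())
#' @export
classify_fraction <- function(bd, windows = fraction_windows()) {
  assert_that(inherits(windows, "fraction_windows"),
              "windows must be a fraction_windows object")
  out <- rep("neither", length(bd))
  out[bd >= windows$light_lo & bd <= windows$light_hi] <- "light"
  out[bd >= windows$heavy_lo & bd <= windows$heavy_hi] <- "heavy"
  out
}
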