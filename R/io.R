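# Plain-text interchange formats: UTF-8, header row, '.' decimal.

#' Write / read an ASV relative-abundance table (TSV)
#'
#' Columns: `asv_id`, optional `taxonomy`, then one numeric column per
#' `<treatment>_<fraction>` key.
#'
#' @param table An [asv_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path) {
  assert_that(inherits(table, "asv_table"), "table must be an asv_table")
  df <- data.frame(asv_id = rownames(table$abundance),
                   check.names = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  df <- cbind(df, as.data.frame(table$abundance, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_asv_table
#' @param check_sums Warn when a column sum deviates from 1 by more than 1e-4.
#' @return `read_asv_table()`: an [asv_table()].
#' @export
read_asv_table <- function(path, check_sums = TRUE) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  assert_that("asv_id" %in% names(df), "missing required column 'asv_id'")
  taxonomy <- if ("taxonomy" %in% names(df)) df$taxonomy else NULL
  value_cols <- setdiff(names(df), c("asv_id", "taxonomy"))
  assert_that(length(value_cols) > 0, "no abundance columns found")
  bad_names <- value_cols[!grepl("^1[23]C_\\d+$", value_cols)]
  assert_that(length(bad_names) == 0,
              "malformed fraction columns: %s", paste(bad_names, collapse = ", "))
  for (cn in value_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort("non-numeric abundance at row %d, column '%s'", bad_row, cn)
    }
    if (anyNA(v)) abort("missing abundance at row %d, column '%s'",
                        which(is.na(v))[1], cn)
    if (any(v < 0)) abort("negative abundance at row %d, column '%s'",
                          which(v < 0)[1], cn)
  }
  m <- as.matrix(df[, value_cols, drop = FALSE])
  rownames(m) <- df$asv_id
  if (check_sums) asv_table(m, taxonomy) else
    suppressWarnings(asv_table(m, taxonomy))
}

#' Write / read fraction metadata (CSV)
#'
#' Columns: `treatment`, `fraction_number`, `buoyant_density_g_ml`,
#' `copies_16S`. One file may hold both treatments.
#'
#' @param fractions A [gradient_run()] or row-bound pair of runs.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fractions <- function(fractions, path) {
  df <- data.frame(treatment = fractions$treatment,
                   fraction_number = fractions$fraction_number,
                   buoyant_density_g_ml = fractions$buoyant_density,
                   copies_16S = fractions$copies_16S)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_fractions
#' @return `read_fractions()`: a data frame with one [gradient_run()] per
#'   treatment, row-bound (columns `treatment`, `fraction_number`,
#'   `buoyant_density`, `copies_16S`).
#' @export
read_fractions <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("treatment", "fraction_number", "buoyant_density_g_ml",
            "copies_16S")
  missing <- setdiff(need, names(df))
  assert_that(length(missing) == 0,
              "missing fraction columns: %s", paste(missing, collapse = ", "))
  runs <- lapply(split(df, df$treatment), function(d) {
    gradient_run(d$treatment, d$fraction_number, d$buoyant_density_g_ml,
                 d$copies_16S)
  })
  out <- do.call(rbind, unname(runs))
  class(out) <- c("gradient_run", "data.frame")
  out
}

#' Write / read single-cell spectra (long CSV)
#'
#' Columns: `cell_id`, `treatment`, `wavenumber_cm1`, `intensity`. Rows may be
#' in any order; cells are reassembled on ascending wavenumber grids. Cells
#' with fewer than `min_points` points, or duplicated
#' `(cell_id, wavenumber)` pairs, are rejected.
#'
#' @param spectra List of [raman_spectrum()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  rows <- lapply(spectra, function(s) {
    data.frame(cell_id = s$cell_id, treatment = s$treatment,
               wavenumber_cm1 = s$wavenumber, intensity = s$intensity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spectra
#' @param min_points Minimum points per cell (default 50).
#' @return `read_spectra()`: a list of [raman_spectrum()] objects, ordered by
#'   cell id.
#' @export
read_spectra <- function(path, min_points = 50L) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("cell_id", "treatment", "wavenumber_cm1", "intensity")
  missing <- setdiff(need, names(df))
  assert_that(length(missing) == 0,
              "missing spectra columns: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df[, c("cell_id", "wavenumber_cm1")])) {
    dup <- df[duplicated(df[, c("cell_id", "wavenumber_cm1")]), ][1, ]
    abort("duplicated (cell_id, wavenumber) pair: %s at %.2f 1/cm",
          dup$cell_id, dup$wavenumber_cm1)
  }
  cells <- split(df, df$cell_id)
  out <- lapply(cells, function(d) {
    if (nrow(d) < min_points) {
      abort("cell %s has %d points (< %d required)",
            d$cell_id[1], nrow(d), min_points)
    }
    d <- d[order(d$wavenumber_cm1), ]
    raman_spectrum(d$cell_id[1], d$treatment[1], d$wavenumber_cm1, d$intensity)
  })
  out[order(names(out))]
}

#' Write / read light-heavy windows (JSON)
#'
#' Format: `{"light": [lo, hi], "heavy": [lo, hi], "fallback": bool}`.
#'
#' @param windows A [fraction_windows()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  jsonlite::write_json(
    list(light = c(windows$light_lo, windows$light_hi),
         heavy = c(windows$heavy_lo, windows$heavy_hi),
         fallback = windows$fallback),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_windows
#' @return `read_windows()`: a [fraction_windows()].
#' @export
read_windows <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fraction_windows(light_lo = x$light[1], light_hi = x$light[2],
                   heavy_lo = x$heavy[1], heavy_hi = x$heavy[2],
                   fallback = isTRUE(x$fallback))
}

#' Write a generic records table as TSV
#'
#' @param records A data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
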