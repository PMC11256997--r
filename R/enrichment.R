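#' Construct an ASV-by-fraction relative-abundance table
#'
#' Rows are ASVs, columns are `<treatment>_<fraction_number>` keys (e.g.
#' `13C_5`), values are relative abundances that sum to 1 within each column.
#'
#' @param abundance Numeric matrix with ASV ids as rownames and fraction keys
#'   as colnames.
#' @param taxonomy Optional character vector of taxonomy labels, named by or
#'   aligned with the ASV ids.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(abundance, taxonomy = NULL) {
  assert_that(is.matrix(abundance) && is.numeric(abundance),
              "abundance must be a numeric matrix")
  assert_that(!is.null(rownames(abundance)) && !is.null(colnames(abundance)),
              "abundance needs ASV rownames and treatment_fraction colnames")
  assert_that(all(abundance >= 0), "abundances must be non-negative")
  assert_that(all(grepl("^1[23]C_\\d+$", colnames(abundance))),
              "colnames must follow '<treatment>_<fraction>', e.g. '13C_5'")
  sums <- colSums(abundance)
  off <- abs(sums - 1) > 1e-4
  if (any(off)) {
    warning(sprintf("column sums deviate from 1 by > 1e-4: %s",
                    paste(colnames(abundance)[off], collapse = ", ")),
            call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    assert_that(length(taxonomy) == nrow(abundance),
                "taxonomy must have one label per ASV")
    taxonomy <- stats::setNames(as.character(taxonomy), rownames(abundance))
  }
  structure(list(abundance = abundance, taxonomy = taxonomy),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d ASVs x %d treatment-fraction columns\n",
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

# fraction keys falling inside one window for one treatment
window_columns <- function(table, windows, fractions, treatment, window) {
  f <- fractions[fractions$treatment == treatment, , drop = FALSE]
  cls <- classify_fraction(f$buoyant_density, windows)
  keys <- fraction_key(treatment, f$fraction_number[cls == window])
  keys <- intersect(keys, colnames(table$abundance))
  if (!length(keys)) {
    abort("no %s-treatment fractions fall in the %s window", treatment, window)
  }
  keys
}

#' Aggregate ASV abundances over the light and heavy windows
#'
#' For each ASV, the aggregate for a (treatment, window) pair is the unweighted
#' arithmetic mean of its relative abundance over the fractions whose buoyant
#' density falls inside that window.
#'
#' @param table An [asv_table()].
#' @param windows A [fraction_windows()].
#' @param fractions Data frame of fraction metadata for both treatments
#'   (columns `treatment`, `fraction_number`, `buoyant_density`), e.g. the
#'   `fractions` element of [simulate_gradient_experiment()].
#' @return Data frame with columns `asv_id`, `A13_heavy`, `A13_light`,
#'   `A12_heavy`, `A12_light`.
#' @export
aggregate_window_abundance <- function(table, windows, fractions) {
  assert_that(inherits(table, "asv_table"), "table must be an asv_table")
  cols <- list(
    A13_heavy = window_columns(table, windows, fractions, "13C", "heavy"),
    A13_light = window_columns(table, windows, fractions, "13C", "light"),
    A12_heavy = window_columns(table, windows, fractions, "12C", "heavy"),
    A12_light = window_columns(table, windows, fractions, "12C", "light"))
  agg <- vapply(cols, function(k) {
    rowMeans(table$abundance[, k, drop = FALSE])
  }, numeric(nrow(table$abundance)))
  out <- data.frame(asv_id = rownames(table$abundance), agg,
                    row.names = NULL, check.names = FALSE)
  attr(out, "window_columns") <- cols
  out
}

#' Relative enrichment factor (REF)
#'
#' The ratio-of-ratios statistic comparing an ASV's heavy/light abundance in
#' the 13C treatment against the same contrast in the 12C control:
#' `REF = (A13_heavy / A13_light) / (A12_heavy / A12_light)`.
#' Values above 1 indicate that labelled substrate moved the ASV's DNA into
#' the heavy fractions; the conventional calling threshold is 2.
#'
#' The pseudocount is added to all four terms of an observation only when at
#' least one of them is zero, so worked examples with strictly positive
#' abundances are computed exactly.
#'
#' @param a13h,a13l,a12h,a12l Aggregated relative abundances (vectorised).
#' @param pseudocount Non-negative stabiliser for zero abundances.
#' @return Numeric REF values.
#' @examples
#' compute_ref(0.309, 0.100, 0.050, 0.050, pseudocount = 0)  # 3.09
#' @export
compute_ref <- function(a13h, a13l, a12h, a12l, pseudocount = 1e-6) {
  n <- length(a13h)
  assert_that(length(a13l) == n && length(a12h) == n && length(a12l) == n,
              "the four abundance vectors must have equal length")
  assert_that(all(c(a13h, a13l, a12h, a12l) >= 0),
              "abundances must be non-negative")
  assert_that(is_number(pseudocount) && pseudocount >= 0,
              "pseudocount must be >= 0")
  eps <- ifelse(a13h == 0 | a13l == 0 | a12h == 0 | a12l == 0, pseudocount, 0)
  ref <- ((a13h + eps) / (a13l + eps)) / ((a12h + eps) / (a12l + eps))
  if (any(!is.finite(ref))) {
    abort("REF undefined for %d observation(s): zero abundances with zero pseudocount",
          sum(!is.finite(ref)))
  }
  ref
}

#' Parameters for calling active degraders
#'
#' @param top_n Only ASVs within the top `top_n` by mean windowed relative
#'   abundance are eligible (default 100).
#' @param threshold REF must strictly exceed this value (default 2.0).
#' @param pseudocount Passed to [compute_ref()].
#' @return An object of class `calling_params`.
#' @export
calling_params <- function(top_n = 100L, threshold = 2.0, pseudocount = 1e-6) {
  assert_that(is_count(top_n), "top_n must be a positive integer")
  assert_that(is_number(threshold) && threshold > 0, "threshold must be > 0")
  assert_that(is_number(pseudocount) && pseudocount >= 0,
              "pseudocount must be >= 0")
  structure(list(top_n = as.integer(top_n), threshold = threshold,
                 pseudocount = pseudocount),
            class = "calling_params")
}

#' Call active substrate degraders by REF
#'
#' Ranks ASVs by their mean relative abundance over all windowed fractions of
#' both treatments (descending; ties broken lexicographically by ASV id) and
#' flags as active those with rank at most `top_n` and REF strictly above the
#' threshold.
#'
#' @param table An [asv_table()].
#' @param windows A [fraction_windows()].
#' @param fractions Fraction metadata as in [aggregate_window_abundance()].
#' @param params A [calling_params()].
#' @return Data frame sorted by REF (descending) with columns `asv_id`,
#'   `taxonomy`, `A13_heavy`, `A13_light`, `A12_heavy`, `A12_light`, `REF`,
#'   `rank`, `active`.
#' @examples
#' sim <- simulate_gradient_experiment(paper_mimic_gradient_config(seed = 1))
#' w <- identify_windows(sim$run_12C, sim$run_13C)
#' calls <- call_active_degraders(sim$asv_table, w, sim$fractions)
#' subset(calls, active)
#' @export
call_active_degraders <- function(table, windows, fractions,
                                  params = calling_params()) {
  assert_that(inherits(params, "calling_params"),
              "params must be a calling_params object")
  agg <- aggregate_window_abundance(table, windows, fractions)
  cols <- attr(agg, "window_columns")
  all_window_cols <- unique(unlist(cols))
  mean_ab <- rowMeans(table$abundance[, all_window_cols, drop = FALSE])

  n_asv <- nrow(agg)
  top_n <- params$top_n
  if (n_asv < top_n) {
    warning(sprintf("only %d ASVs available; top_n reduced from %d",
                    n_asv, top_n), call. = FALSE)
    top_n <- n_asv
  }
  ord <- order(-mean_ab, agg$asv_id)
  rank <- integer(n_asv)
  rank[ord] <- seq_len(n_asv)

  ref <- compute_ref(agg$A13_heavy, agg$A13_light, agg$A12_heavy,
                     agg$A12_light, params$pseudocount)
  taxonomy <- if (is.null(table$taxonomy)) NA_character_ else
    unname(table$taxonomy[agg$asv_id])

  out <- data.frame(asv_id = agg$asv_id,
                    taxonomy = taxonomy,
                    A13_heavy = agg$A13_heavy,
                    A13_light = agg$A13_light,
                    A12_heavy = agg$A12_heavy,
                    A12_light = agg$A12_light,
                    REF = ref,
                    rank = rank,
                    active = rank <= top_n & ref > params$threshold,
                    row.names = NULL)
  out <- out[order(-out$REF, out$asv_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
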