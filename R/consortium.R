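#' Genome-directed medium supplementation rules
#'
#' The packaged, editable rule table mapping gene-annotation keywords to
#' medium supplements: vitamin-metabolism genes trigger a vitamin stock,
#' trace-metal transport genes a mineral stock, an aminoglycoside-resistance
#' gene streptomycin (selecting for the resistant target), and L-lactate
#' dehydrogenase L-lactate as an auxiliary carbon source.
#'
#' @return Data frame with columns `rule`, `pattern` (case-insensitive regex),
#'   `component`, `amount`, `unit`.
#' @export
medium_rules <- function() {
  data.frame(
    rule = c("vitamin_metabolism", "trace_metal_transport",
             "aminoglycoside_resistance", "lactate_dehydrogenase"),
    pattern = c(
      paste0("vitamin|thiamin|riboflavin|niacin|nicotinate|pyridox|biotin|",
             "cobalamin|lipoic|pantothen|folate|retinol"),
      paste0("trace[- ]metal|metal transport|calcium|copper|zinc|cobalt|",
             "sodium|molybd|nickel|\\b(ca|cu|zn|co|na|mo|ni)\\b[^,;]*transport"),
      "aminoglycoside",
      "l-?lactate dehydrogenase|\\bldh\\b"),
    component = c("vitamin stock solution", "mineral stock solution",
                  "streptomycin", "L-lactate"),
    amount = c(10, 10, 5, 50),
    unit = c("ml/L", "ml/L", "mg/L", "mM"),
    stringsAsFactors = FALSE)
}

#' Recommend a cultivation medium from genome annotations
#'
#' Applies the [medium_rules()] table to a set of free-text gene annotations:
#' every rule whose pattern matches at least one annotation contributes its
#' supplement once, citing the first matching annotation as the trigger.
#' Matching is case-insensitive; blank annotation lines are skipped with a
#' warning.
#'
#' @param annotations Character vector of gene-annotation labels for a genome
#'   bin.
#' @param base Name of the base medium.
#' @param rules Rule table as produced by [medium_rules()].
#' @return An object of class `medium_recipe`: a list with `base` and
#'   `supplements` (data frame `component`, `amount`, `unit`, `rule`,
#'   `trigger`).
#' @examples
#' recommend_medium(c("aminoglycoside resistance protein",
#'                    "L-lactate dehydrogenase"))
#' @export
recommend_medium <- function(annotations,
                             base = "modified minimal (MM) medium",
                             rules = medium_rules()) {
  annotations <- as.character(annotations %||% character())
  bad <- is.na(annotations) | !nzchar(trimws(annotations))
  if (any(bad)) {
    warning(sprintf("skipping %d unparseable annotation line(s)", sum(bad)),
            call. = FALSE)
    annotations <- annotations[!bad]
  }
  hits <- lapply(seq_len(nrow(rules)), function(i) {
    m <- grepl(rules$pattern[i], annotations, ignore.case = TRUE, perl = TRUE)
    if (!any(m)) return(NULL)
    data.frame(component = rules$component[i],
               amount = rules$amount[i],
               unit = rules$unit[i],
               rule = rules$rule[i],
               trigger = annotations[which(m)[1]],
               stringsAsFactors = FALSE)
  })
  supplements <- do.call(rbind, hits)
  if (is.null(supplements)) {
    supplements <- data.frame(component = character(), amount = numeric(),
                              unit = character(), rule = character(),
                              trigger = character(), stringsAsFactors = FALSE)
  }
  structure(list(base = base, supplements = supplements),
            class = "medium_recipe")
}

#' @export
print.medium_recipe <- function(x, ...) {
  cat("medium recipe — base:", x$base, "\n")
  if (!nrow(x$supplements)) {
    cat("  no supplements\n")
  } else {
    for (i in seq_len(nrow(x$supplements))) {
      s <- x$supplements[i, ]
      cat(sprintf("  + %g %s %s  [%s: %s]\n", s$amount, s$unit, s$component,
                  s$rule, s$trigger))
    }
  }
  invisible(x)
}

#' Design a two-strain consortium inoculation ratio
#'
#' Snaps the log2 abundance ratio of two strains to the nearest of the tested
#' CFU mixing ratios 2:1, 1:1 and 1:2 (log2 ratios +1, 0, -1); exact midpoints
#' snap toward 1:1.
#'
#' @param abundance_a,abundance_b Positive abundances (relative abundance,
#'   copies, or CFU) of strains A and B.
#' @param strain_a,strain_b Strain labels.
#' @return An object of class `ratio_design`: list with `strain_a`,
#'   `strain_b`, `abundance_a`, `abundance_b`, `log_ratio`,
#'   `recommended_ratio` (one of `"2:1"`, `"1:1"`, `"1:2"`).
#' @examples
#' design_ratios(0.10, 0.05)  # 2:1
#' @export
design_ratios <- function(abundance_a, abundance_b,
                          strain_a = "JB-1", strain_b = "JB-2") {
  assert_that(is_number(abundance_a) && abundance_a > 0,
              "abundance_a must be a positive number")
  assert_that(is_number(abundance_b) && abundance_b > 0,
              "abundance_b must be a positive number")
  lr <- log2(abundance_a / abundance_b)
  candidates <- c(`2:1` = 1, `1:1` = 0, `1:2` = -1)
  d <- abs(lr - candidates)
  # midpoint ties (within numerical tolerance) snap toward 1:1
  tied <- d - min(d) < 1e-9
  ord <- order(!tied, c(2, 1, 2))
  structure(list(strain_a = strain_a, strain_b = strain_b,
                 abundance_a = abundance_a, abundance_b = abundance_b,
                 log_ratio = lr,
                 recommended_ratio = names(candidates)[ord[1]]),
            class = "ratio_design")
}

#' @export
print.ratio_design <- function(x, ...) {
  cat(sprintf("consortium design: %s:%s = %s (log2 abundance ratio %.3f)\n",
              x$strain_a, x$strain_b, x$recommended_ratio, x$log_ratio))
  invisible(x)
}

#' Substrate degradation efficiency
#'
#' Percent removal `100 * (c0 - ct) / c0`, clipped at 0 from below (apparent
#' production is reported as 0) and not clipped above. Optionally subtracts
#' the abiotic removal observed in a sterile control.
#'
#' @param c0 Initial concentration (> 0), e.g. mg/L at day 0.
#' @param ct Concentration at the sampling time (>= 0).
#' @param control_c0,control_ct Matching sterile-control concentrations; used
#'   only when `control_corrected = TRUE`.
#' @param control_corrected Subtract the control's removal fraction (default
#'   `FALSE`, matching raw-removal reporting).
#' @return Efficiency in percent (vectorised).
#' @examples
#' degradation_efficiency(50, 4.65)  # 90.7
#' @export
degradation_efficiency <- function(c0, ct, control_c0 = NULL,
                                   control_ct = NULL,
                                   control_corrected = FALSE) {
  assert_that(all(c0 > 0), "c0 must be > 0")
  assert_that(all(ct >= 0), "ct must be >= 0")
  eff <- 100 * (c0 - ct) / c0
  if (isTRUE(control_corrected)) {
    assert_that(!is.null(control_c0) && !is.null(control_ct),
                "control concentrations required when control_corrected = TRUE")
    assert_that(all(control_c0 > 0), "control_c0 must be > 0")
    eff <- eff - 100 * (control_c0 - control_ct) / control_c0
  }
  pmax(eff, 0)
}
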