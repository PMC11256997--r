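#' Pipeline configuration
#'
#' Bundles input paths and stage parameters for [run_pipeline()]. Either the
#' three file paths (as written by [write_fixture()]) or in-memory objects may
#' be supplied.
#'
#' @param asv_table_path TSV path of the ASV-by-fraction table.
#' @param fractions_path CSV path of fraction metadata (both treatments).
#' @param spectra_path CSV path of long-format single-cell spectra.
#' @param annotations Character vector of gene annotations for medium design
#'   (optional; empty means base medium only).
#' @param out_dir Output directory for stage artifacts.
#' @param calling A [calling_params()].
#' @param bd_split,ratio_min Window-detection parameters, see
#'   [identify_windows()].
#' @param raman List of Raman parameters (`lam`, `p`, `n_iter`, `k`).
#' @param seed Integer seed recorded in the report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(asv_table_path, fractions_path, spectra_path,
                            annotations = character(),
                            out_dir = tempfile("sipracs_out_"),
                            calling = calling_params(),
                            bd_split = 1.72, ratio_min = 1.5,
                            raman = list(lam = 1e5, p = 0.01, n_iter = 10L,
                                         k = 3),
                            seed = 1L) {
  for (p in c(asv_table_path, fractions_path, spectra_path)) {
    assert_that(file.exists(p), "input file not found: %s", p)
  }
  structure(list(asv_table_path = asv_table_path,
                 fractions_path = fractions_path,
                 spectra_path = spectra_path,
                 annotations = annotations,
                 out_dir = out_dir,
                 calling = calling,
                 bd_split = bd_split,
                 ratio_min = ratio_min,
                 raman = raman,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full SIP-RACS analysis pipeline
#'
#' Stages, in the order of the wet-lab workflow they emulate: read inputs;
#' identify light/heavy windows from the paired gradients; call active
#' degraders by REF; classify single cells by the phenylalanine-band redshift
#' and build the sorting manifest; recommend a cultivation medium from gene
#' annotations; design the two-strain inoculation ratio from the top two
#' active ASVs' heavy-window abundances. Writes `windows.json`,
#' `ref_calls.tsv`, `label_calls.tsv`, `sorting_manifest.txt`, `medium.json`,
#' `ratios.json` and `report.json` to the output directory.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly: a list with stage summaries, counts and all
#'   parameter values actually used (including window fallback status).
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  table <- run_stage("read_asv_table", read_asv_table(config$asv_table_path))
  fractions <- run_stage("read_fractions", read_fractions(config$fractions_path))
  spectra <- run_stage("read_spectra", read_spectra(config$spectra_path))

  run12 <- fractions[fractions$treatment == "12C", ]
  run13 <- fractions[fractions$treatment == "13C", ]
  assert_that(nrow(run12) > 0 && nrow(run13) > 0,
              "fractions file must contain both 12C and 13C treatments")

  windows <- run_stage("identify_windows",
                       identify_windows(run12, run13,
                                        bd_split = config$bd_split,
                                        ratio_min = config$ratio_min))
  write_windows(windows, out("windows.json"))

  ref_calls <- run_stage("call_active_degraders",
                         call_active_degraders(table, windows, fractions,
                                               config$calling))
  write_tsv(ref_calls, out("ref_calls.tsv"))
  active <- ref_calls[ref_calls$active, , drop = FALSE]

  label_calls <- run_stage("classify_cells",
                           classify_cells(spectra,
                                          lam = config$raman$lam,
                                          p = config$raman$p,
                                          n_iter = config$raman$n_iter,
                                          k = config$raman$k))
  write_tsv(label_calls, out("label_calls.tsv"))
  manifest <- build_sorting_manifest(label_calls)
  writeLines(c(sprintf("# %d cell(s) to sort", manifest$n),
               sprintf("%s\t%.1f", manifest$cells$cell_id,
                       manifest$cells$band_position)),
             out("sorting_manifest.txt"))

  medium <- run_stage("recommend_medium", recommend_medium(config$annotations))
  jsonlite::write_json(list(base = medium$base,
                            supplements = medium$supplements),
                       out("medium.json"), auto_unbox = TRUE, digits = NA)

  ratios <- NULL
  if (nrow(active) >= 2) {
    ratios <- design_ratios(active$A13_heavy[1], active$A13_heavy[2],
                            strain_a = active$asv_id[1],
                            strain_b = active$asv_id[2])
    jsonlite::write_json(unclass(ratios), out("ratios.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  report <- list(
    parameters = list(seed = config$seed,
                      calling = unclass(config$calling),
                      bd_split = config$bd_split,
                      ratio_min = config$ratio_min,
                      raman = config$raman,
                      windows_fallback = windows$fallback),
    windows = list(light = c(windows$light_lo, windows$light_hi),
                   heavy = c(windows$heavy_lo, windows$heavy_hi)),
    n_asvs = nrow(ref_calls),
    n_active = nrow(active),
    active_asvs = active$asv_id,
    n_cells = length(spectra),
    n_labelled_cells = manifest$n,
    medium_supplements = medium$supplements$component,
    recommended_ratio = if (!is.null(ratios)) ratios$recommended_ratio else NA,
    outputs = c("windows.json", "ref_calls.tsv", "label_calls.tsv",
                "sorting_manifest.txt", "medium.json",
                if (!is.null(ratios)) "ratios.json"))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}
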