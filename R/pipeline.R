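# End-to-end analysis pipeline and run manifest.

#' Run the full analysis pipeline
#'
#' Chains the analysis stages on one input set: compute allelic scores from
#' an intensity table (or take a ready-made ratio table), estimate founder
#' cell numbers per assay, build group summary tables, and (if a Ct table is
#' given) the delta-delta-Ct fold-change table. Each stage's output is
#' written as CSV next to a JSON run manifest recording inputs, parameters,
#' seed and package version. On any stage error the partial outputs are
#' removed.
#'
#' @param intensity_file,ratio_file Exactly one of: path to an intensity
#'   table (scored via [compute_ratios()]) or to a ratio table.
#' @param ct_file Optional path to a Ct table.
#' @param out_prefix Output path prefix (e.g. `"results/run1_"`).
#' @param p_dmr Per-cell methylation probability used for the MP/PM founder
#'   estimates (default 0.1; XI always uses 0.5).
#' @param ddof Variance denominator offset.
#' @param metric,n_min,n_max Distribution-fit options, see
#'   [fit_n_distribution()].
#' @param var_method Variance-equality test for the summaries.
#' @param seed Integer seed recorded in the manifest and applied before any
#'   stage (the analysis itself is deterministic; the seed matters when the
#'   input tables were simulated in the same session).
#' @return Invisibly, a list with the output file paths and the manifest.
#' @export
run_pipeline <- function(intensity_file = NULL, ratio_file = NULL,
                         ct_file = NULL, out_prefix = "epifounder_",
                         p_dmr = 0.1, ddof = 1,
                         metric = c("chi2_binned", "ks"),
                         n_min = 1, n_max = 100,
                         var_method = c("levene_median", "f_test"),
                         seed = NULL) {
  metric <- match.arg(metric)
  var_method <- match.arg(var_method)
  if (is.null(intensity_file) == is.null(ratio_file)) {
    abort("supply exactly one of `intensity_file` or `ratio_file`")
  }
  if (!is.null(seed)) set.seed(seed)

  written <- character(0)
  emit <- function(df, name) {
    path <- paste0(out_prefix, name, ".csv")
    write_table(df, path)
    written <<- c(written, path)
    path
  }

  tryCatch({
    ratios <- if (!is.null(intensity_file)) {
      compute_ratios(read_intensity_table(intensity_file))
    } else {
      read_ratio_table(ratio_file)
    }
    emit(ratios, "ratios")

    assays <- intersect(ef_score_kinds(), unique(ratios$score_kind))
    founders <- purrr::map(assays, function(a) {
      p_assay <- if (a == "XI") 0.5 else p_dmr
      tidy(estimate_founders(ratios, assay = a, p = p_assay, ddof = ddof,
                             metric = metric, n_min = n_min, n_max = n_max))
    }) |> dplyr::bind_rows()
    emit(founders, "founders")

    summaries <- purrr::map(assays, function(a) {
      summarize_groups(ratios, assay = a, var_method = var_method,
                       ddof = ddof) |>
        dplyr::mutate(assay = a, .before = 1)
    }) |> dplyr::bind_rows()
    emit(summaries, "summary")

    fold_changes <- NULL
    if (!is.null(ct_file)) {
      fold_changes <- ddct_table(read_ct_table(ct_file))
      emit(fold_changes, "fold_changes")
    }

    manifest <- list(
      inputs = list(intensity = intensity_file, ratio = ratio_file,
                    ct = ct_file),
      parameters = list(p_dmr = p_dmr, ddof = ddof, metric = metric,
                        n_min = n_min, n_max = n_max,
                        var_method = var_method),
      seed = seed,
      package_version = as.character(packageVersion("epifounder")),
      outputs = written,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    manifest_path <- paste0(out_prefix, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
    written <- c(written, manifest_path)

    invisible(list(outputs = written, manifest = manifest,
                   ratios = ratios, founders = founders,
                   summary = summaries, fold_changes = fold_changes))
  }, error = function(e) {
    unlink(written)
    abort(sprintf("pipeline failed (partial outputs removed): %s",
                  conditionMessage(e)), parent = e)
  })
}

#' Simulate a cohort and write its tables
#'
#' Runs [simulate_cohort()] and writes the ratio and Ct tables plus a JSON
#' manifest of the configuration.
#'
#' @param config A [cohort_config()], or a path to a YAML file for
#'   [read_cohort_config()].
#' @param out_prefix Output path prefix.
#' @return Invisibly, a list of output paths and the simulated tables.
#' @export
run_simulate <- function(config, out_prefix = "sim_") {
  if (is.character(config)) config <- read_cohort_config(config)
  sim <- simulate_cohort(config)
  ratio_path <- paste0(out_prefix, "ratios.csv")
  ct_path <- paste0(out_prefix, "ct.csv")
  write_table(sim$ratios, ratio_path)
  write_table(sim$ct, ct_path)
  manifest <- c(
    unclass(config)[setdiff(names(unclass(config)),
                            c("fold_effects", "ct_baselines"))],
    list(
      fold_effects = config$fold_effects,
      ct_baselines = as.list(config$ct_baselines),
      package_version = as.character(packageVersion("epifounder")),
      outputs = c(ratio_path, ct_path),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  manifest_path <- paste0(out_prefix, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(outputs = c(ratio_path, ct_path, manifest_path),
                 ratios = sim$ratios, ct = sim$ct))
}
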