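#' Run the tiling-screen-to-docking-box pipeline
#'
#' Orchestrates the full analysis path: count-table QC, fold changes and
#' low-frequency filtering, control calibration to NCS, per-residue
#' averaging and Gaussian smoothing, hypersensitive-segment calling, and —
#' when a structure is supplied — structure mapping, annotation files,
#' docking-box definition and a Vina config. When docking-engine outputs are
#' supplied their scores are parsed and the binder-selection rule applied.
#' Later stages are skipped cleanly when their inputs are absent.
#'
#' @param counts_path guide x sample count TSV.
#' @param manifest_path sgRNA library manifest TSV.
#' @param samples_path optional sample-metadata sidecar TSV.
#' @param structure_path optional PDB/mmCIF file.
#' @param chain chain id for the structure (default first).
#' @param offset profile-to-structure residue-number offset (default 0).
#' @param dock_paths optional docking-engine output files.
#' @param out_dir output directory for artifacts and the JSON run report.
#' @param pseudocount,filter_fraction see \code{\link{fold_change_table}}.
#' @param sigma_aa,truncate see \code{\link{smooth_profile}}.
#' @param threshold,min_len,merge_gap,domain_window see
#'   \code{\link{call_segments}}.
#' @param padding,cube see \code{\link{define_box}}.
#' @param top_n,dg_cutoff_kj see \code{\link{select_binders}}; defaults
#'   follow the published top-500 / <= -11.6 kJ/mol rule.
#' @return list of class \code{run_report} (also written as
#'   \code{report.json} under \code{out_dir}).
#' @export
run_tiling_pipeline <- function(counts_path, manifest_path,
                                samples_path = NULL, structure_path = NULL,
                                chain = NULL, offset = 0, dock_paths = NULL,
                                out_dir = tempfile("tica_run_"),
                                pseudocount = 1, filter_fraction = 0.05,
                                sigma_aa = 5.0, truncate = 3.0,
                                threshold = -0.5, min_len = 3, merge_gap = 2,
                                domain_window = NULL, padding = 6.0,
                                cube = TRUE, top_n = 500,
                                dg_cutoff_kj = -11.6) {
  config <- list(counts = counts_path, manifest = manifest_path,
                 samples = samples_path, structure = structure_path,
                 chain = chain, offset = offset,
                 dock_outputs = dock_paths, pseudocount = pseudocount,
                 filter_fraction = filter_fraction, sigma_aa = sigma_aa,
                 truncate = truncate, threshold = threshold,
                 min_len = min_len, merge_gap = merge_gap,
                 domain_window = domain_window, padding = padding,
                 cube = cube, top_n = top_n, dg_cutoff_kj = dg_cutoff_kj)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log,
                         sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e)
      stop_("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  guides <- stage("io_screens", read_guide_library(manifest_path))
  tab <- stage("io_screens", read_count_table(counts_path, samples_path))
  rpm <- stage("io_screens", rpm_normalize(tab, pseudocount))
  d0 <- which(tab$samples$timepoint == "day0")[1]
  qc <- stage("io_screens", library_qc(rpm[, d0]))
  fc <- stage("io_screens",
              fold_change_table(tab, pseudocount, filter_fraction))
  cal <- stage("tiling", calibrate_ncs(fc, guides))
  raw <- stage("tiling", assign_guides_to_residues(cal$ncs, guides))
  profile <- stage("tiling", smooth_profile(raw, sigma_aa, truncate))
  segs <- stage("tiling", call_segments(profile, threshold, min_len,
                                        merge_gap, domain_window))
  write_profile_tsv(profile, file.path(out_dir, "profile.tsv"))
  write_segments(segs, file.path(out_dir, "segments.tsv"))

  report <- list(
    package_version = as.character(utils::packageVersion("crisprtiles")),
    config = config,
    qc = list(pass = qc$pass, fraction_ge_10rpm = qc$fraction_ge_threshold),
    n_guides = nrow(guides), n_kept = sum(fc$kept),
    calibration = list(m_neg = cal$m_neg, m_pos = cal$m_pos),
    segments = as.data.frame(segs))

  if (!is.null(structure_path)) {
    model <- stage("structmap", load_structure(structure_path, chain))
    smap <- stage("structmap", map_profile(profile, model, offset))
    stage("structmap",
          write_annotations(smap, model, file.path(out_dir, "annotated")))
    report$mapping <- list(n_mapped = attr(smap, "n_mapped"),
                           n_profile_scored = attr(smap, "n_profile_scored"))
    if (nrow(segs)) {
      sel <- stage("pocket", segment_residues(segs, smap))
      box <- stage("pocket", define_box(model, sel, padding, cube))
      write_vina_config(box, file.path(out_dir, "vina_box.conf"))
      report$box <- list(center = box$center, size = box$size,
                         n_residues = length(sel))
    }
  }

  if (!is.null(dock_paths) && length(dock_paths)) {
    scores <- stage("dockrank", parse_engine_output(dock_paths))
    selection <- stage("dockrank",
                       select_binders(scores, top_n, dg_cutoff_kj))
    write_selection_csv(selection, file.path(out_dir, "selection.csv"))
    report$docking <- list(n_scored = nrow(scores),
                           n_selected = nrow(selection),
                           n_failed = length(attr(scores, "failures")),
                           best = if (nrow(selection))
                             selection$compound_id[1] else NA)
  }

  report$warnings <- warnings_log
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  report$out_dir <- out_dir
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat(sprintf("  QC: %s (%.1f%% guides >= 10 RPM)\n",
              if (x$qc$pass) "pass" else "FAIL",
              100 * x$qc$fraction_ge_10rpm))
  cat(sprintf("  guides: %d (%d kept)\n", x$n_guides, x$n_kept))
  cat(sprintf("  calibration medians: neg %.4f, pos %.4f\n",
              x$calibration$m_neg, x$calibration$m_pos))
  cat(sprintf("  segments called: %d\n", nrow(x$segments)))
  if (!is.null(x$box))
    cat(sprintf("  docking box: center (%.2f, %.2f, %.2f), edge %.2f A\n",
                x$box$center[1], x$box$center[2], x$box$center[3],
                x$box$size[1]))
  if (!is.null(x$docking))
    cat(sprintf("  docking: %d scored, %d selected\n",
                x$docking$n_scored, x$docking$n_selected))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
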