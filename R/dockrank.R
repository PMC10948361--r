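KCAL_TO_KJ <- 4.184

#' Parse docking-engine score outputs
#'
#' Reads AutoDock Vina-style outputs and keeps the best (lowest-energy) mode
#' per compound. Two dialects are auto-detected per file: the engine log's
#' \code{mode | affinity} table, and PDBQT \code{REMARK VINA RESULT:} lines.
#' The compound id is the file name stem. Malformed files do not abort the
#' run: they are collected and reported in the \code{failures} attribute
#' (and as a warning).
#'
#' @param paths character vector of log/PDBQT files.
#' @return data frame of class \code{dock_scores}: \code{compound_id},
#'   \code{dg_kcal} (engine-native), \code{dg_kj}.
#' @export
parse_engine_output <- function(paths) {
  rows <- list()
  failures <- character(0)
  for (p in paths) {
    res <- tryCatch(parse_one_engine_file(p), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", p, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(failures))
    warn_("%d docking output file(s) failed to parse:\n%s", length(failures),
          paste(failures, collapse = "\n"))
  if (!length(rows)) {
    out <- data.frame(compound_id = character(0), dg_kcal = numeric(0),
                      dg_kj = numeric(0))
  } else {
    out <- do.call(rbind, rows)
  }
  attr(out, "failures") <- failures
  class(out) <- c("dock_scores", "data.frame")
  out
}

parse_one_engine_file <- function(path) {
  if (!file.exists(path)) stop_("file not found")
  ln <- readLines(path, warn = FALSE)
  id <- sub("\\.[^.]*$", "", basename(path))
  # PDBQT dialect
  rem <- grep("^REMARK VINA RESULT:", ln, value = TRUE)
  if (length(rem)) {
    vals <- suppressWarnings(as.numeric(
      vapply(strsplit(trimws(sub("^REMARK VINA RESULT:", "", rem)),
                      "[[:space:]]+"), `[[`, character(1), 1L)))
    if (anyNA(vals)) stop_("unparsable REMARK VINA RESULT line")
    return(data.frame(compound_id = id, dg_kcal = min(vals),
                      dg_kj = min(vals) * KCAL_TO_KJ))
  }
  # log dialect: table rows "  <mode>  <affinity>  <rmsd lb>  <rmsd ub>"
  tab <- grep("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?\\s+", ln, value = TRUE)
  if (!length(tab)) stop_("no recognizable score lines")
  vals <- suppressWarnings(as.numeric(
    vapply(strsplit(trimws(tab), "[[:space:]]+"), `[[`, character(1), 2L)))
  if (anyNA(vals)) stop_("unparsable affinity column")
  data.frame(compound_id = id, dg_kcal = min(vals),
             dg_kj = min(vals) * KCAL_TO_KJ)
}

#' Convert kcal/mol to kJ/mol
#'
#' Docking engines report affinities in kcal/mol while selection thresholds
#' are often quoted in kJ/mol; the factor is exactly 4.184. Both columns are
#' carried through the pipeline so neither unit is silently misread.
#'
#' @param dg_kcal numeric, kcal/mol.
#' @return numeric, kJ/mol.
#' @export
convert_units <- function(dg_kcal) {
  if (any(!is.finite(dg_kcal))) stop_("non-finite binding energy")
  dg_kcal * KCAL_TO_KJ
}

#' Select predicted binders
#'
#' Orders compounds by binding free energy (most negative first; ties break
#' lexicographically by compound id) and applies a top-N rule, an inclusive
#' kJ/mol cutoff (dg_kj <= cutoff), or their intersection.
#'
#' @param scores a \code{dock_scores} data frame.
#' @param top_n optional integer.
#' @param dg_cutoff_kj optional threshold in kJ/mol (inclusive).
#' @return the selected rows, ranked, with a \code{rank} column.
#' @export
select_binders <- function(scores, top_n = NULL, dg_cutoff_kj = NULL) {
  if (!nrow(scores)) stop_("no scores to select from")
  if (is.null(top_n) && is.null(dg_cutoff_kj))
    stop_("selection rule needs top_n and/or dg_cutoff_kj")
  ord <- scores[order(scores$dg_kj, scores$compound_id), , drop = FALSE]
  ord$rank <- seq_len(nrow(ord))
  if (!is.null(dg_cutoff_kj))
    ord <- ord[ord$dg_kj <= dg_cutoff_kj, , drop = FALSE]
  if (!is.null(top_n))
    ord <- utils::head(ord, top_n)
  rownames(ord) <- NULL
  ord
}

#' Write a binder selection as CSV
#'
#' @param selection result of \code{\link{select_binders}}.
#' @param path output path; columns compound_id, dg_kcal, dg_kj, rank.
#' @export
write_selection_csv <- function(selection, path) {
  utils::write.csv(selection[, c("compound_id", "dg_kcal", "dg_kj", "rank")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run an external docking engine over a ligand set
#'
#' Thin subprocess adapter: invokes an AutoDock Vina-compatible executable
#' once per ligand against a fixed receptor and box config, and writes a
#' machine-readable manifest. The whole step is optional — the rest of the
#' pipeline accepts precomputed engine outputs via
#' \code{\link{parse_engine_output}} — so a missing engine fails fast with a
#' distinct error rather than mid-run.
#'
#' @param receptor receptor PDBQT path.
#' @param ligands character vector of ligand PDBQT paths.
#' @param config_path Vina config (from \code{\link{write_vina_config}}).
#' @param engine_path engine executable.
#' @param out_dir output directory.
#' @param exhaustiveness engine search effort (default 8).
#' @param seed engine RNG seed (default 1).
#' @return data frame manifest (\code{ligand}, \code{output}) written to
#'   \code{manifest.csv} in \code{out_dir}.
#' @export
run_engine <- function(receptor, ligands, config_path, engine_path,
                       out_dir, exhaustiveness = 8, seed = 1) {
  if (!nzchar(Sys.which(engine_path)) && !file.exists(engine_path))
    stop_(paste0("docking engine not found at '%s'; either install it or ",
                 "skip this stage and feed precomputed outputs to ",
                 "parse_engine_output()"), engine_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ligands <- ligands[order(basename(ligands))]  # deterministic order
  outs <- file.path(out_dir, paste0(sub("\\.[^.]*$", "", basename(ligands)),
                                    "_out.pdbqt"))
  for (i in seq_along(ligands)) {
    status <- system2(engine_path,
                      c("--receptor", receptor, "--ligand", ligands[i],
                        "--config", config_path, "--out", outs[i],
                        "--exhaustiveness", exhaustiveness, "--seed", seed),
                      stdout = paste0(outs[i], ".log"), stderr = FALSE)
    if (status != 0) stop_("engine failed on ligand %s (exit %d)",
                           ligands[i], status)
  }
  manifest <- data.frame(ligand = ligands, output = outs)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}
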