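#' Load protein structure residues from PDB or mmCIF
#'
#' Reads a structure (format chosen by file extension: \code{.cif} is mmCIF,
#' anything else PDB), restricts to one chain, drops HETATM records and
#' waters, and returns the heavy-atom model.
#'
#' @param path structure file.
#' @param chain chain identifier (default first chain present).
#' @return list of class \code{residue_model}: \code{residues} (data frame
#'   \code{resno}, \code{resid}), \code{atoms} (data frame \code{resno},
#'   \code{elety}, \code{x}, \code{y}, \code{z}), \code{chain}, and the
#'   underlying \code{bio3d} object as \code{pdb}.
#' @export
load_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_("structure file not found: %s", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    suppressWarnings(bio3d::read.cif(path)) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !at$resid %in% c("HOH", "WAT", "DOD"), ,
           drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains)
    stop_("chain '%s' not found; available: %s", chain,
          paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  # heavy atoms only (element symbol column, when present, is authoritative)
  if ("elesy" %in% names(at) && any(nzchar(trimws(at$elesy))))
    at <- at[!trimws(at$elesy) %in% c("H", "D"), , drop = FALSE]
  res <- at[!duplicated(at$resno), c("resno", "resid"), drop = FALSE]
  rownames(res) <- NULL
  structure(list(residues = res,
                 atoms = at[, c("resno", "elety", "x", "y", "z")],
                 chain = chain, pdb = pdb),
            class = "residue_model")
}

#' @export
print.residue_model <- function(x, ...) {
  cat(sprintf("residue_model: chain %s, %d residues, %d heavy atoms (%d-%d)\n",
              x$chain, nrow(x$residues), nrow(x$atoms),
              min(x$residues$resno), max(x$residues$resno)))
  invisible(x)
}

#' Map a smoothed tiling profile onto structure residues
#'
#' Pairs profile position \code{p} with structure residue
#' \code{p + offset}. Positions without a resolved residue (or without a
#' smoothed score) are skipped and counted. A message is emitted when fewer
#' than half of the scored profile positions land on the structure.
#'
#' @param profile a \code{tiling_profile}.
#' @param model a \code{residue_model}.
#' @param offset constant added to profile positions to reach the structure's
#'   author numbering (default 0).
#' @return data frame of class \code{residue_score_map}: \code{position}
#'   (profile), \code{resno} (structure), \code{ncs}; coverage in attributes.
#' @export
map_profile <- function(profile, model, offset = 0) {
  scored <- profile$residue[!is.na(profile$smoothed_ncs)]
  resno <- scored + offset
  hit <- resno %in% model$residues$resno
  if (!any(hit))
    stop_(paste("no profile position maps onto the structure; try an offset",
                "scan (structure residues span %d-%d)"),
          min(model$residues$resno), max(model$residues$resno))
  out <- data.frame(position = scored[hit], resno = resno[hit],
                    ncs = profile$smoothed_ncs[match(scored[hit],
                                                     profile$residue)])
  frac <- nrow(out) / length(scored)
  if (frac < 0.5)
    message(sprintf("only %.0f%% of scored profile positions mapped", 100 * frac))
  attr(out, "chain") <- model$chain
  attr(out, "offset") <- offset
  attr(out, "n_profile_scored") <- length(scored)
  attr(out, "n_mapped") <- nrow(out)
  class(out) <- c("residue_score_map", "data.frame")
  out
}

#' Write structure annotation files for rendering
#'
#' Emits (a) a UCSF Chimera attribute file (\code{defattr} dialect,
#' attribute name \code{ncs}) and (b) a copy of the structure whose B-factor
#' column carries each residue's score formatted to two decimals, with
#' unmapped residues set to the sentinel 99.99 (outside the NCS range, so
#' render palettes can mask it).
#'
#' @param score_map a \code{residue_score_map}.
#' @param model the \code{residue_model} the map was built against.
#' @param out_prefix path prefix; writes \code{<prefix>.defattr} and
#'   \code{<prefix>_ncs.pdb}.
#' @return named character vector of the two paths.
#' @export
write_annotations <- function(score_map, model, out_prefix) {
  if (!nrow(score_map)) stop_("empty score map")
  defattr <- paste0(out_prefix, ".defattr")
  con <- file(defattr, "w")
  writeLines(c("attribute: ncs", "match mode: 1-to-1",
               "recipient: residues"), con)
  writeLines(sprintf("\t:%d.%s\t%.4f", score_map$resno,
                     attr(score_map, "chain"), score_map$ncs), con)
  close(con)

  pdb <- model$pdb
  b <- rep(99.99, nrow(pdb$atom))
  sel <- pdb$atom$chain == model$chain &
    pdb$atom$resno %in% score_map$resno & pdb$atom$type == "ATOM"
  b[sel] <- round(score_map$ncs[match(pdb$atom$resno[sel],
                                      score_map$resno)], 2)
  pdbout <- paste0(out_prefix, "_ncs.pdb")
  bio3d::write.pdb(pdb, file = pdbout, b = b)
  invisible(c(defattr = defattr, pdb = pdbout))
}

#' Read scores back from a B-factor-annotated structure
#'
#' Inverse of the PDB half of \code{\link{write_annotations}}: returns the
#' per-residue B-factor values for a chain, dropping the 99.99 sentinel.
#'
#' @param path annotated PDB.
#' @param chain chain id.
#' @return data frame \code{resno}, \code{ncs}.
#' @export
read_bfactor_scores <- function(path, chain) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$chain == chain & pdb$atom$type == "ATOM", ]
  first <- at[!duplicated(at$resno), ]
  out <- data.frame(resno = first$resno, ncs = first$b)
  out[out$ncs != 99.99, , drop = FALSE]
}
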