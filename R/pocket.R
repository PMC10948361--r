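#' Structure residues inside hypersensitive segments
#'
#' Selects every structure residue whose (profile-frame) position falls in
#' any called segment. Residues missing from the structure are counted and
#' reported via attributes.
#'
#' @param segments a \code{segment_table} (profile coordinates).
#' @param score_map a \code{residue_score_map} linking profile positions to
#'   structure residue numbers.
#' @return integer vector of structure residue numbers; attributes
#'   \code{n_requested} and \code{n_unresolved}.
#' @export
segment_residues <- function(segments, score_map) {
  want <- unlist(lapply(seq_len(nrow(segments)), function(i)
    segments$start[i]:segments$end[i]))
  want <- sort(unique(want))
  hit <- score_map$resno[match(want, score_map$position)]
  sel <- sort(unique(hit[!is.na(hit)]))
  if (!length(sel))
    stop_("no segment residue is resolved in the structure")
  attr(sel, "n_requested") <- length(want)
  attr(sel, "n_unresolved") <- sum(is.na(hit))
  sel
}

#' Define a docking box around selected residues
#'
#' Axis-aligned box: center is the midpoint of the bounding box of all heavy
#' atoms of the selection; each edge is the atom extent on that axis plus
#' twice the padding. With \code{cube = TRUE} all edges are set to the
#' largest.
#'
#' @param model a \code{residue_model}.
#' @param resnos residue numbers to enclose (e.g. from
#'   \code{\link{segment_residues}}); \code{NULL} = all residues.
#' @param padding margin added on every side, in Angstrom (default 6).
#' @param cube force equal edge lengths (default TRUE).
#' @return list of class \code{docking_box} with \code{center} and
#'   \code{size}, both length-3 numeric (x, y, z; Angstrom).
#' @export
define_box <- function(model, resnos = NULL, padding = 6.0, cube = TRUE) {
  at <- model$atoms
  if (!is.null(resnos)) at <- at[at$resno %in% resnos, , drop = FALSE]
  if (!nrow(at)) stop_("empty atom selection for box definition")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  lo <- apply(xyz, 2L, min)
  hi <- apply(xyz, 2L, max)
  center <- (lo + hi) / 2
  size <- (hi - lo) + 2 * padding
  if (cube) size <- rep(max(size), 3L)
  structure(list(center = unname(center), size = unname(size)),
            class = "docking_box")
}

#' @export
print.docking_box <- function(x, ...) {
  cat(sprintf("docking_box: center (%.3f, %.3f, %.3f), size (%.3f, %.3f, %.3f) A\n",
              x$center[1], x$center[2], x$center[3],
              x$size[1], x$size[2], x$size[3]))
  invisible(x)
}

#' Write a docking box as an AutoDock Vina configuration
#'
#' Emits the six \code{center_x = ...} / \code{size_z = ...} lines with
#' values formatted to three decimals, plus optional receptor/output keys.
#'
#' @param box a \code{docking_box}.
#' @param path output path.
#' @param receptor optional receptor PDBQT path to record.
#' @export
write_vina_config <- function(box, path, receptor = NULL) {
  lines <- c(
    if (!is.null(receptor)) sprintf("receptor = %s", receptor),
    sprintf("center_x = %.3f", box$center[1]),
    sprintf("center_y = %.3f", box$center[2]),
    sprintf("center_z = %.3f", box$center[3]),
    sprintf("size_x = %.3f", box$size[1]),
    sprintf("size_y = %.3f", box$size[2]),
    sprintf("size_z = %.3f", box$size[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Grid-based cavity detection by six-direction buriedness
#'
#' A lightweight pocket criterion: grid points inside the box are kept when
#' (a) they are clash-free, i.e. at least \code{probe + r_heavy} from every
#' heavy atom, and (b) an axis ray cast from the point in each of the six
#' cardinal directions hits protein in at least \code{min_buriedness}
#' directions (a ray "hits" when some atom center lies within
#' \code{r_heavy} of the ray beyond the point). Points are returned sorted
#' by decreasing buriedness, then by x, y, z.
#'
#' @param model a \code{residue_model} (or any object with an \code{atoms}
#'   data frame carrying x, y, z).
#' @param box a \code{docking_box} bounding the search.
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param min_buriedness minimum blocked directions out of 6 (default 4).
#' @param r_heavy uniform heavy-atom radius in Angstrom (default 1.7).
#' @return data frame of class \code{cavity_grid}: \code{x}, \code{y},
#'   \code{z}, \code{buriedness}; zero rows (with a warning) when no point
#'   qualifies.
#' @export
detect_cavity <- function(model, box, spacing = 1.0, probe = 1.4,
                          min_buriedness = 4, r_heavy = 1.7) {
  at <- as.matrix(model$atoms[, c("x", "y", "z")])
  lo <- box$center - box$size / 2
  hi <- box$center + box$size / 2
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      buriedness = integer(0))
  class(empty) <- c("cavity_grid", "data.frame")
  attr(empty, "spacing") <- spacing
  if (!nrow(at) || !nrow(pts)) {
    warn_("no cavity points found")
    return(empty)
  }
  clash_d2 <- (probe + r_heavy)^2
  keep <- logical(nrow(pts))
  bur <- integer(nrow(pts))
  r2 <- r_heavy^2
  for (i in seq_len(nrow(pts))) {
    d <- sweep(at, 2L, pts[i, ])
    d2 <- rowSums(d * d)
    if (any(d2 < clash_d2)) next
    b <- 0L
    for (ax in 1:3) {
      perp2 <- d2 - d[, ax]^2
      near <- perp2 <= r2
      if (any(near & d[, ax] > 0)) b <- b + 1L  # + direction blocked
      if (any(near & d[, ax] < 0)) b <- b + 1L  # - direction blocked
    }
    if (b >= min_buriedness) {
      keep[i] <- TRUE
      bur[i] <- b
    }
  }
  if (!any(keep)) {
    warn_("no cavity points found")
    return(empty)
  }
  out <- data.frame(pts[keep, , drop = FALSE], buriedness = bur[keep])
  out <- out[order(-out$buriedness, out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spacing") <- spacing
  class(out) <- c("cavity_grid", "data.frame")
  out
}

#' Export cavity points as PDB pseudo-atoms
#'
#' HETATM records (residue CAV, element C) with the buriedness count in the
#' B-factor column, for visual inspection alongside the structure.
#'
#' @param cavity a \code{cavity_grid}.
#' @param path output path.
#' @export
write_cavity_pdb <- function(cavity, path) {
  lines <- sprintf(
    "HETATM%5d  C   CAV X%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
    seq_len(nrow(cavity)), seq_len(nrow(cavity)),
    cavity$x, cavity$y, cavity$z, as.numeric(cavity$buriedness))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
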