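#' Two-point control calibration of normalized CRISPR scores
#'
#' Rescales per-guide log10 fold changes so that the median of the
#' negative-control guides (non-essential targets) maps to 0 and the median
#' of the positive-control guides (core-essential targets) maps to -1.0:
#' \deqn{NCS(x) = -(x - m_{neg}) / (m_{pos} - m_{neg})}
#' Only guides passing the low-frequency filter enter the control medians.
#'
#' @param fold_changes a \code{fold_change_table} (columns \code{guide_id},
#'   \code{log10_fc}, \code{kept}).
#' @param guides a \code{guide_library} aligned by \code{guide_id}.
#' @param min_controls minimum kept guides required per control category.
#' @return list of class \code{ncs_calibration}: \code{ncs} (named vector over
#'   kept guides), \code{m_neg}, \code{m_pos}.
#' @export
calibrate_ncs <- function(fold_changes, guides, min_controls = 3) {
  fc <- fold_changes[fold_changes$kept, , drop = FALSE]
  cat_of <- guides$category[match(fc$guide_id, guides$guide_id)]
  if (anyNA(cat_of))
    stop_("guide(s) in fold-change table absent from library: %s",
          paste(utils::head(fc$guide_id[is.na(cat_of)], 5), collapse = ", "))
  neg <- fc$log10_fc[cat_of == "negative_control"]
  pos <- fc$log10_fc[cat_of == "positive_control"]
  if (length(neg) < min_controls || length(pos) < min_controls)
    stop_("too few kept control guides (neg=%d, pos=%d; need >= %d each)",
          length(neg), length(pos), min_controls)
  m_neg <- stats::median(neg)
  m_pos <- stats::median(pos)
  if (m_neg == m_pos) stop_("degenerate calibration: control medians coincide")
  ncs <- -(fc$log10_fc - m_neg) / (m_pos - m_neg)
  names(ncs) <- fc$guide_id
  structure(list(ncs = ncs, m_neg = m_neg, m_pos = m_pos),
            class = "ncs_calibration")
}

#' @export
print.ncs_calibration <- function(x, ...) {
  cat(sprintf(
    "NCS calibration: %d guides; control medians m_neg=%.4f, m_pos=%.4f\n",
    length(x$ncs), x$m_neg, x$m_pos))
  invisible(x)
}

#' Average guide scores per codon position
#'
#' Each targeting guide carries a codon (peptide position); the raw residue
#' score is the arithmetic mean of the NCS of all kept guides assigned to
#' that codon. Control guides are excluded. Positions with no guide are NA.
#'
#' @param ncs named numeric vector of per-guide NCS (from
#'   \code{\link{calibrate_ncs}}).
#' @param guides a \code{guide_library}.
#' @param protein_length number of residues in the primary translation
#'   product; defaults to the largest codon seen.
#' @return numeric vector of length \code{protein_length}; NA where no guide.
#' @export
assign_guides_to_residues <- function(ncs, guides, protein_length = NULL) {
  idx <- match(names(ncs), guides$guide_id)
  keep <- !is.na(idx) & guides$category[idx] == "targeting"
  codon <- guides$codon[idx[keep]]
  val <- ncs[keep]
  if (is.null(protein_length)) protein_length <- max(codon)
  if (any(codon > protein_length))
    stop_("guide codon %d exceeds protein length %d",
          max(codon), protein_length)
  raw <- rep(NA_real_, protein_length)
  agg <- tapply(val, codon, mean)
  raw[as.integer(names(agg))] <- as.numeric(agg)
  raw
}

#' Gaussian kernel smoothing of a per-residue profile
#'
#' Nadaraya-Watson smoothing with a truncated Gaussian kernel of bandwidth
#' \code{sigma_aa} residues. Missing positions contribute no weight: the
#' kernel mass is renormalized over observed neighbours, so edges and gaps
#' are not biased toward zero. A residue whose whole window is missing stays
#' missing.
#'
#' @param raw numeric vector of raw per-residue scores (NA = no guide).
#' @param sigma_aa kernel bandwidth in residues (default 5).
#' @param truncate kernel support half-width in bandwidths (default 3).
#' @return data frame of class \code{tiling_profile} with columns
#'   \code{residue}, \code{raw_ncs}, \code{smoothed_ncs}; smoothing
#'   parameters stored as attributes.
#' @export
smooth_profile <- function(raw, sigma_aa = 5.0, truncate = 3.0) {
  if (sigma_aa <= 0) stop_("sigma_aa must be positive")
  L <- length(raw)
  half <- floor(truncate * sigma_aa)
  offs <- -half:half
  w0 <- exp(-(offs^2) / (2 * sigma_aa^2))
  sm <- rep(NA_real_, L)
  obs <- which(!is.na(raw))
  if (length(obs)) {
    for (r in seq_len(L)) {
      j <- r + offs
      ok <- j >= 1L & j <= L
      j <- j[ok]
      w <- w0[ok]
      v <- raw[j]
      has <- !is.na(v)
      if (any(has)) sm[r] <- sum(w[has] * v[has]) / sum(w[has])
    }
  }
  out <- data.frame(residue = seq_len(L), raw_ncs = raw, smoothed_ncs = sm)
  attr(out, "sigma_aa") <- sigma_aa
  attr(out, "truncate") <- truncate
  class(out) <- c("tiling_profile", "data.frame")
  out
}

#' @export
print.tiling_profile <- function(x, ...) {
  cat(sprintf(
    "tiling_profile: %d residues (%d covered), sigma = %g aa, min smoothed NCS = %.3f\n",
    nrow(x), sum(!is.na(x$raw_ncs)), attr(x, "sigma_aa"),
    suppressWarnings(min(x$smoothed_ncs, na.rm = TRUE))))
  invisible(x)
}

#' @export
plot.tiling_profile <- function(x, threshold = -0.5, ...) {
  plot(x$residue, x$smoothed_ncs, type = "l", xlab = "residue",
       ylab = "smoothed NCS", ...)
  graphics::points(x$residue, x$raw_ncs, pch = 16, cex = 0.3,
                   col = grDevices::grey(0.6))
  graphics::abline(h = c(0, -1, threshold), lty = c(3, 3, 2))
  invisible(x)
}

#' Call CRISPR-hypersensitive segments
#'
#' Maximal runs of residues whose smoothed NCS is at or below
#' \code{threshold}; runs separated by at most \code{merge_gap} residues are
#' merged, and merged runs shorter than \code{min_len} are discarded.
#' Optionally restricted to a domain window (1-based inclusive).
#'
#' @param profile a \code{tiling_profile}.
#' @param threshold NCS call threshold, must be negative (default -0.5, half
#'   the positive-control depletion).
#' @param min_len minimum segment length in residues (default 3).
#' @param merge_gap maximum gap bridged between adjacent runs (default 2).
#' @param domain_window optional \code{c(start, end)} residue interval.
#' @return data frame of class \code{segment_table}: \code{start}, \code{end}
#'   (1-based inclusive), \code{min_ncs}, \code{mean_ncs}, sorted by start.
#' @export
call_segments <- function(profile, threshold = -0.5, min_len = 3,
                          merge_gap = 2, domain_window = NULL) {
  if (threshold >= 0) stop_("threshold must be negative")
  sm <- profile$smoothed_ncs
  res <- profile$residue
  if (!is.null(domain_window)) {
    keep <- res >= domain_window[1] & res <= domain_window[2]
    sm <- sm[keep]; res <- res[keep]
  }
  below <- !is.na(sm) & sm <= threshold
  segs <- run_intervals(res, below)
  segs <- merge_close(segs, merge_gap)
  segs <- segs[segs$end - segs$start + 1L >= min_len, , drop = FALSE]
  if (nrow(segs)) {
    stats_ <- t(vapply(seq_len(nrow(segs)), function(i) {
      v <- sm[res >= segs$start[i] & res <= segs$end[i]]
      c(min(v, na.rm = TRUE), mean(v, na.rm = TRUE))
    }, numeric(2)))
    segs$min_ncs <- stats_[, 1]
    segs$mean_ncs <- stats_[, 2]
  } else {
    segs$min_ncs <- numeric(0)
    segs$mean_ncs <- numeric(0)
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  class(segs) <- c("segment_table", "data.frame")
  attr(segs, "threshold") <- threshold
  attr(segs, "min_len") <- min_len
  attr(segs, "merge_gap") <- merge_gap
  segs
}

# contiguous TRUE runs over (possibly non-contiguous) residue coordinates
run_intervals <- function(res, flag) {
  if (!any(flag)) return(data.frame(start = integer(0), end = integer(0)))
  r <- res[flag]
  brk <- c(TRUE, diff(r) != 1L)
  grp <- cumsum(brk)
  data.frame(start = as.integer(tapply(r, grp, min)),
             end = as.integer(tapply(r, grp, max)))
}

merge_close <- function(segs, gap) {
  if (nrow(segs) < 2L) return(segs)
  segs <- segs[order(segs$start), , drop = FALSE]
  out <- segs[1L, , drop = FALSE]
  for (i in 2L:nrow(segs)) {
    if (segs$start[i] - out$end[nrow(out)] - 1L <= gap) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], segs$end[i])
    } else {
      out <- rbind(out, segs[i, , drop = FALSE])
    }
  }
  out
}

#' Export a tiling profile as TSV
#'
#' @param profile a \code{tiling_profile}.
#' @param path output path; columns residue, raw_ncs, smoothed_ncs.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("residue", "raw_ncs",
                                                "smoothed_ncs")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export called segments
#'
#' Default dialect is a BED-like TSV with 1-based inclusive coordinates
#' (documented in the header comment). \code{dialect = "bed"} writes proper
#' 0-based half-open BED instead.
#'
#' @param segments a \code{segment_table}.
#' @param path output path.
#' @param name feature name used in column 1 (e.g. the protein).
#' @param dialect \code{"one_based"} (default) or \code{"bed"}.
#' @export
write_segments <- function(segments, path, name = "profile",
                           dialect = c("one_based", "bed")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(segments)
  if (dialect == "bed") {
    out <- data.frame(chrom = name, chromStart = df$start - 1L,
                      chromEnd = df$end, name = sprintf("segment_%d",
                                                        seq_len(nrow(df))),
                      score = round(df$mean_ncs, 4))
    hdr <- "# BED: 0-based half-open coordinates"
  } else {
    out <- data.frame(name = name, start = df$start, end = df$end,
                      min_ncs = round(df$min_ncs, 4),
                      mean_ncs = round(df$mean_ncs, 4))
    hdr <- "# coordinates: 1-based inclusive residue positions"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
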