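#' Read and validate an sgRNA library manifest
#'
#' The manifest is a TSV with columns \code{guide_id}, \code{protospacer},
#' \code{category}, \code{target_gene}, \code{cut_nt} and \code{strand}.
#' \code{category} is one of \code{targeting}, \code{negative_control} or
#' \code{positive_control}; \code{cut_nt} is the 1-based nucleotide position
#' of the predicted Cas9 blunt cut within the target CDS (empty/NA for
#' control guides). The codon (1-based amino-acid position) is derived as
#' \code{floor((cut_nt - 1) / 3) + 1}.
#'
#' @param path path to the manifest TSV.
#' @return a data frame of class \code{guide_library} with one row per guide
#'   and an added \code{codon} column.
#' @export
read_guide_library <- function(path) {
  if (!file.exists(path)) stop_("library manifest not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("guide_id", "protospacer", "category", "target_gene",
            "cut_nt", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("library manifest missing column(s): %s", paste(miss, collapse = ", "))
  df$cut_nt <- suppressWarnings(as.integer(df$cut_nt))
  validate_guide_library(df)
}

#' @rdname read_guide_library
#' @param guides a data frame with the manifest columns (codon may be absent).
#' @export
validate_guide_library <- function(guides) {
  dup <- guides$guide_id[duplicated(guides$guide_id)]
  if (length(dup))
    stop_("duplicate guide_id: %s", paste(unique(dup), collapse = ", "))
  bad <- which(nchar(guides$protospacer) != 20L |
                 grepl("[^ACGT]", guides$protospacer))
  if (length(bad))
    stop_("invalid protospacer (must be 20 nt over A/C/G/T) at row(s): %s",
          paste(bad, collapse = ", "))
  ok_cat <- c("targeting", "negative_control", "positive_control")
  bad <- which(!guides$category %in% ok_cat)
  if (length(bad))
    stop_("unknown category at row(s): %s", paste(bad, collapse = ", "))
  bad <- which(!guides$strand %in% c("+", "-"))
  if (length(bad))
    stop_("strand must be '+' or '-' at row(s): %s", paste(bad, collapse = ", "))
  targ <- guides$category == "targeting"
  if (any(targ & (is.na(guides$cut_nt) | guides$cut_nt < 1L)))
    stop_("targeting guides require a positive cut_nt")
  guides$codon <- ifelse(is.na(guides$cut_nt), NA_integer_,
                         (guides$cut_nt - 1L) %/% 3L + 1L)
  class(guides) <- c("guide_library", "data.frame")
  guides
}

#' Read a guide-by-sample count table
#'
#' TSV dialect: first column \code{guide_id}, remaining columns one sample
#' each, non-negative integer read counts. Sample metadata (timepoint,
#' replicate) lives in a sidecar TSV with columns \code{sample_id},
#' \code{timepoint} (\code{day0}, \code{day24} or \code{other}) and
#' \code{replicate}.
#'
#' @param path path to the count TSV.
#' @param samples_path optional path to the sample-metadata sidecar TSV. When
#'   omitted, timepoints are guessed from sample names containing
#'   \code{day0}/\code{d0} or \code{day24}/\code{d24}.
#' @return list of class \code{count_table} with elements \code{counts}
#'   (integer matrix, guides x samples) and \code{samples} (data frame).
#' @export
read_count_table <- function(path, samples_path = NULL) {
  if (!file.exists(path)) stop_("count table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop_("count table needs a guide_id column plus samples")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(samples_path)) {
    smp <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
    need <- c("sample_id", "timepoint", "replicate")
    miss <- setdiff(need, names(smp))
    if (length(miss))
      stop_("sample sidecar missing column(s): %s", paste(miss, collapse = ", "))
    miss <- setdiff(colnames(m), smp$sample_id)
    if (length(miss))
      stop_("sample(s) absent from sidecar: %s", paste(miss, collapse = ", "))
    smp <- smp[match(colnames(m), smp$sample_id), , drop = FALSE]
  } else {
    tp <- ifelse(grepl("day0|\\bd0\\b|_d0", colnames(m), ignore.case = TRUE),
                 "day0",
                 ifelse(grepl("day24|d24", colnames(m), ignore.case = TRUE),
                        "day24", "other"))
    smp <- data.frame(sample_id = colnames(m), timepoint = tp,
                      replicate = seq_len(ncol(m)), stringsAsFactors = FALSE)
  }
  count_table(m, smp)
}

#' Construct a count table from a matrix and sample metadata
#'
#' @param counts guides x samples matrix of non-negative counts with guide ids
#'   as row names.
#' @param samples data frame with \code{sample_id}, \code{timepoint},
#'   \code{replicate}; rows aligned with the matrix columns.
#' @export
count_table <- function(counts, samples) {
  if (is.null(rownames(counts))) stop_("counts must carry guide ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop_("duplicate guide_id in count table")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop_("counts must be finite and non-negative")
  zero <- colSums(counts) <= 0
  if (any(zero))
    stop_("sample column(s) with zero total reads: %s",
          paste(colnames(counts)[zero], collapse = ", "))
  if (!all(samples$timepoint %in% c("day0", "day24", "other")))
    stop_("timepoint must be day0, day24 or other")
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d guides x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tp <- table(x$samples$timepoint)
  cat("  timepoints:", paste(sprintf("%s=%d", names(tp), tp), collapse = " "),
      "\n")
  invisible(x)
}

#' Reads-per-million normalization
#'
#' Adds \code{pseudocount} to every raw count, then scales each sample column
#' to one million. With the default pseudocount of 1 the column sums deviate
#' from 1e6 only through the pseudocount's own (tiny) contribution to the
#' column total, which the scaling absorbs: columns still sum to exactly 1e6.
#'
#' @param counts a \code{count_table} or a numeric matrix (guides x samples).
#' @param pseudocount non-negative integer added to raw counts (default 1).
#' @return numeric matrix of RPM values, same dimnames as the input.
#' @export
rpm_normalize <- function(counts, pseudocount = 1) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  if (pseudocount < 0) stop_("pseudocount must be >= 0")
  m <- counts + pseudocount
  tot <- colSums(m)
  if (any(tot <= 0)) stop_("empty sample column (zero total after pseudocount)")
  sweep(m, 2L, tot, "/") * 1e6
}

#' Library representation quality control
#'
#' A screen's day-0 (plasmid/start) sample passes when at least
#' \code{min_fraction} of guides reach \code{threshold_rpm} reads per million
#' (default: at least 90\% of guides at a minimum of 10 RPM).
#'
#' @param rpm numeric vector of day-0 RPM values (one per guide).
#' @param threshold_rpm minimum RPM per guide (default 10).
#' @param min_fraction required fraction of guides at or above the threshold
#'   (default 0.90).
#' @return list with \code{pass} (logical) and \code{fraction_ge_threshold}.
#' @export
library_qc <- function(rpm, threshold_rpm = 10, min_fraction = 0.90) {
  frac <- mean(rpm >= threshold_rpm)
  list(pass = frac >= min_fraction, fraction_ge_threshold = frac)
}

#' Per-guide log10 fold change between two samples
#'
#' log10 of the end/start relative-frequency ratio. Inputs are expected to be
#' pseudocounted RPM so neither side is zero. Vectors must share names (guide
#' ids); a guide present on one side only is an error.
#'
#' @param start_rpm,end_rpm named numeric vectors of RPM values.
#' @return named numeric vector of log10 fold changes.
#' @export
log10_fold_change <- function(start_rpm, end_rpm) {
  if (!is.null(names(start_rpm)) || !is.null(names(end_rpm))) {
    if (is.null(names(start_rpm)) || is.null(names(end_rpm)) ||
        !setequal(names(start_rpm), names(end_rpm)))
      stop_("guides present in one sample only: %s",
            paste(union(setdiff(names(start_rpm), names(end_rpm)),
                        setdiff(names(end_rpm), names(start_rpm))),
                  collapse = ", "))
    end_rpm <- end_rpm[names(start_rpm)]
  } else if (length(start_rpm) != length(end_rpm)) {
    stop_("start and end samples differ in length")
  }
  if (any(start_rpm <= 0) || any(end_rpm <= 0))
    stop_("zero abundance encountered; apply a pseudocount before fold change")
  log10(end_rpm / start_rpm)
}

#' Low-frequency guide filter
#'
#' Guides below a fraction (default 5\%) of the expected uniform frequency in
#' the day-0 sample are flagged for removal. Expected frequency is uniform:
#' \code{1e6 / n_library_guides} RPM. The rule is strictly "below", so a
#' guide sitting exactly on the boundary is kept.
#'
#' @param start_rpm numeric vector of day-0 RPM values.
#' @param n_library_guides library size used for the uniform expectation.
#' @param fraction removal threshold as a fraction of expected (default 0.05).
#' @return logical vector, \code{TRUE} = kept.
#' @export
low_frequency_filter <- function(start_rpm, n_library_guides,
                                 fraction = 0.05) {
  if (n_library_guides <= 0) stop_("n_library_guides must be positive")
  expected_rpm <- 1e6 / n_library_guides
  start_rpm >= fraction * expected_rpm
}

#' Fold-change table for a screen
#'
#' Convenience wrapper running the per-replicate pipeline: RPM normalization
#' with a pseudocount, per-replicate log10 fold change day0 -> day24 averaged
#' across replicate pairs (matched by replicate index), and the low-frequency
#' filter evaluated on the pooled day-0 counts.
#'
#' @param tab a \code{count_table} containing day0 and day24 samples.
#' @param pseudocount added to raw counts before RPM (default 1).
#' @param filter_fraction low-frequency threshold fraction (default 0.05).
#' @return data frame of class \code{fold_change_table} with columns
#'   \code{guide_id}, \code{log10_fc}, \code{kept}.
#' @export
fold_change_table <- function(tab, pseudocount = 1, filter_fraction = 0.05) {
  stopifnot(inherits(tab, "count_table"))
  rpm <- rpm_normalize(tab, pseudocount)
  d0 <- which(tab$samples$timepoint == "day0")
  d24 <- which(tab$samples$timepoint == "day24")
  if (!length(d0) || !length(d24))
    stop_("count table needs at least one day0 and one day24 sample")
  reps0 <- tab$samples$replicate[d0]
  reps24 <- tab$samples$replicate[d24]
  shared <- intersect(reps0, reps24)
  if (!length(shared)) stop_("no replicate index shared between day0 and day24")
  fc <- vapply(shared, function(r) {
    log10_fold_change(rpm[, d0[match(r, reps0)]], rpm[, d24[match(r, reps24)]])
  }, numeric(nrow(rpm)))
  fc <- if (is.matrix(fc)) rowMeans(fc) else fc
  # pooled day-0 counts drive the representation filter
  pooled0 <- rowSums(tab$counts[, d0, drop = FALSE]) + pseudocount
  pooled0_rpm <- pooled0 / sum(pooled0) * 1e6
  kept <- low_frequency_filter(pooled0_rpm, nrow(tab$counts), filter_fraction)
  out <- data.frame(guide_id = rownames(tab$counts), log10_fc = fc,
                    kept = kept, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Write a library QC report as JSON
#'
#' @param qc result of \code{\link{library_qc}}.
#' @param path output path.
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(list(pass = qc$pass,
                            fraction_ge_10rpm = qc$fraction_ge_threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
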