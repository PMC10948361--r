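#' Gene-level CRISPR impact score
#'
#' The impact score of a gene is the exact median log10 fold change across
#' its kept guides (lower/upper-middle mean for even counts).
#'
#' @param fold_changes a \code{fold_change_table}.
#' @param guides a \code{guide_library}.
#' @param gene gene symbol.
#' @return list with \code{gene}, \code{impact_score}, \code{n_guides}.
#' @export
impact_score <- function(fold_changes, guides, gene) {
  idx <- match(fold_changes$guide_id, guides$guide_id)
  sel <- fold_changes$kept & !is.na(idx) &
    guides$target_gene[idx] == gene & guides$category[idx] == "targeting"
  if (!any(guides$target_gene == gene & guides$category == "targeting"))
    stop_("gene not in library: %s", gene)
  if (!any(sel)) stop_("no kept guides for gene: %s", gene)
  list(gene = gene,
       impact_score = stats::median(fold_changes$log10_fc[sel]),
       n_guides = sum(sel))
}

#' Impact scores for every gene in the library
#'
#' @inheritParams impact_score
#' @return data frame with columns \code{gene}, \code{impact_score},
#'   \code{n_guides}, sorted ascending by score.
#' @export
impact_score_table <- function(fold_changes, guides) {
  genes <- sort(unique(guides$target_gene[guides$category == "targeting"]))
  rows <- lapply(genes, function(g)
    as.data.frame(impact_score(fold_changes, guides, g)))
  out <- do.call(rbind, rows)
  out[order(out$impact_score), , drop = FALSE]
}

#' Normalize a growth-competition series to day 0
#'
#' Fluorescent-marker competition assays report the percentage of marker
#' positive (e.g. RFP+) cells over time; each timepoint is expressed as a
#' ratio to the day-0 percentage, so the series starts at 1.0 by definition.
#'
#' @param timepoints numeric vector of days (must include 0).
#' @param pct percentage of marker-positive cells at each timepoint.
#' @return data frame with \code{day}, \code{pct}, \code{normalized}.
#' @export
competition_normalize <- function(timepoints, pct) {
  stopifnot(length(timepoints) == length(pct))
  i0 <- which(timepoints == 0)
  if (length(i0) != 1L) stop_("series must contain exactly one day-0 point")
  if (is.na(pct[i0]) || pct[i0] <= 0) stop_("day-0 percentage missing or zero")
  data.frame(day = timepoints, pct = pct, normalized = pct / pct[i0])
}

#' Codependency ranking from a gene-dependency matrix
#'
#' Ranks all genes by the Pearson correlation of their dependency profiles
#' (e.g. CERES scores across cell lines) with a query gene. Missing cells use
#' pairwise-complete observations with a minimum overlap; zero-variance rows
#' are dropped with a warning; ties in r break lexicographically by symbol.
#'
#' @param mat numeric matrix, genes in rows (rownames = symbols), cell lines
#'   in columns.
#' @param query_gene row name of the query.
#' @param min_overlap minimum shared non-missing cell lines (default 3).
#' @return data frame of class \code{codependency_result}: \code{gene},
#'   \code{pearson_r}, \code{n_lines}, \code{rank} (1 = highest r).
#' @export
codependency_rank <- function(mat, query_gene, min_overlap = 3) {
  if (!query_gene %in% rownames(mat)) stop_("query gene not in matrix")
  if (ncol(mat) < 3) stop_("need at least 3 cell lines")
  q <- mat[query_gene, ]
  if (stats::sd(q, na.rm = TRUE) == 0 || all(is.na(q)))
    stop_("query row has zero variance")
  others <- setdiff(rownames(mat), query_gene)
  sds <- apply(mat[others, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  flat <- others[is.na(sds) | sds == 0]
  if (length(flat)) {
    warn_("dropping %d zero-variance row(s): %s", length(flat),
          paste(utils::head(flat, 5), collapse = ", "))
    others <- setdiff(others, flat)
  }
  res <- lapply(others, function(g) {
    x <- mat[g, ]
    ok <- !is.na(x) & !is.na(q)
    if (sum(ok) < min_overlap) return(c(r = NA_real_, n = sum(ok)))
    c(r = stats::cor(q[ok], x[ok], method = "pearson"), n = sum(ok))
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  n <- vapply(res, `[[`, numeric(1), "n")
  out <- data.frame(gene = others, pearson_r = r, n_lines = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$pearson_r), , drop = FALSE]
  out <- out[order(-out$pearson_r, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "query_gene") <- query_gene
  class(out) <- c("codependency_result", "data.frame")
  out
}
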