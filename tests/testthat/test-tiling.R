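make_fc <- function(ids, fc, kept = TRUE) {
  structure(data.frame(guide_id = ids, log10_fc = fc,
                       kept = rep_len(kept, length(ids)),
                       stringsAsFactors = FALSE),
            class = c("fold_change_table", "data.frame"))
}

make_guides <- function(ids, category, codon = NA_integer_) {
  g <- data.frame(guide_id = ids, category = category,
                  target_gene = ifelse(category == "targeting", "T", ""),
                  cut_nt = ifelse(is.na(codon), NA_integer_, codon * 3L),
                  protospacer = strrep("ACGT", 5), strand = "+",
                  stringsAsFactors = FALSE)
  validate_guide_library(g)
}

ctrl_set <- function(neg_fc, pos_fc) {
  ids <- c(sprintf("n%d", seq_along(neg_fc)), sprintf("p%d", seq_along(pos_fc)))
  list(fc = make_fc(ids, c(neg_fc, pos_fc)),
       guides = make_guides(ids, rep(c("negative_control", "positive_control"),
                                     c(length(neg_fc), length(pos_fc)))))
}

test_that("calibration pins control medians to 0 and -1 and maps linearly", {
  cs <- ctrl_set(c(-0.2, -0.1, 0.0), c(-1.0, -1.1, -1.2))
  extra <- make_fc("x1", -0.6)
  guides <- rbind(cs$guides, make_guides("x1", "targeting", codon = 10))
  cal <- calibrate_ncs(rbind(cs$fc, extra), guides)
  expect_equal(cal$m_neg, -0.1)
  expect_equal(cal$m_pos, -1.1)
  expect_equal(unname(cal$ncs[c("n2", "p2")]), c(0, -1))
  expect_equal(unname(cal$ncs["x1"]), -0.5)  # midpoint of the two-point map
})

test_that("calibration is affine-invariant under a common shift", {
  cs <- ctrl_set(rnorm(9, 0, 0.1), rnorm(9, -1.4, 0.1))
  cal1 <- calibrate_ncs(cs$fc, cs$guides)
  shifted <- cs$fc
  shifted$log10_fc <- shifted$log10_fc + 0.37
  cal2 <- calibrate_ncs(shifted, cs$guides)
  expect_equal(cal1$ncs, cal2$ncs)
})

test_that("degenerate and under-powered calibrations are rejected", {
  cs <- ctrl_set(c(-0.5, -0.5, -0.5), c(-0.5, -0.5, -0.5))
  expect_error(calibrate_ncs(cs$fc, cs$guides), "degenerate")
  cs <- ctrl_set(c(0, 0.1), c(-1, -1.1, -1.2))
  expect_error(calibrate_ncs(cs$fc, cs$guides), "too few")
})

test_that("guide scores average per codon; uncovered residues are missing", {
  ids <- c("a", "b", "c")
  g <- make_guides(ids, rep("targeting", 3), codon = c(34, 34, 36))
  ncs <- c(a = -0.4, b = -0.6, c = -0.2)
  raw <- assign_guides_to_residues(ncs, g, protein_length = 40)
  expect_equal(raw[34], -0.5)
  expect_equal(raw[36], -0.2)
  expect_true(is.na(raw[35]))
  expect_error(assign_guides_to_residues(ncs, g, protein_length = 35),
               "exceeds")
})

test_that("smoothing equals the brute-force windowed convolution oracle", {
  set.seed(21)
  for (sigma in c(2, 5)) {
    raw <- rnorm(120, -0.3, 0.5)
    raw[sample(120, 30)] <- NA  # gaps exercise the renormalization
    sm <- smooth_profile(raw, sigma_aa = sigma, truncate = 3)$smoothed_ncs
    expect_equal(sm, brute_smooth(raw, sigma, 3), tolerance = 1e-9)
  }
})

test_that("smoothing preserves constants and stays within the raw range", {
  raw <- rep(-0.7, 60)
  expect_equal(smooth_profile(raw)$smoothed_ncs, raw)
  raw <- c(rep(0, 49), -1, rep(0, 50))
  pr <- smooth_profile(raw, sigma_aa = 5)
  w <- exp(-(-15:15)^2 / 50)
  expect_equal(pr$smoothed_ncs[50], -w[16] / sum(w), tolerance = 1e-12)
  set.seed(9)
  raw <- rnorm(100)
  sm <- smooth_profile(raw)$smoothed_ncs
  expect_true(all(sm >= min(raw) - 1e-12 & sm <= max(raw) + 1e-12))
})

test_that("an all-missing window stays missing", {
  raw <- c(rep(-1, 5), rep(NA, 60), rep(-1, 5))
  sm <- smooth_profile(raw, sigma_aa = 2, truncate = 3)$smoothed_ncs
  expect_true(all(is.na(sm[20:50])))
  expect_false(anyNA(sm[1:5]))
})

test_that("segment calling thresholds, merges and filters runs", {
  flat <- smooth_profile(rep(0, 80))
  expect_equal(nrow(call_segments(flat)), 0L)
  # hand-built profile: two runs 10-14 and 17-21 separated by gap 2 -> merged
  pr <- smooth_profile(rep(0, 40))
  pr$smoothed_ncs <- rep(0, 40)
  pr$smoothed_ncs[c(10:14, 17:21)] <- -0.8
  segs <- call_segments(pr, threshold = -0.5, min_len = 3, merge_gap = 2)
  expect_equal(nrow(segs), 1L)
  expect_equal(c(segs$start, segs$end), c(10L, 21L))
  # gap 3 exceeds merge_gap -> two segments
  pr$smoothed_ncs <- rep(0, 40)
  pr$smoothed_ncs[c(10:14, 18:22)] <- -0.8
  segs <- call_segments(pr)
  expect_equal(nrow(segs), 2L)
  # short runs are discarded
  pr$smoothed_ncs <- rep(0, 40)
  pr$smoothed_ncs[10:11] <- -0.9
  expect_equal(nrow(call_segments(pr)), 0L)
  # domain window restricts calls
  pr$smoothed_ncs <- rep(-0.8, 40)
  segs <- call_segments(pr, domain_window = c(5, 20))
  expect_equal(c(segs$start, segs$end), c(5L, 20L))
})

test_that("segment calling is monotone in threshold", {
  set.seed(13)
  raw <- rnorm(200, -0.4, 0.4)
  pr <- smooth_profile(raw)
  segs_loose <- call_segments(pr, threshold = -0.3, min_len = 1,
                              merge_gap = 0)
  segs_tight <- call_segments(pr, threshold = -0.6, min_len = 1,
                              merge_gap = 0)
  in_union <- function(segs) {
    if (!nrow(segs)) return(integer(0))
    unlist(mapply(seq, segs$start, segs$end, SIMPLIFY = FALSE))
  }
  expect_true(all(in_union(segs_tight) %in% in_union(segs_loose)))
})

test_that("planted segments are recovered end to end", {
  sim <- simulate_tiling(seed = 3)
  fc <- fold_change_table(sim$counts)
  cal <- calibrate_ncs(fc, sim$guides)
  raw <- assign_guides_to_residues(cal$ncs, sim$guides, 300)
  pr <- smooth_profile(raw)
  segs <- call_segments(pr)
  expect_gte(nrow(segs), 1L)
  # peak within +/- 2 residues of the planted 120-140 center
  peak <- pr$residue[which.min(pr$smoothed_ncs)]
  expect_lte(abs(peak - 130), 2)
  expect_true(any(segs$start <= 140 & segs$end >= 120))

  sim2 <- simulate_tiling(segments = list(c(80, 95, -1.0), c(126, 141, -1.0)),
                          seed = 4)
  fc2 <- fold_change_table(sim2$counts)
  cal2 <- calibrate_ncs(fc2, sim2$guides)
  pr2 <- smooth_profile(assign_guides_to_residues(cal2$ncs, sim2$guides, 300))
  segs2 <- call_segments(pr2)
  expect_equal(nrow(segs2), 2L)
  expect_true(any(segs2$start <= 95 & segs2$end >= 80))
  expect_true(any(segs2$start <= 141 & segs2$end >= 126))
})

test_that("profile and segment writers round-trip their dialects", {
  pr <- smooth_profile(c(rep(0, 10), rep(-1, 10), rep(0, 10)), sigma_aa = 2)
  p <- tempfile(fileext = ".tsv")
  write_profile_tsv(pr, p)
  back <- read.delim(p)
  expect_equal(back$smoothed_ncs, pr$smoothed_ncs)
  segs <- call_segments(pr)
  p1 <- tempfile(); p2 <- tempfile()
  write_segments(segs, p1, name = "toy")
  write_segments(segs, p2, name = "toy", dialect = "bed")
  one <- read.delim(p1, comment.char = "#")
  bed <- read.delim(p2, comment.char = "#")
  expect_equal(bed$chromStart, one$start - 1L)  # 0-based half-open vs 1-based
  expect_equal(bed$chromEnd, one$end)
})
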