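test_that("simulators are pure functions of their seed", {
  a <- simulate_screen(seed = 8)
  b <- simulate_screen(seed = 8)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$guides$protospacer, b$guides$protospacer)
  expect_false(identical(a$counts$counts,
                         simulate_screen(seed = 9)$counts$counts))
  t1 <- simulate_tiling(seed = 5)
  t2 <- simulate_tiling(seed = 5)
  expect_identical(t1$counts$counts, t2$counts$counts)
  s1 <- toy_structure(seed = 4)
  expect_identical(s1$pdb_text, toy_structure(seed = 4)$pdb_text)
  m1 <- simulate_melt_curve(50, seed = 6)
  expect_identical(m1, simulate_melt_curve(50, seed = 6))
})

test_that("simulators restore the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_screen(seed = 99))
  expect_identical(runif(1), before)
})

test_that("a null screen drifts by sampling noise only", {
  # all effects zero: fold changes are pure sampling noise around zero
  sim <- simulate_screen(essential_effects = numeric(0),
                         pos_control_effect = 0, seed = 12)
  fc <- fold_change_table(sim$counts)
  m <- mean(fc$log10_fc)
  se <- sd(fc$log10_fc) / sqrt(nrow(fc))
  expect_lt(abs(m), 3 * se)
})

test_that("the default day-0 library passes representation QC", {
  sim <- simulate_screen(seed = 2)
  rpm <- rpm_normalize(sim$counts)
  d0 <- which(sim$counts$samples$timepoint == "day0")[1]
  expect_true(library_qc(rpm[, d0])$pass)
  sim_t <- simulate_tiling(seed = 2)
  rpm_t <- rpm_normalize(sim_t$counts)
  expect_true(library_qc(rpm_t[, 1])$pass)
})

test_that("positive-control calibration is a fixed point of the simulator", {
  sim <- simulate_screen(seed = 3)
  fc <- fold_change_table(sim$counts)
  cal <- calibrate_ncs(fc, sim$guides)
  cat_of <- sim$guides$category[match(names(cal$ncs), sim$guides$guide_id)]
  expect_equal(median(cal$ncs[cat_of == "positive_control"]), -1.0)
  expect_equal(median(cal$ncs[cat_of == "negative_control"]), 0)
})

test_that("tiling guides are placed at the configured density", {
  sim <- simulate_tiling(protein_length = 300, spacing = 3, seed = 1)
  targ <- sim$guides[sim$guides$category == "targeting", ]
  expect_equal(nrow(targ), 100L, tolerance = 0.05)
  expect_true(all(targ$codon >= 1 & targ$codon <= 300))
  expect_error(simulate_tiling(segments = list(c(250, 400, -1))),
               "outside")
})

test_that("a segment-free tiling screen calls no segments", {
  sim <- simulate_tiling(segments = list(), seed = 10)
  fc <- fold_change_table(sim$counts)
  cal <- calibrate_ncs(fc, sim$guides)
  pr <- smooth_profile(assign_guides_to_residues(cal$ncs, sim$guides, 300))
  expect_equal(nrow(call_segments(pr)), 0L)
})

test_that("toy structures keep the cavity empty and honor n_blades = 0", {
  toy <- toy_structure()
  d <- sqrt(toy$atoms$x^2 + toy$atoms$y^2 + toy$atoms$z^2)
  expect_true(all(d >= toy$config$cavity_radius))
  # ring symmetry: the all-atom box is centered near the ring center
  box <- define_box(toy, padding = 2)
  expect_lt(max(abs(box$center - toy$cavity_center)), 1.0)
  # cavity detector finds the planted pocket
  cav <- detect_cavity(toy, box, spacing = 1.5)
  dc <- sqrt((cav$x - 0)^2 + (cav$y - 0)^2 + (cav$z - 0)^2)
  expect_lt(min(dc), 2.0)
  empty <- toy_structure(n_blades = 0)
  expect_equal(nrow(empty$atoms), 0L)
  expect_error(toy_structure(cavity_radius = 20, blade_radius = 10),
               "smaller")
})

test_that("noiseless melt curves sample the exact sigmoid", {
  cu <- simulate_melt_curve(tm = 60, slope = 3, baseline_low = 0.2,
                            baseline_high = 0.9, noise_sd = 0)
  expect_equal(cu$temperature, seq(25, 99, by = 0.5))
  manual <- 0.2 + 0.7 / (1 + exp((60 - cu$temperature) / 3))
  expect_equal(cu$fluorescence, manual)
})

test_that("fixture writers round-trip through the package readers", {
  sim <- simulate_tiling(seed = 6)
  dir <- tempfile("fix_")
  paths <- write_screen_fixture(sim, dir)
  g <- read_guide_library(paths["library"])
  expect_equal(g$guide_id, sim$guides$guide_id)
  expect_equal(g$codon, sim$guides$codon)
  tab <- read_count_table(paths["counts"], paths["samples"])
  expect_equal(tab$counts, sim$counts$counts)
  expect_equal(tab$samples$timepoint, sim$counts$samples$timepoint)
  cfg <- jsonlite::read_json(paths["config"])
  expect_equal(cfg$seed, 6L)
  toy <- toy_structure(seed = 3)
  tp <- tempfile(fileext = ".pdb")
  write_toy_pdb(toy, tp)
  m <- load_structure(tp, "A")
  expect_equal(nrow(m$atoms), nrow(toy$atoms))
})
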