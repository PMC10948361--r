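fake_map <- function(positions, resnos) {
  out <- data.frame(position = positions, resno = resnos,
                    ncs = rep(-1, length(positions)))
  attr(out, "chain") <- "A"
  class(out) <- c("residue_score_map", "data.frame")
  out
}

fake_segments <- function(...) {
  iv <- list(...)
  data.frame(start = vapply(iv, `[`, 0, 1), end = vapply(iv, `[`, 0, 2))
}

atoms_model <- function(xyz) {
  list(atoms = data.frame(resno = seq_len(nrow(xyz)),
                          elety = rep("C", nrow(xyz)),
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

test_that("segment residues select the mapped interval", {
  smap <- fake_map(45:60, 45:60)
  sel <- segment_residues(fake_segments(c(49, 53)), smap)
  expect_equal(as.integer(sel), 49:53)
  # unresolved residues inside the segment are skipped and counted
  smap2 <- fake_map(c(49, 50, 53), c(49, 50, 53))
  sel2 <- segment_residues(fake_segments(c(49, 53)), smap2)
  expect_equal(as.integer(sel2), c(49, 50, 53))
  expect_equal(attr(sel2, "n_unresolved"), 2L)
  expect_error(segment_residues(fake_segments(c(90, 95)), smap),
               "resolved")
})

test_that("define_box matches closed-form geometry", {
  m1 <- atoms_model(matrix(0, 1, 3))
  b <- define_box(m1, padding = 8, cube = TRUE)
  expect_equal(b$center, c(0, 0, 0))
  expect_equal(b$size, c(16, 16, 16))
  m2 <- atoms_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  b2 <- define_box(m2, padding = 5, cube = FALSE)
  expect_equal(b2$center, c(5, 0, 0))
  expect_equal(b2$size, c(20, 10, 10))
  b3 <- define_box(m2, padding = 5, cube = TRUE)
  expect_equal(b3$size, c(20, 20, 20))
})

test_that("define_box is translation-equivariant and permutation-invariant", {
  set.seed(17)
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  b <- define_box(atoms_model(xyz), padding = 4)
  shift <- c(3.2, -7.1, 11.8)
  b_sh <- define_box(atoms_model(sweep(xyz, 2, -shift)), padding = 4)
  expect_equal(b_sh$center, b$center + shift)
  expect_equal(b_sh$size, b$size)
  b_perm <- define_box(atoms_model(xyz[sample(10), ]), padding = 4)
  expect_equal(b_perm$center, b$center)
  # shrinking the padding never moves the center
  b_small <- define_box(atoms_model(xyz), padding = 1)
  expect_equal(b_small$center, b$center)
})

test_that("vina config lines are formatted to three decimals", {
  b <- structure(list(center = c(1.23456, -2, 0), size = c(20, 20, 20)),
                 class = "docking_box")
  p <- tempfile()
  write_vina_config(b, p)
  ln <- readLines(p)
  expect_equal(ln[1], "center_x = 1.235")
  expect_equal(ln[2], "center_y = -2.000")
  expect_equal(ln[6], "size_z = 20.000")
})

test_that("hollow-shell interior is fully buried; sparse structures are not", {
  shell <- hollow_shell(half = 5, spacing = 1)
  box <- structure(list(center = c(0, 0, 0), size = c(4, 4, 4)),
                   class = "docking_box")
  cav <- detect_cavity(shell, box, spacing = 2)
  expect_gt(nrow(cav), 0)
  expect_true(all(cav$buriedness == 6L))
  # brute-force ray-cast oracle at the exact center of the shell
  at <- as.matrix(shell$atoms[, c("x", "y", "z")])
  blocked <- 0L
  for (dir in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
    along <- at %*% dir
    perp2 <- rowSums(at^2) - along^2
    if (any(perp2 <= 1.7^2 & along > 0)) blocked <- blocked + 1L
  }
  expect_equal(blocked, 6L)
  # empty structure
  expect_warning(
    cav0 <- detect_cavity(atoms_model(matrix(numeric(0), 0, 3)), box),
    "no cavity")
  expect_equal(nrow(cav0), 0L)
  # one isolated atom cannot bury anything
  lone <- atoms_model(matrix(c(10, 0, 0), 1, 3))
  expect_warning(cav1 <- detect_cavity(lone, box, spacing = 2), "no cavity")
  expect_equal(nrow(cav1), 0L)
})

test_that("cavity points are inside the box and clash-free", {
  toy <- toy_structure(seed = 2)
  box <- define_box(toy, padding = 2)
  cav <- detect_cavity(toy, box, spacing = 1.5)
  expect_gt(nrow(cav), 0)
  half <- box$size / 2
  expect_true(all(abs(cav$x - box$center[1]) <= half[1] + 1e-9))
  expect_true(all(abs(cav$y - box$center[2]) <= half[2] + 1e-9))
  expect_true(all(abs(cav$z - box$center[3]) <= half[3] + 1e-9))
  at <- as.matrix(toy$atoms[, c("x", "y", "z")])
  for (i in seq_len(min(nrow(cav), 25))) {
    d <- sqrt(min(rowSums(sweep(at, 2, as.numeric(cav[i, 1:3]))^2)))
    expect_gte(d, 1.4 + 1.7)
  }
})

test_that("cavity pseudo-atom export is parseable PDB", {
  toy <- toy_structure(seed = 2)
  box <- define_box(toy, padding = 2)
  cav <- detect_cavity(toy, box, spacing = 2)
  p <- tempfile(fileext = ".pdb")
  write_cavity_pdb(cav, p)
  pdb <- bio3d::read.pdb(p)
  expect_equal(nrow(pdb$atom), nrow(cav))
  expect_equal(pdb$atom$x, cav$x, tolerance = 1e-3)
  expect_equal(pdb$atom$b, as.numeric(cav$buriedness))
})
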