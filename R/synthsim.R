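random_protospacers <- function(n) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
}

# negative-binomial (Gamma-Poisson) counts around mu; dispersion = 1/size
nb_counts <- function(mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# sample one screen timepoint: expected relative abundance w, total depth
sample_timepoint <- function(w, depth, dispersion) {
  nb_counts(depth * w / sum(w), dispersion)
}

#' Simulate a pooled CRISPR depletion screen
#'
#' Generates a guide library (targeting guides plus spiked negative and
#' positive controls) and a day-0/day-24 count table. Day-0 counts are
#' negative-binomial around a uniform expectation; day-24 expectations scale
#' each guide's share by \code{10^effect} (log10 fitness effect over the
#' screen), so a neutral guide drifts only by noise and a depleted guide
#' loses abundance. Positive controls carry \code{pos_control_effect};
#' negative controls are neutral.
#'
#' @param n_genes,guides_per_gene targeting-library design (defaults 20 x 5).
#' @param n_neg_controls,n_pos_controls spiked control counts (100 / 30).
#' @param essential_effects named numeric vector of per-gene log10 depletion
#'   effects (genes absent default to 0).
#' @param pos_control_effect log10 effect of positive controls (default -1.5).
#' @param depth sequencing depth per sample (default 1e6).
#' @param dispersion negative-binomial dispersion (default 0.05).
#' @param replicates replicate pairs of day0/day24 samples (default 2).
#' @param seed integer seed; identical seeds give identical output.
#' @return list of class \code{screen_sim}: \code{guides}
#'   (\code{guide_library}), \code{counts} (\code{count_table}),
#'   \code{config}.
#' @export
simulate_screen <- function(n_genes = 20, guides_per_gene = 5,
                            n_neg_controls = 100, n_pos_controls = 30,
                            essential_effects = c(gene_1 = -1.0),
                            pos_control_effect = -1.5, depth = 1e6,
                            dispersion = 0.05, replicates = 2, seed = 1) {
  config <- list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                 n_neg_controls = n_neg_controls,
                 n_pos_controls = n_pos_controls,
                 essential_effects = as.list(essential_effects),
                 pos_control_effect = pos_control_effect, depth = depth,
                 dispersion = dispersion, replicates = replicates,
                 seed = seed)
  with_seed(seed, {
    genes <- sprintf("gene_%d", seq_len(n_genes))
    g_targ <- data.frame(
      guide_id = sprintf("%s_sg%d", rep(genes, each = guides_per_gene),
                         rep(seq_len(guides_per_gene), n_genes)),
      category = "targeting",
      target_gene = rep(genes, each = guides_per_gene),
      cut_nt = rep(seq_len(guides_per_gene) * 9L, n_genes),
      stringsAsFactors = FALSE)
    g_neg <- data.frame(guide_id = sprintf("neg_%03d", seq_len(n_neg_controls)),
                        category = "negative_control", target_gene = "",
                        cut_nt = NA_integer_, stringsAsFactors = FALSE)
    g_pos <- data.frame(guide_id = sprintf("pos_%03d", seq_len(n_pos_controls)),
                        category = "positive_control", target_gene = "",
                        cut_nt = NA_integer_, stringsAsFactors = FALSE)
    g <- rbind(g_targ, g_neg, g_pos)
    g$protospacer <- random_protospacers(nrow(g))
    g$strand <- "+"
    g <- validate_guide_library(g)

    eff <- numeric(nrow(g))
    has <- match(g$target_gene, names(essential_effects))
    eff[!is.na(has)] <- unlist(essential_effects)[has[!is.na(has)]]
    eff[g$category == "positive_control"] <- pos_control_effect

    sim_counts_from_effects(g, eff, depth, dispersion, replicates,
                            config, "screen_sim")
  })
}

# shared count-sampling backend for screen and tiling simulators
sim_counts_from_effects <- function(g, eff, depth, dispersion, replicates,
                                    config, cls) {
  n <- nrow(g)
  cols <- list()
  smp <- NULL
  for (r in seq_len(replicates)) {
    cols[[sprintf("day0_rep%d", r)]] <-
      sample_timepoint(rep(1, n), depth, dispersion)
    cols[[sprintf("day24_rep%d", r)]] <-
      sample_timepoint(10^eff, depth, dispersion)
    smp <- rbind(smp, data.frame(
      sample_id = sprintf(c("day0_rep%d", "day24_rep%d"), r),
      timepoint = c("day0", "day24"), replicate = r,
      stringsAsFactors = FALSE))
  }
  m <- do.call(cbind, cols)
  rownames(m) <- g$guide_id
  tab <- count_table(m[, smp$sample_id, drop = FALSE], smp)
  structure(list(guides = g, counts = tab, effects = eff, config = config),
            class = cls)
}

#' Simulate a high-density CRISPR tiling scan
#'
#' Places targeting guides along a protein's coding sequence at a fixed
#' average density (default one guide per 3 amino acids, the resolution of a
#' saturating tiling library), plants hypersensitive segments whose guides
#' are depleted in proportion to the planted NCS depth, spikes control
#' guides, and samples counts as in \code{\link{simulate_screen}}. A planted
#' depth of -1 NCS corresponds to the positive-control depletion, so the
#' calibrated profile recovers the planted depths on average.
#'
#' @param protein_length residues (default 300).
#' @param spacing amino acids per guide (default 3.0).
#' @param segments list of \code{c(start, end, depth_ncs)} planted intervals
#'   (default one segment 120-140 at depth -1).
#' @param noise_sd per-guide Gaussian noise on the log10 effect (default 0.1).
#' @inheritParams simulate_screen
#' @return list of class \code{tiling_sim}: \code{guides}, \code{counts},
#'   \code{segments}, \code{config}.
#' @export
simulate_tiling <- function(protein_length = 300, spacing = 3.0,
                            segments = list(c(120, 140, -1.0)),
                            noise_sd = 0.1, n_neg_controls = 100,
                            n_pos_controls = 30, pos_control_effect = -1.5,
                            depth = 1e6, dispersion = 0.05, replicates = 2,
                            seed = 1) {
  for (s in segments)
    if (s[1] < 1 || s[2] > protein_length || s[1] > s[2])
      stop_("planted segment outside 1..protein_length")
  config <- list(protein_length = protein_length, spacing = spacing,
                 segments = segments, noise_sd = noise_sd,
                 n_neg_controls = n_neg_controls,
                 n_pos_controls = n_pos_controls,
                 pos_control_effect = pos_control_effect, depth = depth,
                 dispersion = dispersion, replicates = replicates,
                 seed = seed)
  with_seed(seed, {
    cut_nt <- unique(pmin(round(seq(2, protein_length * 3 - 1,
                                    by = spacing * 3)),
                          protein_length * 3L))
    g_targ <- data.frame(
      guide_id = sprintf("tile_%04d", seq_along(cut_nt)),
      category = "targeting", target_gene = "TILED",
      cut_nt = as.integer(cut_nt), stringsAsFactors = FALSE)
    g_neg <- data.frame(guide_id = sprintf("neg_%03d", seq_len(n_neg_controls)),
                        category = "negative_control", target_gene = "",
                        cut_nt = NA_integer_, stringsAsFactors = FALSE)
    g_pos <- data.frame(guide_id = sprintf("pos_%03d", seq_len(n_pos_controls)),
                        category = "positive_control", target_gene = "",
                        cut_nt = NA_integer_, stringsAsFactors = FALSE)
    g <- rbind(g_targ, g_neg, g_pos)
    g$protospacer <- random_protospacers(nrow(g))
    g$strand <- "+"
    g <- validate_guide_library(g)

    eff <- numeric(nrow(g))
    for (s in segments) {
      inseg <- g$category == "targeting" & !is.na(g$codon) &
        g$codon >= s[1] & g$codon <= s[2]
      # planted NCS depth -> log10 effect via the positive-control anchor
      eff[inseg] <- s[3] * abs(pos_control_effect)
    }
    eff[g$category == "positive_control"] <- pos_control_effect
    targ <- g$category == "targeting"
    eff[targ] <- eff[targ] + stats::rnorm(sum(targ), 0, noise_sd)

    out <- sim_counts_from_effects(g, eff, depth, dispersion, replicates,
                                   config, "tiling_sim")
    out$segments <- segments
    out
  })
}

#' Generate a propeller-like toy structure with a central cavity
#'
#' Pseudo-atoms arranged as \code{n_blades} wedge clusters on a ring around
#' an empty central cavity, mimicking the blade tips of a beta-propeller
#' domain enclosing its central pocket. The cavity center is at the origin
#' by construction and is returned for geometric ground truth. Atom
#' placement keeps every atom at least \code{cavity_radius} from the origin.
#'
#' @param n_blades wedge clusters (default 7).
#' @param blade_radius outer ring radius, Angstrom (default 15).
#' @param cavity_radius empty central radius, Angstrom (default 6).
#' @param atoms_per_blade pseudo-atoms per wedge (default 80).
#' @param half_height vertical half-extent of the wall, Angstrom (default 4).
#' @param seed integer seed.
#' @return list of class \code{toy_structure}: \code{atoms} (data frame
#'   \code{resno}, \code{elety}, \code{x}, \code{y}, \code{z}),
#'   \code{cavity_center} (c(0,0,0)), \code{pdb_text} (PDB lines),
#'   \code{config}. Usable directly as the \code{model} argument of
#'   \code{\link{define_box}} and \code{\link{detect_cavity}}.
#' @export
toy_structure <- function(n_blades = 7, blade_radius = 15, cavity_radius = 6,
                          atoms_per_blade = 80, half_height = 4, seed = 1) {
  if (n_blades > 0 && cavity_radius >= blade_radius)
    stop_("cavity radius must be smaller than blade radius")
  config <- list(n_blades = n_blades, blade_radius = blade_radius,
                 cavity_radius = cavity_radius,
                 atoms_per_blade = atoms_per_blade,
                 half_height = half_height, seed = seed)
  with_seed(seed, {
    if (n_blades < 1) {
      atoms <- data.frame(resno = integer(0), elety = character(0),
                          x = numeric(0), y = numeric(0), z = numeric(0))
    } else {
      wedge <- 2 * pi / n_blades
      rows <- lapply(seq_len(n_blades), function(k) {
        th0 <- (k - 1) * wedge
        # wedges overlap slightly so the ring wall is angularly closed
        th <- th0 + stats::runif(atoms_per_blade, -0.62 * wedge, 0.62 * wedge)
        r <- stats::runif(atoms_per_blade, cavity_radius + 1.2, blade_radius)
        z <- stats::runif(atoms_per_blade, -half_height, half_height)
        data.frame(x = r * cos(th), y = r * sin(th), z = z)
      })
      xyz <- do.call(rbind, rows)
      atoms <- data.frame(resno = seq_len(nrow(xyz)), elety = "C",
                          x = xyz$x, y = xyz$y, z = xyz$z)
    }
    pdb_text <- c(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      atoms$resno, atoms$resno, atoms$x, atoms$y, atoms$z), "END")
    structure(list(atoms = atoms, cavity_center = c(0, 0, 0),
                   pdb_text = pdb_text, config = config),
              class = "toy_structure")
  })
}

#' Melt-curve fixture presets
#'
#' Named Boltzmann parameter sets for the thermal-shift fixtures. The
#' \code{cpdav2_control} and \code{cpdav2_treated} presets encode the
#' apo/ligand-bound midpoints of the purified integrin alpha-V beta-propeller
#' thermal-shift experiment (52.0 and 58.1 degrees C; shift +6.1).
#'
#' @param name preset name.
#' @return list with \code{tm}, \code{slope}, \code{baseline_low},
#'   \code{baseline_high}.
#' @export
melt_preset <- function(name = c("cpdav2_control", "cpdav2_treated")) {
  name <- match.arg(name)
  switch(name,
         cpdav2_control = list(tm = 52.0, slope = 2.0, baseline_low = 0.1,
                               baseline_high = 1.0),
         cpdav2_treated = list(tm = 58.1, slope = 2.0, baseline_low = 0.1,
                               baseline_high = 1.0))
}

#' Simulate a thermal-shift melt curve
#'
#' Boltzmann sigmoid sampled over a temperature ramp with optional seeded
#' Gaussian noise.
#'
#' @param tm midpoint, degrees C (must lie inside the ramp).
#' @param slope transition slope, degrees C (default 2).
#' @param baseline_low,baseline_high folded/unfolded signal plateaus (AU).
#' @param noise_sd Gaussian noise sd in AU (default 0.01).
#' @param seed integer seed.
#' @param t_min,t_max,t_step ramp, degrees C (defaults 25-99 by 0.5).
#' @return data frame \code{temperature}, \code{fluorescence}.
#' @export
simulate_melt_curve <- function(tm, slope = 2.0, baseline_low = 0.1,
                                baseline_high = 1.0, noise_sd = 0.01,
                                seed = 1, t_min = 25, t_max = 99,
                                t_step = 0.5) {
  if (tm < t_min || tm > t_max) stop_("tm must lie inside the ramp")
  tt <- seq(t_min, t_max, by = t_step)
  f <- baseline_low + (baseline_high - baseline_low) /
    (1 + exp((tm - tt) / slope))
  if (noise_sd > 0)
    f <- with_seed(seed, f + stats::rnorm(length(tt), 0, noise_sd))
  data.frame(temperature = tt, fluorescence = f)
}

#' Simulate a dose-response table
#'
#' Four-parameter logistic response (percent of vehicle) over a
#' concentration series, with seeded multiplicative-free Gaussian noise.
#'
#' @param ic50 half-maximal inhibitory concentration.
#' @param hill hill slope (default 1).
#' @param top,bottom response plateaus in percent (defaults 100 / 0).
#' @param concentrations dose series (default half-log steps 0.1-100).
#' @param noise_sd Gaussian noise in percentage points (default 2).
#' @param seed integer seed.
#' @return data frame \code{concentration}, \code{pct_signal}.
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   concentrations = 10^seq(-1, 2, by = 0.5),
                                   noise_sd = 2, seed = 1) {
  y <- bottom + (top - bottom) / (1 + (concentrations / ic50)^hill)
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  data.frame(concentration = concentrations, pct_signal = y)
}

#' Write a simulated screen to disk in the package's file dialects
#'
#' Emits \code{library.tsv}, \code{counts.tsv}, \code{samples.tsv} and a
#' \code{config.json} sidecar recording the full generator configuration.
#'
#' @param sim a \code{screen_sim} or \code{tiling_sim}.
#' @param dir output directory (created if needed).
#' @return named vector of paths.
#' @export
write_screen_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- file.path(dir, "library.tsv")
  g <- as.data.frame(sim$guides)
  g$codon <- NULL
  utils::write.table(g, lib, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  cnt <- file.path(dir, "counts.tsv")
  df <- data.frame(guide_id = rownames(sim$counts$counts),
                   sim$counts$counts, check.names = FALSE)
  utils::write.table(df, cnt, sep = "\t", quote = FALSE, row.names = FALSE)
  smp <- file.path(dir, "samples.tsv")
  utils::write.table(sim$counts$samples, smp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- file.path(dir, "config.json")
  jsonlite::write_json(sim$config, cfg, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(library = lib, counts = cnt, samples = smp, config = cfg))
}

#' Write a toy structure as a PDB file
#'
#' @param toy a \code{toy_structure}.
#' @param path output path.
#' @export
write_toy_pdb <- function(toy, path) {
  writeLines(toy$pdb_text, path)
  invisible(path)
}
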