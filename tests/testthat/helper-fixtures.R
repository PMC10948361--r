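# fixtures built in code; everything is written to tempfiles at test time

write_manifest <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

manifest_row <- function(id, proto = strrep("ACGT", 5),
                         category = "targeting", gene = "GENE1",
                         cut_nt = 30, strand = "+") {
  list(guide_id = id, protospacer = proto, category = category,
       target_gene = gene, cut_nt = cut_nt, strand = strand)
}

# minimal 3-residue peptide, chain A, plus one water; resnos 1..3
toy_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.300   1.500   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.000   2.700   0.000  1.00  0.00           C",
    "ATOM      6  CA  SER A   3       5.500   2.900   1.000  1.00  0.00           C",
    "HETATM    7  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END")
}

# same 3-residue model in minimal mmCIF
toy_cif_text <- function() {
  c("data_toy",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N   . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N   1",
    "ATOM 2 C CA  . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 ? 1 ALA A CA  1",
    "ATOM 3 C C   . ALA A 1 1 ? 2.000 1.400 0.000 1.00 0.00 ? 1 ALA A C   1",
    "ATOM 4 N N   . GLY A 1 2 ? 3.300 1.500 0.000 1.00 0.00 ? 2 GLY A N   1",
    "ATOM 5 C CA  . GLY A 1 2 ? 4.000 2.700 0.000 1.00 0.00 ? 2 GLY A CA  1",
    "ATOM 6 C CA  . SER A 1 3 ? 5.500 2.900 1.000 1.00 0.00 ? 3 SER A CA  1")
}

write_lines_tmp <- function(lines, ext) {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

vina_log_text <- function(affinities) {
  c("AutoDock Vina v1.2.3",
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    sprintf("%5d %12.1f %10.3f %10.3f", seq_along(affinities), affinities,
            c(0, rep(1.5, length(affinities) - 1)),
            c(0, rep(2.5, length(affinities) - 1))))
}

# hollow axis-aligned cubic shell of pseudo-atoms with empty interior;
# returns an object usable as `model` for detect_cavity
hollow_shell <- function(half = 5, spacing = 1) {
  g <- seq(-half, half, by = spacing)
  pts <- expand.grid(x = g, y = g, z = g)
  on_face <- abs(pts$x) == half | abs(pts$y) == half | abs(pts$z) == half
  pts <- pts[on_face, ]
  list(atoms = data.frame(resno = seq_len(nrow(pts)), elety = "C",
                          x = pts$x, y = pts$y, z = pts$z))
}

# independent brute-force Gaussian smoother used as the oracle
brute_smooth <- function(raw, sigma, truncate) {
  L <- length(raw)
  out <- rep(NA_real_, L)
  half <- floor(truncate * sigma)
  for (r in seq_len(L)) {
    num <- 0; den <- 0
    for (j in max(1, r - half):min(L, r + half)) {
      if (!is.na(raw[j])) {
        w <- exp(-(r - j)^2 / (2 * sigma^2))
        num <- num + w * raw[j]
        den <- den + w
      }
    }
    if (den > 0) out[r] <- num / den
  }
  out
}
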