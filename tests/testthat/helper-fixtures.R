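# Shared fixtures, built in code at test time.

# hand-placed two-chain structure: an alanine at known coordinates on chain
# A plus a glycine on chain B, 20 A away unless shifted
tiny_dimer <- function(shift_b = c(20, 0, 0)) {
  ala <- data.frame(
    element = c("N", "C", "C", "O", "C"),
    x = c(0, 1.46, 2.0, 1.5, 2.0), y = c(0, 0, 1.3, 2.4, -1.2),
    z = 0, chain = "A", res_seq = "5", res_name = "ALA",
    name = c("N", "CA", "C", "O", "CB"),
    b_factor = 10, is_backbone = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  gly <- data.frame(
    element = c("N", "C", "C", "O"),
    x = c(0, 1.46, 2.0, 1.5) + shift_b[1], y = c(0, 0, 1.3, 2.4) + shift_b[2],
    z = shift_b[3], chain = "B", res_seq = "1", res_name = "GLY",
    name = c("N", "CA", "C", "O"),
    b_factor = 20, is_backbone = TRUE,
    stringsAsFactors = FALSE)
  new_structure("TINY", rbind(ala, gly), c(A = "P1", B = "P2"))
}

# minimal PDB text written by hand (known field values, including waters,
# altlocs and an insertion code)
write_tiny_pdb <- function(path, with_extras = FALSE) {
  fmt <- function(serial, name, alt, res, chain, resno, icode, x, y, z, occ,
                  b, elem, rectype = "ATOM  ") {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rectype, serial, name, alt, res, chain, resno, icode, x, y, z,
            occ, b, elem)
  }
  lines <- c(
    fmt(1, " N  ", " ", "ALA", "A", 5, " ", 0, 0, 0, 1, 10, "N"),
    fmt(2, " CA ", " ", "ALA", "A", 5, " ", 1.46, 0, 0, 1, 11.5, "C"))
  if (with_extras) {
    lines <- c(lines,
      # alternate conformations: B has the higher occupancy
      fmt(3, " CB ", "A", "ALA", "A", 5, " ", 2, -1.2, 0, 0.4, 12, "C"),
      fmt(4, " CB ", "B", "ALA", "A", 5, " ", 2.1, -1.1, 0, 0.6, 13, "C"),
      # insertion code 52A
      fmt(5, " CA ", " ", "GLY", "A", 52, "A", 5, 5, 5, 1, 20, "C"),
      fmt(6, " O  ", " ", "HOH", "A", 90, " ", 9, 9, 9, 1, 30, "O",
          rectype = "HETATM"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# minimal mmCIF with an atom_site loop
write_tiny_cif <- function(path) {
  writeLines(c(
    "data_toy", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 5 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.000 1.00 12.00 ? 5 ALA A CA 1",
    "ATOM 3 C C . ALA B 1 1 ? 8.000 2.000 3.000 1.00 11.00 ? 6 ALA B C 1"),
    path)
  path
}

# first mutation code resolvable at a chain-A residue of a structure
toy_mutation <- function(s, res_seq = "8", mut_aa = "G") {
  sel <- s$atoms$chain == "A" & s$atoms$res_seq == res_seq
  wt <- topoddg:::three_to_one(s$atoms$res_name[sel][1])
  if (wt == mut_aa) mut_aa <- if (wt == "G") "A" else "G"
  parse_mutation_code(paste0(wt, "A", res_seq, mut_aa))
}

# ensemble of random labeled point clouds shared by the spectral acceptance
# checks: <= 12 points each, fixed seed, with 5 random snapshot scales
make_cloud_ensemble <- function(n_clouds, seed = 20240606, max_points = 12) {
  set.seed(seed)
  lapply(seq_len(n_clouds), function(i) {
    n <- sample(4:max_points, 1)
    list(coords = matrix(stats::runif(3 * n, 0, 3), ncol = 3),
         groups = sample(c("P1", "P2"), n, replace = TRUE),
         snapshots = sort(stats::runif(5, 0.3, 3.5)))
  })
}

cloud_ensemble_cache <- new.env(parent = emptyenv())

shared_cloud_ensemble <- function(n_clouds = 500) {
  key <- paste0("n", n_clouds)
  if (is.null(cloud_ensemble_cache[[key]])) {
    cloud_ensemble_cache[[key]] <- make_cloud_ensemble(n_clouds)
  }
  cloud_ensemble_cache[[key]]
}
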