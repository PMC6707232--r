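# Fixture builders: all test inputs are generated in code.

# Write raw PDB ATOM records (independent of the package's writer).
write_pdb_fixture <- function(path, chain, resno, resname, elety, xyz,
                              element = substr(trimws(elety), 1, 1)) {
  n <- length(chain)
  lines <- vapply(seq_len(n), function(i) {
    name <- trimws(elety[i])
    name_field <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name_field, resname[i], chain[i], resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0, element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# Minimal mmCIF with an atom_site loop (independent of any writer).
write_cif_fixture <- function(path, chain, resno, resname, elety, xyz) {
  hdr <- c("data_fixture", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.label_alt_id", "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_along(chain), function(i) {
    sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f . 1",
            i, substr(trimws(elety[i]), 1, 1), elety[i], resname[i],
            chain[i], resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  writeLines(c(hdr, rows, "#"), path)
  path
}

# A small helical-ish chain of CA-only residues.
ca_chain_xyz <- function(n, origin = c(0, 0, 0)) {
  t <- seq_len(n)
  cbind(2.3 * cos(0.6 * t), 2.3 * sin(0.6 * t), 1.5 * t) +
    matrix(origin, n, 3, byrow = TRUE)
}

# CA-only test structure with one or more chains.
make_ca_structure <- function(nres_per_chain, chains = LETTERS[seq_along(nres_per_chain)]) {
  path <- tempfile(fileext = ".pdb")
  ch <- rep(chains, nres_per_chain)
  resno <- unlist(lapply(nres_per_chain, seq_len))
  xyz <- do.call(rbind, lapply(seq_along(nres_per_chain), function(k) {
    ca_chain_xyz(nres_per_chain[k], origin = c(30 * (k - 1), 0, 0))
  }))
  write_pdb_fixture(path, ch, resno, rep("ALA", length(ch)),
                    rep("CA", length(ch)), xyz, rep("C", length(ch)))
  read_structure(path)
}

# Hand-built two-conformer pair for the exclusive-satisfaction test:
# link1 satisfied only in the closed model, link2 only in the open one.
make_two_conformers <- function() {
  anchors <- rbind(c(0, 0, 0), c(80, 0, 0), c(40, 60, 0))
  stat <- function(pos_m) {
    bead_model(chain = c("S", "S", "S", "M"), resno = c(1, 2, 3, 1),
               xyz = rbind(anchors, pos_m),
               body = c("S", "S", "S", "M"),
               mobile = c(FALSE, FALSE, FALSE, TRUE))
  }
  list(closed = stat(c(30, 0, 0)),   # 30 from S1, 50 from S2
       open   = stat(c(45, 0, 0)))   # 45 from S1, 35 from S2
}
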