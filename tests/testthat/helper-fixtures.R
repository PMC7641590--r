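# Shared fixtures, built once per test run.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, " ", x, y, z, occ, 0,
          element)
}

# three-residue peptide, CA plus a couple of heavy atoms per residue
pdb_text_3res <- function() {
  lines <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0, element = "C"),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.2, 1.2, 0.0),
    pdb_atom_line(4, "N",  "GLY", "A", 2, 3.5, 1.2, 0.5),
    pdb_atom_line(5, "CA", "GLY", "A", 2, 4.9, 1.6, 0.3, element = "C"),
    pdb_atom_line(6, "C",  "GLY", "A", 2, 5.9, 0.6, 0.9),
    pdb_atom_line(7, "N",  "SER", "A", 3, 7.1, 1.0, 1.2),
    pdb_atom_line(8, "CA", "SER", "A", 3, 8.4, 0.3, 1.4, element = "C"),
    pdb_atom_line(9, "OG", "SER", "A", 3, 9.1, 1.1, 2.4, element = "O"),
    "END")
  paste(lines, collapse = "\n")
}

# one residue with an A/B altloc on CA; B has the higher occupancy
pdb_text_altloc <- function() {
  paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1.0, 0.0, 0.0, occ = 0.4,
                  alt = "A", element = "C"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2.0, 0.0, 0.0, occ = 0.6,
                  alt = "B", element = "C"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 4.0, 0.0, 0.0, element = "C"),
    "END"), collapse = "\n")
}

# short protein chain A + two DNA nucleotides in chain B
pdb_text_protein_dna <- function() {
  nt <- function(serial0, resno, zoff) {
    c(pdb_atom_line(serial0 + 0, "P",   "DA", "B", resno, 10.0, 0.0, zoff, element = "P"),
      pdb_atom_line(serial0 + 1, "OP1", "DA", "B", resno, 10.8, 0.8, zoff, element = "O"),
      pdb_atom_line(serial0 + 2, "OP2", "DA", "B", resno,  9.2, 0.8, zoff, element = "O"),
      pdb_atom_line(serial0 + 3, "C5'", "DA", "B", resno, 10.0, -1.4, zoff + 0.5, element = "C"),
      pdb_atom_line(serial0 + 4, "C4'", "DA", "B", resno, 10.6, -2.4, zoff + 1.2, element = "C"),
      pdb_atom_line(serial0 + 5, "O4'", "DA", "B", resno, 11.8, -2.2, zoff + 1.6, element = "O"),
      pdb_atom_line(serial0 + 6, "C1'", "DA", "B", resno, 12.0, -3.3, zoff + 2.4, element = "C"),
      pdb_atom_line(serial0 + 7, "N9",  "DA", "B", resno, 13.2, -3.4, zoff + 3.1, element = "N"),
      pdb_atom_line(serial0 + 8, "C8",  "DA", "B", resno, 14.1, -2.5, zoff + 3.4, element = "C"),
      pdb_atom_line(serial0 + 9, "N7",  "DA", "B", resno, 15.1, -3.0, zoff + 4.0, element = "N"))
  }
  paste(c(
    pdb_atom_line(1, "CA", "ARG", "A", 1, 6.0, 0.0, 0.0, element = "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 6.0, 0.0, 3.8, element = "C"),
    pdb_atom_line(3, "CA", "GLU", "A", 3, 6.0, 0.0, 7.6, element = "C"),
    nt(4, 1, 0.0),
    nt(14, 2, 6.0),
    "END"), collapse = "\n")
}

# n-residue CA-only chain along a compact curve (for topology combinatorics)
pdb_text_ca_chain <- function(n, resnames = rep("GLY", n)) {
  ang <- (seq_len(n) - 1) * 1.9
  lines <- vapply(seq_len(n), function(i)
    pdb_atom_line(i, "CA", resnames[i], "A", i,
                  2.3 * cos(ang[i]), 2.3 * sin(ang[i]), 1.5 * (i - 1),
                  element = "C"),
    character(1))
  paste(c(lines, "END"), collapse = "\n")
}

toy_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_toy_multidomain(toy_spec(seed = 1))
    val
  }
})

binding_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_toy_binding_system()
    val
  }
})

dpo4_domain_map <- function() {
  domain_map(F = c(11, 77), P = list(c(1, 10), c(78, 166)),
             T = c(167, 229), linker = c(230, 244), LF = c(245, 341))
}
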