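#' Parse a PDB entry into an atomistic structure
#'
#' Reads a PDB file (or raw PDB text) into a light atomistic table used by
#' [coarse_grain()] and [build_contacts()].  Coordinates are converted from
#' Angstrom to nanometres.  Only the first MODEL of a multi-model entry is
#' used.  Alternate locations are resolved to the highest-occupancy copy.
#' Waters and non-nucleic heteroatoms are dropped; nucleotides (DA/DT/DG/DC
#' and ribo equivalents) are kept and flagged nucleic.
#'
#' @param pdb path to a PDB file, or a character string containing PDB text
#'   (anything with a newline is treated as text).
#' @return an object of class `atomistic`: a list with element `atoms`, a
#'   data.frame with columns chain, resno, resname, elety (atom name),
#'   element, x, y, z (nm), occupancy and is_nucleic.
#' @export
parse_pdb <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records found in PDB input")
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad) > 0)
    stop("malformed PDB record at line ", bad[1], ": ", lines[bad[1]])

  # restrict to the first MODEL when present
  mstart <- grep("^MODEL", lines)
  if (length(mstart) >= 2) {
    mend <- grep("^ENDMDL", lines)
    keep_to <- if (length(mend) >= 1) mend[1] else length(lines)
    lines <- lines[seq_len(keep_to)]
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdbobj <- tryCatch(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE),
                     error = function(e) stop("PDB parse error: ",
                                              conditionMessage(e)))
  at <- pdbobj$atom
  nucleic_names <- c("DA", "DT", "DG", "DC", "DU", "DI",
                     "A", "T", "G", "C", "U", "I")
  is_nuc <- at$resid %in% nucleic_names
  keep <- (at$type == "ATOM" | is_nuc) & at$resid != "HOH"
  at <- at[keep, , drop = FALSE]
  is_nuc <- is_nuc[keep]
  if (nrow(at) == 0) stop("PDB entry contains no protein or nucleic atoms")

  # drop hydrogens, resolve altlocs to highest occupancy
  heavy <- !(substr(gsub("[0-9]", "", at$elety), 1, 1) %in% "H")
  at <- at[heavy, , drop = FALSE]
  is_nuc <- is_nuc[heavy]
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]
  is_nuc <- is_nuc[ord]
  occ <- occ[ord]
  first <- !duplicated(key[ord])
  at <- at[first, , drop = FALSE]
  is_nuc <- is_nuc[first]
  occ <- occ[first]

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, resname = at$resid,
    elety = at$elety, element = at$elesy,
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    occupancy = occ, is_nucleic = is_nuc,
    stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL

  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, ]
    if (nrow(sub) == 0) stop("empty chain '", ch, "' in PDB input")
  }
  structure(list(atoms = atoms), class = "atomistic")
}

#' @export
print.atomistic <- function(x, ...) {
  a <- x$atoms
  cat("<atomistic structure> ", nrow(a), " heavy atoms, ",
      length(unique(a$chain)), " chain(s)\n", sep = "")
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, ]
    cat("  chain ", ch, ": residues ", min(sub$resno), "-", max(sub$resno),
        if (any(sub$is_nucleic)) " (nucleic)" else "", "\n", sep = "")
  }
  invisible(x)
}

# minimal PDB text emitter for bead models (toy reference structures)
bead_pdb_text <- function(model) {
  b <- model$beads
  kind_name <- c(CA = "CA", sugar = "CS", base = "CB", phosphate = "P")
  lines <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    resname <- substr(sprintf("%-3s", b$resname[i]), 1, 3)
    lines[i] <- sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, kind_name[[b$kind[i]]], " ", resname, b$chain[i], b$resid[i], " ",
      b$x[i] * 10, b$y[i] * 10, b$z[i] * 10, 1.0, 0.0)
  }
  paste(c(lines, "END"), collapse = "\n")
}
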