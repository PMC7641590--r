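#' Domain definitions
#'
#' A domain map names residue intervals of the protein chain.  Intervals are
#' inclusive and 1-based, matching PDB residue numbering.  The reserved name
#' `linker` marks the flexible connector whose contacts are grouped with the
#' interdomain class.
#'
#' @param ... named interval specs.  Each is either `c(from, to)` or a list
#'   of such vectors for split domains (e.g. the palm domain of DPO4 spans
#'   1-10 and 78-166).
#' @return a named list of integer residue vectors, class `domain_map`.
#' @examples
#' dpo4_domains <- domain_map(
#'   F = c(11, 77), P = list(c(1, 10), c(78, 166)),
#'   T = c(167, 229), linker = c(230, 244), LF = c(245, 341))
#' domain_sizes(dpo4_domains)
#' @export
domain_map <- function(...) {
  defs <- list(...)
  if (is.null(names(defs)) || any(names(defs) == ""))
    stop("all domain definitions must be named")
  out <- lapply(defs, function(d) {
    if (is.list(d)) d <- unlist(lapply(d, function(iv) seq(iv[1], iv[2])))
    else if (length(d) == 2) d <- seq(d[1], d[2])
    as.integer(sort(unique(d)))
  })
  all_res <- unlist(out)
  if (anyDuplicated(all_res))
    stop("domain definitions overlap at residue(s) ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  class(out) <- "domain_map"
  out
}

#' @rdname domain_map
#' @param map a `domain_map`
#' @export
domain_sizes <- function(map) vapply(map, length, integer(1))

# residue -> element name lookup ("linker" included); NA when uncovered
domain_of <- function(map, resno) {
  out <- rep(NA_character_, length(resno))
  for (nm in names(map)) out[resno %in% map[[nm]]] <- nm
  out
}

#' Coarse-grain an atomistic structure
#'
#' Maps each protein residue to one C-alpha bead and each nucleotide to
#' three beads (sugar, base, phosphate), builds the bonded topology (bonds,
#' angles, dihedrals along each protein chain; bonds within and between
#' nucleotide beads), records native bonded geometry, assigns charges via
#' [assign_charges()], and optionally freezes nucleic beads.
#'
#' @param structure an `atomistic` object from [parse_pdb()].
#' @param domains a [domain_map()] covering every protein residue.
#' @param freeze_nucleic logical; freeze all nucleic beads (the binding
#'   partner is held rigid during simulations).
#' @return a `cg_model`: list with `beads` (index, chain, resid, resname,
#'   kind, x, y, z in nm, charge, frozen, domain), `bonds`, `angles`,
#'   `dihedrals` with native values, and `domain_map`.
#' @export
coarse_grain <- function(structure, domains, freeze_nucleic = TRUE) {
  stopifnot(inherits(structure, "atomistic"))
  a <- structure$atoms
  beads <- list()
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    nuc <- any(sub$is_nucleic)
    for (rn in unique(sub$resno)) {
      res <- sub[sub$resno == rn, , drop = FALSE]
      if (!nuc) {
        ca <- res[res$elety == "CA", , drop = FALSE]
        if (nrow(ca) == 0)
          stop("residue ", rn, " in chain ", ch, " has no CA atom")
        beads[[length(beads) + 1]] <- data.frame(
          chain = ch, resid = rn, resname = res$resname[1], kind = "CA",
          x = ca$x[1], y = ca$y[1], z = ca$z[1], stringsAsFactors = FALSE)
      } else {
        grp <- nucleotide_groups(res)
        for (k in c("phosphate", "sugar", "base")) {
          g <- grp[[k]]
          if (nrow(g) == 0)
            stop("nucleotide ", rn, " in chain ", ch, " lacks ", k, " atoms")
          beads[[length(beads) + 1]] <- data.frame(
            chain = ch, resid = rn, resname = res$resname[1], kind = k,
            x = mean(g$x), y = mean(g$y), z = mean(g$z),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  beads <- do.call(rbind, beads)
  beads$index <- seq_len(nrow(beads))
  is_protein <- beads$kind == "CA"
  beads$frozen <- freeze_nucleic & !is_protein
  beads$domain <- NA_character_
  beads$domain[is_protein] <- domain_of(domains, beads$resid[is_protein])
  uncov <- is_protein & is.na(beads$domain)
  if (any(uncov))
    stop("residue(s) not covered by domain map: ",
         paste(unique(beads$resid[uncov]), collapse = ", "))

  model <- list(beads = beads, domain_map = domains)
  class(model) <- "cg_model"
  model <- build_bonded_topology(model)
  assign_charges(model)
}

# group heavy atoms of one nucleotide into phosphate / sugar / base sets
nucleotide_groups <- function(res) {
  nm <- res$elety
  phos <- nm %in% c("P", "OP1", "OP2", "O1P", "O2P")
  sugar <- grepl("'", nm, fixed = TRUE)
  base <- !phos & !sugar
  list(phosphate = res[phos, , drop = FALSE],
       sugar = res[sugar, , drop = FALSE],
       base = res[base, , drop = FALSE])
}

bond_length <- function(p, i, j) {
  sqrt(sum((p[j, ] - p[i, ])^2))
}

bond_angle <- function(p, i, j, k) {
  a <- p[i, ] - p[j, ]; b <- p[k, ] - p[j, ]
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ct)))
}

dihedral_angle <- function(p, i, j, k, l) {
  b1 <- p[j, ] - p[i, ]; b2 <- p[k, ] - p[j, ]; b3 <- p[l, ] - p[k, ]
  n1 <- crossprod3(b1, b2); n2 <- crossprod3(b2, b3)
  m <- crossprod3(n1, n2)
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

build_bonded_topology <- function(model) {
  b <- model$beads
  p <- as.matrix(b[, c("x", "y", "z")])
  bonds <- list(); angles <- list(); dihedrals <- list()
  for (ch in unique(b$chain)) {
    idx <- b$index[b$chain == ch]
    protein <- all(b$kind[idx] == "CA")
    if (protein) {
      n <- length(idx)
      if (n >= 2)
        bonds[[length(bonds) + 1]] <- data.frame(i = idx[-n], j = idx[-1])
      if (n >= 3)
        angles[[length(angles) + 1]] <- data.frame(
          i = idx[1:(n - 2)], j = idx[2:(n - 1)], k = idx[3:n])
      if (n >= 4)
        dihedrals[[length(dihedrals) + 1]] <- data.frame(
          i = idx[1:(n - 3)], j = idx[2:(n - 2)], k = idx[3:(n - 1)],
          l = idx[4:n])
    } else if (!any(b$kind[idx] == "sugar")) {
      # single-bead partner chain (e.g. a frozen phosphate rod): plain chain
      n <- length(idx)
      if (n >= 2)
        bonds[[length(bonds) + 1]] <- data.frame(i = idx[-n], j = idx[-1])
    } else {
      # nucleotide beads come in (phosphate, sugar, base) triplets per residue
      resids <- unique(b$resid[idx])
      for (ri in seq_along(resids)) {
        tri <- idx[b$resid[idx] == resids[ri]]
        ph <- tri[b$kind[tri] == "phosphate"]
        su <- tri[b$kind[tri] == "sugar"]
        ba <- tri[b$kind[tri] == "base"]
        bonds[[length(bonds) + 1]] <- data.frame(i = c(ph, su), j = c(su, ba))
        if (ri > 1) {
          prev_su <- idx[b$resid[idx] == resids[ri - 1] & b$kind[idx] == "sugar"]
          bonds[[length(bonds) + 1]] <- data.frame(i = prev_su, j = ph)
        }
      }
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(0), j = integer(0))
  angles <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(0), j = integer(0), k = integer(0))
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else
    data.frame(i = integer(0), j = integer(0), k = integer(0), l = integer(0))
  bonds$r0 <- vapply(seq_len(nrow(bonds)), function(r)
    bond_length(p, bonds$i[r], bonds$j[r]), numeric(1))
  angles$theta0 <- vapply(seq_len(nrow(angles)), function(r)
    bond_angle(p, angles$i[r], angles$j[r], angles$k[r]), numeric(1))
  dihedrals$phi0 <- vapply(seq_len(nrow(dihedrals)), function(r)
    dihedral_angle(p, dihedrals$i[r], dihedrals$j[r], dihedrals$k[r],
                   dihedrals$l[r]), numeric(1))
  model$bonds <- bonds
  model$angles <- angles
  model$dihedrals <- dihedrals
  model
}

#' Assign bead charges
#'
#' Arg and Lys C-alpha beads carry +1, Asp and Glu carry -1, nucleotide
#' phosphate beads carry -1; every other bead is neutral.  Unrecognised
#' residue names get charge 0 with a warning.
#'
#' @param model a `cg_model`
#' @return the model with the `charge` column of `beads` filled in.
#' @export
assign_charges <- function(model) {
  b <- model$beads
  known <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "DA", "DT", "DG", "DC", "DU", "A", "T", "G", "C",
             "U", "BEA", "NUC")
  charge <- numeric(nrow(b))
  charge[b$kind == "CA" & b$resname %in% c("ARG", "LYS")] <- 1
  charge[b$kind == "CA" & b$resname %in% c("ASP", "GLU")] <- -1
  charge[b$kind == "phosphate"] <- -1
  unk <- !(b$resname %in% known)
  if (any(unk))
    warning("unknown residue name(s) assigned charge 0: ",
            paste(unique(b$resname[unk]), collapse = ", "))
  model$beads$charge <- charge
  model
}

#' @export
print.cg_model <- function(x, ...) {
  b <- x$beads
  cat("<cg_model> ", nrow(b), " beads (", sum(b$kind == "CA"), " CA, ",
      sum(b$kind != "CA"), " nucleic), ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$dihedrals), " dihedrals\n", sep = "")
  if (!is.null(x$domain_map))
    cat("  domains: ", paste(names(x$domain_map), domain_sizes(x$domain_map),
                             sep = ":", collapse = ", "), "\n", sep = "")
  if (any(b$frozen)) cat("  frozen beads: ", sum(b$frozen), "\n", sep = "")
  invisible(x)
}

#' Native bead coordinates of a model
#' @param model a `cg_model`
#' @return an n x 3 matrix in nm
#' @export
native_coords <- function(model) {
  as.matrix(model$beads[, c("x", "y", "z")])
}
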