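#' Build the native contact map
#'
#' Residue pairs whose closest heavy atoms lie within `cutoff` and whose
#' sequence separation is at least `min_separation` become one contact
#' between their beads, with the native bead-bead distance as the contact
#' length sigma.  Protein-nucleic pairs use `min_separation_interchain`
#' (interchain pairs have no meaningful sequence separation) and attach to
#' the nucleotide bead whose atom group holds the closest atom.
#'
#' @param atomistic an `atomistic` structure (same molecule as `model`).
#' @param model the corresponding `cg_model`.
#' @param method `"heavy"` (all-heavy-atom cutoff, the default) or `"ca"`
#'   (bead-bead cutoff, used by the synthetic toy generators whose reference
#'   structures are bead-resolution).
#' @param cutoff distance cutoff in nm (> 0).
#' @param min_separation minimum |resno difference| for intra-chain protein
#'   contacts (default 4).
#' @param min_separation_interchain minimum separation for protein-nucleic
#'   pairs (default 1, i.e. all pairs eligible).
#' @return a `contact_set`: data.frame with columns i, j (bead indices,
#'   i < j), sigma (nm), class, label, basin.  Intra-protein contacts are
#'   left `"unclassified"` until [classify_contacts()]; protein-nucleic
#'   contacts are class `"binding"`.
#' @export
build_contacts <- function(atomistic, model, method = c("heavy", "ca"),
                           cutoff = 0.45, min_separation = 4,
                           min_separation_interchain = 1) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive")
  b <- model$beads
  pos <- native_coords(model)
  rows <- list()

  if (method == "ca") {
    # bead-resolution scan
    n <- nrow(b)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same_chain <- b$chain[i] == b$chain[j]
        protein_pair <- b$kind[i] == "CA" && b$kind[j] == "CA"
        minsep <- if (protein_pair && same_chain) min_separation
                  else min_separation_interchain
        if (same_chain && abs(b$resid[j] - b$resid[i]) < minsep) next
        if (!same_chain && !protein_pair &&
            !(b$kind[i] == "CA" || b$kind[j] == "CA")) next
        d <- sqrt(sum((pos[j, ] - pos[i, ])^2))
        if (d < cutoff) {
          cls <- if (protein_pair && same_chain) "unclassified" else "binding"
          rows[[length(rows) + 1]] <- data.frame(
            i = i, j = j, sigma = d, class = cls, stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    a <- atomistic$atoms
    # map each bead to its atom rows
    bead_atoms <- vector("list", nrow(b))
    for (bi in seq_len(nrow(b))) {
      sel <- a$chain == b$chain[bi] & a$resno == b$resid[bi]
      res <- a[sel, , drop = FALSE]
      if (b$kind[bi] != "CA") {
        grp <- nucleotide_groups(res)
        res <- grp[[b$kind[bi]]]
      }
      bead_atoms[[bi]] <- as.matrix(res[, c("x", "y", "z")])
    }
    # residue-level units: protein residue -> one CA bead; nucleotide -> 3 beads
    units <- unique(b[, c("chain", "resid")])
    nu <- nrow(units)
    for (ui in seq_len(nu - 1)) {
      for (uj in (ui + 1):nu) {
        bi_set <- b$index[b$chain == units$chain[ui] & b$resid == units$resid[ui]]
        bj_set <- b$index[b$chain == units$chain[uj] & b$resid == units$resid[uj]]
        protein_pair <- all(b$kind[c(bi_set, bj_set)] == "CA")
        same_chain <- units$chain[ui] == units$chain[uj]
        minsep <- if (protein_pair && same_chain) min_separation
                  else min_separation_interchain
        if (same_chain &&
            abs(units$resid[uj] - units$resid[ui]) < minsep) next
        # closest heavy-atom pair over every bead-bead combination
        best <- Inf; best_bi <- NA; best_bj <- NA
        for (bi in bi_set) for (bj in bj_set) {
          A <- bead_atoms[[bi]]; B <- bead_atoms[[bj]]
          d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
          dmin <- sqrt(max(0, min(d2)))
          if (dmin < best) { best <- dmin; best_bi <- bi; best_bj <- bj }
        }
        if (best < cutoff) {
          sig <- sqrt(sum((pos[best_bj, ] - pos[best_bi, ])^2))
          cls <- if (protein_pair && same_chain) "unclassified" else "binding"
          rows[[length(rows) + 1]] <- data.frame(
            i = best_bi, j = best_bj, sigma = sig, class = cls,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  cs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(0), j = integer(0), sigma = numeric(0),
               class = character(0), stringsAsFactors = FALSE)
  cs$label <- rep(NA_character_, nrow(cs))
  cs$basin <- rep("apo", nrow(cs))
  cs <- cs[order(cs$i, cs$j), , drop = FALSE]
  rownames(cs) <- NULL
  class(cs) <- c("contact_set", "data.frame")
  cs
}

#' Classify contacts by domain membership
#'
#' Both endpoints in one domain gives `intra` (label = domain); endpoints in
#' two different domains gives `inter` (label = sorted pair); any endpoint in
#' the linker gives class `linker` (linker interactions are grouped with the
#' interdomain class and scaled by the same epsilon); protein-nucleic
#' contacts keep class `binding`.
#'
#' @param contacts a `contact_set`
#' @param model the `cg_model` holding the domain map (or a `domain_map`
#'   plus a beads table via `model$beads`).
#' @return the contact set with class/label columns filled in.
#' @export
classify_contacts <- function(contacts, model) {
  b <- model$beads
  dom <- b$domain
  cls <- contacts$class
  lab <- contacts$label
  for (r in seq_len(nrow(contacts))) {
    if (identical(cls[r], "binding")) next
    di <- dom[contacts$i[r]]; dj <- dom[contacts$j[r]]
    if (is.na(di) || is.na(dj))
      stop("contact endpoint outside the domain map (beads ",
           contacts$i[r], ", ", contacts$j[r], ")")
    if (di == "linker" || dj == "linker") {
      cls[r] <- "linker"
      lab[r] <- paste(sort(c(di, dj)), collapse = "-")
    } else if (di == dj) {
      cls[r] <- "intra"
      lab[r] <- di
    } else {
      cls[r] <- "inter"
      lab[r] <- paste(sort(c(di, dj)), collapse = "-")
    }
  }
  contacts$class <- cls
  contacts$label <- lab
  contacts
}

#' Merge apo and binary-structure contacts into a dual-basin set
#'
#' The union keeps every apo contact (those also present in the bound-form
#' structure are marked basin `"shared"`), adds intra-protein contacts found
#' only in the bound structure as basin `"binary-only"` (in DPO4 these sit
#' at the F-LF interface formed on DNA binding), and appends the
#' protein-nucleic binding contacts of the bound structure.  When a shared
#' contact has conflicting native lengths, the apo value is kept and the
#' difference reported via `message()`.
#'
#' @param apo_contacts classified `contact_set` of the apo structure.
#' @param binary_contacts `contact_set` of the bound structure, computed
#'   with the same method and cutoff, on a model with identical bead
#'   indexing for the shared protein.
#' @param sigma_tol report sigma conflicts larger than this (nm).
#' @return a dual-basin `contact_set`.
#' @export
build_dual_basin <- function(apo_contacts, binary_contacts, sigma_tol = 1e-6) {
  key <- function(cs) paste(cs$i, cs$j, sep = "-")
  apo <- as.data.frame(apo_contacts)
  bin <- as.data.frame(binary_contacts)
  bin_pp <- bin[bin$class != "binding", , drop = FALSE]
  bin_bind <- bin[bin$class == "binding", , drop = FALSE]

  apo$basin <- ifelse(key(apo) %in% key(bin_pp), "shared", "apo")
  shared <- merge(apo[apo$basin == "shared", c("i", "j", "sigma")],
                  bin_pp[, c("i", "j", "sigma")], by = c("i", "j"),
                  suffixes = c("_apo", "_bin"))
  dif <- abs(shared$sigma_apo - shared$sigma_bin) > sigma_tol
  if (any(dif))
    message(sum(dif), " shared contact(s) differ in native length; ",
            "apo values kept (max |delta| = ",
            signif(max(abs(shared$sigma_apo - shared$sigma_bin)), 3), " nm)")

  only_bin <- bin_pp[!(key(bin_pp) %in% key(apo)), , drop = FALSE]
  if (nrow(only_bin)) only_bin$basin <- "binary-only"
  if (nrow(bin_bind)) bin_bind$basin <- "binary-only"
  out <- rbind(apo, only_bin, bin_bind)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_set", "data.frame")
  out
}

#' Count contacts by class
#' @param contacts a `contact_set`
#' @return named integer vector over classes, plus `total`.
#' @export
contact_counts <- function(contacts) {
  tab <- table(factor(contacts$class,
                      levels = c("intra", "inter", "linker", "binding",
                                 "unclassified")))
  out <- c(as.vector(tab), nrow(contacts))
  names(out) <- c(names(tab), "total")
  out
}

#' Select contact subsets
#'
#' Convenience selectors used to define the collective variables: all
#' intra-protein contacts, the interdomain-plus-linker set (the `Q(Inter)`
#' coordinate), per-domain or per-interface sets, and binding contacts.
#'
#' @param contacts a `contact_set`
#' @param what one of "total", "inter", "binding", "intra", or a label such
#'   as a domain name or interface pair name.
#' @param basin optional basin filter (e.g. `c("apo", "shared")` for the
#'   folding contact set of a dual-basin model); `NULL` keeps all.
#' @return a `contact_set` subset.
#' @export
contact_subset <- function(contacts, what = "total", basin = NULL) {
  cs <- contacts
  if (!is.null(basin)) cs <- cs[cs$basin %in% basin, , drop = FALSE]
  sel <- switch(what,
    total = cs$class %in% c("intra", "inter", "linker"),
    inter = cs$class %in% c("inter", "linker"),
    intra = cs$class == "intra",
    binding = cs$class == "binding",
    cs$label == what & !is.na(cs$label))
  out <- cs[sel, , drop = FALSE]
  class(out) <- c("contact_set", "data.frame")
  out
}

#' @export
print.contact_set <- function(x, ...) {
  cnt <- contact_counts(x)
  cat("<contact_set> ", nrow(x), " contacts: ",
      paste(names(cnt)[cnt > 0 & names(cnt) != "total"],
            cnt[cnt > 0 & names(cnt) != "total"],
            sep = "=", collapse = ", "), "\n", sep = "")
  if (any(x$basin != "apo"))
    cat("  basins: ", paste(names(table(x$basin)), table(x$basin),
                            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write / read a contact set as CSV
#'
#' One contact per row: i, j, sigma_nm, class, label, basin.
#' @param contacts a `contact_set`
#' @param path file path
#' @export
write_contacts <- function(contacts, path) {
  df <- as.data.frame(contacts)
  names(df)[names(df) == "sigma"] <- "sigma_nm"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "sigma_nm"] <- "sigma"
  class(df) <- c("contact_set", "data.frame")
  df
}
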