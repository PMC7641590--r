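test_that("PDB parsing recovers residues, coordinates and chains", {
  s <- parse_pdb(pdb_text_3res())
  a <- s$atoms
  expect_equal(length(unique(a$resno)), 3)
  ca <- a[a$elety == "CA", ]
  expect_equal(ca$x, c(1.5, 4.9, 8.4) / 10)  # Angstrom -> nm
  expect_false(any(a$is_nucleic))

  expect_error(parse_pdb("HEADER only, no atoms"), "no ATOM")
  expect_error(parse_pdb("ATOM      1  CA  ALA A"), "malformed.*line 1")
})

test_that("alternate locations resolve to the highest occupancy copy", {
  s <- parse_pdb(pdb_text_altloc())
  ca1 <- s$atoms[s$atoms$resno == 1 & s$atoms$elety == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 0.2)           # the occupancy-0.6 copy at 2 A
  expect_equal(ca1$occupancy, 0.6)
})

test_that("protein-DNA entries keep both chains with nucleotides flagged", {
  s <- parse_pdb(pdb_text_protein_dna())
  expect_setequal(unique(s$atoms$chain), c("A", "B"))
  expect_true(all(s$atoms$is_nucleic[s$atoms$chain == "B"]))
  expect_false(any(s$atoms$is_nucleic[s$atoms$chain == "A"]))
  expect_equal(length(unique(s$atoms$resno[s$atoms$chain == "B"])), 2)
})

test_that("domain interval arithmetic reproduces the DPO4 domain sizes", {
  sizes <- domain_sizes(dpo4_domain_map())
  expect_equal(unname(sizes[c("F", "P", "T", "linker", "LF")]),
               c(67, 99, 63, 15, 97))
  expect_error(domain_map(A = c(1, 10), B = c(5, 20)), "overlap")
})

test_that("coarse-graining builds chain topology and bead kinds", {
  s <- parse_pdb(pdb_text_ca_chain(10))
  m <- coarse_grain(s, domain_map(D1 = c(1, 10)))
  expect_equal(nrow(m$beads), 10)
  expect_equal(nrow(m$bonds), 9)
  expect_equal(nrow(m$angles), 8)
  expect_equal(nrow(m$dihedrals), 7)

  sd2 <- parse_pdb(pdb_text_protein_dna())
  m2 <- coarse_grain(sd2, domain_map(D1 = c(1, 3)))
  dna <- m2$beads[m2$beads$chain == "B", ]
  expect_equal(nrow(dna), 6)          # 2 nucleotides x 3 beads
  expect_setequal(unique(dna$kind), c("phosphate", "sugar", "base"))
  expect_true(all(dna$frozen))
  expect_false(any(m2$beads$frozen[m2$beads$chain == "A"]))

  # a residue without CA is refused by name
  bad <- sub("CA   ALA", "CB   ALA", pdb_text_3res(), fixed = TRUE)
  expect_error(coarse_grain(parse_pdb(bad), domain_map(D1 = c(1, 3))),
               "residue 1.*no CA")
  # uncovered residues are refused
  expect_error(coarse_grain(parse_pdb(pdb_text_3res()),
                            domain_map(D1 = c(1, 2))),
               "not covered")
})

test_that("charge assignment follows the Arg/Lys/Asp/Glu/phosphate rule", {
  s <- parse_pdb(pdb_text_ca_chain(5, c("ARG", "LYS", "ASP", "GLU", "GLY")))
  m <- coarse_grain(s, domain_map(D1 = c(1, 5)))
  expect_equal(m$beads$charge, c(1, 1, -1, -1, 0))

  s2 <- parse_pdb(pdb_text_ca_chain(4, rep("GLY", 4)))
  m2 <- coarse_grain(s2, domain_map(D1 = c(1, 4)))
  expect_true(all(m2$beads$charge == 0))

  m3 <- coarse_grain(parse_pdb(pdb_text_protein_dna()),
                     domain_map(D1 = c(1, 3)))
  ph <- m3$beads$kind == "phosphate"
  expect_true(all(m3$beads$charge[ph] == -1))
  expect_equal(sum(m3$beads$charge[ph]), -2)  # one phosphate per nucleotide
})

test_that("contact building matches a brute-force all-pairs oracle", {
  # compact 28-bead reference structure via its emitted PDB text
  s <- parse_pdb(toy_fixture()$pdb)
  n <- nrow(s$atoms)
  m <- coarse_grain(s, domain_map(D1 = c(1, n)))
  cutoff <- 0.8
  cs <- build_contacts(s, m, method = "ca", cutoff = cutoff,
                       min_separation = 4)

  # independent O(N^2) scan over residue pairs
  pos <- native_coords(m)
  oracle <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i < 4) next
    d <- sqrt(sum((pos[j, ] - pos[i, ])^2))
    if (d < cutoff) oracle[[length(oracle) + 1]] <- c(i, j, d)
  }
  oracle <- do.call(rbind, oracle)
  expect_gt(nrow(oracle), 10)
  expect_equal(nrow(cs), nrow(oracle))
  expect_equal(cs$i, oracle[, 1])
  expect_equal(cs$j, oracle[, 2])
  expect_equal(cs$sigma, oracle[, 3])

  # adjacent residues below the separation floor never form contacts
  expect_true(all(cs$j - cs$i >= 4))
  expect_error(build_contacts(s, m, cutoff = -1), "cutoff")
})

test_that("heavy-atom contacts obey the distance threshold rule", {
  # two residues far in sequence whose side atoms approach to 4 A
  txt <- paste(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0, element = "C"),
    pdb_atom_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0, element = "C"),
    pdb_atom_line(4, "CA", "GLY", "A", 4, 11.4, 0, 0, element = "C"),
    pdb_atom_line(5, "CA", "GLY", "A", 5, 15.2, 0, 0, element = "C"),
    pdb_atom_line(6, "CB", "GLY", "A", 5, 4.0, 0, 0, element = "C"),
    "END"), collapse = "\n")
  s <- parse_pdb(txt)
  m <- coarse_grain(s, domain_map(D1 = c(1, 5)))
  cs <- build_contacts(s, m, method = "heavy", cutoff = 0.45,
                       min_separation = 4)
  expect_equal(nrow(cs), 1)     # residues 1-5 via the 0.40 nm CB approach
  expect_equal(cs$i, 1)
  expect_equal(cs$j, 5)
  # sigma is the bead-bead (CA-CA) distance, not the atom-atom one
  expect_equal(cs$sigma, 1.52)

  cs2 <- build_contacts(s, m, method = "heavy", cutoff = 0.35,
                        min_separation = 4)
  expect_equal(nrow(cs2), 0)
})

test_that("contact classification agrees with an interval oracle", {
  toy <- make_toy_multidomain(toy_spec(n_domains = 3, seed = 4))
  cs <- toy$contacts
  dm <- toy$model$domain_map
  dom_of <- function(b) {
    for (nm in names(dm)) if (b %in% dm[[nm]]) return(nm)
    NA_character_
  }
  oracle_class <- vapply(seq_len(nrow(cs)), function(r) {
    di <- dom_of(cs$i[r]); dj <- dom_of(cs$j[r])
    if (di == "linker" || dj == "linker") "linker"
    else if (di == dj) "intra" else "inter"
  }, character(1))
  expect_equal(cs$class, oracle_class)

  cnt <- contact_counts(cs)
  expect_equal(unname(cnt[["intra"]] + cnt[["inter"]] + cnt[["linker"]]),
               unname(cnt[["total"]]))
})

test_that("dual-basin merge is the union with the right basin labels", {
  toy <- toy_fixture()
  apo <- toy$contacts
  # fake a bound-form contact set: drop two apo rows, add two new pairs
  bin <- apo[-c(1, 2), ]
  extra <- data.frame(i = c(1L, 2L), j = c(20L, 21L), sigma = c(0.7, 0.8),
                      class = "inter", label = "D1-D2", basin = "apo")
  bin <- rbind(as.data.frame(bin), extra)
  class(bin) <- c("contact_set", "data.frame")

  dual <- build_dual_basin(apo, bin)
  key <- function(d) paste(d$i, d$j)
  # every apo contact survives
  expect_true(all(key(apo) %in% key(dual)))
  # binary-only = exactly the pairs absent from apo
  bo <- dual[dual$basin == "binary-only", ]
  expect_setequal(key(bo), key(extra))
  # shared = apo intersect binary
  sh <- dual[dual$basin == "shared", ]
  expect_setequal(key(sh), intersect(key(apo), key(bin)))
  # conflicting sigma keeps the apo value and reports
  bin2 <- bin
  bin2$sigma[5] <- bin2$sigma[5] + 0.1
  expect_message(d2 <- build_dual_basin(apo, bin2), "apo values kept")
  expect_equal(d2$sigma[match(key(apo), key(d2))], apo$sigma)
})

test_that("contact sets serialize deterministically and round-trip", {
  t1 <- make_toy_multidomain(toy_spec(seed = 7))
  t2 <- make_toy_multidomain(toy_spec(seed = 7))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_contacts(t1$contacts, f1)
  write_contacts(t2$contacts, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_contacts(f1)
  expect_equal(back$i, t1$contacts$i)
  expect_equal(back$sigma, t1$contacts$sigma, tolerance = 1e-12)
  expect_equal(back$class, t1$contacts$class)
})
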