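#' Specification for a synthetic toy system
#'
#' Toy systems stand in for a multidomain protein at desk scale: compact
#' helical-coil domains docked with a small shared interface and joined by
#' a flexible linker, optionally with a short frozen charged partner chain
#' emulating a rigid DNA segment.  Geometry is deterministic (templates,
#' not random walks), so the generated native structure is the minimum of
#' the generated Hamiltonian by construction; the seed only controls a tiny
#' symmetry-breaking jitter.
#'
#' @param n_domains number of domains (>= 1).
#' @param beads_per_domain beads per domain.
#' @param linker_length beads per linker between consecutive domains.
#' @param contact_ratio target intra:inter contact-count ratio.
#' @param seed integer seed.
#' @param partner_length partner-chain beads (0 = no partner).
#' @param binding_contacts number of protein-partner native contacts.
#' @param n_binary_contacts partner-induced (bound-form-only) intra-protein
#'   contacts for dual-basin models.
#' @param charged logical; sprinkle +1 beads on the protein interface and
#'   -1 on the partner (the partner is phosphate-like, always -1).
#' @export
toy_spec <- function(n_domains = 2, beads_per_domain = 12, linker_length = 4,
                     contact_ratio = 5, seed = 1L, partner_length = 0,
                     binding_contacts = 6, n_binary_contacts = 2,
                     charged = FALSE) {
  spec <- list(n_domains = n_domains, beads_per_domain = beads_per_domain,
               linker_length = linker_length, contact_ratio = contact_ratio,
               seed = as.integer(seed), partner_length = partner_length,
               binding_contacts = binding_contacts,
               n_binary_contacts = n_binary_contacts, charged = charged)
  class(spec) <- "toy_spec"
  spec
}

# compact globular domain: serpentine walk through a 2 x 2 x nz grid, so
# consecutive beads stay bonded at `spacing` and the core is genuinely 3D
grid_domain <- function(m, spacing = 0.55, origin = c(0, 0, 0)) {
  nz <- ceiling(m / 4)
  pts <- matrix(0, m, 3)
  at <- 0
  for (z in seq_len(nz)) {
    ys <- if (z %% 2 == 1) 1:2 else 2:1
    for (y in ys) {
      xs <- if ((z + y) %% 2 == 0) 1:2 else 2:1
      for (x in xs) {
        at <- at + 1
        if (at > m) break
        pts[at, ] <- origin + spacing * c(x - 1, y - 1, z - 1)
      }
    }
  }
  pts
}

toy_geometry <- function(spec) {
  m <- spec$beads_per_domain
  L <- spec$linker_length
  spacing <- 0.55
  gap <- 0.62           # face-to-face domain separation: shared interface
  dx <- spacing + gap   # origin-to-origin x offset between domains
  coords <- NULL
  domains <- list()
  linker_res <- integer(0)
  at <- 0
  for (d in seq_len(spec$n_domains)) {
    org <- c((d - 1) * (spacing + gap), 0, 0)
    g <- grid_domain(m, spacing, org)
    coords <- rbind(coords, g)
    domains[[paste0("D", d)]] <- at + seq_len(m)
    at <- at + m
    if (d < spec$n_domains && L > 0) {
      # arched linker from the last bead of this domain to the next origin
      from <- g[m, ]
      tosel <- c(d * (spacing + gap), 0, 0)
      tt <- seq_len(L) / (L + 1)
      lk <- cbind(from[1] + tt * (tosel[1] - from[1]),
                  from[2] + tt * (tosel[2] - from[2]) - 0.9 * sin(pi * tt),
                  from[3] + tt * (tosel[3] - from[3]))
      coords <- rbind(coords, lk)
      linker_res <- c(linker_res, at + seq_len(L))
      at <- at + L
    }
  }
  list(coords = coords, domains = domains, linker = linker_res)
}

# assemble a cg_model from bead coordinates (single protein chain unless a
# partner block is supplied)
bead_model <- function(coords, dmap, resnames = NULL, chain = "A",
                       partner_coords = NULL, partner_chain = "B",
                       freeze_partner = TRUE) {
  n <- nrow(coords)
  if (is.null(resnames)) resnames <- rep("BEA", n)
  beads <- data.frame(chain = chain, resid = seq_len(n), resname = resnames,
                      kind = "CA", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], stringsAsFactors = FALSE)
  if (!is.null(partner_coords)) {
    np <- nrow(partner_coords)
    beads <- rbind(beads, data.frame(
      chain = partner_chain, resid = seq_len(np), resname = "NUC",
      kind = "phosphate", x = partner_coords[, 1], y = partner_coords[, 2],
      z = partner_coords[, 3], stringsAsFactors = FALSE))
  }
  beads$index <- seq_len(nrow(beads))
  beads$frozen <- freeze_partner & beads$chain != chain
  beads$domain <- NA_character_
  prot <- beads$chain == chain
  beads$domain[prot] <- domain_of(dmap, beads$resid[prot])
  model <- list(beads = beads, domain_map = dmap)
  class(model) <- "cg_model"
  model <- build_bonded_topology(model)
  assign_charges(model)
}

# pick the k closest eligible pairs from a distance-sorted candidate table
closest_pairs <- function(coords, from, to, k, exclude_key = character(0),
                          max_dist = 1.2) {
  cand <- expand.grid(i = from, j = to)
  cand <- data.frame(i = pmin(cand$i, cand$j), j = pmax(cand$i, cand$j))
  cand <- cand[cand$i < cand$j, , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$i, cand$j)), , drop = FALSE]
  d <- sqrt(rowSums((coords[cand$j, , drop = FALSE] -
                     coords[cand$i, , drop = FALSE])^2))
  cand$sigma <- d
  cand <- cand[!(paste(cand$i, cand$j) %in% exclude_key), , drop = FALSE]
  cand <- cand[cand$sigma <= max_dist, , drop = FALSE]
  cand <- cand[order(cand$sigma, cand$i, cand$j), , drop = FALSE]
  if (nrow(cand) < k) return(NULL)
  cand[seq_len(k), , drop = FALSE]
}

#' Generate a toy multidomain bead protein
#'
#' Builds the deterministic toy geometry of [toy_spec()], its coarse model,
#' a classified native contact set with a controlled intra:inter ratio, and
#' the reference structure as PDB text.  Intradomain contacts are every
#' bead pair within one domain closer than 0.9 nm with sequence separation
#' >= 3; interdomain contacts are the closest cross-domain pairs, taken in
#' distance order until the target ratio is met; two linker-domain contacts
#' per linker populate the linker class.
#'
#' @param spec a [toy_spec()].
#' @return list with `model` (`cg_model`), `contacts` (`contact_set`),
#'   `pdb` (reference PDB text) and `spec`.
#' @export
make_toy_multidomain <- function(spec = toy_spec()) {
  set.seed(spec$seed)
  geo <- toy_geometry(spec)
  coords <- geo$coords + matrix(rnorm(length(geo$coords), sd = 0.005),
                                ncol = 3)
  dm_args <- lapply(geo$domains, function(ix) range(ix))
  if (length(geo$linker)) {
    runs <- split(geo$linker, cumsum(c(1, diff(geo$linker) != 1)))
    dm_args$linker <- lapply(runs, range)
  }
  dmap <- do.call(domain_map, dm_args)
  model <- bead_model(coords, dmap)

  # intradomain: cutoff scan inside each domain
  rows <- list()
  for (dn in names(geo$domains)) {
    ix <- geo$domains[[dn]]
    cand <- expand.grid(i = ix, j = ix)
    cand <- cand[cand$j - cand$i >= 3, , drop = FALSE]
    d <- sqrt(rowSums((coords[cand$j, , drop = FALSE] -
                       coords[cand$i, , drop = FALSE])^2))
    cand$sigma <- d
    rows[[length(rows) + 1]] <- cand[cand$sigma < 0.85, , drop = FALSE]
  }
  intra <- do.call(rbind, rows)
  n_intra <- nrow(intra)

  # interdomain: closest cross-domain pairs to hit the requested ratio
  n_inter <- round(n_intra / spec$contact_ratio)
  dom_ids <- unlist(geo$domains)
  inter <- NULL
  if (spec$n_domains > 1) {
    pairs <- utils::combn(names(geo$domains), 2, simplify = FALSE)
    cand <- do.call(rbind, lapply(pairs, function(pp) {
      a <- geo$domains[[pp[1]]]; b <- geo$domains[[pp[2]]]
      cc <- expand.grid(i = a, j = b)
      cc$sigma <- sqrt(rowSums((coords[cc$j, , drop = FALSE] -
                                coords[cc$i, , drop = FALSE])^2))
      cc[cc$sigma <= 1.2, , drop = FALSE]
    }))
    if (is.null(cand) || nrow(cand) < n_inter)
      stop("unreachable intra:inter contact ratio ", spec$contact_ratio,
           ":1 for this geometry; reduce the ratio or enlarge the domains")
    cand <- cand[order(cand$sigma), , drop = FALSE]
    inter <- cand[seq_len(n_inter), , drop = FALSE]
  }

  # linker contacts: two closest linker-domain pairs per linker
  linker <- NULL
  if (length(geo$linker)) {
    linker <- closest_pairs(coords, geo$linker, dom_ids, k = 2, max_dist = 1.2)
  }

  cs <- rbind(intra, inter, linker)
  cs <- data.frame(i = as.integer(cs$i), j = as.integer(cs$j),
                   sigma = cs$sigma, class = "unclassified",
                   label = NA_character_, basin = "apo",
                   stringsAsFactors = FALSE)
  cs <- cs[!duplicated(paste(cs$i, cs$j)), , drop = FALSE]
  cs <- cs[order(cs$i, cs$j), , drop = FALSE]
  rownames(cs) <- NULL
  class(cs) <- c("contact_set", "data.frame")
  cs <- classify_contacts(cs, model)

  cnt <- contact_counts(cs)
  realized <- cnt[["intra"]] / max(1, cnt[["inter"]])
  if (spec$n_domains > 1 &&
      abs(realized - spec$contact_ratio) / spec$contact_ratio > 0.2)
    stop("realized intra:inter ratio ", signif(realized, 3),
         " deviates more than 20% from target ", spec$contact_ratio)

  list(model = model, contacts = cs, pdb = bead_pdb_text(model), spec = spec)
}

#' Harmonic chain with closed-form statistics
#'
#' A bonded-only bead chain (no angles, dihedrals or contacts): each bond
#' is a radial mode with equilibrium average potential energy kT/2 and
#' length variance kT/(2 K).  Used as the thermostat/equipartition oracle.
#'
#' @param n_beads chain length (>= 2).
#' @param stiffness bond stiffness K (eps/nm^2).
#' @param bond_length native bond length (nm); the default 1.0 keeps the
#'   radial-measure correction to the closed forms negligible.
#' @return list with `model`, empty `contacts`, and `closed_forms`
#'   (functions of temperature).
#' @export
make_harmonic_chain <- function(n_beads = 8, stiffness = 100,
                                bond_length = 1.0) {
  stopifnot(n_beads >= 2)
  coords <- cbind(seq_len(n_beads) * bond_length, 0, 0)
  dmap <- domain_map(D1 = c(1, n_beads))
  model <- bead_model(coords, dmap)
  model$angles <- model$angles[0, , drop = FALSE]
  model$dihedrals <- model$dihedrals[0, , drop = FALSE]
  cs <- data.frame(i = integer(0), j = integer(0), sigma = numeric(0),
                   class = character(0), label = character(0),
                   basin = character(0), stringsAsFactors = FALSE)
  class(cs) <- c("contact_set", "data.frame")
  list(model = model, contacts = cs,
       stiffness = stiffness,
       closed_forms = list(
         mode_pe = function(temperature) temperature / 2,
         bond_variance = function(temperature) temperature / (2 * stiffness)))
}

#' One-dimensional double well
#'
#' `V(x) = barrier (x^2 - 1)^2 + tilt x`: minima near x = -1 and +1, a
#' barrier of `barrier` kT (at tilt 0) at x = 0.  The analytic potential is
#' the reference for WHAM, umbrella sampling and metadynamics rate oracles.
#'
#' @param barrier_kT barrier height (> 0).
#' @param tilt linear bias breaking the symmetry (default 0).
#' @return class `double_well` with `pmf(x)` analytic potential.
#' @export
make_double_well <- function(barrier_kT, tilt = 0) {
  if (barrier_kT <= 0) stop("barrier must be positive")
  dw <- list(barrier = barrier_kT, tilt = tilt, x_min = c(-1, 1),
             pmf = function(x) barrier_kT * (x^2 - 1)^2 + tilt * x)
  class(dw) <- "double_well"
  dw
}

#' Brute-force mean first-passage time of the double well
#'
#' Long unbiased Langevin runs from the left minimum until first arrival at
#' `target`; the oracle against which the metadynamics rescaled transition
#' time is checked.
#'
#' @param dw a `double_well`.
#' @param temperature reduced temperature.
#' @param n_runs number of independent runs.
#' @param seed seed.
#' @param dt,friction integrator settings.
#' @param target arrival threshold on x.
#' @param max_steps per-run step budget.
#' @return list with `mfpt`, per-run `fpt`, `censored` count.
#' @export
double_well_mfpt <- function(dw, temperature = 1, n_runs = 50, seed = 1,
                             dt = 0.005, friction = 1, target = 0.8,
                             max_steps = 2e6) {
  set.seed(seed)
  fpt <- vapply(seq_len(n_runs), function(r)
    dw_first_passage_cpp(dw$barrier, dw$tilt, -1, dt, friction, temperature,
                         target, as.integer(max_steps)), numeric(1))
  list(mfpt = mean(fpt, na.rm = TRUE), fpt = fpt, censored = sum(is.na(fpt)))
}

#' Synthetic melting-curve set
#'
#' Exact sigmoids `P(T) = 1/(1 + exp((T - Tm)/w))` sampled on a temperature
#' grid, with optional Gaussian noise, for exercising the coupling-index
#' and sigmoid-fitting machinery against known parameters.
#'
#' @param tms,widths equal-length vectors of midpoints and widths.
#' @param grid temperature grid.
#' @param noise Gaussian noise sd on P (clipped to \[0, 1\]).
#' @param seed seed used when `noise > 0`.
#' @return list of `melting_curve` objects with true parameters recorded.
#' @export
make_synthetic_melting_set <- function(tms, widths,
                                       grid = seq(0.8, 1.3, by = 0.01),
                                       noise = 0, seed = 1) {
  stopifnot(length(tms) == length(widths))
  if (noise > 0) set.seed(seed)
  out <- lapply(seq_along(tms), function(i) {
    P <- sigmoid_p(grid, tms[i], widths[i])
    if (noise > 0) P <- pmin(1, pmax(0, P + rnorm(length(P), sd = noise)))
    cv <- list(element = paste0("E", i),
               data = data.frame(temperature = grid, P = P),
               tm = tms[i], width = widths[i], degenerate = FALSE)
    class(cv) <- "melting_curve"
    cv
  })
  names(out) <- paste0("E", seq_along(tms))
  out
}

#' Toy protein-partner binding system
#'
#' The toy multidomain protein plus a short frozen partner rod of
#' phosphate-like beads (charge -1) docked along the interdomain groove.
#' Native binding contacts are the closest protein-partner pairs; a
#' dual-basin variant adds bound-form-only cross-domain contacts within
#' the protein.  Protein beads facing the partner are made Arg-like (+1)
#' when `charged`.
#'
#' @param spec a [toy_spec()] with `partner_length > 0`.
#' @return list with `model`, `contacts` (binding + optional binary-only
#'   rows appended), `pdb`, `spec`.
#' @export
make_toy_binding_system <- function(spec = toy_spec(partner_length = 6,
                                                    charged = TRUE)) {
  if (spec$partner_length < 1) stop("spec must include a partner chain")
  base <- make_toy_multidomain(spec)
  coords <- native_coords(base$model)
  np <- spec$partner_length
  # rod parallel to the domain-1 axis, offset from the interdomain groove
  zc <- mean(range(coords[, 3]))
  rod <- cbind((spec$n_domains - 1) * 0.95 / 2,
               -0.65,
               seq(zc - 0.3 * (np - 1) / 2, zc + 0.3 * (np - 1) / 2,
                   length.out = np))
  nprot <- nrow(coords)
  resnames <- rep("BEA", nprot)
  if (spec$charged) {
    # positive patch on the protein face nearest the rod
    dface <- vapply(seq_len(nprot), function(i)
      min(sqrt(rowSums(sweep(rod, 2, coords[i, ])^2))), numeric(1))
    resnames[order(dface)[1:4]] <- "ARG"
  }
  model <- bead_model(coords, base$model$domain_map, resnames = resnames,
                      partner_coords = rod)
  all_coords <- native_coords(model)
  prot_ix <- which(model$beads$chain == "A")
  part_ix <- which(model$beads$chain == "B")

  bind <- closest_pairs(all_coords, prot_ix, part_ix,
                        k = spec$binding_contacts, max_dist = 2.0)
  if (is.null(bind)) stop("partner rod too far from protein for ",
                          spec$binding_contacts, " binding contacts")
  bind_rows <- data.frame(i = as.integer(bind$i), j = as.integer(bind$j),
                          sigma = bind$sigma, class = "binding",
                          label = NA_character_, basin = "binary-only",
                          stringsAsFactors = FALSE)

  cs <- rbind(as.data.frame(base$contacts), bind_rows)

  if (spec$n_binary_contacts > 0 && spec$n_domains > 1) {
    have <- paste(cs$i, cs$j)
    extra <- closest_pairs(all_coords, seq(1, spec$beads_per_domain),
                           prot_ix[prot_ix > spec$beads_per_domain +
                                     spec$linker_length],
                           k = spec$n_binary_contacts, exclude_key = have,
                           max_dist = 2.0)
    if (!is.null(extra)) {
      cs <- rbind(cs, data.frame(i = as.integer(extra$i),
                                 j = as.integer(extra$j),
                                 sigma = extra$sigma, class = "unclassified",
                                 label = NA_character_, basin = "binary-only",
                                 stringsAsFactors = FALSE))
    }
  }
  cs <- cs[order(cs$i, cs$j), , drop = FALSE]
  rownames(cs) <- NULL
  class(cs) <- c("contact_set", "data.frame")
  cs <- classify_contacts(cs, model)

  list(model = model, contacts = cs, pdb = bead_pdb_text(model), spec = spec)
}
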