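#' Force-field parameters for the structure-based model
#'
#' All energies are in reduced units of the intradomain contact depth
#' `eps_intra`.  The ratio `rho = eps_inter / eps_intra` scales interdomain
#' and linker contacts together (`eps_linker == eps_inter` throughout).
#' Bonded terms follow the standard C-alpha structure-based form:
#' `Kb (r - r0)^2` bonds, `Ka (theta - theta0)^2` angles and
#' `Kd [(1 - cos(phi - phi0)) + (1/2)(1 - cos 3(phi - phi0))]` dihedrals,
#' with a `(sigma_ev / r)^12` excluded volume between non-contact pairs.
#' Electrostatics use a Debye-Hueckel screened potential calibrated so that
#' unit opposite charges at 0.5 nm match one native contact (see
#' [calibrate_dh()]).
#'
#' @param eps_intra intradomain contact depth (energy unit, default 1).
#' @param rho ratio of interdomain (and linker) to intradomain strength.
#' @param eps_binding depth of protein-nucleic native contacts.
#' @param eps_binary depth of bound-form-only (dual-basin) contacts.
#' @param kb,ka,kd bonded stiffnesses (eps/nm^2, eps/rad^2, eps).
#' @param excl_sigma excluded-volume diameter (nm).
#' @param debye_length Debye screening length (nm); 0.8 nm corresponds to
#'   roughly 150 mM monovalent salt.
#' @param dh_prefactor electrostatic prefactor; by default calibrated from
#'   `debye_length` via [calibrate_dh()].
#' @param temperature_rescale multiplicative factor `Tf(rho0)/Tf(rho)`
#'   applied to the apo-protein structure-based terms so that kinetic runs
#'   at different `rho` share a common folding temperature (see
#'   [rescale_for_temperature()]).
#' @return an object of class `sbm_forcefield`.
#' @export
forcefield <- function(eps_intra = 1.0, rho = 1.0, eps_binding = 1.0,
                       eps_binary = 1.0, kb = 100, ka = 20, kd = 1,
                       excl_sigma = 0.4, debye_length = 0.8,
                       dh_prefactor = calibrate_dh(debye_length),
                       temperature_rescale = 1.0) {
  if (rho <= 0) stop("rho must be positive")
  if (temperature_rescale <= 0) stop("temperature_rescale must be positive")
  if (debye_length <= 0) stop("debye_length must be positive")
  ff <- list(eps_intra = eps_intra, rho = rho, eps_binding = eps_binding,
             eps_binary = eps_binary, kb = kb, ka = ka, kd = kd,
             excl_sigma = excl_sigma, debye_length = debye_length,
             dh_prefactor = dh_prefactor,
             temperature_rescale = temperature_rescale)
  class(ff) <- "sbm_forcefield"
  ff
}

#' @export
print.sbm_forcefield <- function(x, ...) {
  cat("<sbm_forcefield> eps_intra =", x$eps_intra, " rho =", x$rho,
      " rescale =", signif(x$temperature_rescale, 4), "\n")
  cat("  bonded: kb =", x$kb, " ka =", x$ka, " kd =", x$kd,
      "; excl sigma =", x$excl_sigma, "nm\n")
  cat("  DH: lambda =", x$debye_length, "nm, prefactor =",
      signif(x$dh_prefactor, 4), "\n")
  invisible(x)
}

#' Calibrate the Debye-Hueckel prefactor
#'
#' Returns the prefactor A of `V = A q1 q2 exp(-r/lambda)/r` such that two
#' unit opposite charges at 0.5 nm interact with energy -1, i.e. the same
#' strength as one native contact.
#'
#' @param debye_length screening length lambda in nm (> 0).
#' @return the prefactor A (eps nm / e^2).
#' @export
calibrate_dh <- function(debye_length) {
  if (debye_length <= 0) stop("debye_length must be positive")
  0.5 * exp(0.5 / debye_length)
}

#' Debye-Hueckel pair energy
#' @param r separation (nm)
#' @param q1,q2 charges (e)
#' @param forcefield an `sbm_forcefield`
#' @export
dh_energy <- function(r, q1, q2, forcefield) {
  forcefield$dh_prefactor * q1 * q2 * exp(-r / forcefield$debye_length) / r
}

#' 12-10 native-contact pair energy
#'
#' `V(r) = eps [5 (sigma/r)^12 - 6 (sigma/r)^10]`, with minimum -eps at
#' r = sigma and vanishing at large separation.
#'
#' @param r separation (nm, > 0)
#' @param sigma native distance (nm)
#' @param eps well depth
#' @export
contact_pair_energy <- function(r, sigma, eps = 1) {
  q <- (sigma / r)^2
  eps * (5 * q^6 - 6 * q^5)
}

#' Shift the Hamiltonian to a common folding temperature
#'
#' Kinetic comparisons across `rho` are made at one physical temperature by
#' multiplying the apo-protein structure-based terms by `Tf(rho0)/Tf(rho)`,
#' which maps the folding temperature at `rho` onto the reference one.
#'
#' @param forcefield an `sbm_forcefield`
#' @param tf_rho0 folding temperature at the reference rho (> 0)
#' @param tf_rho folding temperature at the current rho (> 0)
#' @return the force field with `temperature_rescale = tf_rho0 / tf_rho`.
#' @export
rescale_for_temperature <- function(forcefield, tf_rho0, tf_rho) {
  if (tf_rho0 <= 0 || tf_rho <= 0)
    stop("folding temperatures must be positive")
  forcefield$temperature_rescale <- tf_rho0 / tf_rho
  forcefield
}

# ---- system compilation -----------------------------------------------------

# Flatten model + contacts + forcefield into the list consumed by the C++
# kernels.  The temperature rescale and per-class epsilons are folded into
# the constants here; binding / binary-basin / electrostatic terms are not
# rescaled (they are additions on top of the apo-protein Hamiltonian).
compile_system <- function(model, contacts, forcefield) {
  b <- model$beads
  n <- nrow(b)
  rs <- forcefield$temperature_rescale
  # class codes follow the EnergyReport component order:
  # 0 intra, 1 inter, 2 linker, 3 binary basin, 4 binding
  cls_code <- c(intra = 0L, inter = 1L, linker = 2L, binding = 4L)
  cc <- as.data.frame(contacts)
  if (any(cc$class == "unclassified"))
    stop("contacts must be classified before energy evaluation")
  code <- cls_code[cc$class]
  # bound-form-only intra-protein contacts form the second basin
  bin_only <- cc$basin == "binary-only" & cc$class != "binding"
  code[bin_only] <- 3L
  eps <- numeric(nrow(cc))
  eps[code == 0L] <- forcefield$eps_intra * rs
  eps[code %in% c(1L, 2L)] <- forcefield$rho * forcefield$eps_intra * rs
  eps[code == 4L] <- forcefield$eps_binding
  eps[code == 3L] <- forcefield$eps_binary

  # excluded-volume pair list: everything except bonded 1-2/1-3/1-4
  # neighbours and native-contact pairs
  skip <- matrix(FALSE, n, n)
  mark <- function(i, j) {
    ij <- cbind(pmin(i, j), pmax(i, j))
    skip[ij] <<- TRUE
  }
  if (nrow(model$bonds)) mark(model$bonds$i, model$bonds$j)
  if (nrow(model$angles)) mark(model$angles$i, model$angles$k)
  if (nrow(model$dihedrals)) mark(model$dihedrals$i, model$dihedrals$l)
  if (nrow(cc)) mark(cc$i, cc$j)
  ut <- which(upper.tri(skip) & !skip, arr.ind = TRUE)
  # pairs fully inside the frozen partner never move; drop them
  frozen <- b$frozen
  keep <- !(frozen[ut[, 1]] & frozen[ut[, 2]])
  ut <- ut[keep, , drop = FALSE]
  protein_pair <- b$kind[ut[, 1]] == "CA" & b$kind[ut[, 2]] == "CA"
  escale <- ifelse(protein_pair, rs, 1.0)

  # electrostatic pairs: charged, not bonded neighbours (contact pairs kept)
  qs <- b$charge
  eskip <- matrix(FALSE, n, n)
  mk2 <- function(i, j) {
    ij <- cbind(pmin(i, j), pmax(i, j))
    eskip[ij] <<- TRUE
  }
  if (nrow(model$bonds)) mk2(model$bonds$i, model$bonds$j)
  if (nrow(model$angles)) mk2(model$angles$i, model$angles$k)
  if (nrow(model$dihedrals)) mk2(model$dihedrals$i, model$dihedrals$l)
  et <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  qq <- qs[et[, 1]] * qs[et[, 2]]
  ekeep <- qq != 0 & !eskip[et] & !(frozen[et[, 1]] & frozen[et[, 2]])
  et <- et[ekeep, , drop = FALSE]
  eqq <- forcefield$dh_prefactor * qq[ekeep]

  list(
    n = n,
    bonds = unname(as.matrix(model$bonds[, c("i", "j")])) - 1L,
    bond_r0 = model$bonds$r0,
    kb = rep(forcefield$kb * rs, nrow(model$bonds)),
    angles = unname(as.matrix(model$angles[, c("i", "j", "k")])) - 1L,
    theta0 = model$angles$theta0,
    ka = rep(forcefield$ka * rs, nrow(model$angles)),
    dih = unname(as.matrix(model$dihedrals[, c("i", "j", "k", "l")])) - 1L,
    phi0 = model$dihedrals$phi0,
    kd = rep(forcefield$kd * rs, nrow(model$dihedrals)),
    cpair = matrix(as.integer(c(cc$i, cc$j)), ncol = 2) - 1L,
    csig = cc$sigma,
    ceps = eps,
    ccls = code,
    nbpair = matrix(as.integer(c(ut[, 1], ut[, 2])), ncol = 2) - 1L,
    excl_sigma = forcefield$excl_sigma,
    escale = escale,
    epair = matrix(as.integer(c(et[, 1], et[, 2])), ncol = 2) - 1L,
    eqq = eqq,
    debye = forcefield$debye_length,
    frozen = frozen)
}

#' Decomposed potential energy
#'
#' Evaluates the model Hamiltonian at the given coordinates and returns the
#' per-class decomposition required by the rho-reweighting identity
#' `E(rho) = E_bonded + E_intra + rho (E_inter + E_linker) + ...`: the
#' bonded, intradomain, interdomain, linker, bound-form-basin, binding,
#' electrostatic and excluded-volume components, plus their sum.
#'
#' @param model a `cg_model`
#' @param contacts a classified `contact_set`
#' @param forcefield an `sbm_forcefield`
#' @param coords n x 3 coordinate matrix in nm (defaults to native).
#' @return class `energy_report`: named numeric vector of components
#'   and `total`.
#' @export
total_energy <- function(model, contacts, forcefield,
                         coords = native_coords(model)) {
  if (any(!is.finite(coords))) stop("non-finite coordinate")
  sys <- compile_system(model, contacts, forcefield)
  e <- cg_energy_cpp(sys, coords)
  class(e) <- "energy_report"
  e
}

#' @export
print.energy_report <- function(x, ...) {
  y <- unclass(x)
  cat("<energy_report> total =", format(y[["total"]], digits = 6), "\n")
  nz <- y[names(y) != "total" & abs(y) > 0]
  if (length(nz)) print(signif(nz, 6))
  invisible(x)
}

#' Forces on every bead
#'
#' Analytic negative gradient of [total_energy()].  Frozen beads receive
#' exactly zero force.
#'
#' @inheritParams total_energy
#' @return n x 3 matrix of forces (eps/nm).
#' @export
forces <- function(model, contacts, forcefield,
                   coords = native_coords(model)) {
  if (any(!is.finite(coords))) stop("non-finite coordinate")
  sys <- compile_system(model, contacts, forcefield)
  cg_forces_cpp(sys, coords)
}
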