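#' Fraction of native contacts
#'
#' A contact is counted as formed when its bead-bead distance is below
#' `formed_tolerance * sigma` (default tolerance 1.2, the common
#' structure-based convention).
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param contacts a non-empty `contact_set` subset.
#' @param formed_tolerance formation tolerance relative to sigma.
#' @return fraction in \[0, 1\].
#' @export
q_fraction <- function(coords, contacts, formed_tolerance = 1.2) {
  if (nrow(contacts) == 0)
    stop("q_fraction over an empty contact subset is undefined")
  d <- pair_distances(coords, contacts)
  mean(d < formed_tolerance * contacts$sigma)
}

pair_distances <- function(coords, contacts) {
  dx <- coords[contacts$j, , drop = FALSE] - coords[contacts$i, , drop = FALSE]
  sqrt(rowSums(dx^2))
}

#' Distance RMS deviation of binding contacts
#'
#' `dRMS = sqrt(mean((r_ij - sigma_ij)^2))` over the protein-partner native
#' contacts; 0 nm at the native bound pose, growing as unbinding proceeds.
#'
#' @param coords n x 3 coordinates (nm).
#' @param binding_contacts non-empty `contact_set` of binding contacts.
#' @return dRMS in nm.
#' @export
drms <- function(coords, binding_contacts) {
  if (nrow(binding_contacts) == 0)
    stop("dRMS requires a non-empty binding contact set")
  d <- pair_distances(coords, binding_contacts)
  sqrt(mean((d - binding_contacts$sigma)^2))
}

#' Collective-variable series from a trajectory
#'
#' Computes Q over a contact subset (or dRMS over binding contacts) for
#' every recorded frame.
#'
#' @param trajectory a `trajectory_record`.
#' @param contacts contact subset for the coordinate.
#' @param type "q" or "drms".
#' @param formed_tolerance passed to [q_fraction()].
#' @return numeric vector, one value per frame.
#' @export
cv_series <- function(trajectory, contacts, type = c("q", "drms"),
                      formed_tolerance = 1.2) {
  type <- match.arg(type)
  nf <- dim(trajectory$frames)[1]
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- trajectory$frames[f, , ]
    out[f] <- if (type == "q") q_fraction(co, contacts, formed_tolerance)
              else drms(co, contacts)
  }
  out
}

# Kabsch superposition of coords onto ref (both n x 3), returns rotated+
# translated coords
superpose_onto <- function(coords, ref) {
  cm <- colMeans(coords); rm <- colMeans(ref)
  A <- sweep(coords, 2, cm); B <- sweep(ref, 2, rm)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(A %*% t(R), 2, rm, `+`)
}

#' Root-mean-square fluctuation per bead
#'
#' Frames are superposed onto their mean structure (iterated once) before
#' the per-bead RMS deviation from the mean is taken.
#'
#' @param trajectory a `trajectory_record` with at least 2 frames.
#' @param selection bead indices (default: all unfrozen beads).
#' @return list with `per_bead` (nm) and `mean` (scalar mean RMSF).
#' @export
rmsf <- function(trajectory, selection = NULL) {
  fr <- trajectory$frames
  nf <- dim(fr)[1]
  if (nf < 2) stop("RMSF needs at least two frames")
  if (is.null(selection)) selection <- seq_len(dim(fr)[2])
  X <- fr[, selection, , drop = FALSE]
  ref <- apply(X, c(2, 3), mean)
  for (it in 1:2) {
    for (f in seq_len(nf)) X[f, , ] <- superpose_onto(X[f, , ], ref)
    ref <- apply(X, c(2, 3), mean)
  }
  dev2 <- matrix(0, nf, length(selection))
  for (f in seq_len(nf)) dev2[f, ] <- rowSums((X[f, , ] - ref)^2)
  per_bead <- sqrt(colMeans(dev2))
  list(per_bead = per_bead, mean = mean(per_bead))
}

#' Centre-of-mass diffusion coefficient
#'
#' Fits the centre-of-mass mean-squared displacement to `MSD = 6 D t` over
#' a lag window and returns D in nm^2/tau.
#'
#' @param trajectory an unbiased free-chain `trajectory_record`.
#' @param selection beads defining the centre of mass (default: unfrozen).
#' @param lags lag indices (in recorded frames) for the linear fit.
#' @return list with `D`, the `fit` lm object and the MSD table.
#' @export
diffusion_coefficient <- function(trajectory, selection = NULL,
                                  lags = 10:100) {
  fr <- trajectory$frames
  nf <- dim(fr)[1]
  if (max(lags) >= nf)
    stop("lag window exceeds trajectory length (", nf, " frames)")
  if (is.null(selection)) selection <- seq_len(dim(fr)[2])
  com <- t(vapply(seq_len(nf), function(f) {
    m <- matrix(fr[f, selection, ], ncol = 3)
    colMeans(m)
  }, numeric(3)))
  dtim <- diff(trajectory$times[1:2])
  msd <- vapply(lags, function(L) {
    d <- com[(1 + L):nf, , drop = FALSE] - com[1:(nf - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  fit <- stats::lm(msd ~ 0 + I(6 * lags * dtim))
  list(D = unname(coef(fit)[1]), fit = fit,
       msd = data.frame(lag_tau = lags * dtim, msd = msd))
}
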