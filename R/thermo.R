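logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Collect equilibrium samples from a replica-exchange record
#'
#' Flattens the per-temperature trajectories into one sample table carrying
#' everything WHAM and the rho-reweighting need: the total potential energy,
#' the unscaled-by-rho interdomain + linker contact energy, and an optional
#' collective variable per frame.
#'
#' @param remd an `remd_record`.
#' @param cv_list optional list (one numeric vector per replica) of CV
#'   values, e.g. from [cv_series()].
#' @param discard_frac fraction of each trajectory discarded as
#'   equilibration.
#' @return data.frame with columns replica, temperature, E, inter_linker, cv.
#' @export
remd_samples <- function(remd, cv_list = NULL, discard_frac = 0.2) {
  out <- list()
  for (r in seq_along(remd$replicas)) {
    tr <- remd$replicas[[r]]
    n <- length(tr$times)
    keep <- seq_len(n) > floor(discard_frac * n)
    en <- tr$energies
    il <- if (all(c("inter", "linker") %in% names(en)))
      en$inter[keep] + en$linker[keep] else rep(0, sum(keep))
    out[[r]] <- data.frame(
      replica = r, temperature = remd$ladder[r], E = en$total[keep],
      inter_linker = il,
      cv = if (is.null(cv_list)) NA_real_ else cv_list[[r]][keep])
  }
  do.call(rbind, out)
}

#' Temperature WHAM
#'
#' Self-consistent weighted-histogram estimate of the density of states
#' n(E) from replica-exchange samples, giving the heat capacity curve, the
#' folding temperature (the Cv-peak temperature) and per-sample ensemble
#' weights at arbitrary temperatures.
#'
#' @param samples a sample table from [remd_samples()] (or an `remd_record`,
#'   converted internally).
#' @param n_bins number of energy histogram bins.
#' @param breaks explicit energy bin breaks (overrides `n_bins`; useful for
#'   systems with discrete energy levels).
#' @param tol convergence tolerance on the replica free energies.
#' @param max_iter iteration cap.
#' @param t_grid temperatures for the heat-capacity curve (defaults to a
#'   fine grid spanning the ladder).
#' @return class `wham_fit`: energy grid with log density of states,
#'   per-replica free energies, the sample table with log-denominators,
#'   `cv_curve` (T, mean energy, Cv) and `tf` (Cv-peak temperature).
#' @export
wham_temperature <- function(samples, n_bins = 120, breaks = NULL,
                             tol = 1e-8, max_iter = 5000, t_grid = NULL) {
  if (inherits(samples, "remd_record")) samples <- remd_samples(samples)
  temps <- sort(unique(samples$temperature))
  if (length(temps) < 1) stop("no samples")
  betas <- 1 / temps
  N_k <- vapply(temps, function(tt) sum(samples$temperature == tt), numeric(1))
  E <- samples$E
  rngE <- range(E)
  if (length(temps) >= 2) {
    # neighbouring energy histograms must overlap for WHAM to connect them
    for (k in seq_len(length(temps) - 1)) {
      a <- range(E[samples$temperature == temps[k]])
      b <- range(E[samples$temperature == temps[k + 1]])
      if (a[2] < b[1] || b[2] < a[1])
        stop("energy histograms at T = ", temps[k], " and T = ", temps[k + 1],
             " do not overlap")
    }
  }
  if (is.null(breaks))
    breaks <- seq(rngE[1] - 1e-9, rngE[2] + 1e-9, length.out = n_bins + 1)
  n_bins <- length(breaks) - 1
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(E, breaks, rightmost.closed = TRUE)
  H <- matrix(0, length(temps), n_bins)
  for (k in seq_along(temps)) {
    tb <- tabulate(bin[samples$temperature == temps[k]], nbins = n_bins)
    H[k, ] <- tb
  }
  Htot <- colSums(H)
  f <- numeric(length(temps))
  logN <- log(N_k)
  for (it in seq_len(max_iter)) {
    # log n_m = log(sum_k H_km) - logsumexp_k(logN_k + f_k - beta_k E_m)
    denom <- vapply(seq_len(n_bins), function(m)
      logsumexp(logN + f - betas * mid[m]), numeric(1))
    log_n <- ifelse(Htot > 0, log(Htot) - denom, -Inf)
    f_new <- -vapply(seq_along(temps), function(k)
      logsumexp(log_n[Htot > 0] - betas[k] * mid[Htot > 0]), numeric(1))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  # per-sample log denominator for ensemble weights at arbitrary T
  logD <- vapply(seq_along(E), function(i)
    logsumexp(logN + f - betas * E[i]), numeric(1))
  samples$logD <- logD

  if (is.null(t_grid))
    t_grid <- seq(min(temps) , max(temps), length.out = 200)
  ok <- which(is.finite(log_n))
  cvc <- t(vapply(t_grid, function(tt) {
    lw <- log_n[ok] - mid[ok] / tt
    lz <- logsumexp(lw)
    e1 <- sum(exp(lw - lz) * mid[ok])
    e2 <- sum(exp(lw - lz) * mid[ok]^2)
    c(E = e1, Cv = (e2 - e1^2) / tt^2)
  }, numeric(2)))
  cv_curve <- data.frame(temperature = t_grid, E = cvc[, 1], Cv = cvc[, 2])
  tf <- t_grid[which.max(cv_curve$Cv)]

  out <- list(E_mid = mid, log_n = log_n, f = f, temperatures = temps,
              samples = samples, cv_curve = cv_curve, tf = tf,
              iterations = it)
  class(out) <- "wham_fit"
  out
}

#' @export
print.wham_fit <- function(x, ...) {
  cat("<wham_fit> ", length(x$temperatures), " temperatures, ",
      nrow(x$samples), " samples; Tf (Cv peak) = ", signif(x$tf, 4),
      "\n", sep = "")
  invisible(x)
}

#' Per-sample ensemble weights at a target temperature
#'
#' @param fit a `wham_fit`.
#' @param temperature target reduced temperature.
#' @return normalised weights over `fit$samples`.
#' @export
sample_weights <- function(fit, temperature) {
  lw <- -fit$samples$E / temperature - fit$samples$logD
  w <- exp(lw - logsumexp(lw))
  w
}

#' Free-energy surface over a collective variable
#'
#' Weighted histogram of the CV with `F/kT = -ln p`, zeroed at the surface
#' minimum (or at the lowest sampled CV bin).
#'
#' @param cv CV values per sample.
#' @param weights sample weights (e.g. [sample_weights()]), default uniform.
#' @param n_bins histogram bins.
#' @param breaks optional explicit bin breaks (overrides `n_bins`).
#' @param reference `"min"` or `"lowest_cv"` zero convention.
#' @param temperature annotation only (kT units are used throughout).
#' @return class `free_energy_surface`: data.frame (cv_mid, p, F) with
#'   attributes.
#' @export
fes_1d <- function(cv, weights = NULL, n_bins = 30, breaks = NULL,
                   reference = c("min", "lowest_cv"), temperature = NA) {
  reference <- match.arg(reference)
  if (is.null(weights)) weights <- rep(1 / length(cv), length(cv))
  if (is.null(breaks))
    breaks <- seq(min(cv) - 1e-12, max(cv) + 1e-12, length.out = n_bins + 1)
  bin <- findInterval(cv, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= length(breaks) - 1
  p <- vapply(seq_len(length(breaks) - 1), function(m)
    sum(weights[ok & bin == m]), numeric(1))
  p <- p / sum(p)
  FF <- -log(p)
  ref_val <- if (reference == "min") min(FF[is.finite(FF)]) else
    FF[which(is.finite(FF))[1]]
  FF <- FF - ref_val
  out <- data.frame(cv_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    p = p, F = FF)
  attr(out, "temperature") <- temperature
  attr(out, "reference") <- reference
  class(out) <- c("free_energy_surface", "data.frame")
  out
}

#' Two-dimensional free-energy surface
#' @inheritParams fes_1d
#' @param cv1,cv2 the two CV sample vectors (e.g. Q total and Q inter).
#' @param bins1,bins2 bin counts.
#' @export
fes_2d <- function(cv1, cv2, weights = NULL, bins1 = 30, bins2 = 30,
                   temperature = NA) {
  if (is.null(weights)) weights <- rep(1 / length(cv1), length(cv1))
  b1 <- seq(min(cv1) - 1e-12, max(cv1) + 1e-12, length.out = bins1 + 1)
  b2 <- seq(min(cv2) - 1e-12, max(cv2) + 1e-12, length.out = bins2 + 1)
  i1 <- findInterval(cv1, b1, rightmost.closed = TRUE)
  i2 <- findInterval(cv2, b2, rightmost.closed = TRUE)
  p <- matrix(0, bins1, bins2)
  for (s in seq_along(cv1)) p[i1[s], i2[s]] <- p[i1[s], i2[s]] + weights[s]
  p <- p / sum(p)
  FF <- -log(p)
  FF <- FF - min(FF[is.finite(FF)])
  grid <- expand.grid(cv1_mid = (b1[-1] + b1[-length(b1)]) / 2,
                      cv2_mid = (b2[-1] + b2[-length(b2)]) / 2)
  out <- data.frame(grid, p = as.vector(p), F = as.vector(FF))
  attr(out, "temperature") <- temperature
  class(out) <- c("free_energy_surface", "data.frame")
  out
}

#' Umbrella-sampling WHAM
#'
#' Combines harmonically biased windows into one unbiased potential of mean
#' force on the collective-variable grid.
#'
#' @param windows an `umbrella_set` from [run_umbrella()].
#' @param n_bins CV grid resolution.
#' @param temperature reduced temperature of the windows.
#' @param discard_frac equilibration fraction dropped per window.
#' @param tol,max_iter iteration control.
#' @return a `free_energy_surface` over the CV with per-window consistency
#'   residuals in attribute `residuals`.
#' @export
wham_umbrella <- function(windows, n_bins = 60, temperature = NULL,
                          discard_frac = 0.2, tol = 1e-10, max_iter = 20000) {
  K <- length(windows)
  cvs <- lapply(windows, function(w) {
    n <- length(w$cv)
    w$cv[seq_len(n) > floor(discard_frac * n)]
  })
  if (any(vapply(cvs, length, integer(1)) == 0))
    stop("empty umbrella window after equilibration discard")
  if (is.null(temperature)) temperature <- windows[[1]]$temperature
  beta <- 1 / temperature
  centers <- vapply(windows, function(w) w$window$center, numeric(1))
  springs <- vapply(windows, function(w) w$window$k, numeric(1))
  allcv <- unlist(cvs)
  breaks <- seq(min(allcv) - 1e-12, max(allcv) + 1e-12,
                length.out = n_bins + 1)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  H <- matrix(0, K, n_bins)
  for (k in seq_len(K))
    H[k, ] <- tabulate(findInterval(cvs[[k]], breaks, rightmost.closed = TRUE),
                       nbins = n_bins)
  N_k <- rowSums(H)
  Htot <- colSums(H)
  # bias energy of window k evaluated at bin m
  W <- matrix(0, K, n_bins)
  for (k in seq_len(K)) W[k, ] <- 0.5 * springs[k] * (mid - centers[k])^2
  f <- numeric(K)
  for (it in seq_len(max_iter)) {
    denom <- vapply(seq_len(n_bins), function(m)
      logsumexp(log(N_k) + f - beta * W[, m]), numeric(1))
    log_p <- ifelse(Htot > 0, log(Htot) - denom, -Inf)
    log_p <- log_p - logsumexp(log_p[is.finite(log_p)])
    f_new <- -vapply(seq_len(K), function(k)
      logsumexp(log_p[Htot > 0] - beta * W[k, Htot > 0]), numeric(1))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  FF <- -log_p        # in kT
  FF <- FF - min(FF[is.finite(FF)])
  # residual: per-window reconstruction of its own biased histogram
  resid <- vapply(seq_len(K), function(k) {
    pred <- exp(-FF - beta * W[k, ] + f[k])
    pred[!is.finite(pred)] <- 0
    obs <- H[k, ] / max(1, N_k[k])
    mean(abs(pred / sum(pred) - obs))
  }, numeric(1))
  out <- data.frame(cv_mid = mid, p = exp(log_p), F = FF)
  attr(out, "temperature") <- temperature
  attr(out, "reference") <- "min"
  attr(out, "residuals") <- resid
  attr(out, "f_windows") <- f
  class(out) <- c("free_energy_surface", "data.frame")
  out
}

#' Reweight samples across contact-strength ratios
#'
#' The density of states is independent of `rho`, so equilibrium averages
#' at `rho_target` follow from samples generated at `rho0` with weights
#' `exp(-(E(rho) - E(rho0)) / kT)`, where the energy difference is exactly
#' `(rho_target/rho0 - 1)` times the recorded interdomain + linker contact
#' energy.  No new simulation is needed.
#'
#' @param samples sample table with columns `E`, `inter_linker` and
#'   optionally `logD` (from [wham_temperature()], enabling multi-
#'   temperature pooling) and `cv`.
#' @param rho_target target ratio.
#' @param temperature evaluation temperature.
#' @param rho0 ratio at which the samples were generated.
#' @param ess_warn_frac warn when the effective sample size falls below
#'   this fraction of the input.
#' @return list with normalised `weights`, `ess`, and `fes(n_bins, breaks)`
#'   returning the reweighted [fes_1d()] over `cv`.
#' @export
reweight_rho <- function(samples, rho_target, temperature, rho0 = 1.0,
                         ess_warn_frac = 0.1) {
  if (!all(c("E", "inter_linker") %in% names(samples)))
    stop("samples must carry decomposed energies (E, inter_linker)")
  dE <- (rho_target / rho0 - 1) * samples$inter_linker
  # pooled multi-temperature samples (logD present) need the full ensemble
  # weight at the target temperature; samples already equilibrated at
  # (rho0, temperature) only need the energy-difference factor
  lw <- if (!is.null(samples$logD))
    -(samples$E + dE) / temperature - samples$logD
  else -dE / temperature
  w <- exp(lw - logsumexp(lw))
  ess <- 1 / sum(w^2)
  if (ess < ess_warn_frac * length(w))
    warning("effective sample size ", round(ess), " below ",
            100 * ess_warn_frac, "% of ", length(w), " samples")
  structure(list(
    weights = w, ess = ess, rho_target = rho_target, rho0 = rho0,
    temperature = temperature,
    fes = function(n_bins = 30, breaks = NULL)
      fes_1d(samples$cv, w, n_bins = n_bins, breaks = breaks,
             temperature = temperature)),
    class = "rho_reweight")
}

#' @export
print.rho_reweight <- function(x, ...) {
  cat("<rho_reweight> rho ", x$rho0, " -> ", x$rho_target, " at T = ",
      x$temperature, "; ESS = ", round(x$ess), "\n", sep = "")
  invisible(x)
}

# two-parameter unfolding sigmoid: P(T) = 1 / (1 + exp((T - Tm) / w))
sigmoid_p <- function(T, tm, w) 1 / (1 + exp((T - tm) / w))

fit_sigmoid <- function(T, P) {
  sse <- function(par) sum((sigmoid_p(T, par[1], exp(par[2])) - P)^2)
  tm0 <- T[which.min(abs(P - 0.5))]
  w0 <- diff(range(T)) / 10
  fit <- optim(c(tm0, log(w0)), sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(tm = fit$par[1], width = exp(fit$par[2]), sse = fit$value)
}

#' Melting curves of folding elements
#'
#' For each element (domain or interface contact subset) the folded
#' probability `P_I(T) = P(Q_I >= threshold)` is evaluated on the replica
#' ladder and fitted with the two-parameter sigmoid
#' `P = 1 / (1 + exp((T - Tm)/w))`.  Elements that never change state
#' across the ladder are flagged degenerate.
#'
#' @param q_by_element named list; each entry is a list of per-replica Q
#'   series (same ordering as the ladder).
#' @param ladder replica temperatures.
#' @param threshold folded criterion on Q (default 0.75).
#' @param discard_frac equilibration fraction dropped.
#' @return list of `melting_curve` objects (element, data T/P, tm, width,
#'   degenerate flag).
#' @export
melting_curves <- function(q_by_element, ladder, threshold = 0.75,
                           discard_frac = 0.2) {
  lapply(names(q_by_element), function(nm) {
    qs <- q_by_element[[nm]]
    P <- vapply(seq_along(ladder), function(r) {
      q <- qs[[r]]
      keep <- seq_along(q) > floor(discard_frac * length(q))
      mean(q[keep] >= threshold)
    }, numeric(1))
    degenerate <- all(P > 0.99) || all(P < 0.01)
    ft <- if (degenerate) list(tm = NA_real_, width = NA_real_) else
      fit_sigmoid(ladder, P)
    out <- list(element = nm, data = data.frame(temperature = ladder, P = P),
                tm = ft$tm, width = ft$width, degenerate = degenerate)
    class(out) <- "melting_curve"
    out
  }) -> curves
  names(curves) <- names(q_by_element)
  curves
}

#' @export
print.melting_curve <- function(x, ...) {
  cat("<melting_curve> ", x$element, ": Tm = ", signif(x$tm, 4),
      ", width = ", signif(x$width, 3),
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

#' Thermodynamic coupling index
#'
#' `TCI = -ln < |P_I(T) - P_J(T)| >` with the average over a shared
#' temperature grid; identical curves are capped at
#' `-ln(1 / (10 * grid size))` to stay finite and comparable.  Large TCI
#' means the two elements melt synchronously (high folding cooperativity).
#'
#' @param curve_i,curve_j `melting_curve` objects on the same grid, or a
#'   data.frame with columns temperature and P.
#' @return scalar TCI.
#' @export
tci <- function(curve_i, curve_j) {
  di <- if (inherits(curve_i, "melting_curve")) curve_i$data else curve_i
  dj <- if (inherits(curve_j, "melting_curve")) curve_j$data else curve_j
  if (!isTRUE(all.equal(di$temperature, dj$temperature)))
    stop("melting curves are on different temperature grids")
  m <- mean(abs(di$P - dj$P))
  cap <- tci_cap(length(di$temperature))
  min(-log(max(m, .Machine$double.xmin)), cap)
}

tci_cap <- function(grid_size) -log(1 / (10 * grid_size))

#' @rdname tci
#' @param curves list of melting curves (the mean TCI pools the mean
#'   absolute differences over all pairs before taking -ln).
#' @export
mtci <- function(curves) {
  k <- length(curves)
  if (k < 2) stop("MTCI needs at least two curves")
  ds <- lapply(curves, function(cc)
    if (inherits(cc, "melting_curve")) cc$data else cc)
  grid <- ds[[1]]$temperature
  vals <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!isTRUE(all.equal(ds[[i]]$temperature, ds[[j]]$temperature)))
      stop("melting curves are on different temperature grids")
    vals <- c(vals, mean(abs(ds[[i]]$P - ds[[j]]$P)))
  }
  cap <- tci_cap(length(grid))
  min(-log(max(mean(vals), .Machine$double.xmin)), cap)
}

#' Stability of folding states across rho
#'
#' `dF(rho)^S = F_S - F_U` by Boltzmann-weighted integration of the 2D
#' (Q total, Q inter) surface over each state window, and
#' `ddF(rho)^S = dF(rho)^S - dF(rho0)^S`.
#'
#' @param surfaces named list (names = rho values as strings) of 2D
#'   `free_energy_surface`s at each rho's folding temperature.
#' @param states named list of windows
#'   `list(q_total = c(lo, hi), q_inter = c(lo, hi))`; must include `U`.
#' @param rho0 reference rho (name into `surfaces`).
#' @return data.frame (rho, state, dF, ddF), class `stability_table`.
#' @export
state_stabilities <- function(surfaces, states, rho0 = "1") {
  if (!rho0 %in% names(surfaces)) stop("rho0 surface missing")
  if (!"U" %in% names(states)) stop("states must include the unfolded window U")
  window_logZ <- function(surf, win) {
    sel <- surf$cv1_mid >= win$q_total[1] & surf$cv1_mid <= win$q_total[2] &
           surf$cv2_mid >= win$q_inter[1] & surf$cv2_mid <= win$q_inter[2]
    if (!any(sel & surf$p > 0)) stop("empty state window")
    log(sum(surf$p[sel]))
  }
  rows <- list()
  dF0 <- NULL
  for (rho in names(surfaces)) {
    surf <- surfaces[[rho]]
    lzU <- window_logZ(surf, states$U)
    for (s in setdiff(names(states), "U")) {
      dF <- -(window_logZ(surf, states[[s]]) - lzU)
      rows[[length(rows) + 1]] <- data.frame(rho = rho, state = s, dF = dF)
    }
  }
  tab <- do.call(rbind, rows)
  ref <- tab[tab$rho == rho0, c("state", "dF")]
  tab$ddF <- tab$dF - ref$dF[match(tab$state, ref$state)]
  class(tab) <- c("stability_table", "data.frame")
  tab
}

#' Binding affinity from a dRMS potential of mean force
#'
#' The ratio of Boltzmann integrals over the bound and unbound dRMS windows
#' gives the binding free energy at the simulation-box concentration; the
#' standard-state correction through the box volume converts it to a
#' dissociation constant.  With one ligand in volume V the reference
#' concentration is `c_box = 1 / (N_A V)` and `Kd = c_box * Z_unbound /
#' Z_bound`.
#'
#' @param pmf a `free_energy_surface` over dRMS (kT units).
#' @param bound_window dRMS window of the bound state, nm (default < 0.5).
#' @param unbound_window dRMS window of the unbound state (default > 10,
#'   the unbound-state threshold).
#' @param box_volume_nm3 sampling volume in nm^3.
#' @return class `binding_affinity`: list with `dG_bind` (kT), `kd_nM`,
#'   `kd_M`, window definitions and four-state populations.
#' @param state_windows dRMS windows for the US/EC/IS/BS classifier,
#'   echoed into the output.
#' @export
kd_from_pmf <- function(pmf, bound_window = c(0, 0.5),
                        unbound_window = c(10, Inf), box_volume_nm3,
                        state_windows = binding_state_windows()) {
  if (max(pmf$cv_mid) < unbound_window[1])
    stop("PMF does not reach the unbound plateau (dRMS > ",
         unbound_window[1], " nm)")
  zb <- sum(pmf$p[pmf$cv_mid >= bound_window[1] & pmf$cv_mid < bound_window[2]])
  zu <- sum(pmf$p[pmf$cv_mid >= unbound_window[1] &
                  pmf$cv_mid < unbound_window[2]])
  if (zb <= 0 || zu <= 0) stop("empty bound or unbound window")
  dG <- -log(zb / zu)                        # kT, at box concentration
  avogadro <- 6.02214076e23
  c_box_M <- 1 / (avogadro * box_volume_nm3 * 1e-24)  # nm^3 -> L
  kd_M <- c_box_M * zu / zb
  pops <- vapply(state_windows, function(w)
    sum(pmf$p[pmf$cv_mid >= w[1] & pmf$cv_mid < w[2]]), numeric(1))
  pops <- pops / sum(pops)
  out <- list(dG_bind = dG, kd_M = kd_M, kd_nM = kd_M * 1e9,
              box_volume_nm3 = box_volume_nm3,
              bound_window = bound_window, unbound_window = unbound_window,
              state_windows = state_windows, populations = pops)
  class(out) <- "binding_affinity"
  out
}

#' @export
print.binding_affinity <- function(x, ...) {
  cat("<binding_affinity> Kd = ", signif(x$kd_nM, 4), " nM (dG = ",
      signif(x$dG_bind, 4), " kT at box concentration)\n", sep = "")
  cat("  populations:", paste(names(x$populations),
                              signif(x$populations, 3), sep = "=",
                              collapse = ", "), "\n")
  invisible(x)
}

#' Four-state binding classifier windows (dRMS, nm)
#'
#' Unbound (US) beyond 10 nm, encounter complex (EC) between 2.5 and 10 nm,
#' intermediate state (IS) between 0.5 and 2.5 nm, bound state (BS) below
#' 0.5 nm.
#' @export
binding_state_windows <- function() {
  list(BS = c(0, 0.5), IS = c(0.5, 2.5), EC = c(2.5, 10), US = c(10, Inf))
}

#' Classify a dRMS value into US / EC / IS / BS
#' @param drms_value dRMS in nm
#' @param windows window list as in [binding_state_windows()]
#' @export
classify_binding_state <- function(drms_value,
                                   windows = binding_state_windows()) {
  vapply(drms_value, function(d) {
    for (nm in names(windows))
      if (d >= windows[[nm]][1] && d < windows[[nm]][2]) return(nm)
    NA_character_
  }, character(1))
}
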