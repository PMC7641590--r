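#' Simulation protocol
#'
#' Bundles integrator and sampling settings in reduced units (kB = 1, time
#' in tau).  The defaults are a BAOAB Langevin leapfrog with dt = 0.0005 tau
#' and friction 1/tau; tests and examples typically shorten `n_steps` and
#' enlarge `dt` within the stability limit of the stiffest bonded term.
#'
#' @param temperature reduced temperature (single runs) .
#' @param ladder strictly increasing temperature ladder (replica exchange).
#' @param n_steps integrator steps.
#' @param dt timestep (tau).
#' @param friction Langevin friction (1/tau).
#' @param record_interval steps between recorded frames.
#' @param exchange_interval steps between replica-exchange attempts.
#' @param seed integer seed recorded into every trajectory.
#' @export
simulation_protocol <- function(temperature = 1.0, ladder = NULL,
                                n_steps = 100000, dt = 5e-4, friction = 1.0,
                                record_interval = 1000,
                                exchange_interval = 1000, seed = 1L) {
  if (dt <= 0) stop("timestep must be positive")
  if (!is.null(ladder) && any(diff(ladder) < 0))
    stop("temperature ladder must be non-decreasing")
  p <- list(temperature = temperature, ladder = ladder, n_steps = n_steps,
            dt = dt, friction = friction, record_interval = record_interval,
            exchange_interval = exchange_interval, seed = as.integer(seed))
  class(p) <- "simulation_protocol"
  p
}

no_bias <- function() list(type = 0L)

drms_bias_spec <- function(contacts, type, ...) {
  bind <- contact_subset(contacts, "binding")
  if (nrow(bind) == 0) stop("bias on dRMS requires binding contacts")
  c(list(type = type,
         bpair = matrix(as.integer(c(bind$i, bind$j)), ncol = 2) - 1L,
         bsig = bind$sigma),
    list(...))
}

new_trajectory <- function(raw, model, protocol, temperature, extra = list()) {
  nrec <- length(raw$times)
  fr <- raw$frames
  frames <- if (nrec > 0) aperm(array(fr, dim = dim(fr)), c(3, 2, 1)) else
    array(0, dim = c(0, if (is.null(model)) 1 else nrow(model$beads), 3))
  en <- as.data.frame(raw$energies)
  names(en) <- c("bonded", "intra", "inter", "linker", "binary_basin",
                 "binding", "electrostatic", "excluded", "total")
  tr <- c(list(times = raw$times, frames = frames, energies = en,
               cv = raw$cv, bias_energy = raw$bias_energy,
               final_pos = raw$final_pos, temperature = temperature,
               protocol = protocol), extra)
  class(tr) <- "trajectory_record"
  tr
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat("<trajectory_record> ", length(x$times), " frames, T = ",
      x$temperature, ", t = ",
      if (length(x$times)) max(x$times) else 0, " tau\n", sep = "")
  invisible(x)
}

#' Langevin dynamics
#'
#' Runs BAOAB Langevin dynamics on a bead model (or on a 1D double-well
#' reference system from [make_double_well()]).  Frozen beads never move.
#' Trajectories are reproducible: the protocol seed fixes the random stream.
#'
#' @param model a `cg_model` or `double_well` system.
#' @param contacts classified `contact_set` (ignored for 1D systems).
#' @param forcefield an `sbm_forcefield` (ignored for 1D systems).
#' @param protocol a [simulation_protocol()].
#' @param coords starting coordinates (native by default; for 1D systems a
#'   scalar x).
#' @return a `trajectory_record` with frame times, coordinates, decomposed
#'   energies and the protocol echoed.
#' @export
run_langevin <- function(model, contacts = NULL, forcefield = NULL,
                         protocol = simulation_protocol(), coords = NULL) {
  set.seed(protocol$seed)
  if (inherits(model, "double_well")) {
    x0 <- if (is.null(coords)) model$x_min[1] else coords
    raw <- dw_langevin_cpp(model$barrier, model$tilt, x0, protocol$dt,
                           protocol$friction, protocol$temperature,
                           protocol$n_steps, protocol$record_interval,
                           no_bias())
    return(dw_trajectory(raw, protocol, protocol$temperature))
  }
  sys <- compile_system(model, contacts, forcefield)
  pos0 <- if (is.null(coords)) native_coords(model) else coords
  raw <- cg_langevin_cpp(sys, pos0, protocol$dt, protocol$friction,
                         protocol$temperature, protocol$n_steps,
                         protocol$record_interval, no_bias(), 0.0)
  new_trajectory(raw, model, protocol, protocol$temperature)
}

dw_trajectory <- function(raw, protocol, temperature, extra = list()) {
  tr <- c(list(times = raw$times,
               frames = array(raw$x, dim = c(length(raw$x), 1, 1)),
               x = raw$x,
               energies = data.frame(total = raw$energies),
               cv = raw$x, bias_energy = raw$bias_energy,
               final_pos = raw$final_x, temperature = temperature,
               protocol = protocol,
               hills = data.frame(time = raw$hill_times,
                                  center = raw$hills_x,
                                  height = raw$hills_h),
               rescaled_time = raw$rescaled_time,
               arrival_time = raw$arrival_time,
               arrival_rescaled = raw$arrival_rescaled), extra)
  class(tr) <- "trajectory_record"
  tr
}

#' Temperature replica-exchange molecular dynamics
#'
#' Runs one Langevin replica per ladder temperature with Metropolis swap
#' attempts between neighbouring temperatures every `exchange_interval`
#' steps (acceptance `min(1, exp(dbeta * dE))`).  Velocities are redrawn
#' from the Maxwell-Boltzmann distribution after each attempt, and the
#' returned records are per-temperature (ensemble view): each slot holds
#' the configurations that visited that ladder temperature.
#'
#' @inheritParams run_langevin
#' @param coords starting coordinates shared by all replicas.
#' @return class `remd_record`: list with `replicas` (one
#'   `trajectory_record` per ladder temperature), `ladder`, and
#'   `exchange` (per-pair attempt/acceptance counts and the swap log).
#' @export
run_remd <- function(model, contacts, forcefield,
                     protocol = simulation_protocol(ladder = seq(0.8, 1.2, length.out = 8)),
                     coords = NULL) {
  ladder <- protocol$ladder
  if (is.null(ladder) || length(ladder) < 2)
    stop("replica exchange needs a ladder with at least 2 temperatures")
  set.seed(protocol$seed)
  one_d <- inherits(model, "double_well")
  sys <- if (one_d) NULL else compile_system(model, contacts, forcefield)
  pos0 <- if (!is.null(coords)) coords else if (one_d) model$x_min[1] else
    native_coords(model)
  nrep <- length(ladder)
  pos <- replicate(nrep, pos0, simplify = FALSE)
  nchunk <- max(1L, protocol$n_steps %/% protocol$exchange_interval)
  acc <- att <- integer(nrep - 1)
  chunks <- vector("list", nrep)
  for (r in seq_len(nrep)) chunks[[r]] <- vector("list", nchunk)
  swap_log <- list()

  for (ch in seq_len(nchunk)) {
    enr <- numeric(nrep)
    for (r in seq_len(nrep)) {
      if (one_d) {
        raw <- dw_langevin_cpp(model$barrier, model$tilt, pos[[r]],
                               protocol$dt, protocol$friction, ladder[r],
                               protocol$exchange_interval,
                               protocol$record_interval, no_bias())
        pos[[r]] <- raw$final_x
        enr[r] <- model$barrier * (raw$final_x^2 - 1)^2 + model$tilt * raw$final_x
      } else {
        raw <- cg_langevin_cpp(sys, pos[[r]], protocol$dt, protocol$friction,
                               ladder[r], protocol$exchange_interval,
                               protocol$record_interval, no_bias(),
                               (ch - 1) * protocol$exchange_interval * protocol$dt)
        pos[[r]] <- raw$final_pos
        enr[r] <- cg_energy_cpp(sys, raw$final_pos)[["total"]]
      }
      chunks[[r]][[ch]] <- raw
    }
    # neighbour swaps, alternating even/odd pairs
    start <- if (ch %% 2 == 1) 1 else 2
    if (start > nrep - 1) next
    for (r in seq(start, nrep - 1, by = 2)) {
      att[r] <- att[r] + 1L
      dbeta <- 1 / ladder[r] - 1 / ladder[r + 1]
      de <- enr[r] - enr[r + 1]
      if (runif(1) < exp(min(0, dbeta * de))) {
        tmp <- pos[[r]]; pos[[r]] <- pos[[r + 1]]; pos[[r + 1]] <- tmp
        tmp <- enr[r]; enr[r] <- enr[r + 1]; enr[r + 1] <- tmp
        acc[r] <- acc[r] + 1L
        swap_log[[length(swap_log) + 1]] <- c(chunk = ch, pair = r)
      }
    }
  }

  replicas <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    raw <- list(
      times = unlist(lapply(chunks[[r]], `[[`, "times")),
      energies = do.call(rbind, lapply(chunks[[r]], function(z)
        if (one_d) matrix(z$energies, ncol = 1) else z$energies)),
      cv = unlist(lapply(chunks[[r]], `[[`, "cv")),
      bias_energy = unlist(lapply(chunks[[r]], `[[`, "bias_energy")),
      final_pos = pos[[r]])
    if (one_d) {
      raw$x <- unlist(lapply(chunks[[r]], `[[`, "x"))
      raw$energies <- as.vector(raw$energies)
      raw$hill_times <- numeric(0); raw$hills_x <- numeric(0)
      raw$hills_h <- numeric(0); raw$rescaled_time <- 0
      raw$arrival_time <- NA_real_; raw$arrival_rescaled <- NA_real_
      raw$final_x <- pos[[r]]
      replicas[[r]] <- dw_trajectory(raw, protocol, ladder[r])
    } else {
      nb <- nrow(model$beads)
      fr <- lapply(chunks[[r]], function(z) z$frames)
      nf <- vapply(fr, function(f) dim(f)[3], integer(1))
      all_fr <- array(0, dim = c(3, nb, sum(nf)))
      at <- 0L
      for (z in seq_along(fr)) {
        if (nf[z] > 0) all_fr[, , at + seq_len(nf[z])] <- fr[[z]]
        at <- at + nf[z]
      }
      raw$frames <- all_fr
      replicas[[r]] <- new_trajectory(raw, model, protocol, ladder[r])
    }
    # times restart within chunks for the 1D path; rebuild a global clock
    replicas[[r]]$times <- seq_along(replicas[[r]]$times) *
      protocol$record_interval * protocol$dt
  }
  out <- list(replicas = replicas, ladder = ladder,
              exchange = list(attempts = att, accepted = acc,
                              rate = ifelse(att > 0, acc / att, NA),
                              log = do.call(rbind, swap_log)),
              protocol = protocol)
  class(out) <- "remd_record"
  out
}

#' @export
print.remd_record <- function(x, ...) {
  cat("<remd_record> ", length(x$ladder), " replicas, T in [",
      min(x$ladder), ", ", max(x$ladder), "], mean exchange rate ",
      signif(mean(x$exchange$rate, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Umbrella sampling along dRMS (or x for 1D systems)
#'
#' Adds a harmonic bias `k/2 (cv - center)^2` per window and returns one
#' biased trajectory per window.  Windows whose collective-variable
#' histograms fail to overlap their neighbour trigger a warning.
#'
#' @inheritParams run_langevin
#' @param windows data.frame with columns `center` and `k`.
#' @return list of `trajectory_record`s, one per window, each carrying its
#'   `window` parameters; class `umbrella_set`.
#' @export
run_umbrella <- function(model, contacts = NULL, forcefield = NULL, windows,
                         protocol = simulation_protocol(), coords = NULL) {
  stopifnot(is.data.frame(windows), all(c("center", "k") %in% names(windows)))
  one_d <- inherits(model, "double_well")
  sys <- if (one_d) NULL else compile_system(model, contacts, forcefield)
  out <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    set.seed(protocol$seed + w)
    if (one_d) {
      x0 <- if (is.null(coords)) windows$center[w] else coords
      raw <- dw_langevin_cpp(model$barrier, model$tilt, x0, protocol$dt,
                             protocol$friction, protocol$temperature,
                             protocol$n_steps, protocol$record_interval,
                             list(type = 1L, center = windows$center[w],
                                  k = windows$k[w]))
      tr <- dw_trajectory(raw, protocol, protocol$temperature,
                          list(window = windows[w, ]))
    } else {
      pos0 <- if (is.null(coords)) native_coords(model) else coords
      bias <- drms_bias_spec(contacts, 1L, center = windows$center[w],
                             k = windows$k[w])
      raw <- cg_langevin_cpp(sys, pos0, protocol$dt, protocol$friction,
                             protocol$temperature, protocol$n_steps,
                             protocol$record_interval, bias, 0.0)
      tr <- new_trajectory(raw, model, protocol, protocol$temperature,
                           list(window = windows[w, ]))
    }
    if (length(tr$cv) == 0) stop("window ", w, " produced no samples")
    out[[w]] <- tr
  }
  # neighbour-overlap check on CV ranges
  for (w in seq_len(nrow(windows) - 1)) {
    a <- range(out[[w]]$cv); bb <- range(out[[w + 1]]$cv)
    if (a[2] < bb[1] || bb[2] < a[1])
      warning("umbrella windows ", w, " and ", w + 1,
              " have non-overlapping samples")
  }
  class(out) <- c("umbrella_set", "list")
  out
}

#' Well-tempered (infrequent) metadynamics
#'
#' Deposits Gaussian hills on the collective variable (dRMS for bead
#' systems, x for 1D systems) on a schedule, with well-tempered height
#' damping.  The frequency-adaptive variant doubles the deposition interval
#' each time the running acceleration factor `<exp(V_bias/T)>` crosses a
#' power of ten.  The run stops at first arrival in the target CV window;
#' the rescaled transition time `sum dt exp(V_bias/T)` is accumulated for
#' rate estimation.  A run that never arrives is flagged censored.
#'
#' @inheritParams run_langevin
#' @param hill_height initial hill height (eps).
#' @param hill_width Gaussian width (CV units).
#' @param pace deposition interval in steps.
#' @param bias_factor well-tempered bias factor gamma (> 1).
#' @param target CV window `c(lo, hi)` ending the run, or NULL to run out
#'   the step budget.
#' @param freq_adaptive logical, enable the adaptive deposition schedule.
#' @param wall optional `c(position, k)`: a static harmonic upper wall on
#'   the CV confining the search region (kept out of the acceleration
#'   factor).
#' @return a `trajectory_record` with `hills`, `rescaled_time`,
#'   `arrival_time` (NA when censored) and `censored`.
#' @export
run_metadynamics <- function(model, contacts = NULL, forcefield = NULL,
                             protocol = simulation_protocol(),
                             hill_height = 0.3, hill_width = 0.1, pace = 500,
                             bias_factor = 6, target = NULL,
                             freq_adaptive = TRUE, wall = NULL,
                             coords = NULL) {
  set.seed(protocol$seed)
  stop_lo <- if (is.null(target)) NA_real_ else target[1]
  stop_hi <- if (is.null(target)) NA_real_ else target[2]
  mspec <- list(h0 = hill_height, width = hill_width, pace = as.integer(pace),
                biasfactor = bias_factor, stop_lo = stop_lo, stop_hi = stop_hi,
                freq_adaptive = freq_adaptive,
                wall_x = if (is.null(wall)) NA_real_ else wall[1],
                wall_k = if (is.null(wall)) 0 else wall[2],
                hills_x = numeric(0), hills_h = numeric(0))
  if (inherits(model, "double_well")) {
    x0 <- if (is.null(coords)) model$x_min[1] else coords
    raw <- dw_langevin_cpp(model$barrier, model$tilt, x0, protocol$dt,
                           protocol$friction, protocol$temperature,
                           protocol$n_steps, protocol$record_interval,
                           c(list(type = 2L), mspec))
    tr <- dw_trajectory(raw, protocol, protocol$temperature)
  } else {
    sys <- compile_system(model, contacts, forcefield)
    pos0 <- if (is.null(coords)) native_coords(model) else coords
    bias <- c(drms_bias_spec(contacts, 2L), mspec)
    raw <- cg_langevin_cpp(sys, pos0, protocol$dt, protocol$friction,
                           protocol$temperature, protocol$n_steps,
                           protocol$record_interval, bias, 0.0)
    tr <- new_trajectory(raw, model, protocol, protocol$temperature,
                         list(hills = data.frame(time = raw$hill_times,
                                                 center = raw$hills_x,
                                                 height = raw$hills_h),
                              rescaled_time = raw$rescaled_time,
                              arrival_time = raw$arrival_time,
                              arrival_rescaled = raw$arrival_rescaled))
  }
  tr$censored <- !is.null(target) && is.na(tr$arrival_time)
  tr
}
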