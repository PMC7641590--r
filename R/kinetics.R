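#' First passage time of a Q series
#'
#' The folding time is the earliest frame time at which the total fraction
#' of native contacts reaches the threshold (default 0.75); a trajectory
#' that never crosses is censored.
#'
#' @param times frame times (tau) or a `trajectory_record`.
#' @param q Q series aligned with `times` (omit when a trajectory and
#'   `contacts` are given).
#' @param q_threshold folding criterion.
#' @param contacts contact subset used to compute Q from a trajectory.
#' @return list with `fpt` (tau, NA when censored) and `censored`.
#' @export
first_passage <- function(times, q = NULL, q_threshold = 0.75,
                          contacts = NULL) {
  if (inherits(times, "trajectory_record")) {
    tr <- times
    q <- cv_series(tr, contacts)
    times <- tr$times
  }
  hit <- which(q >= q_threshold)
  if (length(hit) == 0) return(list(fpt = NA_real_, censored = TRUE))
  list(fpt = times[hit[1]], censored = FALSE)
}

#' Detect folding backtracking
#'
#' Backtracking is the formation, breaking, and re-formation of a subset of
#' native contacts on the way to the folded state.  The interdomain
#' coordinate is binned along the monotonised folding progress (running
#' maximum of Q total); a backtracking event is a local maximum of the
#' binned Q inter followed by a drop of at least `drop_threshold` before
#' further progress, with later recovery.
#'
#' @param q_total,q_inter aligned CV series from one kinetic trajectory.
#' @param bin_width bin width on the Q-total progress axis.
#' @param drop_threshold minimum Q-inter drop that counts as an event.
#' @param q_domains optional named list of per-domain Q series; domains
#'   with Q above 0.5 at the event peak are reported as implicated.
#' @return data.frame of events (progress at peak, drop magnitude,
#'   implicated domains as a comma string).
#' @export
detect_backtracking <- function(q_total, q_inter, bin_width = 0.02,
                                drop_threshold = 0.05, q_domains = NULL) {
  if (length(q_total) < 4) stop("trajectory too short to bin")
  prog <- cummax(q_total)
  breaks <- seq(min(prog), max(prog) + bin_width, by = bin_width)
  if (length(breaks) < 4) stop("trajectory too short to bin")
  bin <- findInterval(prog, breaks, rightmost.closed = TRUE)
  nb <- max(bin)
  y <- vapply(seq_len(nb), function(b)
    if (any(bin == b)) mean(q_inter[bin == b]) else NA_real_, numeric(1))
  keep <- !is.na(y)
  y <- y[keep]
  centers <- (breaks[-1] - bin_width / 2)[seq_len(nb)][keep]
  events <- list()
  b <- 1
  while (b < length(y)) {
    # next local maximum
    while (b < length(y) && y[b + 1] >= y[b]) b <- b + 1
    if (b >= length(y)) break
    peak <- b
    # deepest valley before recovery above the peak
    v <- peak
    b2 <- peak
    while (b2 < length(y) && y[b2 + 1] < y[peak]) {
      b2 <- b2 + 1
      if (y[b2] < y[v]) v <- b2
    }
    drop <- y[peak] - y[v]
    recovered <- b2 < length(y)  # series rose back above the peak value
    if (drop >= drop_threshold && v > peak && recovered) {
      implicated <- NA_character_
      if (!is.null(q_domains)) {
        at <- which(bin == peak)[1]
        qd <- vapply(q_domains, function(z) z[at], numeric(1))
        implicated <- paste(names(qd)[qd > 0.5], collapse = ",")
      }
      events[[length(events) + 1]] <- data.frame(
        progress = centers[peak], drop = drop, implicated = implicated,
        stringsAsFactors = FALSE)
    }
    b <- max(b2, peak + 1)
  }
  if (length(events)) do.call(rbind, events) else
    data.frame(progress = numeric(0), drop = numeric(0),
               implicated = character(0))
}

#' Folding order of domains and interfaces
#'
#' For each successful folding event, element I folds at step k when it is
#' the k-th element to cross `q_threshold` without later falling below
#' `commitment_fraction * q_threshold` before global folding.  The folding
#' order probability `OP_k^I` is the empirical frequency over events; every
#' column (step) sums to 1, so the mean over elements at any step is 1/n.
#' The step dispersion is
#' `sigma_OPk = sqrt(mean((OP_k^I - 1/n)^2))`.
#'
#' @param events list of events; each is either an integer permutation of
#'   element indices (fold order) or a matrix of per-element Q series
#'   (columns = elements) with attribute "times".
#' @param elements element names (the DPO4 analysis uses 8: four domains
#'   and four interfaces).
#' @param q_threshold,commitment_fraction commitment rule for series input.
#' @return class `op_matrix`: list with `OP` (elements x steps),
#'   `sigma_op` per step, `n_events`, `excluded`.
#' @export
folding_order <- function(events, elements, q_threshold = 0.75,
                          commitment_fraction = 0.67) {
  ne <- length(elements)
  OP <- matrix(0, ne, ne, dimnames = list(elements, paste0("step", 1:ne)))
  used <- 0L; excluded <- 0L
  for (ev in events) {
    perm <- if (is.matrix(ev))
      element_fold_order(ev, q_threshold, commitment_fraction)
    else as.integer(ev)
    if (length(perm) != ne || anyNA(perm) || anyDuplicated(perm)) {
      excluded <- excluded + 1L
      next
    }
    for (k in seq_len(ne)) OP[perm[k], k] <- OP[perm[k], k] + 1
    used <- used + 1L
  }
  if (used == 0) stop("no usable folding events")
  OP <- OP / used
  sigma_op <- apply(OP, 2, function(col) sqrt(mean((col - 1 / ne)^2)))
  out <- list(OP = OP, sigma_op = sigma_op, n_events = used,
              excluded = excluded)
  class(out) <- "op_matrix"
  out
}

# commitment times of each element's Q series; NA when the element never
# commits (crossing that survives above commitment_fraction * threshold)
element_fold_order <- function(q_mat, q_threshold = 0.75,
                               commitment_fraction = 0.67) {
  ne <- ncol(q_mat)
  tcommit <- rep(NA_real_, ne)
  for (e in seq_len(ne)) {
    q <- q_mat[, e]
    above <- which(q >= q_threshold)
    floor_q <- commitment_fraction * q_threshold
    for (a in above) {
      if (all(q[a:length(q)] >= floor_q)) { tcommit[e] <- a; break }
    }
  }
  if (anyNA(tcommit)) return(rep(NA_integer_, ne))
  order(tcommit)
}

#' @export
print.op_matrix <- function(x, ...) {
  cat("<op_matrix> ", nrow(x$OP), " elements, ", x$n_events, " events",
      if (x$excluded) paste0(" (", x$excluded, " excluded)"), "\n", sep = "")
  print(round(x$OP, 3))
  invisible(x)
}

#' Encounter-stage kinetics
#'
#' Runs started in the encounter complex either evolve to the intermediate
#' binding state or dissociate back to the unbound state.  With rates
#' kEvo and kDis taken as outcome counts over the total observation time,
#' the encounter time `kDis/kEvo + 1` is the expected number of encounter
#' attempts per successful evolution.
#'
#' @param outcomes character vector per run: "evolved" or "dissociated".
#' @param durations run durations (tau), equal observation windows by
#'   default.
#' @return class `encounter_stats`: counts, rates, `encounter_time`.
#' @export
encounter_framework <- function(outcomes, durations = rep(1, length(outcomes))) {
  stopifnot(all(outcomes %in% c("evolved", "dissociated")))
  n_evo <- sum(outcomes == "evolved")
  n_dis <- sum(outcomes == "dissociated")
  total_t <- sum(durations)
  k_evo <- n_evo / total_t
  k_dis <- n_dis / total_t
  et <- if (n_evo == 0) NA_real_ else k_dis / k_evo + 1
  out <- list(n_evo = n_evo, n_dis = n_dis, k_evo = k_evo, k_dis = k_dis,
              encounter_time = et, undefined = n_evo == 0)
  class(out) <- "encounter_stats"
  out
}

#' @export
print.encounter_stats <- function(x, ...) {
  cat("<encounter_stats> ", x$n_evo, " evolved / ", x$n_dis,
      " dissociated; encounter time = ",
      if (x$undefined) "undefined" else signif(x$encounter_time, 4),
      "\n", sep = "")
  invisible(x)
}

#' Transition times from infrequent metadynamics
#'
#' Each run's biased first-arrival time is rescaled by the accumulated
#' acceleration `sum dt exp(V_bias/T)`; the mean over runs estimates the
#' unbiased transition time, with a bootstrap error over 50 subsamples.
#' Censored runs (no arrival within the budget) are excluded and counted.
#'
#' @param runs list of metadynamics `trajectory_record`s.
#' @param n_boot bootstrap resamples (default 50).
#' @param barrier_heights optional per-run or per-condition barrier heights
#'   for the thermo-kinetic consistency correlation.
#' @return class `rate_estimate`: per-run rescaled times, mean, bootstrap
#'   SE, censoring count, optional correlation.
#' @export
metad_transition_time <- function(runs, n_boot = 50, barrier_heights = NULL) {
  times <- vapply(runs, function(r)
    if (isTRUE(r$censored)) NA_real_ else r$arrival_rescaled, numeric(1))
  censored <- sum(is.na(times))
  times <- times[!is.na(times)]
  if (length(times) == 0) stop("all metadynamics runs censored")
  boot <- vapply(seq_len(n_boot), function(b)
    mean(sample(times, replace = TRUE)), numeric(1))
  corr <- if (!is.null(barrier_heights) &&
              length(barrier_heights) == length(times))
    stats::cor(log(times), barrier_heights) else NA_real_
  out <- list(times = times, mean = mean(times), se = sd(boot),
              n_boot = n_boot, censored = censored,
              barrier_correlation = corr)
  class(out) <- "rate_estimate"
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> tau_trans = ", signif(x$mean, 4), " +/- ",
      signif(x$se, 3), " tau (", length(x$times), " runs, ", x$censored,
      " censored, ", x$n_boot, " bootstrap subsamples)\n", sep = "")
  invisible(x)
}
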