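#' Map an experimental temperature into reduced units
#'
#' Simulation temperatures are placed on the experimental scale through the
#' linear relation `T(sim) = T(exp) * Tf(sim) / Tf(exp)`, anchoring the
#' simulated folding temperature (the Cv-peak temperature) to the
#' experimental melting temperature.  For DPO4, Tf(exp) = 369 K and
#' Tf(sim) = 1.13 map the optimal growth temperature 353 K to 1.08 and
#' room temperature 300 K to 0.92.
#'
#' @param t_exp_kelvin experimental temperature (K).
#' @param tf_exp_kelvin experimental folding/melting temperature (K).
#' @param tf_sim simulated folding temperature (reduced units).
#' @return the reduced temperature, with attribute `rounded` reporting the
#'   conventional two-decimal value.
#' @examples
#' map_temperature(353, 369, 1.13)  # 1.08
#' map_temperature(300, 369, 1.13)  # 0.92
#' @export
map_temperature <- function(t_exp_kelvin, tf_exp_kelvin, tf_sim) {
  if (t_exp_kelvin <= 0 || tf_exp_kelvin <= 0 || tf_sim <= 0)
    stop("temperatures must be positive")
  val <- t_exp_kelvin * tf_sim / tf_exp_kelvin
  attr(val, "rounded") <- round(val, 2)
  val
}

#' Run configuration
#'
#' Declarative configuration for the three campaign drivers.  Either a YAML
#' file or a named list; missing blocks take campaign defaults.  The
#' configuration is echoed into every campaign output so reruns are
#' reproducible from the output alone.
#'
#' @param config path to a YAML file or a named list.
#' @return class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    toy = list(n_domains = 2, beads_per_domain = 12, linker_length = 4,
               contact_ratio = 5, partner_length = 0),
    rho = seq(0.5, 1.5, by = 0.1),
    rho0 = 1.0,
    seed = 1L,
    fold = list(ladder = NULL, n_steps = 200000, dt = 0.005,
                record_interval = 500, exchange_interval = 500,
                kinetic_runs = 10, kinetic_temperature_frac = 0.85,
                q_threshold = 0.75),
    bind = list(n_windows = 14, window_k = 50, n_steps = 60000,
                umbrella_max = 12, encounter_runs = 40,
                metad_runs = 10, temperature = 0.6, dt = 0.002))
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed ", x$seed, ", rho = ",
      paste(x$rho, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Build campaign: model + contacts
#'
#' Builds either the synthetic toy system named in the config or, when
#' `config$pdb` points to apo (and optionally bound-form) PDB files, the
#' coarse model and (dual-basin) contact map of a real structure.
#'
#' @param config a [run_config()] (or list/path coercible to one).
#' @param outdir optional directory; when given, contacts (CSV), the model
#'   (JSON) and reference PDB text are written there.
#' @return list with `model`, `contacts`, `pdb`, and the echoed `config`.
#' @export
cmd_build <- function(config = run_config(), outdir = NULL) {
  config <- as_run_config(config)
  if (!is.null(config$pdb)) {
    if (!file.exists(config$pdb$apo))
      stop("structure file not found: ", config$pdb$apo)
    apo <- parse_pdb(config$pdb$apo)
    dmap <- do.call(domain_map, config$domains)
    model <- coarse_grain(apo, dmap)
    contacts <- classify_contacts(
      build_contacts(apo, model), model)
    pdb_text <- paste(readLines(config$pdb$apo), collapse = "\n")
    if (!is.null(config$pdb$binary)) {
      if (!file.exists(config$pdb$binary))
        stop("structure file not found: ", config$pdb$binary)
      bnd <- parse_pdb(config$pdb$binary)
      bmodel <- coarse_grain(bnd, dmap)
      bcontacts <- classify_contacts(build_contacts(bnd, bmodel), bmodel)
      contacts <- build_dual_basin(contacts, bcontacts)
      model <- bmodel
    }
    built <- list(model = model, contacts = contacts, pdb = pdb_text)
  } else {
    tspec <- do.call(toy_spec, c(config$toy, list(seed = config$seed)))
    built <- if (tspec$partner_length > 0) make_toy_binding_system(tspec)
             else make_toy_multidomain(tspec)
  }
  built$config <- config
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_contacts(built$contacts, file.path(outdir, "contacts.csv"))
    writeLines(built$pdb, file.path(outdir, "reference.pdb"))
    write_model_json(built$model, file.path(outdir, "model.json"))
    yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  }
  built
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else run_config(config)
}

#' Folding campaign
#'
#' Replica-exchange thermodynamics at the reference contact strengths,
#' WHAM, melting curves and coupling indices, reweighted 1D landscapes for
#' every requested `rho`, and constant-temperature kinetic runs giving
#' MFPT, folding order and backtracking counts.
#'
#' @param config a [run_config()].
#' @param built optional result of [cmd_build()] (rebuilt otherwise).
#' @return list of campaign outputs (see Details in the vignette).
#' @export
cmd_fold <- function(config = run_config(), built = NULL) {
  config <- as_run_config(config)
  if (is.null(built)) built <- cmd_build(config)
  model <- built$model; contacts <- built$contacts
  fc <- config$fold
  ff <- forcefield(rho = config$rho0)

  ladder <- fc$ladder
  if (is.null(ladder)) ladder <- seq(0.75, 1.35, length.out = 10)
  prot <- simulation_protocol(ladder = ladder, n_steps = fc$n_steps,
                              dt = fc$dt, record_interval = fc$record_interval,
                              exchange_interval = fc$exchange_interval,
                              seed = config$seed)
  remd <- run_remd(model, contacts, ff, prot)

  subsets <- folding_elements(contacts)
  q_lists <- lapply(subsets, function(ss)
    lapply(remd$replicas, cv_series, contacts = ss))
  q_total_list <- lapply(remd$replicas, cv_series,
                         contacts = contact_subset(contacts, "total"))

  samples <- remd_samples(remd, cv_list = q_total_list)
  fit <- wham_temperature(samples)
  curves <- melting_curves(q_lists, remd$ladder)
  usable <- !vapply(curves, `[[`, logical(1), "degenerate")
  mtci_val <- if (sum(usable) >= 2) mtci(curves[usable]) else NA_real_

  fes_by_rho <- lapply(config$rho, function(r) {
    rw <- reweight_rho(fit$samples, r, temperature = fit$tf,
                       rho0 = config$rho0)
    rw$fes(n_bins = 24)
  })
  names(fes_by_rho) <- as.character(config$rho)

  # kinetic runs below Tf, from heat-denatured starts
  tkin <- fc$kinetic_temperature_frac * fit$tf
  qtot_sub <- contact_subset(contacts, "total")
  kin <- lapply(seq_len(fc$kinetic_runs), function(r) {
    pk <- simulation_protocol(temperature = 1.6 * fit$tf,
                              n_steps = 20000, dt = fc$dt,
                              record_interval = 2000,
                              seed = config$seed + 1000 + r)
    hot <- run_langevin(model, contacts, ff, pk)
    pf <- simulation_protocol(temperature = tkin, n_steps = fc$n_steps * 4,
                              dt = fc$dt, record_interval = fc$record_interval,
                              seed = config$seed + 2000 + r)
    run_langevin(model, contacts, ff, pf, coords = hot$final_pos)
  })
  fpts <- vapply(kin, function(tr)
    first_passage(tr, contacts = qtot_sub, q_threshold = fc$q_threshold)$fpt,
    numeric(1))
  bt <- lapply(kin, function(tr) {
    qt <- cv_series(tr, qtot_sub)
    qi <- cv_series(tr, contact_subset(contacts, "inter"))
    detect_backtracking(qt, qi)
  })
  orders <- lapply(kin, function(tr) {
    qm <- vapply(subsets, function(ss) cv_series(tr, ss),
                 numeric(length(tr$times)))
    qm
  })
  op <- tryCatch(folding_order(orders, names(subsets),
                               q_threshold = fc$q_threshold),
                 error = function(e) NULL)

  list(remd = remd, wham = fit, tf = fit$tf, melting = curves,
       mtci = mtci_val, fes_by_rho = fes_by_rho,
       mfpt = mean(fpts, na.rm = TRUE), fpts = fpts,
       backtracking = bt, folding_order = op,
       kinetic_temperature = tkin, config = config)
}

# element subsets for melting / folding order: each domain, each interface
# pair present in the contact map, and the linker group
folding_elements <- function(contacts) {
  subs <- list()
  for (lab in sort(unique(contacts$label[contacts$class == "intra"])))
    subs[[lab]] <- contact_subset(contacts, lab)
  inter_labs <- sort(unique(contacts$label[contacts$class %in%
                                             c("inter", "linker")]))
  for (lab in inter_labs) subs[[lab]] <- contact_subset(contacts, lab)
  subs[vapply(subs, nrow, integer(1)) > 0]
}

#' Binding campaign
#'
#' Umbrella sampling along dRMS with WHAM, the binding PMF and Kd, the
#' four-state populations, the free-protein diffusion coefficient, the
#' encounter-stage statistics, and metadynamics transition-time estimates.
#'
#' @param config a [run_config()] whose toy block includes a partner.
#' @param built optional result of [cmd_build()].
#' @return list of campaign outputs.
#' @export
cmd_bind <- function(config = run_config(), built = NULL) {
  config <- as_run_config(config)
  if (is.null(config$toy$partner_length) || config$toy$partner_length < 1)
    config$toy$partner_length <- 6
  if (is.null(built)) built <- cmd_build(config)
  model <- built$model; contacts <- built$contacts
  bc <- config$bind
  ff <- forcefield(rho = config$rho0)
  bind_sub <- contact_subset(contacts, "binding")

  centers <- seq(0.05, bc$umbrella_max, length.out = bc$n_windows)
  wins <- data.frame(center = centers, k = bc$window_k)
  prot <- simulation_protocol(temperature = bc$temperature,
                              n_steps = bc$n_steps, dt = bc$dt,
                              record_interval = 200, seed = config$seed)
  um <- run_umbrella(model, contacts, ff, wins, prot)
  pmf <- wham_umbrella(um)
  box_vol <- (2 * bc$umbrella_max)^3
  affinity <- kd_from_pmf(pmf, box_volume_nm3 = box_vol)

  # free diffusion: the protein alone, partner removed
  apo <- strip_partner(model, contacts)
  free <- run_langevin(apo$model, apo$contacts, ff,
                       simulation_protocol(temperature = bc$temperature,
                                           n_steps = bc$n_steps, dt = bc$dt,
                                           record_interval = 100,
                                           seed = config$seed + 7))
  D <- diffusion_coefficient(free, lags = 5:50)$D
  flx <- rmsf(free)

  # encounter runs: start at the EC boundary, end at IS arrival or US escape
  outcomes <- encounter_campaign(model, contacts, ff, bc, config$seed)
  enc <- encounter_framework(outcomes$outcome, outcomes$duration)

  # IS -> BS transition times by infrequent metadynamics
  mruns <- lapply(seq_len(bc$metad_runs), function(r) {
    run_metadynamics(model, contacts, ff,
                     simulation_protocol(temperature = bc$temperature,
                                         n_steps = bc$n_steps * 4, dt = bc$dt,
                                         record_interval = 500,
                                         seed = config$seed + 4000 + r),
                     hill_height = 0.2, hill_width = 0.15, pace = 2000,
                     target = c(0, 0.3), wall = c(2.5, 20),
                     coords = outcomes$is_pose)
  })
  rate <- tryCatch(metad_transition_time(mruns), error = function(e) NULL)

  list(pmf = pmf, affinity = affinity, diffusion = D, mean_rmsf = flx$mean,
       encounter = enc, transition = rate,
       state_windows = binding_state_windows(), config = config)
}

#' Reduce a two-chain binding model to the free protein
#'
#' Drops the partner chain and every binding or bound-form-only contact,
#' leaving the apo protein model used for free-diffusion and fluctuation
#' analyses.  Partner beads are appended after the protein in all builders,
#' so bead indices are unchanged.
#'
#' @param model a two-chain `cg_model`
#' @param contacts its `contact_set`
#' @return list with protein-only `model` and `contacts`.
#' @export
strip_partner <- function(model, contacts) {
  prot <- which(model$beads$kind == "CA")
  nprot <- length(prot)
  if (any(prot != seq_len(nprot)))
    stop("partner beads must follow the protein beads")
  m <- model
  m$beads <- m$beads[prot, , drop = FALSE]
  keep_b <- m$bonds$i <= nprot & m$bonds$j <= nprot
  m$bonds <- m$bonds[keep_b, , drop = FALSE]
  cs <- contacts[contacts$i <= nprot & contacts$j <= nprot &
                 contacts$class != "binding" &
                 contacts$basin != "binary-only", , drop = FALSE]
  class(cs) <- c("contact_set", "data.frame")
  list(model = m, contacts = cs)
}

# run short trajectories from a perturbed encounter pose and classify the
# outcome by first arrival (IS) or escape (US-ward past the EC window)
encounter_campaign <- function(model, contacts, ff, bc, seed) {
  bind_sub <- contact_subset(contacts, "binding")
  win <- binding_state_windows()
  # generate an IS-like pose by pulling the protein away from the partner
  pose0 <- native_coords(model)
  prot <- model$beads$chain == "A"
  is_pose <- pose0
  is_pose[prot, 2] <- is_pose[prot, 2] + 1.2
  ec_pose <- pose0
  ec_pose[prot, 2] <- ec_pose[prot, 2] + 3.2
  out <- lapply(seq_len(bc$encounter_runs), function(r) {
    tr <- run_langevin(model, contacts, ff,
                       simulation_protocol(temperature = bc$temperature,
                                           n_steps = bc$n_steps, dt = bc$dt,
                                           record_interval = 100,
                                           seed = seed + 3000 + r),
                       coords = ec_pose)
    d <- cv_series(tr, bind_sub, type = "drms")
    hit_is <- which(d < win$IS[2])
    hit_us <- which(d > win$EC[2])
    first_is <- if (length(hit_is)) hit_is[1] else Inf
    first_us <- if (length(hit_us)) hit_us[1] else Inf
    if (first_is <= first_us && is.finite(first_is))
      list(outcome = "evolved", duration = tr$times[first_is])
    else if (is.finite(first_us))
      list(outcome = "dissociated", duration = tr$times[first_us])
    else list(outcome = "dissociated", duration = max(tr$times))
  })
  list(outcome = vapply(out, `[[`, character(1), "outcome"),
       duration = vapply(out, `[[`, numeric(1), "duration"),
       is_pose = is_pose, ec_pose = ec_pose)
}

#' Serialize a coarse model to JSON
#' @param model a `cg_model`
#' @param path output path
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(beads = model$beads, bonds = model$bonds, angles = model$angles,
         dihedrals = model$dihedrals,
         domain_map = lapply(model$domain_map, as.integer)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(beads = raw$beads, bonds = raw$bonds, angles = raw$angles,
                dihedrals = raw$dihedrals,
                domain_map = {
                  dm <- lapply(raw$domain_map, as.integer)
                  class(dm) <- "domain_map"
                  dm
                })
  class(model) <- "cg_model"
  model
}
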