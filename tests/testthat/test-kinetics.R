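test_that("first passage is the earliest threshold crossing", {
  fp <- first_passage(c(1, 2, 3), q = c(0.1, 0.5, 0.8))
  expect_equal(fp$fpt, 3)
  expect_false(fp$censored)
  expect_true(first_passage(c(1, 2, 3), q = c(0.1, 0.2, 0.3))$censored)

  # MFPT over many synthetic series equals an independent scan
  set.seed(17)
  series <- lapply(1:100, function(r) cummax(runif(50)) * 0.9 + 0.05)
  times <- seq_len(50) * 2
  fpts <- vapply(series, function(q) first_passage(times, q = q)$fpt,
                 numeric(1))
  oracle <- vapply(series, function(q) {
    for (k in seq_along(q)) if (q[k] >= 0.75) return(times[k])
    NA_real_
  }, numeric(1))
  expect_equal(fpts, oracle)
  expect_equal(mean(fpts, na.rm = TRUE), mean(oracle, na.rm = TRUE))
})

test_that("backtracking detection finds injected rise-fall-rise events only", {
  n <- 400
  qt <- seq(0.05, 0.95, length.out = n)     # monotone folding progress
  qi_mono <- seq(0.0, 0.9, length.out = n)
  expect_equal(nrow(detect_backtracking(qt, qi_mono, drop_threshold = 0.05)), 0)

  # one injected event of amplitude 2x the threshold around progress 0.5
  bump <- rep(0, n)
  win <- qt > 0.45 & qt < 0.55
  bump[win] <- -0.1 * sin(seq(0, pi, length.out = sum(win)))
  qi <- qi_mono + c(rep(0, n))
  qi[qt > 0.4 & qt <= 0.45] <- qi[qt > 0.4 & qt <= 0.45] + 0.08 # small rise
  qi2 <- qi_mono
  qi2[win] <- qi2[win] + 0.1 * sin(seq(pi / 2, 3 * pi / 2,
                                       length.out = sum(win)))
  ev <- detect_backtracking(qt, qi2, drop_threshold = 0.05)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$progress - 0.5), 0.06)
  expect_gt(ev$drop, 0.05)

  # a drop just below the threshold is not an event
  qi3 <- qi_mono
  qi3[win] <- qi3[win] + 0.02 * sin(seq(pi / 2, 3 * pi / 2,
                                        length.out = sum(win)))
  expect_equal(nrow(detect_backtracking(qt, qi3, drop_threshold = 0.05)), 0)

  # event count never increases with the drop threshold
  set.seed(23)
  for (rep_i in 1:5) {
    qiR <- pmin(1, pmax(0, qi_mono + cumsum(rnorm(n, sd = 0.02))))
    counts <- vapply(c(0.02, 0.05, 0.1, 0.2), function(th)
      nrow(detect_backtracking(qt, qiR, drop_threshold = th)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  expect_error(detect_backtracking(qt[1:2], qi_mono[1:2]), "short")
})

test_that("folding order statistics are column-stochastic with mean 1/n", {
  els <- paste0("E", 1:8)
  # fully deterministic order: one-hot columns, sigma = sqrt(7/64)
  det <- replicate(30, 1:8, simplify = FALSE)
  op <- folding_order(det, els)
  expect_equal(colSums(op$OP), rep(1, 8), ignore_attr = TRUE)
  expect_true(all(op$OP %in% c(0, 1)))
  expect_equal(op$sigma_op, rep(sqrt(7 / 64), 8), ignore_attr = TRUE,
               tolerance = 1e-12)

  # random permutations: columns still sum to 1, dispersion shrinks
  set.seed(4)
  rnd <- replicate(3000, sample(8), simplify = FALSE)
  op2 <- folding_order(rnd, els)
  expect_equal(colSums(op2$OP), rep(1, 8), ignore_attr = TRUE)
  expect_true(all(abs(op2$OP - 1 / 8) < 0.04))
  expect_true(all(op2$sigma_op < 0.02))

  # series input: commitment rule tolerates transient flickers
  times <- 1:100
  mk <- function(t_fold, flicker = FALSE) {
    q <- ifelse(times >= t_fold, 0.9, 0.2)
    if (flicker) q[t_fold + 25] <- 0.4   # late dip below the commitment floor
    q
  }
  ev <- cbind(mk(10), mk(30), mk(50))
  perm <- sbmfold:::element_fold_order(ev)
  expect_equal(perm, c(1, 2, 3))
  ev2 <- cbind(mk(10, flicker = TRUE), mk(30), mk(50))
  perm2 <- sbmfold:::element_fold_order(ev2)
  expect_equal(perm2[1], 2)  # flickering element commits only later
})

test_that("encounter statistics give kDis/kEvo + 1 and match the geometric oracle", {
  out <- c(rep("dissociated", 150), rep("evolved", 50))
  es <- encounter_framework(out)
  expect_equal(es$encounter_time, 4)
  expect_equal(es$n_evo + es$n_dis, 200)

  expect_equal(encounter_framework(rep("evolved", 10))$encounter_time, 1)
  expect_true(encounter_framework(rep("dissociated", 5))$undefined)

  # Bernoulli encounter attempts with success probability p: the mean
  # attempt count is geometric, 1/p
  set.seed(12)
  p <- 0.2
  outcomes <- ifelse(runif(4000) < p, "evolved", "dissociated")
  es2 <- encounter_framework(outcomes)
  attempts <- rgeom(4000, p) + 1
  expect_lt(abs(es2$encounter_time - mean(attempts)) / (1 / p), 0.1)
  expect_lt(abs(es2$encounter_time - 1 / p) / (1 / p), 0.1)
})

test_that("metadynamics transition times rescale correctly and bootstrap", {
  dw <- make_double_well(5)
  # zero bias: the rescaled arrival clock runs at wall speed
  runs0 <- lapply(1:3, function(r)
    run_metadynamics(dw, protocol = simulation_protocol(temperature = 1,
                                                        n_steps = 200000,
                                                        dt = 0.005,
                                                        record_interval = 500,
                                                        seed = 40 + r),
                     hill_height = 0, hill_width = 0.1, pace = 1000,
                     target = c(0.8, Inf), coords = -1))
  for (r in runs0) {
    expect_false(r$censored)
    expect_equal(r$arrival_rescaled, r$arrival_time, tolerance = 1e-9)
  }
  est <- metad_transition_time(runs0, n_boot = 50)
  expect_equal(est$n_boot, 50)
  expect_gt(est$mean, 0)
  expect_gt(est$se, 0)

  cens <- runs0[[1]]; cens$censored <- TRUE
  expect_error(metad_transition_time(list(cens)), "censored")

  # raising the barrier slows the unbiased first passage
  m_lo <- double_well_mfpt(make_double_well(3), n_runs = 25, seed = 5)
  m_hi <- double_well_mfpt(make_double_well(6), n_runs = 25, seed = 5)
  expect_gt(m_hi$mfpt, m_lo$mfpt)
})
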