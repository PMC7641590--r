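# two-level system with energies 0 and eps: closed-form Schottky heat
# capacity and occupancies are the WHAM / reweighting oracles
schottky_cv <- function(T, eps = 1) {
  b <- eps / T
  b^2 * exp(-b) / (1 + exp(-b))^2
}

two_level_samples <- function(temps, n, eps = 1, inter_frac = 0.4, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(temps, function(tt) {
    p1 <- exp(-eps / tt) / (1 + exp(-eps / tt))
    st <- rbinom(n, 1, p1)
    data.frame(replica = match(tt, temps), temperature = tt, E = st * eps,
               inter_linker = st * eps * inter_frac, cv = st)
  }))
}

test_that("temperature WHAM recovers the Schottky heat capacity", {
  temps <- seq(0.3, 2, length.out = 8)
  s <- two_level_samples(temps, 4000, seed = 10)
  fit <- wham_temperature(s, breaks = c(-0.5, 0.5, 1.5))
  sel <- seq(1, nrow(fit$cv_curve), by = 10)
  ref <- schottky_cv(fit$cv_curve$temperature[sel])
  expect_lt(max(abs(fit$cv_curve$Cv[sel] - ref)), 0.02)
  # Cv peak of the two-level system sits near 0.42 eps
  expect_equal(fit$tf, 0.417, tolerance = 0.1)
})

test_that("single-temperature WHAM reduces to plain histogramming", {
  s <- two_level_samples(1.0, 2000, seed = 3)
  fit <- wham_temperature(s, breaks = c(-0.5, 0.5, 1.5))
  w <- sample_weights(fit, 1.0)
  expect_equal(w, rep(1 / nrow(s), nrow(s)), tolerance = 1e-10)
  f <- fes_1d(s$cv, w, breaks = c(-0.5, 0.5, 1.5))
  direct <- -log(table(s$cv) / nrow(s))
  expect_equal(f$F - min(f$F), as.vector(direct - min(direct)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mean energy of a thermostatted harmonic chain is linear in T", {
  hc <- make_harmonic_chain(6, 100)
  temps <- c(0.5, 1.0, 1.5)
  means <- vapply(temps, function(tt) {
    tr <- run_langevin(hc$model, hc$contacts, forcefield(),
                       simulation_protocol(temperature = tt, n_steps = 250000,
                                           dt = 0.002, record_interval = 100,
                                           seed = round(100 * tt)))
    mean(tr$energies$bonded[-(1:500)])
  }, numeric(1))
  # equipartition: 5 bonds x T/2
  expect_equal(means, 2.5 * temps, tolerance = 0.08)
})

test_that("umbrella WHAM reconstructs the double-well potential", {
  dw <- make_double_well(2.5)
  wins <- data.frame(center = seq(-1.4, 1.4, by = 0.2), k = 40)
  um <- run_umbrella(dw, windows = wins,
                     protocol = simulation_protocol(temperature = 1,
                                                    n_steps = 60000,
                                                    dt = 0.005,
                                                    record_interval = 25,
                                                    seed = 5))
  pmf <- wham_umbrella(um, n_bins = 50)
  sel <- pmf$cv_mid > -1.3 & pmf$cv_mid < 1.3 & is.finite(pmf$F)
  vref <- dw$pmf(pmf$cv_mid[sel])
  err <- pmf$F[sel] - (vref - min(vref))
  err <- err - mean(err)
  expect_lt(max(abs(err)), 0.2)
  expect_true(all(attr(pmf, "residuals") < 0.05))
})

test_that("a single unbiased window gives PMF = -ln histogram", {
  dw <- make_double_well(1)
  um <- run_umbrella(dw, windows = data.frame(center = 0, k = 0),
                     protocol = simulation_protocol(temperature = 1,
                                                    n_steps = 40000,
                                                    dt = 0.005,
                                                    record_interval = 20,
                                                    seed = 6))
  pmf <- wham_umbrella(um, n_bins = 20, discard_frac = 0)
  h <- hist(um[[1]]$cv, breaks = seq(min(um[[1]]$cv) - 1e-12,
                                     max(um[[1]]$cv) + 1e-12,
                                     length.out = 21), plot = FALSE)
  ref <- -log(h$counts / sum(h$counts))
  ref <- ref - min(ref)
  expect_equal(pmf$F[is.finite(pmf$F)], ref[is.finite(ref)],
               tolerance = 1e-6)
})

test_that("rho reweighting is exact on a two-level system and at rho0", {
  temps <- c(0.8, 1.0, 1.25)
  s <- two_level_samples(temps, 6000, inter_frac = 0.5, seed = 8)
  # identity: target rho = rho0 leaves the distribution untouched
  rw0 <- reweight_rho(s[s$temperature == 1, ], 1.0, temperature = 1.0)
  expect_equal(rw0$weights, rep(1 / sum(s$temperature == 1),
                                sum(s$temperature == 1)), tolerance = 1e-12)
  expect_equal(rw0$ess, sum(s$temperature == 1), tolerance = 1e-6)

  # closed form: at rho the excited-state energy is E(rho) = 1 + (rho-1)*0.5
  rho <- 0.6
  rw <- reweight_rho(s[s$temperature == 1, ], rho, temperature = 1.0)
  p1_hat <- sum(rw$weights[s$cv[s$temperature == 1] == 1])
  e_rho <- 1 + (rho - 1) * 0.5
  p1_ref <- exp(-e_rho) / (1 + exp(-e_rho))
  expect_lt(abs(p1_hat - p1_ref), 0.02)

  expect_error(reweight_rho(data.frame(E = 1), 0.8, 1), "decomposed")
  expect_warning(
    reweight_rho(data.frame(E = numeric(30),
                            inter_linker = c(numeric(29), -60)),
                 2, temperature = 0.5),
    "effective sample size")
})

test_that("sigmoid melting fits recover known midpoints and widths", {
  tms <- c(0.95, 1.05, 1.2)
  ws <- c(0.03, 0.05, 0.04)
  curves <- make_synthetic_melting_set(tms, ws, noise = 0.01, seed = 4)
  for (i in seq_along(tms)) {
    ft <- sbmfold:::fit_sigmoid(curves[[i]]$data$temperature,
                                curves[[i]]$data$P)
    expect_lt(abs(ft$tm - tms[i]) / tms[i], 0.02)
    expect_lt(abs(ft$width - ws[i]) / ws[i], 0.1)
  }
  # folded probability vanishes far above the melting temperature
  expect_lt(sbmfold:::sigmoid_p(2.0, 1.05, 0.05), 1e-8)

  # flat curves are flagged degenerate by the melting-curve driver
  qs <- list(rep(list(rep(1, 100)), 4)[[1]], rep(0.95, 100), rep(0.9, 100),
             rep(0.92, 100))
  mc <- melting_curves(list(flat = qs), ladder = c(0.8, 0.9, 1.0, 1.1),
                       threshold = 0.75)
  expect_true(mc$flat$degenerate)
})

test_that("coupling indices follow their defining identities", {
  grid <- seq(0.8, 1.2, by = 0.01)
  mk <- function(P) data.frame(temperature = grid, P = P)
  ci <- mk(rep(0.5, length(grid)))
  cj <- mk(rep(0.5 - exp(-2), length(grid)))
  expect_equal(tci(ci, cj), 2, tolerance = 1e-12)
  # identical curves hit the documented cap
  expect_equal(tci(ci, ci), -log(1 / (10 * length(grid))))
  expect_error(tci(ci, mk(rep(0.5, length(grid)))[1:10, ]), "grids")

  # wider Tm spread lowers the mean coupling index
  m1 <- mtci(make_synthetic_melting_set(c(1.0, 1.01, 1.02), rep(0.04, 3)))
  m2 <- mtci(make_synthetic_melting_set(c(0.9, 1.0, 1.1), rep(0.04, 3)))
  expect_gt(m1, m2)

  # MTCI lies between the transformed extremes of the pairwise differences
  set.seed(2)
  curves <- make_synthetic_melting_set(c(0.95, 1.0, 1.1), c(0.03, 0.06, 0.04))
  pair_m <- c()
  for (i in 1:2) for (j in (i + 1):3)
    pair_m <- c(pair_m, mean(abs(curves[[i]]$data$P - curves[[j]]$data$P)))
  expect_gte(mtci(curves), -log(max(pair_m)))
  expect_lte(mtci(curves), -log(min(pair_m)))
})

test_that("state stabilities integrate windows and vanish at rho0", {
  # hand-built two-basin surface on (Q total, Q inter)
  mk_surface <- function(depthA, depthB) {
    grid <- expand.grid(cv1_mid = seq(0.05, 0.95, by = 0.1),
                        cv2_mid = seq(0.05, 0.95, by = 0.1))
    FF <- rep(6, nrow(grid))
    inA <- grid$cv1_mid < 0.3 & grid$cv2_mid < 0.3
    inB <- grid$cv1_mid > 0.7 & grid$cv2_mid > 0.7
    FF[inA] <- depthA
    FF[inB] <- depthB
    p <- exp(-FF); p <- p / sum(p)
    out <- data.frame(grid, p = p, F = -log(p) - min(-log(p)))
    class(out) <- c("free_energy_surface", "data.frame")
    out
  }
  states <- list(U = list(q_total = c(0, 0.3), q_inter = c(0, 0.3)),
                 N = list(q_total = c(0.7, 1), q_inter = c(0.7, 1)))
  surfaces <- list("1" = mk_surface(1, 1), "0.8" = mk_surface(1, 2))
  tab <- state_stabilities(surfaces, states, rho0 = "1")
  expect_equal(tab$ddF[tab$rho == "1"], 0)
  # quadrature oracle: dF = -ln(Z_N / Z_U) over the windows
  s <- surfaces[["0.8"]]
  zU <- sum(s$p[s$cv1_mid < 0.3 & s$cv2_mid < 0.3])
  zN <- sum(s$p[s$cv1_mid > 0.7 & s$cv2_mid > 0.7])
  expect_equal(tab$dF[tab$rho == "0.8"], -log(zN / zU))
  # deepening a basin by delta lowers its dF by delta
  s3 <- list("1" = mk_surface(1, 1), "x" = mk_surface(1, 1 - 0.7))
  t3 <- state_stabilities(s3, states, rho0 = "1")
  expect_equal(t3$dF[t3$rho == "x"] - t3$dF[t3$rho == "1"], -0.7,
               tolerance = 1e-9)
})

test_that("dissociation constants follow the standard-state identities", {
  # symmetric two-basin PMF with equal bound / unbound integrals
  mk_pmf <- function(extra_bound = 0) {
    cv <- seq(0.05, 11.95, by = 0.1)
    FF <- rep(30, length(cv))
    FF[cv < 0.4] <- 0 - extra_bound   # 4 bound bins match 4 unbound bins
    FF[cv > 10 & cv < 10 + 0.4] <- 0   # 4 unbound bins match 4 bound bins
    p <- exp(-FF); p <- p / sum(p)
    out <- data.frame(cv_mid = cv, p = p, F = -log(p) - min(-log(p)))
    class(out) <- c("free_energy_surface", "data.frame")
    out
  }
  avogadro <- 6.02214076e23
  v_1M <- 1 / (avogadro * 1e-24)    # nm^3 per molecule at 1 M
  kd <- kd_from_pmf(mk_pmf(), box_volume_nm3 = v_1M)
  expect_equal(kd$kd_M, 1, tolerance = 1e-9)
  expect_equal(sum(kd$populations), 1)

  # deepening the bound basin by 1 kT divides Kd by e
  kd2 <- kd_from_pmf(mk_pmf(extra_bound = 1), box_volume_nm3 = v_1M)
  expect_equal(kd$kd_M / kd2$kd_M, exp(1), tolerance = 1e-9)

  short <- mk_pmf()[mk_pmf()$cv_mid < 5, ]
  class(short) <- c("free_energy_surface", "data.frame")
  expect_error(kd_from_pmf(short, box_volume_nm3 = v_1M), "plateau")

  expect_equal(classify_binding_state(c(0.1, 1.5, 5, 12)),
               c("BS", "IS", "EC", "US"))
})
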