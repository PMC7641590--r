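test_that("trajectories are reproducible from the protocol seed", {
  toy <- toy_fixture()
  ff <- forcefield()
  pr <- simulation_protocol(temperature = 0.8, n_steps = 5000, dt = 0.002,
                            record_interval = 500, seed = 99)
  t1 <- run_langevin(toy$model, toy$contacts, ff, pr)
  t2 <- run_langevin(toy$model, toy$contacts, ff, pr)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  t3 <- run_langevin(toy$model, toy$contacts, ff,
                     simulation_protocol(temperature = 0.8, n_steps = 5000,
                                         dt = 0.002, record_interval = 500,
                                         seed = 100))
  expect_false(identical(t1$frames, t3$frames))
})

test_that("a cold quench from a perturbed start relaxes into the native funnel", {
  toy <- toy_fixture()
  ff <- forcefield()
  set.seed(5)
  co <- native_coords(toy$model) +
    matrix(rnorm(3 * nrow(toy$model$beads), sd = 0.05), ncol = 3)
  pr <- simulation_protocol(temperature = 1e-6, n_steps = 20000, dt = 0.002,
                            record_interval = 2000, seed = 3)
  tr <- run_langevin(toy$model, toy$contacts, ff, pr, coords = co)
  q <- q_fraction(tr$final_pos, contact_subset(toy$contacts, "total"))
  expect_gt(q, 0.99)
})

test_that("harmonic chain thermostat satisfies equipartition per bonded mode", {
  hc <- make_harmonic_chain(8, 100)
  pr <- simulation_protocol(temperature = 1, n_steps = 150000, dt = 0.002,
                            record_interval = 100, seed = 12)
  tr <- run_langevin(hc$model, hc$contacts, forcefield(), pr)
  pe <- tr$energies$bonded[-(1:300)] / nrow(hc$model$bonds)
  nb <- 30
  batches <- tapply(pe, rep(seq_len(nb), each = ceiling(length(pe) / nb))[
    seq_along(pe)], mean)
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(mean(pe) - hc$closed_forms$mode_pe(1)), 3 * se)
  # bond-length variance closed form kT/(2K)
  b <- vapply(seq_len(dim(tr$frames)[1]), function(f)
    sqrt(sum((tr$frames[f, 2, ] - tr$frames[f, 1, ])^2)), numeric(1))
  expect_equal(var(b[-(1:300)]), hc$closed_forms$bond_variance(1),
               tolerance = 0.1)
})

test_that("replica exchange accepts every swap between equal temperatures", {
  dw <- make_double_well(2)
  pr <- simulation_protocol(ladder = c(0.9, 0.9), n_steps = 20000, dt = 0.005,
                            record_interval = 500, exchange_interval = 500,
                            seed = 2)
  remd <- run_remd(dw, protocol = pr)
  expect_equal(remd$exchange$rate, 1)
})

test_that("replica-exchange sampling reproduces Boltzmann state occupancies", {
  dw <- make_double_well(2, tilt = 1)
  pr <- simulation_protocol(ladder = c(0.6, 0.8, 1.0, 1.3), n_steps = 300000,
                            dt = 0.005, record_interval = 50,
                            exchange_interval = 500, seed = 3)
  remd <- run_remd(dw, protocol = pr)
  expect_true(all(remd$exchange$rate > 0.3))
  for (r in seq_along(pr$ladder)) {
    x <- remd$replicas[[r]]$x
    x <- x[-seq_len(length(x) %/% 3)]
    Tt <- pr$ladder[r]
    f <- function(z) exp(-dw$pmf(z) / Tt)
    p_ref <- integrate(f, 0, 4)$value / integrate(f, -4, 4)$value
    expect_lt(abs(mean(x > 0) - p_ref), 0.05)
  }
})

test_that("umbrella windows track their centers and record the bias energy", {
  dw <- make_double_well(3)
  wins <- data.frame(center = c(-0.5, 0.0), k = c(200, 50))
  pr <- simulation_protocol(temperature = 1, n_steps = 40000, dt = 0.005,
                            record_interval = 50, seed = 8)
  um <- run_umbrella(dw, windows = wins, protocol = pr)
  # stiff spring dominates the underlying potential
  expect_lt(abs(mean(um[[1]]$cv[-(1:100)]) - (-0.5)), 0.05)
  # stored bias energy equals the harmonic formula recomputed from the CVs
  for (w in 1:2)
    expect_equal(um[[w]]$bias_energy,
                 0.5 * wins$k[w] * (um[[w]]$cv - wins$center[w])^2,
                 tolerance = 1e-10)
})

test_that("metadynamics with zero hill height reduces to plain dynamics", {
  dw <- make_double_well(4)
  pr <- simulation_protocol(temperature = 1, n_steps = 20000, dt = 0.005,
                            record_interval = 100, seed = 21)
  plain <- run_langevin(dw, protocol = pr)
  meta <- run_metadynamics(dw, protocol = pr, hill_height = 0,
                           hill_width = 0.1, pace = 500, target = NULL)
  expect_equal(meta$x, plain$x, tolerance = 1e-12)
  # with exp(0) acceleration the rescaled clock runs at wall speed
  expect_equal(meta$rescaled_time, pr$n_steps * pr$dt, tolerance = 1e-9)
})

test_that("deposited metadynamics bias is positive and grows monotonically", {
  dw <- make_double_well(3)
  pr <- simulation_protocol(temperature = 1, n_steps = 60000, dt = 0.005,
                            record_interval = 100, seed = 22)
  meta <- run_metadynamics(dw, protocol = pr, hill_height = 0.4,
                           hill_width = 0.15, pace = 300, target = NULL,
                           freq_adaptive = FALSE)
  h <- meta$hills
  expect_gt(nrow(h), 10)
  expect_true(all(h$height > 0))
  expect_true(all(diff(h$time) > 0))
  # V_bias at a fixed point is non-decreasing as hills accumulate
  vb <- vapply(seq_len(nrow(h)), function(k)
    sum(h$height[1:k] * exp(-0.5 * ((-1 - h$center[1:k]) / 0.15)^2)),
    numeric(1))
  expect_true(all(diff(vb) >= 0))
})
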