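test_that("12-10 contact well has depth -eps at sigma and vanishes far away", {
  expect_equal(contact_pair_energy(0.5, 0.5, 1), -1)
  expect_equal(contact_pair_energy(500, 0.5, 1), 0, tolerance = 1e-12)
  # independent arithmetic at r = 1.2 sigma
  q <- (1 / 1.2)^2
  expect_equal(contact_pair_energy(0.6, 0.5, 1), 5 * q^6 - 6 * q^5)
  expect_equal(contact_pair_energy(0.5, 0.5, 2.5), -2.5)
})

test_that("energy decomposition sums to the total and scales with rho", {
  toy <- toy_fixture()
  ff <- forcefield(rho = 1)
  set.seed(42)
  co <- native_coords(toy$model) +
    matrix(rnorm(3 * nrow(toy$model$beads), sd = 0.04), ncol = 3)
  e <- total_energy(toy$model, toy$contacts, ff, co)
  comp <- unclass(e)
  expect_equal(sum(comp[names(comp) != "total"]), comp[["total"]],
               tolerance = 1e-9)

  e_half <- total_energy(toy$model, toy$contacts, forcefield(rho = 0.5), co)
  expect_equal(e_half[["inter"]], e[["inter"]] / 2, tolerance = 1e-12)
  expect_equal(e_half[["linker"]], e[["linker"]] / 2, tolerance = 1e-12)
  expect_equal(e_half[["intra"]], e[["intra"]], tolerance = 1e-12)

  # rho-linearity underlying the reweighting identity
  e_r <- total_energy(toy$model, toy$contacts, forcefield(rho = 1.3), co)
  expect_equal(e_r[["total"]] - e[["total"]],
               0.3 * (e[["inter"]] + e[["linker"]]), tolerance = 1e-9)

  expect_error(total_energy(toy$model, toy$contacts, ff,
                            co * NA), "non-finite")
})

test_that("total energy matches an independent pairwise summation", {
  bs <- binding_fixture()
  ff <- forcefield(rho = 0.8)
  set.seed(7)
  co <- native_coords(bs$model) +
    matrix(rnorm(3 * nrow(bs$model$beads), sd = 0.03), ncol = 3)
  e <- total_energy(bs$model, bs$contacts, ff, co)

  # brute-force re-evaluation in R from the model tables
  m <- bs$model; cs <- as.data.frame(bs$contacts)
  dvec <- function(i, j) co[j, ] - co[i, ]
  dlen <- function(i, j) sqrt(sum(dvec(i, j)^2))
  eb <- sum(ff$kb * (mapply(dlen, m$bonds$i, m$bonds$j) - m$bonds$r0)^2)
  ang <- function(i, j, k) {
    a <- co[i, ] - co[j, ]; b <- co[k, ] - co[j, ]
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }
  eb <- eb + sum(ff$ka * (mapply(ang, m$angles$i, m$angles$j, m$angles$k) -
                          m$angles$theta0)^2)
  dih <- function(i, j, k, l) {
    b1 <- co[j, ] - co[i, ]; b2 <- co[k, ] - co[j, ]; b3 <- co[l, ] - co[k, ]
    cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                           a[1]*b[2]-a[2]*b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  }
  dphi <- mapply(dih, m$dihedrals$i, m$dihedrals$j, m$dihedrals$k,
                 m$dihedrals$l) - m$dihedrals$phi0
  eb <- eb + sum(ff$kd * ((1 - cos(dphi)) + 0.5 * (1 - cos(3 * dphi))))

  eps_of <- function(r) {
    if (r$basin == "binary-only" && r$class != "binding") return(1)
    switch(r$class, intra = 1, inter = ff$rho, linker = ff$rho, binding = 1)
  }
  ec <- sum(vapply(seq_len(nrow(cs)), function(r)
    contact_pair_energy(dlen(cs$i[r], cs$j[r]), cs$sigma[r],
                        eps_of(cs[r, ])), numeric(1)))

  # electrostatics over all charged pairs not bonded within 3 steps
  q <- m$beads$charge
  near <- rbind(as.matrix(m$bonds[, c("i", "j")]),
                as.matrix(m$angles[, c("i", "k")]),
                as.matrix(m$dihedrals[, c("i", "l")]))
  nearkey <- paste(pmin(near[, 1], near[, 2]), pmax(near[, 1], near[, 2]))
  ee <- 0
  n <- nrow(co)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (q[i] * q[j] == 0) next
    if (paste(i, j) %in% nearkey) next
    if (m$beads$frozen[i] && m$beads$frozen[j]) next
    ee <- ee + dh_energy(dlen(i, j), q[i], q[j], ff)
  }

  got <- e[["bonded"]] + e[["intra"]] + e[["inter"]] + e[["linker"]] +
    e[["binary_basin"]] + e[["binding"]] + e[["electrostatic"]]
  expect_equal(got, eb + ec + ee, tolerance = 1e-8)
})

test_that("forces agree with central finite differences and respect freezing", {
  bs <- binding_fixture()
  ff <- forcefield(rho = 0.9)
  set.seed(11)
  co <- native_coords(bs$model) +
    matrix(rnorm(3 * nrow(bs$model$beads), sd = 0.03), ncol = 3)
  f <- forces(bs$model, bs$contacts, ff, co)
  h <- 1e-6
  num <- f * 0
  for (i in seq_len(nrow(co))) for (d in 1:3) {
    cp <- co; cm <- co
    cp[i, d] <- cp[i, d] + h
    cm[i, d] <- cm[i, d] - h
    num[i, d] <- -(total_energy(bs$model, bs$contacts, ff, cp)[["total"]] -
                   total_energy(bs$model, bs$contacts, ff, cm)[["total"]]) /
      (2 * h)
  }
  frozen <- bs$model$beads$frozen
  expect_true(all(f[frozen, ] == 0))
  expect_lt(max(abs(f - num)[!frozen, ]) / max(abs(f)), 1e-6)

  # near-zero net force at the native minimum (up to excluded-volume tails)
  f0 <- forces(bs$model, bs$contacts, ff)
  expect_lt(max(abs(f0[!frozen, ])) / max(abs(f)), 0.2)
})

test_that("Debye-Hueckel calibration pins unit charges at 0.5 nm to one contact", {
  for (lam in c(0.5, 0.8, 1.5)) {
    A <- calibrate_dh(lam)
    ff <- forcefield(debye_length = lam)
    expect_equal(dh_energy(0.5, 1, -1, ff), -1)
    expect_equal(dh_energy(0.5, 1, 1, ff), 1)
    expect_equal(dh_energy(1.0, 1, -1, ff), -A * exp(-1 / lam) / 1.0)
  }
  expect_error(calibrate_dh(-1), "positive")
})

test_that("temperature rescaling multiplies the apo Hamiltonian linearly", {
  ff <- forcefield()
  expect_equal(rescale_for_temperature(ff, 1, 1)$temperature_rescale, 1)
  ff2 <- rescale_for_temperature(ff, 1.13, 1.00)
  expect_equal(ff2$temperature_rescale, 1.13)
  expect_error(rescale_for_temperature(ff, -1, 1), "positive")

  toy <- toy_fixture()
  set.seed(3)
  co <- native_coords(toy$model) +
    matrix(rnorm(3 * nrow(toy$model$beads), sd = 0.02), ncol = 3)
  e1 <- total_energy(toy$model, toy$contacts, ff, co)
  e2 <- total_energy(toy$model, toy$contacts, ff2, co)
  expect_equal(e2[["total"]], 1.13 * e1[["total"]], tolerance = 1e-9)
})
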