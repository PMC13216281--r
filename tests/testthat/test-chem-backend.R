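# Mean-field and CAS backend contracts: SCF invariants, CAS consistency
# rules, RDM covariance, thermal ensembles.

test_that("RHF satisfies idempotency and electron-count conservation", {
  mf <- fixture_h2()
  S <- mf$ints$S
  g <- mf$gamma
  expect_lt(max(abs(g %*% S %*% g - 2 * g)), 1e-8)
  expect_equal(sum(diag(g %*% S)), mf$mol$nelec, tolerance = 1e-8)
  expect_equal(sum(mf$mo_occ > 0), 1) # H2: exactly one doubly occupied MO
  expect_error(run_mean_field(molecule("H", matrix(c(0, 0, 0), 1)), "cc-pvdz"),
               "even electron count")
})

test_that("CAS over the full MO space recovers FCI consistency rules", {
  mf <- fixture_h2()
  nmo <- ncol(mf$mo_coeff)
  cas <- solve_cas(mf, active = mf$mo_coeff[, 1:4], nelec_active = 2)
  expect_lt(cas$e_tot, mf$energy) # variational improvement
  # 2RDM normalization: the up/down block traces to na * nb
  G <- cas_gamma_ud(cas)
  tr <- sum(vapply(1:4, function(i) {
    sum(vapply(1:4, function(j) G[i, j, i, j], numeric(1)))
  }, numeric(1)))
  expect_equal(tr, cas$na * cas$nb, tolerance = 1e-8)
  # 1RDM from contraction of the 2RDM block: sum_j G[i,j,k,j] = nb * D_ik
  gam <- cas_gamma1(cas)
  for (i in 1:4) for (k in 1:4) {
    contr <- sum(vapply(1:4, function(j) G[i, j, k, j], numeric(1)))
    expect_equal(contr, cas$nb * gam[i, k] / 2, tolerance = 1e-8)
  }
})

test_that("orbital indices and electron counts are validated", {
  mf <- fixture_h2()
  expect_error(solve_cas(mf, active = mf$mo_coeff[, 1:2], nelec_active = 3),
               "inconsistent")
  expect_error(solve_cas(mf, active = mf$mo_coeff[, 1:2], nelec_active = 6),
               "inconsistent")
  bad <- mf$mo_coeff[, 1:2]
  bad[, 2] <- bad[, 1]
  expect_error(solve_cas(mf, active = bad, nelec_active = 2),
               "orthonormal")
})

test_that("RDMs transform covariantly under active-basis rotations", {
  mf <- fixture_h2()
  th <- 0.37
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  c1 <- solve_cas(mf, active = mf$mo_coeff[, 1:2], nelec_active = 2)
  c2 <- solve_cas(mf, active = mf$mo_coeff[, 1:2] %*% R, nelec_active = 2)
  expect_equal(c1$e_tot, c2$e_tot, tolerance = 1e-9)
  g1 <- cas_gamma1(c1)
  g2 <- cas_gamma1(c2)
  expect_lt(max(abs(t(R) %*% g1 %*% R - g2)), 1e-8)
})

test_that("thermal ensembles have Boltzmann weights and averaged RDMs", {
  mf <- fixture_h2()
  cas <- solve_cas(mf, active = mf$mo_coeff[, 1:3], nelec_active = 2,
                   nroots = 4)
  states <- lapply(1:4, function(r) {
    s <- cas
    s$civecs <- cas$civecs[r]
    s$civec <- cas$civecs[[r]]
    s
  })
  # degenerate limit: equal energies -> equal weights
  th0 <- thermal_ensemble(states, rep(-1, 4), beta = 1e3)
  expect_equal(th0$weights, rep(0.25, 4))
  # large beta with a unique ground state -> weight 1
  th1 <- thermal_ensemble(states, cas$energies, beta = 1e6)
  expect_equal(th1$weights[1], 1, tolerance = 1e-10)
  # default beta is 1e3 1/hartree
  expect_equal(formals(thermal_ensemble)$beta, 1e3)
  expect_error(thermal_ensemble(states, cas$energies, beta = -1), "range")
  # thermal RDM is the weighted average of member RDMs
  th <- thermal_ensemble(states, cas$energies, beta = 50)
  rho_th <- two_orbital_rdm(th, 1, 2)
  rho_avg <- Reduce(`+`, Map(function(s, w) w * two_orbital_rdm(s, 1, 2),
                             states, th$weights))
  expect_lt(max(abs(rho_th - rho_avg)), 1e-12)
  expect_equal(sum(diag(rho_th)), 1, tolerance = 1e-10)
})

test_that("unknown basis and element names are rejected", {
  expect_error(load_basis("no-such-basis"), "unknown basis")
  expect_error(molecule("Xx", matrix(0, 1, 3)), "unknown element")
})
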