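# Analytic model states: the idealized covalent bond, GHZ/W registers and
# the synthetic ionicity family.

test_that("symmetric orthogonalization satisfies its closed form and metric", {
  expect_equal(unname(symmetric_orthogonalization(0)), c(1, 0))
  # frozen value evaluated from the closed form at S = 0.5
  ab <- symmetric_orthogonalization(0.5)
  expect_equal(unname(ab), c(1.11536, -0.29886), tolerance = 1e-5)
  for (S in seq(0.05, 0.95, by = 0.1)) {
    ab <- symmetric_orthogonalization(S)
    M <- rbind(c(1, S), c(S, 1))
    Tm <- rbind(c(ab[1], ab[2]), c(ab[2], ab[1]))
    G <- Tm %*% M %*% t(Tm)
    expect_lt(max(abs(G - diag(2))), 1e-12)
  }
  expect_error(symmetric_orthogonalization(1), "invalid overlap")
  expect_error(symmetric_orthogonalization(-0.1), "invalid overlap")
})

test_that("bond state has the stated amplitudes, entropy and objective", {
  v <- bond_state()
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  lab <- attr(v, "labels")
  expect_equal(v[match("|d,u>", lab)], -0.5)
  expect_equal(sort(v[v != 0]), c(-0.5, 0.5, 0.5, 0.5))
  rho_L <- one_orbital_rdm_pure(unclass(v), 1, 2)
  expect_equal(diag(rho_L), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(von_neumann_entropy(rho_L), log(4), tolerance = 1e-12)
  expect_equal(f_meao(mf_gamma(matrix(1, 2, 2)), c(1, 2)), 0.125,
               tolerance = 1e-12)
})

test_that("doubly occupying the bonding orbital reproduces the bond state", {
  # end-to-end identity: any overlap S yields the same maximally entangled
  # state in the symmetrically orthogonalized pair
  for (S in c(0, 0.25, 0.5, 0.8)) {
    expect_lt(max(abs(bond_state_from_overlap(S) - bond_state())), 1e-12)
  }
})

test_that("GHZ and W states have their known GME values", {
  g <- gme(unclass(ghz_state(3)), rep(2, 3))
  expect_equal(g$value, log(2), tolerance = 1e-12)
  w <- gme(unclass(w_state(3)), rep(2, 3))
  expect_equal(w$value, log(3) - 2 / 3 * log(2), tolerance = 1e-12)
  expect_error(ghz_state(2), "invalid size")
  expect_error(w_state(2), "invalid size")
  # GHZ(4) generalization still has GME log 2
  expect_equal(gme(unclass(ghz_state(4)), rep(2, 4))$value, log(2),
               tolerance = 1e-12)
})

test_that("GHZ two-qubit reductions are separable, W reductions are not", {
  psi <- unclass(ghz_state(3))
  rho12 <- partial_trace_pure(psi, c(1, 2), rep(2, 3))
  expect_gt(ppt_minimum_eigenvalue(rho12, 2, 2), -1e-12)
  expect_lt(relative_entropy_of_entanglement(rho12, 2, 2,
                                             factors = "complex")$value, 1e-5)
  psiw <- unclass(w_state(3))
  rw <- partial_trace_pure(psiw, c(1, 2), rep(2, 3))
  expect_lt(ppt_minimum_eigenvalue(rw, 2, 2), -1e-3)
})

test_that("ionicity family interpolates from maximal to zero entanglement", {
  expect_error(ionicity_family(-0.01), "range")
  expect_error(ionicity_family(1.2), "range")
  lam <- seq(0, 1, length.out = 11)
  E <- vapply(lam, function(l) {
    psi <- unclass(ionicity_family(l))
    pure_bipartite_entanglement(psi, 1, c(4, 4), fermionic = TRUE)
  }, numeric(1))
  expect_equal(E[1], log(4), tolerance = 1e-12)
  expect_equal(E[11], 0, tolerance = 1e-12)
  expect_true(all(diff(E) <= 1e-10))
})
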