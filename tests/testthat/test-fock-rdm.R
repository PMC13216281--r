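# Orbital RDMs: entropies, partial traces, superselection structure, and
# the brute-force cross-check of the CI-vector reduction machinery.

test_that("von Neumann entropy handles the standard cases", {
  v <- c(1, rep(0, 3))
  expect_equal(von_neumann_entropy(diag(v)), 0)
  expect_equal(von_neumann_entropy(diag(rep(0.25, 4))), log(4))
  expect_equal(von_neumann_entropy(diag(c(0.5, 0.5, 0, 0))), log(2))
  expect_error(von_neumann_entropy(diag(c(1.5, -0.5, 0, 0))), "negative")
})

test_that("determinant one-orbital RDMs cover the occupation limits", {
  expect_equal(diag(determinant_one_orbital_rdm(1)), c(0, 0, 0, 1))
  expect_equal(diag(determinant_one_orbital_rdm(0)), c(1, 0, 0, 0))
  r <- determinant_one_orbital_rdm(0.5)
  expect_equal(sum(diag(r)), 1)
})

test_that("determinant two-orbital RDM matches the bond-state projector", {
  v <- unclass(bond_state())
  rho <- determinant_two_orbital_rdm(matrix(0.5, 2, 2))
  expect_lt(max(abs(rho - outer(v, v))), 1e-12)
  # partial traces are consistent
  expect_lt(max(abs(reduce_two_orbital_rdm(rho, 1) -
                    determinant_one_orbital_rdm(0.5))), 1e-12)
  expect_equal(sum(diag(rho)), 1, tolerance = 1e-12)
})

test_that("determinant RDM equals brute force for random rotations", {
  # one doubly occupied orbital spread over two sites: the state vector is
  # known in closed form, the Gaussian reduction must reproduce it
  set.seed(11)
  for (rep in 1:5) {
    th <- runif(1, 0, pi)
    cvec <- c(cos(th), sin(th))
    rho <- determinant_two_orbital_rdm(outer(cvec, cvec))
    lab <- two_orbital_labels()
    psi <- numeric(16)
    psi[match("|ud,0>", lab)] <- cvec[1]^2
    psi[match("|u,d>", lab)] <- cvec[1] * cvec[2]
    psi[match("|d,u>", lab)] <- -cvec[2] * cvec[1]
    psi[match("|0,ud>", lab)] <- cvec[2]^2
    expect_lt(max(abs(rho - outer(psi, psi))), 1e-12)
  }
})

test_that("CI-vector orbital RDMs agree with the full-state partial trace", {
  # oracle: reconstruct the full Fock vector of a correlated CAS(4, 2)
  # solution and take dense partial traces; the string-based subset
  # machinery must agree to 1e-10 on every one- and two-orbital RDM
  fx <- fixture_h2_4orb()
  psi <- cas_state_vector(fx$cas)
  expect_equal(sum(psi^2), 1, tolerance = 1e-10)
  for (i in 1:4) {
    direct <- one_orbital_rdm(fx$cas, i)
    brute <- one_orbital_rdm_pure(psi, i, 4)
    expect_lt(max(abs(direct - brute)), 1e-10)
  }
  for (i in 1:3) for (j in (i + 1):4) {
    direct <- two_orbital_rdm(fx$cas, i, j)
    brute <- two_orbital_rdm_pure(psi, i, j, 4)
    expect_lt(max(abs(direct - brute)), 1e-10)
    # trace, hermiticity, superselection purity, partial-trace consistency
    expect_equal(sum(diag(direct)), 1, tolerance = 1e-10)
    expect_lt(offblock_magnitude(direct), 1e-10)
    expect_lt(max(abs(reduce_two_orbital_rdm(direct, 1) -
                      one_orbital_rdm(fx$cas, i))), 1e-10)
  }
})

test_that("orbital RDM eigenvalues are valid probabilities", {
  # LiH minimal IAOs: Li 1s, Li 2s, H 1s (3 orbitals)
  fx <- fixture_lih()
  for (pair in list(c(1, 3), c(2, 3), c(1, 2))) {
    rho <- two_orbital_rdm(fx$cas, pair[1], pair[2])
    ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    expect_equal(sum(ev), 1, tolerance = 1e-10)
    expect_lt(offblock_magnitude(rho), 1e-10)
  }
})

test_that("mutual information is bounded and vanishes for product states", {
  fx <- fixture_lih()
  n <- ncol(fx$meao)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    I <- mutual_information(fx$cas, i, j)
    expect_gte(I, -1e-12)
    expect_lte(I, 2 * log(4) + 1e-10)
  }
  # product state: two separately doubly occupied orbitals
  rho_prod <- determinant_two_orbital_rdm(diag(c(1, 1)))
  I <- mutual_information_rdm(determinant_one_orbital_rdm(1),
                              determinant_one_orbital_rdm(1), rho_prod)
  expect_equal(I, 0, tolerance = 1e-12)
})
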