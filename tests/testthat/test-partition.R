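# Atomic Hilbert-space partitioning: IAO construction and invariants.

test_that("minimal IAO partition has one orbital per reference AO", {
  # He2: a single 1s reference orbital per atom
  mf <- fixture("he2_mf", {
    run_mean_field(read_xyz(pkg_geometry("he2.xyz")), "cc-pvdz")
  })
  part <- build_partition(mf, "iao-minimal")
  expect_equal(ncol(part$coeff), 2)
  expect_equal(part$atom, c(1, 2))
  # ethene: 14 minimal localized orbitals (5 per C, 1 per H)
  mfe <- fixture("c2h4_mf", {
    run_mean_field(read_xyz(pkg_geometry("c2h4.xyz")), "cc-pvdz")
  })
  parte <- build_partition(mfe, "iao-minimal")
  expect_equal(ncol(parte$coeff), 14)
  expect_equal(sum(parte$atom == 1), 5)
  expect_equal(sum(parte$atom == 3), 1)
})

test_that("localized orbitals are orthonormal and span the occupied space", {
  fx <- fixture_lih()
  part <- fx$part
  S <- part$S
  G <- t(part$coeff) %*% S %*% part$coeff
  expect_lt(max(abs(G - diag(ncol(part$coeff)))), 1e-10)
  # occupied MOs are contained in the IAO span: projection is lossless
  Cocc <- fx$mf$mo_coeff[, fx$mf$mo_occ > 0, drop = FALSE]
  P <- part$coeff %*% t(part$coeff) %*% S
  loss <- max(abs(t(Cocc) %*% S %*% Cocc -
                  t(P %*% Cocc) %*% S %*% (P %*% Cocc)))
  expect_lt(loss, 1e-8)
})

test_that("partition subspaces are invariant under intra-atom rotations", {
  fx <- fixture_lih()
  part <- fx$part
  U <- random_block_rotation(part$atom, seed = 17)
  rotated <- part$coeff %*% U
  S <- part$S
  for (m in unique(part$atom)) {
    sel <- part$atom == m
    P1 <- part$coeff[, sel] %*% t(part$coeff[, sel]) %*% S
    P2 <- rotated[, sel] %*% t(rotated[, sel]) %*% S
    expect_lt(max(abs(P1 - P2)), 1e-12)
  }
})

test_that("iao-full extends the partition to the whole basis", {
  mf <- fixture_h2()
  part <- build_partition(mf, "iao-full")
  expect_equal(ncol(part$coeff), nrow(part$coeff))
  G <- t(part$coeff) %*% part$S %*% part$coeff
  expect_lt(max(abs(G - diag(ncol(part$coeff)))), 1e-8)
  expect_true(all(sort(unique(part$atom)) == c(1, 2)))
})

test_that("meta-lowdin scheme yields an orthonormal AO-parented partition", {
  mf <- fixture_h2()
  part <- build_partition(mf, "meta-lowdin")
  G <- t(part$coeff) %*% part$S %*% part$coeff
  expect_lt(max(abs(G - diag(ncol(part$coeff)))), 1e-10)
  expect_equal(length(part$atom), mf$ints$shells$nao)
})

test_that("gamma in the localized basis conserves the electron count", {
  fx <- fixture_lih()
  gl <- partition_gamma(fx$part)
  expect_equal(sum(diag(gl)), fx$mf$mol$nelec, tolerance = 1e-8)
})
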