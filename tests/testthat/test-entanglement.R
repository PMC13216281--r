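# Entanglement measures: pure bipartite entropy, relative entropy of
# entanglement (against its closed-form oracles), and GME modes.

test_that("pure bipartite entanglement has its analytic values", {
  v <- unclass(bond_state())
  expect_equal(pure_bipartite_entanglement(v, 1, c(4, 4), fermionic = TRUE),
               log(4), tolerance = 1e-12)
  # symmetry between a subsystem and its complement
  expect_equal(pure_bipartite_entanglement(v, 2, c(4, 4), fermionic = TRUE),
               log(4), tolerance = 1e-12)
  prod_state <- as.vector(outer(c(1, 0, 0, 0), c(0, 0, 0, 1)))
  expect_equal(pure_bipartite_entanglement(prod_state, 1, c(4, 4)), 0)
  expect_equal(pure_bipartite_entanglement(unclass(ghz_state(3)), 1,
                                           rep(2, 3)), log(2),
               tolerance = 1e-12)
  expect_error(pure_bipartite_entanglement(v / 2, 1, c(4, 4)),
               "invalid usage")
})

test_that("relative entropy of entanglement reproduces known values", {
  # separable diagonal mixture -> 0
  sep <- diag(c(rep(1 / 8, 8), rep(0, 8)))
  expect_lt(relative_entropy_of_entanglement(sep)$value, 1e-6)
  # pure maximally entangled bond state -> log 4
  v <- unclass(bond_state())
  r <- relative_entropy_of_entanglement(outer(v, v), tol = 1e-5,
                                        maxit = 3000)
  expect_equal(r$value, log(4), tolerance = 1e-4)
})

test_that("solver matches the Bell-diagonal closed form (complex mode)", {
  for (p in c(0.55, 0.7, 0.85, 0.95)) {
    rho <- bell_diagonal(p)
    r <- relative_entropy_of_entanglement(rho, dA = 2, dB = 2, tol = 1e-7,
                                          maxit = 20000,
                                          factors = "complex")
    closed <- log(2) + p * log(p) + (1 - p) * log(1 - p)
    expect_equal(r$value, closed, tolerance = 1e-3)
  }
  # below p = 1/2 the state is separable
  r0 <- relative_entropy_of_entanglement(bell_diagonal(0.45), dA = 2, dB = 2,
                                         factors = "complex")
  expect_lt(r0$value, 1e-5)
})

test_that("oracle equivalence: direct simplex minimization agrees", {
  # independent oracle: for a low-rank two-qubit state, minimize over an
  # explicit finite mixture of product states by general-purpose nonlinear
  # optimization, independently of the Frank-Wolfe path
  rho <- bell_diagonal(0.8)
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  s_rho <- -sum(ev[ev > 1e-14] * log(ev[ev > 1e-14]))
  nterms <- 8
  obj <- function(par) {
    w <- exp(par[1:nterms]); w <- w / sum(w)
    sig <- matrix(0, 4, 4)
    for (k in 1:nterms) {
      th <- par[nterms + 4 * (k - 1) + 1:4]
      a <- c(cos(th[1]), sin(th[1]))
      b <- c(cos(th[2]), sin(th[2]))
      a2 <- c(cos(th[3]), sin(th[3]))
      b2 <- c(cos(th[4]), sin(th[4]))
      # complex product vector via two real vectors: x = (a + i a2 scaled)
      x <- kronecker(complex(real = a, imaginary = 0.3 * a2),
                     complex(real = b, imaginary = 0.3 * b2))
      x <- x / sqrt(sum(Mod(x)^2))
      sig <- sig + w[k] * Re(outer(x, Conj(x)))
    }
    es <- eigen(sig, symmetric = TRUE)
    lam <- pmax(es$values, 1e-300)
    logs <- es$vectors %*% (t(es$vectors) * log(lam))
    -sum(rho * t(logs)) - s_rho
  }
  set.seed(4)
  best <- Inf
  for (trial in 1:5) {
    opt <- stats::nlminb(c(rep(0, nterms), runif(4 * nterms, 0, pi)), obj)
    best <- min(best, opt$objective)
  }
  fw <- relative_entropy_of_entanglement(rho, dA = 2, dB = 2, tol = 1e-7,
                                         maxit = 20000, factors = "complex")
  expect_lt(abs(fw$value - best), 1e-3)
})

test_that("entanglement respects its bounds on physical pairs", {
  # LiH minimal IAOs: orbitals (Li 1s, Li 2s, H 1s); inter-center pairs
  fx <- fixture_lih()
  for (pair in list(c(1, 3), c(2, 3)))(function(i, j) {
    rho <- two_orbital_rdm(fx$cas, i, j)
    I <- mutual_information(fx$cas, i, j)
    E <- relative_entropy_of_entanglement(rho, tol = 1e-5, maxit = 2000)
    SA <- von_neumann_entropy(reduce_two_orbital_rdm(rho, 1))
    SB <- von_neumann_entropy(reduce_two_orbital_rdm(rho, 2))
    expect_lte(E$value, I + 1e-4)            # I_ij >= E_ij
    expect_lte(E$value, min(SA, SB) + 1e-3)  # local-entropy bound
    expect_lte(I, 2 * log(4) + 1e-10)
  })(pair[1], pair[2])
})

test_that("superselected value bounds the unrestricted value from above", {
  fx <- fixture_lih()
  rho <- two_orbital_rdm(fx$cas, 2, 3)
  ssr <- relative_entropy_of_entanglement(rho, superselect = TRUE)
  un <- relative_entropy_of_entanglement(rho, factors = "complex",
                                         tol = 1e-6, maxit = 5000)
  expect_gte(ssr$value, un$value - 1e-5)
  expect_equal(ssr$gap, 0)
})

test_that("GME modes agree on small clusters and order correctly", {
  # on every cluster state tested (<= 6 factors) the chain-cut
  # approximation equals the exhaustive minimum
  for (psi in list(unclass(ghz_state(3)), unclass(w_state(3)),
                   unclass(ghz_state(5)))) {
    K <- round(log2(length(psi)))
    ex <- gme(psi, rep(2, K), mode = "exhaustive")
    mc <- gme(psi, rep(2, K), mode = "mps-cuts")
    expect_lte(ex$value, mc$value + 1e-12)
    expect_equal(ex$value, mc$value, tolerance = 1e-10)
  }
  fx <- fixture_h2_4orb()
  ex <- cas_gme(fx$cas, mode = "exhaustive")
  mc <- cas_gme(fx$cas, mode = "mps-cuts")
  expect_lte(ex$value, mc$value + 1e-12)
  expect_equal(ex$value, mc$value, tolerance = 1e-10)
  # biseparable product of a pair and a singleton -> 0
  pair <- unclass(bond_state())
  vac <- c(1, 0, 0, 0)
  psi3 <- as.vector(outer(pair, vac)) # orbital 3 fastest: (pair) x |0>
  expect_lt(gme(psi3, rep(4, 3), fermionic = TRUE)$value, 1e-12)
})
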