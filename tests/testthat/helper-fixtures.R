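# Shared fixtures, built in code and memoized across test files (the suite
# runs in one R process).  All electronic-structure fixtures are small
# molecules in shipped basis sets; no stored binary data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

pkg_geometry <- function(file) {
  system.file("extdata", "geometries", file, package = "meaobond",
              mustWork = TRUE)
}

fixture_h2 <- function() fixture("h2", {
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  run_mean_field(mol, "cc-pvdz")
})

fixture_lih <- function() fixture("lih", {
  mf <- run_mean_field(read_xyz(pkg_geometry("lih.xyz")), "cc-pvdz")
  part <- build_partition(mf, "iao-minimal")
  opt <- optimize_meao(mf_gamma(partition_gamma(part)), part$atom, seed = 1)
  meao <- part$coeff %*% opt$U
  cas <- solve_cas(mf, active = meao, nelec_active = mf$mol$nelec)
  list(mf = mf, part = part, opt = opt, meao = meao, cas = cas)
})

# H2 with two localized orbitals per atom: minimal IAOs plus the first
# orthogonal-complement orbital of each atom, correlated by a CAS(4, 2).
fixture_h2_4orb <- function() fixture("h2_4orb", {
  mf <- fixture_h2()
  part <- build_partition(mf, "iao-full")
  sel <- c(which(part$atom == 1)[1:2], which(part$atom == 2)[1:2])
  active <- part$coeff[, sel]
  atom <- part$atom[sel]
  cas <- solve_cas(mf, active = active, nelec_active = 2)
  list(mf = mf, active = active, atom = atom, cas = cas,
       G = cas_gamma_ud(cas))
})

# vectorized 2-angle grid of the mean-field objective for a (2+2)-orbital
# closed-shell fixture with per-spin 1RDM D = c c^T (one occupied orbital)
mf_objective_grid <- function(cvec, thetas) {
  stopifnot(length(cvec) == 4)
  n <- length(thetas)
  c1 <- outer(cos(thetas), rep(1, n)) * cvec[1] +
        outer(sin(thetas), rep(1, n)) * cvec[2]
  c2 <- outer(-sin(thetas), rep(1, n)) * cvec[1] +
        outer(cos(thetas), rep(1, n)) * cvec[2]
  c3 <- outer(rep(1, n), cos(thetas)) * cvec[3] +
        outer(rep(1, n), sin(thetas)) * cvec[4]
  c4 <- outer(rep(1, n), -sin(thetas)) * cvec[3] +
        outer(rep(1, n), cos(thetas)) * cvec[4]
  # F = sum over ordered inter pairs of D_ij^4, D = c c^T
  2 * ((c1 * c3)^4 + (c1 * c4)^4 + (c2 * c3)^4 + (c2 * c4)^4)
}

random_block_rotation <- function(atom, seed) {
  set.seed(seed)
  blocks <- split(seq_along(atom), atom)
  X <- matrix(0, length(atom), length(atom))
  for (b in blocks) {
    if (length(b) < 2) next
    m <- length(b)
    Xb <- matrix(0, m, m)
    Xb[upper.tri(Xb)] <- rnorm(m * (m - 1) / 2, sd = 0.5)
    X[b, b] <- Xb - t(Xb)
  }
  meaobond:::block_expm(X, blocks)
}

bell_state <- function(k) {
  b <- matrix(0, 2, 2)
  if (k == 1) { b[1, 1] <- 1; b[2, 2] <- 1 }
  else if (k == 2) { b[1, 1] <- 1; b[2, 2] <- -1 }
  else if (k == 3) { b[1, 2] <- 1; b[2, 1] <- 1 }
  else { b[1, 2] <- 1; b[2, 1] <- -1 }
  as.vector(t(b)) / sqrt(2)
}

bell_diagonal <- function(p) {
  rho <- p * outer(bell_state(1), bell_state(1))
  for (k in 2:4) rho <- rho + (1 - p) / 3 * outer(bell_state(k), bell_state(k))
  rho
}
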