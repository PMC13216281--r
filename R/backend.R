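# Correlated-solver backend: complete-active-space CI on top of the RHF
# engine, plus Boltzmann thermal ensembles of CAS eigenstates.
#
# The CAS Hamiltonian is the standard frozen-core construction: closed
# orbitals enter through an effective one-electron operator (Coulomb minus
# half exchange of the doubly occupied core) and a core energy; active
# two-electron integrals are obtained from the packed AO ERIs by
# generalized-Coulomb builds, one per active orbital pair.

# Davidson iteration for the lowest eigenpair(s) of the CI Hamiltonian.
davidson_ci <- function(sigma_fun, hdiag, ndet, nroots = 1L, tol = 1e-9,
                        max_iter = 200L, guess = NULL) {
  dim_dense <- 2500
  if (ndet <= dim_dense) {
    H <- matrix(0, ndet, ndet)
    for (k in seq_len(ndet)) {
      ek <- numeric(ndet); ek[k] <- 1
      H[, k] <- sigma_fun(ek)
    }
    H <- (H + t(H)) / 2
    e <- eigen(H, symmetric = TRUE)
    ord <- order(e$values)
    sel <- ord[seq_len(nroots)]
    return(list(values = e$values[sel],
                vectors = e$vectors[, sel, drop = FALSE]))
  }
  if (nroots > 1) stop("multiple roots require a dense-solvable CI space")
  v <- if (is.null(guess)) {
    g <- numeric(ndet); g[which.min(hdiag)] <- 1; g
  } else guess / sqrt(sum(guess^2))
  V <- matrix(v, ndet, 1)
  W <- matrix(sigma_fun(v), ndet, 1)
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    Hs <- crossprod(V, W)
    Hs <- (Hs + t(Hs)) / 2
    es <- eigen(Hs, symmetric = TRUE)
    k <- which.min(es$values)
    lambda <- es$values[k]
    y <- es$vectors[, k]
    x <- V %*% y
    r <- W %*% y - lambda * x
    rn <- sqrt(sum(r^2))
    if (rn < tol) {
      return(list(values = lambda, vectors = x, iterations = it))
    }
    d <- hdiag - lambda
    d[abs(d) < 1e-8] <- 1e-8
    t <- as.numeric(r) / d
    # orthogonalize against V
    t <- t - V %*% crossprod(V, t)
    tn <- sqrt(sum(t^2))
    if (tn < 1e-12) {
      t <- rnorm(ndet); t <- t - V %*% crossprod(V, t); tn <- sqrt(sum(t^2))
    }
    t <- t / tn
    if (ncol(V) >= 25) { # restart
      V <- x / sqrt(sum(x^2))
      W <- matrix(sigma_fun(as.numeric(V)), ndet, 1)
      Hs <- crossprod(V, W)
    }
    V <- cbind(V, t)
    W <- cbind(W, sigma_fun(as.numeric(t)))
  }
  stop("Davidson failed to converge (residual ", format(rn), ")")
}

#' Solve a complete active space CI problem
#'
#' @param mf `scf_result` providing integrals and the mean-field reference.
#' @param active matrix (nao x nact) of orthonormal active orbitals over the
#'   AO basis.
#' @param core matrix (nao x ncore) of doubly occupied closed orbitals,
#'   orthogonal to the active set (may have zero columns).
#' @param nelec_active number of active electrons (even; Sz = 0).
#' @param nroots number of eigenstates to compute.
#' @return object of class `cas_solution`: CI vector(s), active-space
#'   integrals, orbital coefficient blocks, energies (hartree).
#' @export
solve_cas <- function(mf, active, core = NULL, nelec_active = NULL,
                      nroots = 1L) {
  ints <- mf$ints
  S <- ints$S
  nao <- nrow(S)
  if (is.null(core)) core <- matrix(0, nao, 0)
  nact <- ncol(active)
  ncore <- ncol(core)
  if (is.null(nelec_active)) nelec_active <- mf$mol$nelec - 2L * ncore
  if (nelec_active %% 2 != 0 || nelec_active < 0 ||
      nelec_active > 2 * nact) {
    stop("inconsistent active electron count: ", nelec_active,
         " in ", nact, " orbitals")
  }
  # orthonormality contract
  allC <- cbind(core, active)
  G <- t(allC) %*% S %*% allC
  if (max(abs(G - diag(ncol(allC)))) > 1e-7) {
    stop("active/core orbitals are not orthonormal under the AO metric")
  }
  # effective one-electron operator and core energy
  h <- ints$hcore
  if (ncore > 0) {
    rho_c <- 2 * tcrossprod(core)
    jk <- cpp_fock_jk(ints$eri, rho_c)
    heff <- h + jk$J - 0.5 * jk$K
    e_core <- sum(rho_c * (h + 0.5 * (jk$J - 0.5 * jk$K))) + ints$enuc
  } else {
    heff <- h
    e_core <- ints$enuc
  }
  h_act <- t(active) %*% heff %*% active
  # active ERIs via generalized Coulomb builds
  pairs <- which(upper.tri(diag(nact), diag = TRUE), arr.ind = TRUE)
  Dlist <- lapply(seq_len(nrow(pairs)), function(k) {
    ci <- active[, pairs[k, 1]]; cj <- active[, pairs[k, 2]]
    (outer(ci, cj) + outer(cj, ci)) / 2
  })
  Jlist <- cpp_j_multi(ints$eri, Dlist)
  g <- array(0, dim = rep(nact, 4)) # chemist (ij|kl)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    blk <- t(active) %*% Jlist[[k]] %*% active
    g[i, j, , ] <- blk
    g[j, i, , ] <- blk
  }
  # enforce full permutational symmetry (numerical noise removal)
  gperm <- aperm(g, c(3, 4, 1, 2))
  g <- (g + gperm) / 2
  na <- nelec_active / 2L
  stra <- cpp_strings(nact, na)
  strb <- stra
  exa <- cpp_excitations(stra, nact)
  ndet <- length(stra)^2
  # flatten so the C++ index ((p*n+q)*n+r)*n+s reads chemist (pq|rs)
  gvec <- numeric(nact^4)
  idx <- 1
  for (p in 1:nact) for (q in 1:nact) for (r in 1:nact) for (s in 1:nact) {
    gvec[((p - 1) * nact + (q - 1)) * nact^2 + (r - 1) * nact + s] <-
      g[p, q, r, s]
  }
  sigma_fun <- function(v) {
    Cm <- matrix(v, length(stra), length(strb))
    as.numeric(cpp_fci_sigma(Cm, h_act, gvec, exa, exa, nact))
  }
  hdiag <- as.numeric(cpp_fci_hdiag(stra, strb, h_act, gvec, nact))
  sol <- davidson_ci(sigma_fun, hdiag, ndet, nroots = nroots)
  civecs <- lapply(seq_len(nroots), function(r) {
    v <- sol$vectors[, r]
    matrix(v / sqrt(sum(v^2)), length(stra), length(strb))
  })
  structure(list(civec = civecs[[1]], civecs = civecs,
                 energies = sol$values + e_core,
                 e_tot = sol$values[1] + e_core,
                 e_core = e_core, h_act = h_act, g_act = g,
                 norb = nact, na = na, nb = na,
                 strings_a = stra, strings_b = strb, exc_a = exa,
                 active = active, core = core, mf = mf),
            class = "cas_solution")
}

#' @export
print.cas_solution <- function(x, ...) {
  cat(sprintf("CAS(%d orbitals, %d electrons): E = %.10f hartree (%d roots)\n",
              x$norb, x$na + x$nb, x$e_tot, length(x$energies)))
  invisible(x)
}

#' Spin-free 1RDM of a CAS solution in the active orbital basis
#' @param sol `cas_solution`.
#' @param root state index (1-based).
#' @export
cas_gamma1 <- function(sol, root = 1L) {
  cpp_fci_gamma1(sol$civecs[[root]], sol$exc_a, sol$exc_a, sol$norb)
}

#' Up/down block of the spin-resolved 2RDM of a CAS solution
#'
#' Returns the 4-index array `G[i,j,k,l] = <f_iu+ f_jd+ f_ld f_ku>` in the
#' active orbital basis, the input of the MEAO objective.
#'
#' @param sol `cas_solution`.
#' @param root state index.
#' @export
cas_gamma_ud <- function(sol, root = 1L) {
  n <- sol$norb
  AB <- cpp_fci_spin_generators(sol$civecs[[root]], sol$exc_a, sol$exc_a, n)
  # G[i,j,k,l] = <E^a_ki c, E^b_jl c>;  columns of A/B are (p*n+q) 0-based
  M <- crossprod(AB$A, AB$B) # [(ki), (jl)]
  G <- array(0, dim = rep(n, 4))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
    G[i, j, k, l] <- M[(k - 1) * n + i, (j - 1) * n + l]
  }
  G
}

#' Boltzmann thermal ensemble over correlated eigenstates
#'
#' Weights `w_i = exp(-beta E_i) / Z`; thermal RDMs are the weight-averaged
#' state RDMs.
#'
#' @param states list of states (any objects; carried through).
#' @param energies energies in hartree.
#' @param beta inverse temperature in 1/hartree (default 1e3).
#' @return object of class `thermal_ensemble` with `weights`.
#' @export
thermal_ensemble <- function(states, energies, beta = 1e3) {
  stopifnot(length(states) >= 1, length(states) == length(energies),
            all(is.finite(energies)))
  if (beta < 0) stop("range error: beta must be non-negative")
  w <- exp(-beta * (energies - min(energies)))
  w <- w / sum(w)
  structure(list(states = states, energies = energies, beta = beta,
                 weights = w),
            class = "thermal_ensemble")
}
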