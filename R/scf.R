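# Restricted Hartree-Fock with DIIS acceleration.
#
# The mean-field backend of the bonding-analysis pipeline.  Integrals come
# from the package's own engine; convergence is standard commutator-DIIS
# with early damping and canonical orthogonalization (tolerant of the
# near-linear dependence of diffuse-augmented bases).

#' One- and two-electron integrals for a molecule
#'
#' @param mol `molecule`.
#' @param basis basis name or `basis_set`.
#' @param with_eri compute two-electron integrals (packed, 8-fold symmetry).
#' @return list with `S`, `T`, `V`, `hcore`, `eri` (or `NULL`), `shells`,
#'   `enuc`.
#' @export
molecular_integrals <- function(mol, basis, with_eri = TRUE) {
  shells <- build_shells(mol, basis)
  one <- cpp_one_electron(shells, mol$coords, as.numeric(mol$Z))
  eri <- if (with_eri) cpp_eri(shells) else NULL
  list(S = one$S, T = one$T, V = one$V, hcore = one$T + one$V,
       eri = eri, shells = shells, enuc = nuclear_repulsion(mol), mol = mol)
}

# canonical orthogonalization S^(-1/2) dropping near-null vectors
orthogonalizer <- function(S, tol = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

#' Restricted Hartree-Fock
#'
#' @param mol `molecule` (must have an even electron count).
#' @param basis basis name or `basis_set`.
#' @param ints optionally precomputed [molecular_integrals()].
#' @param max_iter maximum SCF iterations.
#' @param conv_tol convergence threshold on the DIIS error max-norm and the
#'   energy change.
#' @param verbose print per-iteration energies.
#' @return object of class `scf_result`: MO coefficients over the spherical
#'   AO basis, orbital energies, occupations, converged total energy, the
#'   spin-free 1RDM `gamma` (AO basis), and the integral set.
#' @export
run_mean_field <- function(mol, basis, ints = NULL, max_iter = 100L,
                           conv_tol = 1e-9, verbose = FALSE) {
  if (mol$nelec %% 2 != 0) {
    stop("restricted mean field requires an even electron count; got ",
         mol$nelec)
  }
  if (is.null(ints)) ints <- molecular_integrals(mol, basis)
  S <- ints$S; h <- ints$hcore
  n <- nrow(S); nocc <- mol$nelec / 2
  X <- orthogonalizer(S)
  # core-Hamiltonian guess
  # R's eigen() sorts eigenvalues in decreasing order; orbitals ascending
  solve_fock <- function(Fm) {
    e <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
    ord <- order(e$values)
    list(C = X %*% e$vectors[, ord, drop = FALSE], eps = e$values[ord])
  }
  sol <- solve_fock(h)
  C <- sol$C
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  D <- tcrossprod(Cocc) # per-spin density
  E_old <- Inf
  diis_F <- list(); diis_err <- list()
  energy <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    jk <- cpp_fock_jk(ints$eri, 2 * D)
    Fm <- h + jk$J - 0.5 * jk$K
    energy <- sum(D * (h + Fm)) + ints$enuc
    err <- Fm %*% D %*% S - S %*% D %*% Fm
    err <- t(X) %*% err %*% X
    err_norm <- max(abs(err))
    if (verbose) {
      message(sprintf("SCF iter %3d  E = %.10f  |err| = %.2e", it, energy,
                      err_norm))
    }
    if (err_norm < conv_tol && abs(energy - E_old) < conv_tol) {
      converged <- TRUE
      break
    }
    E_old <- energy
    # DIIS
    diis_F[[length(diis_F) + 1]] <- Fm
    diis_err[[length(diis_err) + 1]] <- err
    if (length(diis_F) > 8) { diis_F <- diis_F[-1]; diis_err <- diis_err[-1] }
    m <- length(diis_F)
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in 1:m) for (j in 1:m) {
        B[i, j] <- sum(diis_err[[i]] * diis_err[[j]])
      }
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        Fm <- Reduce(`+`, Map(`*`, diis_F, cf))
      }
    }
    sol <- solve_fock(Fm)
    C <- sol$C
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    Dn <- tcrossprod(Cocc)
    # light damping in the first iterations
    D <- if (it <= 2) 0.5 * D + 0.5 * Dn else Dn
  }
  if (!converged) {
    stop("SCF failed to converge in ", max_iter,
         " iterations (last error ", format(err_norm), ")")
  }
  mo_energy <- sol$eps
  mo_occ <- c(rep(2, nocc), rep(0, length(mo_energy) - nocc))
  gamma <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  structure(list(mol = mol, ints = ints, mo_coeff = C,
                 mo_energy = mo_energy, mo_occ = mo_occ,
                 energy = energy, gamma = gamma, nocc = nocc,
                 iterations = it, converged = converged),
            class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("RHF: E = %.10f hartree (%d iterations, %d AOs, %d electrons)\n",
              x$energy, x$iterations, nrow(x$mo_coeff), x$mol$nelec))
  invisible(x)
}
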