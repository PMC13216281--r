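# Orbital reduced density matrices from CAS CI vectors.
#
# The CI vector is decomposed into (subsystem configuration, environment
# configuration) amplitudes with all fermionic reordering parities; the
# subsystem RDM is then an ordinary Gram matrix.  Thermal variants are
# weighted averages over ensemble members.

ci_subset_rdm <- function(sol, subset, root = 1L) {
  k <- length(subset)
  tri <- cpp_ci_subset(sol$civecs[[root]], sol$strings_a, sol$strings_b,
                       sol$norb, as.integer(sort(subset) - 1L))
  env <- match(tri$env, unique(tri$env))
  M <- matrix(0, 4^k, max(env))
  M[cbind(tri$sub + 1L, env)] <- tri$amp
  rho_bit <- tcrossprod(M)
  perm <- fock_basis_permutation(k)
  rho_bit[perm, perm]
}

#' One-orbital RDM from a CAS solution
#'
#' @param sol `cas_solution` (or `thermal_ensemble` of them).
#' @param i active-orbital index.
#' @param root state index.
#' @return 4x4 density matrix over |0>,|up>,|dn>,|updn>.
#' @export
one_orbital_rdm <- function(sol, i, root = 1L) {
  if (inherits(sol, "thermal_ensemble")) {
    out <- matrix(0, 4, 4)
    for (k in seq_along(sol$states)) {
      out <- out + sol$weights[k] * one_orbital_rdm(sol$states[[k]], i)
    }
    return(out)
  }
  if (i < 1 || i > sol$norb) stop("orbital index out of range: ", i)
  ci_subset_rdm(sol, i, root)
}

#' Two-orbital RDM from a CAS solution
#'
#' @inheritParams one_orbital_rdm
#' @param j second orbital index (`i != j`); the smaller index is the slow
#'   (left) Fock factor.
#' @return 16x16 density matrix.
#' @export
two_orbital_rdm <- function(sol, i, j, root = 1L) {
  if (inherits(sol, "thermal_ensemble")) {
    out <- matrix(0, 16, 16)
    for (k in seq_along(sol$states)) {
      out <- out + sol$weights[k] * two_orbital_rdm(sol$states[[k]], i, j)
    }
    return(out)
  }
  if (i == j) stop("orbital indices must differ")
  if (min(i, j) < 1 || max(i, j) > sol$norb) {
    stop("orbital index out of range")
  }
  ci_subset_rdm(sol, c(i, j), root)
}

#' Mutual information between two active orbitals (nats)
#'
#' @inheritParams two_orbital_rdm
#' @export
mutual_information <- function(sol, i, j, root = 1L) {
  mutual_information_rdm(one_orbital_rdm(sol, i, root),
                         one_orbital_rdm(sol, j, root),
                         two_orbital_rdm(sol, i, j, root))
}

#' Full Fock-space amplitude vector of a CAS state
#'
#' Only for small active spaces (norb <= 8): the 4^norb amplitude vector in
#' the orbital-ordered product basis of the package's mode convention.
#'
#' @param sol `cas_solution`.
#' @param root state index.
#' @export
cas_state_vector <- function(sol, root = 1L) {
  if (sol$norb > 8) stop("full Fock vector limited to 8 orbitals")
  tri <- cpp_ci_subset(sol$civecs[[root]], sol$strings_a, sol$strings_b,
                       sol$norb, as.integer(seq_len(sol$norb) - 1L))
  psi_bit <- numeric(4^sol$norb)
  psi_bit[tri$sub + 1L] <- tri$amp
  psi_bit[fock_basis_permutation(sol$norb)]
}

#' Entanglement entropy of an orbital subset of a CAS state
#'
#' @param sol `cas_solution`.
#' @param subset active-orbital indices forming subsystem A.
#' @param root state index.
#' @return von Neumann entropy of the subset RDM (nats).
#' @export
cas_subset_entropy <- function(sol, subset, root = 1L) {
  rho <- ci_subset_rdm(sol, subset, root)
  von_neumann_entropy(rho)
}

#' GME of a CAS cluster state
#'
#' Genuine multipartite entanglement over the active orbitals of a cluster
#' CAS solution: minimum subset entanglement entropy over bipartitions.
#'
#' @param sol `cas_solution` for the cluster.
#' @param mode `"exhaustive"` or `"mps-cuts"` (see [gme()]).
#' @param root state index.
#' @return list as from [gme()].
#' @export
cas_gme <- function(sol, mode = c("exhaustive", "mps-cuts"), root = 1L) {
  mode <- match.arg(mode)
  K <- sol$norb
  subsets <- list()
  if (mode == "exhaustive") {
    for (m in 1:(2^(K - 1) - 1)) {
      subsets[[length(subsets) + 1]] <- which(bitwAnd(m, 2^(0:(K - 1))) > 0)
    }
  } else {
    for (k in 1:K) subsets[[length(subsets) + 1]] <- k
    if (K > 2) {
      for (i in 1:(K - 1)) for (j in (i + 1):K) {
        subsets[[length(subsets) + 1]] <- c(i, j)
      }
    }
    for (k in 1:(K - 1)) subsets[[length(subsets) + 1]] <- 1:k
    subsets <- unique(subsets)
  }
  best <- Inf; bestA <- NULL
  for (A in subsets) {
    S <- cas_subset_entropy(sol, A, root)
    if (S < best - 1e-15) { best <- S; bestA <- A }
  }
  list(value = best, normalized = best / log(4), minimizer = bestA,
       mode = mode)
}
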