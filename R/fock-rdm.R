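# One- and two-orbital reduced density matrices and entropic measures.
#
# RDMs are plain numeric matrices over the Fock bases of fock-basis.R.
# They can be built from three kinds of "solutions":
#   * pure state vectors on a small orbital set (partial trace),
#   * closed-shell mean-field states (Wick / fermionic-Gaussian reduction,
#     see gaussian-rdm.R),
#   * CAS configuration-interaction vectors (ci-rdm.R),
#   * thermal ensembles (weighted averages of member RDMs).

#' Von Neumann entropy of a density matrix (nats)
#'
#' Eigenvalues below 1e-14 are treated as exact zeros; an eigenvalue below
#' -1e-8 signals an invalid state.
#'
#' @param rho hermitian matrix with unit trace.
#' @return entropy in nats (non-negative).
#' @export
von_neumann_entropy <- function(rho) {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  if (max(abs(rho - t(Conj(rho)))) > 1e-8) stop("rho must be hermitian")
  if (abs(sum(diag(rho)) - 1) > 1e-6) stop("rho must have unit trace")
  w <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(w) < -1e-8) {
    stop("invalid state: negative eigenvalue ", format(min(w)))
  }
  w <- w[w > 1e-14]
  -sum(w * log(w))
}

#' Partial trace of a pure state over a product of Fock factors
#'
#' @param psi amplitude vector over a product basis with factor dimensions
#'   `dims` (first factor slowest).
#' @param keep indices of the factors to keep.
#' @param dims integer vector of factor dimensions.
#' @return density matrix on the kept factors (in their original order).
#' @export
partial_trace_pure <- function(psi, keep, dims) {
  stopifnot(length(psi) == prod(dims), all(keep %in% seq_along(dims)))
  n <- length(dims)
  arr <- array(psi, dim = rev(dims)) # R arrays: first array index fastest
  # array dims correspond to factors n, n-1, ..., 1
  fac_of_axis <- rev(seq_len(n))
  keep_axes <- match(sort(keep), fac_of_axis)
  drop_axes <- setdiff(seq_len(n), keep_axes)
  perm <- c(rev(keep_axes), drop_axes) # kept factors: slowest kept last
  arr <- aperm(arr, perm)
  dk <- prod(dims[sort(keep)])
  M <- matrix(arr, nrow = dk) # rows: kept (sorted keep, first slow? check)
  # After aperm, axis order is rev(keep_axes) (fastest axis = last kept factor
  # in sorted order ... ), flattening gives kept-index with sorted(keep)[1]
  # slowest, matching the product-basis convention.
  Re(M %*% Conj(t(M)))
}

#' One-orbital RDM of a pure multi-orbital Fock state
#'
#' @param psi amplitude vector over `norb` orbital Fock factors (dim 4 each).
#' @param i orbital index.
#' @return 4x4 density matrix over |0>,|up>,|dn>,|updn>.
#' @export
one_orbital_rdm_pure <- function(psi, i, norb = round(log(length(psi), 4))) {
  stopifnot(length(psi) == 4^norb, i >= 1, i <= norb)
  signs <- mode_reorder_signs(norb, i)
  partial_trace_pure(psi * signs, i, rep(4L, norb))
}

#' Two-orbital RDM of a pure multi-orbital Fock state
#'
#' Fermionic signs: the amplitude vector is assumed to be expressed in the
#' orbital-ordered product basis with the site-ascending mode convention, in
#' which the partial trace over complementary *orbitals* (whole 4-dim
#' factors) is sign-free after reordering modes so that the kept orbitals
#' come first; the reordering parity is included here.
#'
#' @param psi amplitude vector over `norb` Fock factors.
#' @param i,j distinct orbital indices (i < j output ordering: factor `i`
#'   slow).
#' @return 16x16 density matrix.
#' @export
two_orbital_rdm_pure <- function(psi, i, j, norb = round(log(length(psi), 4))) {
  stopifnot(i != j, i >= 1, j <= norb)
  ij <- sort(c(i, j))
  signs <- mode_reorder_signs(norb, ij)
  partial_trace_pure(psi * signs, ij, rep(4L, norb))
}

# Parity factors for moving the modes of the kept orbitals in front of the
# rest, per basis state.  For kept orbitals the pair (up,dn) moves together,
# so crossing a kept orbital's 2 modes past an occupied environment mode
# flips sign once per occupied mode crossed per kept electron... computed
# explicitly from bit counts.
mode_reorder_signs <- function(norb, keep) {
  occ <- orbital_occupations()
  nst <- 4^norb
  ks <- matrix(0L, nst, norb)
  rem <- 0:(nst - 1)
  for (p in norb:1) {
    ks[, p] <- rem %% 4L
    rem <- rem %/% 4L
  }
  nel_of <- occ[, 1] + occ[, 2] # electrons in each single-orbital state
  nel <- matrix(nel_of[as.vector(ks) + 1L], nrow(ks), ncol(ks))
  sgn <- rep(1, nst)
  # environment electrons located before each kept orbital (in mode order)
  for (kk in seq_along(keep)) {
    p <- keep[kk]
    env_before <- setdiff(seq_len(p - 1), keep)
    if (length(env_before)) {
      crossings <- rowSums(nel[, env_before, drop = FALSE]) * nel[, p]
      sgn <- sgn * (-1)^(crossings %% 2)
    }
  }
  sgn
}

#' Mutual information between two orbitals (nats)
#'
#' \eqn{I_{ij} = S(rho_i) + S(rho_j) - S(rho_{ij})}; bounded by 2 log 4 and
#' bounding the pair entanglement from above.
#'
#' @param rho_i,rho_j 4x4 one-orbital RDMs.
#' @param rho_ij 16x16 two-orbital RDM.
#' @return mutual information in nats.
#' @export
mutual_information_rdm <- function(rho_i, rho_j, rho_ij) {
  von_neumann_entropy(rho_i) + von_neumann_entropy(rho_j) -
    von_neumann_entropy(rho_ij)
}

#' Superselection block check for a two-orbital RDM
#'
#' For particle-number- and Sz-conserving states the two-orbital RDM is
#' block-diagonal over (N, 2Sz) sectors.  Returns the largest off-block
#' magnitude.
#'
#' @param rho_ij 16x16 two-orbital RDM.
#' @return maximum absolute off-block element.
#' @export
offblock_magnitude <- function(rho_ij) {
  sec <- two_orbital_sectors()
  same <- outer(sec$N, sec$N, "==") & outer(sec$twoSz, sec$twoSz, "==")
  max(abs(rho_ij[!same]))
}

#' Partial trace of a two-orbital RDM onto one factor
#'
#' @param rho_ij 16x16 two-orbital RDM (left factor slow).
#' @param which 1 for the left factor, 2 for the right.
#' @return 4x4 one-orbital RDM.
#' @export
reduce_two_orbital_rdm <- function(rho_ij, which = 1) {
  arr <- array(rho_ij, dim = c(4, 4, 4, 4)) # [rR, rL, cR, cL]
  if (which == 1) {
    out <- matrix(0, 4, 4)
    for (r in 1:4) out <- out + arr[r, , r, ]
  } else {
    out <- matrix(0, 4, 4)
    for (r in 1:4) out <- out + arr[, r, , r]
  }
  out
}
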