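# Closed-form model states: the idealized two-electron covalent bond in a
# symmetrically orthogonalized atomic-orbital pair, GHZ/W qubit registers,
# and a synthetic covalent-to-ionic interpolation family.  These fixtures
# exercise every entanglement routine without an electronic-structure run.

#' Symmetric (Loewdin) orthogonalization of an overlapping orbital pair
#'
#' For two normalized atomic orbitals with overlap \eqn{S = <phi_L|phi_R>},
#' returns the coefficients \eqn{(a, b)} expressing the symmetrically
#' orthogonalized left orbital as \eqn{a phi_L + b phi_R} (the right orbital
#' follows by L/R exchange):
#' \deqn{a = (1/2)(1/\sqrt{1+S} + 1/\sqrt{1-S}), \quad
#'       b = (1/2)(1/\sqrt{1+S} - 1/\sqrt{1-S}).}
#'
#' @param S overlap in `[0, 1)`.
#' @return named numeric vector with elements `a` and `b`; the pair is
#'   orthonormal under the metric `rbind(c(1, S), c(S, 1))`.
#' @examples
#' symmetric_orthogonalization(0)    # (1, 0)
#' symmetric_orthogonalization(0.5)
#' @export
symmetric_orthogonalization <- function(S) {
  stopifnot(is.numeric(S), length(S) == 1L, is.finite(S))
  if (S < 0 || S >= 1) {
    stop("invalid overlap: S must lie in [0, 1), got ", S)
  }
  a <- 0.5 * (1 / sqrt(1 + S) + 1 / sqrt(1 - S))
  b <- 0.5 * (1 / sqrt(1 + S) - 1 / sqrt(1 - S))
  c(a = a, b = b)
}

#' The idealized two-orbital covalent bond state
#'
#' The electron pair in the bonding orbital, re-expressed in the
#' symmetrically orthogonalized atomic orbitals: amplitudes +1/2 on
#' |0,ud>, |u,d>, |ud,0> and -1/2 on |d,u>.  The minus sign is fixed by the
#' site-ascending, up-before-down creation-operator ordering.
#'
#' @return object of class `two_orbital_state`: a numeric vector of length
#'   16 over the two-orbital product Fock basis (left orbital slow).
#' @export
bond_state <- function() {
  v <- numeric(16)
  lab <- two_orbital_labels()
  v[match("|0,ud>", lab)] <- 0.5
  v[match("|u,d>",  lab)] <- 0.5
  v[match("|d,u>",  lab)] <- -0.5
  v[match("|ud,0>", lab)] <- 0.5
  structure(v, class = "two_orbital_state", labels = lab)
}

#' GHZ state on K qubits
#'
#' @param K number of qubits (at least 3).
#' @return object of class `qubit_state`: amplitude vector of length 2^K
#'   (qubit 1 slowest), \eqn{(|0...0> + |1...1>)/\sqrt 2}.
#' @export
ghz_state <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1L)
  K <- as.integer(K)
  if (K < 3L) stop("invalid size: GHZ register needs K >= 3, got ", K)
  v <- numeric(2^K)
  v[1] <- 1 / sqrt(2)
  v[2^K] <- 1 / sqrt(2)
  structure(v, class = "qubit_state", K = K)
}

#' W state on K qubits
#'
#' @param K number of qubits (at least 3).
#' @return object of class `qubit_state`: equal superposition of the K
#'   single-excitation basis states.
#' @export
w_state <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1L)
  K <- as.integer(K)
  if (K < 3L) stop("invalid size: W register needs K >= 3, got ", K)
  v <- numeric(2^K)
  for (k in seq_len(K)) {
    v[2^(K - k) + 1] <- 1 / sqrt(K) # qubit k excited (qubit 1 slowest)
  }
  structure(v, class = "qubit_state", K = K)
}

#' Synthetic covalent-to-ionic interpolation family
#'
#' A normalized interpolation between the covalent bond state (lambda = 0)
#' and the fully ionic product state |ud,0> (lambda = 1):
#' \deqn{|psi(lambda)> \propto (1-lambda) |Psi_bond> + lambda |ud,0>.}
#' Used for monotonicity testing of pairwise entanglement under increasing
#' ionicity; it is a synthetic family, not a reproduction of any published
#' functional form.
#'
#' @param lambda mixing parameter in `[0, 1]`.
#' @return `two_orbital_state`.
#' @export
ionicity_family <- function(lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (lambda < 0 || lambda > 1) {
    stop("range error: lambda must lie in [0, 1], got ", lambda)
  }
  v <- (1 - lambda) * unclass(bond_state())
  lab <- two_orbital_labels()
  v[match("|ud,0>", lab)] <- v[match("|ud,0>", lab)] + lambda
  v <- v / sqrt(sum(v^2))
  structure(v, class = "two_orbital_state", labels = lab)
}

#' Reconstruct the bond state from an overlapping orbital pair
#'
#' End-to-end identity of the single-bond analysis: doubly occupy the
#' bonding orbital built from two atomic orbitals with overlap `S`, then
#' re-express the state in the symmetrically orthogonalized pair.  The
#' result is independent of `S` and equals `bond_state()`.
#'
#' @param S overlap in `[0, 1)`.
#' @return `two_orbital_state`.
#' @export
bond_state_from_overlap <- function(S) {
  ab <- symmetric_orthogonalization(S)
  # bonding orbital phi = (phi_L + phi_R)/sqrt(2(1+S)); express phi over the
  # orthonormal pair (tilde_L, tilde_R): invert the 2x2 coefficient map.
  Tmat <- rbind(c(ab["a"], ab["b"]), c(ab["b"], ab["a"])) # tilde = T %*% (L,R)
  cf <- solve(t(Tmat), c(1, 1) / sqrt(2 * (1 + S)))       # phi over tilde
  cl <- cf[1]; cr <- cf[2]
  # phi_up^dag phi_dn^dag |vac> expanded over modes (Lu, Ld, Ru, Rd)
  v <- numeric(16)
  lab <- two_orbital_labels()
  v[match("|ud,0>", lab)] <- cl * cl
  v[match("|u,d>",  lab)] <- cl * cr
  v[match("|d,u>",  lab)] <- -cr * cl  # Ru^dag Ld^dag = -Ld^dag Ru^dag
  v[match("|0,ud>", lab)] <- cr * cr
  structure(v, class = "two_orbital_state", labels = lab)
}
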