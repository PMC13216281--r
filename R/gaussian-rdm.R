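# Orbital RDMs of closed-shell mean-field (Slater determinant) states.
#
# A determinant is a fermionic Gaussian state: every orbital RDM is a
# functional of the one-particle RDM restricted to the orbitals kept.  The
# two-orbital RDM is built exactly by diagonalizing the 4x4 mode correlation
# matrix, forming the product state over natural modes and rotating back in
# Fock space (Givens lifts), so all coherence signs follow the package's
# fixed mode ordering.

# Givens decomposition of a special orthogonal matrix: list of rotations
# (a, b, theta) such that V = prod_k G(a_k, b_k, theta_k).
givens_decompose <- function(V, tol = 1e-12) {
  n <- nrow(V)
  if (abs(det(V) - 1) > 1e-8) stop("V must be special orthogonal")
  rots <- list()
  W <- V
  for (j in seq_len(n - 1)) {
    for (i in n:(j + 1)) {
      a <- W[i - 1, j]; b <- W[i, j]
      if (abs(b) > tol) {
        r <- sqrt(a^2 + b^2)
        cth <- a / r; sth <- b / r
        G <- diag(n)
        G[i - 1, i - 1] <- cth; G[i, i] <- cth
        G[i - 1, i] <- sth; G[i, i - 1] <- -sth
        W <- G %*% W
        rots[[length(rots) + 1]] <- c(i - 1, i, atan2(sth, cth))
      }
    }
  }
  # W is now diagonal +-1 with even number of -1; pair them as pi rotations
  dd <- diag(W)
  neg <- which(dd < 0)
  if (length(neg) %% 2 != 0) stop("inconsistent Givens decomposition")
  while (length(neg) >= 2) {
    rots[[length(rots) + 1]] <- c(neg[1], neg[2], pi)
    neg <- neg[-(1:2)]
  }
  # G_m ... G_1 V = R  =>  V = G_1^T ... G_m^T R: return in application
  # order (transposed eliminations first, pi-rotations for R last).
  lapply(seq_along(rots), function(k) {
    r <- rots[[k]]
    if (abs(r[3] - pi) < 1e-14) r else c(r[1], r[2], -r[3])
  })
}

# Lift a single-particle Givens rotation on modes (a, b) by angle theta to
# the 2^n-dimensional Fock space: expm(theta (f_a^dag f_b - f_b^dag f_a)).
fock_givens <- function(a, b, theta, F_ops) {
  FD <- lapply(F_ops, function(m) t(m))
  K <- theta * (FD[[a]] %*% F_ops[[b]] - FD[[b]] %*% F_ops[[a]])
  # K is real skew-symmetric: expm via eigen of the hermitian iK
  e <- eigen(1i * K)
  Re(e$vectors %*% diag(exp(-1i * e$values)) %*% Conj(t(e$vectors)))
}

#' Two-orbital RDM of a closed-shell determinant state
#'
#' @param Dij 2x2 per-spin one-particle RDM block over orbitals (i, j):
#'   entries `<f_i^dag f_j>` for one spin channel (closed shell: both spins
#'   equal; for a spin-free 1RDM gamma pass `gamma[c(i,j), c(i,j)] / 2`).
#' @return 16x16 two-orbital RDM in the product Fock basis (left = i slow).
#' @export
determinant_two_orbital_rdm <- function(Dij) {
  stopifnot(is.matrix(Dij), all(dim(Dij) == 2))
  e <- eigen((Dij + t(Dij)) / 2, symmetric = TRUE)
  occ <- pmin(pmax(e$values, 0), 1)
  v <- e$vectors
  if (det(v) < 0) v[, 1] <- -v[, 1]
  # 4 modes (i_up, i_dn, j_up, j_dn); spatial rotation v acts identically on
  # the up modes (1,3) and the dn modes (2,4)
  V4 <- diag(4)
  V4[c(1, 3), c(1, 3)] <- v
  V4[c(2, 4), c(2, 4)] <- v
  F_ops <- jw_annihilation(4)
  U <- diag(16)
  for (r in givens_decompose(V4)) {
    U <- U %*% fock_givens(r[1], r[2], r[3], F_ops)
  }
  lam <- numeric(16)
  nocc <- c(occ[1], occ[1], occ[2], occ[2]) # natural modes, bit order
  for (idx in 0:15) {
    p <- 1
    for (a in 1:4) {
      bit <- bitwAnd(bitwShiftR(idx, a - 1L), 1L)
      p <- p * if (bit) nocc[a] else 1 - nocc[a]
    }
    lam[idx + 1] <- p
  }
  rho_bit <- U %*% (t(U) * lam) # U diag(lam) U^T
  perm <- fock_basis_permutation(2)
  rho_bit[perm, perm]
}

#' One-orbital RDM of a closed-shell determinant state
#'
#' Diagonal in the Fock basis with occupation probabilities from the
#' orbital's spin occupation `n = gamma_ii / 2`.
#'
#' @param n_spin per-spin occupation of the orbital, in `[0, 1]`.
#' @return 4x4 diagonal density matrix.
#' @export
determinant_one_orbital_rdm <- function(n_spin) {
  stopifnot(n_spin >= -1e-10, n_spin <= 1 + 1e-10)
  n <- pmin(pmax(n_spin, 0), 1)
  diag(c((1 - n)^2, n * (1 - n), n * (1 - n), n^2))
}
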