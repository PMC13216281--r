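# Fock-space conventions shared by every module.
#
# Single-orbital Fock basis order: |0>, |up>, |dn>, |updn>, with
# |updn> = f_up^dag f_dn^dag |vac>.  Multi-orbital product bases put the
# left/lower orbital index on the slower axis.  Fermionic modes are ordered
# site-ascending with up before down, i.e. (1up, 1dn, 2up, 2dn, ...); all
# amplitude signs follow from applying creation operators in that order.

#' Occupation bits of the single-orbital Fock states
#'
#' @return integer matrix 4 x 2 with columns (n_up, n_dn) for the basis
#'   states |0>, |up>, |dn>, |updn> in that order.
#' @keywords internal
orbital_occupations <- function() {
  matrix(c(0L, 0L,
           1L, 0L,
           0L, 1L,
           1L, 1L), ncol = 2, byrow = TRUE,
         dimnames = list(c("0", "u", "d", "ud"), c("up", "dn")))
}

#' Jordan-Wigner annihilation operators for n fermionic modes
#'
#' Mode 1 is the least-significant occupation bit of the 2^n-dimensional
#' basis index (bit-ordered basis).  Returned operators satisfy the CAR
#' algebra with the site-ascending, up-before-down sign convention.
#'
#' @param nmodes number of fermionic modes.
#' @return list of 2^nmodes square matrices (annihilation operators).
#' @keywords internal
jw_annihilation <- function(nmodes) {
  I2 <- diag(2)
  Zm <- diag(c(1, -1))
  sm <- matrix(c(0, 0, 1, 0), 2, 2) # |0><1|
  lapply(seq_len(nmodes), function(a) {
    M <- matrix(1, 1, 1)
    for (b in nmodes:1) {
      fac <- if (b < a) Zm else if (b == a) sm else I2
      M <- M %x% fac
    }
    M
  })
}

# Map between the bit-ordered basis (mode occupation bits, JW order) and the
# orbital-ordered product basis |k_1> x |k_2> x ... with k in {0,u,d,ud} and
# orbital 1 slowest.  Both are bases of the same 4^n space; `perm[s]` gives,
# for orbital-ordered index s (1-based), the corresponding bit-ordered index.
fock_basis_permutation <- function(norb) {
  occ <- orbital_occupations()
  nst <- 4L^norb
  perm <- integer(nst)
  for (s in seq_len(nst)) {
    rem <- s - 1L
    ks <- integer(norb)
    for (p in norb:1) { # orbital norb fastest
      ks[p] <- rem %% 4L
      rem <- rem %/% 4L
    }
    bits <- 0L
    for (p in seq_len(norb)) {
      bu <- occ[ks[p] + 1L, 1L]
      bd <- occ[ks[p] + 1L, 2L]
      bits <- bits + bu * 2L^(2L * (p - 1L)) + bd * 2L^(2L * (p - 1L) + 1L)
    }
    perm[s] <- bits + 1L
  }
  perm
}

#' Particle number and Sz labels of the two-orbital product basis
#'
#' @return data.frame with one row per basis state (16 rows) giving the
#'   orbital-ordered index, total particle number N and total 2*Sz.
#' @keywords internal
two_orbital_sectors <- function() {
  occ <- orbital_occupations()
  kL <- rep(0:3, each = 4)
  kR <- rep(0:3, times = 4)
  data.frame(
    index = 1:16,
    N  = occ[kL + 1, 1] + occ[kL + 1, 2] + occ[kR + 1, 1] + occ[kR + 1, 2],
    twoSz = (occ[kL + 1, 1] - occ[kL + 1, 2]) + (occ[kR + 1, 1] - occ[kR + 1, 2])
  )
}

#' Labels of the 16 two-orbital basis states
#' @keywords internal
two_orbital_labels <- function() {
  lab <- c("0", "u", "d", "ud")
  as.vector(t(outer(lab, lab, function(a, b) paste0("|", a, ",", b, ">"))))
}
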