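# Entanglement measures: pure-state bipartite entropy, relative entropy of
# entanglement for mixed two-orbital states, and genuine multipartite
# entanglement (GME) of pure cluster states.

#' Bipartite entanglement of a pure state
#'
#' Von Neumann entropy of the reduced state of subsystem A; for pure global
#' states this equals the entropy of the complement.
#'
#' @param psi amplitude vector over a product basis.
#' @param keep factor indices forming subsystem A.
#' @param dims factor dimensions.
#' @param fermionic if `TRUE`, `dims` must be all-4 orbital factors and the
#'   mode-reordering parity is applied before tracing.
#' @return entanglement in nats.
#' @export
pure_bipartite_entanglement <- function(psi, keep, dims, fermionic = FALSE) {
  nrm <- sum(Mod(psi)^2)
  if (abs(nrm - 1) > 1e-8) stop("invalid usage: state must be pure and normalized")
  if (fermionic) {
    stopifnot(all(dims == 4))
    psi <- psi * mode_reorder_signs(length(dims), sort(keep))
  }
  rho <- partial_trace_pure(psi, keep, dims)
  von_neumann_entropy(rho / sum(diag(rho)))
}

# ---------------------------------------------------------------------------
# Relative entropy of entanglement, E(rho) = min_{sigma separable}
# Tr[rho (log rho - log sigma)], for bipartite dA x dB systems.
# Algorithm: Frank-Wolfe over the separable set whose extreme points are
# pure product states.  The linear subproblem min_x <x x^dag, grad> over
# product states is solved by alternating smallest-eigenvector iterations on
# the two factors; periodically the weights of the collected product atoms
# are re-optimized (fully corrective step).  The Frank-Wolfe gap bounds the
# suboptimality, so the returned value is a certified upper bound tight to
# `tol`.
# ---------------------------------------------------------------------------

ree_gradient <- function(rho, sigma) {
  es <- eigen(sigma, symmetric = TRUE)
  w <- pmax(es$values, 1e-300)
  V <- es$vectors
  rt <- t(V) %*% rho %*% V
  lw <- log(w)
  W <- outer(w, w, "-")
  L <- outer(lw, lw, "-")
  phi <- ifelse(abs(W) > 1e-13, L / ifelse(abs(W) > 1e-13, W, 1),
                1 / outer(w, w, function(a, b) (a + b) / 2))
  -(V %*% (rt * phi) %*% t(V))
}

ree_value <- function(rho, sigma, s_rho) {
  es <- eigen(sigma, symmetric = TRUE)
  w <- pmax(es$values, 1e-300)
  logs <- es$vectors %*% (t(es$vectors) * log(w))
  -sum(rho * t(logs)) - s_rho
}

best_product_direction <- function(G, dA, dB, tries = 6L, iters = 80L) {
  Gr <- array(G, dim = c(dB, dA, dB, dA))
  best <- NULL; bestval <- Inf
  for (t in seq_len(tries)) {
    b <- rnorm(dB); b <- b / sqrt(sum(b^2))
    for (it in seq_len(iters)) {
      MA <- matrix(0, dA, dA)
      for (p in 1:dB) for (q in 1:dB) {
        MA <- MA + b[p] * b[q] * Gr[p, , q, ]
      }
      a <- eigen((MA + t(MA)) / 2, symmetric = TRUE)$vectors[, dA]
      MB <- matrix(0, dB, dB)
      for (p in 1:dA) for (q in 1:dA) {
        MB <- MB + a[p] * a[q] * Gr[, p, , q]
      }
      bn <- eigen((MB + t(MB)) / 2, symmetric = TRUE)$vectors[, dB]
      if (sum((bn - b * sign(sum(b * bn) + 1e-300))^2) < 1e-24) { b <- bn; break }
      b <- bn
    }
    x <- as.vector(outer(b, a)) # index = p_B + dB*(p_A-1): A slow, B fast
    val <- as.numeric(t(x) %*% G %*% x)
    if (val < bestval) { bestval <- val; best <- x }
  }
  list(x = best, val = bestval)
}

#' Relative entropy of entanglement of a bipartite mixed state
#'
#' Minimum quantum relative entropy from `rho` to the convex set of
#' separable states of the `dA` x `dB` factors (unrestricted separability).
#' Solved by away-step Frank-Wolfe whose linear subproblem (best pure
#' product state) uses alternating smallest-eigenvector iterations; the
#' Frank-Wolfe gap certifies the returned upper bound.  With
#' `superselect = TRUE` the separable set is additionally restricted by
#' local particle-number/Sz superselection; since every local (N, Sz)
#' sector of a single orbital is one-dimensional, that set is the diagonal
#' states and the minimum has the closed form
#' `S(diag(rho)) - S(rho)`.
#'
#' The `factors` argument selects the allowed product factors: `"real"`
#' (default) restricts to real product states, the convention under which
#' the published reference values for real molecular wavefunctions are
#' reproduced; `"complex"` is the mathematically unrestricted separable
#' set (required, e.g., to match the Bell-diagonal closed form, whose
#' closest separable states need complex factors).
#'
#' @param rho density matrix of dimension `dA * dB` (A the slow factor).
#' @param dA,dB local dimensions.
#' @param tol convergence threshold on the Frank-Wolfe gap (nats).
#' @param maxit maximum Frank-Wolfe iterations.
#' @param seed RNG seed for the product-state searches.
#' @param tries random restarts of the product-state search per iteration.
#' @param factors `"real"` or `"complex"` product factors.
#' @param superselect use the superselected separable set (closed form).
#' @return list with `value` (nats), `gap` (certified suboptimality bound;
#'   0 for the closed form), `iterations`.
#' @export
relative_entropy_of_entanglement <- function(rho, dA = 4, dB = 4,
                                             tol = 1e-6, maxit = 2000L,
                                             seed = 1L, tries = 4L,
                                             factors = c("real", "complex"),
                                             superselect = FALSE) {
  factors <- match.arg(factors)
  d <- dA * dB
  stopifnot(nrow(rho) == d, ncol(rho) == d)
  if (max(abs(rho - t(rho))) > 1e-8) stop("rho must be symmetric (real)")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("rho must be positive semidefinite")
  if (superselect) {
    pd <- diag(rho)
    pd <- pd[pd > 1e-14]
    evp <- ev[ev > 1e-14]
    val <- -sum(pd * log(pd)) + sum(evp * log(evp))
    return(list(value = max(val, 0), gap = 0, iterations = 0L))
  }
  out <- cpp_ree(rho, dA, dB, tol, maxit, as.integer(seed),
                 as.integer(tries), factors == "complex")
  out[c("value", "gap", "iterations", "sigma")]
}

#' PPT (partial transpose) negativity certificate
#'
#' Minimum eigenvalue of the partial transpose; a negative value certifies
#' entanglement (fast screen used before running the iterative solver).
#'
#' @inheritParams relative_entropy_of_entanglement
#' @return smallest eigenvalue of the partially transposed state.
#' @export
ppt_minimum_eigenvalue <- function(rho, dA = 4, dB = 4) {
  arr <- array(rho, dim = c(dB, dA, dB, dA))
  arr <- aperm(arr, c(3, 2, 1, 4)) # transpose the B factor
  rt <- matrix(arr, dA * dB, dA * dB)
  min(eigen((rt + t(rt)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# ---------------------------------------------------------------------------
# Genuine multipartite entanglement
# ---------------------------------------------------------------------------

#' Genuine multipartite entanglement of a pure register state
#'
#' \eqn{GME = \min_A S(\rho_A)} over bipartitions A|rest.  `exhaustive`
#' mode enumerates all 2^(K-1)-1 bipartitions; `mps-cuts` mode minimizes
#' over single-factor entropies, two-factor entropies and contiguous chain
#' cuts only (the matrix-product-state approximation used for larger
#' clusters).
#'
#' @param psi pure-state amplitude vector.
#' @param dims factor dimensions (e.g. `rep(2, K)` for qubits, `rep(4, K)`
#'   for orbital Fock factors).
#' @param mode `"exhaustive"` or `"mps-cuts"`.
#' @param fermionic apply fermionic mode-reordering parities (orbital
#'   factors).
#' @return list with `value` (nats), `normalized` (value / log(4), the
#'   reporting convention for orbital clusters), `minimizer` (factor index
#'   set), `mode`.
#' @export
gme <- function(psi, dims, mode = c("exhaustive", "mps-cuts"),
                fermionic = FALSE) {
  mode <- match.arg(mode)
  K <- length(dims)
  stopifnot(K >= 2, length(psi) == prod(dims))
  if (abs(sum(Mod(psi)^2) - 1) > 1e-8) stop("state must be pure (unit norm)")
  subsets <- list()
  if (mode == "exhaustive") {
    if (K > 12) stop("exhaustive enumeration limited to 12 factors")
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
    S <- pure_bipartite_entanglement(psi, A, dims, fermionic = fermionic)
    if (S < best - 1e-15) { best <- S; bestA <- A }
  }
  list(value = best, normalized = best / log(4), minimizer = bestA, mode = mode)
}
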