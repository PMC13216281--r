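# MEAO construction: maximize the inter-center coherence objective
#
#   F(B) = sum_{i<j, inter-center} |G[i,i,j,j]|^2 + |G[i,j,j,i]|^2,
#
# over partition-preserving orbital rotations, where G is the up-down block
# of the spin-resolved 2RDM, G[i,j,k,l] = <f_iu^dag f_jd^dag f_ld f_ku>.
# For a closed-shell determinant G[i,j,k,l] = D_ik D_jl with D = gamma/2,
# so F = 2 sum_{i<j, inter} D_ij^4 and everything reduces to cheap matrix
# algebra; for correlated states the full 4-index tensor is contracted.
# Maximization: safeguarded Newton-Raphson on the antisymmetric generator
# (diagonal Hessian by central differences, Levenberg shift when an entry
# is non-positive, backtracking line search; monotone ascent guaranteed).

inter_center_mask <- function(atom) {
  outer(atom, atom, "!=")
}

#' MEAO proxy objective from a spin-resolved 2RDM
#'
#' @param G either an `n^4` array (the up/down 2RDM block
#'   `G[i,j,k,l] = <f_iu+ f_jd+ f_ld f_ku>` in the partition basis) or an
#'   object of class `mf_gamma` (closed-shell mean-field shortcut holding
#'   the per-spin 1RDM `D`).
#' @param atom integer vector assigning each orbital of the basis to an
#'   atomic center.
#' @return the dimensionless objective value (non-negative; only
#'   inter-center pairs contribute).
#' @export
f_meao <- function(G, atom) {
  if (inherits(G, "mf_gamma")) {
    D <- G$D
    stopifnot(nrow(D) == length(atom))
    mask <- inter_center_mask(atom)
    # F = sum_{i<j inter} 2 D_ij^4 = sum over ordered inter pairs of D_ij^4
    return(sum((D * mask)^4))
  }
  n <- length(atom)
  stopifnot(all(dim(G) == n))
  val <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (atom[i] == atom[j]) next
    val <- val + G[i, i, j, j]^2 + G[i, j, j, i]^2
  }
  val
}

#' Closed-shell mean-field 2RDM shortcut
#'
#' @param gamma_loc spin-free 1RDM in the partition's localized basis.
#' @return object of class `mf_gamma`.
#' @export
mf_gamma <- function(gamma_loc) {
  stopifnot(is.matrix(gamma_loc), nrow(gamma_loc) == ncol(gamma_loc))
  structure(list(D = gamma_loc / 2), class = "mf_gamma")
}

# Gradient of F with respect to the antisymmetric generator X (expansion
# around the current basis, X = 0): returns matrix M with grad = M - t(M)
# projected on the partition blocks.
f_meao_gradient_raw <- function(G, atom) {
  n <- length(atom)
  mask <- inter_center_mask(atom)
  if (inherits(G, "mf_gamma")) {
    D <- G$D
    # F = sum_{ordered i!=j inter} D_ij^4, dF = sum_ij W_ij dD_ij
    W <- 4 * (D * mask)^3
    M <- D %*% W + t(D) %*% W
    return(M)
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (atom[i] == atom[j]) next
    g1 <- G[i, i, j, j]; g2 <- G[i, j, j, i]
    for (a in seq_len(n)) {
      M[a, i] <- M[a, i] + 2 * g1 * (G[a, i, j, j] + G[i, a, j, j]) +
        2 * g2 * (G[a, j, j, i] + G[i, j, j, a])
      M[a, j] <- M[a, j] + 2 * g1 * (G[i, i, a, j] + G[i, i, j, a]) +
        2 * g2 * (G[i, a, j, i] + G[i, j, a, i])
    }
  }
  M
}

#' Gradient of the MEAO objective over partition-preserving generators
#'
#' @inheritParams f_meao
#' @param blocks list of orbital index vectors, one per atom.
#' @return antisymmetric matrix (nonzero only inside atom blocks) with the
#'   derivative of `f_meao` with respect to the generator `X` of the
#'   rotation `exp(X)` applied to the current basis.
#' @export
f_meao_gradient <- function(G, atom, blocks = split(seq_along(atom), atom)) {
  M <- f_meao_gradient_raw(G, atom)
  grad <- M - t(M)
  keep <- matrix(FALSE, length(atom), length(atom))
  for (b in blocks) keep[b, b] <- TRUE
  grad * keep
}

# Rotate the 2RDM representation by the orthogonal matrix U (columns = new
# orbitals over current ones).
rotate_meao_input <- function(G, U) {
  if (inherits(G, "mf_gamma")) {
    return(mf_gamma(2 * (t(U) %*% G$D %*% U)))
  }
  n <- dim(G)[1]
  Gm <- matrix(G, n, n^3)               # i x (jkl)
  G1 <- array(crossprod(U, Gm), dim = rep(n, 4))      # i rotated
  G1 <- aperm(G1, c(2, 3, 4, 1))
  Gm <- matrix(G1, n, n^3)
  G2 <- array(crossprod(U, Gm), dim = rep(n, 4))      # j rotated
  G2 <- aperm(G2, c(2, 3, 4, 1))
  Gm <- matrix(G2, n, n^3)
  G3 <- array(crossprod(U, Gm), dim = rep(n, 4))      # k rotated
  G3 <- aperm(G3, c(2, 3, 4, 1))
  Gm <- matrix(G3, n, n^3)
  G4 <- array(crossprod(U, Gm), dim = rep(n, 4))      # l rotated
  aperm(G4, c(2, 3, 4, 1))
}

# Orthogonal exponential of a block-antisymmetric generator.
block_expm <- function(X, blocks) {
  n <- nrow(X)
  U <- diag(n)
  for (b in blocks) {
    if (length(b) < 2) next
    Xb <- X[b, b, drop = FALSE]
    e <- eigen(1i * Xb)
    Ub <- Re(e$vectors %*% (exp(-1i * e$values) * Conj(t(e$vectors))))
    U[b, b] <- Ub
  }
  U
}

# Pack/unpack the free generator coordinates (upper triangles of blocks).
generator_coords <- function(blocks) {
  out <- list()
  for (b in blocks) {
    if (length(b) < 2) next
    m <- length(b)
    iu <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    out[[length(out) + 1]] <- cbind(b[iu[, 1]], b[iu[, 2]])
  }
  if (!length(out)) return(matrix(0L, 0, 2))
  do.call(rbind, out)
}

coords_to_generator <- function(theta, coords, n) {
  X <- matrix(0, n, n)
  if (nrow(coords)) {
    X[coords] <- theta
    X <- X - t(X)
  }
  X
}

#' Maximize the MEAO objective over partition-preserving rotations
#'
#' Safeguarded Newton-Raphson ascent with multiple restarts (identity start
#' plus seeded random block rotations); the best objective over restarts
#' wins, ties broken by lowest restart index.  Deterministic given `seed`.
#'
#' @param G 2RDM input in the starting localized basis (`mf_gamma` or the
#'   4-index up/down block).
#' @param atom atom assignment of the localized orbitals.
#' @param seed integer seed for the random restarts.
#' @param restarts total number of starts (first is the identity).
#' @param gtol convergence threshold on the gradient max-norm.
#' @param maxit maximum Newton iterations per restart.
#' @return list with `U` (orthogonal rotation, columns = MEAOs over the
#'   starting localized orbitals), `objective`, `trace` (per accepted
#'   iteration: objective, gradient norm, step norm), `restart` (winning
#'   restart index), `converged`.
#' @export
optimize_meao <- function(G, atom, seed = 1L, restarts = 4L,
                          gtol = 1e-8, maxit = 200L) {
  n <- length(atom)
  blocks <- split(seq_len(n), atom)
  coords <- generator_coords(blocks)
  npar <- nrow(coords)
  if (npar == 0L) {
    return(list(U = diag(n), objective = f_meao(G, atom),
                trace = data.frame(objective = f_meao(G, atom),
                                   grad_norm = 0, step_norm = 0),
                restart = 1L, converged = TRUE))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  starts <- vector("list", restarts)
  starts[[1]] <- diag(n)
  if (restarts > 1) {
    for (r in 2:restarts) {
      X0 <- coords_to_generator(stats::rnorm(npar, sd = 0.3), coords, n)
      starts[[r]] <- block_expm(X0, blocks)
    }
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    U <- starts[[r]]
    Gr <- rotate_meao_input(G, U)
    fcur <- f_meao(Gr, atom)
    tr <- list()
    converged <- FALSE
    hd_cache <- NULL
    hd_age <- 0L
    for (it in seq_len(maxit)) {
      grad <- f_meao_gradient(Gr, atom, blocks)
      gvec <- grad[coords]
      gnorm <- max(abs(gvec))
      if (gnorm < gtol) { converged <- TRUE
        tr[[length(tr) + 1]] <- c(fcur, gnorm, 0); break }
      # diagonal Hessian by central differences along each coordinate,
      # refreshed every few iterations (the curvature varies slowly)
      if (is.null(hd_cache) || hd_age >= 5L) {
        h <- 1e-4
        hd_cache <- vapply(seq_len(npar), function(k) {
          th <- numeric(npar)
          th[k] <- h
          Xp <- coords_to_generator(th, coords, n)
          fp <- f_meao(rotate_meao_input(Gr, block_expm(Xp, blocks)), atom)
          fm <- f_meao(rotate_meao_input(Gr, block_expm(-Xp, blocks)), atom)
          (fp + fm - 2 * fcur) / h^2
        }, numeric(1))
        hd_age <- 0L
      }
      hd <- hd_cache
      hd_age <- hd_age + 1L
      # ascent: need negative-definite Hessian model; Levenberg shift
      shift <- max(0, max(hd) + 1e-8)
      step <- gvec / (shift - hd + 1e-12)
      # backtracking line search on t in (0, 1]
      tstep <- 1
      accepted <- FALSE
      for (ls in 1:30) {
        Xs <- coords_to_generator(tstep * step, coords, n)
        Us <- block_expm(Xs, blocks)
        fnew <- f_meao(rotate_meao_input(Gr, Us), atom)
        if (fnew > fcur + 1e-4 * tstep * sum(gvec * step)) {
          U <- U %*% Us
          Gr <- rotate_meao_input(G, U)
          fcur <- f_meao(Gr, atom)
          tr[[length(tr) + 1]] <- c(fcur, gnorm, sqrt(sum((tstep * step)^2)))
          accepted <- TRUE
          break
        }
        tstep <- tstep / 2
      }
      if (!accepted) {
        if (hd_age > 1L) { hd_cache <- NULL; next } # retry, fresh curvature
        converged <- gnorm < 1e-6
        tr[[length(tr) + 1]] <- c(fcur, gnorm, 0)
        break
      }
    }
    trace <- as.data.frame(do.call(rbind, tr))
    names(trace) <- c("objective", "grad_norm", "step_norm")
    cand <- list(U = U, objective = fcur, trace = trace, restart = r,
                 converged = converged)
    if (is.null(best) || cand$objective > best$objective + 1e-10) best <- cand
  }
  best
}

#' Sum of inter-center pair entanglements (diagnostic objective)
#'
#' Direct evaluation of the physically motivated objective that the
#' coherence proxy replaces: the sum of relative-entropy entanglements over
#' all inter-center orbital pairs.  Only feasible for small systems.
#'
#' @param rdm_fun function `(i, j) -> 16x16` two-orbital RDM in the current
#'   basis.
#' @param atom atom assignment.
#' @param ... passed to [relative_entropy_of_entanglement()].
#' @return total inter-center entanglement in nats.
#' @export
inter_center_entanglement_sum <- function(rdm_fun, atom, ...) {
  n <- length(atom)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (atom[i] == atom[j]) next
    rho <- rdm_fun(i, j)
    if (ppt_minimum_eigenvalue(rho) > -1e-10) next # separable screen
    tot <- tot + relative_entropy_of_entanglement(rho, ...)$value
  }
  tot
}
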