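# Basis-set handling: parse the plain-text basis tables shipped with the
# package, attach shells to atoms, and build the per-shell normalization /
# Cartesian-to-spherical transforms consumed by the integral engine.
#
# Primitive coefficients are rescaled by the alpha-dependent part of the
# canonical primitive norm, (2a/pi)^(3/4) (4a)^(l/2); all remaining
# (alpha-independent) normalization, including the contracted-shell norm,
# is fixed numerically through the analytic same-center self-overlap, which
# also absorbs any non-normalized published contraction.

basis_aliases <- c("cc-pvdz" = "cc-pvdz",
                   "6-311++g(d,p)" = "6-311++gdp",
                   "6-311++gdp" = "6-311++gdp",
                   "minao" = "minao")

#' Load a basis-set definition
#'
#' @param name basis name (`"cc-pvdz"`, `"6-311++g(d,p)"`, `"minao"`), or a
#'   path to a basis table in the package's plain-text format.
#' @return named list: per element, a list of shells `list(l, exps, coefs)`.
#' @export
load_basis <- function(name) {
  key <- tolower(name)
  if (key %in% names(basis_aliases)) {
    path <- system.file("extdata", "basis",
                        paste0(basis_aliases[[key]], ".txt"),
                        package = "meaobond", mustWork = TRUE)
  } else if (file.exists(name)) {
    path <- name
  } else {
    stop("unknown basis set: ", name)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  el <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      el <- tok[2]
      out[[el]] <- list()
    } else if (tok[1] == "shell") {
      out[[el]][[length(out[[el]]) + 1]] <-
        list(l = as.integer(tok[2]), exps = numeric(0), coefs = numeric(0))
    } else {
      k <- length(out[[el]])
      out[[el]][[k]]$exps <- c(out[[el]][[k]]$exps, as.numeric(tok[1]))
      out[[el]][[k]]$coefs <- c(out[[el]][[k]]$coefs, as.numeric(tok[2]))
    }
  }
  structure(out, class = "basis_set", name = name)
}

# cartesian component exponent triples, canonical order (lx descending)
cart_triples <- function(l) {
  out <- list()
  for (lx in l:0) for (ly in (l - lx):0) {
    out[[length(out) + 1]] <- c(lx, ly, l - lx - ly)
  }
  do.call(rbind, out)
}

# raw real-solid-harmonic rows over cartesian components (unnormalized)
solid_harmonic_rows <- function(l) {
  if (l == 0) return(matrix(1, 1, 1))
  if (l == 1) { # m = -1 (y), 0 (z), +1 (x); cart order (x, y, z)
    return(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  }
  if (l == 2) { # cart order (xx, xy, xz, yy, yz, zz)
    return(rbind(
      c(0, 1, 0, 0, 0, 0),            # m=-2: xy
      c(0, 0, 0, 0, 1, 0),            # m=-1: yz
      c(-1, 0, 0, -1, 0, 2),          # m= 0: 3z^2 - r^2
      c(0, 0, 1, 0, 0, 0),            # m=+1: xz
      c(1, 0, 0, -1, 0, 0)))          # m=+2: x^2 - y^2
  }
  stop("angular momentum l > 2 not supported")
}

# analytic same-center overlap of the contracted raw-cartesian shell
cart_self_overlap <- function(l, exps, coefs) {
  tr <- cart_triples(l)
  nc <- nrow(tr)
  S <- matrix(0, nc, nc)
  gauss1d <- function(n, p) { # int x^n exp(-p x^2) dx
    if (n %% 2 == 1) return(0)
    if (n == 0) return(sqrt(pi / p))
    k <- n / 2
    prod(seq(1, n - 1, by = 2)) / (2 * p)^k * sqrt(pi / p)
  }
  for (a in seq_along(exps)) for (b in seq_along(exps)) {
    p <- exps[a] + exps[b]
    cc <- coefs[a] * coefs[b]
    for (i in 1:nc) for (j in 1:nc) {
      S[i, j] <- S[i, j] + cc *
        gauss1d(tr[i, 1] + tr[j, 1], p) *
        gauss1d(tr[i, 2] + tr[j, 2], p) *
        gauss1d(tr[i, 3] + tr[j, 3], p)
    }
  }
  S
}

#' Build the shell table for a molecule
#'
#' @param mol `molecule`.
#' @param basis basis name or `basis_set` object.
#' @return object of class `shell_table`: the list consumed by the integral
#'   engine plus AO metadata (`ao_atom`, `ao_l`, `ao_m`, `nao`).
#' @export
build_shells <- function(mol, basis) {
  if (!inherits(basis, "basis_set")) basis <- load_basis(basis)
  l <- integer(0); atom <- integer(0)
  exps <- list(); coefs <- list(); Tm <- list(); centers <- NULL
  ao_atom <- integer(0); ao_l <- integer(0); ao_m <- integer(0)
  for (ia in seq_len(mol$natm)) {
    el <- mol$symbols[ia]
    if (is.null(basis[[el]])) stop("basis has no element ", el)
    for (sh in basis[[el]]) {
      scaled <- sh$coefs * (2 * sh$exps / pi)^0.75 * (4 * sh$exps)^(sh$l / 2)
      Scc <- cart_self_overlap(sh$l, sh$exps, scaled)
      W <- solid_harmonic_rows(sh$l)
      nrm <- sqrt(diag(W %*% Scc %*% t(W)))
      W <- W / nrm
      l <- c(l, sh$l); atom <- c(atom, ia - 1L)
      exps[[length(exps) + 1]] <- sh$exps
      coefs[[length(coefs) + 1]] <- scaled
      Tm[[length(Tm) + 1]] <- W
      centers <- rbind(centers, mol$coords[ia, ])
      nsph <- nrow(W)
      ao_atom <- c(ao_atom, rep(ia, nsph))
      ao_l <- c(ao_l, rep(sh$l, nsph))
      ao_m <- c(ao_m, seq_len(nsph) - sh$l - 1L)
    }
  }
  structure(list(l = l, atom = atom, exps = exps, coefs = coefs, T = Tm,
                 centers = centers, ao_atom = ao_atom, ao_l = ao_l,
                 ao_m = ao_m, nao = length(ao_atom), mol = mol,
                 basis_name = attr(basis, "name")),
            class = "shell_table")
}
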