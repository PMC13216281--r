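# Correlation-graph construction and bond clustering (mutual-information
# graph over MEAOs), plus the active-space builder for multicenter
# clusters via the non-active 1RDM natural-occupation classification.

#' Build the mutual-information correlation graph over localized orbitals
#'
#' Edges connect inter-center orbital pairs whose mutual information
#' exceeds `eta * 2 log 4`.  With a `cas_solution` source the mutual
#' information is evaluated from the correlated wavefunction; with an
#' `mf_gamma`/matrix source it is evaluated from the determinant state via
#' the fermionic-Gaussian reduction (the mean-field correlation diagram).
#' Intra-atom pairs are recorded with `I = NA` and never create edges.
#'
#' @param source `cas_solution`, or the spin-free 1RDM (matrix) in the
#'   localized basis, for a closed-shell determinant state.
#' @param atom atom assignment of the localized orbitals.
#' @param eta edge threshold as a fraction of `I_max = 2 log 4`.
#' @return object of class `correlation_graph`: `nodes` (orbital, atom,
#'   entropy), `edges` (i, j, I, I_norm), `eta`, `adjacency`.
#' @export
build_correlation_graph <- function(source, atom, eta = 0.10) {
  n <- length(atom)
  Imax <- 2 * log(4)
  if (inherits(source, "cas_solution") ||
      inherits(source, "thermal_ensemble")) {
    nsrc <- if (inherits(source, "cas_solution")) source$norb else
      source$states[[1]]$norb
    stopifnot(nsrc == n)
    rho1 <- lapply(seq_len(n), function(i) one_orbital_rdm(source, i))
    pair_rho <- function(i, j) two_orbital_rdm(source, i, j)
  } else {
    gamma_loc <- if (inherits(source, "mf_gamma")) 2 * source$D else source
    stopifnot(is.matrix(gamma_loc), nrow(gamma_loc) == n)
    D <- gamma_loc / 2
    rho1 <- lapply(seq_len(n), function(i) {
      determinant_one_orbital_rdm(D[i, i])
    })
    pair_rho <- function(i, j) determinant_two_orbital_rdm(D[c(i, j), c(i, j)])
  }
  S1 <- vapply(rho1, von_neumann_entropy, numeric(1))
  edges <- NULL
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (atom[i] == atom[j]) next
    Iij <- S1[i] + S1[j] - von_neumann_entropy(pair_rho(i, j))
    Iij <- max(Iij, 0)
    edges <- rbind(edges, c(i, j, Iij, Iij / Imax))
    if (Iij > eta * Imax) adj[i, j] <- adj[j, i] <- TRUE
  }
  edges <- as.data.frame(if (is.null(edges)) {
    matrix(numeric(0), 0, 4)
  } else edges)
  names(edges) <- c("i", "j", "I", "I_norm")
  structure(list(
    nodes = data.frame(orbital = seq_len(n), atom = atom, entropy = S1,
                       entropy_norm = S1 / log(4)),
    edges = edges, eta = eta, Imax = Imax, adjacency = adj),
    class = "correlation_graph")
}

#' Build a correlation graph from a precomputed mutual-information table
#'
#' @param I symmetric matrix of pairwise mutual informations (nats);
#'   intra-atom entries are ignored.
#' @param atom atom assignment.
#' @param eta edge threshold as a fraction of `2 log 4`.
#' @param entropy optional per-orbital entropies for the node table.
#' @return `correlation_graph`.
#' @export
correlation_graph_from_I <- function(I, atom, eta = 0.10, entropy = NULL) {
  n <- length(atom)
  stopifnot(is.matrix(I), nrow(I) == n, ncol(I) == n)
  Imax <- 2 * log(4)
  if (is.null(entropy)) entropy <- rep(NA_real_, n)
  edges <- NULL
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (atom[i] == atom[j]) next
    edges <- rbind(edges, c(i, j, I[i, j], I[i, j] / Imax))
    if (I[i, j] > eta * Imax) adj[i, j] <- adj[j, i] <- TRUE
  }
  edges <- as.data.frame(if (is.null(edges)) matrix(numeric(0), 0, 4) else edges)
  names(edges) <- c("i", "j", "I", "I_norm")
  structure(list(
    nodes = data.frame(orbital = seq_len(n), atom = atom, entropy = entropy,
                       entropy_norm = entropy / log(4)),
    edges = edges, eta = eta, Imax = Imax, adjacency = adj),
    class = "correlation_graph")
}

#' Group MEAOs into bond clusters
#'
#' Connected components of the thresholded correlation graph; components
#' with a single vertex are non-bonding and excluded.  Clusters are
#' ordered by decreasing size, then by lowest orbital index; two-vertex
#' clusters are two-center bonds, larger ones multicenter bonds.
#'
#' @param graph `correlation_graph`.
#' @return list of `bond_cluster` objects with fields `orbitals`, `atoms`,
#'   `type`.
#' @export
detect_bond_clusters <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- graph$adjacency
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s; comp <- integer(0); seen[s] <- TRUE
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, u)
      nb <- which(adj[u, ] & !seen)
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    if (length(comp) > 1) comps[[length(comps) + 1]] <- sort(comp)
  }
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, min, integer(1)))
  lapply(comps[ord], function(cp) {
    structure(list(orbitals = cp, atoms = unique(graph$nodes$atom[cp]),
                   type = if (length(cp) == 2) "two-center" else "multicenter"),
              class = "bond_cluster")
  })
}

#' Build the active space for a bond cluster
#'
#' The cluster orbitals form the active space; the non-active block of the
#' spin-free 1RDM is diagonalized and its natural orbitals classified as
#' closed (occupation > 1) or virtual (occupation < 1).  Occupations far
#' from 0 or 2 (by more than `warn_tol`) trigger a warning; an occupation
#' within 1e-6 of exactly 1 is an ambiguous classification error.
#'
#' @param mf `scf_result`.
#' @param meao_coeff localized-orbital coefficients (nao x nloc).
#' @param cluster `bond_cluster` (or integer vector of orbital indices).
#' @param warn_tol tolerance around 0/2 before warning.
#' @return object of class `cas_space`: `active`, `closed`, `virtual`
#'   coefficient blocks, `nelec_active`, `occ_nonactive`.
#' @export
build_cas_for_cluster <- function(mf, meao_coeff, cluster, warn_tol = 0.2) {
  orbs <- if (inherits(cluster, "bond_cluster")) cluster$orbitals else cluster
  S <- mf$ints$S
  n <- ncol(meao_coeff)
  non <- setdiff(seq_len(n), orbs)
  gamma_loc <- t(meao_coeff) %*% S %*% mf$gamma %*% S %*% meao_coeff
  g_non <- gamma_loc[non, non, drop = FALSE]
  e <- eigen((g_non + t(g_non)) / 2, symmetric = TRUE)
  occ <- e$values
  if (any(abs(occ - 1) < 1e-6)) {
    stop("ambiguous classification: non-active natural occupation ",
         "within 1e-6 of 1")
  }
  if (any(pmin(abs(occ), abs(occ - 2)) > warn_tol)) {
    warning("non-active natural occupation(s) far from {0, 2}: ",
            paste(round(occ[pmin(abs(occ), abs(occ - 2)) > warn_tol], 3),
                  collapse = ", "))
  }
  C_non <- meao_coeff[, non, drop = FALSE] %*% e$vectors
  closed <- C_non[, occ > 1, drop = FALSE]
  virt <- C_non[, occ < 1, drop = FALSE]
  nelec_active <- mf$mol$nelec - 2L * ncol(closed)
  structure(list(active = meao_coeff[, orbs, drop = FALSE],
                 closed = closed, virtual = virt,
                 orbitals = orbs, nelec_active = nelec_active,
                 occ_nonactive = occ),
            class = "cas_space")
}

#' @export
print.cas_space <- function(x, ...) {
  cat(sprintf("CAS space: (%d o, %d e), %d closed, %d virtual\n",
              ncol(x$active), x$nelec_active, ncol(x$closed),
              ncol(x$virtual)))
  invisible(x)
}

#' Highest k-orbital GME over connected unions of two-center bonds
#'
#' Negative-control evaluation for systems whose correlation graph contains
#' no k-orbital cluster (e.g. saturated rings): enumerates unions of k/2
#' two-center bond clusters whose atom-sharing graph is connected (a
#' disconnected union is nearly biseparable, so its GME is bounded by the
#' weak inter-component correlation and cannot be maximal), solves the CAS
#' for each union and returns the largest exhaustive GME.
#'
#' @param mf `scf_result`.
#' @param meao_coeff localized-orbital coefficients (nao x nloc).
#' @param clusters list of `bond_cluster`s (from [detect_bond_clusters()]).
#' @param k number of orbitals in the target set (even).
#' @param restrict_atoms optional atom indices; only two-center clusters
#'   whose atoms all lie in this set are considered (e.g. the ring atoms).
#' @return list with `orbitals`, `gme` (as from [cas_gme()]), `solution`,
#'   and `candidates` (number of unions examined).
#' @export
best_k_orbital_gme <- function(mf, meao_coeff, clusters, k,
                               restrict_atoms = NULL) {
  stopifnot(k %% 2 == 0)
  two <- Filter(function(cl) cl$type == "two-center", clusters)
  if (!is.null(restrict_atoms)) {
    two <- Filter(function(cl) all(cl$atoms %in% restrict_atoms), two)
  }
  m <- k / 2
  if (length(two) < m) {
    stop("not enough two-center clusters for a ", k, "-orbital union")
  }
  combos <- utils::combn(length(two), m, simplify = FALSE)
  atom_sets <- lapply(two, `[[`, "atoms")
  connected <- function(idx) {
    if (length(idx) == 1) return(TRUE)
    sets <- atom_sets[idx]
    seen <- 1L
    repeat {
      grown <- FALSE
      for (q in setdiff(seq_along(sets), seen)) {
        if (length(intersect(sets[[q]],
                             unlist(sets[seen]))) > 0) {
          seen <- c(seen, q); grown <- TRUE
        }
      }
      if (!grown) break
    }
    length(seen) == length(sets)
  }
  combos <- Filter(connected, combos)
  if (!length(combos)) stop("no connected ", k, "-orbital union exists")
  best <- NULL
  for (idx in combos) {
    orbs <- sort(unlist(lapply(two[idx], `[[`, "orbitals")))
    space <- build_cas_for_cluster(mf, meao_coeff, orbs)
    sol <- solve_cas(mf, active = space$active, core = space$closed,
                     nelec_active = space$nelec_active)
    g <- cas_gme(sol, mode = "exhaustive")
    if (is.null(best) || g$value > best$gme$value) {
      best <- list(orbitals = orbs, gme = g, solution = sol,
                   candidates = length(combos))
    }
  }
  best
}

#' Export a correlation graph as JSON or GraphML
#'
#' @param graph `correlation_graph`.
#' @param path output file; format from extension (`.json` or `.graphml`).
#' @export
export_graph <- function(graph, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges,
                              eta = graph$eta, Imax = graph$Imax),
                         path, digits = NA, auto_unbox = TRUE)
  } else if (grepl("\\.graphml$", path)) {
    hdr <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             '<key id="atom" for="node" attr.name="atom" attr.type="int"/>',
             '<key id="entropy" for="node" attr.name="entropy" attr.type="double"/>',
             '<key id="I" for="edge" attr.name="I" attr.type="double"/>',
             '<key id="I_norm" for="edge" attr.name="I_norm" attr.type="double"/>',
             '<graph edgedefault="undirected">')
    nodes <- sprintf('<node id="n%d"><data key="atom">%d</data><data key="entropy">%.8f</data></node>',
                     graph$nodes$orbital, graph$nodes$atom,
                     graph$nodes$entropy)
    edges <- sprintf('<edge source="n%d" target="n%d"><data key="I">%.8f</data><data key="I_norm">%.8f</data></edge>',
                     graph$edges$i, graph$edges$j, graph$edges$I,
                     graph$edges$I_norm)
    writeLines(c(hdr, nodes, edges, "</graph>", "</graphml>"), path)
  } else {
    stop("unsupported graph export format: ", path)
  }
  invisible(path)
}
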