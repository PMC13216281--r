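# End-to-end orchestration of the four-step bonding analysis:
# partition -> MEAO -> correlation graph / clusters -> per-bond
# entanglement measures, with configuration, logging and a JSON-serializable
# report.

#' Build and validate a run configuration
#'
#' Defaults mirror the reference workflow: threshold `eta = 0.10`, inverse
#' temperature `beta = 1e3` hartree^-1 with 4 roots for thermal runs,
#' 4 optimizer restarts.  The built-in mean-field engine is restricted
#' Hartree-Fock.
#'
#' @param geometry path to an XYZ file or a `molecule` object.
#' @param basis basis-set name.
#' @param charge molecular charge (ignored when `geometry` is a molecule).
#' @param method mean-field flavor (only `"hf"` is built in).
#' @param partition localization scheme.
#' @param eta correlation-graph threshold (fraction of 2 log 4).
#' @param correlation correlated treatment for two-center bonds:
#'   `"full-minimal"` (CAS over the whole minimal-IAO space),
#'   `"cluster"` (per-cluster CAS), or `"auto"` (full-minimal when the CI
#'   dimension is tractable, else cluster).
#' @param solver active-space solver (only `"fci"` is built in).
#' @param beta inverse temperature for thermal runs (hartree^-1).
#' @param nroots thermal ensemble roots.
#' @param pair_entanglement compute mutual information and relative-entropy
#'   entanglement for two-center bonds (disable when only multicenter GME
#'   is of interest; saves the per-pair CAS and entanglement solves).
#' @param seed RNG seed (optimizer restarts, entanglement solver).
#' @param restarts MEAO optimizer restarts.
#' @param max_full_dim determinant-count cap for the full-minimal CAS.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(geometry, basis = "cc-pvdz", charge = 0,
                       method = "hf",
                       partition = "iao-minimal", eta = 0.10,
                       correlation = c("auto", "full-minimal", "cluster"),
                       solver = "fci", beta = 1e3, nroots = 4L,
                       pair_entanglement = TRUE,
                       seed = 1L, restarts = 4L, max_full_dim = 4e4) {
  correlation <- match.arg(correlation)
  if (!identical(method, "hf")) {
    stop("configuration error: built-in mean-field engine supports only 'hf'")
  }
  if (!identical(solver, "fci")) {
    stop("configuration error: built-in active-space solver is 'fci'")
  }
  if (eta <= 0 || eta >= 1) stop("configuration error: eta must be in (0,1)")
  if (beta < 0) stop("configuration error: beta must be non-negative")
  structure(list(geometry = geometry, basis = basis, charge = charge,
                 method = method, partition = partition, eta = eta,
                 correlation = correlation, solver = solver, beta = beta,
                 pair_entanglement = isTRUE(pair_entanglement),
                 nroots = as.integer(nroots), seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 max_full_dim = max_full_dim),
            class = "run_config")
}

log_line <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)
}

#' Run the full MEAO bonding analysis
#'
#' Executes the four-step workflow and assembles an `entanglement_report`:
#' per-bond normalized mutual information and relative-entropy
#' entanglement for two-center bonds, normalized genuine multipartite
#' entanglement for multicenter clusters, cluster memberships and CAS
#' sizes, and provenance.  Identical configuration and seed give an
#' identical report.
#'
#' @param config `run_config` (or arguments forwarded to [run_config()]).
#' @param verbose log progress lines.
#' @return object of class `entanglement_report`.
#' @export
run_bonding_analysis <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  mol <- if (inherits(config$geometry, "molecule")) config$geometry else
    read_xyz(config$geometry, charge = config$charge)
  log_line(verbose, "stage mean-field: RHF/", config$basis)
  mf <- run_mean_field(mol, config$basis)
  log_line(verbose, sprintf("stage mean-field done: E = %.8f", mf$energy))
  part <- build_partition(mf, config$partition)
  gamma_loc <- partition_gamma(part)
  log_line(verbose, "stage meao: ", ncol(part$coeff), " localized orbitals")
  opt <- optimize_meao(mf_gamma(gamma_loc), part$atom, seed = config$seed,
                       restarts = config$restarts)
  meao <- part$coeff %*% opt$U
  g_meao <- t(opt$U) %*% gamma_loc %*% opt$U
  log_line(verbose, sprintf("stage meao done: F = %.6f (restart %d)",
                            opt$objective, opt$restart))
  graph_mf <- build_correlation_graph(g_meao, part$atom, eta = config$eta)
  clusters <- detect_bond_clusters(graph_mf)
  log_line(verbose, "stage graph: ", length(clusters), " clusters")
  n <- ncol(meao)
  # correlated treatment for pair measures
  ndet_full <- choose(n, mol$nelec / 2)^2
  use_full <- switch(config$correlation,
    "full-minimal" = TRUE,
    "cluster" = FALSE,
    "auto" = ndet_full <= config$max_full_dim)
  sol_full <- NULL
  if (use_full) {
    log_line(verbose, sprintf("stage correlate: full minimal CAS(%d, %d), %d determinants",
                              n, mol$nelec, ndet_full))
    sol_full <- solve_cas(mf, active = meao, nelec_active = mol$nelec)
  }
  pairs <- NULL
  gmes <- NULL
  cluster_rows <- NULL
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    cas_sizes <- NULL
    if (cl$type == "two-center" && !config$pair_entanglement) {
      cluster_rows <- rbind(cluster_rows, data.frame(
        cluster = ci, type = cl$type,
        orbitals = paste(cl$orbitals, collapse = "+"),
        atoms = paste(cl$atoms, collapse = "+")))
      next
    }
    if (cl$type == "two-center") {
      i <- cl$orbitals[1]; j <- cl$orbitals[2]
      if (use_full) {
        sol <- sol_full; ii <- i; jj <- j
        nact <- n; nele <- mol$nelec
      } else {
        space <- build_cas_for_cluster(mf, meao, cl)
        sol <- solve_cas(mf, active = space$active, core = space$closed,
                         nelec_active = space$nelec_active)
        ii <- 1L; jj <- 2L
        nact <- 2L; nele <- space$nelec_active
      }
      Iij <- mutual_information(sol, ii, jj)
      rho <- two_orbital_rdm(sol, ii, jj)
      E <- relative_entropy_of_entanglement(rho, tol = 1e-6, maxit = 5000,
                                            seed = config$seed)
      pairs <- rbind(pairs, data.frame(
        cluster = ci, i = i, j = j,
        atom_i = part$atom[i], atom_j = part$atom[j],
        I_norm = Iij / (2 * log(4)), E_norm = E$value / log(4),
        cas_orbitals = nact, cas_electrons = nele))
    } else {
      space <- build_cas_for_cluster(mf, meao, cl)
      log_line(verbose, sprintf("stage gme: cluster %d CAS(%d, %d)", ci,
                                ncol(space$active), space$nelec_active))
      sol <- solve_cas(mf, active = space$active, core = space$closed,
                       nelec_active = space$nelec_active)
      mode <- if (length(cl$orbitals) <= 8) "exhaustive" else "mps-cuts"
      g <- cas_gme(sol, mode = mode)
      gmes <- rbind(gmes, data.frame(
        cluster = ci, size = length(cl$orbitals),
        orbitals = paste(cl$orbitals, collapse = "+"),
        GME_norm = g$normalized,
        minimizer = paste(cl$orbitals[g$minimizer], collapse = "+"),
        cas_orbitals = ncol(space$active),
        cas_electrons = space$nelec_active))
    }
    cluster_rows <- rbind(cluster_rows, data.frame(
      cluster = ci, type = cl$type,
      orbitals = paste(cl$orbitals, collapse = "+"),
      atoms = paste(cl$atoms, collapse = "+")))
  }
  provenance <- list(
    package = "meaobond",
    version = as.character(utils::packageVersion("meaobond")),
    basis = config$basis, method = config$method,
    partition = config$partition, eta = config$eta,
    correlation = if (use_full) "full-minimal" else "cluster",
    solver = config$solver, seed = config$seed,
    restarts = config$restarts,
    scf_energy = mf$energy,
    objective = opt$objective)
  structure(list(molecule = mol, pairs = pairs, gme = gmes,
                 clusters = cluster_rows, graph = graph_mf,
                 meao = meao, atom = part$atom, mf = mf,
                 provenance = provenance),
            class = "entanglement_report")
}

#' @export
print.entanglement_report <- function(x, ...) {
  cat("MEAO bonding analysis (", x$provenance$basis, ", ",
      x$provenance$partition, ")\n", sep = "")
  if (!is.null(x$pairs)) {
    cat("two-center bonds (normalized I, E):\n")
    p <- x$pairs
    for (k in seq_len(nrow(p))) {
      cat(sprintf("  orbitals %d-%d (atoms %d-%d): I = %.3f  E = %.3f\n",
                  p$i[k], p$j[k], p$atom_i[k], p$atom_j[k],
                  round(p$I_norm[k], 3), round(p$E_norm[k], 3)))
    }
  }
  if (!is.null(x$gme)) {
    cat("multicenter clusters (normalized GME):\n")
    g <- x$gme
    for (k in seq_len(nrow(g))) {
      cat(sprintf("  cluster {%s} CAS(%d, %d): GME = %.3f\n",
                  g$orbitals[k], g$cas_orbitals[k], g$cas_electrons[k],
                  round(g$GME_norm[k], 3)))
    }
  }
  if (is.null(x$pairs) && is.null(x$gme)) cat("no bonds above threshold\n")
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report `entanglement_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  out <- list(provenance = report$provenance,
              clusters = report$clusters,
              pairs = report$pairs,
              gme = report$gme,
              graph = list(nodes = report$graph$nodes,
                           edges = report$graph$edges,
                           eta = report$graph$eta))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a serialized report
#' @param path JSON path written by [write_report()].
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
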