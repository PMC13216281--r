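# Gaussian cube-file export of localized orbitals (visualization interface).

# values of all spherical AOs at the given points (npts x nao)
ao_values <- function(shells, points) {
  npts <- nrow(points)
  out <- matrix(0, npts, shells$nao)
  col <- 1L
  for (s in seq_along(shells$l)) {
    l <- shells$l[s]
    ctr <- shells$centers[s, ]
    dx <- points[, 1] - ctr[1]; dy <- points[, 2] - ctr[2]
    dz <- points[, 3] - ctr[3]
    r2 <- dx^2 + dy^2 + dz^2
    rad <- rep(0, npts)
    for (k in seq_along(shells$exps[[s]])) {
      rad <- rad + shells$coefs[[s]][k] * exp(-shells$exps[[s]][k] * r2)
    }
    tr <- cart_triples(l)
    cart <- matrix(0, npts, nrow(tr))
    for (c2 in seq_len(nrow(tr))) {
      cart[, c2] <- dx^tr[c2, 1] * dy^tr[c2, 2] * dz^tr[c2, 3] * rad
    }
    Tm <- shells$T[[s]]
    out[, col:(col + nrow(Tm) - 1)] <- cart %*% t(Tm)
    col <- col + nrow(Tm)
  }
  out
}

#' Write localized orbitals as Gaussian cube files
#'
#' @param part `atomic_partition` (or any object with `coeff` and `mf`).
#' @param orbitals orbital column indices to export.
#' @param dir output directory.
#' @param spacing grid spacing in bohr.
#' @param margin box margin beyond the molecule in bohr.
#' @return invisibly, the written file paths.
#' @export
write_cube_files <- function(part, orbitals, dir = ".", spacing = 0.4,
                             margin = 4.0) {
  mf <- part$mf
  mol <- mf$mol
  shells <- mf$ints$shells
  lo <- apply(mol$coords, 2, min) - margin
  hi <- apply(mol$coords, 2, max) + margin
  npts <- pmax(ceiling((hi - lo) / spacing), 2)
  axes <- lapply(1:3, function(k) lo[k] + spacing * (seq_len(npts[k]) - 1))
  grid <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]],
                                z = axes[[3]]))
  # cube order: x slow, z fast
  grid <- grid[order(grid[, 1], grid[, 2], grid[, 3]), ]
  vals <- ao_values(shells, grid)
  paths <- character(0)
  for (k in orbitals) {
    v <- vals %*% part$coeff[, k]
    path <- file.path(dir, sprintf("orbital_%03d.cube", k))
    con <- file(path, "w")
    writeLines(c("meaobond localized orbital",
                 sprintf("orbital %d", k),
                 sprintf("%5d %11.6f %11.6f %11.6f", mol$natm,
                         lo[1], lo[2], lo[3]),
                 sprintf("%5d %11.6f %11.6f %11.6f", npts[1], spacing, 0, 0),
                 sprintf("%5d %11.6f %11.6f %11.6f", npts[2], 0, spacing, 0),
                 sprintf("%5d %11.6f %11.6f %11.6f", npts[3], 0, 0, spacing)),
               con)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", mol$Z, mol$Z,
                       mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]),
               con)
    writeLines(paste(formatC(v, format = "e", digits = 5), collapse = " "),
               con)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
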