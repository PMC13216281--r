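# Correlation graph, clustering, and active-space construction.

test_that("edges appear exactly above the threshold", {
  Imax <- 2 * log(4)
  I <- matrix(0, 3, 3)
  I[1, 2] <- I[2, 1] <- 0.9 * Imax
  I[1, 3] <- I[3, 1] <- 0.05 * Imax
  g <- correlation_graph_from_I(I, atom = c(1, 2, 3), eta = 0.10)
  expect_equal(sum(g$adjacency) / 2, 1)
  expect_true(g$adjacency[1, 2])
  cl <- detect_bond_clusters(g)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$orbitals, c(1, 2))
  expect_equal(cl[[1]]$type, "two-center")
})

test_that("an edgeless graph yields no clusters", {
  I <- matrix(0, 4, 4)
  g <- correlation_graph_from_I(I, atom = c(1, 1, 2, 2))
  expect_length(detect_bond_clusters(g), 0)
})

test_that("clusters are ordered by size then lowest orbital index", {
  Imax <- 2 * log(4)
  I <- matrix(0, 7, 7)
  link <- function(i, j) I[i, j] <<- I[j, i] <<- 0.5 * Imax
  link(6, 7)          # pair
  link(1, 2); link(2, 3) # triple
  g <- correlation_graph_from_I(I, atom = 1:7)
  cl <- detect_bond_clusters(g)
  expect_equal(lapply(cl, `[[`, "orbitals"), list(c(1, 2, 3), c(6, 7)))
  expect_equal(cl[[1]]$type, "multicenter")
})

test_that("raising the threshold never merges clusters", {
  set.seed(23)
  Imax <- 2 * log(4)
  for (rep in 1:8) {
    n <- 8
    I <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      I[i, j] <- I[j, i] <- runif(1) * Imax * 0.4
    }
    atom <- seq_len(n)
    cl_lo <- detect_bond_clusters(correlation_graph_from_I(I, atom, 0.05))
    cl_hi <- detect_bond_clusters(correlation_graph_from_I(I, atom, 0.15))
    # every high-threshold cluster is contained in one low-threshold cluster
    for (ch in cl_hi) {
      containing <- Filter(function(cl) all(ch$orbitals %in% cl$orbitals),
                           cl_lo)
      expect_length(containing, 1)
    }
  }
})

test_that("intra-atom pairs never create edges", {
  fx <- fixture_lih()
  g <- build_correlation_graph(partition_gamma(fx$part) |>
                                 (\(gl) t(fx$opt$U) %*% gl %*% fx$opt$U)(),
                               fx$part$atom)
  same_atom <- fx$part$atom[g$edges$i] == fx$part$atom[g$edges$j]
  expect_false(any(same_atom))
})

test_that("ethene pipeline finds six two-center bonds", {
  mfe <- fixture("c2h4_mf", {
    run_mean_field(read_xyz(pkg_geometry("c2h4.xyz")), "cc-pvdz")
  })
  part <- build_partition(mfe, "iao-minimal")
  gl <- partition_gamma(part)
  opt <- optimize_meao(mf_gamma(gl), part$atom, seed = 1)
  g_meao <- t(opt$U) %*% gl %*% opt$U
  graph <- build_correlation_graph(g_meao, part$atom)
  cl <- detect_bond_clusters(graph)
  expect_length(cl, 6)
  expect_true(all(vapply(cl, `[[`, "", "type") == "two-center"))
  # four C-H bonds and two C-C bonds
  kinds <- vapply(cl, function(x) {
    paste(sort(mfe$mol$symbols[x$atoms]), collapse = "-")
  }, "")
  expect_equal(sum(kinds == "C-H"), 4)
  expect_equal(sum(kinds == "C-C"), 2)
})

test_that("cluster CAS construction classifies and conserves electrons", {
  fx <- fixture_lih()
  graph <- build_correlation_graph(
    t(fx$opt$U) %*% partition_gamma(fx$part) %*% fx$opt$U, fx$part$atom)
  cl <- detect_bond_clusters(graph)
  expect_gte(length(cl), 1)
  space <- build_cas_for_cluster(fx$mf, fx$meao, cl[[1]])
  # closed-shell determinant input: non-active occupations exactly 0 or 2
  expect_true(all(pmin(abs(space$occ_nonactive),
                       abs(space$occ_nonactive - 2)) < 1e-8))
  expect_equal(2 * ncol(space$closed) + space$nelec_active,
               fx$mf$mol$nelec)
  # the three blocks are mutually orthogonal and jointly spanning
  allC <- cbind(space$closed, space$active, space$virtual)
  G <- t(allC) %*% fx$part$S %*% allC
  expect_lt(max(abs(G - diag(ncol(allC)))), 1e-8)
})

test_that("graph exports round-trip", {
  fx <- fixture_lih()
  g <- build_correlation_graph(
    t(fx$opt$U) %*% partition_gamma(fx$part) %*% fx$opt$U, fx$part$atom)
  jf <- tempfile(fileext = ".json")
  export_graph(g, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(nrow(back$edges), nrow(g$edges))
  expect_equal(back$edges$I, g$edges$I, tolerance = 1e-12)
  gf <- tempfile(fileext = ".graphml")
  export_graph(g, gf)
  expect_true(any(grepl("graphml", readLines(gf))))
})
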