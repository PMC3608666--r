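# Structural primitives: PDB I/O, superposition, RMSD, Rg.

make_toy_pdb <- function(path) {
  lines <- c(
    "MODEL        1",
    "ATOM      1  N   ARG A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ARG A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ARG A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  NH1 ARG A   1       2.500   2.500   0.500  1.00  0.00           N",
    "ATOM      5  HB2 ARG A   1       2.100   1.500   1.000  1.00  0.00           H",
    "ATOM      6  N   ASP A   2       3.800   0.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  ASP A   2       5.258   0.000   0.000  1.00  0.00           C",
    "ATOM      8  OD1 ASP A   2       6.000   1.300   0.200  1.00  0.00           O",
    "ATOM      9  CA AGLY A   3       7.600   0.100   0.000  0.40  0.00           C",
    "ATOM     10  CA BGLY A   3       7.700   0.000   0.000  0.60  0.00           C",
    "ATOM     11  CA  LEU A   4      11.400   0.000   0.000  1.00  0.00           C",
    "ATOM     12  CA  VAL A   5      15.200   0.000   0.000  1.00  0.00           C",
    "ATOM     13  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ARG A   1       0.000   0.000   1.000  1.00  0.00           N",
    "ATOM      2  CA  ARG A   1       1.458   0.000   1.000  1.00  0.00           C",
    "ATOM      3  CB  ARG A   1       2.000   1.400   1.000  1.00  0.00           C",
    "ATOM      4  NH1 ARG A   1       2.500   2.500   1.500  1.00  0.00           N",
    "ATOM      5  HB2 ARG A   1       2.100   1.500   2.000  1.00  0.00           H",
    "ATOM      6  N   ASP A   2       3.800   0.000   1.000  1.00  0.00           N",
    "ATOM      7  CA  ASP A   2       5.258   0.000   1.000  1.00  0.00           C",
    "ATOM      8  OD1 ASP A   2       6.000   1.300   1.200  1.00  0.00           O",
    "ATOM      9  CA AGLY A   3       7.600   0.100   1.000  0.40  0.00           C",
    "ATOM     10  CA BGLY A   3       7.700   0.000   1.000  0.60  0.00           C",
    "ATOM     11  CA  LEU A   4      11.400   0.000   1.000  1.00  0.00           C",
    "ATOM     12  CA  VAL A   5      15.200   0.000   1.000  1.00  0.00           C",
    "ATOM     13  O   HOH A 101      20.000  20.000  21.000  1.00  0.00           O",
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}

test_that("multi-model PDB reading: frames, water/H filtering, altlocs, classes", {
  path <- make_toy_pdb(tempfile(fileext = ".pdb"))
  out <- read_pdb(path, dt = 10)
  expect_equal(n_frames(out$ensemble), 2L)
  expect_equal(nrow(out$system$residues), 5L)
  expect_equal(out$ensemble$times, c(0, 10))
  # waters and hydrogens are gone
  expect_false(any(out$system$atoms$element == "H"))
  expect_false(any(out$system$residues$resname %in% c("HOH", "WAT")))
  # highest-occupancy altloc kept for GLY CA (x = 7.7)
  gly_row <- which(out$system$residues$resname == "GLY")
  gly_ca <- which(out$system$atoms$res == gly_row &
                    out$system$atoms$name == "CA")
  expect_length(gly_ca, 1L)
  expect_equal(out$system$reference_coords[gly_ca, 1L], 7.7)
  # contact classes from residue chemistry
  expect_equal(out$system$residues$class[out$system$residues$resname == "ARG"],
               "positive")
  expect_equal(out$system$residues$class[out$system$residues$resname == "ASP"],
               "negative")
  # first_model policy
  expect_equal(n_frames(read_pdb(path, "first_model")$ensemble), 1L)
})

test_that("malformed ATOM records are rejected with the line number", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
               "ATOM      2  CA  ALA A   2       bad     0.000   0.000  1.00  0.00"),
             path)
  expect_error(read_pdb(path), "line 2")
})

test_that("chain-count validation and round-trips through PDB and coord table", {
  toy <- toy_complex()
  expect_error(read_pdb(make_toy_pdb(tempfile(fileext = ".pdb")),
                        expected_chains = 2L), "expected 2")
  # multi-model PDB round trip preserves coordinates to format precision
  spec <- synthetic_spec(seed = 3)
  ens2 <- sample_csif_ensembles(spec, "cs_dominant", toy)$bound
  sub <- ensemble(ens2$system, ens2$coords[1:3, , , drop = FALSE],
                  times = ens2$times[1:3])
  p <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(sub, p)
  back <- read_pdb(p)
  expect_equal(n_frames(back$ensemble), 3L)
  expect_equal(back$system$reference_coords,
               unname(frame_coords(sub, 1L)), tolerance = 1e-3)
  # coordinate-table round trip is exact to write precision
  tf <- tempfile(fileext = ".tsv")
  write_coord_table(sub, tf)
  back2 <- read_coord_table(tf)
  expect_equal(back2$ensemble$coords, sub$coords, tolerance = 1e-9)
  expect_equal(back2$system$residues$resname, sub$system$residues$resname)
  # pseudo side chains carry the summed side-chain mass
  cb <- which(back2$system$atoms$name == "CB")[1L]
  rn <- back2$system$residues$resname[back2$system$atoms$res[cb]]
  expect_gt(back2$system$atoms$mass[cb], 12.2)
})

test_that("superposition recovers rigid motions and forbids reflections", {
  set.seed(11)
  x <- matrix(rnorm(30L), 10L, 3L)
  # identity
  sp <- superpose(x, x)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  # 90 degrees about z plus translation is exactly recoverable
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3L, 3L)
  y <- sweep(x %*% Rz, 2L, c(5, 0, 0), "+")
  sp <- superpose(x, y)
  expect_lt(sp$rmsd, 1e-8)
  expect_equal(apply_superposition(sp, x), y, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # determinant stays +1 even for mirrored targets
  ymir <- x %*% diag(c(-1, 1, 1))
  expect_equal(det(superpose(x, ymir)$rotation), 1, tolerance = 1e-9)
  # degenerate selections
  expect_error(superpose(x, y, integer(0)), "empty")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superposed RMSD matches a dense rotation-grid oracle", {
  set.seed(7)
  x <- matrix(rnorm(30L), 10L, 3L)
  y <- matrix(rnorm(30L), 10L, 3L)
  fit <- superpose(x, y)$rmsd
  # oracle: exhaustive search over Euler-angle grid, optimal translation
  # handled by centering
  xc <- sweep(x, 2L, colMeans(x)); yc <- sweep(y, 2L, colMeans(y))
  best <- Inf
  grid <- seq(0, 2 * pi, length.out = 40L)[-40L]
  half <- seq(0, pi, length.out = 20L)
  for (a in grid) for (b in half) for (g in grid) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    r <- sqrt(mean(rowSums((xc %*% (Rz1 %*% Ry %*% Rz2) - yc)^2)))
    if (r < best) best <- r
  }
  expect_lt(abs(fit - best), 1e-3)
  expect_lte(fit, best + 1e-12)   # grid can only be worse
})

test_that("rmsd closed forms, metric behaviour, and fit never hurts", {
  x <- matrix(0, 2L, 3L)
  y <- rbind(c(1, 0, 0), c(3, 0, 0))
  expect_equal(rmsd(x, x), 0)
  expect_equal(rmsd(x, y), sqrt(5))
  set.seed(5)
  for (i in 1:100) {
    a <- matrix(rnorm(24L), 8L, 3L)
    b <- matrix(rnorm(24L), 8L, 3L)
    expect_lte(rmsd(a, b, fit = TRUE), rmsd(a, b) + 1e-12)
    expect_equal(rmsd(a, b, fit = TRUE), rmsd(b, a, fit = TRUE),
                 tolerance = 1e-9)
  }
  # invariance of the fitted rmsd under pre-applied rigid motions
  a <- matrix(rnorm(30L), 10L, 3L)
  b <- matrix(rnorm(30L), 10L, 3L)
  r0 <- rmsd(a, b, fit = TRUE)
  for (s in 1:5)
    expect_lt(abs(rmsd(random_rigid(a, s), b, fit = TRUE) - r0), 1e-8)
})

test_that("radius of gyration: closed forms, oracle, invariance", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1L)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  set.seed(9)
  x <- matrix(rnorm(300L), 100L, 3L)
  w <- runif(100L, 0.5, 2)
  # independent direct-sum oracle
  ctr <- colSums(x * (w / sum(w)))
  oracle <- sqrt(sum((w / sum(w)) * rowSums(sweep(x, 2L, ctr)^2)))
  expect_equal(radius_of_gyration(x, weights = w), oracle, tolerance = 1e-10)
  expect_equal(radius_of_gyration(random_rigid(x, 2), weights = w), oracle,
               tolerance = 1e-10)
  # unweighted oracle
  o2 <- sqrt(mean(rowSums(sweep(x, 2L, colMeans(x))^2)))
  expect_equal(radius_of_gyration(x), o2, tolerance = 1e-10)
})

test_that("system and ensemble validation catch inconsistencies", {
  toy <- toy_complex()
  sys <- toy$system
  expect_error(ensemble(sys, list(matrix(0, 3L, 3L))), "atom count")
  good <- sys$reference_coords
  expect_error(ensemble(sys, list(good, good), times = c(1, 1)),
               "strictly increasing")
  bad_res <- sys$residues
  bad_res$resno[2L] <- bad_res$resno[1L]
  expect_error(system_model(bad_res, sys$atoms, good), "strictly increasing")
})
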