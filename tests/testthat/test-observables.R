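# Ensemble observables: RMSF, dihedral variation, helicity, distance
# differences, free-energy landscapes.

test_that("rmsf: zeros for identical frames, closed form for one oscillator", {
  toy <- toy_complex()
  sys <- toy$system
  ref <- sys$reference_coords
  ens0 <- ensemble(sys, list(ref, ref, ref), dt = 1)
  r0 <- ca_rmsf(ens0)
  expect_true(all(abs(r0$rmsf[!is.na(r0$rmsf)]) < 1e-10))
  # one CA oscillating +/- 1 A along x, everything else fixed: that
  # residue's RMSF ~ 1 A (small leakage through the global fit)
  ca <- ca_indices(sys)
  target <- ca[10L]
  f1 <- ref; f1[target, 1L] <- f1[target, 1L] + 1
  f2 <- ref; f2[target, 1L] <- f2[target, 1L] - 1
  ens1 <- ensemble(sys, list(f1, f2, f1, f2), dt = 1)
  r1 <- ca_rmsf(ens1)
  res_target <- sys$atoms$res[target]
  expect_equal(r1$rmsf[res_target], 1, tolerance = 0.05)
  expect_lt(max(r1$rmsf[-res_target], na.rm = TRUE), 0.2)
})

test_that("rmsf matches a direct two-pass oracle and ignores rigid motion", {
  toy <- toy_complex()
  sys <- toy$system
  set.seed(31)
  frames <- lapply(1:8, function(i)
    sys$reference_coords + matrix(rnorm(length(sys$reference_coords),
                                        sd = 0.3), ncol = 3L))
  ens <- ensemble(sys, frames, dt = 1)
  base <- ca_rmsf(ens)
  # rigid motion of every frame changes nothing
  moved <- ensemble(sys, lapply(seq_along(frames), function(i)
    random_rigid(frames[[i]], seed = 200L + i)), dt = 1)
  expect_equal(ca_rmsf(moved)$rmsf, base$rmsf, tolerance = 1e-6)
  # direct oracle: superpose all frames on the converged mean, then the
  # per-residue root mean square about the mean
  ca <- ca_indices(sys)
  aligned <- lapply(frames, identity)
  for (pass in 1:6) {
    mean_ca <- Reduce(`+`, lapply(aligned, function(x) x[ca, ])) /
      length(aligned)
    ref_full <- frames[[1L]]; ref_full[ca, ] <- mean_ca
    aligned <- lapply(aligned, function(x)
      apply_superposition(superpose(x, ref_full, ca), x))
  }
  mean_ca <- Reduce(`+`, lapply(aligned, function(x) x[ca, ])) /
    length(aligned)
  o <- sqrt(Reduce(`+`, lapply(aligned, function(x)
    rowSums((x[ca, ] - mean_ca)^2))) / length(aligned))
  expect_equal(base$rmsf[sys$atoms$res[ca]], o, tolerance = 1e-3)
})

test_that("dihedral variation: constant angles give 0, wrapping is safe", {
  toy <- toy_complex()
  sys <- toy$system
  ref <- sys$reference_coords
  ens0 <- ensemble(sys, list(ref, ref, ref), dt = 1)
  v0 <- dihedral_variation(ens0)
  expect_true(all(abs(v0$variation[!is.na(v0$variation)]) < 1e-8))
  # circular SD of +/- 10 degrees about a mean is ~10 degrees,
  # independent of where the mean sits on the circle (wraparound check)
  circ_sd <- function(theta) {
    th <- theta * pi / 180
    sqrt(-2 * log(sqrt(mean(cos(th))^2 + mean(sin(th))^2))) * 180 / pi
  }
  expect_equal(circ_sd(c(-10, 10)), circ_sd(c(170, -170)), tolerance = 1e-9)
  expect_equal(circ_sd(c(-10, 10)), 10, tolerance = 0.1)
})

test_that("helical content: canonical helix 1, extended strand 0, half is half", {
  # ideal helix: helix_fraction = 1 builds phi=-57, psi=-47 everywhere
  spec_h <- synthetic_spec(seed = 6, chain_lengths = c(A = 12L, B = 12L),
                           helix_fraction = 1)
  toy_h <- build_toy_complex(spec_h, separation = 60)
  ens_h <- ensemble(toy_h$system,
                    list(toy_h$system$reference_coords,
                         toy_h$system$reference_coords), dt = 1)
  h <- helical_content(ens_h)
  # termini lack phi or psi and cannot count as helical
  expect_gte(h, (12 - 2) / 12 - 1e-9)
  region <- 2:11
  expect_equal(helical_content(ens_h, region = region), 1)
  # strand: phi = -120, psi = +120 is far outside the helical window
  spec_s <- synthetic_spec(seed = 6, chain_lengths = c(A = 12L, B = 12L),
                           helix_fraction = 0)
  # coil is random; build an explicit strand through the spec is not
  # possible, so check the window logic directly on known dihedrals
  expect_false(-120 >= -100 && -120 <= -30)
  toy_s <- build_toy_complex(spec_s, separation = 60)
  ens_s <- ensemble(toy_s$system,
                    list(toy_s$system$reference_coords,
                         toy_s$system$reference_coords), dt = 1)
  expect_lt(helical_content(ens_s), 0.5)
  # half-helical: first half helix, second half coil, via helix_fraction
  spec_half <- synthetic_spec(seed = 6, chain_lengths = c(A = 20L, B = 12L),
                              helix_fraction = 0.5)
  toy_half <- build_toy_complex(spec_half, separation = 60)
  ens_half <- ensemble(toy_half$system,
                       list(toy_half$system$reference_coords), dt = 1)
  hH <- helical_content(ens_half, region = which(
    toy_half$system$residues$chain == "A"))
  expect_gt(hH, 0.2); expect_lt(hH, 0.75)
})

test_that("distance-difference maps: zeros, scaling sign, antisymmetry, oracle", {
  toy <- toy_complex()
  sys <- toy$system
  ref <- sys$reference_coords
  set.seed(17)
  frames_a <- lapply(1:4, function(i)
    ref + matrix(rnorm(length(ref), sd = 0.2), ncol = 3L))
  apo <- ensemble(sys, frames_a, dt = 1)
  same <- distance_difference_map(apo, apo, "A")
  expect_equal(max(abs(same)), 0)
  expect_equal(unclass(same), t(unclass(same)))
  # uniform scaling of the bound state stretches every pair
  bound_scaled <- ensemble(sys, lapply(frames_a, function(x) x * 1.1), dt = 1)
  dd <- distance_difference_map(bound_scaled, apo, "A")
  off <- dd[upper.tri(dd)]
  expect_true(all(off > 0))
  expect_equal(unname(diag(unclass(dd))), rep(0, nrow(dd)))
  # antisymmetric under swapping roles
  dd_swap <- distance_difference_map(apo, bound_scaled, "A")
  expect_equal(unclass(dd), -unclass(dd_swap), tolerance = 1e-12)
  # averaging oracle on a small entry set
  ca <- ca_indices(sys, "A")
  d_mean <- function(ens, i, j) mean(vapply(seq_len(n_frames(ens)),
    function(f) sqrt(sum((frame_coords(ens, f)[ca[i], ] -
                          frame_coords(ens, f)[ca[j], ])^2)), 0))
  for (pr in list(c(1, 5), c(2, 9))) {
    expect_equal(dd[pr[1], pr[2]],
                 d_mean(bound_scaled, pr[1], pr[2]) - d_mean(apo, pr[1], pr[2]),
                 tolerance = 1e-10)
  }
})

test_that("free-energy landscape: normalisation, min F = 0, basins", {
  toy <- toy_complex()
  sys <- toy$system
  ref <- sys$reference_coords
  # degenerate: all frames identical -> one occupied cell at F = 0
  ens1 <- suppressWarnings(free_energy_landscape(
    ensemble(sys, replicate(10L, ref, simplify = FALSE), dt = 1)))
  expect_equal(sum(ens1$P), 1)
  expect_equal(sum(ens1$P > 0), 1L)
  expect_equal(min(ens1$F[is.finite(ens1$F)]), 0)
  # two equally populated conformers: two cells with F = 0
  alt <- ref * 1.25
  ens2 <- suppressWarnings(free_energy_landscape(
    ensemble(sys, rep(list(ref, alt), 10L), dt = 1)))
  expect_equal(sum(ens2$P), 1)
  zero_cells <- sum(abs(ens2$F) < 1e-12 & is.finite(ens2$F))
  expect_equal(zero_cells, 2L)
  # random ensemble: invariants hold, basins are non-empty cell sets
  set.seed(23)
  frames <- lapply(1:60, function(i)
    ref + matrix(rnorm(length(ref), sd = 0.4), ncol = 3L))
  fel <- free_energy_landscape(ensemble(sys, frames, dt = 1))
  expect_equal(sum(fel$P), 1)
  expect_equal(min(fel$F[is.finite(fel$F)]), 0)
  expect_gte(length(fel$basins), 1L)
  expect_true(all(vapply(fel$basins, function(b) length(b$frames) > 0, TRUE)))
})

test_that("gaussian cloud landscape approximates the analytic density", {
  toy <- toy_complex()
  sys <- toy$system
  ref <- sys$reference_coords
  set.seed(29)
  n <- 400L
  frames <- lapply(seq_len(n), function(i)
    ref + matrix(rnorm(length(ref), sd = 0.5), ncol = 3L))
  fel <- free_energy_landscape(ensemble(sys, frames, dt = 1),
                               rg_bin = 0.1, rmsd_bin = 0.1)
  # compare F to -ln of a 2D gaussian KDE-free analytic surrogate: use
  # the empirical mean/sd of (rg, rmsd) and check occupied-cell F against
  # the fitted normal density within a generous 3-sigma style band
  mu <- c(mean(fel$rg), mean(fel$rmsd))
  sd2 <- c(sd(fel$rg), sd(fel$rmsd))
  occ <- which(fel$P > 0, arr.ind = TRUE)
  mids1 <- fel$rg_edges[-1L] - diff(fel$rg_edges) / 2
  mids2 <- fel$rmsd_edges[-1L] - diff(fel$rmsd_edges) / 2
  f_obs <- fel$F[occ]
  f_ana <- -log(stats::dnorm(mids1[occ[, 1L]], mu[1L], sd2[1L]) *
                  stats::dnorm(mids2[occ[, 2L]], mu[2L], sd2[2L]))
  f_ana <- f_ana - min(f_ana)
  # cells with decent occupancy agree within sampling noise
  good <- fel$P[occ] >= 5 / n
  expect_gt(stats::cor(f_obs[good], f_ana[good]), 0.6)
  expect_lt(mean(abs(f_obs[good] - f_ana[good])), 1)
})
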