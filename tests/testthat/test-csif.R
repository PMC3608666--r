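# CS/IF quantification: pairing, distance bins, profiles, KS map, Delta.

csif_ens <- function(mech = "cs_dominant", seed = 3L) {
  cached(paste0("csif_", mech, "_", seed), function()
    sample_csif_ensembles(synthetic_spec(seed = seed), mech,
                          toy_complex(seed)))
}

test_that("bound/apo pairing: grid size, exact-copy argmin, oracle agreement", {
  ens <- csif_ens()
  pa <- pair_bound_apo(ens$bound, ens$apo, ens$chain, 10L, 10L)
  expect_equal(dim(pa$grid), c(10L, 10L))
  expect_equal(length(pa$grid), 100L)
  # argmin matches an exhaustive scan of the grid
  expect_equal(pa$best, apply(pa$grid, 1L, which.min))
  expect_equal(pa$best_rmsd, apply(pa$grid, 1L, min))
  # planting an exact copy of a bound frame at a sampled apo position
  sys <- ens$bound$system
  chain_idx <- chain_atom_indices(sys, ens$chain)
  apo2 <- ens$apo
  target <- pa$apo_frames[3L]
  apo2$coords[target, , ] <- frame_coords(ens$bound, pa$bound_frames[1L])[chain_idx, ]
  pa2 <- pair_bound_apo(ens$bound, apo2, ens$chain, 10L, 10L)
  expect_equal(pa2$best[1L], 3L)
  expect_lt(pa2$best_rmsd[1L], 1e-8)
  # atom mismatch is refused
  expect_error(pair_bound_apo(ens$bound, ens$bound, ens$chain), "atom count")
})

test_that("distance bins implement half-open 0.5 A intervals up to 50 A", {
  ens <- csif_ens()
  sys <- ens$bound$system
  db <- distance_bins(sys$reference_coords, sys, ens$chain)
  # bin arithmetic: d = 0.74 -> bin [0.5, 1.0) = bin 2
  expect_equal(floor(0.74 / 0.5) + 1L, 2L)
  d <- db$dist
  inside <- d < 50
  expect_equal(db$bin[inside], floor(d[inside] / 0.5) + 1L)
  expect_true(all(is.na(db$bin[!inside])))
  # partition: every atom below 50 A is in exactly one of 100 bins
  expect_equal(sum(!is.na(db$bin)), sum(inside))
  expect_true(all(db$bin[inside] >= 1L & db$bin[inside] <= 100L))
  # boundary atom at exactly 50 A overflows
  sys2 <- sys
  ctr <- db$centroid
  chain_idx <- chain_atom_indices(sys, ens$chain)
  xyz <- sys$reference_coords
  v <- xyz[chain_idx[1L], ] - ctr
  xyz[chain_idx[1L], ] <- ctr + v / sqrt(sum(v^2)) * 50
  db2 <- distance_bins(xyz, sys, ens$chain)
  expect_true(is.na(db2$bin[1L]))
})

test_that("distance binning partitions random coordinates exactly", {
  ens <- csif_ens()
  sys <- ens$bound$system
  set.seed(42)
  for (rep in 1:5) {
    xyz <- matrix(runif(nrow(sys$atoms) * 3L, -60, 60), ncol = 3L)
    db <- distance_bins(xyz, sys, ens$chain)
    inside <- db$dist < 50
    tab <- tabulate(db$bin[inside], nbins = 100L)
    expect_equal(sum(tab), sum(inside))          # count conservation
    expect_equal(db$bin[inside], floor(db$dist[inside] / 0.5) + 1L)
  }
})

test_that("local profiles: zero for copies, localized for far perturbations", {
  spec0 <- synthetic_spec(seed = 4, amplitude_near = 0, amplitude_far = 0,
                          residual = 0, if_amplitude = 0)
  ens <- sample_csif_ensembles(spec0, "cs_dominant", toy_complex(4L))
  sys <- ens$bound$system
  chain_idx <- chain_atom_indices(sys, ens$chain)
  nb <- 4L
  # apo identical to the bound chain: every defined bin is 0
  pa <- pair_bound_apo(ens$bound, ens$apo, ens$chain, nb, nb)
  prof <- local_rmsd_profile(ens$bound, ens$apo, pa)
  expect_true(all(prof$per_pair[!is.na(prof$per_pair)] < 1e-8))

  # perturb only apo atoms beyond 18 A of the partner centroid
  db <- distance_bins(sys$reference_coords, sys, ens$chain)
  far <- db$dist > 18
  set.seed(7)
  apo_pert <- ens$apo
  for (f in seq_len(n_frames(apo_pert))) {
    x <- frame_coords(ens$apo, f)
    x[far, ] <- x[far, ] + matrix(rnorm(sum(far) * 3L, sd = 1), sum(far), 3L)
    apo_pert$coords[f, , ] <- x
  }
  pa2 <- pair_bound_apo(ens$bound, apo_pert, ens$chain, nb, nb)
  prof2 <- local_rmsd_profile(ens$bound, apo_pert, pa2)
  near_vals <- mean(prof2$rmsd_other[which(db$edges[-1L] <= 14)], na.rm = TRUE)
  far_vals <- mean(prof2$rmsd_other[which(db$edges[-length(db$edges)] >= 20)],
                   na.rm = TRUE)
  # the global CA fit bleeds a little deviation into near bins, but the
  # perturbed far region must dominate clearly
  expect_gt(far_vals, 2 * near_vals)
  expect_gt(far_vals, 0.5)
})

test_that("ks_map: identical samples P=1, separated samples P~0, calibrated null", {
  set.seed(1)
  x <- rnorm(50L)
  km_same <- ks_map(list(list(x)), list(x))
  expect_equal(unname(km_same$p[1L, 1L]), 1, tolerance = 1e-9)
  km_shift <- ks_map(list(list(x + 5)), list(x))
  expect_lt(km_shift$p[1L, 1L], 1e-6)
  # null calibration (small version): independent replicates, each a
  # fresh pair-vs-baseline comparison from the same distribution
  set.seed(2)
  p_null <- replicate(200L, {
    km <- ks_map(list(list(rnorm(100L))), list(rnorm(99L)))
    km$p[1L, 1L]
  })
  expect_gt(mean(p_null < 0.1), 0.04)
  expect_lt(mean(p_null < 0.1), 0.18)
  # sparse bins yield NA, not errors
  km_na <- ks_map(list(list(numeric(0))), list(rnorm(10L)))
  expect_true(is.na(km_na$p[1L, 1L]))
})

test_that("delta statistic: identity, means, antisymmetry, bin-width independence", {
  expect_equal(delta_statistic(c(1, 2, 3), c(1, 2, 3))$delta, 0)
  expect_equal(delta_statistic(c(2, 2, 2), c(1, 1, 1))$delta, 1)
  set.seed(3)
  a <- runif(40L, 0, 4); b <- runif(25L, 0, 4)
  d1 <- delta_statistic(a, b, bin_width = 0.25)
  d2 <- delta_statistic(b, a, bin_width = 0.25)
  expect_equal(d1$delta, -d2$delta)
  d3 <- delta_statistic(a, b, bin_width = 0.8)
  expect_equal(d1$delta, d3$delta)   # weighted-mean form: bin-width free
  expect_equal(sum(d1$cs_histogram$frequency), d1$n_cs)
  expect_equal(sum(d1$if_histogram$frequency), d1$n_if)
  expect_error(delta_statistic(numeric(0), 1), "nonempty")
})

test_that("planted mechanisms give the expected Delta signs", {
  res_cs <- csif_analysis(csif_ens("cs_dominant")$bound,
                          csif_ens("cs_dominant")$apo, "A",
                          compute_ks = FALSE)
  expect_gt(res_cs$delta_global$delta, 0)
  expect_match(res_cs$verdict, "global conformational selection")
  res_if <- csif_analysis(csif_ens("if_dominant")$bound,
                          csif_ens("if_dominant")$apo, "A",
                          compute_ks = FALSE)
  expect_lt(res_if$delta_local$delta, 0)
  expect_match(res_if$verdict, "local induced fit")
  res_mx <- csif_analysis(csif_ens("mixed")$bound, csif_ens("mixed")$apo,
                          "A", compute_ks = FALSE)
  expect_gt(res_mx$delta_global$delta, 0)
  expect_lt(res_mx$delta_local$delta, 0)
  expect_equal(res_mx$verdict,
               "global conformational selection and local induced fit")
})

test_that("zero-amplitude ensembles give identically zero profiles", {
  spec0 <- synthetic_spec(seed = 5, amplitude_near = 0, amplitude_far = 0,
                          residual = 0, if_amplitude = 0)
  ens <- sample_csif_ensembles(spec0, "cs_dominant", toy_complex(5L))
  pa <- pair_bound_apo(ens$bound, ens$apo, ens$chain)
  prof <- local_rmsd_profile(ens$bound, ens$apo, pa)
  expect_true(all(prof$per_pair[!is.na(prof$per_pair)] < 1e-8))
})

test_that("the csif pipeline is invariant to rigid motion of the apo ensemble", {
  ens <- csif_ens("mixed")
  res0 <- csif_analysis(ens$bound, ens$apo, ens$chain, compute_ks = FALSE)
  apo_mov <- ens$apo
  for (f in seq_len(n_frames(apo_mov)))
    apo_mov$coords[f, , ] <- random_rigid(frame_coords(ens$apo, f), seed = 77)
  res1 <- csif_analysis(ens$bound, apo_mov, ens$chain, compute_ks = FALSE)
  expect_equal(res1$delta_global$delta, res0$delta_global$delta,
               tolerance = 1e-6)
  expect_equal(res1$delta_local$delta, res0$delta_local$delta,
               tolerance = 1e-6)
  expect_equal(res1$pairing$best, res0$pairing$best)
})

test_that("csif result exports per-bin tables with KS columns", {
  ens <- csif_ens("mixed")
  res <- csif_analysis(ens$bound, ens$apo, ens$chain, compute_ks = TRUE)
  df <- as.data.frame(res)
  expect_equal(nrow(df), 100L)
  expect_true(all(c("bin_lo", "bin_hi", "rmsd_best10", "rmsd_other90",
                    "median_p", "frac_p_lt") %in% names(df)))
  defined <- !is.na(df$median_p)
  expect_true(any(defined))
  expect_true(all(df$median_p[defined] >= 0 & df$median_p[defined] <= 1))
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_csif_tables(res, p1, p2)
  expect_equal(nrow(read.delim(p1)), 100L)
  expect_equal(read.delim(p2)$scope, c("global", "local"))
})
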