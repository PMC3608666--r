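# Conformational selection vs induced fit quantification:
# min-RMSD bound/apo pairing, distance-binned local deviations, per-bin
# Kolmogorov-Smirnov significance maps, and the signed Delta statistic.

.even_indices <- function(n, k) {
  if (n < k) stop("cannot sample ", k, " frames evenly from ", n)
  unique(round(seq(1L, n, length.out = k)))
}

#' Pair bound conformations with their most-similar apo conformations
#'
#' Samples `n_bound` frames evenly in time from the bound ensemble and
#' `n_apo` from the apo ensemble, computes the all-C-alpha superposed RMSD
#' for every pair (the `n_bound x n_apo` grid; 10 x 10 = 100 pairs by
#' default) over the atoms of the analysed chain, and records for each
#' bound frame the apo frame minimising the RMSD (ties broken by the
#' earlier apo timestamp).
#'
#' @param bound [ensemble()] of the bound complex (contains the analysed
#'   chain and its partner).
#' @param apo [ensemble()] of the apo analysed chain; its atoms must match
#'   the analysed-chain atoms of the bound system, in order.
#' @param chain label of the analysed chain in the bound system.
#' @param n_bound,n_apo number of frames sampled from each ensemble.
#' @return object of class `pair_assignment` with the RMSD `grid`,
#'   sampled frame indices, and per-bound-frame `best` apo index and
#'   `best_rmsd`.
#' @export
pair_bound_apo <- function(bound, apo, chain, n_bound = 10L, n_apo = 10L) {
  bsys <- bound$system
  chain_idx <- chain_atom_indices(bsys, chain)
  if (length(chain_idx) != nrow(apo$system$atoms))
    stop("apo ensemble atom count (", nrow(apo$system$atoms),
         ") does not match bound chain ", chain, " (", length(chain_idx), ")")
  ca_b <- match(ca_indices(bsys, chain), chain_idx)
  bi <- .even_indices(n_frames(bound), n_bound)
  ai <- .even_indices(n_frames(apo), n_apo)
  grid <- matrix(0, length(bi), length(ai))
  for (p in seq_along(bi)) {
    bxyz <- frame_coords(bound, bi[p])[chain_idx, , drop = FALSE]
    for (q in seq_along(ai)) {
      grid[p, q] <- rmsd(frame_coords(apo, ai[q]), bxyz, ca_b, fit = TRUE)
    }
  }
  best <- apply(grid, 1L, which.min)     # first minimum = earliest apo time
  structure(list(grid = grid, bound_frames = bi, apo_frames = ai,
                 best = best,
                 best_rmsd = grid[cbind(seq_along(bi), best)],
                 chain = chain),
            class = "pair_assignment")
}

#' @export
print.pair_assignment <- function(x, ...) {
  cat("pair_assignment: ", nrow(x$grid), " bound x ", ncol(x$grid),
      " apo frames (", length(x$grid), " pairs), chain ", x$chain, "\n",
      sep = "")
  cat(sprintf("  best-pair RMSD: %.3f .. %.3f Angstrom\n",
              min(x$best_rmsd), max(x$best_rmsd)))
  invisible(x)
}

#' Assign analysed-chain atoms to partner-centroid distance bins
#'
#' The centroid is the mass-weighted center of the partner chain in the
#' bound conformation. Every analysed-chain atom with distance `d < 50` A
#' falls in the half-open bin `[floor(d / 0.5) * 0.5, +0.5)`; atoms at
#' 50 A or beyond go to an overflow group excluded from the 100 bins.
#'
#' @param bound_coords `atoms x 3` coordinates of one bound-complex frame.
#' @param system the bound-complex [system_model()].
#' @param chain analysed chain label (partner = all other chains).
#' @param bin_width,max_dist bin width and range in Angstrom.
#' @return object of class `distance_bins`: `atom_idx` (indices of the
#'   analysed chain's atoms in the bound system), `bin` (bin index per
#'   atom, `NA` = overflow), `edges`, `centroid`, `dist`.
#' @export
distance_bins <- function(bound_coords, system, chain, bin_width = 0.5,
                          max_dist = 50) {
  chain_idx <- chain_atom_indices(system, chain)
  partner_idx <- setdiff(seq_len(nrow(system$atoms)), chain_idx)
  if (!length(partner_idx)) stop("no partner chain distinct from ", chain)
  centroid <- center_of_mass(bound_coords, system, partner_idx)
  d <- sqrt(rowSums(sweep(bound_coords[chain_idx, , drop = FALSE],
                          2L, centroid)^2))
  nbin <- as.integer(round(max_dist / bin_width))
  bin <- ifelse(d < max_dist, floor(d / bin_width) + 1L, NA_integer_)
  structure(list(atom_idx = chain_idx, bin = as.integer(bin),
                 dist = d, centroid = centroid,
                 edges = seq(0, max_dist, by = bin_width), n_bins = nbin),
            class = "distance_bins")
}

# per-atom deviation of one apo frame from one bound frame after global
# all-CA superposition of the apo chain onto the bound chain
.pair_deviation <- function(bound_chain_xyz, apo_xyz, ca_in_chain) {
  sp <- superpose(apo_xyz, bound_chain_xyz, ca_in_chain)
  fitted <- apply_superposition(sp, apo_xyz)
  sqrt(rowSums((fitted - bound_chain_xyz)^2))
}

#' Distance-resolved local RMSD profiles of bound-vs-apo deviations
#'
#' For each sampled (bound, apo) pair, the apo conformation is superposed
#' onto the bound one by all C-alpha atoms of the analysed chain, per-atom
#' deviations are taken, and a per-bin RMSD is computed over the atoms of
#' each partner-centroid distance bin (bins from the bound frame's
#' geometry). Profiles are averaged separately over the most-similar pairs
#' (one per bound frame) and over the remaining pairs.
#'
#' @inheritParams pair_bound_apo
#' @param pairing a [pair_bound_apo()] result for the same ensembles.
#' @param bin_width,max_dist see [distance_bins()].
#' @return object of class `local_rmsd_profile`: matrix `per_pair`
#'   (`n_bound * n_apo` rows x bins), logical `is_best` per row, averaged
#'   `rmsd_best` / `rmsd_other` per bin, per-pair per-atom deviations in
#'   `deviations` and bin memberships in `bins` (per bound frame).
#' @export
local_rmsd_profile <- function(bound, apo, pairing, bin_width = 0.5,
                               max_dist = 50) {
  sys <- bound$system
  chain <- pairing$chain
  chain_idx <- chain_atom_indices(sys, chain)
  ca_in_chain <- match(ca_indices(sys, chain), chain_idx)
  nbin <- as.integer(round(max_dist / bin_width))
  nb <- length(pairing$bound_frames)
  na_ <- length(pairing$apo_frames)
  per_pair <- matrix(NA_real_, nb * na_, nbin)
  is_best <- logical(nb * na_)
  devs <- vector("list", nb * na_)
  bins <- vector("list", nb)
  row <- 0L
  for (p in seq_len(nb)) {
    bxyz_full <- frame_coords(bound, pairing$bound_frames[p])
    db <- distance_bins(bxyz_full, sys, chain, bin_width, max_dist)
    bins[[p]] <- db
    bxyz <- bxyz_full[chain_idx, , drop = FALSE]
    grp <- factor(db$bin, levels = seq_len(nbin))
    for (q in seq_len(na_)) {
      row <- row + 1L
      axyz <- frame_coords(apo, pairing$apo_frames[q])
      dev <- .pair_deviation(bxyz, axyz, ca_in_chain)
      devs[[row]] <- dev
      ms <- tapply(dev^2, grp, mean)
      per_pair[row, ] <- sqrt(as.numeric(ms))
      is_best[row] <- pairing$best[p] == q
    }
  }
  col_mean <- function(m) {
    out <- colMeans(m, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  }
  structure(list(per_pair = per_pair, is_best = is_best,
                 rmsd_best = col_mean(per_pair[is_best, , drop = FALSE]),
                 rmsd_other = col_mean(per_pair[!is_best, , drop = FALSE]),
                 deviations = devs, bins = bins,
                 edges = seq(0, max_dist, by = bin_width),
                 chain = chain),
            class = "local_rmsd_profile")
}

#' Per-bin Kolmogorov-Smirnov significance map
#'
#' For every distance bin, each pair's sample of per-atom deviations is
#' compared against the pooled baseline sample with the two-sample KS
#' test, and the per-bin median P value and fraction of pairs with
#' `P < p_threshold` are reported. Exactness follows [stats::ks.test()]'s
#' default: exact for small samples, asymptotic against large pooled
#' baselines. (With unequal per-bin sample sizes the exact null P
#' distribution is fine-grained and calibrated; forcing equal small
#' samples would make it discrete and conservative.)
#'
#' @param pair_samples list over pairs; each element a list over bins of
#'   numeric deviation vectors.
#' @param baseline_samples list over bins of pooled baseline deviation
#'   vectors.
#' @param p_threshold significance threshold (0.1).
#' @param exact passed to [stats::ks.test()] (`NULL`: its default rule).
#' @param min_n minimum sample size per side for a defined P.
#' @return object of class `ks_map`: matrix `p` (pairs x bins), vectors
#'   `median_p` and `frac_lt` per bin.
#' @export
ks_map <- function(pair_samples, baseline_samples, p_threshold = 0.1,
                   exact = NULL, min_n = 2L) {
  n_pairs <- length(pair_samples)
  n_bins <- length(baseline_samples)
  p <- matrix(NA_real_, n_pairs, n_bins)
  for (b in seq_len(n_bins)) {
    base <- baseline_samples[[b]]
    if (length(base) < min_n) next
    for (k in seq_len(n_pairs)) {
      x <- pair_samples[[k]][[b]]
      if (length(x) < min_n) next
      p[k, b] <- suppressWarnings(
        stats::ks.test(x, base, exact = exact)$p.value)
    }
  }
  median_p <- apply(p, 2L, stats::median, na.rm = TRUE)
  frac_lt <- apply(p, 2L, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(NA_real_)
    mean(col[ok] < p_threshold)
  })
  median_p[is.nan(median_p)] <- NA_real_
  structure(list(p = p, median_p = median_p, frac_lt = frac_lt,
                 p_threshold = p_threshold),
            class = "ks_map")
}

#' @export
print.ks_map <- function(x, ...) {
  def <- !is.na(x$median_p)
  cat("ks_map:", nrow(x$p), "pairs x", ncol(x$p), "bins (",
      sum(def), "bins defined )\n")
  if (any(def))
    cat(sprintf("  median P over defined bins: %.3g; mean fraction P<%g: %.3f\n",
                stats::median(x$median_p[def]), x$p_threshold,
                mean(x$frac_lt[def])))
  invisible(x)
}

#' Signed Delta statistic: conformational selection vs induced fit
#'
#' Builds frequency histograms of the conformational-selection magnitude
#' values and of the induced-fit magnitude values and reports the
#' probability-weighted difference of their means,
#' `Delta = sum(f_i x_i) / N_CS - sum(f_j x_j) / N_IF`.
#' Because the frequency-weighted mean of the observed values equals the
#' sample mean, Delta is independent of the histogram bin width (the
#' histograms are kept for reporting). `Delta > 0` means the
#' conformational-selection magnitude dominates.
#'
#' @param cs_values RMSD magnitudes attributed to conformational
#'   selection (spread among apo conformations), Angstrom.
#' @param if_values RMSD magnitudes attributed to induced fit (residual
#'   bound-to-most-similar-apo deviations), Angstrom.
#' @param bin_width histogram bin width (Angstrom) for reporting.
#' @param scope `"global"` or `"local"` labelling.
#' @return object of class `delta_stat` with `delta` (A, signed),
#'   histograms and counts.
#' @export
delta_statistic <- function(cs_values, if_values, bin_width = 0.25,
                            scope = "global") {
  if (!length(cs_values) || !length(if_values))
    stop("both value sets must be nonempty")
  hist_of <- function(v) {
    br <- seq(0, max(v, bin_width) + bin_width, by = bin_width)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    data.frame(value = h$mids, frequency = h$counts)
  }
  structure(list(delta = mean(cs_values) - mean(if_values),
                 scope = scope,
                 cs_histogram = hist_of(cs_values),
                 if_histogram = hist_of(if_values),
                 n_cs = length(cs_values), n_if = length(if_values)),
            class = "delta_stat")
}

#' @export
print.delta_stat <- function(x, ...) {
  cat(sprintf("delta_stat [%s]: Delta = %+.3f Angstrom (n_cs = %d, n_if = %d)\n",
              x$scope, x$delta, x$n_cs, x$n_if))
  cat("  ", if (x$delta > 0) "conformational selection magnitude dominates"
      else if (x$delta < 0) "induced fit magnitude dominates"
      else "balanced", "\n")
  invisible(x)
}

# local atom subset (within cutoff of the partner centroid) measured on
# a representative bound conformation, as positions within the chain
# atom list
.local_atom_subset <- function(coords, system, chain, local_cutoff) {
  db <- distance_bins(coords, system, chain,
                      bin_width = local_cutoff, max_dist = 2 * local_cutoff)
  which(db$dist < local_cutoff)
}

# mean bound conformation over all frames: a stable geometry for the
# local-scope atom set and the baseline binning
.mean_bound_coords <- function(bound) {
  apply(bound$coords, c(2L, 3L), mean)
}

#' Full conformational-selection / induced-fit analysis for one chain
#'
#' Runs the whole distance-resolved deviation pipeline: even-time frame
#' sampling and min-RMSD bound/apo pairing, per-bin local RMSD profiles
#' (most-similar pairs vs the rest), the per-bin KS significance map
#' against the apo-vs-apo baseline, and the Delta statistic at global
#' scope (all chain atoms) and local scope (atoms within `local_cutoff`
#' of the partner centroid, measured on the ensemble-mean bound
#' conformation for stability).
#'
#' CS magnitudes are the pairwise RMSDs among the sampled apo
#' conformations (the spread available for selection); IF magnitudes are
#' the residual RMSDs between each bound frame and its most-similar apo
#' frame. All RMSDs are measured over the chain's atoms after all-C-alpha
#' superposition.
#'
#' @inheritParams pair_bound_apo
#' @param local_cutoff local-scope distance cutoff (Angstrom).
#' @param bin_width,max_dist distance-bin geometry.
#' @param compute_ks set `FALSE` to skip the (slower) KS map.
#' @param p_threshold KS significance threshold.
#' @return object of class `csif_result`.
#' @export
csif_analysis <- function(bound, apo, chain, n_bound = 10L, n_apo = 10L,
                          local_cutoff = 10, bin_width = 0.5, max_dist = 50,
                          compute_ks = TRUE, p_threshold = 0.1) {
  sys <- bound$system
  pairing <- pair_bound_apo(bound, apo, chain, n_bound, n_apo)
  prof <- local_rmsd_profile(bound, apo, pairing, bin_width, max_dist)
  chain_idx <- chain_atom_indices(sys, chain)
  ca_in_chain <- match(ca_indices(sys, chain), chain_idx)
  mean_bound <- .mean_bound_coords(bound)
  local_atoms <- .local_atom_subset(mean_bound, sys, chain, local_cutoff)
  if (!length(local_atoms))
    stop("no atoms of chain ", chain, " within ", local_cutoff,
         " Angstrom of the partner centroid on the reference structure: ",
         "increase local_cutoff")

  # apo-apo spread: deviations between sampled apo conformations
  ai <- pairing$apo_frames
  apo_xyz <- lapply(ai, function(f) frame_coords(apo, f))
  apo_pairs <- t(utils::combn(length(ai), 2L))
  cs_dev <- vector("list", nrow(apo_pairs))
  for (r in seq_len(nrow(apo_pairs))) {
    cs_dev[[r]] <- .pair_deviation(apo_xyz[[apo_pairs[r, 1L]]],
                                   apo_xyz[[apo_pairs[r, 2L]]], ca_in_chain)
  }
  rms <- function(v) sqrt(mean(v^2))
  cs_global <- vapply(cs_dev, rms, 0)
  cs_local <- vapply(cs_dev, function(d) rms(d[local_atoms]), 0)

  best_rows <- which(prof$is_best)
  if_dev <- prof$deviations[best_rows]
  if_global <- vapply(if_dev, rms, 0)
  if_local <- vapply(if_dev, function(d) rms(d[local_atoms]), 0)

  delta_global <- delta_statistic(cs_global, if_global, scope = "global")
  delta_local <- delta_statistic(cs_local, if_local, scope = "local")

  km <- NULL
  if (compute_ks) {
    nbin <- as.integer(round(max_dist / bin_width))
    # baseline: pooled apo-apo deviations binned on the mean bound geometry
    ref_bins <- distance_bins(mean_bound, sys, chain,
                              bin_width, max_dist)$bin
    baseline <- lapply(seq_len(nbin), function(b) {
      unlist(lapply(cs_dev, function(d) d[which(ref_bins == b)]),
             use.names = FALSE)
    })
    nb <- length(pairing$bound_frames)
    na_ <- length(pairing$apo_frames)
    pair_samples <- vector("list", nb * na_)
    row <- 0L
    for (p in seq_len(nb)) {
      bb <- prof$bins[[p]]$bin
      by_bin <- lapply(seq_len(nbin), function(b) which(bb == b))
      for (q in seq_len(na_)) {
        row <- row + 1L
        dev <- prof$deviations[[row]]
        pair_samples[[row]] <- lapply(by_bin, function(idx) dev[idx])
      }
    }
    km <- ks_map(pair_samples, baseline, p_threshold)
  }

  verdict <- character(0)
  if (delta_global$delta > 0) verdict <- c(verdict, "global conformational selection")
  if (delta_local$delta < 0) verdict <- c(verdict, "local induced fit")
  if (!length(verdict)) verdict <- "indeterminate"

  structure(list(chain = chain, pairing = pairing, profile = prof,
                 ks = km, delta_global = delta_global,
                 delta_local = delta_local,
                 local_atoms = local_atoms,
                 verdict = paste(verdict, collapse = " and ")),
            class = "csif_result")
}

#' @export
print.csif_result <- function(x, ...) {
  cat("csif_result for chain", x$chain, "\n")
  cat(sprintf("  Delta_global = %+.3f A, Delta_local = %+.3f A\n",
              x$delta_global$delta, x$delta_local$delta))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' @export
summary.csif_result <- function(object, ...) {
  df <- as.data.frame(object)
  cat("per-bin profile (defined bins):",
      sum(!is.na(df$rmsd_other)), "of", nrow(df), "\n")
  print.csif_result(object)
  invisible(df)
}

#' @export
as.data.frame.csif_result <- function(x, ...) {
  prof <- x$profile
  edges <- prof$edges
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    rmsd_best10 = prof$rmsd_best,
                    rmsd_other90 = prof$rmsd_other)
  if (!is.null(x$ks)) {
    out$median_p <- x$ks$median_p
    out$frac_p_lt <- x$ks$frac_lt
  }
  out
}

#' @export
plot.csif_result <- function(x, ...) {
  df <- as.data.frame(x)
  mid <- (df$bin_lo + df$bin_hi) / 2
  graphics::plot(mid, df$rmsd_other90, type = "l", col = "grey40",
                 xlab = "distance from partner centroid (A)",
                 ylab = "local RMSD (A)", ...)
  graphics::lines(mid, df$rmsd_best10, col = "red3", lwd = 2)
  graphics::legend("topleft", c("most-similar pairs", "other pairs"),
                   col = c("red3", "grey40"), lwd = c(2, 1), bty = "n")
  invisible(x)
}

#' Write the per-bin CS/IF profile and Delta report as TSV
#'
#' @param x a [csif_analysis()] result.
#' @param profile_path,delta_path output paths (either may be `NULL`).
#' @export
write_csif_tables <- function(x, profile_path = NULL, delta_path = NULL) {
  if (!is.null(profile_path))
    utils::write.table(as.data.frame(x), profile_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(delta_path)) {
    df <- data.frame(scope = c("global", "local"),
                     delta = c(x$delta_global$delta, x$delta_local$delta),
                     n_cs = c(x$delta_global$n_cs, x$delta_local$n_cs),
                     n_if = c(x$delta_global$n_if, x$delta_local$n_if))
    utils::write.table(df, delta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}
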