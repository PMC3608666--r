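# Transition-state identification: pairwise-RMSD Sammon projection,
# time-contiguous segmentation, TS ensemble extraction, Phi-values.

#' Pairwise C-alpha RMSD matrix over strided frames
#'
#' @param ens an [ensemble()].
#' @param stride keep every `stride`-th frame (>= 1).
#' @param atom_selection atoms to fit and measure on; default all
#'   C-alphas.
#' @return object of class `rmsd_matrix`: symmetric matrix `mat` (A),
#'   plus the retained `frames` (indices into the ensemble) and `times`.
#' @export
rmsd_matrix <- function(ens, stride = 1L, atom_selection = NULL) {
  stopifnot(stride >= 1L)
  keep <- seq(1L, n_frames(ens), by = stride)
  if (length(keep) < 2L) stop("fewer than 2 frames after striding")
  sel <- if (is.null(atom_selection)) ca_indices(ens$system) else atom_selection
  n <- length(keep)
  # centered selections once per frame; pairwise fitted RMSD via the
  # closed-form Kabsch identity rmsd^2 = (|P|^2 + |Q|^2 - 2 D) / n_sel,
  # D = sum of singular values of P'Q (smallest sign-corrected)
  cc <- lapply(keep, function(f) {
    x <- frame_coords(ens, f)[sel, , drop = FALSE]
    sweep(x, 2L, colMeans(x))
  })
  tr <- vapply(cc, function(x) sum(x^2), 0)
  nsel <- length(sel)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    s <- svd(crossprod(cc[[i]], cc[[j]]))
    D <- sum(s$d[1:2]) + s$d[3L] * sign(det(s$u) * det(s$v))
    v <- sqrt(max(0, (tr[i] + tr[j] - 2 * D) / nsel))
    # the closed form cancels catastrophically near zero; recompute small
    # entries with the explicit rotation
    if (v < 1e-4) {
      d <- sign(det(s$u %*% t(s$v))); if (d == 0) d <- 1
      R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
      v <- sqrt(mean(rowSums((cc[[i]] %*% R - cc[[j]])^2)))
    }
    m[i, j] <- m[j, i] <- v
  }
  structure(list(mat = m, frames = keep, times = ens$times[keep]),
            class = "rmsd_matrix")
}

.sammon_stress <- function(dstar, d, csum) {
  up <- upper.tri(dstar)
  sum((dstar[up] - d[up])^2 / dstar[up]) / csum
}

#' Sammon nonlinear mapping of a distance matrix to 2D
#'
#' Minimises the Sammon stress
#' `E = (1 / sum d*_ij) * sum (d*_ij - d_ij)^2 / d*_ij`
#' over 2D configurations, where `d*` are the input distances and `d` the
#' projected Euclidean distances. Initialisation is classical metric
#' scaling ([stats::cmdscale()]); descent is Sammon's pseudo-Newton step
#' scaled by a magic factor, with step halving so the stress never
#' increases across accepted iterations. Deterministic for a given seed
#' (the seed only matters for degenerate inputs that need jitter).
#'
#' @param d an [rmsd_matrix()], `dist`, or symmetric numeric matrix.
#' @param seed integer seed for jitter of degenerate configurations.
#' @param max_iter maximum iterations.
#' @param tol stop when the stress improvement falls below `tol`.
#' @param magic gradient step scale (Sammon's magic factor).
#' @return object of class `projection_2d`: `points` (n x 2), `stress`,
#'   `stress_trace`, `iterations`, `seed`, and `times` when the input was
#'   an `rmsd_matrix`.
#' @export
sammon_map <- function(d, seed = 1L, max_iter = 500L, tol = 1e-9,
                       magic = 0.3) {
  times <- NULL
  if (inherits(d, "rmsd_matrix")) { times <- d$times; d <- d$mat }
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 points")
  dstar <- d
  zero_off <- dstar <= 0 & upper.tri(dstar)
  if (any(zero_off)) {
    warning("zero distances between distinct frames: jittered by 1e-6")
    dstar[dstar <= 0] <- 1e-6
    diag(dstar) <- 0
    dstar[lower.tri(dstar)] <- t(dstar)[lower.tri(dstar)]
  }
  csum <- sum(dstar[upper.tri(dstar)])

  y <- suppressWarnings(stats::cmdscale(dstar, k = 2L))
  if (ncol(y) < 2L || any(!is.finite(y)))
    y <- .with_seed(seed, matrix(stats::rnorm(n * 2L, sd = 1e-3), n, 2L))
  if (stats::sd(y[, 2L]) < 1e-12)
    y[, 2L] <- y[, 2L] + .with_seed(seed, stats::rnorm(n, sd = 1e-6))

  proj_dist <- function(y) {
    d1 <- outer(y[, 1L], y[, 1L], "-")
    d2 <- outer(y[, 2L], y[, 2L], "-")
    sqrt(d1 * d1 + d2 * d2)
  }
  dy <- proj_dist(y)
  stress <- .sammon_stress(dstar, dy, csum)
  trace <- stress
  iter <- 0L
  eps <- 1e-12
  for (it in seq_len(max_iter)) {
    dcur <- dy; dcur[dcur < eps] <- eps
    off <- dstar > 0
    diag(off) <- FALSE
    # Sammon pseudo-Newton increments: step_pk = grad_pk / |hess_pk|
    # with both derivatives sharing the common factor -2/c, which cancels.
    w <- matrix(0, n, n)
    w[off] <- (dstar[off] - dcur[off]) / (dcur[off] * dstar[off])
    h <- matrix(0, n, 2L)
    for (k in 1:2) {
      diffk <- outer(y[, k], y[, k], "-")
      num <- matrix(0, n, n)
      num[off] <- ((dstar[off] - dcur[off]) -
                     (diffk[off]^2 / dcur[off]) *
                     (1 + (dstar[off] - dcur[off]) / dcur[off])) /
        (dcur[off] * dstar[off])
      h[, k] <- rowSums(num)
    }
    grad <- cbind(rowSums(w * outer(y[, 1L], y[, 1L], "-")),
                  rowSums(w * outer(y[, 2L], y[, 2L], "-")))
    step <- grad / pmax(abs(h), eps)
    accepted <- FALSE
    mf <- magic
    for (half in 1:20) {
      y_new <- y + mf * step
      dy_new <- proj_dist(y_new)
      s_new <- .sammon_stress(dstar, dy_new, csum)
      if (s_new <= stress) { accepted <- TRUE; break }
      mf <- mf / 2
    }
    if (!accepted) break
    improve <- stress - s_new
    y <- y_new; dy <- dy_new; stress <- s_new
    trace <- c(trace, stress)
    iter <- it
    if (improve < tol) break
  }
  structure(list(points = y, stress = stress, stress_trace = trace,
                 iterations = iter, seed = seed, times = times),
            class = "projection_2d")
}

#' @export
print.projection_2d <- function(x, ...) {
  cat(sprintf("projection_2d: %d points, final stress %.3e after %d iterations\n",
              nrow(x$points), x$stress, x$iterations))
  invisible(x)
}

#' @export
plot.projection_2d <- function(x, segmentation = NULL, ...) {
  col <- "grey30"
  if (!is.null(segmentation)) {
    lab <- integer(nrow(x$points))
    for (s in seq_len(nrow(segmentation$segments)))
      lab[segmentation$segments$start[s]:segmentation$segments$end[s]] <- s
    col <- lab + 1L
  }
  graphics::plot(x$points, type = "o", pch = 16, cex = 0.7, col = col,
                 xlab = "NLM dim 1", ylab = "NLM dim 2", ...)
  invisible(x)
}

#' Segment a sequentially-connected projection into conformational clusters
#'
#' Consecutive points of the 2D projection are connected in time; a new
#' segment opens wherever the consecutive-point displacement exceeds
#' `mean + jump_factor * SD` of all consecutive displacements. Segments
#' shorter than `min_len` points are merged into their neighbours.
#'
#' @param projection a [sammon_map()] result (or an n x 2 matrix).
#' @param times per-point timestamps in ps; taken from the projection when
#'   available.
#' @param jump_factor SD multiplier for the jump threshold.
#' @param min_len minimum segment length in points.
#' @return object of class `cluster_segmentation`: data.frame `segments`
#'   (`start`, `end`, `label`, point indices) and `barrier_times` (ps,
#'   midpoint between the frames flanking each inter-segment jump).
#' @export
segment_by_time <- function(projection, times = NULL, jump_factor = 2,
                            min_len = 3L) {
  pts <- if (inherits(projection, "projection_2d")) projection$points
         else as.matrix(projection)
  if (is.null(times) && inherits(projection, "projection_2d"))
    times <- projection$times
  n <- nrow(pts)
  if (is.null(times)) times <- seq_len(n) - 1
  disp <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                        pts[-n, , drop = FALSE])^2))
  thr <- mean(disp) + jump_factor * stats::sd(disp)
  breaks <- which(disp > thr)            # jump between point b and b+1
  bounds <- c(0L, breaks, n)
  segs <- data.frame(start = bounds[-length(bounds)] + 1L,
                     end = bounds[-1L])
  # merge short segments into the longer adjacent neighbour
  repeat {
    len <- segs$end - segs$start + 1L
    short <- which(len < min_len)
    if (!length(short) || nrow(segs) == 1L) break
    s <- short[1L]
    into <- if (s == 1L) 2L
            else if (s == nrow(segs)) s - 1L
            else if ((segs$end[s - 1L] - segs$start[s - 1L]) >=
                     (segs$end[s + 1L] - segs$start[s + 1L])) s - 1L
            else s + 1L
    segs$start[into] <- min(segs$start[into], segs$start[s])
    segs$end[into] <- max(segs$end[into], segs$end[s])
    segs <- segs[-s, , drop = FALSE]
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  segs$label <- seq_len(nrow(segs))
  barrier <- if (nrow(segs) > 1L)
    (times[segs$end[-nrow(segs)]] + times[segs$start[-1L]]) / 2
  else numeric(0)
  structure(list(segments = segs, barrier_times = barrier, times = times),
            class = "cluster_segmentation")
}

#' @export
print.cluster_segmentation <- function(x, ...) {
  cat("cluster_segmentation:", nrow(x$segments), "segment(s)\n")
  for (s in seq_len(nrow(x$segments)))
    cat(sprintf("  segment %d: points %d..%d (t = %g..%g ps)\n",
                s, x$segments$start[s], x$segments$end[s],
                x$times[x$segments$start[s]], x$times[x$segments$end[s]]))
  if (length(x$barrier_times))
    cat("  barriers at t =", paste(signif(x$barrier_times, 6),
                                   collapse = ", "), "ps\n")
  invisible(x)
}

#' Extract the transition-state ensemble around an inter-segment barrier
#'
#' Collects the frames whose timestamps lie within `half_window_ps` of the
#' chosen barrier time.
#'
#' @param ens the full [ensemble()] the segmentation was derived from.
#' @param segmentation a [segment_by_time()] result.
#' @param barrier_index which barrier (1 = first major barrier).
#' @param half_window_ps half-width of the TS window in ps.
#' @return an [ensemble()] containing the TS frames.
#' @export
ts_ensemble <- function(ens, segmentation, barrier_index = 1L,
                        half_window_ps = 40) {
  bt <- segmentation$barrier_times
  if (length(bt) < barrier_index)
    stop("no barrier with index ", barrier_index,
         " (segmentation has ", length(bt), " barrier(s))")
  t0 <- bt[barrier_index]
  keep <- which(abs(ens$times - t0) <= half_window_ps)
  if (!length(keep))
    stop("no frames within ", half_window_ps, " ps of the barrier at ",
         t0, " ps: widen the window")
  ensemble(ens$system, ens$coords[keep, , , drop = FALSE],
           times = ens$times[keep], label = paste0(ens$label, "_ts"))
}

#' Per-residue Phi-values from TS, folded and unfolded ensembles
#'
#' For each residue i and each ensemble X, `N_i^X` is the mean over frames
#' of the number of native contacts involving i whose side-chain
#' heavy-atom criterion (< 6.5 A) holds. The Phi-value is
#' `(N_i^TS - N_i^U) / (N_i^F - N_i^U)`, undefined (NA) when the
#' denominator is below 1e-9 or the residue has no native contacts. The
#' raw value is kept alongside the `[0, 1]`-clamped value.
#'
#' @param ts,folded,unfolded [ensemble()]s over the same system.
#' @param native a [native_contacts()] set.
#' @return object of class `phi_profile`: data.frame with `chain`,
#'   `resno`, `n_ts`, `n_f`, `n_u`, `phi_raw`, `phi`.
#' @export
phi_values <- function(ts, folded, unfolded, native) {
  sys <- ts$system
  if (!identical(dim(folded$coords)[2L], dim(ts$coords)[2L]) ||
      !identical(dim(unfolded$coords)[2L], dim(ts$coords)[2L]))
    stop("ensembles must cover the same system")
  n_res <- nrow(sys$residues)
  if (nrow(native) == 0L) stop("empty native contact set")
  inc <- matrix(0, nrow(native), n_res)   # contact x residue incidence
  inc[cbind(seq_len(nrow(native)), native$i)] <- 1
  inc[cbind(seq_len(nrow(native)), native$j)] <- 1
  mean_counts <- function(ens) {
    sat <- .contact_satisfaction(ens, native)
    colMeans(sat %*% inc)
  }
  n_ts <- mean_counts(ts)
  n_f <- mean_counts(folded)
  n_u <- mean_counts(unfolded)
  denom <- n_f - n_u
  has_contact <- colSums(inc) > 0
  phi_raw <- ifelse(abs(denom) < 1e-9 | !has_contact, NA_real_,
                    (n_ts - n_u) / denom)
  structure(list(profile = data.frame(
    chain = sys$residues$chain, resno = sys$residues$resno,
    n_ts = n_ts, n_f = n_f, n_u = n_u,
    phi_raw = phi_raw, phi = pmin(1, pmax(0, phi_raw)),
    stringsAsFactors = FALSE)),
    class = "phi_profile")
}

#' @export
print.phi_profile <- function(x, ...) {
  p <- x$profile
  def <- !is.na(p$phi)
  cat("phi_profile:", sum(def), "of", nrow(p), "residues defined;",
      sprintf("mean phi = %.3f\n", mean(p$phi[def])))
  invisible(x)
}

#' @export
as.data.frame.phi_profile <- function(x, ...) x$profile

#' @export
plot.phi_profile <- function(x, ...) {
  p <- x$profile
  graphics::plot(seq_len(nrow(p)), p$phi, type = "h", lwd = 2,
                 ylim = c(0, 1), xlab = "residue", ylab = expression(Phi),
                 ...)
  invisible(x)
}
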