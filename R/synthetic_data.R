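# Seeded synthetic toy systems and ensembles with planted statistical
# structure: a helix-bundle two-chain complex for contact/deviation
# analyses, a ladder complex with residue-disjoint binding contacts for
# exact Markov unfolding, deviation ensembles with planted CS/IF
# mechanisms, exponential Q series, and multi-basin trajectories.
#
# Nothing here is physical: geometry is canonical backbone plus one
# pseudo side-chain heavy atom per residue (at an extended C-beta
# position, carrying the residue's summed side-chain mass), which is
# sufficient for every contact rule in the package.

#' Specification for the synthetic generators
#'
#' Collects every tunable of the synthetic toys in one seeded object.
#' Amplitudes and rates are the planted ground truth that the analysis
#' stages are expected to recover.
#'
#' @param seed integer seed; all generators are deterministic given it.
#' @param chain_lengths named integer vector, residues per chain.
#' @param helix_fraction fraction of each chain built as ideal helix
#'   (phi = -57, psi = -47 degrees); the rest is seeded coil.
#' @param min_binding minimum native binding contacts the placed complex
#'   must realise.
#' @param amplitude_near,amplitude_far per-atom Gaussian deviation
#'   amplitudes (Angstrom) for apo atoms nearer/farther than `crossover`
#'   from the partner centroid.
#' @param crossover near/far crossover distance (Angstrom).
#' @param residual residual amplitude (A) between a bound frame and its
#'   generating apo conformer (conformational-selection channel).
#' @param if_amplitude induced-fit displacement amplitude (A) applied to
#'   interface atoms of bound frames.
#' @param n_frames_csif frames per deviation ensemble.
#' @param break_rate per-contact first-order break rate (ps^-1).
#' @param dt frame interval (ps) of deviation and multi-basin ensembles.
#' @param unfold_dt frame interval (ps) of unfolding trajectories (finer,
#'   so that `break_rate * unfold_dt` is well below 1).
#' @param unfold_frames frames in an unfolding trajectory.
#' @param n_segments,segment_separation,within_sd,frames_per_segment
#'   multi-basin trajectory shape: number of basins, basin-center
#'   C-alpha RMSD scale (A), within-basin per-atom SD (A), dwell length.
#' @return object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L,
                           chain_lengths = c(A = 30L, B = 14L),
                           helix_fraction = 0.6,
                           min_binding = 5L,
                           amplitude_near = 0.2,
                           amplitude_far = 1.5,
                           crossover = 10,
                           residual = 0.1,
                           if_amplitude = 1.5,
                           n_frames_csif = 50L,
                           break_rate = 0.05,
                           dt = 20,
                           unfold_dt = 1,
                           unfold_frames = 60L,
                           n_segments = 3L,
                           segment_separation = 3,
                           within_sd = 0.15,
                           frames_per_segment = 20L) {
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  stopifnot(spec$amplitude_near >= 0, spec$amplitude_far >= 0,
            spec$break_rate >= 0, spec$n_segments >= 1L,
            length(spec$chain_lengths) == 2L)
  if (is.null(names(spec$chain_lengths)))
    names(spec$chain_lengths) <- c("A", "B")
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec (seed ", x$seed, "): chains ",
      paste(names(x$chain_lengths), x$chain_lengths, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# deterministic residue sequence with all contact classes represented
.toy_sequence <- function(n, offset = 0L) {
  pool <- c("LEU", "ALA", "GLU", "LEU", "LYS", "GLY", "ILE", "VAL",
            "ARG", "MET", "ASP", "PHE", "SER", "GLU", "LEU", "LYS")
  pool[((seq_len(n) - 1L + offset) %% length(pool)) + 1L]
}

# build one chain: backbone N/CA/C/O plus one pseudo side-chain atom (CB)
# from internal coordinates; phi/psi from the helix/coil pattern
.build_chain <- function(resnames, chain, phi, psi, resno_start = 1L) {
  n <- length(resnames)
  stopifnot(length(phi) == n, length(psi) == n)
  atoms <- list(); coords <- list(); res_of <- integer(0)
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(68.8 * pi / 180), sin(68.8 * pi / 180), 0)
  for (r in seq_len(n)) {
    if (r > 1L) {
      Np <- N; CAp <- CA; Cp <- C
      N <- .place_atom(Np, CAp, Cp, 1.329, 116.2, psi[r - 1L])
      CA <- .place_atom(CAp, Cp, N, 1.458, 121.7, 180)
      C <- .place_atom(Cp, N, CA, 1.525, 111.2, phi[r])
    }
    psi_r <- if (is.na(psi[r])) 180 else psi[r]
    O <- .place_atom(N, CA, C, 1.231, 120.5, psi_r + 180)
    add <- function(name, xyz, element, mass = NULL) {
      atoms[[length(atoms) + 1L]] <<- list(name = name, element = element,
                                           mass = mass)
      coords[[length(coords) + 1L]] <<- xyz
      res_of[length(res_of) + 1L] <<- r
    }
    add("N", N, "N"); add("CA", CA, "C"); add("C", C, "C"); add("O", O, "O")
    if (resnames[r] != "GLY") {
      SC <- .place_atom(C, N, CA, 2.4, 110.5, 122.5)
      add("CB", SC, "C", mass = unname(.SIDECHAIN_MASS[resnames[r]]))
    }
  }
  atoms_df <- data.frame(
    res = res_of,
    name = vapply(atoms, `[[`, "", "name"),
    element = vapply(atoms, `[[`, "", "element"),
    stringsAsFactors = FALSE)
  atoms_df$mass <- .element_mass(atoms_df$element)
  sc_mass <- vapply(atoms, function(a)
    if (is.null(a$mass)) NA_real_ else a$mass, 0)
  atoms_df$mass[!is.na(sc_mass)] <- sc_mass[!is.na(sc_mass)]
  residues <- data.frame(chain = chain,
                         resno = resno_start + seq_len(n) - 1L,
                         resname = resnames, stringsAsFactors = FALSE)
  list(residues = residues, atoms = atoms_df,
       coords = do.call(rbind, coords))
}

.phi_psi_pattern <- function(n, helix_fraction) {
  n_helix <- round(n * helix_fraction)
  start <- max(1L, floor((n - n_helix) / 2))
  is_helix <- seq_len(n) >= start & seq_len(n) < start + n_helix
  phi <- ifelse(is_helix, -57, stats::runif(n, -150, -60))
  psi <- ifelse(is_helix, -47, stats::runif(n, -60, 150))
  list(phi = phi, psi = psi)
}

# align a coordinate block so its principal axis lies on z, centered
.axis_align <- function(coords) {
  ctr <- colMeans(coords)
  x <- sweep(coords, 2L, ctr)
  v <- svd(x, nu = 0L)$v
  if (det(v) < 0) v[, 3L] <- -v[, 3L]
  x %*% v[, c(2L, 3L, 1L)]   # principal axis -> z
}

.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

#' Build a two-chain toy complex
#'
#' Two chains of ideal-helix plus seeded-coil segments are built from
#' canonical backbone internal coordinates, with one pseudo side-chain
#' heavy atom per residue (extended C-beta position, summed side-chain
#' mass). Chain B is placed against chain A by scanning an approach axis
#' (with seeded rotations as fall-back) until at least
#' `spec$min_binding` inter-chain residue pairs satisfy the 6.5 A
#' side-chain rule without steric clash.
#'
#' @param spec a [synthetic_spec()].
#' @param separation optional fixed center-to-center distance (Angstrom)
#'   that overrides the contact-seeking scan (e.g. 100 for a detached
#'   control).
#' @param require_near_zone also require at least 5 chain-A atoms within
#'   `spec$crossover` of the partner centroid (needed by the local
#'   induced-fit deviation channel; disable for plain contact toys).
#' @return list with `system` ([system_model()]), `ensemble` (single
#'   reference frame) and `native` ([native_contacts()]).
#' @export
build_toy_complex <- function(spec = synthetic_spec(), separation = NULL,
                              require_near_zone = TRUE) {
  .with_seed(spec$seed, {
    nA <- spec$chain_lengths[[1L]]; nB <- spec$chain_lengths[[2L]]
    chA <- names(spec$chain_lengths)[1L]; chB <- names(spec$chain_lengths)[2L]
    ppA <- .phi_psi_pattern(nA, spec$helix_fraction)
    ppB <- .phi_psi_pattern(nB, spec$helix_fraction)
    A <- .build_chain(.toy_sequence(nA), chA, ppA$phi, ppA$psi)
    B <- .build_chain(.toy_sequence(nB, offset = 7L), chB, ppB$phi, ppB$psi,
                      resno_start = nA + 1L)
    A$coords <- .axis_align(A$coords)
    B$coords <- .axis_align(B$coords) %*% .rot_z(180)

    residues <- rbind(A$residues, B$residues)
    atomsB <- B$atoms; atomsB$res <- atomsB$res + nrow(A$residues)
    atoms <- rbind(A$atoms, atomsB)

    place <- function(dx, rot_deg = 0, z_off = 0) {
      bc <- B$coords %*% .rot_z(rot_deg)
      bc[, 1L] <- bc[, 1L] + dx
      bc[, 3L] <- bc[, 3L] + z_off
      rbind(A$coords, bc)
    }
    build_sys <- function(xyz) system_model(residues, atoms, xyz)

    if (!is.null(separation)) {
      sys <- build_sys(place(separation))
    } else {
      # cheap scan: count inter-chain residue pairs whose single
      # side-chain atoms (CA for GLY) come below 6.5 A, and guard clashes
      scA <- A$atoms$name == "CB" |
        (A$atoms$name == "CA" & !(A$atoms$res %in% A$atoms$res[A$atoms$name == "CB"]))
      scB <- B$atoms$name == "CB" |
        (B$atoms$name == "CA" & !(B$atoms$res %in% B$atoms$res[B$atoms$name == "CB"]))
      # approach until just before steric clash (tightest packing), then
      # require the binding-contact minimum; rotate chain B as fall-back
      found <- FALSE
      cand <- expand.grid(rot = c(0, 90, 180, 270, 45, 135, 225, 315),
                          z_off = c(0, 5, -5, 10, -10))
      for (ci in seq_len(nrow(cand))) {
        rot <- cand$rot[ci]
        bc0 <- B$coords %*% .rot_z(rot)
        bc0[, 3L] <- bc0[, 3L] + cand$z_off[ci]
        best_dx <- NA_real_
        for (dx in seq(30, 4, by = -0.25)) {
          bc <- bc0; bc[, 1L] <- bc[, 1L] + dx
          dall <- sqrt(pmax(0, outer(rowSums(A$coords^2), rowSums(bc^2), "+") -
                              2 * A$coords %*% t(bc)))
          if (min(dall) <= 2.8) break
          best_dx <- dx
        }
        if (!is.na(best_dx)) {
          bc <- bc0; bc[, 1L] <- bc[, 1L] + best_dx
          dsc <- sqrt(pmax(0, outer(rowSums(A$coords[scA, , drop = FALSE]^2),
                                    rowSums(bc[scB, , drop = FALSE]^2), "+") -
                             2 * A$coords[scA, , drop = FALSE] %*%
                               t(bc[scB, , drop = FALSE])))
          # the interface must also reach into the near zone around the
          # partner centroid, or the local deviation channel has no atoms
          wB <- atomsB$mass / sum(atomsB$mass)
          ctrB <- colSums(bc * wB)
          dctr <- sqrt(rowSums(sweep(A$coords, 2L, ctrB)^2))
          if (sum(dsc < 6.5) >= spec$min_binding &&
              (!require_near_zone || sum(dctr < spec$crossover) >= 5L)) {
            sys <- build_sys(place(best_dx, rot, cand$z_off[ci]))
            found <- TRUE
            break
          }
        }
      }
      if (!found)
        stop("failed to place chains in contact after bounded retries")
    }
    ens <- ensemble(sys, list(sys$reference_coords), times = 0,
                    label = "bound")
    list(system = sys, ensemble = ens, native = native_contacts(sys))
  })
}

#' Sample bound/apo deviation ensembles with a planted mechanism
#'
#' Generates an apo ensemble of the analysed chain (reference plus
#' Gaussian per-atom displacements with distance-dependent amplitude) and
#' a bound-complex ensemble whose analysed-chain conformations realise
#' the requested mechanism:
#' \describe{
#'   \item{cs_dominant}{large apo spread everywhere; bound frame i tracks
#'     apo conformer i up to a small residual (selection of pre-existing
#'     conformers).}
#'   \item{if_dominant}{small apo spread; bound frames displaced at the
#'     interface (structure imposed by the partner).}
#'   \item{mixed}{large apo spread far from the interface with bound
#'     frames tracking apo conformers there, plus interface displacement
#'     of bound frames: global selection, local induced fit.}
#' }
#'
#' @param spec a [synthetic_spec()].
#' @param mechanism `"cs_dominant"`, `"if_dominant"` or `"mixed"`.
#' @param toy optional prebuilt [build_toy_complex()] result.
#' @return list with `bound` and `apo` [ensemble()]s, the `system`, the
#'   analysed `chain`, and the planted `truth` parameters.
#' @export
sample_csif_ensembles <- function(spec = synthetic_spec(),
                                  mechanism = c("cs_dominant", "if_dominant",
                                                "mixed"),
                                  toy = NULL) {
  mechanism <- match.arg(mechanism)
  if (is.null(toy)) toy <- build_toy_complex(spec)
  sys <- toy$system
  chain <- names(spec$chain_lengths)[1L]
  .with_seed(spec$seed + 1000L, {
    chain_idx <- chain_atom_indices(sys, chain)
    partner_idx <- setdiff(seq_len(nrow(sys$atoms)), chain_idx)
    ref <- sys$reference_coords
    centroid <- center_of_mass(ref, sys, partner_idx)
    d <- sqrt(rowSums(sweep(ref[chain_idx, , drop = FALSE], 2L, centroid)^2))
    near <- d < spec$crossover
    nf <- spec$n_frames_csif
    na_ <- length(chain_idx)

    apo_amp <- switch(mechanism,
      cs_dominant = rep(spec$amplitude_far, na_),
      if_dominant = rep(spec$amplitude_near, na_),
      mixed = ifelse(near, spec$amplitude_near, spec$amplitude_far))

    apo_frames <- vector("list", nf)
    for (f in seq_len(nf))
      apo_frames[[f]] <- ref[chain_idx, , drop = FALSE] +
        matrix(stats::rnorm(na_ * 3L), na_, 3L) * apo_amp

    bound_frames <- vector("list", nf)
    for (f in seq_len(nf)) {
      bxyz <- ref
      bchain <- switch(mechanism,
        cs_dominant = apo_frames[[f]] +
          matrix(stats::rnorm(na_ * 3L, sd = spec$residual), na_, 3L),
        if_dominant = {
          x <- ref[chain_idx, , drop = FALSE] +
            matrix(stats::rnorm(na_ * 3L, sd = spec$residual), na_, 3L)
          x[near, ] <- x[near, , drop = FALSE] +
            matrix(stats::rnorm(sum(near) * 3L, sd = spec$if_amplitude),
                   sum(near), 3L)
          x
        },
        mixed = {
          x <- apo_frames[[f]] +
            matrix(stats::rnorm(na_ * 3L, sd = spec$residual), na_, 3L)
          x[near, ] <- ref[chain_idx, , drop = FALSE][near, , drop = FALSE] +
            matrix(stats::rnorm(sum(near) * 3L, sd = spec$if_amplitude),
                   sum(near), 3L)
          x
        })
      bxyz[chain_idx, ] <- bchain
      bxyz[partner_idx, ] <- ref[partner_idx, , drop = FALSE] +
        matrix(stats::rnorm(length(partner_idx) * 3L, sd = spec$residual),
               length(partner_idx), 3L)
      bound_frames[[f]] <- bxyz
    }

    apo_res <- sys$residues[sys$residues$chain == chain, , drop = FALSE]
    apo_atoms <- sys$atoms[sys$atoms$res %in% which(sys$residues$chain == chain), ,
                           drop = FALSE]
    apo_atoms$res <- match(apo_atoms$res, which(sys$residues$chain == chain))
    apo_sys <- system_model(apo_res, apo_atoms, apo_frames[[1L]])

    list(bound = ensemble(sys, bound_frames, dt = spec$dt, label = "bound"),
         apo = ensemble(apo_sys, apo_frames, dt = spec$dt,
                        label = paste0("apo_", chain)),
         system = sys, chain = chain,
         truth = list(mechanism = mechanism, near = near,
                      apo_amp = apo_amp))
  })
}

#' Build a ladder complex with residue-disjoint binding contacts
#'
#' Two straight 20-residue strands face each other so that residue i of
#' chain A contacts residue i of chain B (side-chain gap 5.6 A) and no
#' other pair falls below the 6.5 A rule: every native contact is a
#' binding contact involving its own residue pair, which makes the
#' per-contact Markov breaking of [sample_unfolding_trajectory()]
#' geometrically exact.
#'
#' @param n_rungs residues per strand.
#' @return list with `system`, `ensemble` (reference frame), `native`.
#' @export
build_ladder_complex <- function(n_rungs = 20L) {
  step <- 3.8; sc_off <- 2.0; gap <- 5.6
  mk <- function(chain, x0, sc_dir, resno_start) {
    res <- data.frame(chain = chain,
                      resno = resno_start + seq_len(n_rungs) - 1L,
                      resname = rep(c("LEU", "VAL"), length.out = n_rungs),
                      stringsAsFactors = FALSE)
    atoms <- list(); coords <- list(); res_of <- integer(0)
    for (r in seq_len(n_rungs)) {
      y <- (r - 1L) * step
      add <- function(name, xyz, el, mass = NULL) {
        atoms[[length(atoms) + 1L]] <<- list(name = name, el = el, mass = mass)
        coords[[length(coords) + 1L]] <<- xyz
        res_of[length(res_of) + 1L] <<- r
      }
      add("N", c(x0 - 0.9 * sc_dir, y - 1.2, 0.4), "N")
      add("CA", c(x0, y, 0), "C")
      add("C", c(x0 - 0.9 * sc_dir, y + 1.2, -0.4), "C")
      add("O", c(x0 - 1.8 * sc_dir, y + 1.4, -0.5), "O")
      add("CB", c(x0 + sc_off * sc_dir, y, 0), "C",
          mass = unname(.SIDECHAIN_MASS[res$resname[r]]))
    }
    atoms_df <- data.frame(res = res_of,
                           name = vapply(atoms, `[[`, "", "name"),
                           element = vapply(atoms, `[[`, "", "el"),
                           stringsAsFactors = FALSE)
    atoms_df$mass <- .element_mass(atoms_df$element)
    scm <- vapply(atoms, function(a)
      if (is.null(a$mass)) NA_real_ else a$mass, 0)
    atoms_df$mass[!is.na(scm)] <- scm[!is.na(scm)]
    list(res = res, atoms = atoms_df, coords = do.call(rbind, coords))
  }
  A <- mk("A", 0, +1, 1L)
  xB <- sc_off + gap + sc_off      # so the facing CB-CB distance is `gap`
  B <- mk("B", xB, -1, n_rungs + 1L)
  atomsB <- B$atoms; atomsB$res <- atomsB$res + n_rungs
  sys <- system_model(rbind(A$res, B$res), rbind(A$atoms, atomsB),
                      rbind(A$coords, B$coords))
  list(system = sys,
       ensemble = ensemble(sys, list(sys$reference_coords), times = 0,
                           label = "bound"),
       native = native_contacts(sys))
}

#' Sample a Markov unfolding trajectory with exact first-order contact loss
#'
#' Each native contact independently breaks with probability
#' `1 - exp(-k dt)` per frame and never reforms; the member residues of a
#' broken contact are interpolated toward a seeded random-coil target
#' placed away from the complex, which pushes the side-chain pair beyond
#' the 6.5 A rule from the break frame on. The expected native-contact
#' fraction is exactly `Q(t) = exp(-k t)`. Designed for systems whose
#' native contacts are residue-disjoint ([build_ladder_complex()]).
#'
#' @param spec a [synthetic_spec()] supplying `break_rate` (ps^-1),
#'   `unfold_dt` (ps), `unfold_frames` and the seed.
#' @param toy optional prebuilt ladder complex.
#' @param jitter thermal positional jitter SD (Angstrom).
#' @return an [ensemble()] with attribute `broken` (frames x contacts
#'   logical matrix of planted contact states) and `native` (the contact
#'   set).
#' @export
sample_unfolding_trajectory <- function(spec = synthetic_spec(), toy = NULL,
                                        jitter = 0.05) {
  if (is.null(toy)) toy <- build_ladder_complex()
  sys <- toy$system
  native <- toy$native
  nc <- nrow(native)
  if (nc == 0L) stop("the toy complex has no native contacts")
  .with_seed(spec$seed + 2000L, {
    p_break <- 1 - exp(-spec$break_rate * spec$unfold_dt)
    nf <- spec$unfold_frames
    ref <- sys$reference_coords
    na_ <- nrow(ref)
    n_res <- nrow(sys$residues)
    # coil target per residue: rigid displacement away from the complex
    ch <- sys$residues$chain
    dir_x <- ifelse(ch == sys$chains[1L], -1, 1)
    coil_shift <- cbind(dir_x * (25 + stats::runif(n_res, 0, 10)),
                        stats::rnorm(n_res, sd = 4),
                        stats::rnorm(n_res, sd = 4))
    broken <- matrix(FALSE, nf, nc)
    state <- rep(FALSE, nc)
    break_frame <- rep(NA_integer_, nc)
    frames <- vector("list", nf)
    res_w <- numeric(n_res)            # interpolation weight per residue
    for (f in seq_len(nf)) {
      if (f > 1L) {
        newly <- !state & stats::runif(nc) < p_break
        break_frame[newly] <- f
        state <- state | newly
      }
      broken[f, ] <- state
      # residues of broken contacts ramp toward coil; 0.5 immediately so
      # the contact is lost at the break frame, then smoothly to 1
      res_w[] <- 0
      for (k in which(state)) {
        age <- f - break_frame[k]
        w <- min(1, 0.5 + 0.1 * age)
        res_w[native$i[k]] <- max(res_w[native$i[k]], w)
        res_w[native$j[k]] <- max(res_w[native$j[k]], w)
      }
      xyz <- ref + matrix(stats::rnorm(na_ * 3L, sd = jitter), na_, 3L)
      moved <- which(res_w > 0)
      for (r in moved) {
        rows <- which(sys$atoms$res == r)
        xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2L,
                             res_w[r] * coil_shift[r, ], "+")
      }
      frames[[f]] <- xyz
    }
    ens <- ensemble(sys, frames, times = (seq_len(nf) - 1) * spec$unfold_dt,
                    label = "unfolding")
    attr(ens, "broken") <- broken
    attr(ens, "native") <- native
    ens
  })
}

#' Synthetic exponentially decaying Q series
#'
#' `q(t) = exp(-k t) + N(0, sigma)`, the direct input for kinetics-fit
#' recovery studies.
#'
#' @param k decay rate (ps^-1).
#' @param times time grid (ps).
#' @param sigma Gaussian noise SD.
#' @param seed integer seed.
#' @return a `q_series` whose `qf` and `qb` channels both carry the
#'   series.
#' @export
sample_q_series <- function(k, times, sigma = 0.01, seed = 1L) {
  q <- .with_seed(seed,
                  exp(-k * times) + stats::rnorm(length(times), sd = sigma))
  structure(list(times = times, qf = q, qb = q,
                 n_native_tertiary = NA_integer_,
                 n_native_binding = NA_integer_),
            class = "q_series")
}

#' Sample a trajectory dwelling in k sequential conformational basins
#'
#' Basin centers are the reference structure plus independent seeded
#' Gaussian deformation fields scaled to `segment_separation`; frames
#' within a basin add per-atom noise of SD `within_sd`. Switch frames are
#' recorded as the planted segmentation.
#'
#' @param spec a [synthetic_spec()] (`n_segments`, `segment_separation`,
#'   `within_sd`, `frames_per_segment`, `dt`, seed).
#' @param toy optional prebuilt toy complex.
#' @return list with `ensemble`, planted `segmentation`
#'   (a `cluster_segmentation`), and `centers`.
#' @export
sample_clustered_trajectory <- function(spec = synthetic_spec(), toy = NULL) {
  if (is.null(toy)) toy <- build_toy_complex(spec)
  sys <- toy$system
  .with_seed(spec$seed + 3000L, {
    k <- spec$n_segments
    ref <- sys$reference_coords
    na_ <- nrow(ref)
    amp <- spec$segment_separation / sqrt(2)
    centers <- lapply(seq_len(k), function(b)
      if (b == 1L) ref else ref + matrix(stats::rnorm(na_ * 3L, sd = amp),
                                         na_, 3L))
    npseg <- spec$frames_per_segment
    nf <- k * npseg
    frames <- vector("list", nf)
    lab <- rep(seq_len(k), each = npseg)
    for (f in seq_len(nf))
      frames[[f]] <- centers[[lab[f]]] +
        matrix(stats::rnorm(na_ * 3L, sd = spec$within_sd), na_, 3L)
    times <- (seq_len(nf) - 1) * spec$dt
    segs <- data.frame(start = seq(1L, nf, by = npseg),
                       end = seq(npseg, nf, by = npseg),
                       label = seq_len(k))
    truth <- structure(list(segments = segs,
                            barrier_times = (times[segs$end[-k]] +
                                             times[segs$start[-1L]]) / 2,
                            times = times),
                       class = "cluster_segmentation")
    list(ensemble = ensemble(sys, frames, times = times, label = "high_T"),
         segmentation = truth, centers = centers)
  })
}
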