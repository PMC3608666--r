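# Internal geometry helpers: torsions and internal-coordinate placement.

# torsion angle a-b-c-d in degrees, vectorized over rows of 4 matrices
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cbind(b1[, 2L] * b2[, 3L] - b1[, 3L] * b2[, 2L],
              b1[, 3L] * b2[, 1L] - b1[, 1L] * b2[, 3L],
              b1[, 1L] * b2[, 2L] - b1[, 2L] * b2[, 1L])
  n2 <- cbind(b2[, 2L] * b3[, 3L] - b2[, 3L] * b3[, 2L],
              b2[, 3L] * b3[, 1L] - b2[, 1L] * b3[, 3L],
              b2[, 1L] * b3[, 2L] - b2[, 2L] * b3[, 1L])
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cbind(n1[, 2L] * b2n[, 3L] - n1[, 3L] * b2n[, 2L],
              n1[, 3L] * b2n[, 1L] - n1[, 1L] * b2n[, 3L],
              n1[, 1L] * b2n[, 2L] - n1[, 2L] * b2n[, 1L])
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

# place atom D given A, B, C with bond |CD|, angle B-C-D and torsion
# A-B-C-D (degrees); the natural-extension (NeRF) construction
.place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  # the minus sign on the out-of-plane term matches the IUPAC torsion
  # sign convention used by .dihedral (phi of -57 measures as -57)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# circular standard deviation of angles in degrees: sqrt(-2 ln Rbar)
.circ_sd_deg <- function(theta_deg) {
  th <- theta_deg[!is.na(theta_deg)] * pi / 180
  if (!length(th)) return(NA_real_)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  rbar <- min(1, rbar)
  if (rbar > 1 - 1e-12) return(0)   # constant angles: exactly zero spread
  sqrt(-2 * log(rbar)) * 180 / pi
}

# indices of backbone atoms per residue for phi/psi: returns a list with
# matrices of atom indices (NA where missing)
.backbone_index_table <- function(system) {
  atm <- system$atoms
  n_res <- nrow(system$residues)
  pick <- function(name) {
    out <- rep(NA_integer_, n_res)
    i <- which(atm$name == name)
    out[atm$res[i]] <- i
    out
  }
  list(N = pick("N"), CA = pick("CA"), C = pick("C"))
}

# per-frame phi/psi in degrees for every residue (NA at chain termini or
# where backbone atoms are missing); returns list(phi, psi) matrices
# frames x residues
.phi_psi <- function(ens) {
  sys <- ens$system
  bb <- .backbone_index_table(sys)
  res <- sys$residues
  n_res <- nrow(res)
  prev_ok <- c(FALSE, res$chain[-1L] == res$chain[-n_res])
  next_ok <- c(res$chain[-n_res] == res$chain[-1L], FALSE)
  phi_ok <- prev_ok & !is.na(bb$C) & !is.na(bb$N) & !is.na(bb$CA) &
    c(NA, bb$C[-n_res])[seq_len(n_res)] > 0
  phi_ok[is.na(phi_ok)] <- FALSE
  psi_ok <- next_ok & !is.na(bb$N) & !is.na(bb$CA) & !is.na(bb$C) &
    c(bb$N[-1L], NA)[seq_len(n_res)] > 0
  psi_ok[is.na(psi_ok)] <- FALSE
  nf <- n_frames(ens)
  phi <- matrix(NA_real_, nf, n_res)
  psi <- matrix(NA_real_, nf, n_res)
  prevC <- c(NA_integer_, bb$C[-n_res])
  nextN <- c(bb$N[-1L], NA_integer_)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    i <- which(phi_ok)
    if (length(i))
      phi[f, i] <- .dihedral(xyz[prevC[i], , drop = FALSE],
                             xyz[bb$N[i], , drop = FALSE],
                             xyz[bb$CA[i], , drop = FALSE],
                             xyz[bb$C[i], , drop = FALSE])
    j <- which(psi_ok)
    if (length(j))
      psi[f, j] <- .dihedral(xyz[bb$N[j], , drop = FALSE],
                             xyz[bb$CA[j], , drop = FALSE],
                             xyz[bb$C[j], , drop = FALSE],
                             xyz[nextN[j], , drop = FALSE])
  }
  list(phi = phi, psi = psi)
}
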