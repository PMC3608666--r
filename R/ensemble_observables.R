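# Descriptive ensemble observables: C-alpha RMSF, phi/psi circular
# variation, helical content, distance-difference maps, and Rg/RMSD
# free-energy landscapes.

#' Per-residue C-alpha root-mean-square fluctuation
#'
#' All frames are superposed on the ensemble-mean C-alpha structure (the
#' mean is refined by a second superposition pass), then
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` per residue.
#'
#' @param ens an [ensemble()] with at least 2 frames.
#' @return data.frame with `chain`, `resno`, `rmsf` (Angstrom; `NA` for
#'   residues without a C-alpha).
#' @export
ca_rmsf <- function(ens) {
  if (n_frames(ens) < 2L) stop("need at least 2 frames")
  sys <- ens$system
  ca <- ca_indices(sys)
  nf <- n_frames(ens)
  stack <- function(reference) {
    arr <- array(0, dim = c(nf, length(ca), 3L))
    for (f in seq_len(nf)) {
      xyz <- frame_coords(ens, f)
      sp <- superpose(xyz, reference, ca)
      arr[f, , ] <- apply_superposition(sp, xyz)[ca, , drop = FALSE]
    }
    arr
  }
  ref_full <- frame_coords(ens, 1L)
  arr <- stack(ref_full)
  # mean CA structure, embedded at the CA rows of a full-size reference
  for (pass in 1:2) {
    mean_ca <- apply(arr, c(2L, 3L), mean)
    ref_full[ca, ] <- mean_ca
    arr <- stack(ref_full)
  }
  mean_ca <- apply(arr, c(2L, 3L), mean)
  dev2 <- matrix(0, nf, length(ca))
  for (f in seq_len(nf))
    dev2[f, ] <- rowSums((matrix(arr[f, , ], ncol = 3L) - mean_ca)^2)
  rmsf_ca <- sqrt(colMeans(dev2))
  out <- data.frame(chain = sys$residues$chain, resno = sys$residues$resno,
                    rmsf = NA_real_, stringsAsFactors = FALSE)
  out$rmsf[sys$atoms$res[ca]] <- rmsf_ca
  out
}

#' Per-residue phi/psi circular variation
#'
#' The circular standard deviation of phi and of psi across frames,
#' reported per residue as their mean, in degrees. Terminal residues
#' (lacking one of the dihedrals) average over the defined one; residues
#' with neither are `NA`.
#'
#' @param ens an [ensemble()] with backbone N/CA/C atoms.
#' @return data.frame with `chain`, `resno`, `phi_sd`, `psi_sd`,
#'   `variation` (degrees).
#' @export
dihedral_variation <- function(ens) {
  pp <- .phi_psi(ens)
  sys <- ens$system
  phi_sd <- apply(pp$phi, 2L, .circ_sd_deg)
  psi_sd <- apply(pp$psi, 2L, .circ_sd_deg)
  variation <- rowMeans(cbind(phi_sd, psi_sd), na.rm = TRUE)
  variation[is.nan(variation)] <- NA_real_
  data.frame(chain = sys$residues$chain, resno = sys$residues$resno,
             phi_sd = phi_sd, psi_sd = psi_sd, variation = variation,
             stringsAsFactors = FALSE)
}

#' Helical content of a residue range across an ensemble
#'
#' A residue-frame is counted helical iff `phi` lies in `[-100, -30]`
#' degrees, `psi` in `[-80, -5]` degrees, and the residue sits in a run of
#' at least `min_run` consecutive helical residues in that frame. The
#' content is helical residue-frames over total residue-frames in the
#' region.
#'
#' @param ens an [ensemble()].
#' @param region integer vector of residue indices (rows of
#'   `system$residues`); default all.
#' @param phi_range,psi_range helical dihedral windows (degrees).
#' @param min_run minimum consecutive helical run length.
#' @return fraction in `[0, 1]`.
#' @export
helical_content <- function(ens, region = NULL,
                            phi_range = c(-100, -30),
                            psi_range = c(-80, -5), min_run = 3L) {
  sys <- ens$system
  if (is.null(region)) region <- seq_len(nrow(sys$residues))
  pp <- .phi_psi(ens)
  ok <- !is.na(pp$phi) & !is.na(pp$psi) &
    pp$phi >= phi_range[1L] & pp$phi <= phi_range[2L] &
    pp$psi >= psi_range[1L] & pp$psi <= psi_range[2L]
  ok[is.na(ok)] <- FALSE
  chain <- sys$residues$chain
  helical <- matrix(FALSE, nrow(ok), ncol(ok))
  for (ch in unique(chain)) {
    cols <- which(chain == ch)
    for (f in seq_len(nrow(ok))) {
      r <- rle(ok[f, cols])
      keep <- rep(r$values & r$lengths >= min_run, r$lengths)
      helical[f, cols] <- keep
    }
  }
  mean(helical[, region, drop = FALSE])
}

#' Distance-difference map between bound and apo ensembles
#'
#' `D(i, j) = <|CA_i - CA_j|>_bound - <|CA_i - CA_j|>_apo` over the
#' residues of one chain: positive entries are stretched in the bound
#' state, negative ones compacted.
#'
#' @param bound,apo [ensemble()]s containing the chain (the bound one may
#'   be the full complex).
#' @param chain chain label present in both systems.
#' @return symmetric `n_res x n_res` matrix (Angstrom) of class
#'   `distance_difference_map`, zero diagonal.
#' @export
distance_difference_map <- function(bound, apo, chain) {
  mean_dist <- function(ens) {
    ca <- ca_indices(ens$system, chain)
    n <- length(ca)
    acc <- matrix(0, n, n)
    for (f in seq_len(n_frames(ens))) {
      xyz <- frame_coords(ens, f)[ca, , drop = FALSE]
      acc <- acc + as.matrix(stats::dist(xyz))
    }
    acc / n_frames(ens)
  }
  mb <- mean_dist(bound)
  ma <- mean_dist(apo)
  if (!all(dim(mb) == dim(ma)))
    stop("chain ", chain, " has different residue counts in the two ensembles")
  structure(mb - ma, class = c("distance_difference_map", "matrix"))
}

#' @export
plot.distance_difference_map <- function(x, ...) {
  m <- unclass(x)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  xlab = "residue", ylab = "residue",
                  col = grDevices::hcl.colors(65, "Blue-Red 3"), ...)
  invisible(x)
}

#' Free-energy landscape over (Rg, RMSD-to-reference)
#'
#' Two-dimensional histogram of per-frame C-alpha radius of gyration and
#' fitted C-alpha RMSD to the reference structure. Cell free energies are
#' `F = -ln(P / P_max)` in kT units; empty cells are `+Inf`. Basins are
#' 4-connected components of cells with `F < basin_cut`.
#'
#' @param ens an [ensemble()] (a warning is issued below 50 frames).
#' @param reference_coords reference structure; default the system
#'   reference.
#' @param rg_bin,rmsd_bin bin widths in Angstrom.
#' @param basin_cut basin free-energy cutoff (kT).
#' @return object of class `free_energy_landscape`: `rg_edges`,
#'   `rmsd_edges`, matrices `P` and `F`, `basins` (list of cell index
#'   matrices with member `frames`), and the per-frame `rg` / `rmsd`.
#' @export
free_energy_landscape <- function(ens, reference_coords = NULL,
                                  rg_bin = 0.5, rmsd_bin = 0.5,
                                  basin_cut = 1) {
  sys <- ens$system
  if (is.null(reference_coords)) reference_coords <- sys$reference_coords
  if (n_frames(ens) < 50L)
    warning("fewer than 50 frames: the landscape will be sparsely sampled")
  ca <- ca_indices(sys)
  nf <- n_frames(ens)
  rg <- numeric(nf); rd <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    rg[f] <- radius_of_gyration(xyz, ca)
    rd[f] <- rmsd(xyz, reference_coords, ca, fit = TRUE)
  }
  e1 <- seq(floor(min(rg) / rg_bin) * rg_bin,
            max(rg) + rg_bin, by = rg_bin)
  e2 <- seq(floor(min(rd) / rmsd_bin) * rmsd_bin,
            max(rd) + rmsd_bin, by = rmsd_bin)
  i1 <- findInterval(rg, e1, rightmost.closed = TRUE)
  i2 <- findInterval(rd, e2, rightmost.closed = TRUE)
  P <- matrix(0, length(e1) - 1L, length(e2) - 1L)
  for (f in seq_len(nf)) P[i1[f], i2[f]] <- P[i1[f], i2[f]] + 1
  P <- P / nf
  F_ <- -log(P / max(P))
  F_[P == 0] <- Inf

  # basins: 4-connected components of low-F cells
  low <- which(F_ < basin_cut, arr.ind = TRUE)
  basins <- list()
  if (nrow(low) > 0L) {
    key <- paste(low[, 1L], low[, 2L])
    comp <- rep(0L, nrow(low))
    cid <- 0L
    for (s in seq_len(nrow(low))) {
      if (comp[s] > 0L) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        cur <- queue[1L]; queue <- queue[-1L]
        nb <- cbind(low[cur, 1L] + c(-1L, 1L, 0L, 0L),
                    low[cur, 2L] + c(0L, 0L, -1L, 1L))
        hit <- match(paste(nb[, 1L], nb[, 2L]), key)
        hit <- hit[!is.na(hit)]
        new <- hit[comp[hit] == 0L]
        comp[new] <- cid
        queue <- c(queue, new)
      }
    }
    for (b in seq_len(cid)) {
      cells <- low[comp == b, , drop = FALSE]
      members <- which(paste(i1, i2) %in% paste(cells[, 1L], cells[, 2L]))
      basins[[b]] <- list(cells = cells, frames = members)
    }
  }
  structure(list(rg_edges = e1, rmsd_edges = e2, P = P, F = F_,
                 basins = basins, rg = rg, rmsd = rd),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat("free_energy_landscape:", sum(x$P > 0), "occupied cells,",
      length(x$basins), "basin(s) below cutoff\n")
  invisible(x)
}

#' @export
plot.free_energy_landscape <- function(x, ...) {
  Fp <- x$F
  Fp[!is.finite(Fp)] <- NA
  graphics::image(x$rg_edges[-1L] - diff(x$rg_edges) / 2,
                  x$rmsd_edges[-1L] - diff(x$rmsd_edges) / 2, Fp,
                  xlab = "Rg (A)", ylab = "RMSD (A)",
                  col = grDevices::hcl.colors(33, "viridis", rev = TRUE),
                  ...)
  invisible(x)
}

#' Write a landscape as gnuplot-style xyz text
#'
#' @param x a [free_energy_landscape()].
#' @param path output path.
#' @export
write_landscape_xyz <- function(x, path) {
  mids1 <- x$rg_edges[-1L] - diff(x$rg_edges) / 2
  mids2 <- x$rmsd_edges[-1L] - diff(x$rmsd_edges) / 2
  df <- expand.grid(rg = mids1, rmsd = mids2)
  df$F <- as.vector(x$F)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
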