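# Core structural data model: topology, ensembles, superposition, RMSD, Rg.

# Residue-class sets. PRO and ALA are hydrophobic (both appear in stable
# hydrophobic interface contacts); HIS is grouped with the positives.
.HYDROPHOBIC <- c("ALA", "VAL", "LEU", "ILE", "PRO", "MET", "PHE", "TRP", "CYS")
.POSITIVE    <- c("ARG", "LYS", "HIS")
.NEGATIVE    <- c("ASP", "GLU")

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

# Summed heavy-atom side-chain masses (Da), used for single-pseudo-atom
# side chains in synthetic systems.
.SIDECHAIN_MASS <- c(
  ALA = 12.011, ARG = 90.065, ASN = 54.028, ASP = 56.020, CYS = 44.071,
  GLN = 66.039, GLU = 68.031, GLY = 0.000,  HIS = 76.058, ILE = 48.044,
  LEU = 48.044, LYS = 62.051, MET = 68.093, PHE = 84.077, PRO = 36.033,
  SER = 28.010, THR = 40.021, TRP = 122.106, TYR = 100.076, VAL = 36.033)

#' Classify residues by side-chain chemistry
#'
#' Maps 3-letter residue names to the classes used by the contact rules:
#' `"hydrophobic"` (ALA, VAL, LEU, ILE, PRO, MET, PHE, TRP, CYS),
#' `"positive"` (ARG, LYS, HIS), `"negative"` (ASP, GLU), else `"other"`.
#'
#' @param resname character vector of 3-letter residue names.
#' @return character vector of classes, same length as `resname`.
#' @export
residue_class <- function(resname) {
  resname <- toupper(resname)
  out <- rep("other", length(resname))
  out[resname %in% .HYDROPHOBIC] <- "hydrophobic"
  out[resname %in% .POSITIVE] <- "positive"
  out[resname %in% .NEGATIVE] <- "negative"
  out
}

.element_mass <- function(element) {
  m <- .ELEMENT_MASS[toupper(element)]
  m[is.na(m)] <- .ELEMENT_MASS[["C"]]
  unname(m)
}

#' Construct a two-chain system model
#'
#' A `system_model` holds the topology of one molecular system: chains,
#' residues (with contact classes), atoms (with masses and backbone flags)
#' and the reference coordinates in Angstrom. Residue identifiers are row
#' indices into `residues`; input residue numbering is preserved verbatim
#' in `residues$resno` and never rewritten.
#'
#' @param residues data.frame with columns `chain`, `resno` (integer,
#'   strictly increasing within a chain), `resname` (3-letter code). A
#'   `class` column is added from [residue_class()] if absent.
#' @param atoms data.frame with columns `res` (integer index into
#'   `residues`), `name` (PDB atom name), `element`, and optionally `mass`
#'   (Da; derived from `element` if absent) and `backbone` (logical;
#'   derived from `name` if absent).
#' @param reference_coords numeric matrix, one row per atom, columns x/y/z
#'   in Angstrom.
#' @return an object of class `system_model`.
#' @export
system_model <- function(residues, atoms, reference_coords) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  residues <- as.data.frame(residues, stringsAsFactors = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(residues$class)) residues$class <- residue_class(residues$resname)
  if (is.null(atoms$mass)) atoms$mass <- .element_mass(atoms$element)
  if (is.null(atoms$backbone)) atoms$backbone <- atoms$name %in% .BACKBONE_ATOMS
  reference_coords <- as.matrix(reference_coords)
  storage.mode(reference_coords) <- "double"

  x <- structure(list(
    chains = unique(as.character(residues$chain)),
    residues = residues,
    atoms = atoms,
    reference_coords = reference_coords
  ), class = "system_model")
  validate_system_model(x)
  x
}

#' @rdname system_model
#' @param x a `system_model`.
#' @export
validate_system_model <- function(x) {
  res <- x$residues
  atm <- x$atoms
  if (nrow(atm) != nrow(x$reference_coords) || ncol(x$reference_coords) != 3)
    stop("reference_coords must be an n_atoms x 3 matrix")
  if (any(is.na(atm$res)) || any(atm$res < 1L) || any(atm$res > nrow(res)))
    stop("every atom must map to exactly one residue")
  if (any(atm$mass <= 0)) stop("atom masses must be positive")
  for (ch in x$chains) {
    rn <- res$resno[res$chain == ch]
    if (any(diff(rn) <= 0))
      stop("residue numbers must be strictly increasing within chain ", ch)
  }
  invisible(x)
}

#' @export
print.system_model <- function(x, ...) {
  cat("system_model:", nrow(x$residues), "residues,", nrow(x$atoms),
      "atoms in", length(x$chains), "chain(s) [",
      paste(x$chains, collapse = ", "), "]\n")
  tab <- table(x$residues$class)
  cat("  residue classes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a conformational ensemble
#'
#' An `ensemble` is an ordered set of frames of coordinates for one system
#' state (for example the bound complex, or one apo chain), with strictly
#' increasing timestamps in picoseconds.
#'
#' @param system a [system_model()].
#' @param coords either a `frames x atoms x 3` array or a list of
#'   `atoms x 3` matrices.
#' @param times numeric vector of per-frame timestamps (ps), strictly
#'   increasing. Defaults to `0, dt, 2 dt, ...`.
#' @param label state label, e.g. `"bound"`, `"apo_A"`, `"apo_B"`.
#' @param dt frame interval (ps) used when `times` is missing.
#' @return an object of class `ensemble`.
#' @export
ensemble <- function(system, coords, times = NULL, label = "bound", dt = 1) {
  if (is.list(coords)) {
    nf <- length(coords)
    na <- nrow(coords[[1L]])
    arr <- array(0, dim = c(nf, na, 3L))
    for (i in seq_len(nf)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  nf <- dim(coords)[1L]
  if (nf < 1L) stop("an ensemble needs at least one frame")
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf) stop("times must have one entry per frame")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (dim(coords)[2L] != nrow(system$atoms))
    stop("frame atom count (", dim(coords)[2L],
         ") does not match system atom count (", nrow(system$atoms), ")")
  structure(list(system = system, coords = coords,
                 times = as.numeric(times), label = label),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble [", x$label, "]: ", n_frames(x), " frames x ",
      dim(x$coords)[2L], " atoms, t = ", x$times[1L], " .. ",
      x$times[n_frames(x)], " ps\n", sep = "")
  invisible(x)
}

#' @rdname ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1L]

#' Extract one frame of an ensemble as a coordinate matrix
#'
#' @param x an [ensemble()].
#' @param i frame index (1-based).
#' @return `atoms x 3` numeric matrix.
#' @export
frame_coords <- function(x, i) {
  matrix(x$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Atom index helpers
#'
#' `ca_indices()` returns the indices of C-alpha atoms, optionally
#' restricted to a chain; `chain_atom_indices()` all atoms of a chain.
#'
#' @param system a [system_model()].
#' @param chain chain label or `NULL` for all chains.
#' @return integer vector of atom indices.
#' @export
ca_indices <- function(system, chain = NULL) {
  idx <- which(system$atoms$name == "CA")
  if (!is.null(chain)) {
    res_chain <- system$residues$chain[system$atoms$res]
    idx <- idx[res_chain[idx] %in% chain]
  }
  idx
}

#' @rdname ca_indices
#' @export
chain_atom_indices <- function(system, chain) {
  which(system$residues$chain[system$atoms$res] %in% chain)
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `target` over the selected atoms. Reflections are
#' forbidden: the rotation determinant is forced to +1 by sign correction
#' of the smallest singular vector.
#'
#' @param mobile,target `n x 3` coordinate matrices covering the same atoms.
#' @param atom_selection integer vector of atom (row) indices to fit on;
#'   default all atoms.
#' @return an object of class `superposition` with elements `rotation`
#'   (3x3, det +1), `translation` (length 3) and `rmsd` (Angstrom, over the
#'   selection). Apply with [apply_superposition()]: fitted
#'   `= mobile %*% rotation + translation` (rows are points).
#' @export
superpose <- function(mobile, target, atom_selection = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("mobile and target must cover the same atoms")
  sel <- if (is.null(atom_selection)) seq_len(nrow(mobile)) else atom_selection
  if (length(sel) == 0L) stop("empty atom selection")
  if (length(sel) < 3L)
    stop("degenerate fit: need at least 3 non-collinear selected atoms")
  P <- mobile[sel, , drop = FALSE]
  Q <- target[sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  P <- sweep(P, 2L, cp); Q <- sweep(Q, 2L, cq)
  # collinearity check: centered selection must span a plane
  dP <- svd(crossprod(P), nu = 0L, nv = 0L)$d   # squared singular values
  if (sqrt(dP[2L]) < 1e-8 * max(1, sqrt(dP[1L])))
    stop("degenerate fit: selected atoms are collinear")
  H <- crossprod(P, Q)                      # 3x3
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)  # applied as p %*% R
  fitted <- P %*% R
  rmsd_val <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cq - cp %*% R),
                 rmsd = rmsd_val),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f Angstrom over fitted selection\n",
              x$rmsd))
  invisible(x)
}

#' @rdname superpose
#' @param sp a `superposition`.
#' @param coords coordinates to transform (`n x 3`).
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% sp$rotation, 2L, sp$translation, "+")
}

#' Root-mean-square deviation between two conformations
#'
#' @param coords_a,coords_b `n x 3` coordinate matrices over the same atoms.
#' @param atom_selection atom indices to measure over (and fit on, when
#'   `fit = TRUE`); default all.
#' @param fit if `TRUE`, superpose `coords_a` onto `coords_b` over the
#'   selection before measuring.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b, atom_selection = NULL, fit = FALSE) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) stop("coordinate sets must match")
  sel <- if (is.null(atom_selection)) seq_len(nrow(coords_a)) else atom_selection
  if (length(sel) == 0L) stop("empty atom selection")
  if (fit) {
    sp <- superpose(coords_a, coords_b, sel)
    coords_a <- apply_superposition(sp, coords_a)
  }
  sqrt(mean(rowSums((coords_a[sel, , drop = FALSE] -
                     coords_b[sel, , drop = FALSE])^2)))
}

#' Radius of gyration
#'
#' Rg about the (optionally mass-weighted) centroid of the selected atoms.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param atom_selection atom indices; default all.
#' @param weights optional per-atom weights (e.g. masses, Da) aligned with
#'   `coords` rows; `NULL` for unit weights.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, atom_selection = NULL, weights = NULL) {
  coords <- as.matrix(coords)
  sel <- if (is.null(atom_selection)) seq_len(nrow(coords)) else atom_selection
  if (length(sel) == 0L) stop("empty atom selection")
  x <- coords[sel, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, length(sel)) else weights[sel]
  w <- w / sum(w)
  ctr <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2L, ctr)^2)))
}

#' Mass-weighted center of mass of an atom selection
#'
#' @param coords `n x 3` matrix.
#' @param system a [system_model()] supplying masses.
#' @param atom_selection atom indices; default all.
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(coords, system, atom_selection = NULL) {
  sel <- if (is.null(atom_selection)) seq_len(nrow(coords)) else atom_selection
  w <- system$atoms$mass[sel]
  w <- w / sum(w)
  colSums(coords[sel, , drop = FALSE] * w)
}

# Run code with a temporary RNG state seeded by `seed`; restores the
# caller's RNG stream afterwards.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
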