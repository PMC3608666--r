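# PDB and plain-text coordinate-table input/output.
#
# Reading goes through bio3d; writing of multi-model ensembles uses a small
# fixed-width ATOM/MODEL/ENDMDL formatter so that one call emits one file.

.WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "TIP3", "SOL")

.is_hydrogen <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    es <- toupper(trimws(elesy))
    known <- es %in% names(.ELEMENT_MASS)
    out <- es == "H"
    # fall back to the atom-name heuristic where the element field is blank
    out[!known] <- grepl("^[0-9]*H", toupper(trimws(elety[!known])))
    return(out)
  }
  grepl("^[0-9]*H", toupper(trimws(elety)))
}

# Light pre-scan so malformed ATOM records fail with a line number before
# bio3d's parser sees them.
.scan_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("malformed ATOM record at line ", i, " of ", path,
           ": record shorter than coordinate fields")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31L, 38L),
                                         substr(ln, 39L, 46L),
                                         substr(ln, 47L, 54L))))
    if (any(is.na(xyz)))
      stop("malformed ATOM record at line ", i, " of ", path,
           ": non-numeric coordinate field")
  }
  invisible(length(atom_lines))
}

#' Read a (multi-model) PDB file into a system model and ensemble
#'
#' Parses ATOM records via bio3d, drops waters, heteroatoms and hydrogens,
#' resolves alternate locations by keeping the highest-occupancy conformer,
#' and assigns residue contact classes from [residue_class()]. Multi-model
#' files yield one ensemble frame per MODEL block.
#'
#' @param path path to a PDB file.
#' @param model_policy `"all_models"` (one frame per MODEL) or
#'   `"first_model"`.
#' @param dt frame interval in ps used to synthesise timestamps
#'   (`frame index * dt`).
#' @param expected_chains optional integer; error if the chain count
#'   differs.
#' @param label ensemble state label.
#' @return list with elements `system` ([system_model()]) and `ensemble`
#'   ([ensemble()]).
#' @export
read_pdb <- function(path, model_policy = c("all_models", "first_model"),
                     dt = 1, expected_chains = NULL, label = "bound") {
  model_policy <- match.arg(model_policy)
  .scan_pdb_records(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  atom <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)

  keep <- atom$type == "ATOM" &
    !(toupper(atom$resid) %in% .WATER_RESNAMES) &
    !.is_hydrogen(atom$elety, atom$elesy)
  # alternate locations: keep the highest-occupancy conformer per atom site
  alt <- atom$alt; alt[is.na(alt)] <- ""
  occ <- atom$o; occ[is.na(occ)] <- 1
  site <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  dup_sites <- unique(site[keep][duplicated(site[keep])])
  for (s in dup_sites) {
    idx <- which(keep & site == s)
    best <- idx[order(-occ[idx], alt[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("no protein ATOM records in ", path)
  atom <- atom[idx, , drop = FALSE]

  chain <- atom$chain; chain[is.na(chain) | chain == ""] <- "A"
  if (!is.null(expected_chains) &&
      length(unique(chain)) != expected_chains)
    stop("expected ", expected_chains, " chain(s) but found ",
         length(unique(chain)), " in ", path)

  rkey <- paste(chain, atom$resno, atom$insert, sep = "|")
  rid <- match(rkey, unique(rkey))
  residues <- data.frame(chain = chain[!duplicated(rid)],
                         resno = atom$resno[!duplicated(rid)],
                         resname = toupper(atom$resid[!duplicated(rid)]),
                         stringsAsFactors = FALSE)
  elesy <- trimws(atom$elesy)
  elesy[is.na(elesy) | elesy == ""] <-
    substr(gsub("^[0-9]+", "", trimws(atom$elety[is.na(elesy) | elesy == ""])), 1L, 1L)
  atoms <- data.frame(res = rid,
                      name = trimws(atom$elety),
                      element = toupper(elesy),
                      stringsAsFactors = FALSE)

  nmodels <- nrow(xyz)
  if (model_policy == "first_model") nmodels <- 1L
  xyz_idx <- bio3d::atom2xyz(idx)
  coords <- lapply(seq_len(nmodels), function(m)
    matrix(xyz[m, xyz_idx], ncol = 3L, byrow = TRUE))

  sys <- system_model(residues, atoms, coords[[1L]])
  ens <- ensemble(sys, coords, times = (seq_len(nmodels) - 1) * dt,
                  label = label)
  list(system = sys, ensemble = ens)
}

.format_atom_line <- function(serial, name, resname, chain, resno, xyz,
                              element) {
  nm <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, substr(nm, 1L, 4L), resname, chain, resno,
          xyz[1L], xyz[2L], xyz[3L], 1, 0, element)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with fixed-width ATOM records.
#'
#' @param ens an [ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path) {
  sys <- ens$system
  atm <- sys$atoms
  res <- sys$residues
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(ens)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    prev_chain <- res$chain[atm$res[1L]]
    for (a in seq_len(nrow(atm))) {
      r <- atm$res[a]
      if (res$chain[r] != prev_chain) {
        writeLines("TER", con)
        prev_chain <- res$chain[r]
      }
      writeLines(.format_atom_line(a, atm$name[a], res$resname[r],
                                   res$chain[r], res$resno[r], xyz[a, ],
                                   atm$element[a]), con)
    }
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Plain-text coordinate table interchange format
#'
#' One row per atom per frame with columns `frame`, `time_ps`, `chain`,
#' `resid`, `resname`, `atom`, `x`, `y`, `z` (tab-separated). This is the
#' interchange format used for synthetic ensembles.
#'
#' @param ens an [ensemble()].
#' @param path output path.
#' @return `path` invisibly (`write_coord_table`); for `read_coord_table`,
#'   a list with `system` and `ensemble`.
#' @export
write_coord_table <- function(ens, path) {
  sys <- ens$system
  nf <- n_frames(ens)
  na <- nrow(sys$atoms)
  r <- sys$atoms$res
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, each = na),
    time_ps = rep(ens$times, each = na),
    chain = rep(sys$residues$chain[r], nf),
    resid = rep(sys$residues$resno[r], nf),
    resname = rep(sys$residues$resname[r], nf),
    atom = rep(sys$atoms$name, nf),
    x = as.vector(t(matrix(ens$coords[, , 1L], nrow = nf))),
    y = as.vector(t(matrix(ens$coords[, , 2L], nrow = nf))),
    z = as.vector(t(matrix(ens$coords[, , 3L], nrow = nf))))
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coord_table
#' @param label state label for the ensemble read back.
#' @export
read_coord_table <- function(path, label = "bound") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("frame", "time_ps", "chain", "resid", "resname", "atom",
            "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  f0 <- df[df$frame == df$frame[1L], , drop = FALSE]
  rkey <- paste(f0$chain, f0$resid, sep = "|")
  rid <- match(rkey, unique(rkey))
  residues <- data.frame(chain = as.character(f0$chain[!duplicated(rid)]),
                         resno = f0$resid[!duplicated(rid)],
                         resname = toupper(f0$resname[!duplicated(rid)]),
                         stringsAsFactors = FALSE)
  nm <- trimws(f0$atom)
  mass <- .element_mass(substr(gsub("^[0-9]+", "", nm), 1L, 1L))
  # synthetic pseudo side chains carry the summed side-chain mass
  pseudo <- nm == "CB" & !(residues$resname[rid] %in% c("GLY"))
  sc_mass <- .SIDECHAIN_MASS[residues$resname[rid]]
  mass[pseudo & !is.na(sc_mass)] <- sc_mass[pseudo & !is.na(sc_mass)]
  atoms <- data.frame(res = rid, name = nm,
                      element = substr(gsub("^[0-9]+", "", nm), 1L, 1L),
                      mass = mass, stringsAsFactors = FALSE)
  frames <- split(seq_len(nrow(df)), df$frame)
  coords <- lapply(frames, function(i)
    cbind(df$x[i], df$y[i], df$z[i]))
  times <- vapply(frames, function(i) df$time_ps[i[1L]], 0)
  sys <- system_model(residues, atoms, coords[[1L]])
  ens <- ensemble(sys, coords, times = as.numeric(times), label = label)
  list(system = sys, ensemble = ens)
}
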