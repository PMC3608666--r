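# Typed residue-residue contacts and native-contact fractions Qf / Qb.
#
# Contact rules:
#   generic       minimum side-chain heavy-atom distance < 6.5 A (GLY: CA
#                 stands in for the side chain); intra-chain pairs need
#                 sequence separation >= 2
#   electrostatic distance between side-chain charge-group centers of mass
#                 of a positive and a negative residue < 11 A
#   hbond         donor-acceptor heavy-atom distance < 3.5 A and
#                 antecedent-donor-acceptor angle > 120 degrees

.CHARGE_GROUP <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  LYS = "NZ",
  HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2", "CG"),
  GLU = c("OE1", "OE2", "CD"))

# side-chain donor/acceptor heavy atoms with their antecedent atom;
# backbone N (antecedent CA) and O (antecedent C) are added for all residues
.HB_DONORS <- list(
  SER = list(c("OG", "CB")), THR = list(c("OG1", "CB")),
  TYR = list(c("OH", "CZ")), CYS = list(c("SG", "CB")),
  ASN = list(c("ND2", "CG")), GLN = list(c("NE2", "CD")),
  LYS = list(c("NZ", "CE")), TRP = list(c("NE1", "CD1")),
  ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
  HIS = list(c("ND1", "CG"), c("NE2", "CD2")))

.HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

# Per-residue side-chain heavy-atom indices; CA substitutes when a residue
# has no side-chain heavy atoms (GLY, or stripped models).
.sidechain_sets <- function(system) {
  atm <- system$atoms
  n_res <- nrow(system$residues)
  out <- vector("list", n_res)
  sc <- which(!atm$backbone & atm$element != "H")
  sc_by_res <- split(sc, atm$res[sc])
  ca <- ca_indices(system)
  ca_by_res <- integer(n_res)
  ca_by_res[atm$res[ca]] <- ca
  for (r in seq_len(n_res)) {
    s <- sc_by_res[[as.character(r)]]
    out[[r]] <- if (length(s)) s else ca_by_res[r]
  }
  out
}

# position of each residue within its chain (for sequence separation)
.chain_positions <- function(system) {
  res <- system$residues
  pos <- integer(nrow(res))
  for (ch in system$chains) {
    i <- which(res$chain == ch)
    pos[i] <- seq_along(i)
  }
  pos
}

.contact_frame <- function(i, j, kind, scope, dist, system) {
  res <- system$residues
  kind <- rep_len(kind, length(i))
  data.frame(i = i, j = j,
             chain_i = res$chain[i], resno_i = res$resno[i],
             resname_i = res$resname[i],
             chain_j = res$chain[j], resno_j = res$resno[j],
             resname_j = res$resname[j],
             kind = kind, scope = scope, dist = dist,
             stringsAsFactors = FALSE)
}

# minimum inter-set distance for many residue pairs at once:
# pairs is a 2-column matrix of residue indices; sets a list of atom
# indices per residue. Returns the min distance per pair.
.min_set_dist <- function(coords, pairs, sets) {
  if (nrow(pairs) == 0L) return(numeric(0))
  na_i <- lengths(sets[pairs[, 1L]])
  na_j <- lengths(sets[pairs[, 2L]])
  ncomb <- na_i * na_j
  gid <- rep.int(seq_len(nrow(pairs)), ncomb)
  ia <- unlist(lapply(seq_len(nrow(pairs)), function(p)
    rep(sets[[pairs[p, 1L]]], times = na_j[p])), use.names = FALSE)
  ib <- unlist(lapply(seq_len(nrow(pairs)), function(p)
    rep(sets[[pairs[p, 2L]]], each = na_i[p])), use.names = FALSE)
  d2 <- rowSums((coords[ia, , drop = FALSE] - coords[ib, , drop = FALSE])^2)
  grp <- factor(gid, levels = seq_len(nrow(pairs)))
  sqrt(unname(vapply(split(d2, grp), min, 0)))
}

# all candidate residue pairs honouring the adjacency rule
.eligible_pairs <- function(system, min_sep = 2L) {
  n_res <- nrow(system$residues)
  pr <- t(utils::combn(n_res, 2L))
  ch <- system$residues$chain
  pos <- .chain_positions(system)
  same <- ch[pr[, 1L]] == ch[pr[, 2L]]
  sep_ok <- !same | abs(pos[pr[, 1L]] - pos[pr[, 2L]]) >= min_sep
  list(pairs = pr[sep_ok, , drop = FALSE],
       scope = ifelse(same[sep_ok], "tertiary", "binding"))
}

#' Assign generic (side-chain proximity) contacts on one conformation
#'
#' A residue pair is in contact iff the minimum distance between their
#' side-chain heavy atoms is strictly below `cutoff` (6.5 Angstrom by
#' default); for glycine the C-alpha substitutes for the side chain.
#' Intra-chain pairs must be separated by at least `min_sep` positions in
#' sequence ("not adjacent"); all inter-chain pairs are eligible.
#'
#' @param coords `atoms x 3` coordinate matrix covering `system`.
#' @param system a [system_model()].
#' @param cutoff contact distance cutoff in Angstrom (strict `<`).
#' @param min_sep minimum intra-chain sequence separation.
#' @return data.frame of contacts with residue indices `i < j`, chain and
#'   residue identifiers, `kind`, `scope` (`"tertiary"`/`"binding"`) and the
#'   realised minimum distance.
#' @export
assign_generic_contacts <- function(coords, system, cutoff = 6.5,
                                    min_sep = 2L) {
  el <- .eligible_pairs(system, min_sep)
  sets <- .sidechain_sets(system)
  d <- .min_set_dist(coords, el$pairs, sets)
  hit <- d < cutoff
  .contact_frame(el$pairs[hit, 1L], el$pairs[hit, 2L], "generic",
                 el$scope[hit], d[hit], system)
}

# charge-center atoms for one residue: canonical charge-group atoms when
# present, otherwise all side-chain heavy atoms (reduced representations)
.charge_sets <- function(system) {
  atm <- system$atoms
  res <- system$residues
  sets <- .sidechain_sets(system)
  for (r in which(res$class %in% c("positive", "negative"))) {
    grp <- .CHARGE_GROUP[[res$resname[r]]]
    if (!is.null(grp)) {
      hit <- sets[[r]][atm$name[sets[[r]]] %in% grp]
      if (length(hit)) sets[[r]] <- hit
    }
  }
  sets
}

#' Assign electrostatic (salt-bridge) contacts
#'
#' A contact holds iff one residue is positively charged (ARG, LYS, HIS),
#' the other negatively (ASP, GLU), and the distance between the two
#' side-chain charge-group centers of mass is strictly below `cutoff`
#' (11 Angstrom by default).
#'
#' @inheritParams assign_generic_contacts
#' @param cutoff charge-center distance cutoff in Angstrom (strict `<`).
#' @return contact data.frame as in [assign_generic_contacts()], with
#'   `kind = "electrostatic"`.
#' @export
assign_electrostatic_contacts <- function(coords, system, cutoff = 11,
                                          min_sep = 2L) {
  res <- system$residues
  el <- .eligible_pairs(system, min_sep)
  cls_i <- res$class[el$pairs[, 1L]]
  cls_j <- res$class[el$pairs[, 2L]]
  opp <- (cls_i == "positive" & cls_j == "negative") |
         (cls_i == "negative" & cls_j == "positive")
  pr <- el$pairs[opp, , drop = FALSE]
  scope <- el$scope[opp]
  if (nrow(pr) == 0L)
    return(.contact_frame(integer(0), integer(0), character(0),
                          character(0), numeric(0), system))
  sets <- .charge_sets(system)
  masses <- system$atoms$mass
  centers <- t(vapply(seq_len(nrow(res)), function(r) {
    s <- sets[[r]]
    w <- masses[s] / sum(masses[s])
    colSums(coords[s, , drop = FALSE] * w)
  }, numeric(3L)))
  d <- sqrt(rowSums((centers[pr[, 1L], , drop = FALSE] -
                     centers[pr[, 2L], , drop = FALSE])^2))
  hit <- d < cutoff
  .contact_frame(pr[hit, 1L], pr[hit, 2L], "electrostatic", scope[hit],
                 d[hit], system)
}

# donor/acceptor tables for a system: matrices of atom indices
.hb_atoms <- function(system) {
  atm <- system$atoms
  res <- system$residues
  don <- list(); acc_idx <- integer(0)
  atom_of <- function(r, name) {
    i <- which(atm$res == r & atm$name == name)
    if (length(i)) i[1L] else NA_integer_
  }
  for (r in seq_len(nrow(res))) {
    # backbone donor N (antecedent CA) and acceptor O
    n_i <- atom_of(r, "N"); ca_i <- atom_of(r, "CA"); o_i <- atom_of(r, "O")
    if (!is.na(n_i) && !is.na(ca_i)) don[[length(don) + 1L]] <- c(n_i, ca_i, r)
    if (!is.na(o_i)) acc_idx <- c(acc_idx, o_i)
    sd <- .HB_DONORS[[res$resname[r]]]
    if (!is.null(sd)) for (da in sd) {
      d_i <- atom_of(r, da[1L]); a_i <- atom_of(r, da[2L])
      if (!is.na(d_i) && !is.na(a_i)) don[[length(don) + 1L]] <- c(d_i, a_i, r)
    }
    sa <- .HB_ACCEPTORS[[res$resname[r]]]
    if (!is.null(sa)) for (an in sa) {
      a_i <- atom_of(r, an)
      if (!is.na(a_i)) acc_idx <- c(acc_idx, a_i)
    }
  }
  list(donors = if (length(don)) do.call(rbind, don) else
         matrix(integer(0), ncol = 3L),
       acceptors = unique(acc_idx))
}

#' Assign hydrogen bonds (heavy-atom geometric criterion)
#'
#' A hydrogen bond is counted between a donor heavy atom D (backbone N or
#' a polar side-chain N/O/S) and an acceptor heavy atom A when
#' `d(D, A) < dist_cutoff` and the antecedent-D-A angle exceeds
#' `angle_cutoff`. Atom pairs are aggregated to residue pairs; the
#' atom-level detail is kept in `attr(x, "pairs")`.
#'
#' @inheritParams assign_generic_contacts
#' @param dist_cutoff donor-acceptor distance cutoff in Angstrom.
#' @param angle_cutoff minimum antecedent-donor-acceptor angle in degrees.
#' @return contact data.frame with `kind = "hbond"`.
#' @export
assign_hbonds <- function(coords, system, dist_cutoff = 3.5,
                          angle_cutoff = 120, min_sep = 2L) {
  hb <- .hb_atoms(system)
  atm <- system$atoms
  pos <- .chain_positions(system)
  ch <- system$residues$chain
  rows <- list()
  for (k in seq_len(nrow(hb$donors))) {
    d_i <- hb$donors[k, 1L]; ant <- hb$donors[k, 2L]; rd <- hb$donors[k, 3L]
    for (a_i in hb$acceptors) {
      ra <- atm$res[a_i]
      if (ra == rd) next
      same <- ch[ra] == ch[rd]
      if (same && abs(pos[ra] - pos[rd]) < min_sep) next
      v_da <- coords[a_i, ] - coords[d_i, ]
      dist <- sqrt(sum(v_da^2))
      if (dist >= dist_cutoff) next
      v_dant <- coords[ant, ] - coords[d_i, ]
      cosang <- sum(v_da * v_dant) /
        (dist * sqrt(sum(v_dant^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= angle_cutoff) next
      rows[[length(rows) + 1L]] <-
        data.frame(donor_res = rd, acceptor_res = ra,
                   donor_atom = atm$name[d_i], acceptor_atom = atm$name[a_i],
                   dist = dist, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- .contact_frame(integer(0), integer(0), character(0),
                          character(0), numeric(0), system)
    attr(out, "pairs") <- data.frame()
    return(out)
  }
  det <- do.call(rbind, rows)
  i <- pmin(det$donor_res, det$acceptor_res)
  j <- pmax(det$donor_res, det$acceptor_res)
  key <- paste(i, j)
  first <- !duplicated(key)
  dmin <- vapply(split(det$dist, key), min, 0)[unique(key)]
  scope <- ifelse(ch[i[first]] == ch[j[first]], "tertiary", "binding")
  out <- .contact_frame(i[first], j[first], "hbond", scope, unname(dmin),
                        system)
  attr(out, "pairs") <- det
  out
}

#' Native contacts of a reference structure
#'
#' The set of generic contacts evaluated on the reference coordinates,
#' partitioned into tertiary (intra-chain) and binding (inter-chain)
#' scopes and flagged native. This set defines Qf and Qb.
#'
#' @param system a [system_model()].
#' @param reference_coords coordinates to evaluate on; defaults to
#'   `system$reference_coords`.
#' @inheritParams assign_generic_contacts
#' @return an object of class `contact_set`: the contact data.frame with a
#'   `native` column and counts in attributes `n_native_tertiary`,
#'   `n_native_binding`.
#' @export
native_contacts <- function(system, reference_coords = system$reference_coords,
                            cutoff = 6.5, min_sep = 2L) {
  cs <- assign_generic_contacts(reference_coords, system, cutoff, min_sep)
  cs$native <- TRUE
  attr(cs, "n_native_tertiary") <- sum(cs$scope == "tertiary")
  attr(cs, "n_native_binding") <- sum(cs$scope == "binding")
  attr(cs, "cutoff") <- cutoff
  class(cs) <- c("contact_set", class(cs))
  cs
}

#' @export
print.contact_set <- function(x, ...) {
  cat("contact_set:", nrow(x), "native contacts (",
      attr(x, "n_native_tertiary"), "tertiary,",
      attr(x, "n_native_binding"), "binding )\n")
  invisible(x)
}

# frames x contacts logical matrix: is each native contact satisfied
# (generic criterion) in each frame?
.contact_satisfaction <- function(ens, native) {
  sets <- .sidechain_sets(ens$system)
  cutoff <- attr(native, "cutoff")
  if (is.null(cutoff)) cutoff <- 6.5
  pairs <- cbind(native$i, native$j)
  nf <- n_frames(ens)
  out <- matrix(FALSE, nf, nrow(pairs))
  for (f in seq_len(nf)) {
    d <- .min_set_dist(frame_coords(ens, f), pairs, sets)
    out[f, ] <- d < cutoff
  }
  out
}

#' Native-contact fraction time series (Qf and Qb)
#'
#' For every frame, `qf` is the fraction of native tertiary contacts whose
#' generic criterion still holds, and `qb` the analogous fraction over
#' native binding contacts. A channel with zero native contacts is
#' returned as `NA` (undefined), never as 0/0.
#'
#' @param ens an [ensemble()].
#' @param native a [native_contacts()] set for the same system.
#' @return object of class `q_series` with fields `times`, `qf`, `qb`,
#'   `n_native_tertiary`, `n_native_binding`.
#' @export
q_series <- function(ens, native) {
  sat <- .contact_satisfaction(ens, native)
  tert <- native$scope == "tertiary"
  bind <- native$scope == "binding"
  nt <- sum(tert); nb <- sum(bind)
  qf <- if (nt > 0L) rowMeans(sat[, tert, drop = FALSE]) else
    rep(NA_real_, nrow(sat))
  qb <- if (nb > 0L) rowMeans(sat[, bind, drop = FALSE]) else
    rep(NA_real_, nrow(sat))
  structure(list(times = ens$times, qf = qf, qb = qb,
                 n_native_tertiary = nt, n_native_binding = nb),
            class = "q_series")
}

#' @export
print.q_series <- function(x, ...) {
  cat("q_series:", length(x$times), "frames;",
      x$n_native_tertiary, "native tertiary,",
      x$n_native_binding, "native binding contacts\n")
  if (x$n_native_tertiary > 0L)
    cat(sprintf("  qf: %.3f -> %.3f\n", x$qf[1L], x$qf[length(x$qf)]))
  if (x$n_native_binding > 0L)
    cat(sprintf("  qb: %.3f -> %.3f\n", x$qb[1L], x$qb[length(x$qb)]))
  invisible(x)
}

#' @export
as.data.frame.q_series <- function(x, ...) {
  data.frame(time_ps = x$times, qf = x$qf, qb = x$qb)
}

#' Fraction of frames in which a contact criterion holds
#'
#' Evaluates the criterion matching each contact's `kind` (generic /
#' electrostatic / hbond) frame by frame.
#'
#' @param ens an [ensemble()].
#' @param contacts contact data.frame (one or more rows) as produced by
#'   the `assign_*` functions or [native_contacts()].
#' @param cutoff distance cutoff for generic-kind contacts.
#' @return numeric vector of populations in `[0, 1]`, one per contact row.
#' @export
contact_population <- function(ens, contacts, cutoff = 6.5) {
  nf <- n_frames(ens)
  if (nf == 0L) stop("ensemble is empty")
  sys <- ens$system
  sets <- .sidechain_sets(sys)
  pop <- numeric(nrow(contacts))
  kinds <- contacts$kind
  for (kind in unique(kinds)) {
    rows <- which(kinds == kind)
    count <- numeric(length(rows))
    for (f in seq_len(nf)) {
      xyz <- frame_coords(ens, f)
      hit <- switch(kind,
        electrostatic = {
          ec <- assign_electrostatic_contacts(xyz, sys)
          paste(contacts$i[rows], contacts$j[rows]) %in% paste(ec$i, ec$j)
        },
        hbond = {
          hc <- assign_hbonds(xyz, sys)
          paste(contacts$i[rows], contacts$j[rows]) %in% paste(hc$i, hc$j)
        },
        .min_set_dist(xyz, cbind(contacts$i[rows], contacts$j[rows]),
                      sets) < cutoff)
      count <- count + hit
    }
    pop[rows] <- count / nf
  }
  pop
}

#' Write a contact table as TSV
#'
#' @param contacts contact data.frame; a `population` column is included
#'   when present.
#' @param path output path.
#' @export
write_contact_table <- function(contacts, path) {
  cols <- intersect(c("chain_i", "resno_i", "resname_i", "chain_j",
                      "resno_j", "resname_j", "kind", "scope", "native",
                      "dist", "population"), names(contacts))
  utils::write.table(contacts[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
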