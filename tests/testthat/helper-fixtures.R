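# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toy_complex <- function(seed = 3L) {
  cached(paste0("toy_", seed), function()
    build_toy_complex(synthetic_spec(seed = seed)))
}

ladder <- function() cached("ladder", function() build_ladder_complex())

# minimal hand-built system: n residues on one or two chains, one CA and
# one side-chain atom each, at caller-given positions
tiny_system <- function(resnames, chains, ca, sc = NULL) {
  n <- length(resnames)
  residues <- data.frame(chain = chains,
                         resno = unlist(lapply(split(seq_len(n), chains),
                                               seq_along))[order(order(chains))],
                         resname = resnames, stringsAsFactors = FALSE)
  # keep it simple: resno = position within chain in input order
  pos <- stats::ave(seq_len(n), chains, FUN = seq_along)
  residues$resno <- pos
  atoms <- data.frame(res = rep(seq_len(n), each = if (is.null(sc)) 1L else 2L),
                      name = if (is.null(sc)) "CA" else rep(c("CA", "CB"), n),
                      element = if (is.null(sc)) "C" else rep(c("C", "C"), n),
                      stringsAsFactors = FALSE)
  coords <- if (is.null(sc)) ca else {
    out <- matrix(0, 2L * n, 3L)
    out[seq(1L, 2L * n, by = 2L), ] <- ca
    out[seq(2L, 2L * n, by = 2L), ] <- sc
    out
  }
  system_model(residues, atoms, coords)
}

# random rigid motion applied to a coordinate matrix
random_rigid <- function(coords, seed = 1L) {
  set.seed(seed)
  ang <- runif(3L, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3L, 3L)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3L, 3L)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                 -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3L, 3L)
  sweep(coords %*% (Rx %*% Ry %*% Rz), 2L, runif(3L, -20, 20), "+")
}

# brute-force contact oracles, written independently of the package
# internals: plain double loops over residue pairs
oracle_sidechain_atoms <- function(sys, r) {
  idx <- which(sys$atoms$res == r & !sys$atoms$backbone &
                 sys$atoms$element != "H")
  if (!length(idx)) idx <- which(sys$atoms$res == r & sys$atoms$name == "CA")
  idx
}

oracle_generic <- function(coords, sys, cutoff = 6.5) {
  n <- nrow(sys$residues)
  pos <- stats::ave(seq_len(n), sys$residues$chain, FUN = seq_along)
  hits <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    same <- sys$residues$chain[i] == sys$residues$chain[j]
    if (same && abs(pos[i] - pos[j]) < 2L) next
    ai <- oracle_sidechain_atoms(sys, i)
    aj <- oracle_sidechain_atoms(sys, j)
    dmin <- Inf
    for (a in ai) for (b in aj)
      dmin <- min(dmin, sqrt(sum((coords[a, ] - coords[b, ])^2)))
    if (dmin < cutoff) hits <- rbind(hits, c(i, j))
  }
  hits
}

oracle_electrostatic <- function(coords, sys, cutoff = 11) {
  charge_atoms <- list(ARG = c("NE", "CZ", "NH1", "NH2"), LYS = "NZ",
                       HIS = c("ND1", "NE2"), ASP = c("OD1", "OD2", "CG"),
                       GLU = c("OE1", "OE2", "CD"))
  n <- nrow(sys$residues)
  pos <- stats::ave(seq_len(n), sys$residues$chain, FUN = seq_along)
  center <- function(r) {
    sel <- oracle_sidechain_atoms(sys, r)
    canon <- sel[sys$atoms$name[sel] %in%
                   charge_atoms[[sys$residues$resname[r]]]]
    if (length(canon)) sel <- canon
    w <- sys$atoms$mass[sel] / sum(sys$atoms$mass[sel])
    colSums(coords[sel, , drop = FALSE] * w)
  }
  hits <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- sys$residues$class[i]; cj <- sys$residues$class[j]
    if (!((ci == "positive" && cj == "negative") ||
          (ci == "negative" && cj == "positive"))) next
    same <- sys$residues$chain[i] == sys$residues$chain[j]
    if (same && abs(pos[i] - pos[j]) < 2L) next
    if (sqrt(sum((center(i) - center(j))^2)) < cutoff)
      hits <- rbind(hits, c(i, j))
  }
  hits
}

contact_key <- function(df) sort(paste(df$i, df$j))
oracle_key <- function(m) if (is.null(m)) character(0) else
  sort(paste(m[, 1L], m[, 2L]))

oracle_hbond <- function(coords, sys, dist_cutoff = 3.5, angle_cutoff = 120) {
  # independent re-derivation: enumerate donor/acceptor atoms by table,
  # then plain loops with explicit vector geometry
  donors <- list(SER = list(c("OG", "CB")), THR = list(c("OG1", "CB")),
                 TYR = list(c("OH", "CZ")), CYS = list(c("SG", "CB")),
                 ASN = list(c("ND2", "CG")), GLN = list(c("NE2", "CD")),
                 LYS = list(c("NZ", "CE")), TRP = list(c("NE1", "CD1")),
                 ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
                 HIS = list(c("ND1", "CG"), c("NE2", "CD2")))
  acceptors <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                    ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                    TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")
  n <- nrow(sys$residues)
  pos <- stats::ave(seq_len(n), sys$residues$chain, FUN = seq_along)
  atom_of <- function(r, nm) {
    i <- which(sys$atoms$res == r & sys$atoms$name == nm)
    if (length(i)) i[1L] else NA_integer_
  }
  don <- NULL
  acc <- integer(0)
  for (r in seq_len(n)) {
    ni <- atom_of(r, "N"); cai <- atom_of(r, "CA"); oi <- atom_of(r, "O")
    if (!is.na(ni) && !is.na(cai)) don <- rbind(don, c(ni, cai, r))
    if (!is.na(oi)) acc <- c(acc, oi)
    for (da in donors[[sys$residues$resname[r]]] %||% list()) {
      di <- atom_of(r, da[1L]); ai <- atom_of(r, da[2L])
      if (!is.na(di) && !is.na(ai)) don <- rbind(don, c(di, ai, r))
    }
    for (an in acceptors[[sys$residues$resname[r]]] %||% character(0)) {
      ai <- atom_of(r, an)
      if (!is.na(ai)) acc <- c(acc, ai)
    }
  }
  acc <- unique(acc)
  hits <- NULL
  if (is.null(don)) return(NULL)
  for (k in seq_len(nrow(don))) {
    for (a in acc) {
      rd <- don[k, 3L]; ra <- sys$atoms$res[a]
      if (rd == ra) next
      if (sys$residues$chain[rd] == sys$residues$chain[ra] &&
          abs(pos[rd] - pos[ra]) < 2L) next
      v1 <- coords[a, ] - coords[don[k, 1L], ]
      d <- sqrt(sum(v1^2))
      if (d >= dist_cutoff) next
      v2 <- coords[don[k, 2L], ] - coords[don[k, 1L], ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) / (d * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang <= angle_cutoff) next
      hits <- rbind(hits, c(min(rd, ra), max(rd, ra)))
    }
  }
  if (is.null(hits)) NULL else unique(hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
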