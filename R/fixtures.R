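# Deterministic synthetic structures: a toy C4 "channel" (a barrel of
# beta-strand pillars with three named contact rings and a tunable charged
# pocket) and a toy basic peptide (compact helical core + mobile basic
# C-terminal tail). Everything is exactly reproducible from the seed; the
# channel itself is fully deterministic (the seed only drives optional
# coordinate noise and the peptide tail jitter).
#
# Ring side chains are placed synthetically: the designated tip atom sits at
# EXACTLY the requested radial distance from the pore (z) axis, pointing
# inward, so ring-diameter math has an analytic ground truth (diameter = 2r).

#' Parameters for the synthetic C4 channel
#'
#' @param n_res_per_leg residues per vertical strand (default 7).
#' @param n_legs strands per subunit serpentine (default 3).
#' @param wall_radius radial distance of the subunit strand axis from the
#'   pore axis, Angstrom (default 8).
#' @param rings named list of ring placements, each
#'   `list(depth =, radius =, restype =, atom =)`; defaults give an upper
#'   acidic "turret" ring, a mid-level glutamate pocket ring and a narrow
#'   lower "pore" ring.
#' @param pocket `"negative"` (default: acidic pocket ring, the
#'   toxin-sensitive state), `"positive"` (charge-reversed, lysine tips) or
#'   `"none"` (neutral amide tips, same shape).
#' @param noise optional isotropic coordinate noise sd, Angstrom.
#' @param seed integer seed fixing all stochastic elements.
#' @return list of class `toy_channel_params`.
#' @export
toy_channel_params <- function(n_res_per_leg = 7, n_legs = 3,
                               wall_radius = 9.5,
                               rings = NULL, pocket = "negative",
                               noise = 0, seed = 1L) {
  if (wall_radius <= 0 || n_res_per_leg < 3 || n_legs < 1)
    stop("geometrically impossible toy-channel parameters", call. = FALSE)
  if (is.null(rings)) rings <- list(
    turret = list(depth = 5, radius = 8.0, restype = "ASP", atom = "OD1"),
    mid = list(depth = 0, radius = 6.0, restype = "GLU", atom = "OE1"),
    pore = list(depth = -6, radius = 3.5, restype = "TYR", atom = "OH")
  )
  for (r in rings) if (r$radius <= 0 || r$radius >= wall_radius)
    stop("ring radius must lie inside the wall", call. = FALSE)
  structure(list(n_res_per_leg = n_res_per_leg, n_legs = n_legs,
                 wall_radius = wall_radius, rings = rings, pocket = pocket,
                 noise = noise, seed = as.integer(seed)),
            class = "toy_channel_params")
}

# Side-chain atom names laid inward for each pocket chemistry.
POCKET_RESTYPE <- c(negative = "GLU", positive = "LYS", none = "GLN")
POCKET_TIP <- c(negative = "OE1", positive = "NZ", none = "OE1")

SYN_SC_ATOMS <- list(
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")
)

# Build a synthetic inward-pointing side chain: atoms evenly spaced from CB
# to the tip; the tip atom lands exactly at radial distance `radius` at the
# CA's azimuth and z = CA z; the "partner" terminal atom (OD2/OE2/NE2/CD2)
# is offset in z so carboxylates stay two-atom groups.
synth_inward_sidechain <- function(restype, tip_atom, CA, radius) {
  names_sc <- SYN_SC_ATOMS[[restype]]
  az <- atan2(CA[2], CA[1])
  r_ca <- sqrt(CA[1]^2 + CA[2]^2)
  tip <- c(radius * cos(az), radius * sin(az), CA[3])
  cb <- CA + 1.53 * vunit(tip - CA)
  k <- match(tip_atom, names_sc)
  stopifnot(!is.na(k))
  frac <- if (k > 1) seq(0, 1, length.out = k) else 1
  main <- t(vapply(frac, function(f) cb + f * (tip - cb), double(3)))
  rows <- list()
  for (i in seq_len(k))
    rows[[names_sc[i]]] <- main[i, ]
  for (nm in setdiff(names_sc, names(rows))) {
    off <- 1.1 * (if (length(rows) %% 2) 1 else -1)
    rows[[nm]] <- tip + c(0, 0, off)
  }
  nm <- names(rows)
  data.frame(name = nm,
             x = vapply(rows, `[`, 0, 1), y = vapply(rows, `[`, 0, 2),
             z = vapply(rows, `[`, 0, 3),
             element = substr(nm, 1, 1), row.names = NULL,
             stringsAsFactors = FALSE)
}

res_block <- function(resname, resseq, chain, names, coords) {
  data.frame(serial = 0L, name = names, altloc = "", resname = resname,
             chain = chain, resseq = resseq, icode = "",
             x = coords[, 1], y = coords[, 2], z = coords[, 3], occ = 1,
             element = substr(names, 1, 1), stringsAsFactors = FALSE)
}

# One straight vertical strand of n residues: built as an ideal beta
# strand, principal CA axis exactly on z, zig-zag plane on y-z (so side
# chains extend along +-x, i.e. radially once the leg is placed on the
# wall), centered at the origin, N-terminus at the bottom.
make_leg <- function(n) {
  bb <- build_backbone(rep(-139, n), rep(135, n))
  ca <- t(vapply(bb, function(r) r$CA, double(3)))
  ctr <- colMeans(ca)
  cv <- crossprod(sweep(ca, 2, ctr))
  ev <- eigen(cv, symmetric = TRUE)
  R1 <- t(ev$vectors[, c(2, 3, 1)])
  if (det(R1) < 0) R1[1, ] <- -R1[1, ]
  ap <- function(R, v) as.vector(R %*% v)
  for (i in seq_len(n)) for (nm in names(bb[[i]]))
    bb[[i]][[nm]] <- ap(R1, bb[[i]][[nm]] - ctr)
  if (bb[[1]]$CA[3] > bb[[n]]$CA[3]) {       # N-terminus down
    Rf <- diag(c(1, -1, -1))
    for (i in seq_len(n)) for (nm in names(bb[[i]]))
      bb[[i]][[nm]] <- ap(Rf, bb[[i]][[nm]])
  }
  # put the CA zig-zag in the y-z plane
  ca <- t(vapply(bb, function(r) r$CA, double(3)))
  dev <- ca[1, ] - ca[2, ]; dev[3] <- 0
  if (vnorm(dev) > 1e-9) {
    th <- atan2(dev[2], dev[1])
    Rz <- matrix(c(cos(-th), -sin(-th), 0, sin(-th), cos(-th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    for (i in seq_len(n)) for (nm in names(bb[[i]]))
      bb[[i]][[nm]] <- ap(Rz, bb[[i]][[nm]])
  }
  bb
}

rigid_place <- function(bb, Rz_angle, shift) {
  R <- matrix(c(cos(Rz_angle), -sin(Rz_angle), 0,
                sin(Rz_angle), cos(Rz_angle), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  lapply(bb, function(res) lapply(res, function(v) as.vector(R %*% v) + shift))
}

# Solve a single bridging residue between fixed anchor atoms C_prev and
# N_next: all four backbone bonds land in the 1.2-1.6 A window.
make_turn_residue <- function(C_prev, N_next) {
  u <- vunit(N_next - C_prev)
  N <- C_prev + 1.33 * u
  C <- N_next - 1.33 * u
  d <- vnorm(C - N)
  if (d > 2.95) stop("toy-channel turn cannot be closed", call. = FALSE)
  mid <- (N + C) / 2
  h <- sqrt(max(1.49^2 - (d / 2)^2, 0.2))
  perp <- vcross(u, c(0, 0, 1))
  if (vnorm(perp) < 1e-6) perp <- vcross(u, c(1, 0, 0))
  CA <- mid + h * vunit(perp)
  O <- C + 1.23 * vunit(C - CA)
  list(N = N, CA = CA, C = C, O = O)
}

#' Generate the synthetic C4 channel tetramer
#'
#' The subunit is a palisade of `n_legs` antiparallel vertical strands on a
#' cylinder of radius `wall_radius`, joined by bridging turn residues; four
#' symmetry copies close the barrel around the pore (z) axis.
#'
#' @param params a [toy_channel_params()].
#' @return list with `tetramer` (chains A-D), `subunit` (chain A), `rings`
#'   (ring definitions consumable by [contact_rings()]), `pocket_position`
#'   (1-based position of the pocket-ring residue in the subunit chain) and
#'   `params`.
#' @export
make_toy_channel <- function(params = toy_channel_params()) {
  p <- params
  n_leg <- p$n_res_per_leg
  leg0 <- make_leg(n_leg)
  leg_flip <- lapply(leg0, function(res)
    lapply(res, function(v) as.vector(diag(c(1, -1, -1)) %*% v)))
  daz <- min(2 * pi / (4 * p$n_legs), 4.2 / p$wall_radius)  # pillar spacing
  az0 <- -daz * (p$n_legs - 1) / 2
  bb <- list()
  leg_of <- integer(0)
  for (l in seq_len(p$n_legs)) {
    src <- if (l %% 2 == 1) leg0 else leg_flip  # antiparallel legs
    placed <- rigid_place(src, 0,
                          c(p$wall_radius * cos(az0 + (l - 1) * daz),
                            p$wall_radius * sin(az0 + (l - 1) * daz), 0))
    if (l > 1) {
      prev <- bb[[length(bb)]]
      bb[[length(bb) + 1L]] <- make_turn_residue(prev$C, placed[[1]]$N)
      leg_of <- c(leg_of, 0L)
    }
    bb <- c(bb, placed)
    leg_of <- c(leg_of, rep(l, n_leg))
  }
  n <- length(bb)
  ca <- t(vapply(bb, function(r) r$CA, double(3)))
  # assign ring residues: leg-1 residue with CA z nearest each ring depth
  restype <- rep(c("ALA", "SER"), length.out = n)
  restype[leg_of == 0L] <- "GLY"          # bridging turn residues
  ring_assign <- list()
  taken <- integer(0)
  rings <- p$rings
  if (!is.null(rings$mid)) {
    rings$mid$restype <- POCKET_RESTYPE[[p$pocket]]
    rings$mid$atom <- POCKET_TIP[[p$pocket]]
  }
  for (rn in names(rings)) {
    rg <- rings[[rn]]
    cand <- setdiff(seq_len(n_leg), taken)
    ri <- cand[which.min(abs(ca[cand, 3] - rg$depth))]
    taken <- c(taken, ri)
    restype[ri] <- rg$restype
    ring_assign[[rn]] <- list(name = rn, resseq = ri, atom = rg$atom,
                              radius = rg$radius, depth = ca[ri, 3])
  }
  rows <- list()
  for (i in seq_len(n)) {
    bbn <- c("N", "CA", "C", "O")
    bbc <- t(vapply(bbn, function(nm) bb[[i]][[nm]], double(3)))
    rt <- restype[i]
    block <- res_block(rt, i, "A", bbn, bbc)
    ring_here <- Filter(function(r) r$resseq == i, ring_assign)
    if (length(ring_here)) {
      rg <- ring_here[[1]]
      sc <- synth_inward_sidechain(rt, rg$atom, bb[[i]]$CA, rg$radius)
    } else if (rt != "GLY") {
      sc <- build_sidechain(rt, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C,
                            chi = c(-60, 180, 180, 180))
    } else sc <- empty_sc()
    if (nrow(sc))
      block <- rbind(block, res_block(rt, i, "A",
                                      sc$name, as.matrix(sc[, c("x", "y", "z")])))
    rows[[i]] <- block
  }
  atoms <- do.call(rbind, rows)
  if (p$noise > 0) {
    set.seed(p$seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, p$noise)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, p$noise)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, p$noise)
  }
  atoms$serial <- seq_len(nrow(atoms))
  subunit <- structure_bundle(list(atoms), id = "toy_subunit")
  tet <- assemble_oligomer(subunit, c4_operators())
  tet$id <- sprintf("toy_channel_%s", p$pocket)
  ring_defs <- lapply(ring_assign, function(r)
    list(name = r$name, resseq = r$resseq, atom = r$atom))
  list(tetramer = tet, subunit = subunit, rings = ring_defs,
       pocket_position = ring_assign$mid$resseq %||% NA_integer_,
       params = p)
}

#' Generate the synthetic basic peptide
#'
#' A compact helical core followed by `basic_tail` C-terminal lysines,
#' principal axis on z with the tail pointing down (-z). Multi-model output
#' perturbs only the tail coordinates (seeded), emulating an NMR bundle
#' with a mobile basic tail.
#'
#' @param length total residue count (>= 5).
#' @param basic_tail number of C-terminal lysines (< length).
#' @param n_models number of conformers (default 1).
#' @param tail_jitter per-coordinate jitter sd for models > 1, Angstrom.
#' @param seed integer seed.
#' @return a [structure_bundle()] (chain P).
#' @export
make_toy_peptide <- function(length = 9, basic_tail = 3, n_models = 1,
                             tail_jitter = 0.8, seed = 1L) {
  if (length < 5) stop("toy peptide needs length >= 5", call. = FALSE)
  if (basic_tail >= length)
    stop("basic_tail must be smaller than length", call. = FALSE)
  core <- length - basic_tail
  seq1 <- c(rep(c("A", "N", "I", "S", "A"), length.out = core),
            rep("K", basic_tail))
  bb <- build_backbone(rep(-57, length), rep(-47, length))
  rows <- list()
  for (i in seq_len(length)) {
    rt <- AA_1TO3[[seq1[i]]]
    bbn <- c("N", "CA", "C", "O")
    bbc <- t(vapply(bbn, function(nm) bb[[i]][[nm]], double(3)))
    block <- res_block(rt, i, "P", bbn, bbc)
    if (rt != "GLY") {
      sc <- build_sidechain(rt, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C,
                            chi = c(-60, 180, 180, 180))
      block <- rbind(block, res_block(rt, i, "P", sc$name,
                                      as.matrix(sc[, c("x", "y", "z")])))
    }
    rows[[i]] <- block
  }
  atoms <- do.call(rbind, rows)
  xyz <- atom_coords(atoms)
  ctr <- colMeans(xyz); xyz <- sweep(xyz, 2, ctr)
  ca_idx <- which(atoms$name == "CA")
  cv <- crossprod(xyz[ca_idx, , drop = FALSE] -
                    rep(1, length(ca_idx)) %o% colMeans(xyz[ca_idx, , drop = FALSE]))
  ev <- eigen(cv, symmetric = TRUE)
  R1 <- t(ev$vectors[, c(2, 3, 1)])
  if (det(R1) < 0) R1[1, ] <- -R1[1, ]
  xyz <- xyz %*% t(R1)
  # tail down: last CA below first CA
  if (xyz[ca_idx[length(ca_idx)], 3] > xyz[ca_idx[1], 3]) {
    Rx <- diag(c(1, -1, -1))
    xyz <- xyz %*% t(Rx)
  }
  atoms <- set_atom_coords(atoms, sweep(xyz, 2, colMeans(xyz)))
  atoms$serial <- seq_len(nrow(atoms))
  models <- list(atoms)
  if (n_models > 1) {
    set.seed(seed)
    tail_rows <- atoms$resseq > core
    for (m in 2:n_models) {
      a <- atoms
      nj <- sum(tail_rows)
      a$x[tail_rows] <- a$x[tail_rows] + stats::rnorm(nj, 0, tail_jitter)
      a$y[tail_rows] <- a$y[tail_rows] + stats::rnorm(nj, 0, tail_jitter)
      a$z[tail_rows] <- a$z[tail_rows] + stats::rnorm(nj, 0, tail_jitter)
      models[[m]] <- a
    }
  }
  structure_bundle(models, id = "toy_peptide")
}
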