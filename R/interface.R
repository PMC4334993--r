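# Interface analysis of a docked complex: Shrake-Rupley solvent-accessible
# surface area, footprint classification by buried area, geometric
# hydrogen-bond and salt-bridge detection, and the contact-ring geometry
# of a z-aligned tetramer vestibule.

# deterministic near-uniform unit sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param structure atom table or `structure_bundle` (first model).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @return numeric vector of per-atom areas (Angstrom^2) with attribute
#'   `residue` (data.frame of per-residue sums).
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960) {
  atoms <- if (inherits(structure, "structure_bundle"))
    model_atoms(structure, 1L) else structure
  n <- nrow(atoms)
  if (n == 0L) stop("empty structure", call. = FALSE)
  xyz <- atom_coords(atoms)
  rad <- vdw_radius(atoms$element) + probe
  unknown <- !(atoms$element %in% names(VDW_RADII))
  if (any(unknown))
    warning("default vdW radius used for element(s): ",
            paste(unique(atoms$element[unknown]), collapse = ", "))
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  # neighbor prefilter via cell binning would be overkill at desk scale;
  # a distance cut per atom is fast enough
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + maxr)^2 & d2 > 0)
    nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- rowSums(sweep(p[free, , drop = FALSE], 2, xyz[j, ])^2)
        keep <- dj2 >= rad[j]^2
        free[free] <- keep
      }
      frac <- mean(free)
    } else frac <- 1
    areas[i] <- frac * 4 * pi * rad[i]^2
  }
  key <- residue_key(atoms)
  per_res <- stats::aggregate(areas, by = list(key = key), FUN = sum)
  rt <- residue_table(atoms)
  per_res <- per_res[match(rt$key, per_res$key), ]
  attr(areas, "residue") <- data.frame(rt, area = per_res$x,
                                       row.names = NULL)
  areas
}

residue_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  attr(sasa(atoms, probe, n_points), "residue")
}

#' Classify the receptor footprint of a docked ligand
#'
#' Per-residue categories, most specific wins:
#' `bonded-link` (interfacing and in at least one H-bond/salt bridge),
#' `interfacing` (buried area > `interface_threshold`), `inaccessible`
#' (free-receptor SASA < `inaccessible_threshold`), else
#' `solvent-accessible`.
#'
#' @param receptor receptor structure (bundle or atom table).
#' @param ligand_pose atom table of the ligand already placed in the
#'   receptor frame (e.g. from [apply_pose()]).
#' @param probe,n_points SASA parameters.
#' @param interface_threshold buried-area cutoff, Angstrom^2 (default 1).
#' @param inaccessible_threshold free-SASA cutoff, Angstrom^2 (default 5).
#' @return data.frame (chain, resseq, icode, resname, category,
#'   buried_area, free_area) with the ligand contact records in
#'   `attr(, "contacts")`.
#' @export
classify_footprint <- function(receptor, ligand_pose, probe = 1.4,
                               n_points = 960, interface_threshold = 1.0,
                               inaccessible_threshold = 5.0) {
  rec <- if (inherits(receptor, "structure_bundle"))
    model_atoms(receptor, 1L) else receptor
  free <- residue_sasa(rec, probe, n_points)
  complex_atoms <- rbind(rec, ligand_pose)
  cx <- residue_sasa(complex_atoms, probe, n_points)
  cx <- cx[match(free$key, cx$key), ]
  buried <- pmax(free$area - cx$area, 0)
  hb <- detect_hbonds(rec, ligand_pose)
  sb <- detect_salt_bridges(rec, ligand_pose)
  contacts <- rbind(hb, sb)
  linked_keys <- unique(paste(contacts$chain_a, contacts$resseq_a,
                              contacts$icode_a))
  category <- ifelse(buried > interface_threshold, "interfacing",
                     ifelse(free$area < inaccessible_threshold,
                            "inaccessible", "solvent-accessible"))
  category[free$key %in% linked_keys & category == "interfacing"] <-
    "bonded-link"
  out <- data.frame(chain = free$chain, resseq = free$resseq,
                    icode = free$icode, resname = free$resname,
                    category = category, buried_area = buried,
                    free_area = free$area, stringsAsFactors = FALSE)
  attr(out, "contacts") <- contacts
  out
}

# donor heavy atoms and their bonded antecedent (for the angle proxy);
# backbone N handled separately
DONORS <- list(
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  CYS = c(SG = "CB"), LYS = c(NZ = "CE"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2"), ASN = c(ND2 = "CG"),
  GLN = c(NE2 = "CD"), TRP = c(NE1 = "CD1")
)
ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

donor_atoms <- function(atoms) {
  rows <- list()
  key <- residue_key(atoms)
  for (i in seq_len(nrow(atoms))) {
    rn <- atoms$resname[i]; nm <- atoms$name[i]
    ante <- NULL
    if (nm == "N" && rn != "PRO") ante <- "CA"
    else if (!is.null(DONORS[[rn]]) && nm %in% names(DONORS[[rn]]))
      ante <- DONORS[[rn]][[nm]]
    if (is.null(ante)) next
    j <- which(key == key[i] & atoms$name == ante)
    if (length(j) != 1L) next
    rows[[length(rows) + 1L]] <- c(i, j)
  }
  if (!length(rows)) return(matrix(integer(), ncol = 2))
  do.call(rbind, rows)
}

acceptor_atoms <- function(atoms) {
  hit <- atoms$name %in% c("O", "OXT")
  for (rn in names(ACCEPTORS))
    hit <- hit | (atoms$resname == rn & atoms$name %in% ACCEPTORS[[rn]])
  which(hit)
}

contact_record_frame <- function() {
  data.frame(kind = character(),
             chain_a = character(), resseq_a = integer(), icode_a = character(),
             resname_a = character(), atom_a = character(),
             chain_b = character(), resseq_b = integer(), icode_b = character(),
             resname_b = character(), atom_b = character(),
             distance = double(), angle = double(), stringsAsFactors = FALSE)
}

mk_records <- function(kind, a, ai, b, bi, dist, ang = NA_real_) {
  data.frame(kind = kind,
             chain_a = a$chain[ai], resseq_a = a$resseq[ai],
             icode_a = a$icode[ai], resname_a = a$resname[ai],
             atom_a = a$name[ai],
             chain_b = b$chain[bi], resseq_b = b$resseq[bi],
             icode_b = b$icode[bi], resname_b = b$resname[bi],
             atom_b = b$name[bi],
             distance = dist, angle = ang, stringsAsFactors = FALSE)
}

#' Detect inter-molecular hydrogen bonds
#'
#' Geometric criteria on heavy atoms: donor-acceptor distance <= `d_max`
#' and antecedent-donor-acceptor angle >= `angle_min` (a proxy for an
#' idealized donor hydrogen pointing at the acceptor; input hydrogens are
#' dropped on read, so criteria never depend on them). Backbone carbonyl
#' oxygens always count as acceptors, so selectivity-filter carbonyl
#' contacts are detectable.
#'
#' @param mol_a,mol_b atom tables (receptor and placed ligand, either
#'   order; detection is symmetric).
#' @param d_max donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_min minimum antecedent-donor-acceptor angle, degrees
#'   (default 120).
#' @return data.frame of contact records (kind `"hbond"`, side `a` = donor),
#'   sorted by distance.
#' @export
detect_hbonds <- function(mol_a, mol_b, d_max = 3.5, angle_min = 120) {
  if (inherits(mol_a, "structure_bundle")) mol_a <- model_atoms(mol_a, 1L)
  if (inherits(mol_b, "structure_bundle")) mol_b <- model_atoms(mol_b, 1L)
  one_way <- function(da, db) {
    don <- donor_atoms(da)
    acc <- acceptor_atoms(db)
    if (nrow(don) == 0L || length(acc) == 0L) return(contact_record_frame())
    dx <- atom_coords(da)[don[, 1], , drop = FALSE]
    ax <- atom_coords(db)[acc, , drop = FALSE]
    d2 <- pair_dist2(dx, ax)
    hit <- which(d2 <= d_max^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(contact_record_frame())
    out <- list()
    for (r in seq_len(nrow(hit))) {
      di <- hit[r, 1]; aj <- hit[r, 2]
      dpos <- dx[di, ]
      apos <- ax[aj, ]
      ante <- atom_coords(da)[don[di, 2], ]
      v1 <- ante - dpos; v2 <- apos - dpos
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) *
        180 / pi
      if (ang < angle_min) next
      out[[length(out) + 1L]] <- mk_records(
        "hbond", da, don[di, 1], db, acc[aj], sqrt(d2[di, aj]), ang)
    }
    if (!length(out)) return(contact_record_frame())
    do.call(rbind, out)
  }
  res <- rbind(one_way(mol_a, mol_b), one_way(mol_b, mol_a))
  res[order(res$distance), , drop = FALSE]
}

#' Detect inter-molecular salt bridges
#'
#' Opposite-sign charged-group heavy atoms (per [assign_charges()]) within
#' `d_max`; inter-molecular only, symmetric in molecule order.
#'
#' @param mol_a,mol_b atom tables.
#' @param d_max cutoff, Angstrom (default 4.0).
#' @return data.frame of contact records (kind `"saltbridge"`, side `a`
#'   from `mol_a`), sorted by distance.
#' @export
detect_salt_bridges <- function(mol_a, mol_b, d_max = 4.0) {
  if (inherits(mol_a, "structure_bundle")) mol_a <- model_atoms(mol_a, 1L)
  if (inherits(mol_b, "structure_bundle")) mol_b <- model_atoms(mol_b, 1L)
  qa <- assign_charges(mol_a)$charges
  qb <- assign_charges(mol_b)$charges
  ia <- which(qa != 0); ib <- which(qb != 0)
  if (!length(ia) || !length(ib)) return(contact_record_frame())
  d2 <- pair_dist2(atom_coords(mol_a)[ia, , drop = FALSE],
                   atom_coords(mol_b)[ib, , drop = FALSE])
  opp <- outer(qa[ia], qb[ib]) < 0
  hit <- which(d2 <= d_max^2 & opp, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(contact_record_frame())
  res <- mk_records("saltbridge", mol_a, ia[hit[, 1]], mol_b, ib[hit[, 2]],
                    sqrt(d2[hit]))
  res[order(res$distance), , drop = FALSE]
}

#' Contact-ring geometry of a z-aligned tetramer vestibule
#'
#' For each named ring the designated atom is collected from every chain;
#' the ring diameter is the mean distance between opposing chain pairs
#' (A-C, B-D for a C4 tetramer) and the axial depth is the mean z. With a
#' ligand pose, per-ring contact counts (ligand atoms within
#' `contact_cutoff` of a ring atom) are added.
#'
#' @param receptor_tetramer tetramer `structure_bundle`, pore axis on z.
#' @param ring_definitions list of `list(name =, resseq =, atom =)` (the
#'   `rings` element of [make_toy_channel()] has this shape).
#' @param ligand_pose optional placed ligand atom table.
#' @param contact_cutoff Angstrom (default 4.5).
#' @return data.frame (name, n_chains, diameter, depth, contacts).
#' @export
contact_rings <- function(receptor_tetramer, ring_definitions,
                          ligand_pose = NULL, contact_cutoff = 4.5) {
  atoms <- model_atoms(receptor_tetramer, 1L)
  chains <- sort(unique(atoms$chain))
  out <- list()
  for (rd in ring_definitions) {
    sel <- atoms[atoms$resseq == rd$resseq & atoms$name == rd$atom, ,
                 drop = FALSE]
    sel <- sel[match(chains, sel$chain), , drop = FALSE]
    if (anyNA(sel$serial))
      stop(sprintf("ring '%s': residue %d atom %s missing in chain %s",
                   rd$name, rd$resseq, rd$atom,
                   paste(chains[is.na(sel$serial)], collapse = ",")),
           call. = FALSE)
    if (nrow(sel) < 2L)
      stop("ring '", rd$name, "' needs atoms from >= 2 chains", call. = FALSE)
    xyz <- atom_coords(sel)
    nc <- nrow(xyz)
    half <- nc %/% 2
    dia <- mean(vapply(seq_len(half), function(i)
      vnorm(xyz[i, ] - xyz[i + half, ]), 0))
    contacts <- NA_integer_
    if (!is.null(ligand_pose)) {
      d2 <- pair_dist2(xyz, atom_coords(ligand_pose))
      contacts <- sum(d2 <= contact_cutoff^2)
    }
    out[[length(out) + 1L]] <- data.frame(
      name = rd$name, n_chains = nc, diameter = dia,
      depth = mean(xyz[, 3]), contacts = contacts,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
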