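# Grid-based rigid-body docking. A receptor is rasterized once into
# surface/core/charge grids; for every rotation in a deterministic SO(3)
# set the ligand is rasterized and a translational scan is run as an FFT
# circular cross-correlation. The per-displacement grid score is
#
#   w_shape * (surface.surface - core_penalty * core.core) + w_elec * elec
#
# with elec = -(charge.charge correlation), so complementary charge pairs
# score positively. Top candidates per rotation are pooled and rescored
# with a coarse pairwise contact potential; the global top-N poses are
# kept with full score decomposition. The default path has no randomness.
#
# Scores are dimensionless and only comparable within a run; the toolkit
# follows the field's practice of comparing ranked score profiles, never
# absolute values.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               K = 2.75, F = 1.47, CL = 1.75, NA. = 2.27, MG = 1.73,
               CA = 2.31, ZN = 1.39)
DEFAULT_RADIUS <- 1.8

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- DEFAULT_RADIUS
  unname(r)
}

#' Docking configuration
#'
#' @param spacing grid spacing, Angstrom (0.5-3.0; default 1.2).
#' @param surface_thickness surface-shell thickness outside the core,
#'   Angstrom (default 1.5).
#' @param rotation_step angular step of the rotation set, degrees
#'   (default 30; decrease for denser SO(3) sampling).
#' @param top_n poses retained (default 2000).
#' @param weights named vector: shape, elec, contact score weights.
#' @param core_penalty core-core overlap penalty factor (default 9).
#' @param contact_cutoff contact-potential distance cutoff, Angstrom.
#' @param candidates_per_rotation translational candidates retained per
#'   rotation before contact rescoring (beam width; default 10).
#' @param max_dim hard cap on grid dimensions.
#' @return list of class `dock_config`.
#' @export
dock_config <- function(spacing = 1.2, surface_thickness = 1.5,
                        rotation_step = 30, top_n = 2000,
                        weights = c(shape = 1, elec = 0.5, contact = 1),
                        core_penalty = 9, contact_cutoff = 4.5,
                        candidates_per_rotation = 10, max_dim = 128) {
  if (spacing < 0.5 || spacing > 3.0)
    stop("spacing must be in [0.5, 3.0] Angstrom", call. = FALSE)
  if (rotation_step <= 0 || rotation_step > 90)
    stop("rotation_step must be in (0, 90] degrees", call. = FALSE)
  if (top_n < 1) stop("top_n must be positive", call. = FALSE)
  stopifnot(all(c("shape", "elec", "contact") %in% names(weights)))
  structure(list(spacing = spacing, surface_thickness = surface_thickness,
                 rotation_step = rotation_step, top_n = as.integer(top_n),
                 weights = weights, core_penalty = core_penalty,
                 contact_cutoff = contact_cutoff,
                 candidates_per_rotation = as.integer(candidates_per_rotation),
                 max_dim = as.integer(max_dim)),
            class = "dock_config")
}

#' Assign formal charges at pH 7
#'
#' Formal scheme: Arg/Lys +1 (split over guanidinium NH1/NH2, or on NZ),
#' Asp/Glu -1 (split over the carboxylate oxygens), His neutral by default,
#' +1 on each chain's free N-terminal nitrogen, -1 on the C-terminal
#' carboxylate (OXT if present, else the terminal O), Cys 0 (free or
#' disulfide-bonded). Unknown residues get zero charge with a warning.
#'
#' @param structure `structure_bundle` or atom table.
#' @param scheme only `"formal_pH7"`.
#' @param his_charge charge put on histidine (default 0, split ND1/NE2).
#' @param termini logical: charge the chain termini (default TRUE).
#' @return list of class `charge_model`: `charges` (per-atom vector aligned
#'   with the atom table), `total`, `scheme`.
#' @export
assign_charges <- function(structure, scheme = "formal_pH7", his_charge = 0,
                           termini = TRUE) {
  if (!identical(scheme, "formal_pH7"))
    stop("unknown charge scheme: ", scheme, call. = FALSE)
  atoms <- if (inherits(structure, "structure_bundle"))
    model_atoms(structure, 1L) else structure
  q <- numeric(nrow(atoms))
  put <- function(mask, value) {
    n <- sum(mask)
    if (n > 0) q[mask] <<- q[mask] + value / n
  }
  known <- c(names(AA_3TO1), "HOH", "K", "NA", "CL", "MG", "CA", "ZN")
  unk <- setdiff(unique(atoms$resname), known)
  if (length(unk))
    warning("unknown residue(s) assigned zero charge: ",
            paste(unk, collapse = ", "))
  key <- residue_key(atoms)
  for (rkey in unique(key)) {
    rows <- key == rkey
    rn <- atoms$resname[rows][1]
    nm <- atoms$name
    if (rn == "ARG") put(rows & nm %in% c("NH1", "NH2"), +1)
    else if (rn == "LYS") put(rows & nm == "NZ", +1)
    else if (rn == "ASP") put(rows & nm %in% c("OD1", "OD2"), -1)
    else if (rn == "GLU") put(rows & nm %in% c("OE1", "OE2"), -1)
    else if (rn == "HIS" && his_charge != 0)
      put(rows & nm %in% c("ND1", "NE2"), his_charge)
    else if (rn == "K") put(rows, +1)
    else if (rn == "NA") put(rows, +1)
    else if (rn == "CL") put(rows, -1)
    else if (rn %in% c("MG", "CA", "ZN")) put(rows, +2)
  }
  if (termini) {
    for (ch in unique(atoms$chain)) {
      in_ch <- atoms$chain == ch & atoms$resname %in% names(AA_3TO1)
      if (!any(in_ch)) next
      rt <- residue_table(atoms[in_ch, , drop = FALSE])
      first <- key == rt$key[1] & atoms$name == "N"
      last_key <- rt$key[nrow(rt)]
      oxt <- key == last_key & atoms$name == "OXT"
      last <- if (any(oxt)) oxt else key == last_key & atoms$name == "O"
      put(first, +1)
      put(last, -1)
    }
  }
  structure(list(charges = q, total = sum(q), scheme = scheme),
            class = "charge_model")
}

#' Deterministic near-uniform rotation set
#'
#' Euler z-y-z lattice: polar angle beta stepped uniformly, azimuth count
#' scaled by sin(beta) for near-uniform sphere coverage, spin gamma stepped
#' uniformly. The identity is always element 1 and the ordering is fixed.
#'
#' @param angular_step step in degrees, 0 < step <= 90.
#' @return list of 3x3 rotation matrices with attribute `step`.
#' @export
rotation_set <- function(angular_step) {
  if (!is.finite(angular_step) || angular_step <= 0 || angular_step > 90)
    stop("invalid angular step: must be in (0, 90] degrees", call. = FALSE)
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  ry <- function(b) {
    b <- b * pi / 180
    matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
           byrow = TRUE)
  }
  betas <- seq(0, 180, by = angular_step)
  gammas <- seq(0, 360 - angular_step, by = angular_step)
  out <- list()
  for (b in betas) {
    na <- max(1L, as.integer(round(360 * sin(b * pi / 180) / angular_step)))
    alphas <- seq(0, 360, length.out = na + 1L)[seq_len(na)]
    for (a in alphas) for (g in gammas)
      out[[length(out) + 1L]] <- rz(a) %*% ry(b) %*% rz(g)
  }
  attr(out, "step") <- angular_step
  out
}

good_fft_size <- function(n) {
  # smallest 5-smooth integer >= n (keeps stats::fft fast)
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

#' Rasterize a structure into docking score grids
#'
#' The `core` layer marks voxels whose centers fall within an atom's van
#' der Waals radius; the `surface` layer marks a shell of the stated
#' thickness outside the core; the `charge` layer deposits atomic charges
#' with trilinear splatting (charge is conserved to rounding).
#'
#' @param atoms atom table (or `structure_bundle`, first model).
#' @param charge_model a [assign_charges()] result (or NULL for no charges).
#' @param spacing voxel edge, Angstrom (0.5-3.0).
#' @param surface_thickness shell thickness, Angstrom.
#' @param margin clearance added around the atom extent (Angstrom).
#' @param dims,origin optional explicit grid geometry (used to put a ligand
#'   on a receptor-compatible grid).
#' @param center_at optional point forced to the center voxel.
#' @param max_dim dimension cap.
#' @return list of class `score_grids`.
#' @export
build_grids <- function(atoms, charge_model = NULL, spacing = 1.2,
                        surface_thickness = 1.5, margin = 4,
                        dims = NULL, origin = NULL, center_at = NULL,
                        max_dim = 128) {
  if (inherits(atoms, "structure_bundle")) atoms <- model_atoms(atoms, 1L)
  if (nrow(atoms) == 0L) stop("cannot grid an empty structure", call. = FALSE)
  if (spacing < 0.5 || spacing > 3.0)
    stop("spacing must be in [0.5, 3.0] Angstrom", call. = FALSE)
  xyz <- atom_coords(atoms)
  rad <- vdw_radius(atoms$element)
  reach <- rad + surface_thickness
  if (is.null(dims)) {
    lo <- apply(xyz - reach, 2, min) - margin
    hi <- apply(xyz + reach, 2, max) + margin
    dims <- vapply(ceiling((hi - lo) / spacing) + 1, good_fft_size, 0)
    if (any(dims > max_dim))
      stop(sprintf("structure too large for grid: needs %s voxels (cap %d)",
                   paste(dims, collapse = "x"), max_dim), call. = FALSE)
    if (is.null(center_at)) {
      ctr <- (lo + hi) / 2
    } else ctr <- center_at
    origin <- ctr - (dims - 1) / 2 * spacing
  } else {
    dims <- as.integer(dims)
    if (is.null(origin)) {
      ctr <- if (is.null(center_at)) colMeans(xyz) else center_at
      origin <- ctr - (dims - 1) / 2 * spacing
    }
  }
  core <- array(0, dims); surface <- array(0, dims); charge <- array(0, dims)
  idx_of <- function(p) (p - origin) / spacing + 1  # fractional voxel index
  for (i in seq_len(nrow(atoms))) {
    p <- xyz[i, ]
    rr <- reach[i]
    f <- idx_of(p)
    i0 <- pmax(1, floor(f - rr / spacing)); i1 <- pmin(dims, ceiling(f + rr / spacing))
    if (any(i0 > i1)) next
    gx <- seq.int(i0[1], i1[1]); gy <- seq.int(i0[2], i1[2]); gz <- seq.int(i0[3], i1[3])
    dx2 <- (origin[1] + (gx - 1) * spacing - p[1])^2
    dy2 <- (origin[2] + (gy - 1) * spacing - p[2])^2
    dz2 <- (origin[3] + (gz - 1) * spacing - p[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    core_hit <- d2 <= rad[i]^2
    surf_hit <- d2 <= rr^2 & !core_hit
    core[gx, gy, gz][core_hit] <- 1
    sl <- surface[gx, gy, gz]; sl[surf_hit] <- 1
    surface[gx, gy, gz] <- sl
  }
  surface[core == 1] <- 0
  if (!is.null(charge_model)) {
    q <- charge_model$charges
    for (i in which(q != 0)) {
      f <- idx_of(xyz[i, ])
      b <- floor(f); w <- f - b
      if (any(b < 1) || any(b + 1 > dims)) next
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wgt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
        charge[b[1] + dx, b[2] + dy, b[3] + dz] <-
          charge[b[1] + dx, b[2] + dy, b[3] + dz] + q[i] * wgt
      }
    }
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 surface = surface, core = core, charge = charge),
            class = "score_grids")
}

#' Truncated Coulomb kernel on a periodic grid
#'
#' `332 / max(r, spacing)` for `r <= r_cut`, laid out over signed voxel
#' displacements (wrap convention of the FFT scan). Convolving the
#' receptor charge layer with this kernel yields the receptor
#' electrostatic potential used by [scan_translations()]. The constant 332
#' gives kcal/mol for unit charges at Angstrom distances; no screening
#' (distance-independent dielectric), initial-stage scoring only.
#'
#' @param dims grid dimensions; @param spacing voxel edge, Angstrom.
#' @param r_cut truncation radius, Angstrom (default 10; keep below the
#'   grid margin so periodic images cannot reach valid displacements).
#' @keywords internal
coulomb_kernel <- function(dims, spacing, r_cut = 10) {
  d <- lapply(dims, function(m) {
    v <- seq_len(m) - 1L; v[v > m / 2] <- v[v > m / 2] - m; v * spacing
  })
  r2 <- outer(outer(d[[1]]^2, d[[2]]^2, `+`), d[[3]]^2, `+`)
  r <- sqrt(r2)
  k <- 332 / pmax(r, spacing)
  k[r > r_cut] <- 0
  k
}

fft_layers <- function(grids, r_cut = 10) {
  kf <- stats::fft(coulomb_kernel(grids$dims, grids$spacing, r_cut))
  list(surface = stats::fft(grids$surface),
       core = stats::fft(grids$core),
       potential = stats::fft(grids$charge) * kf)
}

#' FFT translational scan for one ligand orientation
#'
#' Computes circular cross-correlations `C(d) = sum_v R(v) L(v - d)` of the
#' receptor and ligand layers by FFT, giving per-displacement shape and
#' electrostatic score maps (identical to direct summation up to floating
#' point). Displacements are voxel offsets of the ligand grid relative to
#' the receptor grid, wrapped periodically; `attr(,"displacement")` maps
#' array index to signed voxel offset.
#'
#' @param receptor_grids,ligand_grids [build_grids()] results with equal
#'   spacing and dimensions.
#' @param core_penalty core-core overlap penalty factor.
#' @param receptor_fft optional precomputed [stats::fft()] of the receptor
#'   layers (internal reuse across rotations).
#' @return list with 3-D arrays `shape` and `elec`.
#' @export
scan_translations <- function(receptor_grids, ligand_grids, core_penalty = 9,
                              receptor_fft = NULL) {
  if (!isTRUE(all.equal(receptor_grids$spacing, ligand_grids$spacing)))
    stop("grid spacing mismatch", call. = FALSE)
  if (!identical(as.integer(receptor_grids$dims),
                 as.integer(ligand_grids$dims)))
    stop("grid dimension mismatch", call. = FALSE)
  rf <- receptor_fft %||% fft_layers(receptor_grids)
  n <- prod(receptor_grids$dims)
  corr <- function(rl, ll) Re(stats::fft(rl * Conj(stats::fft(ll)),
                                         inverse = TRUE)) / n
  ss <- corr(rf$surface, ligand_grids$surface)
  cc <- corr(rf$core, ligand_grids$core)
  # receptor potential field x ligand charges; negated so complementary
  # (opposite-sign) interactions score positively
  qq <- corr(rf$potential, ligand_grids$charge)
  shape <- ss - core_penalty * cc
  elec <- -qq
  d <- lapply(receptor_grids$dims, function(m) {
    v <- seq_len(m) - 1L; v[v > m / 2] <- v[v > m / 2] - m; v
  })
  structure(list(shape = shape, elec = elec), displacement = d,
            class = "score_map")
}

# Pairwise contact potential over coarse element types (step function
# within the cutoff; favorability, higher is better).
CONTACT_TABLE <- local({
  el <- c("C", "N", "O", "S")
  m <- matrix(c(
    0.40, 0.10, 0.10, 0.40,
    0.10, -0.10, 0.25, 0.10,
    0.10, 0.25, -0.10, 0.10,
    0.40, 0.10, 0.10, 0.40), 4, 4, byrow = TRUE,
    dimnames = list(el, el))
  m
})

contact_type <- function(element) {
  t <- ifelse(element %in% rownames(CONTACT_TABLE), element, "C")
  t
}

#' Pairwise statistical contact energy of a docked pose
#'
#' Sum over inter-molecular heavy-atom pairs within `cutoff` of a bundled
#' element-typed pair-potential table. Symmetric in molecule order; an
#' empty interface scores 0.
#'
#' @param receptor,ligand atom tables (or bundles, first model).
#' @param pose list/row with `rotation` (3x3) and `translation` (length 3,
#'   ligand-centroid displacement); NULL docks the ligand as-is.
#' @param cutoff distance cutoff, Angstrom (default 4.5).
#' @return dimensionless contact score.
#' @export
contact_energy <- function(receptor, ligand, pose = NULL, cutoff = 4.5) {
  if (inherits(receptor, "structure_bundle")) receptor <- model_atoms(receptor, 1L)
  if (inherits(ligand, "structure_bundle")) ligand <- model_atoms(ligand, 1L)
  lx <- atom_coords(ligand)
  if (!is.null(pose)) lx <- pose_transform(lx, pose)
  rx <- atom_coords(receptor)
  # bbox prefilter
  lo <- apply(lx, 2, min) - cutoff; hi <- apply(lx, 2, max) + cutoff
  keep <- rx[, 1] >= lo[1] & rx[, 1] <= hi[1] &
    rx[, 2] >= lo[2] & rx[, 2] <= hi[2] &
    rx[, 3] >= lo[3] & rx[, 3] <= hi[3]
  if (!any(keep)) return(0)
  rx <- rx[keep, , drop = FALSE]
  rt <- contact_type(receptor$element[keep])
  lt <- contact_type(ligand$element)
  d2 <- pair_dist2(lx, rx)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(0)
  sum(CONTACT_TABLE[cbind(lt[hit[, 1]], rt[hit[, 2]])])
}

# apply a pose (rotation about the ligand centroid, then centroid
# displacement) to coordinates
pose_transform <- function(xyz, pose, centroid = NULL) {
  ctr <- centroid %||% colMeans(xyz)
  rot <- pose$rotation
  if (is.null(rot)) rot <- diag(3)
  sweep(sweep(xyz, 2, ctr) %*% t(rot), 2, -(ctr + pose$translation))
}

#' Coordinates of a docked pose applied to a ligand
#' @param ligand atom table or bundle (first model).
#' @param poses a `pose_list`.
#' @param i pose rank to apply.
#' @return atom table with transformed coordinates.
#' @export
apply_pose <- function(ligand, poses, i = 1L) {
  if (inherits(ligand, "structure_bundle")) ligand <- model_atoms(ligand, 1L)
  p <- poses$poses[i, ]
  rot <- poses$rotations[[p$rotation_index]]
  xyz <- pose_transform(atom_coords(ligand),
                        list(rotation = rot,
                             translation = c(p$tx, p$ty, p$tz)),
                        centroid = poses$ligand_centroid)
  set_atom_coords(ligand, xyz)
}

#' Rigid-body dock of one ligand conformer onto a receptor
#'
#' Deterministic: rotations from [rotation_set()], FFT translational scan
#' per rotation, per-rotation beam of translational candidates pooled and
#' rescored with the contact potential, global top-N kept. Ties are broken
#' by (score, rotation index, lexicographic translation).
#'
#' @param receptor `structure_bundle` or atom table.
#' @param ligand_model atom table or single-model bundle.
#' @param config a [dock_config()].
#' @return object of class `pose_list`: `poses` (data.frame: rank, score,
#'   shape, elec, contact, rotation_index, tx, ty, tz), `rotations`,
#'   `ligand_centroid`, `receptor_id`, `ligand_id`, `config`.
#' @export
dock_rigid <- function(receptor, ligand_model, config = dock_config()) {
  rec_id <- if (inherits(receptor, "structure_bundle")) receptor$id else "receptor"
  lig_id <- if (inherits(ligand_model, "structure_bundle")) ligand_model$id else "ligand"
  rec_atoms <- if (inherits(receptor, "structure_bundle"))
    model_atoms(receptor, 1L) else receptor
  lig_atoms <- if (inherits(ligand_model, "structure_bundle"))
    model_atoms(ligand_model, 1L) else ligand_model
  rq <- assign_charges(rec_atoms)
  lq <- assign_charges(lig_atoms)
  lx0 <- atom_coords(lig_atoms)
  lctr <- colMeans(lx0)
  lrad <- sqrt(max(rowSums(sweep(lx0, 2, lctr)^2)))
  margin <- lrad + config$surface_thickness + 2
  rec_grids <- build_grids(rec_atoms, rq, spacing = config$spacing,
                           surface_thickness = config$surface_thickness,
                           margin = margin, max_dim = config$max_dim)
  rf <- fft_layers(rec_grids)
  dims <- rec_grids$dims
  grid_center <- rec_grids$origin + (dims - 1) / 2 * rec_grids$spacing
  rots <- rotation_set(config$rotation_step)
  w <- config$weights
  cand <- list()
  for (ri in seq_along(rots)) {
    lx <- sweep(sweep(lx0, 2, lctr) %*% t(rots[[ri]]), 2, -grid_center)
    la <- set_atom_coords(lig_atoms, lx)
    lg <- build_grids(la, lq, spacing = config$spacing,
                      surface_thickness = config$surface_thickness,
                      dims = dims, origin = rec_grids$origin,
                      max_dim = config$max_dim)
    sm <- scan_translations(rec_grids, lg, core_penalty = config$core_penalty,
                            receptor_fft = rf)
    disp <- attr(sm, "displacement")
    # mask displacements that push the ligand occupancy out of the grid
    occ <- which(lg$core + lg$surface > 0, arr.ind = TRUE)
    lo_occ <- apply(occ, 2, min); hi_occ <- apply(occ, 2, max)
    ok <- lapply(1:3, function(k)
      disp[[k]] >= 1 - lo_occ[k] & disp[[k]] <= dims[k] - hi_occ[k])
    valid <- outer(outer(ok[[1]], ok[[2]], `&`), ok[[3]], `&`)
    score <- w[["shape"]] * sm$shape + w[["elec"]] * sm$elec
    score[!valid] <- -Inf
    nb <- min(config$candidates_per_rotation, sum(valid))
    if (nb == 0) next
    top <- order(score, decreasing = TRUE)[seq_len(nb)]
    ai <- arrayInd(top, dims)
    cand[[length(cand) + 1L]] <- data.frame(
      rotation_index = ri,
      shape = sm$shape[top], elec = sm$elec[top],
      dx = disp[[1]][ai[, 1]], dy = disp[[2]][ai[, 2]], dz = disp[[3]][ai[, 3]])
  }
  if (!length(cand)) stop("no valid pose: ligand larger than receptor grid margin",
                          call. = FALSE)
  cand <- do.call(rbind, cand)
  sp <- rec_grids$spacing
  cand$tx <- grid_center[1] + cand$dx * sp - lctr[1]
  cand$ty <- grid_center[2] + cand$dy * sp - lctr[2]
  cand$tz <- grid_center[3] + cand$dz * sp - lctr[3]
  cand$contact <- vapply(seq_len(nrow(cand)), function(i) {
    contact_energy(rec_atoms, lig_atoms,
                   list(rotation = rots[[cand$rotation_index[i]]],
                        translation = c(cand$tx[i], cand$ty[i], cand$tz[i])),
                   cutoff = config$contact_cutoff)
  }, 0)
  cand$score <- w[["shape"]] * cand$shape + w[["elec"]] * cand$elec +
    w[["contact"]] * cand$contact
  ord <- order(-cand$score, cand$rotation_index, cand$tx, cand$ty, cand$tz)
  cand <- cand[ord, , drop = FALSE]
  keep <- seq_len(min(config$top_n, nrow(cand)))
  poses <- cand[keep, c("score", "shape", "elec", "contact",
                        "rotation_index", "tx", "ty", "tz")]
  poses <- cbind(rank = keep, poses)
  rownames(poses) <- NULL
  structure(list(poses = poses, rotations = rots, ligand_centroid = lctr,
                 receptor_id = rec_id, ligand_id = lig_id, config = config),
            class = "pose_list")
}

#' @export
print.pose_list <- function(x, ...) {
  cat(sprintf("<pose_list: %d poses, %s vs %s, best score %.3f>\n",
              nrow(x$poses), x$receptor_id, x$ligand_id, x$poses$score[1]))
  invisible(x)
}

#' Write a pose list as TSV (with a JSON config snapshot alongside)
#' @param poses `pose_list`.
#' @param path output TSV path.
#' @export
write_poses <- function(poses, path) {
  utils::write.table(poses$poses, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cfgpath <- paste0(sub("\\.tsv$", "", path), "_config.json")
  jsonlite::write_json(poses$config[names(poses$config) != "class"],
                       cfgpath, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
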