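# Tetramer assembly. Operators are derived from a template tetramer by
# rigid superposition of chain A onto each chain; assembly applies them to
# 1 (homo) or 4 (hetero) subunits. The pore axis is the normal of the
# plane spanned by the four chain centroids (the principal direction of
# least centroid variance), z-aligned on output for ring-diameter math.

#' Derive C4 assembly operators from a template tetramer
#'
#' @param template_tetramer a [structure_bundle()] whose first model has 4
#'   chains with matching residue topology.
#' @return list of 4 operators (class `symmetry_operator`), in cyclic order
#'   about the pore axis starting from chain A->A (identity). Each has
#'   `rotation`, `translation`, `source_chain`, `target_chain`, `rmsd`.
#'   The pore axis and its center are in attributes `pore_axis` and
#'   `pore_center`.
#' @export
derive_operators <- function(template_tetramer) {
  atoms <- model_atoms(template_tetramer, 1L)
  chains <- unique(atoms$chain)
  if (length(chains) != 4L)
    stop("assembly error: template must have exactly 4 chains, found ",
         length(chains), call. = FALSE)
  per <- lapply(chains, function(ch) atoms[atoms$chain == ch, , drop = FALSE])
  names(per) <- chains
  sig <- vapply(per, function(a) paste(a$resname, a$name, collapse = "|"), "")
  if (length(unique(sig)) != 1L)
    stop("assembly error: chain topologies do not match", call. = FALSE)

  cents <- t(vapply(per, function(a) colMeans(atom_coords(a)), double(3)))
  center <- colMeans(cents)
  cv <- crossprod(sweep(cents, 2, center))
  ev <- eigen(cv, symmetric = TRUE)
  axis <- ev$vectors[, 3]
  if (axis[3] < 0) axis <- -axis
  # cyclic order: angle of each chain centroid about the axis
  ref <- cents[1, ] - center
  ref <- ref - sum(ref * axis) * axis
  if (vnorm(ref) < 1e-9) ref <- c(1, 0, 0) - axis[1] * axis
  e1 <- vunit(ref); e2 <- vcross(axis, e1)
  ang <- apply(cents, 1, function(p) {
    v <- p - center; atan2(sum(v * e2), sum(v * e1))
  })
  ord <- order((ang - ang[1]) %% (2 * pi))
  a_coords <- atom_coords(per[[1]])
  ops <- lapply(ord, function(k) {
    fit <- suppressWarnings(superpose(a_coords, atom_coords(per[[k]])))
    structure(list(rotation = fit$rotation, translation = fit$translation,
                   source_chain = chains[1], target_chain = chains[k],
                   rmsd = fit$rmsd), class = "symmetry_operator")
  })
  attr(ops, "pore_axis") <- axis
  attr(ops, "pore_center") <- center
  ops
}

#' Exact C4 operators about the z axis
#'
#' Convenience constructor for ideal fourfold symmetry (used by the
#' synthetic-structure generator and tests).
#' @param center axis location (x, y), default origin.
#' @return list of 4 `symmetry_operator`s (rotations of 0/90/180/270 deg).
#' @export
c4_operators <- function(center = c(0, 0)) {
  lapply(0:3, function(k) {
    th <- k * pi / 2
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    t <- c(center[1], center[2], 0) - as.vector(R %*% c(center[1], center[2], 0))
    structure(list(rotation = R, translation = t, source_chain = "A",
                   target_chain = LETTERS[k + 1], rmsd = 0),
              class = "symmetry_operator")
  })
}

#' Assemble a tetramer from subunits and symmetry operators
#'
#' @param subunits one `structure_bundle` (homotetramer) or a list of 4
#'   (heterotetramer, applied in cyclic order).
#' @param operators list of 4 operators from [derive_operators()] or
#'   [c4_operators()].
#' @param clash_cutoff inter-chain backbone clash distance (default 2.0 A);
#'   violations are reported, not fatal.
#' @return tetramer `structure_bundle` with chains A-D; data.frame of
#'   inter-chain backbone clashes in `attr(, "clash_report")`.
#' @export
assemble_oligomer <- function(subunits, operators, clash_cutoff = 2.0) {
  if (inherits(subunits, "structure_bundle")) subunits <- list(subunits)
  if (!length(subunits) %in% c(1L, 4L))
    stop("unsupported subunit count: ", length(subunits),
         " (need 1 for homo- or 4 for hetero-tetramer)", call. = FALSE)
  if (length(operators) != 4L)
    stop("need exactly 4 operators", call. = FALSE)
  if (length(subunits) == 1L) subunits <- rep(subunits, 4L)
  chains <- list()
  for (k in 1:4) {
    a <- model_atoms(subunits[[k]], 1L)
    op <- operators[[k]]
    xyz <- transform_coords(atom_coords(a), op$rotation, op$translation)
    a <- set_atom_coords(a, xyz)
    a$chain <- LETTERS[k]
    chains[[k]] <- a
  }
  atoms <- do.call(rbind, chains)
  atoms$serial <- seq_len(nrow(atoms))
  out <- structure_bundle(list(atoms), id = "tetramer")
  # inter-chain backbone clash check
  bb <- atoms[atoms$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  cl <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    ai <- bb[bb$chain == LETTERS[i], , drop = FALSE]
    aj <- bb[bb$chain == LETTERS[j], , drop = FALSE]
    d2 <- pair_dist2(atom_coords(ai), atom_coords(aj))
    hit <- which(d2 < clash_cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) cl[[length(cl) + 1L]] <- data.frame(
      chain_a = LETTERS[i], res_a = ai$resseq[hit[, 1]],
      atom_a = ai$name[hit[, 1]],
      chain_b = LETTERS[j], res_b = aj$resseq[hit[, 2]],
      atom_b = aj$name[hit[, 2]],
      dist = sqrt(d2[hit]), stringsAsFactors = FALSE)
  }
  attr(out, "clash_report") <-
    if (length(cl)) do.call(rbind, cl) else
      data.frame(chain_a = character(), res_a = integer(), atom_a = character(),
                 chain_b = character(), res_b = integer(), atom_b = character(),
                 dist = double())
  out
}

#' Serialize symmetry operators to JSON
#' @param operators list of `symmetry_operator`s.
#' @param path output path.
#' @export
write_operators <- function(operators, path) {
  payload <- lapply(operators, function(op) list(
    rotation = as.vector(t(op$rotation)), translation = op$translation,
    source_chain = op$source_chain, target_chain = op$target_chain,
    rmsd = op$rmsd))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
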