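# Internal-coordinate geometry: torsions, NeRF atom placement, ideal
# backbone generation and a coarse side-chain rotamer builder.
#
# Bond lengths/angles are standard small-molecule values; side-chain
# geometry is idealized (no library refinement) which is all the fixed-
# backbone threading below requires.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
vnorm <- function(a) sqrt(sum(a^2))
vunit <- function(a) a / vnorm(a)

#' Torsion angle defined by four points
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place atom D given positions A, B, C and internal coordinates:
# |C-D| = bond, angle(B,C,D) = ang (deg), torsion(A,B,C,D) = tors (deg).
nerf_place <- function(A, B, C, bond, ang, tors) {
  ang <- ang * pi / 180; tors <- tors * pi / 180
  b1 <- B - A; b2 <- C - B
  b2u <- vunit(b2)
  n <- vunit(vcross(b1, b2))
  m <- vcross(n, b2u)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tors),
         -bond * sin(ang) * sin(tors))
  C + d[1] * b2u + d[2] * m + d[3] * n
}

BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

#' Generate an ideal polypeptide backbone from phi/psi angles
#'
#' @param phi,psi numeric vectors (degrees), one value per residue;
#'   `phi[1]` and `psi[n]` are unused (undefined at termini).
#' @param omega peptide-bond torsion, default 180 (trans).
#' @return list of per-residue lists with named positions N, CA, C, O.
#' @keywords internal
build_backbone <- function(phi, psi, omega = 180) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- BB_GEOM
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  a <- g$ang_n_ca_c * pi / 180
  C <- CA + c(-g$ca_c * cos(a), g$ca_c * sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Np <- res[[i - 1]]$N; CAp <- res[[i - 1]]$CA; Cp <- res[[i - 1]]$C
      N <- nerf_place(Np, CAp, Cp, g$c_n, g$ang_ca_c_n, psi[i - 1])
      CA <- nerf_place(CAp, Cp, N, g$n_ca, g$ang_c_n_ca, omega)
      C <- nerf_place(Cp, N, CA, g$ca_c, g$ang_n_ca_c, phi[i])
    }
    res[[i]] <- list(N = N, CA = CA, C = C)
  }
  for (i in seq_len(n)) {
    ps <- if (i < n) psi[i] else 180
    nxt <- if (i < n) res[[i + 1]]$N else NULL
    # O is anti to the next N across the carbonyl
    res[[i]]$O <- nerf_place(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                             g$c_o, g$ang_ca_c_o, ps + 180)
  }
  res
}

# Side-chain topology. Each atom: refs (r1, r2, r3 = bonded parent), bond,
# angle, and torsion given as either a number or c(chi = k, offset).
sc_atom <- function(name, r1, r2, r3, bond, angle, chi = NA, offset = 0,
                    tors = NA) {
  list(name = name, r1 = r1, r2 = r2, r3 = r3, bond = bond, angle = angle,
       chi = chi, offset = offset, tors = tors)
}

SC_TOPO <- list(
  GLY = list(),
  ALA = list(),
  SER = list(sc_atom("OG", "N", "CA", "CB", 1.417, 110.8, chi = 1)),
  CYS = list(sc_atom("SG", "N", "CA", "CB", 1.808, 113.8, chi = 1)),
  THR = list(sc_atom("OG1", "N", "CA", "CB", 1.433, 109.6, chi = 1),
             sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1, offset = -120)),
  VAL = list(sc_atom("CG1", "N", "CA", "CB", 1.527, 110.5, chi = 1),
             sc_atom("CG2", "N", "CA", "CB", 1.527, 110.5, chi = 1, offset = 122)),
  LEU = list(sc_atom("CG", "N", "CA", "CB", 1.530, 116.3, chi = 1),
             sc_atom("CD1", "CA", "CB", "CG", 1.524, 110.7, chi = 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.525, 110.4, chi = 2, offset = 122)),
  ILE = list(sc_atom("CG1", "N", "CA", "CB", 1.530, 110.4, chi = 1),
             sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1, offset = -122),
             sc_atom("CD1", "CA", "CB", "CG1", 1.513, 113.8, chi = 2)),
  MET = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.0, chi = 1),
             sc_atom("SD", "CA", "CB", "CG", 1.803, 112.7, chi = 2),
             sc_atom("CE", "CB", "CG", "SD", 1.791, 100.9, chi = 3)),
  PRO = list(sc_atom("CG", "N", "CA", "CB", 1.495, 104.5, tors = -26),
             sc_atom("CD", "CA", "CB", "CG", 1.507, 106.1, tors = 36)),
  PHE = list(sc_atom("CG", "N", "CA", "CB", 1.502, 113.8, chi = 1),
             sc_atom("CD1", "CA", "CB", "CG", 1.384, 120.8, chi = 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.384, 120.8, chi = 2, offset = 180),
             sc_atom("CE1", "CB", "CG", "CD1", 1.384, 121.0, tors = 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.384, 121.0, tors = 180),
             sc_atom("CZ", "CG", "CD1", "CE1", 1.382, 120.0, tors = 0)),
  TYR = list(sc_atom("CG", "N", "CA", "CB", 1.502, 113.8, chi = 1),
             sc_atom("CD1", "CA", "CB", "CG", 1.384, 120.8, chi = 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.384, 120.8, chi = 2, offset = 180),
             sc_atom("CE1", "CB", "CG", "CD1", 1.384, 121.0, tors = 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.384, 121.0, tors = 180),
             sc_atom("CZ", "CG", "CD1", "CE1", 1.382, 120.0, tors = 0),
             sc_atom("OH", "CD1", "CE1", "CZ", 1.376, 119.9, tors = 180)),
  TRP = list(sc_atom("CG", "N", "CA", "CB", 1.498, 113.6, chi = 1),
             sc_atom("CD1", "CA", "CB", "CG", 1.365, 126.9, chi = 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.433, 126.6, chi = 2, offset = 180),
             sc_atom("NE1", "CB", "CG", "CD1", 1.374, 110.2, tors = 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.409, 107.2, tors = 180),
             sc_atom("CE3", "CB", "CG", "CD2", 1.398, 133.9, tors = 0),
             sc_atom("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, tors = 180),
             sc_atom("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, tors = 180),
             sc_atom("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, tors = 0)),
  ASP = list(sc_atom("CG", "N", "CA", "CB", 1.516, 113.0, chi = 1),
             sc_atom("OD1", "CA", "CB", "CG", 1.249, 118.5, chi = 2),
             sc_atom("OD2", "CA", "CB", "CG", 1.249, 118.5, chi = 2, offset = 180)),
  ASN = list(sc_atom("CG", "N", "CA", "CB", 1.516, 112.7, chi = 1),
             sc_atom("OD1", "CA", "CB", "CG", 1.231, 120.8, chi = 2),
             sc_atom("ND2", "CA", "CB", "CG", 1.328, 116.5, chi = 2, offset = 180)),
  GLU = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.0, chi = 1),
             sc_atom("CD", "CA", "CB", "CG", 1.516, 112.6, chi = 2),
             sc_atom("OE1", "CB", "CG", "CD", 1.249, 118.5, chi = 3),
             sc_atom("OE2", "CB", "CG", "CD", 1.249, 118.5, chi = 3, offset = 180)),
  GLN = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.0, chi = 1),
             sc_atom("CD", "CA", "CB", "CG", 1.516, 112.6, chi = 2),
             sc_atom("OE1", "CB", "CG", "CD", 1.231, 120.8, chi = 3),
             sc_atom("NE2", "CB", "CG", "CD", 1.328, 116.5, chi = 3, offset = 180)),
  LYS = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.0, chi = 1),
             sc_atom("CD", "CA", "CB", "CG", 1.520, 111.3, chi = 2),
             sc_atom("CE", "CB", "CG", "CD", 1.520, 111.3, chi = 3),
             sc_atom("NZ", "CG", "CD", "CE", 1.489, 111.9, chi = 4)),
  ARG = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.0, chi = 1),
             sc_atom("CD", "CA", "CB", "CG", 1.520, 111.3, chi = 2),
             sc_atom("NE", "CB", "CG", "CD", 1.461, 112.0, chi = 3),
             sc_atom("CZ", "CG", "CD", "NE", 1.329, 124.2, chi = 4),
             sc_atom("NH1", "CD", "NE", "CZ", 1.326, 120.3, tors = 0),
             sc_atom("NH2", "CD", "NE", "CZ", 1.326, 120.3, tors = 180)),
  HIS = list(sc_atom("CG", "N", "CA", "CB", 1.497, 113.8, chi = 1),
             sc_atom("ND1", "CA", "CB", "CG", 1.371, 122.7, chi = 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.356, 131.0, chi = 2, offset = 180),
             sc_atom("CE1", "CB", "CG", "ND1", 1.319, 109.2, tors = 180),
             sc_atom("NE2", "CB", "CG", "CD2", 1.374, 107.2, tors = 180))
)

N_CHI <- c(GLY = 0, ALA = 0, SER = 1, CYS = 1, THR = 1, VAL = 1, PRO = 0,
           LEU = 2, ILE = 2, PHE = 2, TYR = 2, TRP = 2, ASP = 2, ASN = 2,
           HIS = 2, MET = 3, GLU = 3, GLN = 3, LYS = 4, ARG = 4)

# Ideal CB from backbone N, CA, C (tetrahedral, fixed handedness).
place_cb <- function(N, CA, C, bond = 1.53) {
  v1 <- vunit(N - CA); v2 <- vunit(C - CA)
  bis <- vunit(v1 + v2)
  nrm <- vunit(vcross(v1, v2))
  CA + bond * vunit(-0.612 * bis + 0.791 * nrm)
}

# Deterministic coarse rotamer grid: first two variable chis sampled at
# staggered values, chi3+ held trans.
rotamer_grid <- function(restype) {
  nchi <- N_CHI[[restype]]
  if (is.null(nchi) || nchi == 0) return(list(numeric(0)))
  vals1 <- c(-60, 180, 60)
  if (nchi == 1) return(lapply(vals1, function(a) a))
  g <- expand.grid(chi1 = vals1, chi2 = c(180, -60, 60, 90, -90))
  lapply(seq_len(nrow(g)), function(i) {
    chi <- c(g$chi1[i], g$chi2[i], rep(180, max(0, nchi - 2)))
    chi
  })
}

# Build all side-chain heavy atoms (CB onward) for one residue type on the
# given backbone positions, at the given chi vector.
build_sidechain <- function(restype, N, CA, C, chi = numeric(0)) {
  if (restype == "GLY") return(empty_sc())
  pos <- list(N = N, CA = CA, C = C)
  pos$CB <- place_cb(N, CA, C)
  out <- list(CB = pos$CB)
  topo <- SC_TOPO[[restype]]
  if (is.null(topo)) stop("no side-chain topology for ", restype, call. = FALSE)
  for (a in topo) {
    tors <- if (!is.na(a$chi)) {
      base <- if (a$chi <= length(chi)) chi[a$chi] else 180
      base + a$offset
    } else if (!is.na(a$tors)) a$tors else 180
    p <- nerf_place(pos[[a$r1]], pos[[a$r2]], pos[[a$r3]],
                    a$bond, a$angle, tors)
    pos[[a$name]] <- p
    out[[a$name]] <- p
  }
  nm <- names(out)
  data.frame(name = nm,
             x = vapply(out, `[`, 0, 1),
             y = vapply(out, `[`, 0, 2),
             z = vapply(out, `[`, 0, 3),
             element = substr(nm, 1, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

empty_sc <- function() {
  data.frame(name = character(), x = double(), y = double(), z = double(),
             element = character(), stringsAsFactors = FALSE)
}
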