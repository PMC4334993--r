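test_that("SASA matches analytic spheres and sampling is stable", {
  for (el in c("C", "N", "O", "S")) {
    one <- atoms_df(el, "UNK", 1, matrix(0, 1, 3), element = el)
    r <- vestidock:::vdw_radius(el) + 1.4
    got <- sasa(one)
    expect_lt(abs(got - 4 * pi * r^2) / (4 * pi * r^2), 0.01)
    # doubling n_points moves a single-atom area by < 0.5%
    got2 <- sasa(one, n_points = 1920)
    expect_lt(abs(got2 - got) / got, 0.005)
  }
  # an atom enclosed in a tight cage is fully buried
  dirs <- unname(rbind(diag(3), -diag(3),
                       as.matrix(expand.grid(c(-1, 1), c(-1, 1),
                                             c(-1, 1))) / sqrt(3)))
  cage <- atoms_df(c("C", rep("S", 14)), "UNK", 1:15,
                   rbind(c(0, 0, 0), dirs * 2.0))
  cage$element <- c("C", rep("S", 14))
  areas <- sasa(cage)
  expect_equal(areas[1], 0)
  expect_warning(sasa(atoms_df("X", "UNK", 1, matrix(0, 1, 3),
                               element = "XX")), "default vdW")
})

test_that("two overlapping spheres match a Monte-Carlo oracle within 2%", {
  two <- atoms_df(c("C", "O"), "UNK", 1:2,
                  matrix(c(0, 0, 0, 2.2, 0, 0), ncol = 3, byrow = TRUE))
  two$element <- c("C", "O")
  got <- sum(sasa(two, n_points = 1920))
  want <- oracle_two_sphere_mc(1.7 + 1.4, 1.52 + 1.4, 2.2)
  expect_lt(abs(got - want) / want, 0.02)
})

test_that("complex SASA never exceeds the sum of parts; buried area >= 0", {
  tc <- toy_channel_neg(); pep <- toy_peptide1()
  pl <- cached_dock("neg_fast", tc$tetramer, pep, fast_cfg())
  lig <- apply_pose(pep, pl, 1)
  rec <- model_atoms(tc$tetramer)
  s_rec <- sum(sasa(rec, n_points = 240))
  s_lig <- sum(sasa(lig, n_points = 240))
  s_cx <- sum(sasa(rbind(rec, lig), n_points = 240))
  expect_lte(s_cx, s_rec + s_lig + 1e-9)
})

test_that("footprint classes react to ligand placement", {
  tc <- toy_channel_neg(); pep <- toy_peptide1()
  rec <- model_atoms(tc$tetramer)
  far <- model_atoms(pep)
  far <- set_atom_coords(far, sweep(atom_coords(far), 2, c(100, 0, 0), `+`))
  fp_far <- classify_footprint(tc$tetramer, far, n_points = 240)
  expect_equal(sum(fp_far$category %in% c("interfacing", "bonded-link")), 0L)
  expect_true(all(fp_far$category %in%
                    c("inaccessible", "solvent-accessible")))
  expect_true(all(fp_far$buried_area >= 0))

  pl <- cached_dock("neg_fast", tc$tetramer, pep, fast_cfg())
  lig <- apply_pose(pep, pl, 1)
  fp <- classify_footprint(tc$tetramer, lig, n_points = 240)
  expect_true(all(fp$category %in% c("inaccessible", "solvent-accessible",
                                     "interfacing", "bonded-link")))
  expect_gt(sum(fp$category %in% c("interfacing", "bonded-link")), 0L)
  # oracle: buried area recomputed by direct two-run subtraction
  free_o <- attr(sasa(rec, n_points = 240), "residue")
  cx_o <- attr(sasa(rbind(rec, lig), n_points = 240), "residue")
  buried_o <- pmax(free_o$area - cx_o$area[match(free_o$key, cx_o$key)], 0)
  expect_equal(fp$buried_area, buried_o, tolerance = 1e-9)
  # every bonded-link residue appears in a contact record
  contacts <- attr(fp, "contacts")
  linked <- fp[fp$category == "bonded-link", ]
  if (nrow(linked)) {
    ck <- paste(contacts$chain_a, contacts$resseq_a)
    expect_true(all(paste(linked$chain, linked$resseq) %in% ck))
  }
})

test_that("hydrogen-bond geometry criteria act as documented", {
  # ideal backbone N-H...O=C: CA-N-O angle near 120, distance 2.9
  don <- atoms_df(c("N", "CA"), "ALA", 1,
                  matrix(c(0, 0, 0, -0.7, -1.2, 0), ncol = 3, byrow = TRUE),
                  chain = "A")
  acc <- atoms_df(c("O", "C"), "ALA", 1,
                  matrix(c(2.9, 0, 0, 3.9, 0.8, 0), ncol = 3, byrow = TRUE),
                  chain = "B")
  hb <- detect_hbonds(don, acc)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$kind, "hbond")
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_gte(hb$angle, 120)
  # same pair at 5 A: not detected
  acc5 <- acc; acc5$x <- acc5$x + 2.1
  expect_equal(nrow(detect_hbonds(don, acc5)), 0L)
  # poor antecedent angle: not detected
  don_bad <- don; don_bad[2, c("x", "y", "z")] <- c(1.2, 0.4, 0)
  expect_equal(nrow(detect_hbonds(don_bad, acc)), 0L)
  # detection is symmetric in molecule order
  hb_sw <- detect_hbonds(acc, don)
  expect_equal(nrow(hb_sw), 1L)
  expect_equal(hb_sw$distance, hb$distance)
})

test_that("salt bridges need opposite charges within the cutoff", {
  lys <- seq_structure("K", chain = "A")
  glu <- seq_structure("E", chain = "B")
  nz <- which(lys$name == "NZ")
  shift_to <- function(mol, at, target) {
    d <- target - unlist(mol[mol$name == at, c("x", "y", "z")])
    set_atom_coords(mol, sweep(atom_coords(mol), 2, d, `+`))
  }
  oe <- unlist(glu[glu$name == "OE1", c("x", "y", "z")])
  lys3 <- shift_to(lys, "NZ", oe + c(3, 0, 0))
  sb <- detect_salt_bridges(lys3, glu)
  expect_true(any(sb$atom_a == "NZ" & sb$atom_b %in% c("OE1", "OE2")))
  # like charges never pair
  lys_b <- seq_structure("K", chain = "B")
  lys_b <- shift_to(lys_b, "NZ",
                    unlist(lys3[lys3$name == "NZ", c("x", "y", "z")]) + c(3, 0, 0))
  sb2 <- detect_salt_bridges(lys3, lys_b)
  expect_false(any(sb2$atom_a == "NZ" & sb2$atom_b == "NZ"))
  # beyond 4 A: not detected
  lys45 <- shift_to(lys, "NZ", oe + c(4.5, 0, 0))
  sb3 <- detect_salt_bridges(lys45, glu)
  expect_false(any(sb3$atom_a == "NZ" & sb3$atom_b == "OE1"))
  expect_true(all(sb3$distance <= 4.0))
})

test_that("contact rings report exact diameters and ligand contacts", {
  tc <- toy_channel_neg()
  cr <- contact_rings(tc$tetramer, tc$rings)
  radii <- vapply(tc$params$rings, `[[`, 0, "radius")
  expect_equal(cr$diameter, unname(2 * radii[cr$name]), tolerance = 1e-9)
  expect_equal(cr$n_chains, rep(4L, 3))
  # independent recomputation from raw coordinates
  a <- model_atoms(tc$tetramer)
  for (rd in tc$rings) {
    at <- a[a$resseq == rd$resseq & a$name == rd$atom, ]
    at <- at[order(at$chain), ]
    d13 <- sqrt(sum((unlist(at[1, c("x", "y", "z")]) -
                       unlist(at[3, c("x", "y", "z")]))^2))
    d24 <- sqrt(sum((unlist(at[2, c("x", "y", "z")]) -
                       unlist(at[4, c("x", "y", "z")]))^2))
    expect_equal(cr$diameter[cr$name == rd$name], mean(c(d13, d24)),
                 tolerance = 1e-9)
  }
  # custom placement: radial distance 3 => diameter 6
  tc3 <- make_toy_channel(toy_channel_params(rings = list(
    pore = list(depth = -5, radius = 3, restype = "TYR", atom = "OH"))))
  cr3 <- contact_rings(tc3$tetramer, tc3$rings)
  expect_equal(cr3$diameter, 6, tolerance = 1e-9)

  expect_error(contact_rings(tc$tetramer, list(list(name = "bad", resseq = 999,
                                                    atom = "CA"))),
               "missing")
  # ligand contacts counted when a pose is provided
  pep <- toy_peptide1()
  pl <- cached_dock("neg_fast", tc$tetramer, pep, fast_cfg())
  cr_lig <- contact_rings(tc$tetramer, tc$rings, apply_pose(pep, pl, 1))
  expect_true(all(is.finite(cr_lig$contacts)))
  expect_gt(sum(cr_lig$contacts), 0)
})
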