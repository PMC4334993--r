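test_that("formal pH7 charges follow the residue scheme", {
  tox <- seq_structure(TPN_SEQ)
  cm <- assign_charges(tox)
  # N-term +1, Arg +1, 4 Lys +4, C-term -1, His 0, Cys 0 => +5
  expect_equal(cm$total, 5)
  expect_equal(sum(cm$charges), cm$total)
  # per-group placement: each lysine's charge rides on NZ
  nz <- tox$name == "NZ"
  expect_true(all(cm$charges[nz] == 1))
  # free lysine residue carries +1 (side chain) +1/-1 termini
  lys <- seq_structure("K")
  expect_equal(assign_charges(lys)$total, 1)
  # neutral-capped polyglycine is zero
  gly <- seq_structure("GGGG")
  expect_equal(assign_charges(gly, termini = FALSE)$total, 0)
  expect_warning(assign_charges(atoms_df("C1", "LIG", 1,
                                         matrix(0, 1, 3))), "unknown")
})

test_that("rotation_set is deterministic, orthonormal and re-enumerable", {
  expect_error(rotation_set(0), "invalid")
  expect_error(rotation_set(91), "invalid")
  for (step in c(90, 45, 30)) {
    rs <- rotation_set(step)
    expect_equal(rs[[1]], diag(3), tolerance = 1e-12)
    for (R in rs[seq(1, length(rs), by = 7)]) {
      expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
      expect_equal(det(R), 1, tolerance = 1e-10)
    }
  }
  # independent re-enumeration of the documented construction at 30 deg
  step <- 30
  count <- 0L
  for (b in seq(0, 180, by = step)) {
    na <- max(1, round(360 * sin(b * pi / 180) / step))
    count <- count + na * length(seq(0, 360 - step, by = step))
  }
  expect_equal(length(rotation_set(30)), count)
  expect_identical(rotation_set(30), rotation_set(30))
})

test_that("grid rasterization marks cores and conserves charge", {
  one <- atoms_df("C", "UNK", 1, matrix(c(0.3, -0.2, 0.1), 1))
  g <- build_grids(one, spacing = 1.0, surface_thickness = 1.5, margin = 3)
  # oracle: per-voxel distance test
  core_count <- 0L; surf_count <- 0L
  r <- vestidock:::vdw_radius("C")
  for (i in seq_len(g$dims[1])) for (j in seq_len(g$dims[2]))
    for (k in seq_len(g$dims[3])) {
      p <- g$origin + (c(i, j, k) - 1) * g$spacing
      d <- sqrt(sum((p - c(0.3, -0.2, 0.1))^2))
      if (d <= r) core_count <- core_count + 1L
      else if (d <= r + 1.5) surf_count <- surf_count + 1L
    }
  expect_equal(sum(g$core), core_count)
  expect_equal(sum(g$surface), surf_count)
  expect_true(all(g$surface * g$core == 0))

  expect_error(build_grids(empty_atom_table()), "empty")
  expect_error(build_grids(one, spacing = 0.1), "spacing")

  pep <- toy_peptide1()
  cm <- assign_charges(model_atoms(pep))
  gp <- build_grids(model_atoms(pep), cm, spacing = 1.2)
  expect_equal(sum(gp$charge), cm$total, tolerance = 1e-9)
})

test_that("FFT scan equals direct summation and behaves at the extremes", {
  r <- random_grids(101); l <- random_grids(202)
  sm <- scan_translations(r, l)
  oracle <- direct_scan_oracle(r, l)
  expect_lt(max(abs(sm$shape - oracle$shape)), 1e-6)
  expect_lt(max(abs(sm$elec - oracle$elec)), 1e-6)

  # ligand identical to receptor at zero offset: every core voxel overlaps,
  # so the core-core penalty dominates the self-surface reward
  self <- scan_translations(r, r)
  expect_equal(self$shape[1, 1, 1],
               sum(r$surface) - 9 * sum(r$core), tolerance = 1e-6)
  expect_lt(self$shape[1, 1, 1], 0)

  # zero charges => elec identically zero
  l0 <- l; l0$charge[] <- 0
  expect_equal(max(abs(scan_translations(r, l0)$elec)), 0)

  l_bad <- l; l_bad$spacing <- 2.4
  expect_error(scan_translations(r, l_bad), "spacing")
  l_bad2 <- random_grids(1, dims = c(8, 8, 8))
  expect_error(scan_translations(r, l_bad2), "dimension")
})

test_that("two single atoms score best at surface-shell contact", {
  mk1 <- function(p) build_grids(atoms_df("C", "UNK", 1, matrix(p, 1)),
                                 spacing = 1.0, surface_thickness = 1.5,
                                 margin = 6, dims = c(20, 20, 20),
                                 origin = c(-10, -10, -10))
  r <- mk1(c(0, 0, 0)); l <- mk1(c(0, 0, 0))
  sm <- scan_translations(r, l)
  oracle <- direct_scan_oracle(r, l)
  expect_equal(which.max(sm$shape), which.max(oracle$shape))
  best <- arrayInd(which.max(sm$shape), r$dims)
  disp <- attr(sm, "displacement")
  d <- c(disp[[1]][best[1]], disp[[2]][best[2]], disp[[3]][best[3]])
  # optimal displacement puts the two atoms at shell-overlap distance:
  # beyond core-core contact, within the summed shell reach
  expect_gt(sqrt(sum(d^2)), 2 * 1.7 - 1.0)
  expect_lt(sqrt(sum(d^2)), 2 * (1.7 + 1.5))
})

test_that("contact energy is a symmetric cutoff table sum", {
  a <- atoms_df("C", "UNK", 1, matrix(c(0, 0, 0), 1))
  b <- atoms_df("C", "UNK", 1, matrix(c(4, 0, 0), 1))
  expect_equal(contact_energy(a, b), vestidock:::CONTACT_TABLE["C", "C"])
  b_far <- atoms_df("C", "UNK", 1, matrix(c(40, 0, 0), 1))
  expect_equal(contact_energy(a, b_far), 0)

  tc <- toy_channel_neg(); pep <- toy_peptide1()
  rec <- model_atoms(tc$tetramer); lig <- model_atoms(pep)
  lig2 <- set_atom_coords(lig, sweep(atom_coords(lig), 2, c(0, 0, -12)))
  got <- contact_energy(rec, lig2)
  # brute-force O(n^2) oracle, no prefilter
  tt <- vestidock:::CONTACT_TABLE
  typ <- function(e) ifelse(e %in% rownames(tt), e, "C")
  acc <- 0
  lx <- atom_coords(lig2); rx <- atom_coords(rec)
  for (i in seq_len(nrow(lx))) for (j in seq_len(nrow(rx))) {
    if (sum((lx[i, ] - rx[j, ])^2) <= 4.5^2)
      acc <- acc + tt[typ(lig2$element[i]), typ(rec$element[j])]
  }
  expect_gt(abs(got), 0)
  expect_equal(got, acc)
  expect_equal(contact_energy(lig2, rec), got)  # molecule-order symmetry
})

test_that("dock_rigid is deterministic, sorted and pool-limited", {
  tc <- toy_channel_neg(); pep <- toy_peptide1()
  cfg <- fast_cfg()
  pl1 <- dock_rigid(tc$tetramer, pep, cfg)
  pl2 <- dock_rigid(tc$tetramer, pep, cfg)
  expect_identical(pl1$poses, pl2$poses)
  expect_true(all(diff(pl1$poses$score) <= 1e-12))
  expect_equal(pl1$poses$score,
               with(pl1$poses, cfg$weights[["shape"]] * shape +
                      cfg$weights[["elec"]] * elec +
                      cfg$weights[["contact"]] * contact))
  # N larger than the scanned pool: all candidates returned, no padding
  cfg_big <- dock_config(rotation_step = 90, top_n = 10000,
                         candidates_per_rotation = 3)
  pl3 <- dock_rigid(tc$tetramer, pep, cfg_big)
  expect_lte(nrow(pl3$poses), length(rotation_set(90)) * 3)
  expect_equal(nrow(pl3$poses), nrow(unique(pl3$poses[, c("rotation_index",
                                                          "tx", "ty", "tz")])))
})

test_that("grid score is invariant under a common rigid motion", {
  tc <- toy_channel_neg(); pep <- toy_peptide1()
  cfg <- fast_cfg()
  base <- dock_rigid(tc$tetramer, pep, cfg)$poses$score[1]
  R <- exact_rz(90)  # voxel-exact rotation
  move <- function(b) {
    a <- model_atoms(b, 1L)
    structure_bundle(list(set_atom_coords(
      a, sweep(atom_coords(a) %*% t(R), 2, c(1.2, -2.4, 3.6), `+`))), id = b$id)
  }
  moved <- dock_rigid(move(tc$tetramer), move(pep), cfg)$poses$score[1]
  expect_lt(abs(moved - base) / abs(base), 0.05)  # one-voxel discretization
})

test_that("raising the core penalty never promotes a clashing pose", {
  tc <- toy_channel_neg(); pep <- toy_peptide1()
  lo <- dock_rigid(tc$tetramer, pep, fast_cfg(core_penalty = 3))
  hi <- dock_rigid(tc$tetramer, pep, fast_cfg(core_penalty = 30))
  keyify <- function(pl) paste(pl$poses$rotation_index, pl$poses$tx,
                               pl$poses$ty, pl$poses$tz)
  klo <- keyify(lo); khi <- keyify(hi)
  shared <- intersect(klo, khi)
  s_lo <- lo$poses$score[match(shared, klo)]
  s_hi <- hi$poses$score[match(shared, khi)]
  # core-core overlap inferred from the penalty response of the shape term
  cc <- (lo$poses$shape[match(shared, klo)] -
           hi$poses$shape[match(shared, khi)]) / (30 - 3)
  expect_true(all(cc >= -1e-9))
  clashing <- cc > 1e-9
  expect_gt(sum(clashing), 0)
  # scores of clashing poses strictly decrease; clean poses are unchanged
  expect_true(all(s_hi[clashing] < s_lo[clashing]))
  expect_equal(s_hi[!clashing], s_lo[!clashing], tolerance = 1e-9)
  # no clashing pose overtakes a clean pose it was below
  for (i in which(clashing)) {
    above <- which(!clashing & s_lo >= s_lo[i])
    expect_true(all(s_hi[above] >= s_hi[i]))
  }
})
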