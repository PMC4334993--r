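test_that("splice_vestibule replaces exactly the window", {
  tmpl <- "AAAAACCCCCTTTTT"
  expect_equal(splice_vestibule(tmpl, c(6, 10), "CCCCC"), tmpl)  # identity
  out <- splice_vestibule(tmpl, c(6, 10), "WYWYW")
  expect_equal(substr(out, 1, 5), "AAAAA")
  expect_equal(substr(out, 6, 10), "WYWYW")
  expect_equal(substr(out, 11, 15), "TTTTT")
  expect_error(splice_vestibule(tmpl, c(6, 10), "WYWYWWW"), "splice error")
  expect_equal(nchar(splice_vestibule(tmpl, c(6, 10), "WYW", tolerance = 2)),
               13L)
  expect_error(splice_vestibule(tmpl, c(0, 10), "x"), "invalid span")
})

test_that("apply_mutations is checked, positional and order-independent", {
  span <- segment_span("A", 1, 10)
  base <- chimera_spec("t", span, "HASAHALACA",
                       mutations = "H1Y+S3P+C9F")
  out <- apply_mutations(base)
  expect_equal(out$replacement_sequence, "YAPAHALAFA")
  expect_equal(nrow(out$mutations), 0L)
  # order independence
  base2 <- chimera_spec("t", span, "HASAHALACA", mutations = "C9F+H1Y+S3P")
  expect_equal(apply_mutations(base2)$replacement_sequence,
               out$replacement_sequence)
  # empty mutation list is the identity
  expect_equal(apply_mutations(chimera_spec("t", span, "HASAHALACA")),
               chimera_spec("t", span, "HASAHALACA"))
  # from mismatch names the position
  bad <- chimera_spec("t", span, "AASAHALACA", mutations = "H1Y")
  expect_error(apply_mutations(bad), "position 1")
  expect_error(chimera_spec("t", span, "HASAHALACA", mutations = "H1Y+H1W"),
               "duplicate")
})

test_that("threading conserves the template backbone bit-exactly", {
  tc <- toy_channel_neg()
  tmpl <- tc$subunit
  n <- nrow(residue_table(model_atoms(tmpl)))
  span <- segment_span("A", 1, n)
  seq0 <- extract_segment_sequence(tmpl)

  # identity threading reproduces the template exactly
  id_spec <- chimera_spec("toy", span, seq0)
  out <- thread_chimera(tmpl, id_spec)
  expect_same_atoms(model_atoms(out), model_atoms(tmpl))

  # point mutation S->A changes exactly that side chain, to CB only
  spos <- regexpr("S", seq0)[1]
  mut <- chimera_spec("toy", span, seq0,
                      mutations = sprintf("S%dA", spos))
  out2 <- thread_chimera(tmpl, mut)
  a0 <- model_atoms(tmpl); a2 <- model_atoms(out2)
  other0 <- a0[a0$resseq != spos, ]; other2 <- a2[a2$resseq != spos, ]
  expect_same_atoms(other2, other0)
  res2 <- a2[a2$resseq == spos, ]
  expect_setequal(res2$name, c("N", "CA", "C", "O", "CB"))
  bb0 <- a0[a0$resseq == spos & a0$name %in% c("N", "CA", "C", "O"), ]
  bb2 <- res2[res2$name %in% c("N", "CA", "C", "O"), ]
  expect_identical(atom_coords(bb2), atom_coords(bb0))

  # threading is idempotent on its own output
  seq2 <- extract_segment_sequence(out2)
  out3 <- thread_chimera(out2, chimera_spec("toy", span, seq2))
  expect_same_atoms(model_atoms(out3), model_atoms(out2))

  expect_error(thread_chimera(tmpl, chimera_spec("toy", span, "AAA")),
               "splice error")
  expect_error(thread_chimera(tmpl,
                              chimera_spec("toy", segment_span("A", 900, 905),
                                           "AAAAAA")),
               "not resolvable")
  expect_error(thread_chimera(tmpl, chimera_spec(
    "toy", span, paste0("X", substr(seq0, 2, n)))), "non-standard")
})

test_that("a bulky residue threaded into open space finds a clash-free rotamer", {
  # an isolated extended strand: residue 3 faces open solvent
  tmpl <- structure_bundle(list(seq_structure("AAAAAA", phi = -130,
                                              psi = 130)), id = "strand")
  a0 <- model_atoms(tmpl)
  spec <- chimera_spec("strand", segment_span("A", 1, 6), "AAAAAA",
                       mutations = "A3F")
  # oracle: exhaustive rotamer enumeration shows a clash-free rotamer exists
  bb <- a0[a0$resseq == 3 & a0$name %in% c("N", "CA", "C"), ]
  getp <- function(nm) unlist(bb[bb$name == nm, c("x", "y", "z")],
                              use.names = FALSE)
  env <- atom_coords(a0[a0$resseq != 3 &
                          !(a0$resseq %in% c(2, 4) &
                              a0$name %in% c("N", "CA", "C", "O")), ])
  any_clash_free <- FALSE
  for (chi in vestidock:::rotamer_grid("PHE")) {
    sc <- vestidock:::build_sidechain("PHE", getp("N"), getp("CA"), getp("C"),
                                      chi = chi)
    d2 <- vestidock:::pair_dist2(as.matrix(sc[, c("x", "y", "z")]), env)
    if (min(d2) >= 2.4^2) { any_clash_free <- TRUE; break }
  }
  expect_true(any_clash_free)
  out <- expect_silent(thread_chimera(tmpl, spec))  # no clash warning
  a2 <- model_atoms(out)
  placed <- a2[a2$resseq == 3 & !(a2$name %in% c("N", "CA", "C", "O")), ]
  d2 <- vestidock:::pair_dist2(atom_coords(placed), env)
  expect_gte(sqrt(min(d2)), 2.4)
  expect_equal(attr(out, "build_report")$clashes, 0L)
})

test_that("ramachandran classes match ideal secondary structures", {
  helix <- structure_bundle(list(seq_structure(strrep("A", 10),
                                               phi = -57, psi = -47)))
  rep_h <- ramachandran_report(helix)
  expect_true(all(rep_h$class == "favored A"))
  expect_equal(nrow(rep_h), 8L)                  # termini excluded
  expect_equal(attr(rep_h, "fraction_favored"), 1)

  strand <- structure_bundle(list(seq_structure(strrep("A", 10),
                                                phi = -130, psi = 130)))
  expect_true(all(ramachandran_report(strand)$class == "favored B"))

  # a residue with a missing backbone atom is counted unevaluable
  a <- seq_structure(strrep("A", 6))
  a <- a[!(a$resseq == 3 & a$name == "CA"), ]
  rep_m <- ramachandran_report(structure_bundle(list(a)))
  expect_true("unevaluable" %in% rep_m$class)
})
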