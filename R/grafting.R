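# "Limited" homology modelling: splice a replacement outer-vestibule
# sequence into a template subunit and thread it onto the *fixed* template
# backbone. The defining guarantee is that backbone atoms (N, CA, C, O) and
# all atoms of unchanged residues are bit-identical to the template;
# substituted residues get idealized side chains chosen by clash
# minimization over a coarse rotamer grid. No loop modelling: equal-length
# substitution only (tolerance 0 by default).

#' Specify a chimeric subunit build
#'
#' @param template_id free-text template identifier.
#' @param span a [segment_span()] addressing the vestibule in the template.
#' @param replacement_sequence one-letter replacement sequence.
#' @param mutations data.frame with columns `pos` (1-based vestibule
#'   position), `from`, `to`; or a label like `"H8Y+A11D+C44F"` parsed by
#'   [parse_mutations()].
#' @param label free text; derived from mutations when missing.
#' @param position_map optional named integer vector mapping vestibule
#'   positions to native full-length numbering (documentation only).
#' @return object of class `chimera_spec`.
#' @export
chimera_spec <- function(template_id, span, replacement_sequence,
                         mutations = NULL, label = NULL,
                         position_map = NULL) {
  if (is.character(mutations) && length(mutations) == 1L)
    mutations <- parse_mutations(mutations)
  if (is.null(mutations)) mutations <- empty_mutations()
  stopifnot(all(c("pos", "from", "to") %in% names(mutations)))
  if (anyDuplicated(mutations$pos))
    stop("duplicate mutation positions in chimera_spec", call. = FALSE)
  structure(list(template_id = template_id, span = span,
                 replacement_sequence = toupper(replacement_sequence),
                 mutations = mutations,
                 label = label %||% mutation_label(mutations),
                 position_map = position_map),
            class = "chimera_spec")
}

empty_mutations <- function()
  data.frame(pos = integer(), from = character(), to = character(),
             stringsAsFactors = FALSE)

#' Parse a mutation label such as "H8Y+A11D+C44F"
#' @param label `+`-separated point mutations in from/position/to notation.
#' @return data.frame with columns pos, from, to.
#' @export
parse_mutations <- function(label) {
  if (is.null(label) || !nzchar(label) || identical(label, "base"))
    return(empty_mutations())
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("cannot parse mutation '", parts[bad][1], "'", call. = FALSE)
  data.frame(pos = as.integer(vapply(m, `[`, "", 3)),
             from = vapply(m, `[`, "", 2),
             to = vapply(m, `[`, "", 4), stringsAsFactors = FALSE)
}

mutation_label <- function(mutations) {
  if (nrow(mutations) == 0L) return("base")
  paste(sprintf("%s%d%s", mutations$from, mutations$pos, mutations$to),
        collapse = "+")
}

#' Splice a replacement segment into a template sequence
#'
#' @param template_sequence one-letter template sequence.
#' @param span_offsets integer `(start, end)` offsets within the sequence,
#'   1-based inclusive.
#' @param replacement one-letter replacement segment.
#' @param tolerance allowed length difference (default 0: indels rejected,
#'   never silently loop-modelled).
#' @return the chimeric sequence.
#' @export
splice_vestibule <- function(template_sequence, span_offsets, replacement,
                             tolerance = 0L) {
  s <- span_offsets[1]; e <- span_offsets[2]
  n <- nchar(template_sequence)
  if (s < 1L || e > n || s > e)
    stop("invalid span offsets for splice", call. = FALSE)
  span_len <- e - s + 1L
  if (abs(nchar(replacement) - span_len) > tolerance)
    stop(sprintf(
      "splice error: replacement length %d vs span length %d exceeds tolerance %d",
      nchar(replacement), span_len, tolerance), call. = FALSE)
  paste0(substr(template_sequence, 1, s - 1L), replacement,
         substr(template_sequence, e + 1L, n))
}

#' Apply point mutations to a chimera specification
#'
#' Positions are 1-based within the replacement (vestibule) sequence. Every
#' `from` residue must match the current sequence; the result is
#' order-independent. The returned spec has the mutations folded into
#' `replacement_sequence` (the mutation list is cleared, the label kept).
#'
#' @param spec a [chimera_spec()].
#' @return mutated `chimera_spec`.
#' @export
apply_mutations <- function(spec) {
  mut <- spec$mutations
  if (nrow(mut) == 0L) return(spec)
  seq <- strsplit(spec$replacement_sequence, "")[[1]]
  for (i in seq_len(nrow(mut))) {
    p <- mut$pos[i]
    if (p < 1L || p > length(seq))
      stop("mutation position ", p, " outside vestibule sequence",
           call. = FALSE)
    if (seq[p] != mut$from[i])
      stop(sprintf(
        "mutation consistency error at vestibule position %d: expected %s, found %s",
        p, mut$from[i], seq[p]), call. = FALSE)
    seq[p] <- mut$to[i]
  }
  out <- spec
  out$replacement_sequence <- paste(seq, collapse = "")
  out$mutations <- empty_mutations()
  out
}

#' Thread a chimeric sequence onto the fixed template backbone
#'
#' Residues whose identity is unchanged are copied verbatim from the
#' template. Substituted residues keep their template backbone (N, CA, C, O)
#' bit-identically and receive idealized side chains: for each substituted
#' position every rotamer in a coarse chi grid is built and the one with the
#' fewest heavy-atom clashes (< `clash_cutoff` to atoms of other residues)
#' is kept; ties go to the smaller summed overlap, then to grid order.
#' Irreparable clashes are recorded in the build report, never silently
#' dropped.
#'
#' @param template a [structure_bundle()]; the chain addressed by the spec's
#'   span must be present (first model used).
#' @param spec a [chimera_spec()]; pending mutations are applied first.
#' @param clash_cutoff heavy-atom clash distance, Angstrom (default 2.4).
#' @return single-chain subunit `structure_bundle`; the build report
#'   (data.frame of rotamer choices and clash counts) is in
#'   `attr(, "build_report")`.
#' @export
thread_chimera <- function(template, spec, clash_cutoff = 2.4) {
  spec <- apply_mutations(spec)
  atoms <- model_atoms(template, 1L)
  atoms <- atoms[atoms$chain == spec$span$chain, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("template chain '", spec$span$chain, "' not found", call. = FALSE)
  span_res <- resolve_span(atoms, spec$span)
  repl <- strsplit(spec$replacement_sequence, "")[[1]]
  if (length(repl) != nrow(span_res))
    stop(sprintf("splice error: replacement length %d != span length %d",
                 length(repl), nrow(span_res)), call. = FALSE)
  bad <- !(repl %in% names(AA_1TO3))
  if (any(bad))
    stop("non-standard residue '", repl[bad][1],
         "' cannot be threaded", call. = FALSE)

  key <- residue_key(atoms)
  report <- list()
  for (i in seq_len(nrow(span_res))) {
    rkey <- span_res$key[i]
    new3 <- AA_1TO3[[repl[i]]]
    old3 <- span_res$resname[i]
    if (new3 == old3) next
    rows <- which(key == rkey)
    res_atoms <- atoms[rows, , drop = FALSE]
    bb <- res_atoms[res_atoms$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% bb$name))
      stop("missing backbone atoms at ", rkey, call. = FALSE)
    getp <- function(nm) unlist(bb[bb$name == nm, c("x", "y", "z")],
                                use.names = FALSE)
    # clash environment: everything except the residue itself and the
    # backbone of its covalent neighbors (1-3/1-4 contacts are bonded
    # geometry, not clashes)
    rt_all <- residue_table(atoms)
    ri <- match(rkey, rt_all$key)
    adj <- rt_all$key[c(ri - 1L, ri + 1L)]
    adj <- adj[!is.na(adj)]
    env_mask <- key != rkey &
      !(key %in% adj & atoms$name %in% c("N", "CA", "C", "O"))
    env <- atom_coords(atoms[env_mask, , drop = FALSE])
    best <- NULL
    grid <- rotamer_grid(new3)
    for (gi in seq_along(grid)) {
      sc <- build_sidechain(new3, getp("N"), getp("CA"), getp("C"),
                            chi = grid[[gi]])
      if (nrow(sc) == 0) { best <- list(sc = sc, clashes = 0L, gi = gi); break }
      d2 <- pair_dist2(as.matrix(sc[, c("x", "y", "z")]), env)
      mind <- sqrt(apply(d2, 1, min))
      clashes <- sum(mind < clash_cutoff)
      overlap <- sum(pmax(0, clash_cutoff - mind))
      if (is.null(best) || clashes < best$clashes ||
          (clashes == best$clashes && overlap < best$overlap)) {
        best <- list(sc = sc, clashes = clashes, overlap = overlap, gi = gi)
      }
    }
    report[[length(report) + 1L]] <- data.frame(
      residue = rkey, from = old3, to = new3, rotamer = best$gi,
      clashes = best$clashes, stringsAsFactors = FALSE)
    if (best$clashes > 0L)
      warning(sprintf("threading clash at %s (%s->%s): %d contact(s) < %.1f A",
                      rkey, old3, new3, best$clashes, clash_cutoff))
    # rebuild residue: template backbone + new side chain
    keep_bb <- res_atoms[match(intersect(c("N", "CA", "C", "O"), res_atoms$name),
                               res_atoms$name), , drop = FALSE]
    sc <- best$sc
    new_rows <- if (nrow(sc)) data.frame(
      serial = 0L, name = sc$name, altloc = "",
      resname = new3, chain = res_atoms$chain[1],
      resseq = res_atoms$resseq[1], icode = res_atoms$icode[1],
      x = sc$x, y = sc$y, z = sc$z, occ = 1, element = sc$element,
      stringsAsFactors = FALSE) else empty_atom_table()
    keep_bb$resname <- new3
    res_new <- rbind(keep_bb, new_rows)
    atoms <- rbind(atoms[seq_len(rows[1] - 1L), , drop = FALSE],
                   res_new,
                   atoms[setdiff(seq_len(nrow(atoms)),
                                 seq_len(rows[length(rows)])), , drop = FALSE])
    key <- residue_key(atoms)
  }
  atoms$serial <- seq_len(nrow(atoms))
  out <- structure_bundle(list(atoms),
                          id = paste0(spec$template_id, "/", spec$label))
  attr(out, "build_report") <-
    if (length(report)) do.call(rbind, report) else
      data.frame(residue = character(), from = character(), to = character(),
                 rotamer = integer(), clashes = integer())
  out
}

# squared distance matrix between two coordinate sets (n x 3, m x 3);
# clamped at zero (tcrossprod can go epsilon-negative)
pair_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# Rectangular Ramachandran class boxes (documented approximation: regions
# named A/B/L with no published boundaries; these boxes cover the standard
# favored areas).
RAMA_BOXES <- list(
  A = function(phi, psi) phi >= -160 & phi <= -20 & psi >= -120 & psi <= 50,
  B = function(phi, psi) phi >= -180 & phi <= -20 &
    ((psi > 50 & psi <= 180) | (psi >= -180 & psi <= -170)),
  L = function(phi, psi) phi >= 20 & phi <= 160 & psi >= -60 & psi <= 90
)

#' Per-residue Ramachandran classification
#'
#' Classifies each residue's (phi, psi) into favored alpha (A), beta (B),
#' left-handed alpha (L) rectangular regions or `outlier`. Chain termini
#' (undefined phi or psi) are excluded; residues with missing backbone
#' atoms are counted `unevaluable`.
#'
#' @param subunit a [structure_bundle()] (first model analysed).
#' @return data.frame (chain, resseq, icode, resname, phi, psi, class) with
#'   attribute `fraction_favored`.
#' @export
ramachandran_report <- function(subunit) {
  atoms <- model_atoms(subunit, 1L)
  res <- list()
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    rt <- residue_table(a)
    n <- nrow(rt)
    if (n < 3) next
    key <- residue_key(a)
    getp <- function(ri, nm) {
      rows <- which(key == rt$key[ri] & a$name == nm)
      if (length(rows) != 1L) return(NULL)
      c(a$x[rows], a$y[rows], a$z[rows])
    }
    for (ri in 2:(n - 1)) {
      Cp <- getp(ri - 1, "C"); N <- getp(ri, "N"); CA <- getp(ri, "CA")
      C <- getp(ri, "C"); Nn <- getp(ri + 1, "N")
      if (is.null(Cp) || is.null(N) || is.null(CA) || is.null(C) ||
          is.null(Nn)) {
        res[[length(res) + 1L]] <- data.frame(
          chain = ch, resseq = rt$resseq[ri], icode = rt$icode[ri],
          resname = rt$resname[ri], phi = NA_real_, psi = NA_real_,
          class = "unevaluable", stringsAsFactors = FALSE)
        next
      }
      phi <- dihedral_angle(Cp, N, CA, C)
      psi <- dihedral_angle(N, CA, C, Nn)
      cls <- if (RAMA_BOXES$A(phi, psi)) "favored A"
             else if (RAMA_BOXES$B(phi, psi)) "favored B"
             else if (RAMA_BOXES$L(phi, psi)) "favored L"
             else "outlier"
      res[[length(res) + 1L]] <- data.frame(
        chain = ch, resseq = rt$resseq[ri], icode = rt$icode[ri],
        resname = rt$resname[ri], phi = phi, psi = psi, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  ev <- out$class != "unevaluable"
  attr(out, "fraction_favored") <-
    if (any(ev)) mean(startsWith(out$class[ev], "favored")) else NA_real_
  out
}
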