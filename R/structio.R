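# Structure I/O and rigid-body geometry primitives.
#
# Atoms are kept in a plain data.frame ("atom table") with one row per atom:
#   serial, name, altloc, resname, chain, resseq, icode, x, y, z, occ, element
# Author (PDB) numbering is authoritative throughout; residues are addressed
# by (chain, resseq, icode) in file order.

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA_1TO3 <- stats::setNames(names(AA_3TO1), unname(AA_3TO1))

#' Create an empty atom table
#'
#' @return zero-row data.frame with the canonical atom columns.
#' @keywords internal
empty_atom_table <- function() {
  data.frame(
    serial = integer(), name = character(), altloc = character(),
    resname = character(), chain = character(), resseq = integer(),
    icode = character(), x = double(), y = double(), z = double(),
    occ = double(), element = character(), stringsAsFactors = FALSE
  )
}

#' Bundle one or more structure models
#'
#' A `structure_bundle` holds an ordered list of models (each an atom table
#' sharing one residue topology for NMR-style bundles), an identifier and an
#' optional source path. It is the container used for crystal templates,
#' NMR conformer bundles, subunits and assembled tetramers alike.
#'
#' @param models list of atom tables (data.frames).
#' @param id free-text identifier.
#' @param source optional source path.
#' @return object of class `structure_bundle`.
#' @export
structure_bundle <- function(models, id = "structure", source = NULL) {
  if (!is.list(models) || length(models) < 1L)
    stop("structure_bundle needs at least one model", call. = FALSE)
  models <- lapply(models, as_atom_table)
  structure(list(models = models, id = id, source = source),
            class = "structure_bundle")
}

as_atom_table <- function(df) {
  need <- names(empty_atom_table())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("atom table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  df$resseq <- as.integer(df$resseq)
  df$serial <- as.integer(df$serial)
  rownames(df) <- NULL
  df
}

#' @export
print.structure_bundle <- function(x, ...) {
  cat(sprintf("<structure_bundle '%s': %d model(s), %d atoms, chains %s>\n",
              x$id, length(x$models), nrow(x$models[[1]]),
              paste(unique(x$models[[1]]$chain), collapse = "")))
  invisible(x)
}

#' Number of models in a bundle
#' @param bundle structure_bundle.
#' @export
n_models <- function(bundle) length(bundle$models)

#' Extract one model's atom table
#' @param bundle structure_bundle.
#' @param i model index (1-based).
#' @export
model_atoms <- function(bundle, i = 1L) {
  if (i < 1L || i > length(bundle$models))
    stop("model index out of range", call. = FALSE)
  bundle$models[[i]]
}

#' Coordinates of an atom table as an n x 3 matrix
#' @param atoms atom table.
#' @export
atom_coords <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace coordinates in an atom table
#' @param atoms atom table.
#' @param xyz n x 3 matrix.
#' @export
set_atom_coords <- function(atoms, xyz) {
  stopifnot(nrow(xyz) == nrow(atoms))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# Unique residue key, stable under file order.
residue_key <- function(atoms) paste(atoms$chain, atoms$resseq, atoms$icode)

# Residue-level view: one row per residue in order of first appearance.
residue_table <- function(atoms) {
  key <- residue_key(atoms)
  first <- !duplicated(key)
  data.frame(
    key = key[first], chain = atoms$chain[first],
    resseq = atoms$resseq[first], icode = atoms$icode[first],
    resname = atoms$resname[first], stringsAsFactors = FALSE
  )
}

element_from_name <- function(name) {
  # PDB atom-name columns 13-16; element is usually the first letter after
  # any leading digit. Two-letter elements in proteins are rare (SE, FE ...).
  n <- gsub("^[0-9 ]+", "", name)
  ifelse(nchar(n) > 0, substr(n, 1, 1), "X")
}

#' Read a PDB structure file
#'
#' Parses `ATOM`/`HETATM`/`MODEL`/`ENDMDL` records. One model is produced per
#' `MODEL` record (one implicit model when none are present). Hydrogens and
#' deuteriums are dropped; for alternate locations the highest-occupancy
#' altloc is retained (ties resolved by first appearance). Waters and other
#' heteroatoms can be stripped (default keeps `K` ions, drops `HOH`).
#'
#' @param path PDB file path.
#' @param dialect only `"pdb"` is supported.
#' @param keep_hetatm `"ions"` (default: drop water, keep monatomic ions),
#'   `"all"`, or `"none"`.
#' @return a [structure_bundle()].
#' @export
read_structure <- function(path, dialect = "pdb", keep_hetatm = "ions") {
  if (!identical(dialect, "pdb"))
    stop("unsupported dialect: ", dialect, call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  if (!any(is_atom)) {
    bad <- which(!grepl("^(ATOM|HETATM|MODEL|ENDMDL|TER|END|REMARK|HEADER|TITLE|COMPND|SOURCE|SEQRES|CRYST1|SCALE|ORIGX|MASTER|EXPDTA|AUTHOR|REVDAT|JRNL|HELIX|SHEET|SSBOND|LINK|CONECT|ANISOU|HET|FORMUL|SITE|DBREF|SEQADV|MODRES|CISPEP|NUMMDL|MDLTYP|SPRSDE|CAVEAT|OBSLTE|KEYWDS|SPLIT|SIGATM|SIGUIJ|TVECT|\\s*$)", lines))
    if (length(bad))
      stop(sprintf("cannot parse '%s': unrecognized record at line %d: %s",
                   path, bad[1], substr(lines[bad[1]], 1, 30)), call. = FALSE)
    stop("empty structure: no ATOM/HETATM records in ", path, call. = FALSE)
  }
  # model id per line: cumulative count of MODEL records (0 -> implicit 1)
  model_no <- cumsum(is_model)
  model_no[model_no == 0L] <- 1L
  al <- lines[is_atom]
  parse_num <- function(s) suppressWarnings(as.numeric(s))
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = trimws(substr(al, 13, 16)),
    altloc = trimws(substr(al, 17, 17)),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resseq = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode = trimws(substr(al, 27, 27)),
    x = parse_num(substr(al, 31, 38)),
    y = parse_num(substr(al, 39, 46)),
    z = parse_num(substr(al, 47, 54)),
    occ = parse_num(substr(al, 55, 60)),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || anyNA(atoms$resseq)) {
    bad <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z) |
                   is.na(atoms$resseq))[1]
    stop(sprintf("cannot parse '%s': malformed ATOM record (atom line %d)",
                 path, bad), call. = FALSE)
  }
  atoms$occ[is.na(atoms$occ)] <- 1.0
  no_el <- atoms$element == ""
  atoms$element[no_el] <- element_from_name(atoms$name[no_el])
  atoms$element <- toupper(atoms$element)
  atoms$model <- model_no[is_atom]
  atoms$het <- rec[is_atom] == "HETATM"

  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (keep_hetatm == "none") {
    atoms <- atoms[!atoms$het, , drop = FALSE]
  } else if (keep_hetatm == "ions") {
    drop <- atoms$het & !(atoms$resname %in% c("K", "NA", "CL", "MG", "CA", "ZN"))
    atoms <- atoms[!drop, , drop = FALSE]
  }
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms retained from ", path, call. = FALSE)

  models <- lapply(split(atoms, atoms$model), function(m) {
    # altloc: keep highest occupancy per atom address, first on ties
    key <- paste(m$chain, m$resseq, m$icode, m$name)
    ord <- order(match(key, unique(key)), -m$occ,
                 seq_len(nrow(m)))
    m <- m[ord, , drop = FALSE]
    m <- m[!duplicated(paste(m$chain, m$resseq, m$icode, m$name)), , drop = FALSE]
    m$model <- NULL; m$het <- NULL
    as_atom_table(m)
  })
  structure_bundle(unname(models), id = sub("\\.pdb$", "", basename(path)),
                  source = path)
}

#' Define an inclusive residue span on a chain
#'
#' @param chain single-character chain identifier.
#' @param start,end author residue numbers (inclusive).
#' @param start_icode,end_icode optional insertion codes.
#' @return object of class `segment_span`.
#' @export
segment_span <- function(chain, start, end, start_icode = "", end_icode = "") {
  structure(list(chain = chain, start = as.integer(start),
                 end = as.integer(end), start_icode = start_icode,
                 end_icode = end_icode),
            class = "segment_span")
}

# Resolve a span to residue-table row indices (file order within the chain).
resolve_span <- function(atoms, span) {
  rt <- residue_table(atoms)
  rt <- rt[rt$chain == span$chain, , drop = FALSE]
  if (nrow(rt) == 0L)
    stop("span chain '", span$chain, "' not found", call. = FALSE)
  i0 <- which(rt$resseq == span$start & rt$icode == span$start_icode)
  i1 <- which(rt$resseq == span$end & rt$icode == span$end_icode)
  if (length(i0) != 1L || length(i1) != 1L)
    stop(sprintf("span %s%d%s-%d%s not resolvable", span$chain, span$start,
                 span$start_icode, span$end, span$end_icode), call. = FALSE)
  if (i0 > i1)
    stop("span start is after span end in author-numbering order",
         call. = FALSE)
  rt[i0:i1, , drop = FALSE]
}

#' Extract the one-letter sequence of a residue span
#'
#' Non-standard residues map to `X`.
#'
#' @param structure a [structure_bundle()].
#' @param span a [segment_span()], or `NULL` for the whole first chain.
#' @param model_index model to read (default 1).
#' @return one-letter sequence string.
#' @export
extract_segment_sequence <- function(structure, span = NULL, model_index = 1L) {
  atoms <- model_atoms(structure, model_index)
  if (is.null(span)) {
    ch <- atoms$chain[1]
    rt <- residue_table(atoms)
    rt <- rt[rt$chain == ch, , drop = FALSE]
  } else {
    rt <- resolve_span(atoms, span)
  }
  letters1 <- AA_3TO1[rt$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `|| mobile %*% t(R) + t - target ||`. Degenerate (collinear or fewer than
#' 3 distinct directions) point sets produce a warning but still return the
#' least-squares solution.
#'
#' @param mobile,target n x 3 matrices with matched row order, n >= 3.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (post-fit, Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target)))
    stop("point-count mismatch in superpose", call. = FALSE)
  if (nrow(mobile) < 3L) stop("superpose needs >= 3 points", call. = FALSE)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    warning("degenerate (collinear) point set in superpose; ",
            "rotation not uniquely determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.vector(R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param rotation 3x3 matrix; @param translation length-3 vector.
#' @export
transform_coords <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}

fmt_atom_name <- function(name, element) {
  # standard PDB alignment: element right-justified in cols 13-14
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         ifelse(nchar(element) == 2, formatC(name, width = -4),
                paste0(" ", formatC(name, width = -3))))
}

#' Write a structure bundle as a PDB file
#'
#' Multi-model bundles are written with `MODEL`/`ENDMDL` records; a round
#' trip through [read_structure()] preserves atoms, numbering and model
#' count (coordinates at PDB precision, 3 decimals).
#'
#' @param structure a [structure_bundle()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  if (!inherits(structure, "structure_bundle"))
    stop("write_structure expects a structure_bundle", call. = FALSE)
  if (any(vapply(structure$models, nrow, 0L) == 0L))
    stop("refusing to write an empty structure", call. = FALSE)
  multi <- length(structure$models) > 1L
  out <- character(0)
  for (mi in seq_along(structure$models)) {
    m <- structure$models[[mi]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", mi))
    ser <- seq_len(nrow(m))
    lines <- sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ser %% 100000L, fmt_atom_name(m$name, m$element), m$altloc, m$resname,
      m$chain, m$resseq, ifelse(m$icode == "", " ", m$icode),
      m$x, m$y, m$z, m$occ, 0, m$element)
    # TER after each chain block
    chain_end <- which(m$chain != c(m$chain[-1], NA_character_))
    pieces <- character(0)
    prev <- 0L
    for (ce in c(chain_end, nrow(m))) {
      if (ce <= prev) next
      pieces <- c(pieces, lines[(prev + 1L):ce], "TER")
      prev <- ce
    }
    out <- c(out, pieces)
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write structure to ", path, call. = FALSE)
  invisible(path)
}

#' Write sequences in FASTA format
#' @param sequences named character vector of one-letter sequences.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  out <- unlist(lapply(seq_along(sequences), function(i) {
    c(paste0(">", names(sequences)[i] %||% paste0("seq", i)),
      gsub("(.{60})", "\\1\n", sequences[[i]]))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")), "")
  stats::setNames(seqs, sub("^>\\s*", "", lines[hdr]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
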