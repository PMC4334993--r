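# Peptide-bundle analytics: conformer mobility, net charge vs pH,
# disulfide detection and basic-residue counting.

#' Ionization parameters for net-charge calculation
#'
#' Default pKa set (no single set is canonical; the bundled values are
#' conventional textbook ones): N-terminus 9.0, C-terminus 3.1, Lys 10.5,
#' Arg 12.0, His 6.0, Asp 3.9, Glu 4.1, Tyr 10.1, free Cys 8.3.
#'
#' @param pH solution pH (0-14).
#' @param cys_bonded `"all"` (every Cys in a disulfide, excluded from
#'   ionization), `"none"`, or an integer vector of bonded positions.
#' @param pka named replacement pKa values.
#' @return object of class `charge_params`.
#' @export
charge_params <- function(pH = 7, cys_bonded = "all", pka = NULL) {
  if (pH < 0 || pH > 14) stop("pH out of range", call. = FALSE)
  base <- c(Nterm = 9.0, Cterm = 3.1, K = 10.5, R = 12.0, H = 6.0,
            D = 3.9, E = 4.1, Y = 10.1, C = 8.3)
  if (!is.null(pka)) base[names(pka)] <- pka
  if (any(base <= 0)) stop("pKa values must be positive", call. = FALSE)
  structure(list(pH = pH, pka = base, cys_bonded = cys_bonded),
            class = "charge_params")
}

#' Henderson-Hasselbalch net charge of a peptide sequence
#'
#' Sums fractional charges of ionizable side chains plus the free termini.
#' Disulfide-bonded cysteines (per `params$cys_bonded`) are excluded.
#'
#' @param sequence one-letter sequence.
#' @param params a [charge_params()].
#' @return net charge in elementary-charge units.
#' @export
net_charge <- function(sequence, params = charge_params()) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% names(AA_1TO3)))
    stop("unknown residue letter in sequence: ",
         paste(unique(aa[!aa %in% names(AA_1TO3)]), collapse = ""),
         call. = FALSE)
  pH <- params$pH; pka <- params$pka
  fpos <- function(pk) 1 / (1 + 10^(pH - pk))   # basic group, charge +
  fneg <- function(pk) -1 / (1 + 10^(pk - pH))  # acidic group, charge -
  q <- fpos(pka[["Nterm"]]) + fneg(pka[["Cterm"]])
  for (i in seq_along(aa)) {
    a <- aa[i]
    q <- q + switch(a,
      K = fpos(pka[["K"]]), R = fpos(pka[["R"]]), H = fpos(pka[["H"]]),
      D = fneg(pka[["D"]]), E = fneg(pka[["E"]]), Y = fneg(pka[["Y"]]),
      C = {
        bonded <- identical(params$cys_bonded, "all") ||
          (is.numeric(params$cys_bonded) && i %in% params$cys_bonded)
        if (bonded) 0 else fneg(pka[["C"]])
      },
      0)
  }
  unname(q)
}

#' Count basic residues (Arg, Lys, His)
#' @param sequence one-letter sequence.
#' @export
count_basic <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  sum(aa %in% c("R", "K", "H"))
}

#' Detect disulfide bridges from sulfur geometry
#'
#' Pairs Cys SG atoms within `s_s_max`, nearest first, each sulfur used at
#' most once.
#'
#' @param model atom table or `structure_bundle` (first model used).
#' @param s_s_max maximum S-S distance, Angstrom (default 2.3).
#' @return data.frame with 1-based chain residue positions `pos1`, `pos2`
#'   (and author numbers `resseq1`, `resseq2`), sorted so pos1 < pos2.
#' @export
find_disulfides <- function(model, s_s_max = 2.3) {
  atoms <- if (inherits(model, "structure_bundle")) model_atoms(model, 1L)
           else model
  sg <- atoms[atoms$resname == "CYS" & atoms$name == "SG", , drop = FALSE]
  empty <- data.frame(pos1 = integer(), pos2 = integer(),
                      resseq1 = integer(), resseq2 = integer())
  if (nrow(sg) < 2L) return(empty)
  rt <- residue_table(atoms)
  pos_of <- match(paste(sg$chain, sg$resseq, sg$icode), rt$key)
  d <- sqrt(pair_dist2(atom_coords(sg), atom_coords(sg)))
  diag(d) <- Inf
  d[lower.tri(d)] <- Inf
  pairs <- which(d <= s_s_max, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(empty)
  ord <- order(d[pairs])
  used <- logical(nrow(sg))
  out <- list()
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    p <- sort(c(pos_of[i], pos_of[j]))
    out[[length(out) + 1L]] <- data.frame(
      pos1 = p[1], pos2 = p[2],
      resseq1 = rt$resseq[p[1]], resseq2 = rt$resseq[p[2]])
  }
  res <- do.call(rbind, out)
  res[order(res$pos1), , drop = FALSE]
}

#' Per-residue C-alpha mobility across a conformer bundle
#'
#' Each model is rigidly superposed onto the reference model (model 1),
#' then for every residue the RMSD of its C-alpha position over all models
#' relative to the reference model is reported.
#'
#' @param bundle multi-model [structure_bundle()] with consistent topology.
#' @param frame `"all_ca"` (default: all-C-alpha least-squares frame) or
#'   `"n_anchored"` (all-C-alpha rotation, then translation anchoring the
#'   first residue's C-alpha).
#' @return data.frame (pos, resseq, resname, rmsd) of class
#'   `mobility_profile`.
#' @export
ca_mobility_profile <- function(bundle, frame = c("all_ca", "n_anchored")) {
  frame <- match.arg(frame)
  if (n_models(bundle) < 2L)
    stop("mobility profile needs >= 2 models", call. = FALSE)
  cas <- lapply(bundle$models, function(m)
    m[m$name == "CA", , drop = FALSE])
  topo <- vapply(cas, function(m) paste(m$resname, collapse = "|"), "")
  if (length(unique(topo)) != 1L)
    stop("bundle models do not share residue topology", call. = FALSE)
  ref <- atom_coords(cas[[1]])
  aligned <- lapply(cas, function(m) {
    xyz <- atom_coords(m)
    fit <- suppressWarnings(superpose(xyz, ref))
    fitted <- transform_coords(xyz, fit$rotation, fit$translation)
    if (frame == "n_anchored")
      fitted <- sweep(fitted, 2, fitted[1, ] - ref[1, ])
    fitted
  })
  nres <- nrow(ref)
  rmsd <- vapply(seq_len(nres), function(j) {
    devs <- vapply(aligned, function(m) sum((m[j, ] - ref[j, ])^2), 0)
    sqrt(mean(devs))
  }, 0)
  out <- data.frame(pos = seq_len(nres), resseq = cas[[1]]$resseq,
                    resname = cas[[1]]$resname, rmsd = rmsd)
  class(out) <- c("mobility_profile", class(out))
  out
}
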