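# In silico site-directed mutagenesis: enumerate mutation combinations,
# rebuild each chimeric channel with identical settings, re-dock, and rank
# vestibule hotspots by their docking-score gain over the base channel.

#' Enumerate mutation-combination variants
#'
#' All subsets of the given single mutations of size 1..`combine_up_to`,
#' in deterministic order (by subset size, then by combination index).
#' Combinations touching the same position twice are skipped with a
#' warning.
#'
#' @param base a [chimera_spec()] the mutations apply to.
#' @param singles list of single mutations (labels like `"C44F"` or
#'   one-row data.frames).
#' @param combine_up_to maximum combination size (0 gives an empty list).
#' @return list of `chimera_spec`s, labelled like `"H8Y+A11D"`.
#' @export
enumerate_variants <- function(base, singles, combine_up_to = 1L) {
  singles <- lapply(singles, function(s)
    if (is.character(s)) parse_mutations(s) else s)
  out <- list()
  seen <- character(0)
  if (combine_up_to < 1L || length(singles) == 0L) return(out)
  for (k in seq_len(min(combine_up_to, length(singles)))) {
    idx <- utils::combn(length(singles), k)
    for (ci in seq_len(ncol(idx))) {
      mut <- do.call(rbind, singles[idx[, ci]])
      if (anyDuplicated(mut$pos)) {
        warning("skipping combination with conflicting positions: ",
                mutation_label(mut))
        next
      }
      mut <- mut[order(mut$pos), , drop = FALSE]
      lab <- mutation_label(mut)
      if (lab %in% seen) next
      seen <- c(seen, lab)
      v <- base
      v$mutations <- mut
      v$label <- lab
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

build_channel <- function(spec, template, operators, clash_cutoff = 2.4) {
  sub <- suppressWarnings(thread_chimera(template, spec,
                                         clash_cutoff = clash_cutoff))
  tet <- assemble_oligomer(sub, operators)
  tet$id <- spec$label
  tet
}

#' Run an in silico mutagenesis docking scan
#'
#' The base spec and every variant are threaded onto the template,
#' assembled as homotetramers with the same operators, and docked with an
#' identical configuration. A variant that fails to build or dock is
#' recorded as a failed row; the scan continues. Fully deterministic.
#'
#' @param base base [chimera_spec()] (its own row is always included).
#' @param variants list of `chimera_spec`s (e.g. [enumerate_variants()]).
#' @param template template `structure_bundle` for threading.
#' @param operators 4 assembly operators.
#' @param ligand peptide conformer: atom table or bundle (model 1 used).
#' @param config a [dock_config()].
#' @param k top-k for the summary metric (default 5).
#' @param references optional named list of [score_profile()]s to compare
#'   every variant against (dominance fraction reported per reference).
#' @param N profile length retained per variant.
#' @return list of class `scan_result`: `table` (data.frame: label,
#'   n_mutations, top_k_mean, gain, status, one dominance column per
#'   reference) and `profiles` (named list of `score_profile`s).
#' @export
mutation_scan <- function(base, variants, template, operators, ligand,
                          config = dock_config(), k = 5, references = NULL,
                          N = 2000) {
  if (inherits(ligand, "structure_bundle")) ligand <- model_atoms(ligand, 1L)
  specs <- c(list(base), variants)
  labels <- vapply(specs, function(s) s$label, "")
  labels[1] <- "base"
  profiles <- list()
  rows <- list()
  for (i in seq_along(specs)) {
    lab <- labels[i]
    res <- tryCatch({
      tet <- build_channel(specs[[i]], template, operators)
      pl <- dock_rigid(tet, ligand, config)
      score_profile(pl, N = N, channel_label = lab)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("variant '", lab, "' failed: ", conditionMessage(res))
      rows[[i]] <- data.frame(label = lab,
                              n_mutations = nrow(specs[[i]]$mutations),
                              top_k_mean = NA_real_, status = "failed",
                              stringsAsFactors = FALSE)
      next
    }
    profiles[[lab]] <- res
    row <- data.frame(label = lab, n_mutations = nrow(specs[[i]]$mutations),
                      top_k_mean = top_k_mean(res, k), status = "ok",
                      stringsAsFactors = FALSE)
    for (rn in names(references))
      row[[paste0("dominance_vs_", rn)]] <-
        compare_profiles(res, references[[rn]])$dominance
    rows[[i]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  base_tkm <- tab$top_k_mean[tab$label == "base"][1]
  tab$gain <- tab$top_k_mean - base_tkm
  structure(list(table = tab, profiles = profiles, k = k),
            class = "scan_result")
}

#' Rank scan variants by docking-score gain
#'
#' @param scan a [mutation_scan()] result.
#' @param metric only `"top_k_mean_gain"`.
#' @return the scan table without the base row, sorted by descending gain
#'   (ties broken by label); failed variants sink to the bottom.
#' @export
hotspot_rank <- function(scan, metric = "top_k_mean_gain") {
  if (!identical(metric, "top_k_mean_gain"))
    stop("unknown hotspot metric: ", metric, call. = FALSE)
  tab <- scan$table[scan$table$label != "base", , drop = FALSE]
  ord <- order(-ifelse(is.na(tab$gain), -Inf, tab$gain), tab$label)
  out <- tab[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
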