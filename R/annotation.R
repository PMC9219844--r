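# ppm-tolerance compound x adduct annotation of LC-MS features, and grouping
# of co-eluting adducts of the same compound.

#' Build a sorted compound x adduct annotation index
#'
#' Enumerates the theoretical m/z of every (compound, adduct) pair in the
#' registry, sorted by m/z so queries can use binary search.
#'
#' @param registry A `compound_registry` from [load_registry()].
#' @param adducts Adduct table; defaults to the registry's own.
#' @return Data frame `compound`, `adduct`, `theoretical_mz`, `priority`,
#'   sorted by `theoretical_mz`.
#' @export
build_annotation_index <- function(registry, adducts = registry$adducts) {
  comp <- registry$compounds
  n_c <- nrow(comp); n_a <- nrow(adducts)
  idx <- data.frame(
    compound = rep(comp$name, each = n_a),
    adduct = rep(adducts$name, times = n_c),
    theoretical_mz = (rep(comp$neutral_mass, each = n_a) +
                        rep(adducts$mass_shift, times = n_c)) /
      rep(adducts$charge, times = n_c),
    stringsAsFactors = FALSE
  )
  idx$priority <- adduct_priority(idx$adduct)
  idx <- idx[idx$theoretical_mz > 0, ]
  idx[order(idx$theoretical_mz), ]
}

#' Annotate one m/z value against the registry
#'
#' Returns every (compound, adduct) candidate whose theoretical m/z lies
#' within `tol_ppm` of the query, ordered by |ppm error| with ties broken by
#' adduct priority (protonated first, doubly charged last) then compound
#' name. Equivalent to a brute-force scan of the full grid.
#'
#' @param mz Query m/z in Th.
#' @param registry A `compound_registry`.
#' @param adducts Adduct table.
#' @param tol_ppm Positive tolerance in ppm (relative to the theoretical m/z).
#' @param index Optional precomputed [build_annotation_index()] result.
#' @return Data frame of candidates: `compound`, `adduct`, `theoretical_mz`,
#'   `ppm_error` (signed), `rank`. Zero rows when nothing matches.
#' @export
annotate_feature <- function(mz, registry, adducts = registry$adducts,
                             tol_ppm = 10, index = NULL) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (is.null(index)) index <- build_annotation_index(registry, adducts)
  # |mz - theo| / theo <= tol  <=>  theo in [mz/(1+tol), mz/(1-tol)]
  lo <- mz / (1 + tol_ppm * 1e-6)
  hi <- mz / (1 - tol_ppm * 1e-6)
  from <- findInterval(lo, index$theoretical_mz, left.open = TRUE) + 1L
  to <- findInterval(hi, index$theoretical_mz)
  if (from > to)
    return(data.frame(compound = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  hits <- index[from:to, ]
  hits$ppm_error <- ppm_error(mz, hits$theoretical_mz)
  hits <- hits[abs(hits$ppm_error) <= tol_ppm, , drop = FALSE]
  hits <- hits[order(abs(hits$ppm_error), hits$priority, hits$compound), ]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits[, c("compound", "adduct", "theoretical_mz", "ppm_error", "rank")]
}

#' Annotate a differential feature table and group co-eluting adducts
#'
#' Attaches each feature's rank-1 candidate (or NA when unannotated) and
#' groups features whose rank-1 compound agrees and whose retention times
#' fall within a co-elution window (chained: a feature joins the group of its
#' nearest-eluting groupmate when the gap is within the window).
#'
#' @param diff_table Data frame with at least `id`, `mz`, `rt` (typically the
#'   output of [diff_features()]).
#' @param registry A `compound_registry`.
#' @param adducts Adduct table.
#' @param tol_ppm Annotation tolerance in ppm.
#' @param co_elution_window Maximum retention-time gap (minutes) between
#'   consecutive members of an adduct group.
#' @return List with `table` (input plus columns `compound`, `compound_cas`,
#'   `adduct`, `theoretical_mz`, `ppm_error`, `adduct_group_id`) and `groups`
#'   (data frame `adduct_group_id`, `compound`, `n_members`, `members`,
#'   `rt_spread`).
#' @export
annotate_table <- function(diff_table, registry, adducts = registry$adducts,
                           tol_ppm = 10, co_elution_window = 0.2) {
  if (nrow(diff_table) == 0L) stop("diff_table is empty")
  index <- build_annotation_index(registry, adducts)
  out <- diff_table
  out$compound <- NA_character_
  out$adduct <- NA_character_
  out$theoretical_mz <- NA_real_
  out$ppm_error <- NA_real_
  for (i in seq_len(nrow(out))) {
    cand <- annotate_feature(out$mz[i], registry, adducts, tol_ppm, index = index)
    if (nrow(cand)) {
      out$compound[i] <- cand$compound[1]
      out$adduct[i] <- cand$adduct[1]
      out$theoretical_mz[i] <- cand$theoretical_mz[1]
      out$ppm_error[i] <- cand$ppm_error[1]
    }
  }
  out$compound_cas <- registry$compounds$cas[match(out$compound,
                                                   registry$compounds$name)]
  out$adduct_group_id <- NA_character_

  groups <- list()
  gi <- 0L
  for (cmp in unique(stats::na.omit(out$compound))) {
    sel <- which(out$compound == cmp)
    sel <- sel[order(out$rt[sel])]
    brk <- c(0, which(diff(out$rt[sel]) > co_elution_window), length(sel))
    for (k in seq_len(length(brk) - 1L)) {
      gi <- gi + 1L
      members <- sel[(brk[k] + 1L):brk[k + 1L]]
      gid <- sprintf("AG%04d", gi)
      out$adduct_group_id[members] <- gid
      groups[[gi]] <- data.frame(
        adduct_group_id = gid, compound = cmp, n_members = length(members),
        members = paste(out$id[members], collapse = ";"),
        rt_spread = max(out$rt[members]) - min(out$rt[members]),
        stringsAsFactors = FALSE)
    }
  }
  groups <- if (length(groups)) do.call(rbind, groups) else
    data.frame(adduct_group_id = character(0), compound = character(0),
               n_members = integer(0), members = character(0),
               rt_spread = numeric(0), stringsAsFactors = FALSE)
  list(table = out, groups = groups)
}
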