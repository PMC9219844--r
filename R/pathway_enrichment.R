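# Mummichog-style pathway activity scoring: per-pathway Fisher's exact test
# on significant vs all annotated features, plus an empirical permutation
# null that resamples significant feature sets of equal size.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer cell counts
#'   (significant-in-pathway, significant-outside; nonsignificant-in,
#'   nonsignificant-outside).
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("cells must be non-negative integers")
  stats::fisher.test(m)$p.value
}

#' Permutation-calibrated pathway activity scores
#'
#' The universe is the set of annotated features (rank-1 compound assigned).
#' For each pathway, membership is by rank-1 compound; a Fisher test scores
#' the significant/membership 2x2 table, and an empirical p-value is the
#' add-one-corrected fraction of `B` random significant sets of equal size
#' whose pathway hit count reaches the observed one. Pathways with no
#' annotated members are reported with p = 1 and flagged. Deterministic
#' given `seed`.
#'
#' @param annotated Annotated differential table (the `table` element of
#'   [annotate_table()]; needs `id`, `compound`, `p_value`,
#'   `signed_fold_change`).
#' @param pathway_table Data frame with columns `pathway`, `compound` (one
#'   membership pair per row).
#' @param sig_threshold Raw-p significance cutoff defining the significant
#'   feature set.
#' @param B Number of permutations (>= 99).
#' @param seed Integer seed for the permutation draws.
#' @return Data frame sorted by `empirical_p`: `pathway`,
#'   `n_annotated_members`, `n_significant_hits`, `fisher_p`, `empirical_p`,
#'   `direction_summary` (mean signed fold-change of the significant members,
#'   falling back to all members when none are significant), `members`
#'   (semicolon-joined feature ids), `flagged`.
#' @export
pathway_activity <- function(annotated, pathway_table, sig_threshold = 0.001,
                             B = 999, seed = 1) {
  if (B < 99) stop("B must be >= 99")
  if (nrow(pathway_table) == 0L) stop("pathway table is empty")
  uni <- annotated[!is.na(annotated$compound), , drop = FALSE]
  n_uni <- nrow(uni)
  sig <- !is.na(uni$p_value) & uni$p_value < sig_threshold
  n_sig <- sum(sig)
  pathways <- unique(pathway_table$pathway)
  member <- sapply(pathways, function(p) {
    uni$compound %in% pathway_table$compound[pathway_table$pathway == p]
  })
  member <- matrix(member, nrow = n_uni, dimnames = list(NULL, pathways))
  obs_hits <- as.integer(colSums(member & sig))
  n_mem <- as.integer(colSums(member))

  exceed <- integer(length(pathways))
  if (n_sig > 0 && n_uni > 0) {
    withr::with_seed(seed, {
      for (b in seq_len(B)) {
        perm <- sample.int(n_uni, n_sig)
        hits <- colSums(member[perm, , drop = FALSE])
        exceed <- exceed + as.integer(hits >= obs_hits)
      }
    })
  } else {
    exceed <- rep(B, length(pathways))
  }

  res <- data.frame(pathway = pathways, n_annotated_members = n_mem,
                    n_significant_hits = obs_hits,
                    fisher_p = NA_real_, empirical_p = (1 + exceed) / (B + 1),
                    direction_summary = NA_real_, members = NA_character_,
                    flagged = n_mem == 0L, stringsAsFactors = FALSE)
  for (j in seq_along(pathways)) {
    if (n_mem[j] == 0L) {
      res$fisher_p[j] <- 1
      res$empirical_p[j] <- 1
      next
    }
    tab <- matrix(c(obs_hits[j], n_sig - obs_hits[j],
                    n_mem[j] - obs_hits[j],
                    n_uni - n_sig - (n_mem[j] - obs_hits[j])), 2L, 2L)
    res$fisher_p[j] <- fisher_exact_2x2(tab)
    in_path <- member[, j]
    fc_rows <- if (obs_hits[j] > 0L) in_path & sig else in_path
    res$direction_summary[j] <- mean(uni$signed_fold_change[fc_rows])
    res$members[j] <- paste(uni$id[in_path], collapse = ";")
  }
  res <- res[order(res$empirical_p, res$fisher_p, res$pathway), ]
  rownames(res) <- NULL
  res
}
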