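# Feature-level differential abundance for LC-MS metabolomics: retention-time
# alignment across runs, technical-replicate averaging, Welch testing on log2
# intensities, BH-FDR, and the signed fold-change display convention.

#' Align retention times across LC-MS runs
#'
#' Peak-group style alignment: features are matched across runs by m/z within
#' a ppm tolerance; groups represented in at least `anchor_min_presence` of
#' the runs (one feature per run) become anchors. Each run is corrected by a
#' monotone piecewise-linear map interpolating the anchor offsets toward the
#' cross-run median retention time; outside the anchor range retention times
#' are left unchanged.
#'
#' @param runs Named list of per-run data frames with columns `id`, `mz`,
#'   `rt` (minutes) and intensity column(s).
#' @param mz_tol_ppm m/z matching tolerance for anchor detection.
#' @param anchor_min_presence Minimum fraction of runs an anchor group must
#'   cover.
#' @return List with `runs` (input tables with corrected `rt`) and `anchors`
#'   (data frame of anchor groups: `anchor`, `run`, `rt`, `rt_corrected`).
#' @export
align_retention <- function(runs, mz_tol_ppm = 10, anchor_min_presence = 0.9) {
  if (!is.list(runs) || length(runs) < 2L)
    stop("need at least 2 runs to align")
  if (is.null(names(runs)) || any(!nzchar(names(runs))))
    names(runs) <- paste0("run", seq_along(runs))
  pool <- do.call(rbind, lapply(names(runs), function(r) {
    data.frame(run = r, mz = runs[[r]]$mz, rt = runs[[r]]$rt,
               row = seq_len(nrow(runs[[r]])), stringsAsFactors = FALSE)
  }))
  pool <- pool[order(pool$mz), ]
  # single-linkage grouping on sorted m/z: split where the gap exceeds tol
  gap_ppm <- c(Inf, diff(pool$mz) / pool$mz[-nrow(pool)] * 1e6)
  pool$grp <- cumsum(gap_ppm > mz_tol_ppm)
  keep <- vapply(split(pool$run, pool$grp), function(r) {
    length(r) == length(unique(r)) &&
      length(r) >= ceiling(anchor_min_presence * length(runs))
  }, logical(1))
  anchors <- pool[pool$grp %in% as.integer(names(keep)[keep]), ]
  if (nrow(anchors) == 0L)
    stop("no alignment anchors found; consider a larger m/z tolerance")
  med <- tapply(anchors$rt, anchors$grp, stats::median)
  anchors$rt_target <- med[as.character(anchors$grp)]

  out <- runs
  anchors$rt_corrected <- NA_real_
  for (r in names(runs)) {
    a <- anchors[anchors$run == r, ]
    a <- a[order(a$rt), ]
    # enforce a monotone target sequence so the map is non-decreasing
    a$rt_target <- cummax(a$rt_target)
    offset <- a$rt_target - a$rt
    correct <- function(rt) {
      if (nrow(a) == 1L) {
        shift <- ifelse(abs(rt - a$rt) < .Machine$double.eps^0.5, offset, 0)
        return(rt + shift)
      }
      rt + stats::approx(a$rt, offset, xout = rt, ties = "ordered",
                         yleft = 0, yright = 0)$y
    }
    out[[r]]$rt <- correct(runs[[r]]$rt)
    anchors$rt_corrected[anchors$run == r] <- correct(anchors$rt[anchors$run == r])
  }
  list(runs = out,
       anchors = data.frame(anchor = anchors$grp, run = anchors$run,
                            rt = anchors$rt, rt_corrected = anchors$rt_corrected,
                            stringsAsFactors = FALSE))
}

#' Merge aligned runs into a single feature table
#'
#' Runs sharing feature ids (as produced by the simulator or an upstream
#' peak-grouping step) are merged by id: consensus m/z and retention time are
#' medians over runs, and one intensity column per run is kept.
#'
#' @param runs Named list of per-run data frames with columns `id`, `mz`,
#'   `rt`, `intensity`.
#' @return Data frame with columns `id`, `mz`, `rt`, then one intensity
#'   column per run.
#' @export
merge_runs <- function(runs) {
  ids <- Reduce(union, lapply(runs, function(x) x$id))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  mz_m <- sapply(runs, function(x) x$mz[match(ids, x$id)])
  rt_m <- sapply(runs, function(x) x$rt[match(ids, x$id)])
  out$mz <- apply(as.matrix(mz_m), 1, stats::median, na.rm = TRUE)
  out$rt <- apply(as.matrix(rt_m), 1, stats::median, na.rm = TRUE)
  for (r in names(runs))
    out[[r]] <- runs[[r]]$intensity[match(ids, runs[[r]]$id)]
  out
}

#' Average technical replicates into biological samples
#'
#' Arithmetic mean of the technical-replicate columns belonging to each
#' biological sample; a singleton replicate passes through unchanged.
#'
#' @param intensities Numeric matrix or data frame, one column per technical
#'   run.
#' @param replicate_map Named character vector mapping run (column) name to
#'   biological sample name.
#' @return Matrix with one column per biological sample.
#' @export
average_technical_replicates <- function(intensities, replicate_map) {
  m <- as.matrix(intensities)
  if (is.null(colnames(m))) stop("intensity columns must be named")
  missing <- setdiff(colnames(m), names(replicate_map))
  if (length(missing))
    stop("run(s) absent from replicate map: ", paste(missing, collapse = ", "))
  bio <- unique(replicate_map[colnames(m)])
  out <- sapply(bio, function(b) {
    cols <- colnames(m)[replicate_map[colnames(m)] == b]
    if (length(cols) == 0L) stop("empty replicate group for sample ", b)
    rowMeans(m[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), bio))
  out
}

#' Welch test of one feature's intensities on the log2 scale
#'
#' Two-sided Welch t-test of `log2(intensity + pseudo)` between groups; the
#' log2 fold-change is the difference of group means on that scale. If both
#' groups are constant the p-value is 1 when the groups are equal and 0
#' otherwise; with fewer than 2 values in either group the p-value is NA
#' (flagged) but the fold-change is still returned.
#'
#' @param control,treated Non-negative intensity vectors.
#' @param pseudo Positive pseudo-intensity added before taking logs.
#' @return List with `p_value` and `log2fc` (treated minus control).
#' @export
test_feature <- function(control, treated, pseudo = 1) {
  if (pseudo <= 0) stop("pseudo must be > 0")
  if (any(c(control, treated) < 0)) stop("intensities must be >= 0")
  lc <- log2(control + pseudo)
  lt <- log2(treated + pseudo)
  log2fc <- mean(lt) - mean(lc)
  if (length(control) < 2L || length(treated) < 2L)
    return(list(p_value = NA_real_, log2fc = log2fc))
  p <- tryCatch(stats::t.test(lt, lc)$p.value,
                error = function(e) if (abs(log2fc) < 1e-12) 1 else 0)
  if (stats::sd(lc) == 0 && stats::sd(lt) == 0)
    p <- if (abs(log2fc) < 1e-12) 1 else 0
  list(p_value = p, log2fc = log2fc)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Signed fold-change display convention
#'
#' Maps a log2 fold-change to the ratio scale, with decreases shown as the
#' negative reciprocal: +2 means a doubling, -5 a five-fold decrease.
#' `abs(result) >= 1` always.
#'
#' @param log2fc Finite log2 fold-change (vectorized).
#' @return Signed fold-change.
#' @export
signed_fold_change <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  r <- 2^log2fc
  ifelse(r >= 1, r, -1 / r)
}

#' Feature-level differential abundance over a feature table
#'
#' Applies [test_feature()] to every feature, adjusts p-values with
#' [bh_adjust()], and reports the signed fold-change and direction.
#'
#' @param features Data frame with columns `id`, `mz`, `rt` and one intensity
#'   column per biological sample.
#' @param sample_groups Named character vector mapping sample column name to
#'   `"control"` or `"treated"`; every intensity column must be mapped.
#' @param pseudo Pseudo-intensity for [test_feature()].
#' @return Data frame with columns `id`, `mz`, `rt`, `signed_fold_change`,
#'   `log2fc`, `p_value`, `q_value`, `direction` (fixed order).
#' @export
diff_features <- function(features, sample_groups, pseudo = 1) {
  samp <- setdiff(names(features), c("id", "mz", "rt"))
  unmapped <- setdiff(samp, names(sample_groups))
  if (length(unmapped))
    stop("sample(s) not assigned to a group: ", paste(unmapped, collapse = ", "))
  grp <- sample_groups[samp]
  if (!all(grp %in% c("control", "treated")))
    stop("groups must be 'control' or 'treated'")
  ctrl <- samp[grp == "control"]
  trt <- samp[grp == "treated"]
  if (length(ctrl) == 0L || length(trt) == 0L)
    stop("both groups must contain at least one sample")
  res <- lapply(seq_len(nrow(features)), function(i) {
    test_feature(as.numeric(features[i, ctrl]), as.numeric(features[i, trt]),
                 pseudo = pseudo)
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  lfc <- vapply(res, `[[`, numeric(1), "log2fc")
  data.frame(
    id = features$id, mz = features$mz, rt = features$rt,
    signed_fold_change = signed_fold_change(lfc),
    log2fc = lfc,
    p_value = p,
    q_value = bh_adjust(p),
    direction = ifelse(lfc >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}
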