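# Count normalization and a deliberately simple differential-expression
# stage for gene-level count matrices: median-of-ratios size factors, Welch
# tests on log2 normalized counts, and BH-FDR. This is a documented
# simplified stand-in for a negative-binomial GLM engine; it is validated on
# synthetic ground truth, not intended to reproduce any particular tool's
# per-gene statistics.

#' Median-of-ratios size factors
#'
#' Per-sample scale factors: for each sample, the median across genes of the
#' ratio of its count to the gene's geometric mean across samples. Genes with
#' a zero count in any sample are excluded from the reference.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be >= 0")
  log_ref <- rowMeans(log(m))
  use <- is.finite(log_ref)
  if (!any(use))
    stop("no gene has a nonzero count in every sample")
  apply(m[use, , drop = FALSE], 2, function(col)
    stats::median(exp(log(col) - log_ref[use])))
}

#' Differential expression on a count matrix
#'
#' Normalizes by [size_factors()], then per gene applies a Welch test on
#' `log2(normalized count + pseudo)` via [test_feature()], adjusts with
#' [bh_adjust()], and reports the base mean (mean normalized count) and the
#' signed fold-change display value.
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param sample_groups Named character vector mapping sample to `"control"`
#'   or `"treated"`.
#' @param pseudo Pseudo-count added to normalized counts before logs.
#' @return Data frame `gene`, `base_mean`, `fold_change`, `log2fc`,
#'   `p_value`, `q_value`.
#' @export
de_test <- function(counts, sample_groups, pseudo = 1) {
  m <- as.matrix(counts)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs gene row names and sample column names")
  unmapped <- setdiff(colnames(m), names(sample_groups))
  if (length(unmapped))
    stop("sample(s) not assigned to a group: ", paste(unmapped, collapse = ", "))
  grp <- sample_groups[colnames(m)]
  ctrl <- colnames(m)[grp == "control"]
  trt <- colnames(m)[grp == "treated"]
  if (length(ctrl) < 2L || length(trt) < 2L)
    stop("need at least 2 samples per group")
  norm <- sweep(m, 2, size_factors(m), "/")
  res <- lapply(seq_len(nrow(norm)), function(i)
    test_feature(norm[i, ctrl], norm[i, trt], pseudo = pseudo))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  lfc <- vapply(res, `[[`, numeric(1), "log2fc")
  data.frame(
    gene = rownames(m),
    base_mean = rowMeans(norm),
    fold_change = signed_fold_change(lfc),
    log2fc = lfc,
    p_value = p,
    q_value = bh_adjust(p),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-level count matrix from a delimited file
#'
#' Tab-separated, first column gene id, one column per sample.
#'
#' @param path File path.
#' @return Integer matrix with gene row names.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
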