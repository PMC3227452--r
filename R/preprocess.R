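#' Quantile-normalize beta-value matrices
#'
#' Forces every sample column onto a common reference distribution — the
#' mean of the order statistics across all columns — to remove chip-level
#' distributional differences. Ties within a column receive the mean of the
#' reference values at the tied ranks; missing values are left missing.
#' Multiple tables are combined on their shared CpG set (with a warning if
#' the sets differ) and normalized together, so datasets from different
#' studies can be placed on one scale before joint analysis. The transform
#' is idempotent: normalizing a normalized table changes nothing.
#'
#' The heavy lifting is delegated to [limma::normalizeQuantiles()], the
#' standard implementation of this reference distribution and tie rule.
#'
#' @param ... One or more beta tables (`cpg_id` column plus numeric sample
#'   columns) sharing CpG ids.
#' @return A single normalized beta tibble over the common CpG set.
#' @examples
#' b <- tibble::tibble(cpg_id = c("a", "b", "c"),
#'                     s1 = c(0.1, 0.2, 0.3), s2 = c(0.4, 0.5, 0.6))
#' quantile_normalize(b)
#' @export
quantile_normalize <- function(...) {
  tabs <- list(...)
  if (!length(tabs)) abort("at least one beta table is required.")
  mats <- lapply(tabs, beta_matrix)
  common <- Reduce(intersect, lapply(mats, rownames))
  if (!length(common)) abort("no shared CpG ids across inputs.")
  if (any(vapply(mats, nrow, 1L) != length(common))) {
    warn(sprintf("CpG id sets differ; intersection of %d sites taken.",
                 length(common)))
  }
  m <- do.call(cbind, lapply(mats, function(x) x[common, , drop = FALSE]))
  check_beta_range(m)
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids across inputs.")
  if (ncol(m) < 2) abort("quantile normalization needs at least 2 samples.")
  nn <- colSums(!is.na(m))
  if (any(nn < 2)) {
    abort(paste0("columns with <2 non-missing values: ",
                 paste(colnames(m)[nn < 2], collapse = ", ")))
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  beta_tbl(out)
}

#' Divide each CpG row by its mean
#'
#' The heatmap transform used for displaying relative methylation: every
#' value is divided by its row (CpG) mean, so each row of the output
#' averages exactly 1.
#'
#' @param beta Beta table (`cpg_id` + sample columns).
#' @return Transformed tibble of the same shape.
#' @export
row_mean_scale <- function(beta) {
  m <- if (is.data.frame(beta)) beta_matrix(beta) else beta
  rm <- rowMeans(m, na.rm = TRUE)
  if (any(rm <= 0 | is.na(rm))) {
    abort(paste0("rows with non-positive mean: ",
                 paste(rownames(m)[rm <= 0 | is.na(rm)], collapse = ", ")))
  }
  beta_tbl(m / rm)
}

#' Dendrogram leaf order for heatmap display
#'
#' Agglomerative hierarchical clustering with Euclidean distance
#' (average linkage by default, the common viewer default) along the chosen
#' axis; returns the leaf labels in dendrogram order.
#'
#' @param beta Beta table.
#' @param axis `"cpg"` (rows) or `"sample"` (columns).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Character vector of labels in leaf order; the `hclust` object is
#'   attached as attribute `"hclust"`.
#' @export
hierarchical_order <- function(beta, axis = c("cpg", "sample"),
                               linkage = "average") {
  axis <- match.arg(axis)
  m <- beta_matrix(beta)
  if (axis == "sample") m <- t(m)
  if (nrow(m) < 2) abort("need at least 2 items to cluster.")
  hc <- hclust(dist(m, method = "euclidean"), method = linkage)
  structure(rownames(m)[hc$order], hclust = hc)
}

#' Select CpGs whose group-mean beta difference exceeds a threshold
#'
#' The scatter-plot filter: a CpG is hyper-methylated when
#' `mean(group2) - mean(group1) > threshold` and hypo-methylated when the
#' reverse difference exceeds it (strict inequality; the threshold is an
#' absolute beta difference, 0.15 meaning 15 percentage points of
#' methylation). Orientation: `group1` is the reference (e.g. early
#' passage), `group2` the comparison (late passage), so "hyper" means
#' methylation gained in `group2`.
#'
#' @param beta Beta table.
#' @param group1,group2 Character vectors of sample ids (disjoint,
#'   nonempty).
#' @param threshold Absolute beta difference that must be exceeded.
#' @return Tibble of exceeding CpGs: `cpg_id`, `mean_group1`,
#'   `mean_group2`, `delta_beta`, `direction` (`"hyper"`/`"hypo"`).
#' @examples
#' b <- tibble::tibble(cpg_id = c("a", "b"), s1 = c(0.1, 0.5),
#'                     s2 = c(0.1, 0.5), s3 = c(0.4, 0.5), s4 = c(0.4, 0.5))
#' delta_beta_filter(b, c("s1", "s2"), c("s3", "s4"))
#' @export
delta_beta_filter <- function(beta, group1, group2, threshold = 0.15) {
  m <- beta_matrix(beta)
  check_groups(m, group1, group2)
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1].")
  m1 <- rowMeans(m[, group1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(m[, group2, drop = FALSE], na.rm = TRUE)
  delta <- m2 - m1
  tibble(cpg_id = rownames(m), mean_group1 = m1, mean_group2 = m2,
         delta_beta = delta) %>%
    filter(abs(.data$delta_beta) > threshold) %>%
    mutate(direction = ifelse(.data$delta_beta > 0, "hyper", "hypo")) %>%
    arrange(desc(abs(.data$delta_beta)))
}
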