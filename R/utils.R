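#' Convert a beta-value tibble to a numeric matrix
#'
#' Beta-value tables travel through the package in their on-disk layout: a
#' `cpg_id` character column followed by one numeric column per sample.
#' `beta_matrix()` converts that layout to a CpG x sample numeric matrix with
#' `cpg_id` as rownames; [beta_tbl()] is the inverse.
#'
#' @param beta A data frame with a `cpg_id` column and numeric sample columns.
#' @return A numeric matrix (CpGs in rows, samples in columns).
#' @export
beta_matrix <- function(beta) {
  if (is.matrix(beta)) return(beta)
  stopifnot(is.data.frame(beta))
  if (!"cpg_id" %in% names(beta)) {
    abort("`beta` must contain a `cpg_id` column.")
  }
  ids <- as.character(beta$cpg_id)
  if (anyDuplicated(ids)) abort("`cpg_id` values must be unique.")
  m <- as.matrix(beta[setdiff(names(beta), "cpg_id")])
  if (!is.numeric(m)) abort("sample columns must be numeric beta values.")
  rownames(m) <- ids
  m
}

# Range check for tables that must hold raw beta fractions.
check_beta_range <- function(m) {
  v <- m[!is.na(m)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    abort("beta values must lie in [0, 1].")
  }
  invisible(m)
}

#' @rdname beta_matrix
#' @param m A numeric matrix with CpG rownames.
#' @export
beta_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  dplyr::bind_cols(tibble(cpg_id = rownames(m)), as_tibble(m))
}

# Two disjoint, nonempty sample groups resolved against matrix columns.
check_groups <- function(m, group1, group2) {
  if (!length(group1) || !length(group2)) abort("both groups must be nonempty.")
  if (length(intersect(group1, group2))) {
    abort("sample groups overlap; they must be disjoint.")
  }
  missing <- setdiff(c(group1, group2), colnames(m))
  if (length(missing)) {
    abort(paste0("samples not found in the beta matrix: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# Deterministic child seeds from one master seed (kept below 2^31).
child_seed <- function(seed, stream) {
  (as.integer(seed) + 1103L * as.integer(stream)) %% 2147483562L + 1L
}

# Drop CpGs with any missing beta value, reporting the count.
drop_incomplete_cpgs <- function(m, quiet = FALSE) {
  keep <- complete.cases(m)
  if (!all(keep) && !quiet) {
    inform(sprintf("dropped %d CpG sites with missing beta values", sum(!keep)))
  }
  m[keep, , drop = FALSE]
}
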