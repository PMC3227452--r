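#' A chromatin-mark target set
#'
#' Holds a named set of targets from a published ChIP experiment
#' (e.g. H3K4me3, H3K27me3, H3K9me3 marks or EZH2 binding), exposed as a
#' RefSeq-ID list and/or genomic intervals. Intervals use the BED
#' convention (0-based half-open) on disk and in this structure.
#'
#' @param name Category name (nonempty).
#' @param refseq_ids Character vector of RefSeq accessions (versions
#'   allowed; stripped at matching time).
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), or `NULL`.
#' @param source Free-text provenance label (e.g. `"hESC"`, `"MSC-AT"`).
#' @return A `mark_set` object.
#' @export
mark_set <- function(name, refseq_ids = character(),
                     intervals = NULL, source = NA_character_) {
  if (!nzchar(name)) abort("mark set name must be nonempty.")
  if (is.null(intervals)) {
    intervals <- tibble(chrom = character(), start = integer(), end = integer())
  }
  intervals <- as_tibble(intervals)
  if (!all(c("chrom", "start", "end") %in% names(intervals))) {
    abort("intervals need columns chrom, start, end.")
  }
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    abort("intervals must satisfy start < end (0-based half-open).")
  }
  structure(list(name = name, source = source,
                 refseq_ids = unique(as.character(refseq_ids)),
                 intervals = intervals),
            class = "mark_set")
}

#' @export
print.mark_set <- function(x, ...) {
  cat(sprintf("mark set '%s' (%s): %d RefSeq ids, %d intervals\n",
              x$name, x$source, length(x$refseq_ids), nrow(x$intervals)))
  invisible(x)
}

strip_refseq_version <- function(x) sub("\\.\\d+$", "", x)

#' Map CpG sites onto a chromatin-mark target set
#'
#' A CpG belongs to the category if its RefSeq accession (version
#' stripped) appears in the set's ID list, or if its coordinate expanded by
#' `window` base pairs up- and down-stream touches any of the set's
#' intervals. Both matching paths are recorded. Position matching compares
#' the closed probe window `[pos - window, pos + window]` directly against
#' the stored BED coordinates, so an interval starting at coordinate
#' `pos + window` still matches while `pos + window + 1` does not.
#'
#' @param annotation Probe annotation: `cpg_id`, `refseq_id`, `chrom`,
#'   `pos` (1-based).
#' @param mark A [mark_set()].
#' @param window Flank in base pairs on each side of the CpG coordinate.
#' @return Tibble of member CpGs: `cpg_id`, `category`, `match_path`
#'   (`"refseq"`, `"position"` or `"both"`).
#' @export
match_cpg_to_mark <- function(annotation, mark, window = 100) {
  stopifnot(inherits(mark, "mark_set"))
  ann <- as_tibble(annotation)
  req <- c("cpg_id", "refseq_id", "chrom", "pos")
  if (!all(req %in% names(ann))) {
    abort(paste0("annotation needs columns: ", paste(req, collapse = ", ")))
  }
  by_id <- strip_refseq_version(ann$refseq_id) %in%
    strip_refseq_version(mark$refseq_ids)
  by_pos <- rep(FALSE, nrow(ann))
  iv <- mark$intervals
  if (nrow(iv)) {
    shared <- intersect(unique(ann$chrom), unique(iv$chrom))
    if (!length(shared)) {
      abort(paste0("chromosome naming mismatch between annotation (",
                   paste(head(unique(ann$chrom), 3), collapse = ", "),
                   ", ...) and mark intervals (",
                   paste(head(unique(iv$chrom), 3), collapse = ", "), ", ...)"))
    }
    q <- GenomicRanges::GRanges(ann$chrom,
                                IRanges::IRanges(ann$pos - window, ann$pos + window))
    s <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
    hit <- GenomicRanges::countOverlaps(q, s) > 0
    by_pos <- as.logical(hit)
  }
  member <- by_id | by_pos
  tibble(cpg_id = ann$cpg_id[member], category = mark$name,
         match_path = case_when(by_id[member] & by_pos[member] ~ "both",
                                by_id[member] ~ "refseq",
                                TRUE ~ "position"))
}

#' @rdname match_cpg_to_mark
#' @param marks A list of [mark_set()] objects.
#' @export
match_cpg_to_marks <- function(annotation, marks, window = 100) {
  purrr::map_dfr(marks, match_cpg_to_mark, annotation = annotation,
                 window = window)
}

#' Restrict a category to members not found in other categories
#'
#' Set algebra over computed membership maps, used to build mutually
#' exclusive variants such as "H3K27me3 only" (sites carrying H3K27me3 but
#' not H3K4me3).
#'
#' @param membership Tibble of `cpg_id`, `category` rows (as returned by
#'   [match_cpg_to_marks()]).
#' @param include Category whose members to keep.
#' @param exclude Categories whose members to remove.
#' @param name Name of the derived category (default
#'   `"<include>_only"`).
#' @return Membership tibble for the derived category.
#' @export
exclusive_membership <- function(membership, include, exclude,
                                 name = paste0(include, "_only")) {
  inc <- membership$cpg_id[membership$category == include]
  exc <- membership$cpg_id[membership$category %in% exclude]
  tibble(cpg_id = setdiff(inc, exc), category = name)
}

#' Methylation summaries per chromatin category
#'
#' For each category (plus the mandatory `"all"` category covering every
#' CpG in the matrix) summarizes the distribution of CpG-wise mean beta
#' values over the selected samples: median, quartiles and the 5th/95th
#' percentiles — the numbers behind box-plot comparisons of marks against
#' the array-wide background. Empty categories are reported with `NA`
#' summaries rather than dropped.
#'
#' @param beta Beta table.
#' @param membership Membership tibble (`cpg_id`, `category`).
#' @param samples Optional character vector restricting the sample columns.
#' @param categories Optional category names to report even when they have
#'   no members.
#' @return Tibble: `category`, `n_cpg`, `median`, `q25`, `q75`, `p05`,
#'   `p95` (beta fractions).
#' @export
methylation_by_category <- function(beta, membership, samples = NULL,
                                    categories = NULL) {
  m <- beta_matrix(beta)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) abort(paste0("unknown samples: ", paste(missing, collapse = ", ")))
    m <- m[, samples, drop = FALSE]
  }
  stray <- setdiff(membership$cpg_id, rownames(m))
  if (length(stray)) {
    abort(paste0("membership CpGs absent from the matrix: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  cpg_mean <- rowMeans(m, na.rm = TRUE)
  summarise_one <- function(v) {
    if (!length(v)) {
      return(tibble(n_cpg = 0L, median = NA_real_, q25 = NA_real_,
                    q75 = NA_real_, p05 = NA_real_, p95 = NA_real_))
    }
    q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE)
    tibble(n_cpg = length(v), median = q[[3]], q25 = q[[2]], q75 = q[[4]],
           p05 = q[[1]], p95 = q[[5]])
  }
  cats <- union(unique(membership$category), categories)
  out <- purrr::map_dfr(cats, function(cat) {
    ids <- unique(membership$cpg_id[membership$category == cat])
    dplyr::bind_cols(tibble(category = cat), summarise_one(cpg_mean[ids]))
  })
  bind_rows(dplyr::bind_cols(tibble(category = "all"), summarise_one(cpg_mean)),
            out)
}

#' Box-plot style display of per-category methylation levels
#'
#' @param summary Output of [methylation_by_category()].
#' @return A ggplot object (crossbars for quartiles, whiskers at the
#'   5th/95th percentiles).
#' @export
plot_category_beta <- function(summary) {
  dat <- summary %>% filter(!is.na(.data$median))
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$category, .data$median))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p05, ymax = .data$p95),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q25,
                                        ymax = .data$q75), fill = "grey85") +
    ggplot2::labs(x = NULL, y = "mean beta value per CpG") +
    ggplot2::coord_flip() + ggplot2::theme_minimal()
}
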