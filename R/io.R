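# Tabular I/O for the formats the pipeline consumes and emits: beta-value
# TSV (cpg_id + one column per sample, the series-matrix-style export),
# sample sheet CSV, probe annotation TSV, mark sets as RefSeq lists or BED,
# dilution and growth CSVs, JSON run manifests.

#' Read and write beta-value tables
#'
#' The on-disk layout is a TSV whose first column is `cpg_id` followed by
#' one numeric column per sample (the usual series-matrix export of array
#' beta values).
#'
#' @param path File path.
#' @return [read_beta_tsv()] returns a tibble; the writers return `path`
#'   invisibly.
#' @export
read_beta_tsv <- function(path) {
  b <- readr::read_tsv(path, show_col_types = FALSE)
  names(b)[1] <- "cpg_id"
  check_beta_range(beta_matrix(b))
  b
}

#' @rdname read_beta_tsv
#' @param beta Beta tibble.
#' @export
write_beta_tsv <- function(beta, path) {
  readr::write_tsv(beta, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `tissue`, `donor_id`, `passage_class`,
#' `passage_number`, `gender`.
#'
#' @param path File path.
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("sample_id", "tissue", "donor_id", "passage_class")
  if (!all(req %in% names(s))) {
    abort(paste0("sample sheet needs columns: ", paste(req, collapse = ", ")))
  }
  s
}

#' Read a CpG probe annotation table
#'
#' TSV with columns `cpg_id`, `refseq_id`, `chrom`, `pos` (1-based) and
#' optionally `strand`.
#'
#' @param path File path.
#' @export
read_annotation <- function(path) {
  a <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("cpg_id", "refseq_id", "chrom", "pos")
  if (!all(req %in% names(a))) {
    abort(paste0("annotation needs columns: ", paste(req, collapse = ", ")))
  }
  a
}

#' Read a chromatin-mark target set
#'
#' `read_mark_refseq()` reads a one-accession-per-line text file;
#' `read_mark_bed()` reads a BED file (0-based half-open intervals, first
#' three columns used) via `rtracklayer`.
#'
#' @param path File path.
#' @param name Category name; defaults to the file name without extension.
#' @param source Provenance label.
#' @return A [mark_set()].
#' @export
read_mark_refseq <- function(path, name = NULL, source = NA_character_) {
  ids <- readr::read_lines(path)
  ids <- trimws(ids[nzchar(trimws(ids))])
  mark_set(name %||% sub("\\.[^.]*$", "", basename(path)),
           refseq_ids = ids, source = source)
}

#' @rdname read_mark_refseq
#' @export
read_mark_bed <- function(path, name = NULL, source = NA_character_) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading BED requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "BED")
  iv <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,  # back to 0-based
               end = GenomicRanges::end(gr))
  mark_set(name %||% sub("\\.[^.]*$", "", basename(path)),
           intervals = iv, source = source)
}

#' @rdname read_mark_refseq
#' @param mark A [mark_set()].
#' @export
write_mark_bed <- function(mark, path) {
  readr::write_tsv(mark$intervals, path, col_names = FALSE)
  invisible(path)
}

#' @rdname read_mark_refseq
#' @export
write_mark_refseq <- function(mark, path) {
  readr::write_lines(mark$refseq_ids, path)
  invisible(path)
}

#' Read limiting-dilution and growth-series CSVs
#'
#' Dilution files carry `dose`, `wells_total`, `wells_positive`; growth
#' files `passage`, `seeded`, `harvested` and optionally `f`, `days`.
#'
#' @param path File path.
#' @export
read_dilution_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("dose", "wells_total", "wells_positive")
  if (!all(req %in% names(d))) {
    abort(paste0("dilution file needs columns: ", paste(req, collapse = ", ")))
  }
  d
}

#' @rdname read_dilution_csv
#' @export
read_growth_csv <- function(path) {
  check_growth_series(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed, package version, per-stage row counts
#' and output-file checksums of a pipeline run.
#'
#' @param manifest A named list.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$software <- paste0("senemeth ",
                              as.character(utils::packageVersion("senemeth")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
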