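#' Configuration for the synthetic methylation-array generator
#'
#' Bundles every knob of [simulate_methylation()] with validated defaults that
#' emulate a promoter CpG array study of cultured mesenchymal stromal cells:
#' a bimodal beta-value background whose array-wide median sits near 5%, a
#' planted set of senescence-associated (SA) CpG sites that shift between
#' early and late passage, a larger planted tissue signature separating
#' adipose-derived from bone-marrow-derived samples, and chromatin-mark
#' target categories that preferentially occupy the high-methylation stratum
#' and are over-represented among the planted SA sites.
#'
#' @param n_cpg Number of CpG sites on the simulated array.
#' @param samples Sample sheet: a data frame with columns `sample_id`,
#'   `tissue` (`"AT"`, `"BM"`, `"Hip"`, ...), `donor_id`, `passage_class`
#'   (`"early"` or `"late"`), `passage_number`, `gender`. Defaults to a
#'   paired design of 4 adipose, 3 bone-marrow and 3 hip donors, each
#'   profiled at an early and a late passage (see [default_samples()]).
#' @param low_frac Fraction of CpGs in the low-methylation (promoter)
#'   stratum.
#' @param low_mean,low_precision Mean and beta-distribution precision
#'   (`shape1 + shape2`) of the low stratum baseline.
#' @param high_mean,high_precision Same for the high-methylation stratum.
#' @param n_sa_planted Number of planted senescence-associated CpGs.
#' @param sa_delta Planted mean beta shift between passage classes
#'   (fraction, early vs late).
#' @param sa_hyper_frac Fraction of planted SA sites that gain methylation
#'   with passage (the remainder lose it).
#' @param n_tissue_planted,tissue_delta Planted tissue-specific sites
#'   (adipose vs bone-marrow contrast) and their mean shift.
#' @param marks Mark-category layout: data frame with columns `name`, `size`,
#'   `high_frac` (fraction of members drawn from the high stratum) and
#'   `sa_enrichment` (relative over-representation of planted SA sites
#'   inside the category; 1 = none). See [default_marks()].
#' @param noise_precision Beta-distribution precision of per-sample noise
#'   around each CpG's group mean.
#' @param mark_id_frac Fraction of each category's members exposed through
#'   the RefSeq-ID list of the mark set.
#' @param mark_interval_frac Fraction exposed through genomic intervals
#'   centred on the CpG coordinate (both paths may cover a member).
#' @param rng_seed Integer master seed; identical seeds give identical
#'   output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_cpg = 27578,
                         samples = default_samples(),
                         low_frac = 0.75,
                         low_mean = 0.05, low_precision = 15,
                         high_mean = 0.50, high_precision = 6,
                         n_sa_planted = 517,
                         sa_delta = 0.25,
                         sa_hyper_frac = 0.30,
                         n_tissue_planted = 2000,
                         tissue_delta = 0.25,
                         marks = default_marks(),
                         noise_precision = 200,
                         mark_id_frac = 0.8,
                         mark_interval_frac = 0.4,
                         rng_seed = 1L) {
  samples <- as_tibble(samples)
  req <- c("sample_id", "tissue", "donor_id", "passage_class",
           "passage_number", "gender")
  if (!all(req %in% names(samples))) {
    abort(paste0("`samples` must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in `samples`.")
  if (!all(samples$passage_class %in% c("early", "late", "senescent"))) {
    abort("passage_class must be early/late/senescent.")
  }
  if (is.null(marks)) {
    marks <- tibble(name = character(), size = integer(),
                    high_frac = double(), sa_enrichment = double())
  }
  marks <- as_tibble(marks)
  if (nrow(marks) &&
      !all(c("name", "size", "high_frac", "sa_enrichment") %in% names(marks))) {
    abort("`marks` needs columns name, size, high_frac, sa_enrichment.")
  }
  cfg <- list(
    n_cpg = as.integer(n_cpg), samples = samples,
    low_frac = low_frac, low_mean = low_mean, low_precision = low_precision,
    high_mean = high_mean, high_precision = high_precision,
    n_sa_planted = as.integer(n_sa_planted), sa_delta = sa_delta,
    sa_hyper_frac = sa_hyper_frac,
    n_tissue_planted = as.integer(n_tissue_planted),
    tissue_delta = tissue_delta,
    marks = marks, noise_precision = noise_precision,
    mark_id_frac = mark_id_frac, mark_interval_frac = mark_interval_frac,
    rng_seed = as.integer(rng_seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_cpg < 1) abort("n_cpg must be positive.")
    if (n_sa_planted + n_tissue_planted > n_cpg) {
      abort("planted counts exceed n_cpg.")
    }
    if (nrow(marks) && any(marks$size > n_cpg)) {
      abort("mark category sizes exceed n_cpg.")
    }
    if (sa_delta < 0 || sa_delta >= 1 || tissue_delta < 0 || tissue_delta >= 1) {
      abort("deltas must lie in [0, 1).")
    }
    if (nrow(marks) && any(marks$sa_enrichment < 0)) {
      abort("sa_enrichment must be >= 0.")
    }
    if (low_frac < 0 || low_frac > 1) abort("low_frac must be in [0, 1].")
    for (p in c(low_mean, high_mean)) {
      if (p <= 0 || p >= 1) abort("stratum means must be in (0, 1).")
    }
    if (min(low_precision, high_precision, noise_precision) <= 0) {
      abort("precisions must be positive.")
    }
  })
  invisible(cfg)
}

#' @rdname synth_config
#' @param n_at,n_bm,n_hip Donor counts per tissue in the default paired
#'   design.
#' @export
default_samples <- function(n_at = 4, n_bm = 3, n_hip = 3) {
  tissues <- rep(c("AT", "BM", "Hip"), times = c(n_at, n_bm, n_hip))
  n_donor <- length(tissues)
  donors <- sprintf("donor%02d", seq_len(n_donor))
  genders <- rep(c("F", "M"), length.out = n_donor)
  tibble(
    sample_id = paste0(rep(donors, each = 2), "_", rep(c("early", "late"), n_donor)),
    tissue = rep(tissues, each = 2),
    donor_id = rep(donors, each = 2),
    passage_class = rep(c("early", "late"), n_donor),
    passage_number = rep(c(5L, 10L), n_donor),
    gender = rep(genders, each = 2))
}

#' @rdname synth_config
#' @export
default_marks <- function() {
  tibble(
    name = c("H3K4me3_hESC", "H3K4me3_MSC", "H3K27me3_hESC",
             "H3K27me3_MSC", "H3K9me3_MSC", "EZH2_MSCBM"),
    size = c(9000L, 8000L, 3500L, 2500L, 1500L, 2500L),
    high_frac = c(0.05, 0.08, 0.60, 0.85, 0.85, 0.70),
    sa_enrichment = c(1, 1, 5, 5, 5, 5))
}
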