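#' Simulate a promoter methylation array with known ground truth
#'
#' Draws a CpG x sample beta-value table from a two-stratum background
#' mixture, plants senescence-associated and tissue-specific mean shifts,
#' assigns chromatin-mark target categories biased toward the
#' high-methylation stratum and over-represented among the planted
#' senescence-associated (SA) sites, and synthesises a probe annotation on a
#' small artificial genome. Every random choice derives from
#' `config$rng_seed`, so a given configuration is bit-reproducible.
#'
#' Shifts act additively on the beta scale; group means are clipped to
#' `[0.001, 0.999]` before per-sample noise is drawn from a beta
#' distribution parameterized by mean and precision, and the drawn values
#' are clipped to the same range. Hyper-methylating SA sites are planted
#' only where the baseline leaves room for the shift (and conversely for
#' hypo-methylating sites), so the realized group difference matches
#' `sa_delta` in expectation.
#'
#' @param config A [synth_config()].
#' @return A list with elements `beta` (tibble: `cpg_id` + one column per
#'   sample), `samples` (the sample sheet), `annotation` (tibble: `cpg_id`,
#'   `refseq_id`, `chrom`, `pos`, `strand`), `marks` (a list of
#'   [mark_set()] objects), and `truth` (list: `sa_hyper_ids`,
#'   `sa_hypo_ids`, `tissue_ids`, `membership` tibble of `cpg_id`,
#'   `category`, and `enrichment` — the realized SA odds ratio per
#'   category).
#' @seealso [simulate_dilution()], [simulate_growth()]
#' @examples
#' sim <- simulate_methylation(synth_config(n_cpg = 500, n_sa_planted = 20,
#'                                          n_tissue_planted = 40,
#'                                          marks = NULL, rng_seed = 7))
#' dim(beta_matrix(sim$beta))
#' @export
simulate_methylation <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  cfg <- config
  if (is.null(cfg$marks)) cfg$marks <- tibble(name = character(), size = integer(),
                                              high_frac = double(),
                                              sa_enrichment = double())
  n <- cfg$n_cpg
  ids <- sprintf("cg%07d", seq_len(n))

  set.seed(child_seed(cfg$rng_seed, 1L))
  n_low <- round(n * cfg$low_frac)
  stratum <- rep(c("low", "high"), times = c(n_low, n - n_low))
  stratum <- sample(stratum)
  baseline <- numeric(n)
  lo <- stratum == "low"
  baseline[lo]  <- rbeta(sum(lo), cfg$low_mean * cfg$low_precision,
                         (1 - cfg$low_mean) * cfg$low_precision)
  baseline[!lo] <- rbeta(sum(!lo), cfg$high_mean * cfg$high_precision,
                         (1 - cfg$high_mean) * cfg$high_precision)
  baseline <- pmin(pmax(baseline, 0.001), 0.999)

  # Mark categories: round(size * high_frac) members from the high stratum,
  # the remainder from the low stratum.
  set.seed(child_seed(cfg$rng_seed, 2L))
  membership <- purrr::pmap_dfr(cfg$marks, function(name, size, high_frac, ...) {
    n_hi <- min(round(size * high_frac), sum(!lo))
    n_lo <- min(size - n_hi, sum(lo))
    mem <- c(sample(which(!lo), n_hi), sample(which(lo), n_lo))
    tibble(cpg_id = ids[sort(mem)], category = name)
  })

  # Plant SA sites with weighted sampling: a CpG inside a category with
  # sa_enrichment e is e times as likely to be picked as one outside.
  set.seed(child_seed(cfg$rng_seed, 3L))
  w <- rep(1, n)
  if (nrow(membership)) {
    idx <- split(match(membership$cpg_id, ids), membership$category)
    for (cat in names(idx)) {
      e <- cfg$marks$sa_enrichment[cfg$marks$name == cat]
      w[idx[[cat]]] <- pmax(w[idx[[cat]]], e)
    }
  }
  sa_idx <- if (cfg$n_sa_planted > 0) {
    sort(sample.int(n, cfg$n_sa_planted, prob = w))
  } else integer()

  # Direction: hyper sites need headroom above, hypo sites below.
  margin <- 0.02
  n_hyper <- round(cfg$n_sa_planted * cfg$sa_hyper_frac)
  can_hypo <- baseline[sa_idx] > cfg$sa_delta + margin
  can_hyper <- baseline[sa_idx] < 1 - cfg$sa_delta - margin
  hypo_pool <- sa_idx[can_hypo]
  n_hypo <- min(cfg$n_sa_planted - n_hyper, length(hypo_pool))
  sa_hypo <- if (n_hypo > 0) sample(hypo_pool, n_hypo) else integer()
  hyper_pool <- setdiff(sa_idx[can_hyper], sa_hypo)
  sa_hyper <- if (length(hyper_pool)) {
    sample(hyper_pool, min(cfg$n_sa_planted - n_hypo, length(hyper_pool)))
  } else integer()

  # Tissue signature planted with balanced direction (about as many sites
  # gain as lose methylation in the adipose samples, as in real cross-tissue
  # comparisons); each direction is drawn from the baselines that can
  # accommodate the shift.
  set.seed(child_seed(cfg$rng_seed, 4L))
  free <- setdiff(seq_len(n), c(sa_hyper, sa_hypo))
  tis_up <- tis_dn <- integer()
  if (cfg$n_tissue_planted > 0) {
    up_pool <- free[baseline[free] < 1 - cfg$tissue_delta - margin]
    dn_pool <- free[baseline[free] > cfg$tissue_delta + margin]
    n_up <- min(ceiling(cfg$n_tissue_planted / 2), length(up_pool))
    tis_up <- sample(up_pool, n_up)
    dn_pool <- setdiff(dn_pool, tis_up)
    tis_dn <- sample(dn_pool, min(cfg$n_tissue_planted - n_up, length(dn_pool)))
  }
  tis_idx <- c(tis_up, tis_dn)
  tis_sign <- rep(c(1, -1), c(length(tis_up), length(tis_dn)))
  ord <- order(tis_idx)
  tis_idx <- tis_idx[ord]; tis_sign <- tis_sign[ord]

  # Group means and per-sample beta noise.
  set.seed(child_seed(cfg$rng_seed, 5L))
  smp <- cfg$samples
  late <- smp$passage_class != "early"
  at <- smp$tissue == "AT"
  vals <- matrix(NA_real_, n, nrow(smp), dimnames = list(ids, smp$sample_id))
  for (j in seq_len(nrow(smp))) {
    mu <- baseline
    if (late[j]) {
      mu[sa_hyper] <- mu[sa_hyper] + cfg$sa_delta
      mu[sa_hypo]  <- mu[sa_hypo] - cfg$sa_delta
    }
    if (at[j] && length(tis_idx)) mu[tis_idx] <- mu[tis_idx] + tis_sign * cfg$tissue_delta
    mu <- pmin(pmax(mu, 0.001), 0.999)
    v <- rbeta(n, mu * cfg$noise_precision, (1 - mu) * cfg$noise_precision)
    vals[, j] <- pmin(pmax(v, 0.001), 0.999)
  }

  annotation <- synth_annotation(ids, cfg)
  marks <- synth_mark_sets(membership, annotation, cfg)

  enr <- realized_enrichment(membership, ids[c(sa_hyper, sa_hypo)], ids)
  truth <- list(
    sa_hyper_ids = ids[sort(sa_hyper)],
    sa_hypo_ids = ids[sort(sa_hypo)],
    tissue_ids = ids[tis_idx],
    stratum = setNames(stratum, ids),
    baseline = setNames(baseline, ids),
    membership = membership,
    enrichment = enr)

  list(beta = beta_tbl(vals), samples = smp, annotation = annotation,
       marks = marks, truth = truth)
}

# One RefSeq id per CpG; coordinates laid out on 22 artificial chromosomes.
synth_annotation <- function(ids, cfg) {
  n <- length(ids)
  chrom_n <- min(22L, max(1L, n %/% 50L + 1L))
  chrom <- paste0("chr", rep_len(seq_len(chrom_n), n))
  pos <- integer(n)
  for (c in unique(chrom)) {
    k <- sum(chrom == c)
    pos[chrom == c] <- seq(5000L, by = 1000L, length.out = k)
  }
  tibble(cpg_id = ids,
         refseq_id = sprintf("NM_%06d", seq_len(n)),
         chrom = chrom, pos = pos, strand = "+")
}

# Expose each category through a RefSeq list and/or BED-like intervals so
# both matching paths of match_cpg_to_mark() get exercised.
synth_mark_sets <- function(membership, annotation, cfg) {
  if (!nrow(membership)) return(list())
  set.seed(child_seed(cfg$rng_seed, 6L))
  out <- list()
  for (cat in unique(membership$category)) {
    mem <- membership$cpg_id[membership$category == cat]
    ann <- annotation[match(mem, annotation$cpg_id), ]
    k <- length(mem)
    by_id <- sample(k, round(k * cfg$mark_id_frac))
    by_iv <- sample(k, round(k * cfg$mark_interval_frac))
    # members exposed neither way would be silently lost
    orphan <- setdiff(seq_len(k), union(by_id, by_iv))
    by_id <- union(by_id, orphan)
    intervals <- tibble(chrom = ann$chrom[by_iv],
                        start = pmax(ann$pos[by_iv] - 51L, 0L),
                        end = ann$pos[by_iv] + 50L)
    src <- sub("^[^_]+_", "", cat)
    out[[cat]] <- mark_set(name = cat, source = src,
                           refseq_ids = ann$refseq_id[by_id],
                           intervals = intervals)
  }
  out
}

# Realized SA odds ratio per category: (inside rate) / (outside rate).
realized_enrichment <- function(membership, sa_ids, universe) {
  if (!nrow(membership)) return(tibble(category = character(), enrichment = double()))
  membership %>%
    group_by(.data$category) %>%
    summarise(K = dplyr::n(),
              k = sum(.data$cpg_id %in% sa_ids), .groups = "drop") %>%
    mutate(N = length(universe), n_sa = length(sa_ids),
           enrichment = (.data$k / .data$K) /
             pmax((.data$n_sa - .data$k) / (.data$N - .data$K), 1e-12)) %>%
    select("category", "K", "k", "enrichment")
}
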