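#' Tissue-contrast analysis
#'
#' The cross-tissue arm of the pipeline: quantile normalization of the
#' combined dataset, the delta-beta scatter filter between the two tissue
#' groups (early-passage samples), unpaired SAM with permutation FDR, and —
#' when a term map is supplied — Fisher exact enrichment of the genes
#' linked to the SAM-selected CpGs.
#'
#' @param beta Beta table (`cpg_id` + sample columns).
#' @param meta Sample sheet (must cover every sample column).
#' @param group1,group2 Sample ids of the two tissue groups (disjoint).
#' @param annotation Optional probe annotation (needed for gene-level
#'   enrichment).
#' @param term_map Optional term -> gene-set map for
#'   [fisher_set_enrichment()].
#' @param delta_threshold Delta-beta filter threshold.
#' @param fdr_target SAM target FDR.
#' @param B,seed,s0 Passed to [sam_test()].
#' @return A list of class `tissue_report`: `delta_table`, `sam` (the
#'   fit), `selection`, `heatmap_order`, `enrichment` (or `NULL`),
#'   `manifest`.
#' @export
run_tissue_contrast <- function(beta, meta, group1, group2,
                                annotation = NULL, term_map = NULL,
                                delta_threshold = 0.15, fdr_target = 0.05,
                                B = 1000, seed = 1L, s0 = "auto") {
  m <- beta_matrix(beta)
  check_groups(m, group1, group2)
  norm <- quantile_normalize(beta)
  nm <- drop_incomplete_cpgs(beta_matrix(norm))
  sub <- nm[, c(group1, group2), drop = FALSE]

  delta_table <- delta_beta_filter(beta_tbl(nm), group1, group2,
                                   threshold = delta_threshold)
  labels <- rep(c("group1", "group2"), c(length(group1), length(group2)))
  fit <- sam_test(sub, labels, mode = "unpaired", fdr_target = fdr_target,
                  B = B, seed = seed, s0 = s0)
  sel <- fit$selection

  heat_order <- if (sel$called >= 2) {
    hierarchical_order(beta_tbl(sub[sel$cpg_ids, , drop = FALSE]), "cpg")
  } else character(0)

  enrichment <- NULL
  if (!is.null(term_map) && !is.null(annotation) && sel$called > 0) {
    ann <- as_tibble(annotation)
    genes <- strip_refseq_version(ann$refseq_id[ann$cpg_id %in% sel$cpg_ids])
    uni <- strip_refseq_version(ann$refseq_id[ann$cpg_id %in% rownames(nm)])
    enrichment <- fisher_set_enrichment(term_map, unique(genes), unique(uni))
  }

  manifest <- list(
    stage_counts = list(cpg_in = nrow(m), cpg_complete = nrow(nm),
                        delta_hyper = sum(delta_table$direction == "hyper"),
                        delta_hypo = sum(delta_table$direction == "hypo"),
                        sam_called = sel$called),
    thresholds = list(delta_beta = delta_threshold, fdr = fdr_target),
    seed = seed)
  structure(list(delta_table = delta_table, sam = fit, selection = sel,
                 heatmap_order = heat_order, enrichment = enrichment,
                 normalized = beta_tbl(nm), manifest = manifest),
            class = "tissue_report")
}

#' Senescence (early vs late passage) analysis
#'
#' The main arm of the pipeline: quantile normalization, PCA with a report
#' of which components separate tissue and passage class, the delta-beta
#' filter on the adipose-tissue subset (early vs late), paired-by-donor SAM
#' across all tissues, the hyper/hypo split of the selected
#' senescence-associated (SA) set, mapping onto chromatin-mark target sets,
#' per-category methylation summaries and hypergeometric enrichment of the
#' SA set in every category.
#'
#' @param beta Beta table.
#' @param meta Sample sheet with `sample_id`, `tissue`, `donor_id`,
#'   `passage_class`.
#' @param annotation Probe annotation (required for mark overlap).
#' @param marks List of [mark_set()] objects (may be empty).
#' @param delta_threshold,fdr_target,B,seed,s0 As in
#'   [run_tissue_contrast()].
#' @param window Flank for [match_cpg_to_marks()].
#' @param delta_tissue Tissue label used for the delta-beta subset
#'   (default `"AT"`).
#' @return A list of class `senescence_report` with elements `pca`,
#'   `pc_tissue`, `pc_passage`, `delta_table`, `sam`, `selection`,
#'   `membership`, `category_summary`, `enrichment`, `normalized`,
#'   `manifest`.
#' @export
run_senescence_analysis <- function(beta, meta, annotation = NULL,
                                    marks = list(), delta_threshold = 0.15,
                                    fdr_target = 0.05, B = 1000, seed = 1L,
                                    s0 = "auto", window = 100,
                                    delta_tissue = "AT") {
  meta <- as_tibble(meta)
  m <- beta_matrix(beta)
  missing_meta <- setdiff(colnames(m), meta$sample_id)
  if (length(missing_meta)) {
    abort(paste0("samples without metadata: ", paste(missing_meta, collapse = ", ")))
  }
  meta <- meta[match(colnames(m), meta$sample_id), ]

  norm <- quantile_normalize(beta)
  nm <- drop_incomplete_cpgs(beta_matrix(norm))

  pca <- beta_pca(beta_tbl(nm), meta = meta)
  pc_tissue <- pc_association(pca, "tissue")
  pc_passage <- pc_association(pca, "passage_class")

  at_early <- meta$sample_id[meta$tissue == delta_tissue &
                             meta$passage_class == "early"]
  at_late <- meta$sample_id[meta$tissue == delta_tissue &
                            meta$passage_class != "early"]
  delta_table <- if (length(at_early) && length(at_late)) {
    delta_beta_filter(beta_tbl(nm), at_early, at_late, delta_threshold)
  } else tibble()

  fit <- sam_test(nm, labels = meta$passage_class, mode = "paired",
                  pairs = meta$donor_id, fdr_target = fdr_target,
                  B = B, seed = seed, s0 = s0)
  sel <- fit$selection

  membership <- if (length(marks) && !is.null(annotation)) {
    match_cpg_to_marks(annotation, marks, window = window)
  } else tibble(cpg_id = character(), category = character(),
                match_path = character())
  membership <- semi_join(membership, tibble(cpg_id = rownames(nm)),
                          by = "cpg_id")

  early_ids <- meta$sample_id[meta$passage_class == "early"]
  category_summary <- if (nrow(membership)) {
    bind_rows(methylation_by_category(beta_tbl(nm), membership,
                                      samples = early_ids),
              methylation_by_category(
                beta_tbl(nm),
                tibble(cpg_id = sel$cpg_ids, category = "SA_CpG"),
                samples = early_ids) %>% filter(.data$category == "SA_CpG"))
  } else tibble()

  enrichment <- if (nrow(membership) && sel$called > 0) {
    hypergeom_enrichment(sel$cpg_ids, membership, universe = rownames(nm))
  } else {
    if (!sel$called) inform("SA set empty; enrichment stage skipped.")
    NULL
  }

  manifest <- list(
    stage_counts = list(cpg_in = nrow(m), cpg_complete = nrow(nm),
                        delta_hyper = sum(delta_table$direction == "hyper"),
                        delta_hypo = sum(delta_table$direction == "hypo"),
                        sam_called = sel$called,
                        sam_hyper = length(sel$hyper_ids),
                        sam_hypo = length(sel$hypo_ids)),
    thresholds = list(delta_beta = delta_threshold, fdr = fdr_target,
                      window = window),
    seed = seed)
  structure(list(pca = pca, pc_tissue = pc_tissue, pc_passage = pc_passage,
                 delta_table = delta_table, sam = fit, selection = sel,
                 membership = membership, category_summary = category_summary,
                 enrichment = enrichment, normalized = beta_tbl(nm),
                 manifest = manifest),
            class = "senescence_report")
}

#' @export
print.senescence_report <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("Senescence analysis report\n")
  cat(sprintf("  CpGs: %d in, %d complete\n", sc$cpg_in, sc$cpg_complete))
  cat(sprintf("  delta-beta filter: %d hyper / %d hypo\n",
              sc$delta_hyper, sc$delta_hypo))
  cat(sprintf("  paired SAM: %d SA CpGs (%d hyper, %d hypo) at FDR %.3g\n",
              sc$sam_called, sc$sam_hyper, sc$sam_hypo,
              x$selection$fdr_achieved))
  bt <- which.max(x$pc_tissue$r_squared)
  bp <- which.max(x$pc_passage$r_squared)
  cat(sprintf("  PCA: tissue separates on PC%d, passage class on PC%d\n", bt, bp))
  if (!is.null(x$enrichment)) {
    top <- x$enrichment %>% arrange(.data$p_over) %>% head(3)
    cat("  top enrichment:",
        paste(sprintf("%s (p=%.2g)", top$category, top$p_over), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
print.tissue_report <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("Tissue-contrast report\n")
  cat(sprintf("  delta-beta filter: %d hyper / %d hypo\n",
              sc$delta_hyper, sc$delta_hypo))
  cat(sprintf("  unpaired SAM: %d CpGs called at FDR %.3g\n",
              sc$sam_called, x$selection$fdr_achieved))
  invisible(x)
}

#' Best-effort replication run on locally downloaded array exports
#'
#' Reads user-supplied series-matrix-style beta TSVs (never downloads),
#' intersects their CpG universes, runs [run_senescence_analysis()] and
#' returns the report together with a side-by-side table of the observed
#' set sizes and published reference counts from long-term MSC culture
#' (517 SA CpGs at FDR 4.8%, 156 hyper / 361 hypo, 233 / 186 beyond the
#' 15% delta-beta filter). Unstated settings of the reference SAM analysis
#' (permutation count, pi0, cut-point details) preclude guaranteed
#' equality, so the table compares without asserting.
#'
#' @param beta_paths Character vector of beta TSV paths.
#' @param sample_sheet_path Sample sheet CSV path.
#' @param annotation_path Optional annotation TSV path.
#' @param ... Passed to [run_senescence_analysis()].
#' @return List: `report` (the [run_senescence_analysis()] result) and
#'   `comparison` (tibble of quantity, observed, published).
#' @export
replicate_published <- function(beta_paths, sample_sheet_path,
                                annotation_path = NULL, ...) {
  missing <- c(beta_paths, sample_sheet_path)[!file.exists(c(beta_paths, sample_sheet_path))]
  if (length(missing)) {
    abort(paste0(
      "input file(s) not found: ", paste(missing, collapse = ", "),
      "\nExpected: beta TSVs (cpg_id + one column per sample) and a sample ",
      "sheet CSV (sample_id, tissue, donor_id, passage_class, ...)."))
  }
  betas <- lapply(beta_paths, read_beta_tsv)
  common <- Reduce(intersect, lapply(betas, function(b) b$cpg_id))
  if (!length(common)) abort("no shared CpG ids across the beta files.")
  inform(sprintf("CpG universe after intersection: %d sites", length(common)))
  betas <- lapply(betas, function(b) b[match(common, b$cpg_id), ])
  beta <- Reduce(function(a, b) dplyr::bind_cols(a, b[-1]), betas)
  meta <- read_sample_sheet(sample_sheet_path)
  annotation <- if (!is.null(annotation_path)) read_annotation(annotation_path)
  report <- run_senescence_analysis(beta, meta, annotation = annotation, ...)
  sc <- report$manifest$stage_counts
  comparison <- tibble(
    quantity = c("SA CpG sites (paired SAM)", "SA hyper-methylated",
                 "SA hypo-methylated", "delta-beta > 0.15 hyper",
                 "delta-beta > 0.15 hypo"),
    observed = c(sc$sam_called, sc$sam_hyper, sc$sam_hypo,
                 sc$delta_hyper, sc$delta_hypo),
    published = c(517L, 156L, 361L, 233L, 186L))
  list(report = report, comparison = comparison)
}
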