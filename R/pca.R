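#' Principal component analysis of methylation profiles
#'
#' Samples are the observations, CpGs the variables; variables are centred
#' but not scaled (beta values already share a scale). Scores come from the
#' singular value decomposition via [stats::prcomp()]; the sign of every
#' component is fixed by making its largest-magnitude loading positive, so
#' results are reproducible across platforms. Missing beta values are not
#' tolerated here — drop incomplete CpGs (the package's complete-case
#' policy) or impute first.
#'
#' @param beta Beta table (`cpg_id` + sample columns).
#' @param k Number of components to keep (default: all available,
#'   `min(n_samples - 1, n_cpg)`).
#' @param meta Optional sample sheet joined onto the score table by
#'   `sample_id`.
#' @return An object of class `beta_pca`: list with `scores` (tibble:
#'   `sample_id`, `PC1`..`PCk`, any metadata), `var_explained` (fraction
#'   per component), `rotation` (loadings matrix), `center`.
#' @examples
#' sim <- simulate_methylation(synth_config(n_cpg = 300, marks = NULL,
#'                                          rng_seed = 3))
#' fit <- beta_pca(sim$beta, k = 4, meta = sim$samples)
#' glance(fit)
#' @export
beta_pca <- function(beta, k = NULL, meta = NULL) {
  m <- beta_matrix(beta)
  if (anyNA(m)) {
    abort(paste0("beta matrix contains missing values; drop incomplete ",
                 "CpGs or impute before PCA."))
  }
  if (ncol(m) < 2) abort("PCA needs at least 2 samples.")
  kmax <- min(ncol(m) - 1L, nrow(m))
  k <- if (is.null(k)) kmax else as.integer(k)
  if (k < 1 || k > kmax) abort(sprintf("k must be in 1..%d.", kmax))
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  # deterministic orientation: dominant loading of each component positive
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- dplyr::bind_cols(tibble(sample_id = colnames(m)),
                             as_tibble(fit$x[, seq_len(k), drop = FALSE]))
  if (!is.null(meta)) scores <- left_join(scores, as_tibble(meta), by = "sample_id")
  structure(list(scores = scores, var_explained = ve[seq_len(k)],
                 rotation = fit$rotation[, seq_len(k), drop = FALSE],
                 center = fit$center, k = k),
            class = "beta_pca")
}

#' @export
print.beta_pca <- function(x, ...) {
  cat(sprintf("PCA of methylation profiles: %d samples, %d components\n",
              nrow(x$scores), x$k))
  cat("variance explained:",
      paste0(sprintf("PC%d=%.1f%%", seq_len(min(x$k, 6)),
                     100 * x$var_explained[seq_len(min(x$k, 6))]),
             collapse = " "), "\n")
  invisible(x)
}

#' @rdname beta_pca
#' @param x A `beta_pca` object.
#' @param ... Unused.
#' @method tidy beta_pca
#' @export
tidy.beta_pca <- function(x, ...) {
  x$scores %>%
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score") %>%
    mutate(component = as.integer(sub("^PC", "", .data$component)))
}

#' @rdname beta_pca
#' @method glance beta_pca
#' @export
glance.beta_pca <- function(x, ...) {
  tibble(component = seq_len(x$k), var_explained = x$var_explained)
}

#' How strongly each principal component separates a grouping factor
#'
#' For every component, the between-group R-squared of the scores against
#' the factor (from a one-way ANOVA decomposition). The component with the
#' highest R-squared is the one "separating" that factor, the quantity used
#' to ask e.g. whether tissue of origin separates on an earlier component
#' than passage class.
#'
#' @param pca A [beta_pca()] fit.
#' @param factor Either the name of a metadata column present in
#'   `pca$scores` or a vector with one value per sample.
#' @return Tibble: `component`, `r_squared`, ordered by component.
#' @export
pc_association <- function(pca, factor) {
  stopifnot(inherits(pca, "beta_pca"))
  f <- if (is.character(factor) && length(factor) == 1) {
    if (!factor %in% names(pca$scores)) abort(sprintf("column `%s` not in scores.", factor))
    pca$scores[[factor]]
  } else factor
  f <- as.factor(f)
  purrr::map_dfr(seq_len(pca$k), function(j) {
    s <- pca$scores[[paste0("PC", j)]]
    ssb <- sum(tapply(s, f, function(v) length(v) * (mean(v) - mean(s))^2))
    tibble(component = j, r_squared = ssb / sum((s - mean(s))^2))
  })
}

#' @rdname beta_pca
#' @param object A `beta_pca` object.
#' @param components Pair of component indices to plot.
#' @param colour Optional metadata column name mapped to point colour.
#' @method autoplot beta_pca
#' @export
autoplot.beta_pca <- function(object, components = c(1, 2), colour = NULL, ...) {
  xn <- paste0("PC", components[1]); yn <- paste0("PC", components[2])
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(.data[[xn]], .data[[yn]]))
  p <- if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", xn, 100 * object$var_explained[components[1]]),
    y = sprintf("%s (%.1f%%)", yn, 100 * object$var_explained[components[2]])) +
    ggplot2::theme_minimal()
}
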