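#' Significance Analysis of Microarrays for methylation contrasts
#'
#' One-call SAM: computes the moderated d statistic (with an automatically
#' estimated fudge factor by default), builds the permutation null
#' (exhaustive when the design allows), tabulates permutation FDRs over a
#' delta grid and selects the significant CpG set at the target FDR.
#'
#' Orientation: in unpaired mode the contrast is `level 2 - level 1` of
#' `factor(labels)`; in paired mode it is late minus early within each
#' donor. Positive `d` therefore means methylation gained ("hyper") in the
#' second condition.
#'
#' @inheritParams sam_statistic
#' @param fdr_target Target false discovery rate for the selected set.
#' @param B Permutation budget (exhaustive enumeration when the design has
#'   at most `B` distinct permutations).
#' @param seed RNG seed for permutation sampling; recorded in the fit.
#' @param s0 `"auto"` (estimate via [estimate_s0()]) or a non-negative
#'   number.
#' @param pi0 Null-fraction assumption for the FDR (1, or `"estimate"`).
#' @param deltas Optional delta grid for [sam_fdr()].
#' @return An object of class `sam_fit`; see [tidy.sam_fit()] and
#'   [glance.sam_fit()].
#' @examples
#' sim <- simulate_methylation(synth_config(n_cpg = 200, n_sa_planted = 20,
#'                                          n_tissue_planted = 0,
#'                                          marks = NULL, rng_seed = 5))
#' fit <- sam_test(sim$beta, labels = sim$samples$passage_class,
#'                 mode = "paired", pairs = sim$samples$donor_id, seed = 1)
#' glance(fit)
#' @export
sam_test <- function(beta, labels, mode = c("unpaired", "paired"),
                     pairs = NULL, fdr_target = 0.05, B = 1000, seed = 1L,
                     s0 = "auto", pi0 = 1, deltas = NULL) {
  mode <- match.arg(mode)
  m <- if (is.data.frame(beta)) beta_matrix(beta) else beta
  m <- drop_incomplete_cpgs(m)
  rs <- sam_observed_rs(m, labels, mode, pairs)
  s0_val <- if (identical(s0, "auto")) estimate_s0(rs$r, rs$s) else {
    stopifnot(is.numeric(s0), s0 >= 0); s0
  }
  d <- setNames(rs$r / (rs$s + s0_val), rownames(m))
  perms <- sam_permute(m, labels, mode, s0 = s0_val, pairs = pairs,
                       B = B, seed = seed)
  fdr_table <- sam_fdr(d, perms, deltas = deltas, pi0 = pi0)
  sel <- select_significant(d, fdr_table, fdr_target)
  structure(list(d = d, r = rs$r, s = rs$s, s0 = s0_val, dbar = perms$dbar,
                 n_perm = perms$n_perm, exhaustive = perms$exhaustive,
                 fdr_table = fdr_table, selection = sel, mode = mode,
                 fdr_target = fdr_target, seed = seed, pi0 = pi0),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf("SAM (%s mode): %d features, %d permutations%s, s0 = %.4g\n",
              x$mode, length(x$d), x$n_perm,
              if (x$exhaustive) " (exhaustive)" else "", x$s0))
  cat(sprintf("at FDR target %.3g: %d called (%d hyper, %d hypo), achieved FDR %.3g\n",
              x$fdr_target, x$selection$called,
              length(x$selection$hyper_ids), length(x$selection$hypo_ids),
              x$selection$fdr_achieved))
  invisible(x)
}

#' Per-CpG and per-fit summaries of a SAM fit
#'
#' `tidy()` returns one row per CpG with the observed statistic, the
#' expected order statistic at its rank, the call and its direction;
#' `glance()` one row with the fit-level numbers.
#'
#' @param x,object A [sam_test()] fit.
#' @param ... Unused.
#' @method tidy sam_fit
#' @export
tidy.sam_fit <- function(x, ...) {
  ord <- order(x$d)
  rank_of <- integer(length(x$d)); rank_of[ord] <- seq_along(ord)
  tibble(cpg_id = names(x$d), d = unname(x$d),
         dbar = x$dbar[rank_of],
         called = names(x$d) %in% x$selection$cpg_ids,
         direction = case_when(
           names(x$d) %in% x$selection$hyper_ids ~ "hyper",
           names(x$d) %in% x$selection$hypo_ids ~ "hypo",
           TRUE ~ NA_character_)) %>%
    arrange(desc(abs(.data$d)))
}

#' @rdname tidy.sam_fit
#' @method glance sam_fit
#' @export
glance.sam_fit <- function(x, ...) {
  tibble(n_features = length(x$d), s0 = x$s0, n_perm = x$n_perm,
         exhaustive = x$exhaustive, mode = x$mode,
         fdr_target = x$fdr_target, delta = x$selection$delta,
         fdr_achieved = x$selection$fdr_achieved,
         called = x$selection$called,
         n_hyper = length(x$selection$hyper_ids),
         n_hypo = length(x$selection$hypo_ids))
}

#' @rdname tidy.sam_fit
#' @method autoplot sam_fit
#' @export
autoplot.sam_fit <- function(object, ...) {
  dat <- tibble(dbar = object$dbar, d = sort(object$d))
  ggplot2::ggplot(dat, ggplot2::aes(.data$dbar, .data$d)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "expected order statistic", y = "observed d") +
    ggplot2::theme_minimal()
}
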