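#' Population doublings per passage
#'
#' `pdp()` computes `log2(h / s)`, the number of population doublings implied
#' by seeding `s` cells and harvesting `h`. A harvest of zero marks a
#' terminal passage: no doubling is computable, so `NA` is returned with a
#' warning rather than `-Inf`.
#'
#' @param s Cells seeded (> 0). Vectorized.
#' @param h Cells harvested (>= 0). Vectorized.
#' @return Numeric vector of doublings; `NA` at terminal passages.
#' @examples
#' pdp(10000, 40000)   # 2 doublings
#' pdp(10000, 25000)   # log2(2.5)
#' @export
pdp <- function(s, h) {
  if (any(s <= 0)) abort("seeded cell counts must be positive.")
  if (any(h < 0)) abort("harvested cell counts must be non-negative.")
  out <- ifelse(h > 0, log2(h / s), NA_real_)
  if (anyNA(out)) warn("terminal passage (h = 0): doubling not computable, set to NA.")
  out
}

check_growth_series <- function(series) {
  series <- as_tibble(series)
  req <- c("passage", "seeded", "harvested")
  if (!all(req %in% names(series))) {
    abort(paste0("growth series needs columns: ", paste(req, collapse = ", ")))
  }
  if (!nrow(series)) abort("growth series is empty.")
  if (is.unsorted(series$passage, strictly = TRUE)) {
    abort("passage indices must be strictly increasing.")
  }
  if (!is.null(series[["f"]]) &&
      any(!is.na(series[["f"]]) & (series[["f"]] <= 0 | series[["f"]] > 1))) {
    abort("CFU-f frequencies f must lie in (0, 1].")
  }
  series
}

#' Cumulative population doublings
#'
#' Adds `pdp` and its running sum `cpd` to a growth series
#' (`CPD_n = sum_{i<=n} log2(h_i / s_i)`). A terminal passage (harvest 0)
#' ends the curve: its own and all later cumulative values are `NA`.
#'
#' @param series Data frame with columns `passage`, `seeded`, `harvested`
#'   (and optionally `f`, `days`).
#' @return The series as a tibble with `pdp`, `cpd` and `terminal` columns
#'   appended.
#' @examples
#' cumulative_pd(tibble::tibble(passage = 1:3, seeded = 1e4,
#'                              harvested = 4e4))
#' @export
cumulative_pd <- function(series) {
  series <- check_growth_series(series)
  p <- withCallingHandlers(pdp(series$seeded, series$harvested),
                           warning = function(w) invokeRestart("muffleWarning"))
  terminal <- series$harvested == 0
  if (any(terminal)) {
    inform(sprintf("terminal passage at index %d ends the growth curve.",
                   series$passage[which(terminal)[1]]))
  }
  cpd <- cumsum(ifelse(is.na(p), 0, p))
  cpd[cumsum(terminal) > 0] <- NA_real_
  series %>% mutate(pdp = p, cpd = cpd, terminal = terminal)
}

#' CFU-f-adjusted population doublings
#'
#' Conventional doublings treat every seeded cell as proliferative; in
#' ageing cultures only the CFU-f fraction `f_i` is. The adjusted doubling
#' counts doublings of that proliferative subset,
#' `log2(h_i / (s_i * f_i))`, and its running sum gives the
#' CFU-f-adjusted growth curve. (The logarithm is part of the definition of
#' a doubling; an adjusted count without it would not be commensurate with
#' `pdp`.) Since `f_i <= 1`, the adjusted curve is always at or above the
#' conventional one, with equality exactly when every `f_i = 1`.
#'
#' @param series Growth series with columns `passage`, `seeded`,
#'   `harvested` and `f` (CFU-f frequency per passage, in (0, 1]).
#' @return Tibble with `pdp`, `cpd`, `pdp_cfu`, `cpd_cfu`, `terminal`
#'   columns appended.
#' @examples
#' cfu_adjusted_pd(tibble::tibble(passage = 1, seeded = 1e4,
#'                                harvested = 4e4, f = 0.25))
#' @export
cfu_adjusted_pd <- function(series) {
  series <- check_growth_series(series)
  if (is.null(series[["f"]])) abort("column `f` (CFU-f frequency) is required.")
  if (anyNA(series[["f"]])) {
    abort(paste0("missing CFU-f frequency at passage ",
                 paste(series$passage[is.na(series[["f"]])], collapse = ", ")))
  }
  out <- cumulative_pd(series)
  padj <- withCallingHandlers(pdp(out$seeded * out$f, out$harvested),
                              warning = function(w) invokeRestart("muffleWarning"))
  cadj <- cumsum(ifelse(is.na(padj), 0, padj))
  cadj[cumsum(out$terminal) > 0] <- NA_real_
  out %>% mutate(pdp_cfu = padj, cpd_cfu = cadj)
}

#' Per-passage growth-kinetics table
#'
#' Convenience wrapper producing the full per-passage table: conventional
#' and (when `f` is available) CFU-f-adjusted doublings.
#'
#' @inheritParams cfu_adjusted_pd
#' @return A tibble, one row per passage.
#' @export
growth_table <- function(series) {
  series <- check_growth_series(series)
  if (is.null(series[["f"]])) cumulative_pd(series) else cfu_adjusted_pd(series)
}

#' Plot conventional vs CFU-f-adjusted growth curves
#'
#' @param table Output of [growth_table()] or [cfu_adjusted_pd()].
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(table) {
  long <- table %>%
    select("passage", CPD = "cpd",
           dplyr::any_of(c(`CFU-f adjusted CPD` = "cpd_cfu"))) %>%
    tidyr::pivot_longer(-"passage", names_to = "curve", values_to = "cpd")
  ggplot2::ggplot(long, ggplot2::aes(.data$passage, .data$cpd,
                                     colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "passage", y = "cumulative population doublings",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
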