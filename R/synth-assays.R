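#' Simulate a limiting-dilution CFU-f assay
#'
#' Wells seeded with `dose` cells are scored positive (a fibroblastoid colony
#' grew) under the single-hit Poisson model: each seeded cell founds a colony
#' independently with probability `true_freq`, so
#' `P(positive) = 1 - exp(-dose * true_freq)`.
#'
#' @param true_freq True CFU-f frequency, in (0, 1].
#' @param doses Cells seeded per well at each dilution. The study design is
#'   1, 3, 10 and 30 cells per well.
#' @param wells_per_dose Replicate wells per dilution (48 in the study
#'   design).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `dose`, `wells_total`, `wells_positive`.
#' @examples
#' simulate_dilution(0.2, seed = 1)
#' @export
simulate_dilution <- function(true_freq, doses = c(1, 3, 10, 30),
                              wells_per_dose = 48, seed = 1L) {
  if (true_freq <= 0 || true_freq > 1) abort("true_freq must be in (0, 1].")
  if (any(doses <= 0)) abort("doses must be positive.")
  if (anyDuplicated(doses)) abort("doses must be distinct.")
  set.seed(as.integer(seed))
  p <- 1 - exp(-doses * true_freq)
  tibble(dose = doses,
         wells_total = as.integer(wells_per_dose),
         wells_positive = rbinom(length(doses), wells_per_dose, p))
}

#' Simulate a long-term culture growth series
#'
#' Emulates serial passaging of a heterogeneous culture in which only a
#' declining fraction of cells (the CFU-f compartment) proliferates. At
#' passage `i` the CFU-f frequency is
#' `f_i = f1 * exp(-decline_rate * (i - 1))`, the proliferative subset
#' expands by `divisions` doublings, and the harvest is
#' `h_i = s * f_i * 2^divisions` times a small lognormal counting error.
#' The default trajectory falls from 20% in the first passage to below 1%
#' by passage ten, the hallmark of replicative senescence in these
#' cultures.
#'
#' @param f1 CFU-f frequency at the first passage, in (0, 1].
#' @param decline_rate Exponential per-passage decline rate (>= 0; 0 keeps
#'   `f` constant).
#' @param divisions Doublings each proliferative cell contributes per
#'   passage.
#' @param n_passages Number of passages to simulate.
#' @param seeded Cells seeded at every passage.
#' @param count_cv Coefficient of variation of the lognormal counting
#'   error on harvests.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `passage`, `seeded`, `harvested`, `f`
#'   (the true CFU-f frequency used), `days`.
#' @examples
#' simulate_growth(seed = 1)
#' @export
simulate_growth <- function(f1 = 0.20, decline_rate = 0.35, divisions = 5,
                            n_passages = 10, seeded = 4e5,
                            count_cv = 0.05, seed = 1L) {
  if (f1 <= 0 || f1 > 1) abort("f1 must be in (0, 1].")
  if (decline_rate < 0 || divisions <= 0 || n_passages < 1) {
    abort("rates and counts must be positive.")
  }
  set.seed(as.integer(seed))
  i <- seq_len(n_passages)
  f <- pmin(f1 * exp(-decline_rate * (i - 1)), 1)
  sdlog <- sqrt(log(1 + count_cv^2))
  noise <- rlnorm(n_passages, -sdlog^2 / 2, sdlog)
  harvested <- pmax(round(seeded * f * 2^divisions * noise), 0)
  tibble(passage = i, seeded = seeded, harvested = harvested,
         f = f, days = 7L * i)
}
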