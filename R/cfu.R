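# Single-hit Poisson log-likelihood for a limiting-dilution assay.
# p_d = 1 - exp(-d * f); binomial likelihood per dose, constants dropped.
dilution_loglik <- function(f, dose, total, pos) {
  if (f < 0) return(-Inf)
  p <- -expm1(-dose * f)
  ll <- 0
  for (i in seq_along(dose)) {
    if (pos[i] > 0) {
      if (p[i] <= 0) return(-Inf)
      ll <- ll + pos[i] * log(p[i])
    }
    if (pos[i] < total[i]) ll <- ll - (total[i] - pos[i]) * dose[i] * f
  }
  ll
}

# Score dL/df; strictly decreasing in f, so the MLE is its unique root.
dilution_score <- function(f, dose, total, pos) {
  e <- exp(-dose * f)
  sum(pos * dose * e / (1 - e)) - sum((total - pos) * dose)
}

#' Estimate CFU-f frequency from a limiting-dilution assay
#'
#' Fits the single-hit Poisson model, under which a well seeded with `d`
#' cells stays negative with probability `exp(-d * f)`. The maximum-
#' likelihood estimate pools all doses through the binomial likelihood
#' `prod_d C(N_d, k_d) p_d^{k_d} (1 - p_d)^{N_d - k_d}` with
#' `p_d = 1 - exp(-d f)`; the 95% confidence interval is obtained by
#' profile likelihood at the `qchisq(0.95, 1) / 2` drop. With a single
#' informative dose the MLE has the closed form `-log(1 - k/N) / d`, which
#' the numeric solution reproduces.
#'
#' Degenerate assays are flagged rather than solved: if every well at every
#' dose is positive only a lower confidence bound is identified
#' (`status = "all_positive"`, `f_hat = 1`); if every well is negative only
#' an upper bound is (`status = "all_negative"`, `f_hat = 0`).
#'
#' @param assay Data frame with columns `dose`, `wells_total`,
#'   `wells_positive` (one row per dilution).
#' @param method `"ml"` for the pooled maximum-likelihood fit (default) or
#'   `"proportion"` for the naive estimate `positives / (wells * dose)` at
#'   the lowest dose, kept for sensitivity analysis.
#' @param conf_level Confidence level of the profile-likelihood interval.
#' @return A one-row tibble: `f_hat`, `ci_low`, `ci_high`, `loglik`,
#'   `method`, `status` (`"ok"` or the degeneracy flag).
#' @examples
#' estimate_cfu_frequency(simulate_dilution(0.2, seed = 1))
#' @export
estimate_cfu_frequency <- function(assay, method = c("ml", "proportion"),
                                   conf_level = 0.95) {
  method <- match.arg(method)
  assay <- as_tibble(assay)
  req <- c("dose", "wells_total", "wells_positive")
  if (!all(req %in% names(assay))) {
    abort(paste0("assay needs columns: ", paste(req, collapse = ", ")))
  }
  d <- assay$dose; N <- assay$wells_total; k <- assay$wells_positive
  if (any(d <= 0)) abort("doses must be positive.")
  if (anyDuplicated(d)) abort("doses must be distinct.")
  if (any(k < 0 | k > N)) abort("wells_positive must lie in [0, wells_total].")

  if (method == "proportion") {
    i <- which.min(d)
    f <- min(k[i] / (N[i] * d[i]), 1)
    return(tibble(f_hat = f, ci_low = NA_real_, ci_high = NA_real_,
                  loglik = dilution_loglik(f, d, N, k),
                  method = method, status = "ok"))
  }

  if (all(k == 0)) {
    ci_hi <- profile_bound(0, d, N, k, conf_level, upper = TRUE)
    return(tibble(f_hat = 0, ci_low = 0, ci_high = ci_hi,
                  loglik = dilution_loglik(0, d, N, k),
                  method = method, status = "all_negative"))
  }
  if (all(k == N)) {
    ci_lo <- profile_bound(1, d, N, k, conf_level, upper = FALSE)
    return(tibble(f_hat = 1, ci_low = ci_lo, ci_high = 1,
                  loglik = dilution_loglik(1, d, N, k),
                  method = method, status = "all_positive"))
  }

  # Score is strictly decreasing; bracket the root then solve tightly.
  lo <- 1e-12
  if (dilution_score(1, d, N, k) > 0) {
    f_hat <- 1  # frequency is a fraction; MLE capped at 1
  } else {
    f_hat <- uniroot(dilution_score, c(lo, 1), dose = d, total = N, pos = k,
                     tol = 1e-14)$root
  }
  ll <- dilution_loglik(f_hat, d, N, k)
  ci_lo <- profile_bound(f_hat, d, N, k, conf_level, upper = FALSE, ll_max = ll)
  ci_hi <- profile_bound(f_hat, d, N, k, conf_level, upper = TRUE, ll_max = ll)
  tibble(f_hat = f_hat, ci_low = ci_lo, ci_high = ci_hi, loglik = ll,
         method = method, status = "ok")
}

# One-sided profile-likelihood bound at the chi-square(1) drop.
profile_bound <- function(f_hat, d, N, k, conf_level, upper,
                          ll_max = dilution_loglik(f_hat, d, N, k)) {
  drop <- qchisq(conf_level, 1) / 2
  g <- function(f) dilution_loglik(f, d, N, k) - (ll_max - drop)
  if (upper) {
    if (f_hat >= 1 || g(1) > 0) return(1)
    uniroot(g, c(f_hat, 1), tol = 1e-12)$root
  } else {
    if (f_hat <= 0 || g(1e-12) > 0) return(0)
    uniroot(g, c(1e-12, f_hat), tol = 1e-12)$root
  }
}
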