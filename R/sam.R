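# --- Significance Analysis of Microarrays: core machinery -------------------
#
# Two-class (unpaired) and paired formulations of the moderated statistic
# d_i = r_i / (s_i + s0): r_i is the group-mean difference (unpaired) or the
# mean within-pair difference (paired), s_i the matching standard error, and
# s0 a "fudge factor" that keeps low-variance features from dominating. The
# null distribution comes from label permutations (unpaired) or within-pair
# sign flips (paired); false-discovery rates from the permutation null with
# asymmetric cut-points.

# r and s for every feature, for one or many permutations at once.
# `assign` is an n x B 0/1 matrix marking group-1 membership (unpaired) or
# an n_pairs x B +/-1 sign matrix (paired). Returns p x B matrices r and s.
sam_rs <- function(m, assign, mode) {
  if (mode == "unpaired") {
    n <- nrow(assign)
    n1 <- colSums(assign)
    n2 <- n - n1
    m2 <- m * m
    S1 <- m %*% assign
    SS1 <- m2 %*% assign
    tot <- rowSums(m); tot2 <- rowSums(m2)
    S2 <- tot - S1; SS2 <- tot2 - SS1
    r <- sweep(S2, 2, n2, "/") - sweep(S1, 2, n1, "/")
    pooled <- sweep(SS1 - sweep(S1^2, 2, n1, "/") +
                    SS2 - sweep(S2^2, 2, n2, "/"), 2, n - 2, "/")
    pooled[pooled < 0] <- 0  # numerical guard
    s <- sqrt(sweep(pooled, 2, 1 / n1 + 1 / n2, "*"))
  } else {
    nd <- nrow(assign)
    r <- (m %*% assign) / nd
    ss <- rowSums(m * m)  # invariant under sign flips
    v <- (ss - nd * r^2) / (nd - 1)
    v[v < 0] <- 0
    s <- sqrt(v / nd)
  }
  list(r = r, s = s)
}

# Per-donor late-minus-early difference matrix for the paired mode.
paired_diffs <- function(m, class, pairs) {
  class <- as.character(class)
  if (!all(class %in% c("early", "late"))) {
    abort('paired mode expects classes "early" and "late".')
  }
  tab <- table(pairs, class)
  bad <- rownames(tab)[tab[, "early"] != 1 | tab[, "late"] != 1]
  if (length(bad)) {
    abort(paste0("incomplete early/late pairing for donor(s): ",
                 paste(bad, collapse = ", ")))
  }
  donors <- sort(unique(as.character(pairs)))
  if (length(donors) < 2) abort("paired mode needs at least 2 complete pairs.")
  d <- vapply(donors, function(dn) {
    m[, which(pairs == dn & class == "late")] -
      m[, which(pairs == dn & class == "early")]
  }, numeric(nrow(m)))
  dimnames(d) <- list(rownames(m), donors)
  d
}

#' SAM moderated d statistic
#'
#' Computes `d_i = r_i / (s_i + s0)` per CpG. Unpaired mode contrasts the
#' two levels of `labels` (difference is second level minus first level,
#' pooled-variance standard error); paired mode uses per-donor
#' late-minus-early differences (`labels` = passage class, `pairs` = donor).
#' With `s0 = 0` the unpaired statistic is exactly the classical
#' pooled-variance two-sample t statistic.
#'
#' @param beta Beta table or numeric matrix (features x samples).
#' @param labels Two-level grouping vector, one entry per sample column.
#' @param mode `"unpaired"` or `"paired"`.
#' @param s0 Fudge factor (>= 0). See [estimate_s0()].
#' @param pairs Donor identifiers (paired mode only).
#' @return Named numeric vector of d statistics.
#' @examples
#' m <- rbind(a = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
#' sam_statistic(m, rep(c("g1", "g2"), each = 3))
#' @export
sam_statistic <- function(beta, labels, mode = c("unpaired", "paired"),
                          s0 = 0, pairs = NULL) {
  mode <- match.arg(mode)
  m <- if (is.data.frame(beta)) beta_matrix(beta) else beta
  rs <- sam_observed_rs(m, labels, mode, pairs)
  d <- rs$r / (rs$s + s0)
  if (s0 == 0 && any(rs$s == 0 & rs$r != 0)) {
    warn("features with zero variance and s0 = 0 give infinite d statistics.")
  }
  setNames(as.numeric(d), rownames(m))
}

sam_observed_rs <- function(m, labels, mode, pairs) {
  if (mode == "unpaired") {
    f <- factor(labels)
    if (nlevels(f) != 2) abort("labels must have exactly two levels.")
    if (any(table(f) < 2)) abort("each class needs at least 2 samples.")
    assign <- matrix(as.integer(f == levels(f)[1]), ncol = 1)
    rs <- sam_rs(m, assign, "unpaired")
  } else {
    if (is.null(pairs)) abort("paired mode requires `pairs`.")
    D <- paired_diffs(m, labels, pairs)
    rs <- sam_rs(D, matrix(1, ncol(D), 1), "paired")
  }
  list(r = drop(rs$r), s = drop(rs$s))
}

#' Estimate the SAM fudge factor s0
#'
#' Follows the original recipe: candidate values are the percentiles
#' (0, 5, ..., 100) of the per-feature standard errors `s`; for each
#' candidate the features are split into quantile bins of `s`, the median
#' absolute deviation (divided by 0.64) of `d = r / (s + s0)` is computed
#' per bin, and the candidate minimizing the coefficient of variation of
#' those bin scales is chosen. This makes the spread of `d` roughly
#' independent of `s`.
#'
#' @param r Per-feature numerators (group differences).
#' @param s Per-feature standard errors.
#' @param candidates Quantile probabilities defining the s0 grid.
#' @return The chosen s0 (a value of the `s` distribution).
#' @export
estimate_s0 <- function(r, s, candidates = seq(0, 1, by = 0.05)) {
  p <- length(s)
  if (p < 100) warn("fewer than 100 features: s0 estimate may be unstable.")
  if (diff(range(s)) == 0) {
    warn("degenerate s distribution (all equal); s0 set to that value.")
    return(s[1])
  }
  nbins <- max(2L, min(100L, p %/% 20L))
  breaks <- unique(quantile(s, seq(0, 1, length.out = nbins + 1)))
  bin <- cut(s, breaks, include.lowest = TRUE)
  cand <- unique(quantile(s, candidates))
  if (any(s == 0)) {
    # zero-variance features (e.g. rows made constant by normalization)
    # would give 0/0 at s0 = 0; only strictly positive candidates work
    cand <- cand[cand > 0]
    if (!length(cand)) {
      warn("all s0 candidates are zero; falling back to max(s).")
      return(max(s))
    }
  }
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, bin, function(x) mad(x[is.finite(x)], constant = 1) / 0.64)
    v <- v[!is.na(v)]
    if (!length(v) || mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  unname(cand[which.min(cv)])
}

#' Permutation null for SAM
#'
#' Unpaired mode permutes the class labels over samples; paired mode flips
#' the sign of each donor's difference. When the number of distinct
#' permutations (label assignments `choose(n, n1)`, sign patterns
#' `2^n_donors`) is at most `B`, all of them are enumerated and the result
#' is seed-independent; otherwise `B` distinct permutations are drawn
#' without replacement. The identity permutation is part of the enumerated
#' set. Expected order statistics `dbar` are the means, over permutations,
#' of the sorted null statistics.
#'
#' @inheritParams sam_statistic
#' @param B Permutation budget.
#' @param seed RNG seed (used only when sampling permutations).
#' @return List: `dbar` (expected order statistics, ascending), `null_d`
#'   (features x permutations matrix of null statistics), `n_perm`,
#'   `exhaustive`.
#' @export
sam_permute <- function(beta, labels, mode = c("unpaired", "paired"),
                        s0 = 0, pairs = NULL, B = 1000, seed = 1L) {
  mode <- match.arg(mode)
  if (B < 1) abort("B must be >= 1.")
  m <- if (is.data.frame(beta)) beta_matrix(beta) else beta
  if (mode == "unpaired") {
    f <- factor(labels)
    if (nlevels(f) != 2) abort("labels must have exactly two levels.")
    n <- ncol(m); n1 <- sum(f == levels(f)[1])
    n_distinct <- choose(n, n1)
    if (n_distinct <= B) {
      sets <- combn(n, n1)
      exhaustive <- TRUE
    } else {
      sets <- sample_distinct_sets(n, n1, B, seed)
      exhaustive <- FALSE
    }
    assign <- matrix(0L, n, ncol(sets))
    assign[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n1))] <- 1L
    rs <- sam_rs(m, assign, "unpaired")
  } else {
    D <- paired_diffs(m, labels, pairs)
    nd <- ncol(D)
    n_distinct <- 2^nd
    if (n_distinct <= B) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), nd)))
      signs <- t(signs)
      exhaustive <- TRUE
    } else {
      signs <- sample_distinct_signs(nd, B, seed)
      exhaustive <- FALSE
    }
    rs <- sam_rs(D, signs, "paired")
  }
  if (!exhaustive && B > n_distinct) {
    inform("B exceeds the number of distinct permutations; enumerating all.")
  }
  null_d <- rs$r / (rs$s + s0)
  dbar <- rowMeans(apply(null_d, 2, sort))
  list(dbar = dbar, null_d = null_d, n_perm = ncol(null_d),
       exhaustive = exhaustive)
}

sample_distinct_sets <- function(n, n1, B, seed) {
  set.seed(as.integer(seed))
  seen <- character(0)
  out <- vector("list", 0)
  tries <- 0L
  while (length(out) < B && tries < 100L) {
    draw <- replicate(B, sort(sample.int(n, n1)), simplify = FALSE)
    for (s in draw) {
      key <- paste(s, collapse = ",")
      if (!key %in% seen) { seen <- c(seen, key); out <- c(out, list(s)) }
      if (length(out) == B) break
    }
    tries <- tries + 1L
  }
  matrix(unlist(out), nrow = n1)
}

sample_distinct_signs <- function(nd, B, seed) {
  set.seed(as.integer(seed))
  seen <- character(0)
  out <- vector("list", 0)
  tries <- 0L
  while (length(out) < B && tries < 100L) {
    draw <- replicate(B, sample(c(1, -1), nd, replace = TRUE), simplify = FALSE)
    for (s in draw) {
      key <- paste(s, collapse = "")
      if (!key %in% seen) { seen <- c(seen, key); out <- c(out, list(s)) }
      if (length(out) == B) break
    }
    tries <- tries + 1L
  }
  matrix(unlist(out), nrow = nd)
}

# Asymmetric cut-points for a given delta: walk outward from the centre of
# the expected order statistics (dbar is non-decreasing, so the centre is
# where it changes sign — a tie-robust criterion); the first sorted observed
# d whose departure from dbar reaches delta sets the threshold, and
# everything beyond it is called ("beyond the first crossing").
sam_cutpoints <- function(d_sorted, dbar, delta) {
  dif <- d_sorted - dbar
  up <- which(dbar >= 0 & dif >= delta)
  lo <- which(dbar <= 0 & dif <= -delta)
  c(cut_low = if (length(lo)) unname(d_sorted[max(lo)]) else -Inf,
    cut_up = if (length(up)) unname(d_sorted[min(up)]) else Inf)
}

#' Permutation false-discovery-rate table for SAM
#'
#' For each threshold `delta`, CpGs are called significant when their
#' observed statistic lies beyond the asymmetric cut-points (see
#' `sam_cutpoints()` internals); the expected number of false calls is the
#' median, over permutations, of null statistics beyond the same
#' cut-points, and `FDR = pi0 * median_false / called` (0 when nothing is
#' called, capped at 1).
#'
#' @param d Observed statistics (named vector from [sam_statistic()]).
#' @param perms Result of [sam_permute()].
#' @param deltas Thresholds to tabulate; defaults to a quantile grid of the
#'   observed departures `|sort(d) - dbar|`.
#' @param pi0 Prior fraction of truly null features; 1 (conservative) by
#'   default, or `"estimate"` for the quantile-based estimate from the
#'   central half of the permutation null.
#' @return Tibble: `delta`, `called`, `false_median`, `fdr`, `cut_low`,
#'   `cut_up`.
#' @export
sam_fdr <- function(d, perms, deltas = NULL, pi0 = 1) {
  d_sorted <- sort(d)
  dbar <- perms$dbar
  if (length(d_sorted) != length(dbar)) abort("d and permutation null differ in length.")
  if (identical(pi0, "estimate")) pi0 <- estimate_pi0(d, perms$null_d)
  if (is.null(deltas)) {
    # percentile ladder plus the exact top departures, so thresholds inside
    # a gap between null-like and strongly shifted features are reachable
    dev <- abs(d_sorted - dbar)
    deltas <- sort(unique(c(0, unname(quantile(dev, seq(0, 1, length.out = 101))),
                            utils::tail(sort(dev), 100))))
  }
  if (!length(deltas)) abort("delta grid is empty.")
  purrr::map_dfr(deltas, function(delta) {
    cp <- sam_cutpoints(d_sorted, dbar, delta)
    called <- sum(d >= cp["cut_up"] | d <= cp["cut_low"])
    false_b <- colSums(perms$null_d >= cp["cut_up"] |
                       perms$null_d <= cp["cut_low"])
    fm <- median(false_b)
    tibble(delta = delta, called = called, false_median = fm,
           fdr = if (called == 0) 0 else min(1, pi0 * fm / called),
           cut_low = unname(cp["cut_low"]), cut_up = unname(cp["cut_up"]))
  })
}

# Quantile-based pi0: fraction of observed d inside the central null half,
# relative to the 50% expected there under the complete null.
estimate_pi0 <- function(d, null_d) {
  q <- quantile(as.vector(null_d), c(0.25, 0.75))
  min(1, sum(d > q[1] & d < q[2]) / (0.5 * length(d)))
}

#' Select the significant set at a target FDR
#'
#' Picks the smallest tabulated delta whose estimated FDR is at or below
#' `fdr_target` and returns the CpGs called at that threshold, split by the
#' sign of `d`. With the package's orientation (late minus early, or second
#' group minus first), positive `d` means methylation gained — reported as
#' `"hyper"` — and negative `d` as `"hypo"`. If no delta achieves the
#' target, the selection is empty and the smallest achievable FDR is
#' reported.
#'
#' @param d Observed statistics (named).
#' @param fdr_table Output of [sam_fdr()].
#' @param fdr_target Target false discovery rate, in (0, 1].
#' @return List: `cpg_ids`, `hyper_ids`, `hypo_ids`, `delta`,
#'   `fdr_achieved`, `called`.
#' @export
select_significant <- function(d, fdr_table, fdr_target = 0.05) {
  ok <- fdr_table$fdr <= fdr_target
  if (!any(ok)) {
    return(list(cpg_ids = character(0), hyper_ids = character(0),
                hypo_ids = character(0), delta = NA_real_,
                fdr_achieved = min(fdr_table$fdr), called = 0L))
  }
  row <- fdr_table[which(ok)[1], ]
  sel <- names(d)[d >= row$cut_up | d <= row$cut_low]
  list(cpg_ids = sel,
       hyper_ids = names(d)[d >= row$cut_up & names(d) %in% sel],
       hypo_ids = names(d)[d <= row$cut_low & names(d) %in% sel],
       delta = row$delta, fdr_achieved = row$fdr, called = length(sel))
}
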