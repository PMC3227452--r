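# Independent oracles, written with plain loops and base R so they share no
# code path with the package implementation.

# Pooled-variance two-sample statistic d = (mean2 - mean1)/(s + s0) for one
# feature vector split by a logical group-1 indicator.
oracle_d_one <- function(x, in1, s0 = 0) {
  a <- x[in1]; b <- x[!in1]
  n1 <- length(a); n2 <- length(b)
  r <- mean(b) - mean(a)
  pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  s <- sqrt(pooled * (1 / n1 + 1 / n2))
  r / (s + s0)
}

# Full SAM brute force for an unpaired two-class matrix: enumerates every
# distinct group-1 assignment, computes null statistics, expected order
# statistics, asymmetric cut-points at delta (first departure >= delta
# walking out from the centre of dbar) and the FDR.
oracle_sam <- function(m, n1, s0 = 0) {
  n <- ncol(m)
  d_obs <- apply(m, 1, function(x) {
    oracle_d_one(x, seq_len(n) <= n1, s0)
  })
  sets <- combn(n, n1)
  null_d <- matrix(NA_real_, nrow(m), ncol(sets))
  for (b in seq_len(ncol(sets))) {
    in1 <- seq_len(n) %in% sets[, b]
    null_d[, b] <- apply(m, 1, oracle_d_one, in1 = in1, s0 = s0)
  }
  sorted_null <- apply(null_d, 2, sort)
  dbar <- apply(sorted_null, 1, mean)
  list(d = d_obs, dbar = dbar, null_d = null_d)
}

oracle_cutpoints <- function(d_sorted, dbar, delta) {
  p <- length(d_sorted)
  cut_up <- Inf
  for (i in 1:p) {
    if (dbar[i] >= 0 && d_sorted[i] - dbar[i] >= delta) {
      cut_up <- d_sorted[i]; break
    }
  }
  cut_low <- -Inf
  for (i in p:1) {
    if (dbar[i] <= 0 && dbar[i] - d_sorted[i] >= delta) {
      cut_low <- d_sorted[i]; break
    }
  }
  c(unname(cut_low), unname(cut_up))
}

oracle_fdr <- function(d, null_d, dbar, delta, pi0 = 1) {
  cp <- oracle_cutpoints(sort(d), dbar, delta)
  called <- sum(d <= cp[1] | d >= cp[2])
  false_b <- numeric(ncol(null_d))
  for (b in seq_len(ncol(null_d))) {
    false_b[b] <- sum(null_d[, b] <= cp[1] | null_d[, b] >= cp[2])
  }
  fdr <- if (called == 0) 0 else min(1, pi0 * median(false_b) / called)
  list(cut_low = cp[1], cut_up = cp[2], called = called,
       false_median = median(false_b), fdr = fdr)
}

# 1-D grid maximizer of the single-hit Poisson likelihood.
oracle_cfu_grid <- function(assay, grid = seq(1e-6, 1, length.out = 200001)) {
  ll <- vapply(grid, function(f) {
    p <- 1 - exp(-assay$dose * f)
    sum(stats::dbinom(assay$wells_positive, assay$wells_total, p, log = TRUE))
  }, numeric(1))
  grid[which.max(ll)]
}

# Exhaustive hypergeometric tails: enumerate all C(N, n) draws from a
# universe with K marked members and count overlaps.
oracle_hyper_tails <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  ks <- apply(draws, 2, function(dr) sum(dr %in% marked))
  c(p_over = mean(ks >= k), p_under = mean(ks <= k))
}

# Brute-force average-linkage agglomeration returning the merge heights.
oracle_average_linkage <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

# Small standard configs used across tests.
small_marks <- function() {
  tibble::tibble(name = c("H3K4me3", "H3K27me3"),
                 size = c(200L, 150L),
                 high_frac = c(0.05, 0.85),
                 sa_enrichment = c(1, 5))
}

small_sim <- function(seed = 1, ...) {
  simulate_methylation(synth_config(
    n_cpg = 1000, n_sa_planted = 50, sa_delta = 0.3,
    n_tissue_planted = 60, tissue_delta = 0.25,
    samples = default_samples(4, 2, 2), noise_precision = 800,
    marks = small_marks(), rng_seed = seed, ...))
}
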