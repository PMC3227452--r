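test_that("with s0 = 0 the unpaired d equals the pooled t statistic", {
  set.seed(21)
  m <- matrix(runif(200), 20, 10,
              dimnames = list(sprintf("cg%02d", 1:20), paste0("s", 1:10)))
  labels <- rep(c("g1", "g2"), each = 5)
  d <- sam_statistic(m, labels, mode = "unpaired", s0 = 0)
  for (i in 1:20) {
    tt <- t.test(m[i, 6:10], m[i, 1:5], var.equal = TRUE)
    expect_equal(unname(d[i]), unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("the 2x3 toy statistic matches a hand computation", {
  m <- rbind(cg1 = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  colnames(m) <- paste0("s", 1:6)
  d <- sam_statistic(m, rep(c("A", "B"), each = 3), s0 = 0)
  # r = 0.3, pooled sd = 0.1, s = 0.1 * sqrt(2/3)
  expect_equal(unname(d), 0.3 / (0.1 * sqrt(2 / 3)), tolerance = 1e-12)
})

test_that("constant features and zero-variance cases behave", {
  m <- rbind(flat = rep(0.4, 6), diff = c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5))
  colnames(m) <- paste0("s", 1:6)
  expect_warning(d <- sam_statistic(m, rep(c("A", "B"), each = 3), s0 = 0),
                 "zero variance")
  expect_equal(unname(d["flat"]), NaN)  # 0/0: no signal, no spread
  expect_true(is.infinite(d["diff"]))
  d2 <- sam_statistic(m, rep(c("A", "B"), each = 3), s0 = 0.1)
  expect_equal(unname(d2["flat"]), 0)
  expect_equal(unname(d2["diff"]), 4)
})

test_that("paired d grows without bound as s0 -> 0 for constant differences", {
  m <- cbind(e1 = c(0.2, 0.3), l1 = c(0.4, 0.5), e2 = c(0.25, 0.35),
             l2 = c(0.45, 0.55), e3 = c(0.3, 0.2), l3 = c(0.5, 0.4))
  rownames(m) <- c("cg1", "cg2")
  labels <- rep(c("early", "late"), 3)
  pairs <- rep(c("d1", "d2", "d3"), each = 2)
  d_small <- sam_statistic(m, labels, mode = "paired", s0 = 1e-6, pairs = pairs)
  d_big <- sam_statistic(m, labels, mode = "paired", s0 = 0.1, pairs = pairs)
  expect_true(all(d_small > d_big))
  expect_true(all(d_small > 1e4))  # differences all exactly 0.2
})

test_that("incomplete pairing errors name the offending donor", {
  m <- matrix(runif(8), 2, 4,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_error(
    sam_statistic(m, c("early", "late", "early", "early"), mode = "paired",
                  pairs = c("d1", "d1", "d2", "d2")),
    "d2")
})

test_that("s0 estimation stabilizes variance-inflated small-s features", {
  set.seed(22)
  p <- 2000
  s <- runif(p, 0.01, 0.5)
  # spread of r inflated at small s, the signature s0 corrects
  r <- rnorm(p, 0, s + 0.1)
  s0 <- estimate_s0(r, s)
  expect_gt(s0, 0)
  cv <- function(s0c) {
    d <- r / (s + s0c)
    bin <- cut(s, unique(quantile(s, seq(0, 1, length.out = 101))),
               include.lowest = TRUE)
    v <- tapply(d, bin, function(x) mad(x, constant = 1) / 0.64)
    sd(v) / mean(v)
  }
  expect_lte(cv(s0), cv(0))

  expect_warning(res <- estimate_s0(rnorm(200), rep(0.3, 200)), "degenerate")
  expect_equal(res, 0.3)
})

test_that("exhaustive paired permutations are enumerated and seed-invariant", {
  set.seed(23)
  m <- matrix(runif(80), 10, 8,
              dimnames = list(sprintf("cg%02d", 1:10), paste0("s", 1:8)))
  labels <- rep(c("early", "late"), 4)
  pairs <- rep(paste0("d", 1:4), each = 2)
  p1 <- sam_permute(m, labels, "paired", s0 = 0.05, pairs = pairs,
                    B = 1000, seed = 1)
  p2 <- sam_permute(m, labels, "paired", s0 = 0.05, pairs = pairs,
                    B = 1000, seed = 999)
  expect_true(p1$exhaustive)
  expect_equal(p1$n_perm, 16)
  expect_identical(p1$dbar, p2$dbar)
  # identity permutation present: observed d occurs among the null columns
  d <- sam_statistic(m, labels, mode = "paired", s0 = 0.05, pairs = pairs)
  hit <- apply(p1$null_d, 2, function(col) isTRUE(all.equal(unname(col), unname(d))))
  expect_true(any(hit))
})

test_that("sampled permutations are distinct and reproducible", {
  set.seed(24)
  m <- matrix(runif(300), 10, 30,
              dimnames = list(sprintf("cg%02d", 1:10), paste0("s", 1:30)))
  labels <- rep(c("A", "B"), each = 15)
  p1 <- sam_permute(m, labels, "unpaired", s0 = 0.05, B = 50, seed = 5)
  p2 <- sam_permute(m, labels, "unpaired", s0 = 0.05, B = 50, seed = 5)
  expect_false(p1$exhaustive)
  expect_equal(p1$n_perm, 50)
  expect_identical(p1$null_d, p2$null_d)
  expect_equal(anyDuplicated(t(p1$null_d)), 0)
})

test_that("every SAM quantity matches brute-force enumeration on a 3v3 toy", {
  set.seed(25)
  m <- matrix(runif(60, 0.1, 0.9), 10, 6,
              dimnames = list(sprintf("cg%02d", 1:10), paste0("s", 1:6)))
  m[1:2, 4:6] <- m[1:2, 4:6] + 0.4  # two shifted features
  labels <- rep(c("A", "B"), each = 3)
  s0 <- 0.02

  oracle <- oracle_sam(m, n1 = 3, s0 = s0)
  d <- sam_statistic(m, labels, s0 = s0)
  expect_equal(unname(d), unname(oracle$d), tolerance = 1e-10)

  perms <- sam_permute(m, labels, s0 = s0, B = 1000, seed = 1)
  expect_true(perms$exhaustive)
  expect_equal(perms$n_perm, choose(6, 3))
  expect_equal(perms$dbar, oracle$dbar, tolerance = 1e-10)

  for (delta in c(0, 0.5, 1, 2, 5, Inf)) {
    got <- sam_fdr(d, perms, deltas = delta)
    want <- oracle_fdr(oracle$d, oracle$null_d, oracle$dbar, delta)
    expect_equal(got$cut_low, want$cut_low, tolerance = 1e-10)
    expect_equal(got$cut_up, want$cut_up, tolerance = 1e-10)
    expect_equal(got$called, want$called)
    expect_equal(got$false_median, want$false_median, tolerance = 1e-10)
    expect_equal(got$fdr, want$fdr, tolerance = 1e-10)
  }
})

test_that("the FDR table is monotone and handles boundary deltas", {
  set.seed(26)
  m <- matrix(runif(400), 50, 8,
              dimnames = list(sprintf("cg%02d", 1:50), paste0("s", 1:8)))
  labels <- rep(c("A", "B"), each = 4)
  d <- sam_statistic(m, labels, s0 = 0.05)
  perms <- sam_permute(m, labels, s0 = 0.05, B = 1000, seed = 2)
  tab <- sam_fdr(d, perms)
  expect_true(all(diff(tab$called) <= 0))
  expect_true(all(diff(tab$false_median) <= 1e-12))
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))

  inf_row <- sam_fdr(d, perms, deltas = Inf)
  expect_equal(inf_row$called, 0)
  expect_equal(inf_row$fdr, 0)

  zero_row <- sam_fdr(d, perms, deltas = 0)
  # at delta 0 essentially everything beyond the sign boundary is called
  expect_gte(zero_row$called, 48)
  expect_gt(zero_row$fdr, 0.5)       # null data: nearly everything is false
})

test_that("selection at a target FDR splits calls by sign of d", {
  sim <- small_sim(seed = 31)
  fit <- sam_test(sim$beta, sim$samples$passage_class, mode = "paired",
                  pairs = sim$samples$donor_id, seed = 3)
  expect_true(fit$exhaustive)  # 8 donors -> 256 sign patterns
  sel <- fit$selection
  expect_equal(sort(c(sel$hyper_ids, sel$hypo_ids)), sort(sel$cpg_ids))
  expect_true(all(fit$d[sel$hyper_ids] > 0))
  expect_true(all(fit$d[sel$hypo_ids] < 0))
  expect_lte(sel$fdr_achieved, fit$fdr_target)
  expect_equal(sel$called, length(sel$cpg_ids))

  # fdr_target = 1 calls everything beyond any departure (delta 0 row)
  sel_all <- select_significant(fit$d, fit$fdr_table, fdr_target = 1)
  expect_equal(sel_all$delta, 0)

  # unattainable target: empty set but the achievable FDR is reported
  fake_tab <- tibble::tibble(delta = 1, called = 10L, false_median = 5,
                             fdr = 0.5, cut_low = -1, cut_up = 1)
  none <- select_significant(fit$d, fake_tab, fdr_target = 0.01)
  expect_length(none$cpg_ids, 0)
  expect_equal(none$fdr_achieved, 0.5)
})

test_that("tidy and glance summarise a fit consistently", {
  sim <- small_sim(seed = 32)
  fit <- sam_test(sim$beta, sim$samples$passage_class, mode = "paired",
                  pairs = sim$samples$donor_id, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$d))
  expect_equal(sum(td$called), fit$selection$called)
  gl <- glance(fit)
  expect_equal(gl$called, fit$selection$called)
  expect_equal(gl$n_hyper + gl$n_hypo, gl$called)
})
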