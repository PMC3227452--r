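make_beta <- function(m) beta_tbl(m)

test_that("quantile normalization maps columns onto the order-statistic means", {
  b <- tibble::tibble(cpg_id = c("a", "b", "c"),
                      s1 = c(0.1, 0.2, 0.3), s2 = c(0.4, 0.5, 0.6))
  out <- beta_matrix(quantile_normalize(b))
  expect_equal(unname(out[, "s1"]), c(0.25, 0.35, 0.45))
  expect_equal(unname(out[, "s2"]), c(0.25, 0.35, 0.45))

  same <- tibble::tibble(cpg_id = c("a", "b", "c"),
                         s1 = c(0.3, 0.1, 0.2), s2 = c(0.3, 0.1, 0.2))
  expect_equal(beta_matrix(quantile_normalize(same)),
               beta_matrix(same))
})

test_that("normalized columns share one sorted value vector and the map is idempotent", {
  set.seed(4)
  m <- matrix(runif(500), 100, 5,
              dimnames = list(sprintf("cg%03d", 1:100), paste0("s", 1:5)))
  out <- beta_matrix(quantile_normalize(make_beta(m)))
  ref <- unname(sort(out[, 1]))
  for (j in 2:5) expect_equal(unname(sort(out[, j])), ref, tolerance = 1e-12)
  twice <- beta_matrix(quantile_normalize(beta_tbl(out)))
  expect_equal(twice, out, tolerance = 1e-12)
})

test_that("normalization combines datasets on the shared CpG set", {
  set.seed(5)
  m1 <- matrix(runif(40), 20, 2,
               dimnames = list(sprintf("cg%03d", 1:20), c("a1", "a2")))
  m2 <- matrix(runif(36), 18, 2,
               dimnames = list(sprintf("cg%03d", 3:20), c("b1", "b2")))
  expect_warning(out <- quantile_normalize(make_beta(m1), make_beta(m2)),
                 "intersection")
  expect_equal(nrow(out), 18)
  expect_equal(setdiff(names(out), "cpg_id"), c("a1", "a2", "b1", "b2"))
})

test_that("missing values stay missing through normalization", {
  m <- matrix(runif(60), 20, 3,
              dimnames = list(sprintf("cg%03d", 1:20), paste0("s", 1:3)))
  m[3, 2] <- NA
  out <- beta_matrix(quantile_normalize(make_beta(m)))
  expect_true(is.na(out[3, 2]))
  expect_equal(sum(is.na(out)), 1)
})

test_that("row-mean scaling yields unit row means", {
  b <- tibble::tibble(cpg_id = c("a", "b"), s1 = c(0.2, 0.1), s2 = c(0.2, 0.3))
  out <- beta_matrix(row_mean_scale(b))
  expect_equal(unname(out["a", ]), c(1, 1), ignore_attr = TRUE)
  expect_equal(unname(out["b", ]), c(0.5, 1.5), ignore_attr = TRUE)

  set.seed(6)
  m <- matrix(runif(200, 0.05, 0.95), 40, 5,
              dimnames = list(sprintf("cg%03d", 1:40), paste0("s", 1:5)))
  out <- beta_matrix(row_mean_scale(make_beta(m)))
  expect_equal(unname(rowMeans(out)), rep(1, 40), tolerance = 1e-12)

  zero <- tibble::tibble(cpg_id = "a", s1 = 0, s2 = 0)
  expect_error(row_mean_scale(zero), "non-positive")
})

test_that("hierarchical ordering matches brute-force average linkage", {
  set.seed(8)
  m <- matrix(runif(25), 5, 5,
              dimnames = list(paste0("i", 1:5), paste0("s", 1:5)))
  ord <- hierarchical_order(make_beta(m), axis = "cpg")
  hc <- attr(ord, "hclust")
  expect_equal(sort(hc$height), sort(oracle_average_linkage(m)),
               tolerance = 1e-10)

  # identical pair merges first
  m2 <- rbind(i1 = rep(0.1, 4), i2 = rep(0.1, 4), i3 = rep(0.9, 4))
  colnames(m2) <- paste0("s", 1:4)
  ord2 <- hierarchical_order(make_beta(m2))
  hc2 <- attr(ord2, "hclust")
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1))

  # permuting input rows preserves the partition structure (heights)
  perm <- sample(5)
  ordp <- hierarchical_order(make_beta(m[perm, ]))
  expect_equal(sort(attr(ordp, "hclust")$height), sort(hc$height),
               tolerance = 1e-12)
})

test_that("delta-beta filter applies a strict absolute threshold", {
  b <- tibble::tibble(cpg_id = c("none", "hyper", "edge", "hypo"),
                      e1 = c(0.5, 0.10, 0.10, 0.90),
                      e2 = c(0.5, 0.10, 0.10, 0.90),
                      l1 = c(0.5, 0.30, 0.25, 0.60),
                      l2 = c(0.5, 0.30, 0.25, 0.60))
  out <- delta_beta_filter(b, c("e1", "e2"), c("l1", "l2"), threshold = 0.15)
  expect_setequal(out$cpg_id, c("hyper", "hypo"))
  expect_equal(unname(out$direction[out$cpg_id == "hyper"]), "hyper")
  expect_equal(unname(out$direction[out$cpg_id == "hypo"]), "hypo")
  # 0.15 difference exactly is excluded (strict >)
  expect_false("edge" %in% out$cpg_id)

  # swapping the groups swaps hyper and hypo
  rev <- delta_beta_filter(b, c("l1", "l2"), c("e1", "e2"), threshold = 0.15)
  expect_setequal(out$cpg_id[out$direction == "hyper"],
                  rev$cpg_id[rev$direction == "hypo"])

  expect_error(delta_beta_filter(b, c("e1", "l1"), c("l1", "l2")), "disjoint")
})

test_that("identical groups give an empty filter result", {
  b <- tibble::tibble(cpg_id = letters[1:4],
                      a1 = runif(4), a2 = runif(4))
  b$b1 <- b$a1; b$b2 <- b$a2
  out <- delta_beta_filter(b, c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(out), 0)
})

test_that("PCA recovers a planted one-dimensional structure", {
  set.seed(10)
  base <- runif(200, 0.2, 0.8)
  shift <- c(rep(0, 4), rep(0.3, 4))
  m <- sapply(1:8, function(j) base + shift[j] + rnorm(200, 0, 0.002))
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(sprintf("cg%03d", 1:200), paste0("s", 1:8))
  fit <- beta_pca(make_beta(m))
  expect_gt(fit$var_explained[1], 0.99)
  g1 <- fit$scores$PC1[1:4]; g2 <- fit$scores$PC1[5:8]
  expect_true(max(g1) < min(g2) || min(g1) > max(g2))
})

test_that("PCA scores reconstruct the centred data and loadings are orthonormal", {
  set.seed(11)
  m <- matrix(runif(300), 50, 6,
              dimnames = list(sprintf("cg%03d", 1:50), paste0("s", 1:6)))
  fit <- beta_pca(make_beta(m))  # full rank
  R <- fit$rotation
  expect_equal(crossprod(R), diag(ncol(R)), tolerance = 1e-10,
               ignore_attr = TRUE)
  S <- as.matrix(fit$scores[paste0("PC", seq_len(fit$k))])
  recon <- S %*% t(R)
  centred <- t(m) - matrix(fit$center, ncol(m), nrow(m), byrow = TRUE)
  expect_equal(unname(recon), unname(centred), tolerance = 1e-10)

  dup <- cbind(m, s7 = m[, "s1"])
  fit2 <- beta_pca(make_beta(dup))
  expect_equal(unlist(fit2$scores[fit2$scores$sample_id == "s1", -1]),
               unlist(fit2$scores[fit2$scores$sample_id == "s7", -1]),
               ignore_attr = TRUE, tolerance = 1e-10)

  m[1, 1] <- NA
  expect_error(beta_pca(make_beta(m)), "missing")
})

test_that("pc_association scores the separating component highest", {
  set.seed(12)
  base <- runif(100, 0.3, 0.7)
  tissue <- rep(c("A", "B"), each = 4)
  m <- sapply(1:8, function(j) {
    base + ifelse(tissue[j] == "A", 0.2, 0) + rnorm(100, 0, 0.01)
  })
  dimnames(m) <- list(sprintf("cg%03d", 1:100), paste0("s", 1:8))
  fit <- beta_pca(make_beta(m))
  assoc <- pc_association(fit, tissue)
  expect_equal(which.max(assoc$r_squared), 1L)
})
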