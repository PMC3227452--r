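toy_annotation <- function() {
  tibble::tibble(cpg_id = c("cg1", "cg2", "cg3", "cg4"),
                 refseq_id = c("NM_000001.2", "NM_000002", "NM_000003", "NM_000004"),
                 chrom = "chr1", pos = c(1000L, 5000L, 9000L, 20000L),
                 strand = "+")
}

test_that("RefSeq matching strips version suffixes", {
  mk <- mark_set("markA", refseq_ids = c("NM_000001", "NM_000004.1"))
  mem <- match_cpg_to_mark(toy_annotation(), mk)
  expect_setequal(mem$cpg_id, c("cg1", "cg4"))
  expect_true(all(mem$match_path == "refseq"))
})

test_that("position matching honours the window boundary convention", {
  ann <- tibble::tibble(cpg_id = "cg1", refseq_id = "NM_999999",
                        chrom = "chr1", pos = 1000L, strand = "+")
  w <- 100
  at_window <- mark_set("m", intervals = tibble::tibble(
    chrom = "chr1", start = 1000L + w, end = 1000L + w + 50L))
  expect_equal(match_cpg_to_mark(ann, at_window, window = w)$cpg_id, "cg1")
  expect_equal(match_cpg_to_mark(ann, at_window, window = w)$match_path,
               "position")
  past_window <- mark_set("m", intervals = tibble::tibble(
    chrom = "chr1", start = 1000L + w + 1L, end = 1000L + w + 51L))
  expect_equal(nrow(match_cpg_to_mark(ann, past_window, window = w)), 0)
  # upstream side
  before <- mark_set("m", intervals = tibble::tibble(
    chrom = "chr1", start = 1000L - w - 50L, end = 1000L - w))
  expect_equal(match_cpg_to_mark(ann, before, window = w)$cpg_id, "cg1")
})

test_that("both matching paths are recorded", {
  ann <- toy_annotation()
  mk <- mark_set("m", refseq_ids = "NM_000002",
                 intervals = tibble::tibble(chrom = "chr1",
                                            start = c(4950L, 8950L),
                                            end = c(5050L, 9050L)))
  mem <- match_cpg_to_mark(ann, mk)
  expect_equal(mem$match_path[mem$cpg_id == "cg2"], "both")
  expect_equal(mem$match_path[mem$cpg_id == "cg3"], "position")
})

test_that("degenerate mark sets and convention mismatches are handled", {
  expect_equal(nrow(match_cpg_to_mark(toy_annotation(), mark_set("empty"))), 0)
  bad <- mark_set("m", intervals = tibble::tibble(chrom = "1", start = 1L,
                                                  end = 100L))
  expect_error(match_cpg_to_mark(toy_annotation(), bad), "chromosome naming")
  expect_error(mark_set("m", intervals = tibble::tibble(
    chrom = "chr1", start = 10L, end = 10L)), "start < end")
  expect_error(mark_set(""), "nonempty")
})

test_that("exclusive membership subtracts other categories", {
  mem <- tibble::tibble(cpg_id = c("a", "b", "c", "b", "d"),
                        category = c("K27", "K27", "K27", "K4", "K4"))
  only <- exclusive_membership(mem, "K27", "K4")
  expect_setequal(only$cpg_id, c("a", "c"))
  expect_equal(unique(only$category), "K27_only")
})

test_that("category summaries cover the all category and empties", {
  b <- tibble::tibble(cpg_id = c("a", "b", "c"),
                      s1 = c(0.1, 0.3, 0.5), s2 = c(0.3, 0.5, 0.7))
  mem <- tibble::tibble(cpg_id = c("a", "b"), category = "m")
  out <- methylation_by_category(b, mem)
  expect_equal(out$median[out$category == "all"], 0.4)
  expect_equal(out$median[out$category == "m"], 0.3)  # means 0.2 and 0.4
  empty <- methylation_by_category(b, mem, categories = "void")
  expect_true(is.na(empty$median[empty$category == "void"]))
  expect_equal(empty$n_cpg[empty$category == "void"], 0L)
  expect_error(methylation_by_category(
    b, tibble::tibble(cpg_id = "zz", category = "m")), "absent")
})

test_that("simulated repressive marks sit above the array-wide median", {
  sim <- small_sim(seed = 41)
  mem <- match_cpg_to_marks(sim$annotation, sim$marks)
  summ <- methylation_by_category(sim$beta, mem)
  all_med <- summ$median[summ$category == "all"]
  expect_gt(summ$median[summ$category == "H3K27me3"], all_med)
  expect_lte(summ$median[summ$category == "H3K4me3"], all_med)
})

test_that("mark files round-trip membership through both paths", {
  sim <- small_sim(seed = 42)
  truth_mem <- sim$truth$membership
  found_mem <- match_cpg_to_marks(sim$annotation, sim$marks)
  for (cat in unique(truth_mem$category)) {
    planted <- truth_mem$cpg_id[truth_mem$category == cat]
    found <- found_mem$cpg_id[found_mem$category == cat]
    expect_true(all(planted %in% found))
    # position windows may pull in a few neighbours, never lose members
    expect_lt(length(setdiff(found, planted)) / length(planted), 0.3)
  }
})
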