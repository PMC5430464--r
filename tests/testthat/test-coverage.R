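# Coverage summaries, copy number and pair-class tracks.

test_that("mean depth averages all positions including zeros", {
  d <- data.frame(replicon = "p1", pos = 1:100, depth = 10L)
  expect_equal(mean_depth(d, "p1")$mean_depth, 10)
  d0 <- data.frame(replicon = "p1", pos = 1:50, depth = 0L)
  expect_equal(mean_depth(d0, "p1")$mean_depth, 0)
  # sparse records with an explicit length: absent positions count as zero
  ds <- data.frame(replicon = "p1", pos = c(1L, 2L), depth = c(10L, 10L))
  expect_equal(mean_depth(ds, "p1", length = 10L)$mean_depth, 2)
  expect_error(mean_depth(d, "nope"), "not present")

  set.seed(81)
  dr <- data.frame(replicon = "x", pos = 1:500,
                   depth = rpois(500, 30))
  expect_equal(mean_depth(dr, "x")$mean_depth, sum(dr$depth) / 500)
})

test_that("copy number reproduces the printed-table rounding convention", {
  expect_equal(copy_number(219.75, 135.41)$rounded, 1.6)
  expect_equal(copy_number(298.92, 135.41)$rounded, 2.2)
  expect_equal(copy_number(135.41, 135.41)$rounded, 1.0)
  expect_error(copy_number(10, 0), "positive")
  # scale invariance
  for (c in c(0.5, 3, 100))
    expect_equal(copy_number(219.75 * c, 135.41 * c)$ratio,
                 copy_number(219.75, 135.41)$ratio)
})

test_that("copy-number report normalises to the chromosome", {
  d <- rbind(data.frame(replicon = "chrom", pos = 1:200, depth = 50L),
             data.frame(replicon = "pA", pos = 1:100, depth = 100L))
  rep <- copy_number_report(d, "chrom")
  expect_equal(rep$ratio[rep$replicon == "chrom"], 1.0)
  expect_equal(rep$copy_number[rep$replicon == "pA"], 2.0)
  expect_error(copy_number_report(d, "missing"), "not in depth")
})

test_that("concordant pairs produce zero broken coverage", {
  sam <- withr::local_tempfile(fileext = ".sam")
  recs <- list()
  for (i in 1:20) {
    p1 <- 10L * i; p2 <- p1 + 250L
    recs[[2 * i - 1]] <- list(qname = sprintf("q%02d", i),
                              flag = pair_flag(TRUE, FALSE, TRUE),
                              rname = "ref", pos = p1, len = 100L,
                              mrnm = "=", mpos = p2, isize = 350L)
    recs[[2 * i]] <- list(qname = sprintf("q%02d", i),
                          flag = pair_flag(FALSE, TRUE, FALSE),
                          rname = "ref", pos = p2, len = 100L,
                          mrnm = "=", mpos = p1, isize = -350L)
  }
  recs <- recs[order(vapply(recs, `[[`, integer(1), "pos"))]
  write_test_sam(sam, c(ref = 1000L), recs)
  tr <- pair_class_coverage(sam, "ref", insert_bounds = c(100, 600))
  expect_identical(sum(tr$broken_cov), 0L)
  expect_identical(tr$n_broken, 0L)
  expect_gt(sum(tr$proper_cov), 0L)
  # conservation: per-position class counts sum to total mapped coverage
  tr2 <- pair_class_coverage(sam, "ref", insert_bounds = c(500, 600))
  expect_identical(tr$proper_cov + tr$broken_cov,
                   tr2$proper_cov + tr2$broken_cov)
})

test_that("discordant orientations and cross-replicon mates are broken", {
  sam <- withr::local_tempfile(fileext = ".sam")
  recs <- list(
    # FF orientation pair
    list(qname = "ff", flag = pair_flag(TRUE, FALSE, FALSE), rname = "ref",
         pos = 100L, len = 100L, mrnm = "=", mpos = 400L, isize = 400L),
    # cross-replicon pair
    list(qname = "xr", flag = pair_flag(TRUE, FALSE, TRUE), rname = "ref",
         pos = 300L, len = 100L, mrnm = "other", mpos = 50L, isize = 0L),
    list(qname = "ff", flag = pair_flag(FALSE, FALSE, FALSE), rname = "ref",
         pos = 400L, len = 100L, mrnm = "=", mpos = 100L, isize = -400L))
  write_test_sam(sam, c(ref = 1000L, other = 500L), recs)
  tr <- pair_class_coverage(sam, "ref", insert_bounds = c(100, 600))
  expect_identical(tr$n_broken, 3L)
  expect_identical(tr$n_proper, 0L)
  expect_identical(unname(tr$broken_cov[100L]), 1L)
  expect_identical(unname(tr$broken_cov[350L]), 1L)
})

test_that("unsorted alignments are rejected", {
  sam <- withr::local_tempfile(fileext = ".sam")
  recs <- list(
    list(qname = "a", flag = pair_flag(TRUE, FALSE, TRUE), rname = "ref",
         pos = 500L, len = 50L, mrnm = "=", mpos = 700L, isize = 250L),
    list(qname = "b", flag = pair_flag(TRUE, FALSE, TRUE), rname = "ref",
         pos = 100L, len = 50L, mrnm = "=", mpos = 300L, isize = 250L))
  write_test_sam(sam, c(ref = 1000L), recs)
  expect_error(pair_class_coverage(sam, "ref", insert_bounds = c(100, 600)),
               "sorted")
})

test_that("a population arrangement mismatching the reference elevates broken pairs only in the locus", {
  # reference arrangement vs a population fixed on the inverted segment:
  # mates mapping within the inverted block flip orientation; pairs fully
  # outside the locus stay concordant.
  locus <- tiny_locus(n = 1L, seed = 82L)
  inv <- arrangement(1L, -1L)
  seg_lo <- locus$locus_start + nchar(locus$pilv_anchor) +
    nchar(locus$junctions[1L])                      # 0-based body start
  seg_hi <- seg_lo + nchar(locus$segments[[1L]]$body)
  set.seed(83)
  recs <- list(); rl <- 80L
  for (i in 1:120) {
    s0 <- sample.int(locus$plasmid_len - 500L, 1L)  # 0-based insert start
    e0 <- s0 + 400L
    inside1 <- s0 >= seg_lo && (s0 + rl) <= seg_hi
    inside2 <- (e0 - rl) >= seg_lo && e0 <= seg_hi
    if ((s0 < seg_hi && e0 > seg_lo) && !(inside1 || inside2)) next
    # mapping back to the reference: a mate inside the inverted block keeps
    # its span (symmetric placement unimportant) but flips strand
    r1rev <- inside1; r2rev <- !inside2
    recs[[length(recs) + 1L]] <-
      list(qname = sprintf("p%03d", i), flag = pair_flag(TRUE, r1rev, r2rev),
           rname = "ref", pos = s0 + 1L, len = rl, mrnm = "=",
           mpos = e0 - rl + 1L, isize = 400L)
    recs[[length(recs) + 1L]] <-
      list(qname = sprintf("p%03d", i), flag = pair_flag(FALSE, r2rev, r1rev),
           rname = "ref", pos = e0 - rl + 1L, len = rl, mrnm = "=",
           mpos = s0 + 1L, isize = -400L)
  }
  recs <- recs[order(vapply(recs, `[[`, integer(1), "pos"))]
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, stats::setNames(locus$plasmid_len, "ref"), recs)
  tr <- pair_class_coverage(sam, "ref", insert_bounds = c(100, 700))
  outside <- c(seq_len(max(1L, locus$locus_start - 400L)),
               seq.int(locus$locus_end + 400L, locus$plasmid_len))
  expect_identical(sum(tr$broken_cov[outside]), 0L)
  expect_gt(sum(tr$broken_cov[(seg_lo - 400L):(seg_hi + 400L)]), 0L)
})
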