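# pilV variant typing and cross-platform comparison.

test_that("synthetic junction reads type to the fused ORF end", {
  locus <- tiny_locus(n = 2L, seed = 51L)
  s1 <- locus$segments[[1L]]
  # pilV 3' (30 nt) + repeat junction + segment start (30 nt), "+" orientation
  # fuses the left ORF of segment 1 to pilV
  read <- paste0(substr(locus$pilv_anchor, nchar(locus$pilv_anchor) - 29L,
                        nchar(locus$pilv_anchor)),
                 locus$junctions[1L], substr(s1$body, 1L, 30L))
  expect_identical(type_read(read, locus, "short"), s1$orf_left)
  # strand symmetry
  expect_identical(type_read(rc(read), locus, "short"), s1$orf_left)
  # inverted segment fuses the right ORF instead
  read_inv <- paste0(substr(locus$pilv_anchor, nchar(locus$pilv_anchor) - 29L,
                            nchar(locus$pilv_anchor)),
                     locus$junctions[1L], substr(rc(s1$body), 1L, 30L))
  expect_identical(type_read(read_inv, locus, "short"), s1$orf_right)
  # segment sequence alone carries no junction
  expect_identical(type_read(substr(s1$body, 1L, 100L), locus, "short"),
                   NA_character_)
})

test_that("a single informative read gives one variant at ratio 1", {
  locus <- tiny_locus(n = 1L, seed = 52L)
  s1 <- locus$segments[[1L]]
  read <- paste0(substr(locus$pilv_anchor, nchar(locus$pilv_anchor) - 39L,
                        nchar(locus$pilv_anchor)),
                 locus$junctions[1L], substr(s1$body, 1L, 40L))
  vt <- variant_ratios(c(r1 = read), locus, "short")
  expect_identical(attr(vt, "total_informative"), 1L)
  expect_identical(vt$ratio[vt$variant == s1$orf_left], 1)
  expect_equal(sum(vt$ratio), 1, tolerance = 1e-9)
})

test_that("zero informative reads give a flagged empty table", {
  locus <- tiny_locus(n = 1L, seed = 53L)
  set.seed(5)
  junk <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  vt <- variant_ratios(c(x = junk), locus, "short")
  expect_true(attr(vt, "empty"))
  expect_identical(attr(vt, "total_informative"), 0L)
})

test_that("error-free 50/50 population types within the binomial 99% CI", {
  locus <- tiny_locus(n = 1L, seed = 54L)
  space <- enumerate_arrangements(locus)
  pop <- sample_population(space, frequencies = c(0.5, 0.5))
  cfg <- errorfree_config(n = 1L, seed = 54L)
  jpos <- locus$locus_start + nchar(locus$pilv_anchor)
  sim <- simulate_short_pairs(locus, pop, 300L, cfg, seed = 55L,
                              region = c(jpos - 180L, jpos + 20L))
  vt <- variant_ratios(list(r1 = sim$r1, r2 = sim$r2), locus, "short")
  tot <- attr(vt, "total_informative")
  expect_gt(tot, 100L)
  k <- vt$count[vt$variant == locus$segments[[1L]]$orf_left]
  ci <- binom_ci99(k, tot)
  expect_gte(0.5, ci[1L])
  expect_lte(0.5, ci[2L])
})

test_that("pair typing requires mate agreement", {
  locus <- tiny_locus(n = 2L, seed = 56L)
  s <- locus$segments
  mk <- function(seg, orient) {
    body <- if (orient > 0) s[[seg]]$body else rc(s[[seg]]$body)
    paste0(substr(locus$pilv_anchor, nchar(locus$pilv_anchor) - 29L,
                  nchar(locus$pilv_anchor)),
           locus$junctions[1L], substr(body, 1L, 30L))
  }
  # disagreeing mates: uninformative pair
  vt <- variant_ratios(list(r1 = c(p = mk(1L, 1L)), r2 = c(p = mk(2L, 1L))),
                       locus, "short")
  expect_identical(attr(vt, "total_informative"), 0L)
  # agreeing mates count once
  vt2 <- variant_ratios(list(r1 = c(p = mk(1L, 1L)), r2 = c(p = rc(mk(1L, 1L)))),
                        locus, "short")
  expect_identical(attr(vt2, "total_informative"), 1L)
})

test_that("structure marginals equal junction typing on error-free long reads", {
  locus <- tiny_locus(n = 2L, seed = 57L)
  space <- enumerate_arrangements(locus)
  pop <- sample_population(space, seed = 58L)
  cfg <- errorfree_config(n = 2L, seed = 57L)
  sim <- simulate_long_reads(locus, pop, 80L, cfg, seed = 59L,
                             spanning_only = TRUE)
  tab <- quantify_structures(sim$reads, locus)
  marg <- structure_variant_marginals(tab, locus)
  typed <- variant_ratios(sim$reads, locus, "long")
  expect_identical(attr(marg, "total_informative"),
                   attr(typed, "total_informative"))
  expect_identical(marg$count, typed$count)
})

test_that("platform comparison is exact on identical tables and validates labels", {
  locus <- tiny_locus(n = 2L, seed = 60L)
  s1 <- locus$segments[[1L]]
  read <- paste0(substr(locus$pilv_anchor, nchar(locus$pilv_anchor) - 29L,
                        nchar(locus$pilv_anchor)),
                 locus$junctions[1L], substr(s1$body, 1L, 30L))
  read2 <- paste0(substr(locus$pilv_anchor, nchar(locus$pilv_anchor) - 29L,
                         nchar(locus$pilv_anchor)),
                  locus$junctions[1L], substr(rc(s1$body), 1L, 30L))
  vt <- variant_ratios(c(a = read, b = read2), locus, "short")
  cmp <- compare_platforms(vt, vt)
  expect_identical(cmp$r_squared, 1)

  other <- vt
  other$variant <- paste0("Z", other$variant)
  expect_error(compare_platforms(vt, other), "label sets")
  expect_error(compare_platforms(vt[1L, ], vt[1L, ]), "at least 2")
})
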