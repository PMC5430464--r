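# Long-read assignment and abundance quantification.

test_that("exact, reverse-complement and truncated reads are classified correctly", {
  locus <- tiny_locus(n = 2L, seed = 31L)
  cands <- candidate_set(locus)
  k <- 5L
  read <- unname(cands$sequences[k]); names(read) <- "r"

  a <- assign_read(read, cands)
  expect_identical(a$status, "assigned")
  expect_identical(a$arrangement, names(cands$sequences)[k])
  expect_gte(a$score, a$runner_up_score)

  # strand symmetry
  a_rc <- assign_read(rc(read), cands)
  expect_identical(a_rc$status, "assigned")
  expect_identical(a_rc$arrangement, names(cands$sequences)[k])

  # truncated before the rci anchor: not spanning
  trunc <- substr(read, 1L, nchar(read) - nchar(locus$rci_anchor) - 10L)
  expect_identical(assign_read(trunc, cands)$status, "non_spanning")

  # unrelated sequence: no match
  set.seed(1)
  junk <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_identical(assign_read(junk, cands)$status, "no_match")

  expect_error(assign_read("", cands), "empty")
})

test_that("error-free counting recovers mixture ratios exactly", {
  locus <- tiny_locus(n = 1L, seed = 32L)
  cands <- candidate_set(locus)
  # 60/40 mixture of the two candidates, embedded in plasmid context
  space <- enumerate_arrangements(locus)
  # exact 60/40 composition of error-free spanning reads
  idx <- c(rep(1L, 60L), rep(2L, 40L))
  plas <- vapply(space$arrangements,
                 function(a) shufflonq:::variant_plasmid(locus, a),
                 character(1))
  reads <- vapply(seq_along(idx), function(i)
    substr(plas[idx[i]], locus$locus_start - 200L, locus$locus_end + 200L),
    character(1))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  tab <- quantify_structures(reads, locus, candidates = cands)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$count[order(tab$arrangement)],
                   c(60L, 40L)[order(space$labels)])
  expect_equal(sum(tab$ratio), 1, tolerance = 1e-9)
  expect_equal(sort(tab$ratio), c(0.4, 0.6), tolerance = 1e-12)
})

test_that("status classes partition the read set and totals are conserved", {
  locus <- tiny_locus(n = 1L, seed = 34L)
  cands <- candidate_set(locus)
  set.seed(3)
  reads <- c(exact = unname(cands$sequences[1L]),
             rcof = rc(unname(cands$sequences[2L])),
             trunc = substr(cands$sequences[1L], 1L, 200L),
             junk = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                          collapse = ""))
  asn <- assign_reads(reads, cands)
  tot <- attr(quantify_structures(reads, locus, candidates = cands), "totals")
  expect_identical(unname(tot["total"]), 4L)
  expect_identical(unname(tot["assigned"] + tot["ambiguous"] +
                            tot["non_spanning"] + tot["no_match"]), 4L)
  # arrangement present iff assigned
  expect_identical(is.na(asn$arrangement), asn$status != "assigned")
})

test_that("zero assignable reads yield a flagged empty table", {
  locus <- tiny_locus(n = 1L, seed = 35L)
  set.seed(4)
  junk <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1))
  names(junk) <- paste0("j", 1:3)
  tab <- quantify_structures(junk, locus)
  expect_true(attr(tab, "empty"))
  expect_identical(nrow(tab), 0L)
  expect_identical(unname(attr(tab, "totals")["total"]), 3L)
})

test_that("marker reconstruction agrees with BLAST assignment on error-free reads", {
  locus <- tiny_locus(n = 2L, seed = 36L)
  cands <- candidate_set(locus)
  space <- enumerate_arrangements(locus)
  pop <- sample_population(space, seed = 37L)
  cfg <- errorfree_config(n = 2L, seed = 36L)
  sim <- simulate_long_reads(locus, pop, 60L, cfg, seed = 38L,
                             spanning_only = TRUE)
  asn <- assign_reads(sim$reads, cands)
  rec <- vapply(sim$reads, function(r) {
    a <- reconstruct_from_markers(r, locus)
    if (is.null(a)) NA_character_ else arrangement_label(a, locus$segments)
  }, character(1))
  expect_true(all(asn$status == "assigned"))
  expect_false(anyNA(rec))
  # mode agreement, and both agree with the generating truth
  expect_identical(unname(rec), asn$arrangement)
  expect_identical(asn$arrangement, sim$truth$arrangement)
})

test_that("marker reconstruction returns NULL without both anchors", {
  locus <- tiny_locus(n = 1L, seed = 39L)
  expect_null(reconstruct_from_markers(locus$segments[[1L]]$body, locus))
  read <- paste0(locus$pilv_anchor, locus$junctions[1L],
                 locus$segments[[1L]]$body)  # no rci side
  expect_null(reconstruct_from_markers(read, locus))
})

test_that("estimated ratios stay within binomial 99% CIs across replicates", {
  locus <- tiny_locus(n = 1L, seed = 40L)
  cands <- candidate_set(locus)
  space <- enumerate_arrangements(locus)
  pop <- sample_population(space, frequencies = c(0.7, 0.3))
  cfg <- tiny_config(n = 1L, seed = 40L,
                     long_read = list(mean_len = 2000, sdlog = 0.2,
                                      sub = 0.015, ins = 0.09, del = 0.04))
  for (rep_seed in c(41L, 42L)) {
    sim <- simulate_long_reads(locus, pop, 120L, cfg, seed = rep_seed,
                               spanning_only = TRUE)
    tab <- quantify_structures(sim$reads, locus, candidates = cands)
    top <- tab[tab$arrangement == space$labels[1L], ]
    n_assigned <- unname(attr(tab, "totals")["assigned"])
    ci <- binom_ci99(top$count, n_assigned)
    expect_gte(0.7, ci[1L])
    expect_lte(0.7, ci[2L])
  }
})
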