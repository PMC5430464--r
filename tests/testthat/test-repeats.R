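# Inverted-repeat conservation analysis.

CONSENSUS <- "GTGCCAATCCGGTNNGTGGA"

make_repeats_from_consensus <- function(n = 6L, seed = 71L) {
  set.seed(seed)
  ch <- strsplit(CONSENSUS, "")[[1L]]
  nn <- which(ch == "N")
  reps <- vapply(seq_len(n), function(i) {
    x <- ch
    x[nn] <- sample(c("A", "C", "G", "T"), length(nn), replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  names(reps) <- sprintf("R%d", seq_len(n))
  reps
}

test_that("degenerate consensus recovers the shared site with N at variable positions", {
  reps <- make_repeats_from_consensus()
  # positions 14-15 (the N positions) were randomised; everything else is
  # unanimous, so the strict consensus reproduces the degenerate site
  expect_identical(degenerate_consensus(reps), CONSENSUS)
  # identical repeats: no N
  expect_identical(degenerate_consensus(rep("ACGTACGT", 4L)), "ACGTACGT")
  # single repeat is its own consensus
  expect_identical(degenerate_consensus("GATTACA"), "GATTACA")
  expect_error(degenerate_consensus(c("ACGT", "ACGTA")), "equal lengths")
  expect_error(degenerate_consensus(rep("ACGT", 2L), 0.4), "ambiguity_threshold")
})

test_that("consensus has N exactly where any disagreement exists", {
  set.seed(72)
  for (i in 1:5) {
    reps <- vapply(1:4, function(j)
      paste(sample(c("A", "C", "G"), 15, TRUE), collapse = ""), character(1))
    cons <- strsplit(degenerate_consensus(reps), "")[[1L]]
    m <- do.call(rbind, strsplit(reps, ""))
    disagree <- apply(m, 2L, function(col) length(unique(col)) > 1L)
    expect_identical(cons == "N", unname(disagree))
  }
})

test_that("pairwise identity counts matches per position", {
  a <- "GTGCCAATCCGGTAAGTGGA"
  b <- "GTGCCAATCCGGTCCGTGGT"  # 3 mismatches of 20 -> 85%
  m <- pairwise_identity(c(x = a, y = b))
  expect_identical(unname(diag(m)), c(100, 100))
  expect_equal(m["x", "y"], 85)
  expect_equal(m["y", "x"], 85)
  expect_equal(pairwise_identity(c(a, a))[1L, 2L], 100)
  # symmetry on random sets
  set.seed(73)
  reps <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), character(1))
  M <- pairwise_identity(reps)
  expect_identical(M, t(M))
})

test_that("hamming matrix equals brute-force counting and obeys the triangle inequality", {
  a <- strrep("A", 23L)
  b <- paste0(strrep("A", 17L), "CCCCCC")  # 6 window mismatches
  hm <- hamming_matrix(c(a = a, b = b), window = 23L)
  expect_identical(hm["a", "b"], 6L)
  expect_identical(hm["a", "a"], 0L)
  expect_error(hamming_matrix(c(a, b), window = 24L), "window")

  set.seed(74)
  reps <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), character(1))
  names(reps) <- paste0("r", 1:6)
  hm <- hamming_matrix(reps, window = 23L)
  # independent per-position recomputation
  for (i in 1:5) for (j in (i + 1):6) {
    d <- sum(strsplit(substr(reps[i], 1, 23), "")[[1L]] !=
               strsplit(substr(reps[j], 1, 23), "")[[1L]])
    expect_identical(unname(hm[i, j]), d)
  }
  # triangle inequality
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(hm[i, j], hm[i, k] + hm[k, j])
})

test_that("position frequency matrix columns sum to the repeat count", {
  reps <- make_repeats_from_consensus(n = 6L, seed = 75L)
  pfm <- position_frequency_matrix(reps)
  expect_equal(unname(colSums(pfm)), rep(6, nchar(CONSENSUS)))
  # majority-rule consistency with the strict consensus at unanimous columns
  cons <- strsplit(degenerate_consensus(reps), "")[[1L]]
  for (j in which(cons != "N"))
    expect_identical(rownames(pfm)[which.max(pfm[, j])], cons[j])
})

test_that("identity profile matches per-position fractions and pairwise identity", {
  ref <- "ACGTACGTAC"
  seqs <- c(ref, "ACGTACGTAC", "ACCTACGTAC")
  prof <- identity_profile(seqs, ref)
  expect_identical(prof[3L], 2 / 3)
  expect_true(all(prof[-3L] == 1))
  # profile mean equals mean identity to the reference / 100
  ids <- pairwise_identity(c(ref, seqs))[1L, -1L]
  expect_equal(mean(prof), mean(ids) / 100)
  expect_error(identity_profile(character(0), ref), "empty")
})

test_that("MSN tree weight equals the exhaustive spanning-tree minimum", {
  set.seed(76)
  for (nn in c(4L, 5L, 6L)) {
    reps <- vapply(seq_len(nn), function(i)
      paste(sample(c("A", "C", "G", "T"), 23, TRUE), collapse = ""),
      character(1))
    names(reps) <- paste0("n", seq_len(nn))
    d <- hamming_matrix(reps, window = 23L)
    net <- min_spanning_network(d)
    expect_true(net$connected)
    expect_equal(net$tree_weight, brute_mst_weight(d))
    # every edge weight equals its recomputed Hamming distance
    for (r in seq_len(nrow(net$edges)))
      expect_identical(net$edges$weight[r],
                       d[net$edges$from[r], net$edges$to[r]])
  }
})

test_that("MSN keeps co-minimal alternative edges", {
  # 3 nodes with distances 1, 1, 2: tree of weight 2, third edge dropped
  d <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3L, 3L,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- min_spanning_network(d)
  expect_identical(net$tree_weight, 2)
  expect_identical(nrow(net$edges), 2L)
  # all distances equal: every edge ties the tree path maximum
  d2 <- matrix(1, 4L, 4L, dimnames = list(letters[1:4], letters[1:4]))
  diag(d2) <- 0
  net2 <- min_spanning_network(d2)
  expect_identical(nrow(net2$edges), 6L)  # complete graph retained
  expect_error(min_spanning_network(matrix(c(0, 1, 2, 0), 2L)), "symmetric")
})

test_that("per-end repeat extraction is consensus-oriented", {
  locus <- tiny_locus(n = 3L, seed = 77L)
  reps <- repeat_set(locus)
  expect_identical(length(reps), 6L)
  expect_identical(sort(names(reps)),
                   sort(as.vector(outer(vapply(locus$segments, `[[`,
                                               character(1), "name"),
                                        c("_L", "_R"), paste0))))
  # every site differs from the consensus only at its N positions
  ch <- strsplit(CONSENSUS, "")[[1L]]
  fixed <- which(ch != "N")
  for (r in reps)
    expect_identical(strsplit(r, "")[[1L]][fixed], ch[fixed])
  # the left site is stored reverse-complemented on the plasmid: junction 0
  # equals the reverse complement of segment 1's left site
  expect_identical(locus$junctions[1L], rc(locus$segments[[1L]]$left_repeat))
  # 23-nt windows extend into the segment ends
  win <- repeat_set(locus, window_len = 23L)
  expect_true(all(nchar(win) == 23L))
  expect_identical(unname(substr(win[1L], 1L, 20L)), reps[[1L]])
})
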