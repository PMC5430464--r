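# Shared fixtures: compact loci and independent oracles.

# A small, fast locus: short anchors/segments keep alignment work light
# while remaining well above the 50-nt anchor minimum.
tiny_config <- function(n = 2L, seed = 101L, ...) {
  sim_config(n_segments = n, segment_len = 120L, anchor_len = 120L,
             plasmid_len = 8000L, locus_start = 2000L, seed = seed, ...)
}

tiny_locus <- function(n = 2L, seed = 101L, ...) {
  make_locus(tiny_config(n = n, seed = seed, ...))
}

# Error-free read model (exact substrings of the source plasmid).
errorfree_config <- function(n = 2L, seed = 101L, ...) {
  tiny_config(n = n, seed = seed,
              long_read = list(mean_len = 3000, sdlog = 0.2,
                               sub = 0, ins = 0, del = 0),
              short_read = list(read_len = 150L, insert_mean = 250,
                                insert_sd = 25, sub = 0), ...)
}

# Independent signed-permutation generator (brute force, no package code):
# all orderings x all orientation sign vectors, as "order/orient" keys.
brute_signed_permutations <- function(n) {
  perm_rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  perms <- perm_rec(seq_len(n))
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  keys <- character(0)
  for (p in perms) for (r in seq_len(nrow(signs))) {
    keys <- c(keys, paste(paste(p, collapse = ","),
                          paste(signs[r, ], collapse = ","), sep = "/"))
  }
  sort(unique(keys))
}

# Exhaustive minimum spanning tree weight by enumerating all spanning trees
# (edge subsets of size n-1 that connect the graph).
brute_mst_weight <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- Inf
  idx <- utils::combn(m, n - 1L)
  for (c in seq_len(ncol(idx))) {
    sel <- pairs[idx[, c], , drop = FALSE]
    # connectivity by union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in seq_len(nrow(sel)))
      parent[find(sel[r, 1L])] <- find(sel[r, 2L])
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1L)
      best <- min(best, sum(d[sel]))
  }
  best
}

# Two-sided binomial 99% CI for a proportion.
binom_ci99 <- function(k, n) {
  stats::binom.test(k, n, conf.level = 0.99)$conf.int
}

# Minimal SAM writer for pair-classification tests.
write_test_sam <- function(path, targets, records) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets))
  body <- vapply(records, function(r)
    paste(r$qname, r$flag, r$rname, r$pos, 60L,
          sprintf("%dM", r$len), r$mrnm, r$mpos, r$isize,
          strrep("A", r$len), strrep("I", r$len), sep = "\t"),
    character(1))
  writeLines(c(hdr, body), path)
  path
}

# SAM FLAG for one mate of a mapped pair (both mates mapped).
pair_flag <- function(mate1, rev, mrev) {
  f <- 1L
  if (rev) f <- f + 16L
  if (mrev) f <- f + 32L
  f + if (mate1) 64L else 128L
}
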