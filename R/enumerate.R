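# Arrangement-space enumeration, candidate sequence construction and the
# inversion-closure oracle.
#
# For n invertible segments each carrying two pilV ORF 3' ends, the number
# of whole-shufflon structures is 2^n * n! (orderings times orientations).
# The closure of the reference state under "invert the region between any
# two repeat sites" reaches exactly this set: an inversion bounded by the
# left site of position p and the right site of position q reverses block
# p..q and flips its orientations, and signed block reversals generate the
# full signed symmetric group.

#' Number of whole-shufflon structural combinations
#'
#' Computes `2^n * n!` for a locus of `n` two-ORF segments (2, 8 and 48 for
#' n = 1, 2, 3).  The formula counts distinct sequence structures only when
#' every segment carries two pilV ORF ends; mixed loci with one-ORF segments
#' should be enumerated exhaustively instead (see [enumerate_arrangements()]).
#'
#' @param n number of invertible segments (>= 0).
#' @return integer count of arrangements.
#' @export
count_arrangements <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop_val("n must be a single non-negative integer")
  as.integer(2^n * factorial(n))
}

permutations_of <- function(n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0L) { out[[length(out) + 1L]] <<- prefix; return() }
    for (x in sort(rest)) rec(c(prefix, x), setdiff(rest, x))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Enumerate the whole-shufflon arrangement space
#'
#' Generates every (order, orientation) pair for the locus's segments in a
#' deterministic order (lexicographic by permutation, then by orientation
#' vector with "+" before "-").
#'
#' @param locus a [shufflon_locus()] object, or an integer segment count.
#' @return an object of class `arrangement_space`: list with `n`,
#'   `arrangements` (list of [arrangement()]), `labels` and `count`.
#' @export
enumerate_arrangements <- function(locus) {
  n <- if (inherits(locus, "shufflon_locus")) n_segments(locus) else as.integer(locus)
  perms <- permutations_of(n)
  # lexicographic orientation order with "+" before "-": treat the vector as
  # a binary number, first position most significant, 0 = "+".
  ors <- matrix(1L, nrow = 2^n, ncol = n)
  if (n > 0L) for (i in seq_len(2^n)) {
    bits <- as.integer(intToBits(i - 1L))[seq_len(n)]
    ors[i, ] <- 1L - 2L * rev(bits)
  }
  arrangements <- vector("list", length(perms) * nrow(ors))
  k <- 0L
  for (p in perms) for (i in seq_len(nrow(ors))) {
    k <- k + 1L
    arrangements[[k]] <- arrangement(p, ors[i, ])
  }
  labels <- if (inherits(locus, "shufflon_locus"))
    vapply(arrangements, arrangement_label, character(1), locus$segments)
  else vapply(arrangements, arrangement_key, character(1))
  structure(list(n = n, arrangements = arrangements, labels = labels,
                 count = length(arrangements)),
            class = "arrangement_space")
}

#' @export
print.arrangement_space <- function(x, ...) {
  cat(sprintf("arrangement space: n = %d segments, %d arrangements (2^n x n! = %d)\n",
              x$n, x$count, count_arrangements(x$n)))
  invisible(x)
}

#' Build the candidate sequence of one arrangement
#'
#' Concatenates pilV anchor, junction elements and oriented segment bodies:
#' anchors and junctions stay in place while bodies are permuted and
#' reverse-complemented per the arrangement.  The reference arrangement
#' reproduces the annotated locus substring byte-for-byte.
#'
#' @param locus a [shufflon_locus()].
#' @param arr an [arrangement()].
#' @return the candidate DNA string.
#' @export
build_candidate_sequence <- function(locus, arr) locus_sequence(locus, arr)

#' Build all candidate sequences for a locus
#'
#' @param locus a [shufflon_locus()].
#' @param space optionally, a pre-computed [enumerate_arrangements()] result.
#' @return an object of class `candidate_set`: list with `space`, `sequences`
#'   (named character vector, names = arrangement labels) and `anchor_spans`
#'   (1-based spans of the pilV/rci anchors within every candidate, which are
#'   equal across candidates because only bodies move).
#' @export
candidate_set <- function(locus, space = enumerate_arrangements(locus)) {
  seqs <- vapply(space$arrangements, function(a) locus_sequence(locus, a),
                 character(1))
  names(seqs) <- space$labels
  if (anyDuplicated(space$labels))
    stop_val("arrangement labels are not unique; are segment ORF labels distinct?")
  L <- nchar(seqs[[1L]])
  structure(list(space = space, sequences = seqs,
                 anchor_spans = list(
                   pilv = c(1L, nchar(locus$pilv_anchor)),
                   rci = c(L - nchar(locus$rci_anchor) + 1L, L))),
            class = "candidate_set")
}

#' Closure of the reference arrangement under repeat-pair inversions
#'
#' Breadth-first search from the reference state under the Rci operation
#' "invert everything strictly between any two inverted-repeat sites".  At
#' the arrangement level an inversion reverses a contiguous block of
#' positions and flips its orientations.  Serves as an independent oracle
#' for [enumerate_arrangements()].
#'
#' @param locus a [shufflon_locus()] (or integer segment count).
#' @param max_states search guard; exceeded state counts raise an error.
#' @return list of reachable [arrangement()]s (keyed set order).
#' @export
inversion_closure <- function(locus, max_states = 10000L) {
  n <- if (inherits(locus, "shufflon_locus")) n_segments(locus) else as.integer(locus)
  start <- arrangement(seq_len(n), rep(1L, n))
  seen <- new.env(parent = emptyenv())
  assign(arrangement_key(start), start, envir = seen)
  queue <- list(start)
  while (length(queue) > 0L) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (p in seq_len(n)) for (q in p:n) {
      ord <- cur$order; ori <- cur$orient
      ord[p:q] <- rev(ord[p:q])
      ori[p:q] <- -rev(ori[p:q])
      nxt <- arrangement(ord, ori)
      key <- arrangement_key(nxt)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        if (length(ls(seen)) >= max_states)
          stop_val("inversion closure exceeded max_states = %d", max_states)
        assign(key, nxt, envir = seen)
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  mget(sort(ls(seen)), envir = seen)
}

#' Number of possible pilV variants for a segment set
#'
#' Each two-ORF segment contributes two pilV 3'-end variants, each one-ORF
#' segment contributes one (7 for the R64 model: three two-ORF segments plus
#' segment D).
#'
#' @param segments list of [segment_def()]s, or a [shufflon_locus()].
#' @return integer variant count.
#' @export
count_pilv_variants <- function(segments) {
  if (inherits(segments, "shufflon_locus")) segments <- segments$segments
  if (length(segments) == 0L) return(0L)
  sum(vapply(segments, function(s) if (isTRUE(s$two_orf)) 2L else 1L, integer(1)))
}
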