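# Inverted-repeat conservation analysis: per-end repeat extraction,
# degenerate consensus, identity/Hamming matrices, position frequency
# matrix, identity profile and the SNV minimum spanning network.
#
# Repeats are fixed-length recombination sites; comparisons are gap-free.
# Left-end sites are annotated on the minus strand and are stored in
# consensus orientation, so all 2n per-end sequences are directly alignable.

#' Extract the per-end repeat set of a locus
#'
#' Returns one sequence per segment end (2n for an n-segment locus, e.g. six
#' for a 3-segment locus), each in consensus orientation (minus-strand left
#' sites reverse-complemented onto the right-repeat strand), optionally
#' extended inward into the segment body to a conserved-window length.
#'
#' @param locus a [shufflon_locus()].
#' @param window_len total window length per repeat; `NULL` keeps the bare
#'   repeat site.  The window is the repeat site plus
#'   `window_len - nchar(site)` nt of the adjacent segment end, read in
#'   consensus orientation (default 23 for a 20-nt site: 3 nt extension).
#' @return named character vector labelled `<segment>_L` / `<segment>_R`.
#' @export
repeat_set <- function(locus, window_len = NULL) {
  out <- character(0)
  for (s in locus$segments) {
    left <- s$left_repeat       # consensus-oriented; body continues 3'->5'
    right <- s$right_repeat
    if (!is.null(window_len)) {
      extl <- window_len - nchar(left)
      extr <- window_len - nchar(right)
      if (extl < 0L || extr < 0L)
        stop_val("window_len %d shorter than repeat site", window_len)
      # consensus orientation points outward from the segment: the window
      # extension continues into the segment end adjacent to each site.
      if (extl > 0L)
        left <- paste0(left, rc(substr(s$body, 1L, extl)))
      if (extr > 0L)
        right <- paste0(right, substr(s$body, nchar(s$body) - extr + 1L,
                                      nchar(s$body)))
    }
    out[paste0(s$name, "_L")] <- left
    out[paste0(s$name, "_R")] <- right
  }
  out
}

check_equal_lengths <- function(repeats) {
  if (length(repeats) == 0L) stop_val("empty repeat set")
  L <- nchar(repeats)
  if (length(unique(L)) != 1L)
    stop_val("repeats must have equal lengths (got %s)",
             paste(unique(L), collapse = ", "))
  invisible(L[1L])
}

repeat_matrix <- function(repeats) {
  check_equal_lengths(repeats)
  m <- do.call(rbind, strsplit(repeats, "", fixed = TRUE))
  rownames(m) <- names(repeats)
  m
}

#' Degenerate consensus of a repeat set
#'
#' Per position, emits the base whose frequency reaches
#' `ambiguity_threshold` (default 1.0, strict unanimity) and `N` otherwise,
#' reproducing degenerate site descriptions such as
#' `GTGCCAATCCGGTNNGTGGA`.
#'
#' @param repeats equal-length character vector of repeat sequences.
#' @param ambiguity_threshold frequency threshold in (0.5, 1].
#' @return consensus DNA string with `N` at non-conserved positions.
#' @export
degenerate_consensus <- function(repeats, ambiguity_threshold = 1.0) {
  if (ambiguity_threshold <= 0.5 || ambiguity_threshold > 1)
    stop_val("ambiguity_threshold must be in (0.5, 1]")
  m <- repeat_matrix(repeats)
  paste(apply(m, 2L, function(col) {
    tb <- table(col)
    top <- which.max(tb)
    if (tb[top] / length(col) >= ambiguity_threshold) names(tb)[top] else "N"
  }), collapse = "")
}

#' Position frequency matrix of a repeat set
#'
#' @param repeats equal-length character vector.
#' @return integer matrix with rows A, C, G, T; column sums equal the number
#'   of repeats.
#' @export
position_frequency_matrix <- function(repeats) {
  m <- repeat_matrix(repeats)
  bases <- c("A", "C", "G", "T")
  pfm <- vapply(seq_len(ncol(m)), function(j)
    table(factor(m[, j], levels = bases)), integer(4))
  rownames(pfm) <- bases
  colnames(pfm) <- seq_len(ncol(m))
  pfm
}

#' Pairwise percent identity matrix
#'
#' Gap-free per-position comparison: identity = matches / length * 100.
#'
#' @param repeats equal-length character vector.
#' @return symmetric numeric matrix (diagonal 100).
#' @export
pairwise_identity <- function(repeats) {
  m <- repeat_matrix(repeats)
  n <- nrow(m); L <- ncol(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    id <- 100 * sum(m[i, ] == m[j, ]) / L
    out[i, j] <- id; out[j, i] <- id
  }
  out
}

#' Hamming distance matrix over a conserved window
#'
#' @param repeats equal-length character vector.
#' @param window number of leading positions compared (default 23, the
#'   conserved-window length); must not exceed the repeat length.
#' @return symmetric integer matrix of per-window mismatch counts.
#' @export
hamming_matrix <- function(repeats, window = 23L) {
  L <- check_equal_lengths(repeats)
  if (window > L) stop_val("window %d exceeds repeat length %d", window, L)
  m <- repeat_matrix(repeats)[, seq_len(window), drop = FALSE]
  n <- nrow(m)
  out <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- sum(m[i, ] != m[j, ])
    out[i, j] <- d; out[j, i] <- d
  }
  out
}

#' Per-position identity profile against a reference
#'
#' Fraction of sequences matching the reference base at each position,
#' optionally smoothed with a sliding window mean.
#'
#' @param sequences equal-length character vector anchored to the reference
#'   coordinates.
#' @param reference reference sequence (same length).
#' @param window_step sliding window width (1 = per position).
#' @return numeric vector of identical fractions.
#' @export
identity_profile <- function(sequences, reference, window_step = 1L) {
  if (length(sequences) == 0L) stop_val("empty input")
  L <- check_equal_lengths(c(sequences, reference))
  m <- repeat_matrix(sequences)
  ref <- seq_chars(reference)
  prof <- colMeans(sweep(m, 2L, ref, "=="))
  if (window_step > 1L)
    prof <- stats::filter(prof, rep(1 / window_step, window_step), sides = 2)
  as.numeric(prof)
}

#' Minimum spanning network of repeat SNVs
#'
#' Builds a minimum spanning tree on the Hamming distance matrix (Kruskal,
#' deterministic label-sorted tie-breaking) and augments it with every
#' non-tree edge whose weight ties the maximum edge weight on the tree path
#' between its endpoints (the epsilon-0 minimum spanning network used for
#' haplotype-style SNV networks).  Edge weights are SNV counts.
#'
#' @param dist_matrix symmetric non-negative distance matrix with labelled
#'   rows/columns.
#' @return object of class `snv_network`: list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `weight`, `in_tree`), `tree_weight`,
#'   `connected`.
#' @export
min_spanning_network <- function(dist_matrix) {
  if (!isSymmetric(unname(dist_matrix))) stop_val("distance matrix must be symmetric")
  nodes <- rownames(dist_matrix) %||% as.character(seq_len(nrow(dist_matrix)))
  n <- length(nodes)
  pairs <- which(upper.tri(dist_matrix), arr.ind = TRUE)
  e <- data.frame(from = nodes[pairs[, 1L]], to = nodes[pairs[, 2L]],
                  weight = dist_matrix[pairs], stringsAsFactors = FALSE)
  e <- e[order(e$weight, e$from, e$to), , drop = FALSE]
  # Kruskal with union-find
  parent <- seq_len(n); names(parent) <- nodes
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  e$in_tree <- FALSE
  for (i in seq_len(nrow(e))) {
    ra <- find(match(e$from[i], nodes)); rb <- find(match(e$to[i], nodes))
    if (ra != rb) { parent[ra] <- rb; e$in_tree[i] <- TRUE }
  }
  tree <- e[e$in_tree, , drop = FALSE]
  # adjacency of the tree for path-max queries
  path_max <- function(a, b) {
    # DFS from a to b over tree edges, tracking the max weight en route
    stack <- list(list(node = a, mx = -Inf, from = NA))
    while (length(stack)) {
      s <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (s$node == b) return(s$mx)
      inc <- which((tree$from == s$node | tree$to == s$node))
      for (i in inc) {
        nb <- if (tree$from[i] == s$node) tree$to[i] else tree$from[i]
        if (!identical(nb, s$from))
          stack[[length(stack) + 1L]] <- list(node = nb,
                                              mx = max(s$mx, tree$weight[i]),
                                              from = s$node)
      }
    }
    Inf  # disconnected
  }
  keep <- e$in_tree
  for (i in which(!e$in_tree))
    if (e$weight[i] <= path_max(e$from[i], e$to[i])) keep[i] <- TRUE
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 tree_weight = sum(tree$weight),
                 connected = sum(tree$in_tree) == n - 1L),
            class = "snv_network")
}

#' @export
print.snv_network <- function(x, ...) {
  cat(sprintf("SNV minimum spanning network: %d nodes, %d edges (tree weight %g)\n",
              length(x$nodes), nrow(x$edges), x$tree_weight))
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' @method plot snv_network
#' @export
plot.snv_network <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop_val("plotting the network requires the igraph package")
  g <- igraph::graph_from_data_frame(x$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = x$nodes)
  igraph::plot.igraph(g, edge.label = x$edges$weight, ...)
  invisible(x)
}
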