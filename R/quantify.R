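# Long-read quantitative structural variation analysis: candidate sequences
# for every arrangement are searched against the reads with BLASTN, HSPs are
# chained collinearly per read/candidate/strand, and a read is counted only
# when its best chain covers the shufflon-adjacent parts of both the pilV
# and rci anchors (a "spanning" read).

#' Parameters for read-to-arrangement assignment
#'
#' @param min_identity minimum chain-level percent identity / 100
#'   (default 0.80, indel-tolerant long-read setting).
#' @param margin ambiguity margin: the best candidate's chain score must
#'   exceed the runner-up candidate's by this fraction of the best score
#'   (default 0.02), otherwise the read is `ambiguous`.
#' @param min_anchor_cov nt of each anchor, adjacent to the shufflon, that
#'   the chain must cover for the read to count as spanning (default 50).
#' @param anchor_extent nt of each anchor retained in the BLAST search
#'   sequences (default 150; anchors beyond this carry no arrangement
#'   information and only slow the search).
#' @param word_size BLASTN word size (default 16, `-task blastn`).
#' @param reward,penalty,gapopen,gapextend BLASTN match/mismatch/gap scores
#'   (defaults 1/-2/2/2, a gap-tolerant scheme suited to indel-dominated
#'   long-read error profiles).
#' @param evalue BLASTN e-value cutoff.
#' @param max_overlap maximum coordinate overlap tolerated between chained
#'   HSPs (nt).
#' @return a list of class `assign_params`.
#' @export
assign_params <- function(min_identity = 0.80, margin = 0.02,
                          min_anchor_cov = 50L, anchor_extent = 150L,
                          word_size = 16L, evalue = 1e-10,
                          reward = 1L, penalty = -2L,
                          gapopen = 2L, gapextend = 2L,
                          max_overlap = 25L) {
  if (anchor_extent < min_anchor_cov)
    stop_val("anchor_extent must be >= min_anchor_cov")
  structure(list(min_identity = min_identity, margin = margin,
                 min_anchor_cov = as.integer(min_anchor_cov),
                 anchor_extent = as.integer(anchor_extent),
                 word_size = as.integer(word_size), evalue = evalue,
                 reward = as.integer(reward), penalty = as.integer(penalty),
                 gapopen = as.integer(gapopen),
                 gapextend = as.integer(gapextend),
                 max_overlap = as.integer(max_overlap)),
            class = "assign_params")
}

check_blast <- function() {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop_val("NCBI BLAST+ (blastn/makeblastdb) must be on the PATH")
}

# Run blastn of reads (query) against candidate sequences (subject db) and
# return the tabular HSP table with normalised subject coordinates.
blast_hsps <- function(reads, candidates, params) {
  check_blast()
  td <- tempfile("shufflonq_blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  db_fa <- file.path(td, "cand.fa")
  q_fa <- file.path(td, "reads.fa")
  cand_names <- sprintf("cand%04d", seq_along(candidates))
  writeLines(paste0(">", cand_names, "\n", unname(candidates)), db_fa)
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  writeLines(paste0(">", names(reads), "\n", unname(reads)), q_fa)
  out <- file.path(td, "hits.tsv")
  status <- system2("makeblastdb",
                    c("-in", db_fa, "-dbtype", "nucl", "-logfile",
                      file.path(td, "db.log")))
  if (status != 0L) stop_val("makeblastdb failed")
  status <- system2("blastn",
                    c("-task", "blastn", "-db", db_fa, "-query", q_fa,
                      "-word_size", params$word_size, "-evalue",
                      format(params$evalue), "-dust", "no",
                      "-reward", params$reward, "-penalty", params$penalty,
                      "-gapopen", params$gapopen, "-gapextend", params$gapextend,
                      "-max_target_seqs", "500",
                      "-outfmt", shQuote(paste("6 qseqid sseqid pident length",
                                               "qstart qend sstart send bitscore")),
                      "-out", out))
  if (status != 0L) stop_val("blastn failed")
  if (file.size(out) == 0L) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      bitscore = numeric(0), strand = character(0),
                      s1 = integer(0), s2 = integer(0)))
  }
  h <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE,
                         quote = "", comment.char = "",
                         col.names = c("qseqid", "sseqid", "pident", "length",
                                       "qstart", "qend", "sstart", "send",
                                       "bitscore"))
  h$sseqid <- candidates_label(h$sseqid, cand_names, names(candidates))
  h$strand <- ifelse(h$sstart <= h$send, "+", "-")
  h$s1 <- pmin(h$sstart, h$send)
  h$s2 <- pmax(h$sstart, h$send)
  h
}

candidates_label <- function(ids, cand_names, labels) labels[match(ids, cand_names)]

# Best collinear chain of HSPs for one read/candidate/strand group.
# Coordinates must increase together along query and subject (subject axis
# flipped for minus-strand groups).  Returns score, identity and covered
# subject intervals.
best_chain <- function(g, cand_len, max_overlap) {
  k <- nrow(g)
  cs <- if (g$strand[1L] == "+") g$s1 else cand_len - g$s2 + 1L
  ce <- if (g$strand[1L] == "+") g$s2 else cand_len - g$s1 + 1L
  o <- order(g$qstart, g$qend)
  g <- g[o, , drop = FALSE]; cs <- cs[o]; ce <- ce[o]
  best <- g$bitscore
  prev <- rep(0L, k)
  if (k > 1L) for (i in 2:k) for (j in 1:(i - 1L)) {
    if (g$qend[j] <= g$qstart[i] + max_overlap &&
        ce[j] <= cs[i] + max_overlap) {
      sc <- best[j] + g$bitscore[i]
      if (sc > best[i]) { best[i] <- sc; prev[i] <- j }
    }
  }
  top <- which.max(best)
  chain <- integer(0); i <- top
  while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
  len <- sum(g$length[chain])
  list(score = best[top],
       identity = sum(g$pident[chain] * g$length[chain]) / len / 100,
       s1 = g$s1[chain], s2 = g$s2[chain])
}

# Does a set of subject intervals cover [a, b] entirely?
covers_interval <- function(s1, s2, a, b) {
  o <- order(s1)
  s1 <- s1[o]; s2 <- s2[o]
  reach <- a - 1L
  for (i in seq_along(s1)) {
    if (s1[i] > reach + 1L) break
    reach <- max(reach, s2[i])
    if (reach >= b) return(TRUE)
  }
  FALSE
}

#' Assign reads to whole-shufflon arrangements
#'
#' Each candidate arrangement sequence (and its reverse complement, via
#' strand-aware chaining) is locally aligned against every read with BLASTN;
#' HSPs are chained collinearly and a read is `assigned` to the top-scoring
#' candidate whose chain covers the shufflon-adjacent `min_anchor_cov` nt of
#' both anchors, provided the score margin over the runner-up candidate is
#' met.  Reads failing the anchor requirement are `non_spanning`; reads with
#' no alignment at all are `no_match`; margin failures are `ambiguous`.
#'
#' @param reads named character vector / `DNAStringSet` of reads.
#' @param candidates a [candidate_set()].
#' @param params an [assign_params()].
#' @return data.frame with one row per read: `read_id`, `status`,
#'   `arrangement`, `score`, `runner_up_score`.
#' @export
assign_reads <- function(reads, candidates, params = assign_params()) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads); reads <- as.character(reads); names(reads) <- nm
  }
  if (length(reads) == 0L) stop_val("no reads supplied")
  if (any(!nzchar(reads))) stop_val("empty read supplied")
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  A <- candidates$anchor_spans
  ext <- min(params$anchor_extent, A$pilv[2L] - A$pilv[1L] + 1L,
             A$rci[2L] - A$rci[1L] + 1L)
  # search sequences keep `ext` nt of each anchor; coordinates shift left by
  # the trimmed pilV prefix
  trim0 <- A$pilv[2L] - ext
  seqs <- substr(candidates$sequences, trim0 + 1L, A$rci[1L] + ext - 1L)
  names(seqs) <- names(candidates$sequences)
  cand_len <- nchar(seqs[[1L]])
  cov <- params$min_anchor_cov
  pilv_win <- c(ext - cov + 1L, ext)                       # touches J0
  rci_win <- c(A$rci[1L] - trim0, A$rci[1L] - trim0 + cov - 1L)  # touches Jn

  h <- blast_hsps(reads, seqs, params)
  res <- data.frame(read_id = names(reads), status = "no_match",
                    arrangement = NA_character_, score = NA_real_,
                    runner_up_score = NA_real_, stringsAsFactors = FALSE)
  if (nrow(h) == 0L) return(res)
  # drop seed-sized HSPs: they neither cover anchors nor discriminate bodies
  keep <- h$length >= 40L
  if (any(keep)) h <- h[keep, , drop = FALSE]
  groups <- split(h, paste(h$qseqid, h$sseqid, h$strand, sep = "\r"),
                  drop = TRUE)
  chains <- lapply(groups, best_chain, cand_len = cand_len,
                   max_overlap = params$max_overlap)
  key <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  meta <- data.frame(read = key[, 1L], cand = key[, 2L], strand = key[, 3L],
                     stringsAsFactors = FALSE)
  meta$score <- vapply(chains, `[[`, numeric(1), "score")
  meta$identity <- vapply(chains, `[[`, numeric(1), "identity")
  meta$spanning <- vapply(chains, function(ch)
    covers_interval(ch$s1, ch$s2, pilv_win[1L], pilv_win[2L]) &&
    covers_interval(ch$s1, ch$s2, rci_win[1L], rci_win[2L]), logical(1))

  for (m in split(meta, meta$read)) {
    rid <- m$read[1L]
    ok <- m[m$spanning & m$identity >= params$min_identity, , drop = FALSE]
    i <- match(rid, res$read_id)
    if (nrow(ok) == 0L) { res$status[i] <- "non_spanning"; next }
    # best chain per candidate (either strand)
    percand <- vapply(split(ok$score, ok$cand), max, numeric(1))
    percand <- sort(percand, decreasing = TRUE)
    best <- percand[1L]
    runner <- if (length(percand) > 1L) percand[2L] else NA_real_
    res$score[i] <- best
    res$runner_up_score[i] <- runner
    if (is.na(runner) || runner < best * (1 - params$margin)) {
      res$status[i] <- "assigned"
      res$arrangement[i] <- names(percand)[1L]
    } else {
      res$status[i] <- "ambiguous"
    }
  }
  res
}

#' Assign a single read
#'
#' Single-read convenience wrapper around [assign_reads()].
#'
#' @param read one read sequence (character).
#' @param candidates a [candidate_set()].
#' @param params an [assign_params()].
#' @return one-row assignment data.frame (see [assign_reads()]).
#' @export
assign_read <- function(read, candidates, params = assign_params()) {
  if (length(read) != 1L || is.na(read) || !nzchar(read))
    stop_val("assign_read expects a single non-empty read")
  if (is.null(names(read))) names(read) <- "read1"
  assign_reads(read, candidates, params)
}

#' Quantify whole-shufflon structure abundances from long reads
#'
#' Runs [assign_reads()] over all reads against the full candidate set of
#' the locus and tabulates per-arrangement counts and ratios over assigned
#' reads (ambiguous reads are excluded from the denominator and reported in
#' the totals).
#'
#' @param reads named character vector, `DNAStringSet`, or path to a
#'   FASTA/FASTQ file.
#' @param locus a [shufflon_locus()].
#' @param params an [assign_params()].
#' @param candidates optional pre-built [candidate_set()].
#' @return an object of class `abundance_table`: data.frame with columns
#'   `arrangement`, `count`, `ratio` (sorted by ratio descending, ties by
#'   label), with attributes `totals`, `n_candidates` and `assignments`.
#' @export
quantify_structures <- function(reads, locus, params = assign_params(),
                                candidates = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_sequences(reads)
  if (is.null(candidates)) candidates <- candidate_set(locus)
  asn <- assign_reads(reads, candidates, params)
  tab_from_assignments(asn, candidates$space$count)
}

tab_from_assignments <- function(asn, n_candidates) {
  totals <- c(total = nrow(asn),
              assigned = sum(asn$status == "assigned"),
              ambiguous = sum(asn$status == "ambiguous"),
              non_spanning = sum(asn$status == "non_spanning"),
              no_match = sum(asn$status == "no_match"))
  hit <- asn[asn$status == "assigned", , drop = FALSE]
  if (nrow(hit) == 0L) {
    tab <- data.frame(arrangement = character(0), count = integer(0),
                      ratio = numeric(0))
    attr(tab, "empty") <- TRUE
  } else {
    cnt <- table(hit$arrangement)
    tab <- data.frame(arrangement = names(cnt), count = as.integer(cnt),
                      ratio = as.integer(cnt) / sum(cnt),
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$ratio, tab$arrangement), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "empty") <- FALSE
  }
  attr(tab, "totals") <- totals
  attr(tab, "n_candidates") <- n_candidates
  attr(tab, "assignments") <- asn
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

#' @export
print.abundance_table <- function(x, digits = 3, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("Whole-shufflon abundance table: %d of %d candidate structures detected\n",
              nrow(x), attr(x, "n_candidates")))
  cat(sprintf("reads: %d total | %d assigned | %d ambiguous | %d non-spanning | %d no-match\n",
              tot["total"], tot["assigned"], tot["ambiguous"],
              tot["non_spanning"], tot["no_match"]))
  if (isTRUE(attr(x, "empty"))) {
    cat("  (no assigned reads; ratio section empty)\n")
  } else {
    df <- as.data.frame(x)
    df$ratio <- sprintf(paste0("%.", digits - 2, "f%%"), 100 * df$ratio)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' @method summary abundance_table
#' @export
summary.abundance_table <- function(object, ...) {
  tot <- attr(object, "totals")
  structure(list(table = as.data.frame(object), totals = tot,
                 n_detected = nrow(object),
                 n_candidates = attr(object, "n_candidates")),
            class = "summary.abundance_table")
}

#' @export
print.summary.abundance_table <- function(x, ...) {
  cat(sprintf("%d/%d structures detected; top: %s (%.1f%%)\n",
              x$n_detected, x$n_candidates,
              if (nrow(x$table)) x$table$arrangement[1] else "-",
              if (nrow(x$table)) 100 * x$table$ratio[1] else 0))
  print(x$totals)
  invisible(x)
}

#' Reconstruct an arrangement directly from marker matches
#'
#' Independent oracle for [assign_reads()]: locates exact (or
#' near-exact) matches of the anchor markers and every segment body in the
#' read, orders them by position and reads off the (order, orientation)
#' vector without any candidate construction.  Intended for clean reads;
#' returns `NULL` when markers are missing, duplicated or out of order.
#'
#' @param read one read (character).
#' @param locus a [shufflon_locus()].
#' @param marker_len anchor marker length (nt, taken adjacent to the locus).
#' @param max_mismatch allowed mismatches (with indels when > 0).
#' @return an [arrangement()], or `NULL`.
#' @export
reconstruct_from_markers <- function(read, locus, marker_len = 50L,
                                     max_mismatch = 0L) {
  if (length(read) != 1L || !nzchar(read)) return(NULL)
  n <- n_segments(locus)
  pilv_m <- substr(locus$pilv_anchor,
                   nchar(locus$pilv_anchor) - marker_len + 1L,
                   nchar(locus$pilv_anchor))
  rci_m <- substr(locus$rci_anchor, 1L, marker_len)
  find1 <- function(pattern, subject) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = max_mismatch,
                                  with.indels = max_mismatch > 0L)
    if (length(m) != 1L) return(NA_integer_)
    Biostrings::start(m)
  }
  for (orient_read in c(FALSE, TRUE)) {
    subj <- Biostrings::DNAString(if (orient_read) rc(read) else read)
    p0 <- find1(pilv_m, subj)
    if (is.na(p0)) next
    r0 <- find1(rci_m, subj)
    if (is.na(r0) || r0 <= p0) next
    pos <- integer(n); ori <- integer(n)
    ok <- TRUE
    for (k in seq_len(n)) {
      body <- locus$segments[[k]]$body
      fwd <- find1(body, subj)
      rev <- find1(rc(body), subj)
      if (is.na(fwd) == is.na(rev)) { ok <- FALSE; break }  # none or both
      pos[k] <- if (!is.na(fwd)) fwd else rev
      ori[k] <- if (!is.na(fwd)) 1L else -1L
      if (pos[k] < p0 || pos[k] > r0) { ok <- FALSE; break }
    }
    if (!ok) next
    o <- order(pos)
    return(arrangement(order = o, orient = ori[o]))
  }
  NULL
}
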