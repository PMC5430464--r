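# pilV variant typing from junction-containing reads.
#
# A read is informative for the pilV variant when it contains part of the
# main pilV 3' constant region, an inverted-repeat site, and part of the
# adjacent shufflon segment.  The variant is the ORF-end label fused to the
# pilV 3' end across the repeat; typing works on both platforms (PacBio-like
# long reads and MiSeq-like short pairs) with platform-specific identity
# thresholds.

#' Parameters for pilV junction typing
#'
#' @param min_pilv minimum nt of the pilV 3' constant region that must be
#'   aligned (default 20).
#' @param min_seg minimum nt of segment sequence that must be aligned
#'   (default 20).
#' @param min_repeat_overlap minimum nt of the inverted repeat that must be
#'   covered (default 10).
#' @param identity_short,identity_long minimum alignment identity per
#'   platform (defaults 0.90 / 0.80).
#' @return a list of class `pilv_params`.
#' @export
pilv_params <- function(min_pilv = 20L, min_seg = 20L,
                        min_repeat_overlap = 10L,
                        identity_short = 0.90, identity_long = 0.80) {
  structure(list(min_pilv = as.integer(min_pilv),
                 min_seg = as.integer(min_seg),
                 min_repeat_overlap = as.integer(min_repeat_overlap),
                 identity_short = identity_short,
                 identity_long = identity_long),
            class = "pilv_params")
}

# Junction reference sequences: pilV tail + J0 + oriented segment head, one
# per (segment, orientation) that places an ORF end next to pilV.
junction_refs <- function(locus, params = pilv_params(), flank = 30L) {
  j0 <- locus$junctions[1L]
  pilv_tail <- substr(locus$pilv_anchor,
                      nchar(locus$pilv_anchor) - flank + 1L,
                      nchar(locus$pilv_anchor))
  refs <- list()
  for (k in seq_along(locus$segments)) {
    s <- locus$segments[[k]]
    for (o in c(1L, -1L)) {
      lab <- if (o > 0L) s$orf_left else s$orf_right
      if (is.na(lab)) next
      body <- if (o > 0L) s$body else rc(s$body)
      refs[[length(refs) + 1L]] <- list(
        label = lab,
        seq = paste0(pilv_tail, j0, substr(body, 1L, flank)),
        pilv_end = nchar(pilv_tail),
        rep_end = nchar(pilv_tail) + nchar(j0))
    }
  }
  refs
}

# Precomputed typing context: junction references plus an exact k-mer
# dictionary over the pilV anchor tail, built once per read set.
pilv_typer_ctx <- function(locus, params = pilv_params(), k = 16L,
                           tail_len = 100L, flank = 30L) {
  tl <- min(tail_len, nchar(locus$pilv_anchor))
  if (tl < k) stop_val("pilV anchor shorter than the locator k-mer")
  tail_seq <- substr(locus$pilv_anchor,
                     nchar(locus$pilv_anchor) - tl + 1L,
                     nchar(locus$pilv_anchor))
  kmers <- substring(tail_seq, 1:(tl - k + 1L), k:tl)
  refs <- junction_refs(locus, params, flank = flank)
  list(pd = Biostrings::PDict(kmers), tl = tl,
       refs = refs,
       labels = vapply(refs, `[[`, character(1), "label"),
       # indel-tolerant local alignment scoring (gap cost ~ mismatch cost)
       submat = Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                         mismatch = -4),
       gap_open = 3, gap_ext = 2)
}

# k-mer based localisation of the pilV anchor tail in a read.  Returns
# list(strand, junction_pos) or NULL; junction_pos is the estimated 1-based
# read position just after the pilV anchor.
locate_pilv_junction <- function(read, locus, k = 16L, tail_len = 100L,
                                 ctx = NULL) {
  if (is.null(ctx)) ctx <- pilv_typer_ctx(locus, k = k, tail_len = tail_len)
  for (strand in c("+", "-")) {
    subj <- Biostrings::DNAString(if (strand == "+") read else rc(read))
    m <- Biostrings::matchPDict(ctx$pd, subj)
    starts <- Biostrings::startIndex(m)
    hits <- which(lengths(starts) > 0L)
    if (length(hits) < 2L) next
    # estimate of the anchor-end position from each hit
    est <- unlist(lapply(hits, function(i) starts[[i]] + (ctx$tl - i + 1L)))
    return(list(strand = strand, junction_pos = as.integer(stats::median(est))))
  }
  NULL
}

#' Type the pilV variant of one read
#'
#' Locates the pilV 3' junction in the read (either strand), then aligns
#' every ORF-end junction reference across the repeat and returns the label
#' of the best reference meeting the identity threshold and the minimum
#' pilV-side, repeat and segment-side coverage.  Returns `NA` for
#' uninformative reads (no junction, threshold failures, or score ties).
#'
#' @param read one read (character).
#' @param locus a [shufflon_locus()].
#' @param platform `"long"` or `"short"` (selects the identity threshold).
#' @param params a [pilv_params()].
#' @param .ctx precomputed typing context (internal; [variant_ratios()]
#'   builds it once per read set).
#' @return a variant label, or `NA_character_`.
#' @export
type_read <- function(read, locus, platform = c("short", "long"),
                      params = pilv_params(), .ctx = NULL) {
  platform <- match.arg(platform)
  if (length(read) != 1L || is.na(read) || !nzchar(read)) return(NA_character_)
  type_reads(read, locus, platform, params, .ctx = .ctx)[[1L]]
}

# Vectorised junction typing: one batched local alignment per junction
# reference over all located windows.
type_reads <- function(reads, locus, platform = c("short", "long"),
                       params = pilv_params(), .ctx = NULL) {
  platform <- match.arg(platform)
  min_id <- if (platform == "short") params$identity_short else params$identity_long
  ctx <- .ctx %||% pilv_typer_ctx(locus, params)
  res <- rep(NA_character_, length(reads))
  ok <- !is.na(reads) & nzchar(reads)
  locs <- vector("list", length(reads))
  locs[ok] <- lapply(reads[ok], locate_pilv_junction, locus, ctx = ctx)
  found <- which(!vapply(locs, is.null, logical(1)))
  if (length(found) == 0L) return(res)
  refs <- ctx$refs
  ref_len <- nchar(refs[[1L]]$seq)
  pilv_end <- refs[[1L]]$pilv_end
  windows <- vapply(found, function(i) {
    loc <- locs[[i]]
    oriented <- if (loc$strand == "+") reads[[i]] else rc(reads[[i]])
    w1 <- max(1L, loc$junction_pos - pilv_end - 20L)
    w2 <- min(nchar(oriented), loc$junction_pos + (ref_len - pilv_end) + 40L)
    substr(oriented, w1, w2)
  }, character(1))
  subj <- Biostrings::DNAStringSet(windows)
  M <- length(found); R <- length(refs)
  scores <- matrix(-Inf, M, R)
  for (i in seq_len(R)) {
    r <- refs[[i]]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(rep(r$seq, M)), subj, type = "local",
      substitutionMatrix = ctx$submat,
      gapOpening = ctx$gap_open, gapExtension = ctx$gap_ext)
    pr <- Biostrings::pattern(aln)
    a <- Biostrings::start(pr); b <- Biostrings::end(pr)
    pilv_cov <- pmax(0L, pmin(b, r$pilv_end) - a + 1L)
    rep_cov <- pmax(0L, pmin(b, r$rep_end) - pmax(a, r$pilv_end + 1L) + 1L)
    seg_cov <- pmax(0L, b - pmax(a, r$rep_end + 1L) + 1L)
    ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    pass <- pilv_cov >= params$min_pilv & seg_cov >= params$min_seg &
      rep_cov >= params$min_repeat_overlap & ident >= min_id
    sc <- Biostrings::score(aln)
    scores[pass, i] <- sc[pass]
  }
  labels <- ctx$labels
  for (m in seq_len(M)) {
    sc <- scores[m, ]
    if (!any(is.finite(sc))) next
    best <- which.max(sc)
    others <- sc[labels != labels[best]]
    if (length(others) && max(others) >= sc[best]) next  # tie: uninformative
    res[found[m]] <- labels[best]
  }
  res
}

#' pilV variant ratios over a read set
#'
#' Types every read (or read pair) with [type_read()] and tabulates per
#' variant counts and ratios over informative reads.  For paired input the
#' mates are typed independently and a pair contributes one count only when
#' the typed mates agree (a disagreeing pair is uninformative).
#'
#' @param reads named character vector / `DNAStringSet` / FASTA/FASTQ path;
#'   or a list with elements `r1` and `r2` for paired reads.
#' @param locus a [shufflon_locus()].
#' @param platform `"short"` or `"long"`.
#' @param params a [pilv_params()].
#' @return object of class `variant_table`: data.frame `variant`, `count`,
#'   `ratio`, with attributes `total_informative`, `platform`.
#' @export
variant_ratios <- function(reads, locus, platform = c("short", "long"),
                           params = pilv_params()) {
  platform <- match.arg(platform)
  as_chr <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      x <- read_sequences(x)
    if (inherits(x, "DNAStringSet")) {
      nm <- names(x); x <- as.character(x); names(x) <- nm
    }
    x
  }
  ctx <- pilv_typer_ctx(locus, params)
  if (is.list(reads) && !is.null(reads$r1)) {
    r1 <- as_chr(reads$r1); r2 <- as_chr(reads$r2)
    t1 <- type_reads(r1, locus, platform, params, .ctx = ctx)
    t2 <- type_reads(r2, locus, platform, params, .ctx = ctx)
    lab <- ifelse(is.na(t1), t2,
                  ifelse(is.na(t2), t1, ifelse(t1 == t2, t1, NA_character_)))
  } else {
    r <- as_chr(reads)
    lab <- type_reads(r, locus, platform, params, .ctx = ctx)
  }
  lab <- lab[!is.na(lab)]
  variant_table(lab, locus, platform)
}

variant_table <- function(labels, locus, platform) {
  all_labs <- sort(unlist(lapply(locus$segments, function(s)
    c(s$orf_left, s$orf_right))))
  all_labs <- all_labs[!is.na(all_labs)]
  cnt <- table(factor(labels, levels = all_labs))
  tab <- data.frame(variant = names(cnt), count = as.integer(cnt),
                    ratio = if (sum(cnt) > 0) as.integer(cnt) / sum(cnt)
                            else rep(NA_real_, length(cnt)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "total_informative") <- as.integer(sum(cnt))
  attr(tab, "platform") <- platform
  attr(tab, "empty") <- sum(cnt) == 0L
  class(tab) <- c("variant_table", "data.frame")
  tab
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("pilV variant ratios (%s platform): %d informative reads%s\n",
              attr(x, "platform"), attr(x, "total_informative"),
              if (isTRUE(attr(x, "empty"))) " [empty]" else ""))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Marginal pilV variant frequencies of an abundance table
#'
#' Collapses whole-structure abundances to pilV variant frequencies by
#' mapping every arrangement to the ORF end its first oriented segment fuses
#' to pilV.  Cross-check for [variant_ratios()] on the same reads.
#'
#' @param tab an `abundance_table` from [quantify_structures()].
#' @param locus the [shufflon_locus()] the table was computed on.
#' @return a `variant_table`.
#' @export
structure_variant_marginals <- function(tab, locus) {
  space <- enumerate_arrangements(locus)
  adj <- vapply(space$arrangements, pilv_adjacent_orf, character(1),
                locus$segments)
  names(adj) <- space$labels
  labels <- rep(adj[tab$arrangement], tab$count)
  variant_table(labels[!is.na(labels)], locus, platform = "long")
}

#' Compare pilV variant ratios between two platforms
#'
#' Pairs the per-variant ratios of two [variant_ratios()] tables and
#' computes the squared Pearson correlation (the coefficient of
#' determination of the cross-platform scatter).
#'
#' @param table_a,table_b `variant_table` objects over the same variant set.
#' @return object of class `platform_comparison`: list with `variants`,
#'   `ratio_a`, `ratio_b`, `r_squared`, `platforms`.
#' @export
compare_platforms <- function(table_a, table_b) {
  la <- sort(table_a$variant); lb <- sort(table_b$variant)
  if (!identical(la, lb))
    stop_val("variant label sets differ between the two tables")
  if (length(la) < 2L)
    stop_val("need at least 2 shared variants for a correlation")
  a <- table_a$ratio[match(la, table_a$variant)]
  b <- table_b$ratio[match(la, table_b$variant)]
  if (any(is.na(a)) || any(is.na(b)))
    stop_val("both tables must contain informative reads")
  r2 <- stats::cor(a, b)^2
  structure(list(variants = la, ratio_a = a, ratio_b = b,
                 r_squared = r2,
                 platforms = c(attr(table_a, "platform") %||% "A",
                               attr(table_b, "platform") %||% "B")),
            class = "platform_comparison")
}

#' @export
print.platform_comparison <- function(x, ...) {
  cat(sprintf("Cross-platform pilV variant comparison (%s vs %s): R^2 = %.3f\n",
              x$platforms[1L], x$platforms[2L], x$r_squared))
  print(data.frame(variant = x$variants, ratio_a = x$ratio_a,
                   ratio_b = x$ratio_b), row.names = FALSE)
  invisible(x)
}
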