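# Shufflon locus model: domain types, GFF3/FASTA I/O and validation.
#
# A shufflon locus is modelled as an alternating skeleton
#   pilV_anchor  J0  S1  J1  S2 ... Sn  Jn  rci_anchor
# where S_k are invertible segment bodies (repeat-free) and J_i are junction
# elements made of one or two annotated inverted-repeat sites.  File-facing
# coordinates follow GFF3 (1-based, inclusive); internally everything is
# 0-based half-open.

LOCUS_FEATURE_TYPES <- c("pilv_anchor", "rci_anchor",
                         "shufflon_segment", "inverted_repeat")

#' Define a shufflon segment
#'
#' A segment is an invertible unit carrying one or two partial pilV ORF 3'
#' ends, one at each extremity (e.g. segment BD of IncI2 plasmids carries
#' ORF B' and ORF D'; segment D of R64 carries only ORF D).
#'
#' @param name segment label, e.g. `"BD"`.
#' @param body repeat-free segment interior sequence (ACGT only).
#' @param left_repeat,right_repeat flanking inverted-repeat site sequences in
#'   consensus orientation (~19-23 nt; IUPAC codes allowed).
#' @param orf_left,orf_right ORF-end labels at the left/right extremity in
#'   reference orientation, or `NULL` for a one-ORF segment.
#' @return an object of class `segment_def`.
#' @export
segment_def <- function(name, body, left_repeat, right_repeat,
                        orf_left = NULL, orf_right = NULL) {
  if (nchar(body) < 1L) stop_val("segment '%s': empty body", name)
  if (!is_dna(body)) stop_val("segment '%s': body must be ACGT only (no N)", name)
  for (r in list(left_repeat, right_repeat)) {
    if (is.null(r) || !nzchar(r)) stop_val("segment '%s': empty repeat", name)
    if (!is_dna(r, allow_iupac = TRUE)) stop_val("segment '%s': bad repeat alphabet", name)
  }
  orf_left <- orf_left %||% NA_character_
  orf_right <- orf_right %||% NA_character_
  two_orf <- !is.na(orf_left) && !is.na(orf_right)
  if (is.na(orf_left) && is.na(orf_right))
    stop_val("segment '%s': at least one ORF label required", name)
  structure(list(name = name, body = body,
                 left_repeat = left_repeat, right_repeat = right_repeat,
                 orf_left = orf_left, orf_right = orf_right,
                 two_orf = two_orf),
            class = "segment_def")
}

#' Construct a shufflon locus object
#'
#' Normally produced by [load_locus()] or [make_locus()]; exposed for
#' programmatic construction.
#'
#' @param plasmid_id replicon identifier.
#' @param plasmid_seq full plasmid sequence (character).
#' @param locus_start 0-based start of the pilV anchor on the plasmid.
#' @param pilv_anchor,rci_anchor constant flanking sequences (plus strand).
#' @param segments list of [segment_def()] objects in reference order.
#' @param junctions character vector of n+1 junction-element sequences
#'   (plasmid strand) interleaving anchors and segment bodies.
#' @param features annotation table (internal 0-based half-open coordinates)
#'   used for round-trip export; built automatically when `NULL`.
#' @param circular is the replicon circular?
#' @param min_anchor_len minimum accepted anchor length.
#' @return an object of class `shufflon_locus`.
#' @export
shufflon_locus <- function(plasmid_id, plasmid_seq, locus_start,
                           pilv_anchor, rci_anchor, segments, junctions,
                           features = NULL, circular = TRUE,
                           min_anchor_len = 50L) {
  n <- length(segments)
  if (n < 1L) stop_val("a shufflon locus needs at least one segment")
  if (length(junctions) != n + 1L)
    stop_val("expected %d junction elements for %d segments", n + 1L, n)
  if (nchar(pilv_anchor) < min_anchor_len || nchar(rci_anchor) < min_anchor_len)
    stop_val("anchors must be at least %d nt", min_anchor_len)
  stopifnot(all(vapply(segments, inherits, logical(1), "segment_def")))
  loc <- structure(list(
    plasmid_id = plasmid_id,
    plasmid_seq = toupper(plasmid_seq),
    plasmid_len = nchar(plasmid_seq),
    circular = circular,
    locus_start = as.integer(locus_start),
    pilv_anchor = toupper(pilv_anchor),
    rci_anchor = toupper(rci_anchor),
    segments = segments,
    junctions = toupper(junctions),
    features = features,
    reference_arrangement = arrangement(seq_len(n), rep(1L, n))
  ), class = "shufflon_locus")
  loc$locus_end <- loc$locus_start + nchar(locus_sequence(loc))
  if (is.null(loc$features)) loc$features <- default_features(loc)
  ref <- substr(loc$plasmid_seq, loc$locus_start + 1L, loc$locus_end)
  if (!identical(locus_sequence(loc), ref))
    stop_val("reference arrangement does not reproduce the annotated plasmid substring")
  loc
}

n_segments <- function(locus) length(locus$segments)

#' @export
print.shufflon_locus <- function(x, ...) {
  n <- n_segments(x)
  cat(sprintf("Shufflon locus on %s (%s, %d nt)\n", x$plasmid_id,
              if (x$circular) "circular" else "linear", x$plasmid_len))
  cat(sprintf("  locus span [%d, %d) (0-based), %d segment%s\n",
              x$locus_start, x$locus_end, n, if (n == 1L) "" else "s"))
  for (s in x$segments)
    cat(sprintf("  segment %-4s %4d nt  ORFs: %s%s\n", s$name, nchar(s$body),
                if (is.na(s$orf_left)) "-" else s$orf_left,
                if (is.na(s$orf_right)) "" else paste0("/", s$orf_right)))
  cat(sprintf("  reference: %s\n",
              arrangement_label(x$reference_arrangement, x$segments)))
  invisible(x)
}

# Sequence of the locus under an arrangement: anchors and junction elements
# stay fixed, segment bodies are permuted and oriented.  Inversions
# reverse-complement everything strictly between the recombining repeat pair,
# so a candidate differs from the reference only in its body blocks.
locus_sequence <- function(locus, arr = locus$reference_arrangement) {
  n <- n_segments(locus)
  bodies <- character(n)
  for (p in seq_len(n)) {
    b <- locus$segments[[arr$order[p]]]$body
    bodies[p] <- if (arr$orient[p] > 0L) b else rc(b)
  }
  parts <- character(2L * n + 3L)
  parts[1L] <- locus$pilv_anchor
  parts[2L] <- locus$junctions[1L]
  for (p in seq_len(n)) {
    parts[2L * p + 1L] <- bodies[p]
    parts[2L * p + 2L] <- locus$junctions[p + 1L]
  }
  parts[2L * n + 3L] <- locus$rci_anchor
  paste(parts, collapse = "")
}

# Default annotation table when a locus is built programmatically: each
# junction element is annotated as inverted-repeat sites, minus strand for
# left sites (their consensus orientation points back toward the segment).
default_features <- function(locus) {
  n <- n_segments(locus)
  rows <- list()
  pos <- locus$locus_start
  add <- function(type, len, strand = "+", name = NA, ol = NA, or = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, start0 = pos, end0 = pos + len, strand = strand,
      name = name, orf_left = ol, orf_right = or, stringsAsFactors = FALSE)
    pos <<- pos + len
  }
  add("pilv_anchor", nchar(locus$pilv_anchor))
  for (i in seq_len(n + 1L)) {
    jn <- locus$junctions[i]
    right_of <- if (i > 1L) locus$segments[[i - 1L]] else NULL
    left_of <- if (i <= n) locus$segments[[i]] else NULL
    rlen <- if (!is.null(right_of)) nchar(right_of$right_repeat) else 0L
    llen <- if (!is.null(left_of)) nchar(left_of$left_repeat) else 0L
    if (rlen + llen != nchar(jn))
      stop_val("junction %d length %d does not tile into repeat sites (%d + %d)",
               i - 1L, nchar(jn), rlen, llen)
    if (rlen > 0L)
      add("inverted_repeat", rlen, "+", paste0(right_of$name, "_R"))
    if (llen > 0L)
      add("inverted_repeat", llen, "-", paste0(left_of$name, "_L"))
    if (!is.null(left_of))
      add("shufflon_segment", nchar(left_of$body), "+", left_of$name,
          left_of$orf_left, left_of$orf_right)
  }
  add("rci_anchor", nchar(locus$rci_anchor))
  do.call(rbind, rows)
}

#' Load a shufflon locus from FASTA + GFF3
#'
#' The annotation must tile the locus contiguously with feature types
#' `pilv_anchor`, `inverted_repeat`, `shufflon_segment` and `rci_anchor`
#' (GFF3 coordinates are 1-based inclusive; they are converted to the
#' internal 0-based half-open convention).  Segment features carry `Name`,
#' `orf_left` and (for two-ORF segments) `orf_right` attributes.  Features
#' annotated on the minus strand are reverse-complemented into locus
#' orientation.
#'
#' @param fasta_path plasmid FASTA file.
#' @param annotation_path GFF3 annotation file.
#' @param min_anchor_len minimum accepted anchor length (nt).
#' @param circular is the plasmid circular?
#' @return a validated [shufflon_locus()] object.
#' @export
load_locus <- function(fasta_path, annotation_path, min_anchor_len = 50L,
                       circular = TRUE) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  gr <- rtracklayer::import(annotation_path)
  ft <- data.frame(
    type = as.character(gr$type),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    seqname = as.character(GenomicRanges::seqnames(gr)),
    stringsAsFactors = FALSE)
  ft$name <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  ft$orf_left <- if (!is.null(gr$orf_left)) as.character(gr$orf_left) else NA_character_
  ft$orf_right <- if (!is.null(gr$orf_right)) as.character(gr$orf_right) else NA_character_
  ft <- ft[ft$type %in% LOCUS_FEATURE_TYPES, , drop = FALSE]
  if (nrow(ft) == 0L) stop_val("no shufflon features in %s", annotation_path)

  plasmid_id <- ft$seqname[1L]
  ix <- which(sub("\\s.*$", "", names(fa)) == plasmid_id)
  if (length(ix) == 0L)
    stop_val("plasmid record '%s' not found in %s", plasmid_id, fasta_path)
  pseq <- toupper(as.character(fa[[ix[1L]]]))

  ft <- ft[order(ft$start0), !(names(ft) %in% "seqname"), drop = FALSE]
  validate_feature_table(ft, min_anchor_len)

  feat_seq <- function(row) {
    s <- substr(pseq, row$start0 + 1L, row$end0)
    if (row$strand == "-") rc(s) else s
  }
  segs_ix <- which(ft$type == "shufflon_segment")
  segments <- vector("list", length(segs_ix))
  for (k in seq_along(segs_ix)) {
    i <- segs_ix[k]
    left <- ft[i - 1L, ]; right <- ft[i + 1L, ]
    segments[[k]] <- segment_def(
      name = ft$name[i] %||% paste0("S", k),
      body = feat_seq(ft[i, ]),
      left_repeat = feat_seq(left), right_repeat = feat_seq(right),
      orf_left = if (is.na(ft$orf_left[i])) NULL else ft$orf_left[i],
      orf_right = if (is.na(ft$orf_right[i])) NULL else ft$orf_right[i])
  }
  # Junction elements: plasmid-strand substrings between anchors/bodies.
  bounds <- c(ft$end0[ft$type == "pilv_anchor"],
              as.vector(rbind(ft$start0[segs_ix], ft$end0[segs_ix])),
              ft$start0[ft$type == "rci_anchor"])
  junctions <- vapply(seq_len(length(segs_ix) + 1L), function(i)
    substr(pseq, bounds[2L * i - 1L] + 1L, bounds[2L * i]), character(1))

  pa <- ft[ft$type == "pilv_anchor", ]
  ra <- ft[ft$type == "rci_anchor", ]
  shufflon_locus(plasmid_id = plasmid_id, plasmid_seq = pseq,
                 locus_start = pa$start0,
                 pilv_anchor = substr(pseq, pa$start0 + 1L, pa$end0),
                 rci_anchor = substr(pseq, ra$start0 + 1L, ra$end0),
                 segments = segments, junctions = junctions,
                 features = ft, circular = circular,
                 min_anchor_len = min_anchor_len)
}

validate_feature_table <- function(ft, min_anchor_len) {
  for (ty in c("pilv_anchor", "rci_anchor"))
    if (sum(ft$type == ty) != 1L)
      stop_val("annotation must contain exactly one %s feature", ty)
  if (ft$type[1L] != "pilv_anchor" || ft$type[nrow(ft)] != "rci_anchor")
    stop_val("pilv_anchor must be the first and rci_anchor the last feature")
  for (i in seq_len(nrow(ft) - 1L)) {
    if (ft$start0[i + 1L] < ft$end0[i])
      stop_val("feature '%s' (%s) overlaps '%s' (%s)",
               ft$name[i + 1L] %||% "?", ft$type[i + 1L],
               ft$name[i] %||% "?", ft$type[i])
    if (ft$start0[i + 1L] > ft$end0[i])
      stop_val("gap before feature '%s' (%s): locus must tile contiguously",
               ft$name[i + 1L] %||% "?", ft$type[i + 1L])
  }
  widths <- ft$end0 - ft$start0
  anch <- ft$type %in% c("pilv_anchor", "rci_anchor")
  if (any(widths[anch] < min_anchor_len))
    stop_val("anchor shorter than min_anchor_len = %d nt", min_anchor_len)
  ir <- ft$type == "inverted_repeat"
  if (any(widths[ir] < 10L))
    stop_val("inverted repeat '%s' shorter than 10 nt",
             ft$name[ir & widths < 10L][1L])
  segs <- which(ft$type == "shufflon_segment")
  if (length(segs) == 0L) stop_val("no shufflon_segment features")
  for (i in segs)
    if (ft$type[i - 1L] != "inverted_repeat" || ft$type[i + 1L] != "inverted_repeat")
      stop_val("segment '%s' must be flanked by inverted_repeat features",
               ft$name[i] %||% "?")
  invisible(TRUE)
}

#' Write a shufflon locus back to FASTA + GFF3
#'
#' Inverse of [load_locus()]: feature coordinates are converted back to the
#' 1-based inclusive GFF3 convention.
#'
#' @param locus a [shufflon_locus()] object.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the paths written.
#' @export
write_locus <- function(locus, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(locus$plasmid_seq)
  names(seqs) <- locus$plasmid_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  ft <- locus$features
  gr <- GenomicRanges::GRanges(
    seqnames = locus$plasmid_id,
    ranges = IRanges::IRanges(start = ft$start0 + 1L, end = ft$end0),
    strand = ft$strand)
  gr$source <- "shufflonq"
  gr$type <- ft$type
  gr$Name <- ft$name
  gr$orf_left <- ft$orf_left
  gr$orf_right <- ft$orf_right
  rtracklayer::export(gr, annotation_path, format = "GFF3")
  invisible(c(fasta_path, annotation_path))
}

#' Arrangement of shufflon segments
#'
#' One whole-shufflon structure: a permutation of the segments and an
#' orientation (+1/-1) per position, read from pilV to rci.
#'
#' @param order integer permutation of segment indices.
#' @param orient integer vector of +1 (reference) / -1 (inverted) per position.
#' @return an object of class `arrangement`.
#' @export
arrangement <- function(order, orient) {
  order <- as.integer(order); orient <- as.integer(orient)
  n <- length(order)
  if (length(orient) != n) stop_val("order and orient lengths differ")
  if (!setequal(order, seq_len(n))) stop_val("order is not a permutation of 1..%d", n)
  if (!all(orient %in% c(-1L, 1L))) stop_val("orientations must be +1/-1")
  structure(list(order = order, orient = orient), class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat(sprintf("arrangement: %s\n",
              paste(sprintf("%d%s", x$order, ifelse(x$orient > 0, "+", "-")),
                    collapse = " ")))
  invisible(x)
}

# Compact key for set operations over arrangements.
arrangement_key <- function(arr) {
  paste(paste(arr$order, collapse = ","),
        paste(arr$orient, collapse = ","), sep = "/")
}

#' Canonical label of an arrangement
#'
#' Lists, from pilV to rci, the ORF-end labels in their resulting
#' orientation: a two-ORF segment in "-" orientation swaps its two labels; a
#' one-ORF segment shows its single ORF in either orientation.
#'
#' @param arr an [arrangement()].
#' @param segments list of [segment_def()] objects the arrangement refers to.
#' @return a string such as `"pilV-B'-D'-rci"`.
#' @export
arrangement_label <- function(arr, segments) {
  labs <- unlist(lapply(seq_along(arr$order), function(p) {
    s <- segments[[arr$order[p]]]
    lr <- c(s$orf_left, s$orf_right)
    if (arr$orient[p] < 0L) lr <- rev(lr)
    lr[!is.na(lr)]
  }))
  paste(c("pilV", labs, "rci"), collapse = "-")
}

# ORF-end label fused to the pilV 3' end under an arrangement (NA when a
# one-ORF segment presents its ORF-less end).
pilv_adjacent_orf <- function(arr, segments) {
  s <- segments[[arr$order[1L]]]
  if (arr$orient[1L] > 0L) s$orf_left else s$orf_right
}
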