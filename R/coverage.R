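# Coverage summaries, plasmid copy number and proper/broken paired-end
# coverage tracks.
#
# Copy number follows the printed-table convention: plasmid mean coverage
# divided by chromosomal mean coverage, rounded half-up to one decimal
# (219.75/135.41 -> 1.6; 298.92/135.41 -> 2.2).

#' Mean depth of one replicon
#'
#' Arithmetic mean over all reference positions, zero-depth positions
#' included.
#'
#' @param depth_records data.frame with columns `replicon`, `pos` (1-based)
#'   and `depth`, as produced by e.g. `samtools depth -a`.
#' @param replicon replicon to summarise.
#' @param length reference length; positions absent from the records are
#'   counted as zero depth.  Defaults to the maximum recorded position.
#' @return object of class `depth_summary`: list `replicon`, `mean_depth`,
#'   `length`.
#' @export
mean_depth <- function(depth_records, replicon, length = NULL) {
  d <- depth_records[depth_records$replicon == replicon, , drop = FALSE]
  if (nrow(d) == 0L) stop_val("replicon '%s' not present in depth records", replicon)
  len <- as.integer(length %||% max(d$pos))
  if (is.na(len)) len <- as.integer(max(d$pos))
  if (len <= 0L) stop_val("replicon length must be positive")
  structure(list(replicon = replicon,
                 mean_depth = sum(as.numeric(d$depth)) / len,
                 length = len),
            class = "depth_summary")
}

#' @export
print.depth_summary <- function(x, ...) {
  cat(sprintf("%s: mean depth %.2f over %d nt\n", x$replicon, x$mean_depth,
              x$length))
  invisible(x)
}

#' Plasmid copy number from coverage
#'
#' Ratio of plasmid mean coverage to chromosomal mean coverage, rounded
#' half-up to one decimal.
#'
#' @param plasmid_summary,chromosome_summary [mean_depth()] summaries (or
#'   bare numeric mean depths).
#' @return list with `replicon`, `ratio` and `rounded`.
#' @export
copy_number <- function(plasmid_summary, chromosome_summary) {
  pm <- if (inherits(plasmid_summary, "depth_summary"))
    plasmid_summary$mean_depth else as.numeric(plasmid_summary)
  cm <- if (inherits(chromosome_summary, "depth_summary"))
    chromosome_summary$mean_depth else as.numeric(chromosome_summary)
  if (!is.finite(cm) || cm <= 0) stop_val("chromosome mean depth must be positive")
  ratio <- pm / cm
  list(replicon = if (inherits(plasmid_summary, "depth_summary"))
         plasmid_summary$replicon else NA_character_,
       ratio = ratio, rounded = round_half_up(ratio, 1L))
}

#' Copy-number report over several replicons
#'
#' @param depth_records depth table (see [mean_depth()]).
#' @param chromosome replicon name of the chromosome.
#' @param lengths optional named vector of replicon lengths.
#' @return data.frame `replicon`, `mean_depth`, `ratio`, `copy_number`
#'   (chromosome row has ratio 1 by construction).
#' @export
copy_number_report <- function(depth_records, chromosome, lengths = NULL) {
  reps <- unique(depth_records$replicon)
  if (!chromosome %in% reps) stop_val("chromosome '%s' not in depth records", chromosome)
  sums <- lapply(reps, function(r)
    mean_depth(depth_records, r, length = lengths[r] %||% NULL))
  names(sums) <- reps
  chrom <- sums[[chromosome]]
  out <- do.call(rbind, lapply(reps, function(r) {
    cn <- copy_number(sums[[r]], chrom)
    data.frame(replicon = r, mean_depth = sums[[r]]$mean_depth,
               ratio = cn$ratio, copy_number = cn$rounded,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read alignment records from a SAM/BAM file
#'
#' Consumes alignments produced by an external mapper via Rsamtools and
#' returns a flat record table for pair classification.
#'
#' @param path SAM or BAM file.
#' @return data.frame: `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `mrnm`, `mpos`, `isize`, plus attribute `targets` (named vector of
#'   reference lengths from the header).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile("shufflonq_aln"),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "mrnm", "mpos",
                                        "isize"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  df <- data.frame(qname = b$qname, flag = b$flag,
                   rname = as.character(b$rname), pos = b$pos,
                   mapq = b$mapq, cigar = b$cigar,
                   mrnm = as.character(b$mrnm), mpos = b$mpos,
                   isize = b$isize, stringsAsFactors = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  attr(df, "targets") <- hdr
  df
}

#' Proper/broken paired-end coverage track
#'
#' Classifies every mapped read pair as `proper` (both mates on the same
#' replicon, FR orientation, insert size within bounds) or `broken`
#' (orientation-discordant, cross-replicon, or aberrant insert) and
#' accumulates per-position coverage for each class on the target replicon.
#' Broken-pair coverage concentrated over a locus flags structural
#' heterogeneity against the mapping reference.
#'
#' @param alignments coordinate-sorted record table from
#'   [read_alignments()] (or a SAM/BAM path).
#' @param target_replicon replicon to build the track for.
#' @param insert_bounds numeric `c(lo, hi)`; `NULL` estimates
#'   mean +/- 4 SD from the FR same-replicon pairs.
#' @param target_length reference length (default from the SAM header).
#' @return object of class `pair_class_track`: list with `replicon`,
#'   `proper_cov`, `broken_cov` (integer vectors of per-position depth),
#'   `insert_bounds`, `n_proper`, `n_broken`.
#' @export
pair_class_coverage <- function(alignments, target_replicon,
                                insert_bounds = NULL, target_length = NULL) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  a <- alignments
  tlen <- target_length %||% unname(attr(a, "targets")[target_replicon])
  if (is.null(tlen) || is.na(tlen))
    stop_val("unknown length for replicon '%s'", target_replicon)
  a <- a[!is.na(a$pos) & !bitwAnd(a$flag, 4L), , drop = FALSE]
  for (r in unique(a$rname)) {
    pr <- a$pos[a$rname == r]
    if (is.unsorted(pr)) stop_val("alignments are not coordinate-sorted")
  }
  a$ref_width <- cigar_ref_width(a$cigar)
  a$rev <- bitwAnd(a$flag, 16L) > 0L
  mate_mapped <- !bitwAnd(a$flag, 8L)
  paired <- bitwAnd(a$flag, 1L) > 0L
  a <- a[paired & mate_mapped, , drop = FALSE]

  mate_same <- a$mrnm == "=" | a$mrnm == a$rname
  # FR orientation: leftmost mate forward with reverse mate, and vice versa
  mrev <- bitwAnd(a$flag, 32L) > 0L
  left_fwd <- !a$rev & mrev & a$pos <= a$mpos
  right_rev <- a$rev & !mrev & a$pos >= a$mpos
  fr <- mate_same & (left_fwd | right_rev)

  if (is.null(insert_bounds)) {
    ins <- abs(a$isize[fr & a$isize != 0L])
    if (length(ins) < 2L) stop_val("cannot estimate insert bounds: too few FR pairs")
    insert_bounds <- c(max(0, mean(ins) - 4 * stats::sd(ins)),
                       mean(ins) + 4 * stats::sd(ins))
  }
  ins_ok <- abs(a$isize) >= insert_bounds[1L] & abs(a$isize) <= insert_bounds[2L]
  proper <- fr & ins_ok
  on_target <- a$rname == target_replicon

  proper_cov <- integer(tlen); broken_cov <- integer(tlen)
  add_cov <- function(cov, rows) {
    for (i in rows) {
      s <- a$pos[i]; e <- min(tlen, a$pos[i] + a$ref_width[i] - 1L)
      if (s <= tlen) cov[s:e] <- cov[s:e] + 1L
    }
    cov
  }
  proper_cov <- add_cov(proper_cov, which(proper & on_target))
  broken_cov <- add_cov(broken_cov, which(!proper & on_target))
  structure(list(replicon = target_replicon, proper_cov = proper_cov,
                 broken_cov = broken_cov, insert_bounds = insert_bounds,
                 n_proper = sum(proper & on_target),
                 n_broken = sum(!proper & on_target)),
            class = "pair_class_track")
}

#' @export
print.pair_class_track <- function(x, ...) {
  cat(sprintf("pair-class track on %s: %d proper / %d broken mate records\n",
              x$replicon, x$n_proper, x$n_broken))
  cat(sprintf("  insert bounds [%.0f, %.0f]; broken coverage max %d\n",
              x$insert_bounds[1L], x$insert_bounds[2L], max(x$broken_cov)))
  invisible(x)
}

#' @method plot pair_class_track
#' @export
plot.pair_class_track <- function(x, ...) {
  graphics::plot(x$proper_cov, type = "h", col = "grey70",
                 xlab = "position", ylab = "coverage",
                 main = sprintf("proper (grey) vs broken (red) pairs: %s",
                                x$replicon), ...)
  graphics::lines(x$broken_cov, type = "h", col = "red")
  invisible(x)
}
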