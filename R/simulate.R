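# Synthetic-data generator: seeded loci, heterogeneous arrangement
# populations, and error-bearing long/short reads with ground truth.
#
# The generator emulates the statistical structure of a clonal isolate
# carrying a single-copy plasmid whose shufflon is heterogeneous over
# arrangements: PacBio-RSII-like multi-kb reads with indel-dominated errors
# and MiSeq-like 2 x 300 bp pairs from ~400 bp inserts.

REPEAT_CONSENSUS <- "GTGCCAATCCGGTNNGTGGA"

#' Simulation configuration
#'
#' @param n_segments number of invertible segments.
#' @param segment_len segment body length (nt).
#' @param anchor_len pilV/rci anchor length (nt).
#' @param repeat_consensus inverted-repeat consensus; `N` positions are drawn
#'   independently per repeat site.
#' @param plasmid_len total plasmid length (nt).
#' @param locus_start 0-based plasmid position of the locus.
#' @param seed mandatory RNG seed; every generator output is a deterministic
#'   function of the configuration.
#' @param long_read list: `mean_len`, `sdlog` (log-normal length model),
#'   `sub`, `ins`, `del` per-base error rates.
#' @param short_read list: `read_len`, `insert_mean`, `insert_sd`, `sub`.
#' @param segment_names,orf_labels optional labels; defaults are A, C, BD
#'   style names with primed ORF ends.
#' @param one_orf logical vector flagging one-ORF segments (default none).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_segments = 3L, segment_len = 300L, anchor_len = 500L,
                       repeat_consensus = REPEAT_CONSENSUS,
                       plasmid_len = 60000L, locus_start = 10000L,
                       seed,
                       long_read = list(mean_len = 8000, sdlog = 0.4,
                                        sub = 0.015, ins = 0.09, del = 0.04),
                       short_read = list(read_len = 300L, insert_mean = 400,
                                         insert_sd = 40, sub = 0.005),
                       segment_names = NULL, orf_labels = NULL,
                       one_orf = NULL) {
  if (missing(seed)) stop_val("sim_config: seed is mandatory")
  lr <- utils::modifyList(list(mean_len = 8000, sdlog = 0.4,
                               sub = 0.015, ins = 0.09, del = 0.04), long_read)
  sr <- utils::modifyList(list(read_len = 300L, insert_mean = 400,
                               insert_sd = 40, sub = 0.005), short_read)
  rates <- c(lr$sub, lr$ins, lr$del, sr$sub)
  if (any(rates < 0 | rates >= 1)) stop_val("error rates must be in [0, 1)")
  if (!is_dna(repeat_consensus, allow_iupac = TRUE))
    stop_val("bad repeat consensus alphabet")
  if (is.null(segment_names))
    segment_names <- make.unique(rep(LETTERS, length.out = n_segments), sep = "")
  if (is.null(one_orf)) one_orf <- rep(FALSE, n_segments)
  structure(list(n_segments = as.integer(n_segments),
                 segment_len = as.integer(segment_len),
                 anchor_len = as.integer(anchor_len),
                 repeat_consensus = toupper(repeat_consensus),
                 plasmid_len = as.integer(plasmid_len),
                 locus_start = as.integer(locus_start),
                 seed = as.integer(seed),
                 long_read = lr, short_read = sr,
                 segment_names = segment_names, orf_labels = orf_labels,
                 one_orf = one_orf),
            class = "sim_config")
}

# Fill N positions of the consensus with random bases.
draw_repeat <- function(consensus) {
  ch <- seq_chars(consensus)
  nn <- which(ch == "N")
  ch[nn] <- sample(c("A", "C", "G", "T"), length(nn), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate a synthetic shufflon locus
#'
#' Builds a circular plasmid with random background sequence and a shufflon
#' locus (pilV anchor, `n` two-ORF segments bounded by imperfect inverted
#' repeats drawn from the consensus, rci anchor) embedded at a fixed
#' position.  Deterministic for a given config seed.
#'
#' @param config a [sim_config()].
#' @return a [shufflon_locus()].
#' @export
make_locus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_segments
  names <- config$segment_names
  segments <- vector("list", n)
  for (k in seq_len(n)) {
    ol <- if (!is.null(config$orf_labels)) config$orf_labels[[k]][1L] else names[k]
    or <- if (!is.null(config$orf_labels)) config$orf_labels[[k]][2L]
          else paste0(names[k], "'")
    if (config$one_orf[k]) or <- NULL
    segments[[k]] <- segment_def(
      name = names[k], body = random_dna(config$segment_len),
      left_repeat = draw_repeat(config$repeat_consensus),
      right_repeat = draw_repeat(config$repeat_consensus),
      orf_left = ol, orf_right = or)
  }
  # junction elements: J0 = minus-strand left site of S1; interior J_i =
  # right site of S_i followed by minus-strand left site of S_{i+1};
  # Jn = right site of Sn.
  junctions <- character(n + 1L)
  junctions[1L] <- rc(segments[[1L]]$left_repeat)
  if (n > 1L) for (i in seq_len(n - 1L))
    junctions[i + 1L] <- paste0(segments[[i]]$right_repeat,
                                rc(segments[[i + 1L]]$left_repeat))
  junctions[n + 1L] <- segments[[n]]$right_repeat

  pilv_anchor <- random_dna(config$anchor_len)
  rci_anchor <- random_dna(config$anchor_len)
  locus_len <- nchar(pilv_anchor) + nchar(rci_anchor) +
    sum(nchar(junctions)) + sum(vapply(segments, function(s) nchar(s$body), 0L))
  bg_len <- config$plasmid_len - locus_len
  if (bg_len < config$locus_start)
    stop_val("plasmid_len too small for locus at locus_start")
  before <- random_dna(config$locus_start)
  after <- random_dna(bg_len - config$locus_start)
  locus_seq <- paste0(pilv_anchor, junctions[1L],
                      paste(vapply(seq_len(n), function(i)
                        paste0(segments[[i]]$body, junctions[i + 1L]),
                        character(1)), collapse = ""),
                      rci_anchor)
  plasmid <- paste0(before, locus_seq, after)
  shufflon_locus(plasmid_id = sprintf("sim_plasmid_n%d_seed%d", n, config$seed),
                 plasmid_seq = plasmid, locus_start = config$locus_start,
                 pilv_anchor = pilv_anchor, rci_anchor = rci_anchor,
                 segments = segments, junctions = junctions)
}

#' Fix an arrangement population
#'
#' Defines the arrangement mixture used by the read simulators, either from
#' an explicit frequency vector or from a seeded symmetric Dirichlet draw.
#'
#' @param space an [enumerate_arrangements()] result.
#' @param frequencies optional numeric vector over `space$arrangements`
#'   (must be non-negative and sum to 1).
#' @param seed RNG seed used when `frequencies` is `NULL`.
#' @param concentration Dirichlet concentration parameter (default 1, i.e.
#'   uniform over the simplex).
#' @return an object of class `shufflon_population`: list with `space`,
#'   `labels` and `freq`.
#' @export
sample_population <- function(space, frequencies = NULL, seed = NULL,
                              concentration = 1) {
  stopifnot(inherits(space, "arrangement_space"))
  if (is.null(frequencies)) {
    if (is.null(seed)) stop_val("seed required for a Dirichlet population draw")
    set.seed(seed)
    g <- stats::rgamma(space$count, shape = concentration, rate = 1)
    frequencies <- g / sum(g)
  }
  if (length(frequencies) != space$count)
    stop_val("need %d frequencies, got %d", space$count, length(frequencies))
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-9)
    stop_val("frequencies must be non-negative and sum to 1")
  structure(list(space = space, labels = space$labels,
                 freq = as.numeric(frequencies)),
            class = "shufflon_population")
}

# Apply a per-base substitution/insertion/deletion error model to one
# sequence.  Each position is deleted with prob `del`, substituted with prob
# `sub`, and followed by one inserted random base with prob `ins`.
apply_read_errors <- function(seq, sub, ins, del) {
  if (sub == 0 && ins == 0 && del == 0) return(seq)
  ch <- seq_chars(seq)
  L <- length(ch)
  keep <- stats::runif(L) >= del
  do_sub <- stats::runif(L) < sub
  bases <- c("A", "C", "G", "T")
  if (any(do_sub)) {
    # substitute with a uniformly chosen *different* base
    offs <- sample(1:3, sum(do_sub), replace = TRUE)
    cur <- match(ch[do_sub], bases)
    ch[do_sub] <- bases[((cur - 1L + offs) %% 4L) + 1L]
  }
  do_ins <- stats::runif(L) < ins
  ins_base <- character(L)
  ins_base[do_ins] <- sample(bases, sum(do_ins), replace = TRUE)
  out <- character(2L * L)
  out[2L * seq_len(L) - 1L] <- ifelse(keep, ch, "")
  out[2L * seq_len(L)] <- ins_base
  paste(out, collapse = "")
}

# Full plasmid sequence carrying a given arrangement (locus region replaced
# by the candidate sequence; flanks untouched).
variant_plasmid <- function(locus, arr) {
  paste0(substr(locus$plasmid_seq, 1L, locus$locus_start),
         locus_sequence(locus, arr),
         substr(locus$plasmid_seq, locus$locus_end + 1L,
                locus$plasmid_len))
}

# Substring of a circular sequence, 0-based start, wrapping the origin.
circular_substr <- function(seq, start0, len) {
  L <- nchar(seq)
  start0 <- start0 %% L
  if (start0 + len <= L) return(substr(seq, start0 + 1L, start0 + len))
  paste0(substr(seq, start0 + 1L, L), substr(seq, 1L, start0 + len - L))
}

#' Simulate PacBio-like long reads from an arrangement population
#'
#' Per read: an arrangement is drawn by population frequency, a start drawn
#' uniformly on the circular plasmid carrying that arrangement, a length
#' drawn log-normal, substitution/insertion/deletion errors applied and the
#' strand flipped with probability 1/2.  Ground truth is recorded per read.
#'
#' @param locus a [shufflon_locus()].
#' @param population a [sample_population()] result.
#' @param count number of reads.
#' @param config a [sim_config()] (error/length model).
#' @param seed RNG seed for the read draw.
#' @param spanning_only if `TRUE`, every read is drawn to cover the whole
#'   locus span (anchor to anchor), emulating the spanning subreads used for
#'   whole-shufflon quantification.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read_id, arrangement, start0, length, strand).
#' @export
simulate_long_reads <- function(locus, population, count, config, seed,
                                spanning_only = FALSE) {
  stopifnot(inherits(population, "shufflon_population"))
  set.seed(seed)
  lr <- config$long_read
  plasmids <- vapply(population$space$arrangements,
                     function(a) variant_plasmid(locus, a), character(1))
  L <- nchar(plasmids[1L])
  span_len <- locus$locus_end - locus$locus_start
  meanlog <- log(lr$mean_len) - lr$sdlog^2 / 2
  idx <- sample.int(length(plasmids), count, replace = TRUE,
                    prob = population$freq)
  reads <- character(count)
  truth <- data.frame(read_id = sprintf("lr_%05d", seq_len(count)),
                      arrangement = population$labels[idx],
                      start0 = NA_integer_, length = NA_integer_,
                      strand = sample(c("+", "-"), count, replace = TRUE),
                      stringsAsFactors = FALSE)
  for (i in seq_len(count)) {
    repeat {
      len <- max(200L, round(stats::rlnorm(1, meanlog, lr$sdlog)))
      len <- min(len, L)
      start0 <- if (spanning_only && len >= span_len) {
        # uniform over starts whose read covers [locus_start, locus_end)
        cand <- seq.int(locus$locus_end - len, locus$locus_start)
        cand[sample.int(length(cand), 1L)]
      } else {
        sample.int(L, 1L) - 1L
      }
      if (!spanning_only || len >= span_len) break
    }
    raw <- circular_substr(plasmids[idx[i]], start0, len)
    err <- apply_read_errors(raw, lr$sub, lr$ins, lr$del)
    if (truth$strand[i] == "-") err <- rc(err)
    reads[i] <- err
    truth$start0[i] <- start0
    truth$length[i] <- len
  }
  names(reads) <- truth$read_id
  list(reads = reads, truth = truth,
       freq = population$freq, labels = population$labels)
}

#' Simulate MiSeq-like short read pairs
#'
#' Inserts are drawn Normal(insert_mean, insert_sd) truncated at the read
#' length, placed uniformly on the circular plasmid of a frequency-drawn
#' arrangement (optionally restricted to a window), read in FR orientation
#' with substitution errors only.
#'
#' @param locus a [shufflon_locus()].
#' @param population a [sample_population()] result.
#' @param pairs number of read pairs.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param region optional 0-based half-open window `c(start, end)` on the
#'   plasmid from which insert starts are drawn (e.g. around the pilV
#'   junction to emulate the junction-covering fraction of a deep run).
#' @return list with `r1`, `r2` (named character vectors, R2 reverse
#'   strand) and `truth` (read pair ground truth).
#' @export
simulate_short_pairs <- function(locus, population, pairs, config, seed,
                                 region = NULL) {
  stopifnot(inherits(population, "shufflon_population"))
  set.seed(seed)
  sr <- config$short_read
  plasmids <- vapply(population$space$arrangements,
                     function(a) variant_plasmid(locus, a), character(1))
  L <- nchar(plasmids[1L])
  idx <- sample.int(length(plasmids), pairs, replace = TRUE,
                    prob = population$freq)
  ins_len <- pmax(sr$read_len,
                  round(stats::rnorm(pairs, sr$insert_mean, sr$insert_sd)))
  start0 <- if (is.null(region)) {
    sample.int(L, pairs, replace = TRUE) - 1L
  } else {
    w <- seq.int(region[1L], region[2L] - 1L)
    w[sample.int(length(w), pairs, replace = TRUE)]
  }
  flip <- sample(c(FALSE, TRUE), pairs, replace = TRUE)
  r1 <- character(pairs); r2 <- character(pairs)
  for (i in seq_len(pairs)) {
    insert <- circular_substr(plasmids[idx[i]], start0[i], ins_len[i])
    if (flip[i]) insert <- rc(insert)
    m1 <- substr(insert, 1L, sr$read_len)
    m2 <- rc(substr(insert, nchar(insert) - sr$read_len + 1L, nchar(insert)))
    r1[i] <- apply_read_errors(m1, sr$sub, 0, 0)
    r2[i] <- apply_read_errors(m2, sr$sub, 0, 0)
  }
  ids <- sprintf("sp_%05d", seq_len(pairs))
  names(r1) <- ids; names(r2) <- ids
  truth <- data.frame(read_id = ids, arrangement = population$labels[idx],
                      start0 = start0, insert_len = ins_len,
                      strand = ifelse(flip, "-", "+"),
                      stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, truth = truth,
       freq = population$freq, labels = population$labels)
}
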