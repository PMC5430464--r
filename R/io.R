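# Sequence I/O and the umbrella pipeline.

#' Read sequences from FASTA/FASTQ
#'
#' Format is sniffed from the first record character; gzip input and CRLF
#' line endings are handled.  Sequences are uppercased; FASTQ quality
#' strings are preserved in the `"qualities"` attribute for round trips.
#'
#' @param path FASTA or FASTQ file, plain or gzip.
#' @return a `DNAStringSet` (with a `qualities` attribute for FASTQ input).
#' @export
read_sequences <- function(path) {
  con <- gzfile(path, "rb")
  head <- rawToChar(readBin(con, "raw", 4096L))
  close(con)
  if (!nzchar(head)) stop_val("%s: empty sequence file", path)
  first <- substr(gsub("^[\r\n]+", "", head), 1L, 1L)
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                stop_val("%s: not FASTA/FASTQ (starts with '%s')", path, first))
  use_path <- path
  if (grepl("\r", head, fixed = TRUE)) {
    # normalise CRLF input for the parser
    lines <- readLines(path, warn = FALSE)
    use_path <- tempfile(fileext = paste0(".", fmt))
    writeLines(lines, use_path)
    on.exit(unlink(use_path), add = TRUE)
  }
  res <- tryCatch({
    if (fmt == "fastq") {
      x <- Biostrings::readDNAStringSet(use_path, format = "fastq",
                                        with.qualities = TRUE)
    } else {
      x <- Biostrings::readDNAStringSet(use_path, format = "fasta")
    }
    x
  }, error = function(e) stop_val("%s: malformed %s (%s)", path, fmt,
                                  conditionMessage(e)))
  q <- S4Vectors::mcols(res)$qualities
  res <- Biostrings::DNAStringSet(toupper(res))
  if (!is.null(q)) attr(res, "qualities") <- as.character(q)
  res
}

#' Write sequences to FASTA/FASTQ
#'
#' @param records `DNAStringSet` or named character vector.
#' @param path output path; a `.fastq`/`.fq` suffix (optionally `.gz`)
#'   selects FASTQ output.
#' @param qualities optional quality strings for FASTQ; default constant
#'   `"I"` (Q40) per base, as downstream analyses are quality-agnostic.
#' @return invisibly, `path`.
#' @export
write_sequences <- function(records, path, qualities = NULL) {
  if (!inherits(records, "DNAStringSet")) {
    nm <- names(records)
    records <- Biostrings::DNAStringSet(as.character(records))
    names(records) <- nm %||% sprintf("seq%d", seq_along(records))
  }
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  if (fastq) {
    q <- qualities %||% attr(records, "qualities") %||%
      vapply(Biostrings::width(records),
             function(w) strrep("I", w), character(1))
    Biostrings::writeXStringSet(records, path, format = "fastq",
                                compress = grepl("\\.gz$", path),
                                qualities = Biostrings::BStringSet(q))
  } else {
    Biostrings::writeXStringSet(records, path,
                                compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

write_tsv_report <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# shufflonq %s",
                     as.character(utils::packageVersion("shufflonq"))), con)
  for (nm in names(params))
    writeLines(sprintf("# %s = %s", nm,
                       paste(format(params[[nm]]), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full shufflon quantification pipeline
#'
#' Orchestrates enumerate -> quantify (long reads) -> pilV typing (long and,
#' when given, short reads) -> platform comparison -> repeat analysis,
#' writing TSV outputs plus a JSON run summary to `out_dir`.  Any stage
#' failure aborts with the stage name.
#'
#' @param config list with entries `locus_fasta`, `locus_gff`, `out_dir`,
#'   optional `long_reads`, `short_r1`, `short_r2` (paths), `seed`, and
#'   optional parameter lists `assign` and `pilv` passed to
#'   [assign_params()] / [pilv_params()].
#' @return invisibly, a result bundle: list of the computed objects and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_val("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  for (f in c("locus_fasta", "locus_gff", "out_dir"))
    if (is.null(config[[f]])) stop_val("config is missing '%s'", f)
  for (f in c("locus_fasta", "locus_gff", "long_reads", "short_r1", "short_r2"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop_val("pipeline stage '%s' failed: file not found: %s", f, config[[f]])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(x) file.path(config$out_dir, x)
  aprm <- do.call(assign_params, config$assign %||% list())
  pprm <- do.call(pilv_params, config$pilv %||% list())

  locus <- stage("load_locus",
                 load_locus(config$locus_fasta, config$locus_gff))
  space <- stage("enumerate", enumerate_arrangements(locus))
  cands <- stage("enumerate", candidate_set(locus, space))
  write_sequences(cands$sequences, out("candidates.fa"))

  bundle <- list(locus = locus, space = space, candidates = cands,
                 paths = out("candidates.fa"))

  if (!is.null(config$long_reads)) {
    ab <- stage("quantify",
                quantify_structures(config$long_reads, locus, aprm, cands))
    write_tsv_report(as.data.frame(ab), out("abundance.tsv"),
                     c(list(n_candidates = space$count),
                       as.list(attr(ab, "totals"))))
    vl <- stage("type-pilv-long",
                variant_ratios(config$long_reads, locus, "long", pprm))
    write_tsv_report(as.data.frame(vl), out("variants_long.tsv"),
                     list(platform = "long",
                          informative = attr(vl, "total_informative")))
    bundle$abundance <- ab; bundle$variants_long <- vl
  }
  if (!is.null(config$short_r1)) {
    sreads <- if (is.null(config$short_r2)) config$short_r1
              else list(r1 = read_sequences(config$short_r1),
                        r2 = read_sequences(config$short_r2))
    vs <- stage("type-pilv-short", variant_ratios(sreads, locus, "short", pprm))
    write_tsv_report(as.data.frame(vs), out("variants_short.tsv"),
                     list(platform = "short",
                          informative = attr(vs, "total_informative")))
    bundle$variants_short <- vs
    if (!is.null(bundle$variants_long)) {
      cmp <- stage("compare-platforms",
                   compare_platforms(bundle$variants_long, vs))
      bundle$comparison <- cmp
    }
  }

  reps <- stage("repeats", repeat_set(locus, window_len = NULL))
  win <- stage("repeats", repeat_set(locus, window_len = 23L))
  cons <- stage("repeats", degenerate_consensus(reps))
  idm <- stage("repeats", pairwise_identity(reps))
  hm <- stage("repeats", hamming_matrix(win, window = 23L))
  msn <- stage("repeats", min_spanning_network(hm))
  pfm <- stage("repeats", position_frequency_matrix(reps))
  writeLines(cons, out("consensus.txt"))
  utils::write.table(idm, out("identity.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(hm, out("hamming.tsv"), sep = "\t", quote = FALSE)
  write_tsv_report(msn$edges, out("msn.tsv"),
                   list(tree_weight = msn$tree_weight))
  utils::write.table(pfm, out("pfm.tsv"), sep = "\t", quote = FALSE)
  bundle$repeats <- list(set = reps, windows = win, consensus = cons,
                         identity = idm, hamming = hm, msn = msn, pfm = pfm)

  summary <- list(
    package = "shufflonq",
    version = as.character(utils::packageVersion("shufflonq")),
    seed = config$seed %||% NA,
    n_segments = n_segments(locus),
    n_candidates = space$count,
    params = list(assign = unclass(aprm), pilv = unclass(pprm)),
    inputs = config[intersect(names(config),
                              c("locus_fasta", "locus_gff", "long_reads",
                                "short_r1", "short_r2"))],
    outputs = list.files(config$out_dir))
  jsonlite::write_json(summary, out("run_summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  bundle$summary <- summary
  invisible(bundle)
}
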