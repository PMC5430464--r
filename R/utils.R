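# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' accepts IUPAC ambiguity codes.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA string
#'
#' Uniform i.i.d. bases from the current RNG stream.
#'
#' @param n length in nucleotides.
#' @return a single DNA string.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Conserved fraction of a reference sequence
#'
#' Percentage of a reference replicon covered by regions conserved across a
#' comparison set (e.g. 47,362 conserved nt of a 61,805 nt plasmid =
#' 76.63%).
#'
#' @param conserved_len total conserved length (nt).
#' @param total_len reference length (nt).
#' @param digits decimals in the printed percentage (default 2).
#' @return percentage, rounded half-up.
#' @export
conserved_fraction <- function(conserved_len, total_len, digits = 2L) {
  if (total_len <= 0) stop_val("total_len must be positive")
  round_half_up(100 * conserved_len / total_len, digits)
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() uses banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Split a DNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_dna <- function(x, allow_iupac = FALSE) {
  alphabet <- if (allow_iupac) "ACGTMRWSYKVHDBN" else "ACGT"
  all(grepl(sprintf("^[%s]+$", alphabet), x))
}

stop_val <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    w <- 0L
    for (tk in toks) {
      op <- substr(tk, nchar(tk), nchar(tk))
      if (op %in% c("M", "D", "N", "=", "X"))
        w <- w + as.integer(substr(tk, 1L, nchar(tk) - 1L))
    }
    w
  }, integer(1), USE.NAMES = FALSE)
}
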