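## Internal string/sequence helpers shared across modules.
## Sequences are plain uppercase character vectors over the DNA alphabet
## internally (U accepted on input and normalised to T); Biostrings objects
## are used at the I/O boundary and for pattern matching.

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, U tolerated).
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  x <- normalize_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalise sequences to the internal DNA alphabet
#'
#' Uppercases and replaces U with T.
#'
#' @param x character vector.
#' @return character vector over {A,C,G,T,N}.
#' @export
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed summary tables in this field
#' use conventional half-up rounding, so percentages are rounded with this
#' rule throughout.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a total, in a fixed rounding dialect
#'
#' Computes `100 * count / total` rounded half-up to `digits` decimals --
#' the convention used by the summary tables (1 decimal for length
#' tallies, 2 decimals for class tallies).
#'
#' @param count numeric vector of counts.
#' @param total the denominator.
#' @param digits decimal places.
#' @return numeric vector of percentages.
#' @export
percent_of <- function(count, total, digits = 1) {
  check_that(total > 0, "total must be positive")
  round_half_up(100 * count / total, digits)
}

## GC fraction of a character vector of sequences
gc_fraction <- function(x) {
  x <- normalize_dna(x)
  n <- nchar(x)
  gc <- vapply(strsplit(x, ""), function(b) sum(b %in% c("G", "C")),
               integer(1))
  gc / pmax(n, 1L)
}

## Phred+33 quality string -> integer vector(s)
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

## integer vector -> Phred+33 string
int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

## mean Phred score per read, vectorised
mean_phred <- function(qual) {
  vapply(phred_to_int(qual), mean, numeric(1))
}

## sample a random DNA string of length n with GC probability gc
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## stopifnot-style check with a clean message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}
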