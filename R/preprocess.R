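## Read-cleaning cascade: quality filter, adapter trimming, ambiguous-base
## removal, 18-25 nt length window, and collapsing into unique tags with
## per-library counts. The cascade partitions every input read into exactly
## one of: quality-removed, N-removed, too-short, too-long, retained.

#' Filter reads on mean Phred quality
#'
#' A read is retained when its mean Phred score is at least `qmin`
#' (default 13). `rule = "min"` switches to requiring every base to reach
#' `qmin`.
#'
#' @param reads read data.frame (`id`, `seq`, `qual`).
#' @param qmin minimum quality.
#' @param rule "mean" (default) or "min".
#' @return filtered read data.frame, input order preserved.
#' @export
quality_filter <- function(reads, qmin = 13, rule = c("mean", "min")) {
  rule <- match.arg(rule)
  check_that(qmin >= 0, "qmin must be >= 0")
  if (nrow(reads) == 0) return(reads)
  q <- phred_to_int(reads$qual)
  score <- if (rule == "mean") vapply(q, mean, numeric(1))
           else vapply(q, min, numeric(1))
  reads[score >= qmin, , drop = FALSE]
}

#' Trim 3' (and optionally 5') adapter sequences
#'
#' Removes the longest read suffix that exactly matches a prefix of
#' `adapter3`, requiring at least `min_overlap` matching bases; with
#' `adapter5`, symmetrically removes the longest read prefix matching a
#' suffix of the 5' adapter. Reads without a qualifying match pass through
#' unchanged. Qualities are trimmed alongside.
#'
#' @param reads read data.frame.
#' @param adapter3 3' adapter sequence.
#' @param adapter5 optional 5' adapter sequence.
#' @param min_overlap minimum exact overlap.
#' @return read data.frame with trimmed `seq`/`qual`.
#' @export
trim_adapters <- function(reads, adapter3, adapter5 = NULL,
                          min_overlap = 8) {
  check_that(nzchar(adapter3), "adapter3 must be non-empty")
  if (nrow(reads) == 0) return(reads)
  adapter3 <- normalize_dna(adapter3)
  seq <- normalize_dna(reads$seq)
  qual <- reads$qual
  len <- nchar(seq)
  keep_len <- len
  ## longest overlap first: stop updating a read once trimmed
  for (k in seq(min(nchar(adapter3), max(len)), min_overlap)) {
    ap <- substr(adapter3, 1L, k)
    cand <- keep_len == len & len >= k
    hit <- cand & substr(seq, len - k + 1L, len) == ap
    keep_len[hit] <- len[hit] - k
  }
  seq <- substr(seq, 1L, keep_len)
  qual <- substr(qual, 1L, keep_len)
  if (!is.null(adapter5)) {
    adapter5 <- normalize_dna(adapter5)
    len <- nchar(seq)
    cut <- integer(length(seq))
    for (k in seq(min(nchar(adapter5), max(len)), min_overlap)) {
      ap <- substr(adapter5, nchar(adapter5) - k + 1L, nchar(adapter5))
      hit <- cut == 0L & len >= k & substr(seq, 1L, k) == ap
      cut[hit] <- k
    }
    seq <- substr(seq, cut + 1L, len)
    qual <- substr(qual, cut + 1L, len)
  }
  out <- reads
  out$seq <- seq
  out$qual <- qual
  out
}

#' Remove reads containing ambiguous bases
#'
#' @param reads read data.frame.
#' @return reads without any N (case-insensitive).
#' @export
drop_ambiguous <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  reads[!grepl("N", reads$seq, ignore.case = TRUE), , drop = FALSE]
}

#' Length-filter reads and tally the length window
#'
#' @param reads read data.frame.
#' @param lo,hi inclusive length window (default 18-25).
#' @return list with `reads` (retained) and `summary`, a data.frame of
#'   read tallies for the total, in-window, short and long classes with
#'   half-up one-decimal percentages.
#' @export
length_filter <- function(reads, lo = 18, hi = 25) {
  check_that(lo <= hi, "lo must be <= hi")
  len <- nchar(reads$seq)
  n <- length(len)
  tally <- c(total = n,
             in_range = sum(len >= lo & len <= hi),
             short = sum(len < lo),
             long = sum(len > hi))
  pct <- if (n > 0) percent_of(tally, n, 1) else rep(0, 4)
  summary <- data.frame(
    class = c("total", sprintf("%d-%d nt", lo, hi),
              sprintf("<%d nt", lo), sprintf(">%d nt", hi)),
    reads = as.integer(tally), percent = pct,
    stringsAsFactors = FALSE, row.names = NULL)
  list(reads = reads[len >= lo & len <= hi, , drop = FALSE],
       summary = summary)
}

#' Run the full cleaning cascade on one library
#'
#' Order: quality filter, adapter trim, N removal, length window. The
#' returned accounting partitions every input read.
#'
#' @param reads raw read data.frame.
#' @param adapter3 3' adapter.
#' @param adapter5 optional 5' adapter.
#' @param qmin quality threshold.
#' @param lo,hi length window.
#' @return list with `reads` (clean) and `accounting` (named integer
#'   vector: input, quality_removed, n_removed, short, long, retained).
#' @export
preprocess_library <- function(reads, adapter3, adapter5 = NULL,
                               qmin = 13, lo = 18, hi = 25) {
  n0 <- nrow(reads)
  hq <- quality_filter(reads, qmin)
  trimmed <- trim_adapters(hq, adapter3, adapter5)
  noamb <- drop_ambiguous(trimmed)
  lf <- length_filter(noamb, lo, hi)
  acc <- c(input = n0,
           quality_removed = n0 - nrow(hq),
           n_removed = nrow(trimmed) - nrow(noamb),
           short = sum(nchar(noamb$seq) < lo),
           long = sum(nchar(noamb$seq) > hi),
           retained = nrow(lf$reads))
  list(reads = lf$reads, accounting = acc, length_summary = lf$summary)
}

#' Collapse cleaned reads into unique tags with per-library counts
#'
#' @param libraries named list of cleaned read data.frames.
#' @return data.frame with `sequence` (DNA, U normalised to T), one
#'   `count_<library>` column per library, `total` and `class`
#'   ("unassigned").
#' @export
collapse_tags <- function(libraries) {
  check_that(length(libraries) > 0 && !is.null(names(libraries)),
             "libraries must be a named list")
  seqs <- unique(unlist(lapply(libraries, function(r)
    normalize_dna(r$seq)), use.names = FALSE))
  seqs <- sort(seqs)
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (lib in names(libraries)) {
    tab <- table(normalize_dna(libraries[[lib]]$seq))
    cnt <- as.integer(tab[seqs])
    cnt[is.na(cnt)] <- 0L
    out[[paste0("count_", lib)]] <- cnt
  }
  out$total <- rowSums(out[, paste0("count_", names(libraries)),
                           drop = FALSE])
  out$class <- "unassigned"
  out[out$total > 0, , drop = FALSE]
}

#' Per-length totals and tag diversity
#'
#' @param tags tag data.frame from [collapse_tags()].
#' @param lo,hi length window reported.
#' @param by_library if TRUE, report per-library totals as extra columns.
#' @return data.frame with `length`, `total_reads`, `distinct_tags` (and
#'   per-library read totals when requested) for every length in
#'   `lo:hi`.
#' @export
length_distribution <- function(tags, lo = 18, hi = 25,
                                by_library = FALSE) {
  lens <- lo:hi
  tl <- nchar(tags$sequence)
  out <- data.frame(length = lens)
  out$total_reads <- vapply(lens, function(L)
    sum(tags$total[tl == L]), numeric(1))
  out$distinct_tags <- vapply(lens, function(L) sum(tl == L), integer(1))
  if (by_library) {
    for (col in grep("^count_", names(tags), value = TRUE)) {
      out[[col]] <- vapply(lens, function(L)
        sum(tags[[col]][tl == L]), numeric(1))
    }
  }
  out
}

#' Write collapsed tags as FASTA
#'
#' Headers follow `tag{serial}|{lib}:{count}|...`.
#'
#' @param tags tag data.frame.
#' @param path output FASTA.
#' @export
write_tag_fasta <- function(tags, path) {
  libs <- sub("^count_", "", grep("^count_", names(tags), value = TRUE))
  hdr <- sprintf("tag%06d", seq_len(nrow(tags)))
  for (lib in libs) {
    hdr <- paste0(hdr, "|", lib, ":", tags[[paste0("count_", lib)]])
  }
  seqs <- stats::setNames(tags$sequence, hdr)
  write_fasta(seqs, path)
}
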