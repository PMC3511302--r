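## File-format boundary: FASTA/FASTQ via Biostrings, GFF3 and TSV writers.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Phred+33).
#' @return data.frame with columns `id`, `seq`, `qual` (quality string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- normalize_dna(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(normalize_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## GFF3-like feature writer (1-based inclusive coordinates)
write_gff3 <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df) > 0) {
    writeLines(paste(df$seqid, df$source, df$type, df$start, df$end,
                     df$score, df$strand, ".", df$attributes, sep = "\t"),
               con)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
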