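## RNA secondary structure via ViennaRNA's RNAfold (minimum free energy,
## pseudoknot-free). Sequences are folded in batch through one external
## call; tests assert structural invariants, never engine-specific
## energies.

#' Is RNAfold available on the PATH?
#'
#' @return logical.
#' @export
rnafold_available <- function() {
  nzchar(Sys.which("RNAfold"))
}

#' Fold sequences to minimum-free-energy structures
#'
#' @param seqs character vector of sequences (A/C/G/T/U; T treated as U).
#'   Names are used as identifiers when present.
#' @return data.frame with `id`, `sequence` (input, DNA alphabet),
#'   `dot_bracket`, `mfe` (kcal/mol, <= 0).
#' @export
fold_many <- function(seqs) {
  check_that(length(seqs) > 0, "no sequences to fold")
  dna <- normalize_dna(seqs)
  bad <- grepl("[^ACGT]", dna)
  if (any(bad)) {
    stop("non-nucleotide symbols in sequence(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  check_that(rnafold_available(), "RNAfold not found on PATH")
  ids <- if (!is.null(names(seqs))) names(seqs)
         else sprintf("seq%04d", seq_along(seqs))
  fin <- tempfile(fileext = ".fa")
  on.exit(unlink(fin))
  writeLines(paste0(">", ids, "\n", chartr("T", "U", dna)), fin)
  out <- system2("RNAfold", c("--noPS", "--infile", fin), stdout = TRUE)
  ## output triplets: >id / sequence / structure (energy)
  struct_lines <- out[seq(3, length(out), by = 3)]
  m <- regmatches(struct_lines,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$",
                          struct_lines))
  check_that(all(lengths(m) == 3), "unexpected RNAfold output")
  data.frame(id = ids,
             sequence = unname(dna),
             dot_bracket = vapply(m, `[`, character(1), 2),
             mfe = as.numeric(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold a single sequence
#'
#' @param sequence one nucleotide string (length >= 40 for meaningful
#'   hairpin candidates; shorter sequences fold but are not candidate
#'   material).
#' @return list with `dot_bracket` and `mfe` (kcal/mol).
#' @export
fold <- function(sequence) {
  r <- fold_many(stats::setNames(sequence, "q"))
  list(dot_bracket = r$dot_bracket, mfe = r$mfe)
}

#' Base-pair partner table from a dot-bracket string
#'
#' @param dot_bracket dot-bracket structure.
#' @return integer vector; position `i` holds the 1-based partner of base
#'   `i`, or `NA` when unpaired.
#' @export
pair_table <- function(dot_bracket) {
  chars <- strsplit(dot_bracket, "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      check_that(length(stack) > 0, "unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  check_that(length(stack) == 0, "unbalanced dot-bracket")
  partner
}

#' Hairpin loop regions of a structure
#'
#' A hairpin loop is the unpaired region enclosed by a pair with no other
#' pair inside.
#'
#' @param dot_bracket dot-bracket structure.
#' @return data.frame with `start`, `end` (1-based inclusive loop region)
#'   and `depth` (number of pairs enclosing the loop); zero rows when the
#'   structure has no pairs.
#' @export
hairpin_loops <- function(dot_bracket) {
  pt <- pair_table(dot_bracket)
  loops <- list()
  for (i in which(!is.na(pt))) {
    j <- pt[i]
    if (j > i + 1 && all(is.na(pt[seq(i + 1, j - 1)]))) {
      depth <- sum(!is.na(pt[seq_len(i)]) & pt[seq_len(i)] > j)
      loops[[length(loops) + 1]] <-
        data.frame(start = i + 1L, end = j - 1L, depth = depth + 1L)
    }
  }
  if (length(loops) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      depth = integer(0)))
  }
  do.call(rbind, loops)
}
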