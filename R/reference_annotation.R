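## Tag annotation against reference sets: ncRNA/organellar exclusion by
## exact substring containment on either strand, conserved mature miRNA
## identification by full-length zero-mismatch identity, family grouping
## with evolutionary merges, and the class tally table.

CLASS_PRECEDENCE <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                      "mtRNA", "cpRNA")

## families grouped because of shared evolutionary origin
FAMILY_MERGES <- list("MIR156/157" = c("MIR156", "MIR157"),
                      "MIR165/166" = c("MIR165", "MIR166"),
                      "MIR170/171" = c("MIR170", "MIR171"))

#' Classify tags against ncRNA and organellar references
#'
#' A tag receives a non-miRNA class when its full sequence occurs as an
#' exact substring of any reference of that class, on either strand.
#' When a tag hits several classes the precedence
#' miRNA > rRNA > tRNA > snRNA > snoRNA > mtRNA > cpRNA applies (miRNA
#' assignments are made by [match_conserved()], which takes priority so a
#' conserved miRNA is never swallowed by the exclusion set).
#'
#' @param tags tag data.frame from [collapse_tags()].
#' @param references data.frame with `id`, `seq`, `class`.
#' @return tags with `class` filled in ("unassigned" when nothing hits).
#' @export
classify_ncrna <- function(tags, references) {
  if (nrow(tags) == 0) return(tags)
  refs <- references
  refs$seq <- normalize_dna(refs$seq)
  classes <- intersect(CLASS_PRECEDENCE, unique(refs$class))
  ## one haystack per class including the minus strand
  haystacks <- lapply(classes, function(cl) {
    s <- refs$seq[refs$class == cl]
    paste(c(s, revcomp(s)), collapse = "|")
  })
  names(haystacks) <- classes
  cls <- tags$class
  unset <- cls %in% c("unassigned", NA)
  for (cl in classes) {
    todo <- which(unset)
    if (length(todo) == 0) break
    hit <- vapply(tags$sequence[todo], function(s)
      grepl(s, haystacks[[cl]], fixed = TRUE), logical(1))
    cls[todo[hit]] <- cl
    unset[todo[hit]] <- FALSE
  }
  tags$class <- cls
  tags
}

#' Parse a miRNA family label from a mature reference id
#'
#' Strips the species prefix, the "miR"/"MIR" token, paralog letter/number
#' suffixes and arm labels: "ath-miR156a-5p" -> "MIR156".
#'
#' @param ids character vector of reference ids.
#' @return character vector of family labels.
#' @export
mirna_family <- function(ids) {
  num <- sub("^.*?mir-?([0-9]+).*$", "\\1", tolower(ids))
  ifelse(grepl("mir", tolower(ids)) & grepl("^[0-9]+$", num),
         paste0("MIR", num), toupper(ids))
}

## apply the evolutionary merge map to family labels
merge_family_label <- function(fams) {
  for (merged in names(FAMILY_MERGES)) {
    fams[fams %in% FAMILY_MERGES[[merged]]] <- merged
  }
  fams
}

#' Identify conserved miRNAs by exact identity
#'
#' A tag is assigned if and only if its sequence is identical, full length,
#' to a reference mature miRNA (zero mismatches, equal length). Matching
#' tags get class "miRNA".
#'
#' @param tags tag data.frame.
#' @param mature_refs named character vector of mature miRNA sequences
#'   (names are reference ids, e.g. "ath-miR156a").
#' @return list with `tags` (class updated) and `assignments`, a
#'   data.frame of matched tags with reference ids, merged family and
#'   per-library counts.
#' @export
match_conserved <- function(tags, mature_refs) {
  refseq <- normalize_dna(mature_refs)
  ## references deduplicated by sequence for matching; all ids retained
  ids_by_seq <- split(names(refseq), refseq)
  hit <- tags$sequence %in% names(ids_by_seq)
  tags$class[hit] <- "miRNA"
  count_cols <- grep("^count_", names(tags), value = TRUE)
  if (!any(hit)) {
    assignments <- data.frame(sequence = character(0),
                              ref_ids = character(0),
                              family = character(0),
                              stringsAsFactors = FALSE)
    return(list(tags = tags, assignments = assignments))
  }
  mseq <- tags$sequence[hit]
  refids <- ids_by_seq[mseq]
  fam <- vapply(refids, function(ids)
    merge_family_label(mirna_family(ids))[1], character(1))
  assignments <- data.frame(
    sequence = mseq,
    ref_ids = vapply(refids, paste, character(1), collapse = ","),
    family = unname(fam),
    stringsAsFactors = FALSE, row.names = NULL)
  assignments <- cbind(assignments,
                       tags[hit, count_cols, drop = FALSE])
  rownames(assignments) <- NULL
  list(tags = tags, assignments = assignments)
}

#' Family table with member and read counts
#'
#' Members are distinct tag sequences; families already carry the
#' MIR156/157, MIR165/166 and MIR170/171 merges from [match_conserved()].
#'
#' @param assignments assignment data.frame from [match_conserved()].
#' @return data.frame with `family`, `members`, per-library read totals,
#'   sorted by members descending.
#' @export
merge_families <- function(assignments) {
  count_cols <- grep("^count_", names(assignments), value = TRUE)
  fams <- unique(assignments$family)
  out <- data.frame(family = fams, stringsAsFactors = FALSE)
  out$members <- vapply(fams, function(f)
    length(unique(assignments$sequence[assignments$family == f])),
    integer(1))
  for (cc in count_cols) {
    out[[cc]] <- vapply(fams, function(f)
      sum(assignments[[cc]][assignments$family == f]), numeric(1))
  }
  out <- out[order(-out$members, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Class tally with percentages (small-RNA categorization table)
#'
#' Per-class read totals over the 18-25 nt tags with half-up two-decimal
#' percentages of the in-window total; unmatched reads are reported as
#' "other sRNA".
#'
#' @param tags classified tag data.frame.
#' @param library optional library name; default tallies the `total`
#'   column.
#' @return data.frame with `class`, `reads`, `percent` rows for every
#'   class in precedence order plus "other sRNA" and "Total".
#' @export
categorize <- function(tags, library = NULL) {
  col <- if (is.null(library)) "total" else paste0("count_", library)
  check_that(col %in% names(tags), paste("no column", col))
  total <- sum(tags[[col]])
  reads <- vapply(CLASS_PRECEDENCE, function(cl)
    sum(tags[[col]][tags$class == cl]), numeric(1))
  other <- total - sum(reads)
  counts <- c(reads, `other sRNA` = other)
  pct <- if (total > 0) percent_of(counts, total, 2)
         else rep(0, length(counts))
  data.frame(class = c(names(counts), "Total"),
             reads = c(counts, total),
             percent = c(pct, if (total > 0) 100 else 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate tags against a full reference bundle
#'
#' Runs conserved matching first (precedence), then ncRNA classification
#' on the remainder.
#'
#' @param tags tag data.frame.
#' @param refs list with `ncrna` (data.frame) and `plant_mature` (named
#'   character vector), as produced by [simulate_references()] or loaded
#'   from FASTA.
#' @return list with `tags`, `assignments`, `families`, `categories`.
#' @export
annotate_tags <- function(tags, refs) {
  mc <- match_conserved(tags, refs$plant_mature)
  tags <- classify_ncrna(mc$tags, refs$ncrna)
  list(tags = tags,
       assignments = mc$assignments,
       families = merge_families(mc$assignments),
       categories = categorize(tags))
}
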