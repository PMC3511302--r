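## Pre-miRNA discovery on transcript contigs: exact tag mapping, block
## anchoring (one or two read stacks, same orientation, >= 11 reads),
## window extraction, RNAfold hairpin validation with MFE/MFEI and
## arm/star criteria, mature + star + isomiR calling, and category
## assignment (known in Bna / known in plants / novel).

#' Map tags exactly onto contigs
#'
#' Reports every exact full-length occurrence of each tag on both strands.
#' Coordinates are 0-based half-open on the plus strand of the contig.
#'
#' @param tags tag data.frame (needs `sequence`; other columns ignored).
#' @param contigs named character vector of contig sequences.
#' @return data.frame with `sequence`, `contig_id`, `start`, `end`,
#'   `strand`.
#' @export
map_tags <- function(tags, contigs) {
  empty <- data.frame(sequence = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (nrow(tags) == 0 || length(contigs) == 0) return(empty)
  seqs <- normalize_dna(tags$sequence)
  subj <- Biostrings::DNAStringSet(normalize_dna(contigs))
  names(subj) <- names(contigs)
  out <- list()
  for (strand in c("+", "-")) {
    pats <- if (strand == "+") seqs else revcomp(seqs)
    for (w in unique(nchar(pats))) {
      idx <- which(nchar(pats) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats[idx]))
      for (ci in seq_along(subj)) {
        if (length(subj[[ci]]) < w) next
        m <- Biostrings::matchPDict(pd, subj[[ci]])
        nh <- S4Vectors::elementNROWS(m)
        for (p in which(nh > 0)) {
          st <- BiocGenerics::start(m[[p]]) - 1L
          out[[length(out) + 1]] <- data.frame(
            sequence = seqs[idx[p]], contig_id = names(subj)[ci],
            start = st, end = st + w, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- unique(do.call(rbind, out))
  res <- res[order(res$contig_id, res$strand, res$start, res$sequence), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

## chain sorted hits into blocks: two hits share a block iff their
## intervals overlap or their starts differ by <= chain_gap, transitively
chain_blocks <- function(starts, ends, chain_gap) {
  n <- length(starts)
  block <- integer(n)
  block[1] <- 1L
  max_end <- ends[1]
  last_start <- starts[1]
  for (i in seq_len(n)[-1]) {
    if (starts[i] < max_end || starts[i] - last_start <= chain_gap) {
      block[i] <- block[i - 1]
    } else {
      block[i] <- block[i - 1] + 1L
    }
    max_end <- max(max_end, ends[i])
    last_start <- starts[i]
  }
  block
}

#' Group mapped tags into anchor blocks and judge each contig
#'
#' A contig-strand passes the anchoring filter when its hits chain into
#' one or two blocks, all hits share one orientation, and summed read
#' counts reach `min_reads` (the ">10 reads / at least 11 in total" rule).
#'
#' @param hits data.frame from [map_tags()] with an added `total` column
#'   (summed per-library counts of each tag).
#' @param min_reads minimum summed reads per contig-strand.
#' @param max_blocks maximum number of blocks.
#' @param chain_gap maximum start-position gap chaining two hits into one
#'   block.
#' @return list with `blocks` (data.frame: contig_id, strand, block,
#'   start, end, reads, distinct) and `verdicts` (data.frame per contig:
#'   n_blocks, single_strand, reads, strand, pass).
#' @export
find_blocks <- function(hits, min_reads = 11, max_blocks = 2,
                        chain_gap = 3) {
  check_that("total" %in% names(hits), "hits need a 'total' count column")
  blocks <- list()
  verdicts <- list()
  for (cid in unique(hits$contig_id)) {
    h <- hits[hits$contig_id == cid, , drop = FALSE]
    strands <- unique(h$strand)
    single <- length(strands) == 1
    ## blocks are still reported per strand for inspection
    for (s in strands) {
      hs <- h[h$strand == s, , drop = FALSE]
      hs <- hs[order(hs$start, hs$end), , drop = FALSE]
      b <- chain_blocks(hs$start, hs$end, chain_gap)
      for (bi in unique(b)) {
        sel <- b == bi
        blocks[[length(blocks) + 1]] <- data.frame(
          contig_id = cid, strand = s, block = bi,
          start = min(hs$start[sel]), end = max(hs$end[sel]),
          reads = sum(hs$total[sel]),
          distinct = length(unique(hs$sequence[sel])),
          stringsAsFactors = FALSE)
      }
    }
    nb <- if (single) max(chain_blocks(
      sort(h$start), h$end[order(h$start, h$end)], chain_gap)) else NA_integer_
    reads <- sum(h$total)
    verdicts[[length(verdicts) + 1]] <- data.frame(
      contig_id = cid,
      n_blocks = nb,
      single_strand = single,
      reads = reads,
      strand = if (single) strands else "*",
      pass = single && !is.na(nb) && nb >= 1 && nb <= max_blocks &&
        reads >= min_reads,
      stringsAsFactors = FALSE)
  }
  list(blocks = if (length(blocks)) do.call(rbind, blocks) else
         data.frame(),
       verdicts = if (length(verdicts)) do.call(rbind, verdicts) else
         data.frame())
}

#' Extract the candidate folding window around anchor blocks
#'
#' The window spans the blocks plus `flank` nt on each side, clipped to
#' the contig; contigs no longer than `max_window` are used whole. Minus
#' strand blocks yield the reverse-complemented window sequence.
#'
#' @param contig contig sequence (single string).
#' @param blocks block data.frame for this contig and strand.
#' @param flank flanking nt added on each side.
#' @param max_window contigs at or below this length are folded whole.
#' @return list with `sequence`, `start`, `end` (0-based half-open on the
#'   plus strand) and `strand`.
#' @export
extract_window <- function(contig, blocks, flank = 20, max_window = 300) {
  len <- nchar(contig)
  strand <- blocks$strand[1]
  if (len <= max_window) {
    ws <- 0L
    we <- len
  } else {
    ws <- as.integer(max(0, min(blocks$start) - flank))
    we <- as.integer(min(len, max(blocks$end) + flank))
  }
  s <- substr(contig, ws + 1L, we)
  if (strand == "-") s <- revcomp(s)
  list(sequence = s, start = ws, end = we, strand = strand)
}

#' Hairpin plausibility metrics
#'
#' GC content (percent), adjusted MFE (AMFE, kcal/mol per 100 nt) and the
#' MFE index MFEI = AMFE / GC. Plant pre-miRNAs are expected to satisfy
#' |MFEI| >= 0.85.
#'
#' @param mfe minimum free energy, kcal/mol.
#' @param sequence the folded sequence.
#' @return list with `length`, `gc` (percent), `amfe`, `mfei`.
#' @export
hairpin_metrics <- function(mfe, sequence) {
  L <- nchar(sequence)
  check_that(L > 0, "empty sequence")
  gc <- 100 * gc_fraction(sequence)
  if (mfe == 0) {
    return(list(length = L, gc = gc, amfe = 0, mfei = 0))
  }
  check_that(gc > 0, "MFEI undefined for GC = 0")
  amfe <- mfe / L * 100
  list(length = L, gc = gc, amfe = amfe, mfei = amfe / gc)
}

#' Validate a candidate hairpin structure
#'
#' A candidate passes when |MFEI| >= `min_mfei`, the dominant block lies
#' on one arm with at least `min_paired_frac` of its bases paired across
#' the terminal loop to the opposite arm, and no more than
#' `max_loop_overlap` of its bases fall inside the terminal loop. The
#' terminal loop is the hairpin loop with the deepest enclosing stem.
#'
#' @param dot_bracket structure of the window.
#' @param mfei MFE index from [hairpin_metrics()].
#' @param block_start,block_end dominant block interval, 0-based half-open
#'   in window coordinates.
#' @param min_mfei minimum |MFEI|.
#' @param min_paired_frac minimum fraction of block bases paired to the
#'   opposite arm.
#' @param max_loop_overlap maximum block bases inside the terminal loop.
#' @return list with `pass`, `reasons` (character), `arm` ("5p"/"3p"),
#'   `paired_frac`, `loop_overlap`, `loop_start`, `loop_end` (1-based
#'   inclusive window coordinates).
#' @export
validate_hairpin <- function(dot_bracket, mfei, block_start, block_end,
                             min_mfei = 0.85, min_paired_frac = 0.75,
                             max_loop_overlap = 3) {
  loops <- hairpin_loops(dot_bracket)
  if (nrow(loops) == 0) {
    return(list(pass = FALSE, reasons = "no_hairpin", arm = NA_character_,
                paired_frac = 0, loop_overlap = 0,
                loop_start = NA_integer_, loop_end = NA_integer_))
  }
  main <- loops[which.max(loops$depth), ]
  pt <- pair_table(dot_bracket)
  p <- seq(block_start + 1L, block_end)      # 1-based block positions
  partner <- pt[p]
  cross <- !is.na(partner) &
    ((p < main$start & partner > main$end) |
       (p > main$end & partner < main$start))
  paired_frac <- sum(cross) / length(p)
  loop_overlap <- sum(p >= main$start & p <= main$end)
  arm <- if (stats::median(p) < (main$start + main$end) / 2) "5p" else "3p"
  reasons <- character(0)
  if (abs(mfei) < min_mfei) reasons <- c(reasons, "mfei_below_threshold")
  if (paired_frac < min_paired_frac) {
    reasons <- c(reasons, "arm_pairing_insufficient")
  }
  if (loop_overlap > max_loop_overlap) reasons <- c(reasons, "in_loop")
  list(pass = length(reasons) == 0, reasons = reasons, arm = arm,
       paired_frac = paired_frac, loop_overlap = loop_overlap,
       loop_start = main$start, loop_end = main$end)
}

## pick the dominant row: highest total, ties by lexicographically
## smallest sequence
dominant_row <- function(df) {
  df <- df[order(-df$total, df$sequence), , drop = FALSE]
  df[1, , drop = FALSE]
}

#' Call mature, star and isomiR loci on a validated candidate
#'
#' Per arm, the dominant tag is the one with the highest summed count
#' (ties break to the lexicographically smallest sequence); other tags on
#' the same arm whose start and end offsets from the dominant are within
#' `isomir_window` are its isomiRs. The dominant of the opposite arm is
#' the star.
#'
#' @param whits window-coordinate hits for the candidate: data.frame with
#'   `sequence`, `wstart`, `wend` (0-based half-open in the window),
#'   `total` and per-library `count_*` columns.
#' @param loop_start,loop_end terminal loop, 1-based inclusive window
#'   coordinates.
#' @param isomir_window maximum 5'/3' offset of an isomiR.
#' @return list with `loci` (one row per occupied arm: arm, sequence,
#'   wstart, wend, counts, star sequence, n_isomirs, first_nt) and
#'   `isomirs` (arm, sequence, offset5, offset3, counts).
#' @export
call_mature_star_isomirs <- function(whits, loop_start, loop_end,
                                     isomir_window = 3) {
  count_cols <- grep("^count_", names(whits), value = TRUE)
  mid <- (whits$wstart + whits$wend) / 2
  whits$arm <- ifelse(mid < (loop_start + loop_end) / 2, "5p", "3p")
  loci <- list()
  isomirs <- list()
  for (arm in intersect(c("5p", "3p"), unique(whits$arm))) {
    ah <- whits[whits$arm == arm, , drop = FALSE]
    dom <- dominant_row(ah)
    rest <- ah[ah$sequence != dom$sequence, , drop = FALSE]
    off5 <- rest$wstart - dom$wstart
    off3 <- rest$wend - dom$wend
    iso <- abs(off5) <= isomir_window & abs(off3) <= isomir_window
    if (any(iso)) {
      isomirs[[arm]] <- data.frame(
        arm = arm, sequence = rest$sequence[iso],
        offset5 = off5[iso], offset3 = off3[iso],
        rest[iso, c("total", count_cols), drop = FALSE],
        stringsAsFactors = FALSE, row.names = NULL)
    }
    loci[[arm]] <- data.frame(
      arm = arm, sequence = dom$sequence,
      wstart = dom$wstart, wend = dom$wend,
      dom[, c("total", count_cols), drop = FALSE],
      n_isomirs = sum(iso),
      first_nt = chartr("T", "U", substr(dom$sequence, 1, 1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  loci <- do.call(rbind, loci)
  ## star = dominant of the opposite arm
  loci$star <- NA_character_
  if (nrow(loci) == 2) {
    loci$star <- rev(loci$sequence)
  }
  rownames(loci) <- NULL
  list(loci = loci,
       isomirs = if (length(isomirs)) do.call(rbind, isomirs)
                 else data.frame())
}

#' Classify a candidate precursor by its dominant mature
#'
#' @param mature_seq dominant mature sequence (DNA alphabet).
#' @param bna_matures named character vector of known Bna matures.
#' @param plant_matures named character vector of known plant matures.
#' @return "known_bna", "known_plant" or "novel".
#' @export
classify_precursor <- function(mature_seq, bna_matures, plant_matures) {
  m <- normalize_dna(mature_seq)
  if (m %in% normalize_dna(bna_matures)) return("known_bna")
  if (m %in% normalize_dna(plant_matures)) return("known_plant")
  "novel"
}

#' Acceptance filter for novel families
#'
#' A novel candidate is kept when its mature is present in every library,
#' or a star sequence was detected in at least one library.
#'
#' @param mature_counts numeric vector of per-library mature counts.
#' @param star_present logical, star tag detected in any library.
#' @return logical.
#' @export
novel_family_filter <- function(mature_counts, star_present) {
  all(mature_counts > 0) || isTRUE(star_present)
}

#' First-nucleotide profile of mature miRNAs
#'
#' @param matures character vector of mature sequences.
#' @return named integer vector of counts for A, C, G, U.
#' @export
first_nucleotide_profile <- function(matures) {
  first <- chartr("T", "U", substr(normalize_dna(matures), 1, 1))
  counts <- table(factor(first, levels = c("A", "C", "G", "U")))
  stats::setNames(as.integer(counts), names(counts))
}

## map a plus-strand contig interval into window coordinates
to_window <- function(start, end, win) {
  if (win$strand == "+") {
    data.frame(wstart = start - win$start, wend = end - win$start)
  } else {
    data.frame(wstart = win$end - end, wend = win$end - start)
  }
}

#' Discover pre-miRNA candidates end to end
#'
#' Runs mapping, block anchoring, window folding, hairpin validation,
#' mature/star/isomiR calling, categorisation and the novel-family filter
#' over all contigs. Candidates whose contig passes anchoring but whose
#' window fails structural validation are kept with status "partial" only
#' when their dominant tag is identical to a known Bna mature.
#'
#' @param tags annotated tag data.frame (only classes "unassigned" and
#'   "miRNA" are mapped).
#' @param contigs named character vector of contig sequences.
#' @param bna_matures,plant_matures named character vectors of reference
#'   matures.
#' @param min_reads,max_blocks,chain_gap anchoring parameters, see
#'   [find_blocks()].
#' @param flank,max_window window parameters, see [extract_window()].
#' @param min_mfei,min_paired_frac,max_loop_overlap validation parameters,
#'   see [validate_hairpin()].
#' @param isomir_window isomiR offset window.
#' @return list with `candidates` (one row per accepted precursor with
#'   window, structure, MFE/AMFE/MFEI/GC, category, status, mfe_band_warn),
#'   `loci` (mature/star records with window and contig coordinates),
#'   `isomirs`, `hits`, `verdicts`.
#' @export
discover_precursors <- function(tags, contigs, bna_matures, plant_matures,
                                min_reads = 11, max_blocks = 2,
                                chain_gap = 3, flank = 20,
                                max_window = 300, min_mfei = 0.85,
                                min_paired_frac = 0.75,
                                max_loop_overlap = 3, isomir_window = 3) {
  count_cols <- grep("^count_", names(tags), value = TRUE)
  eligible <- tags[tags$class %in% c("unassigned", "miRNA"), , drop = FALSE]
  hits <- map_tags(eligible, contigs)
  empty_out <- list(candidates = data.frame(), loci = data.frame(),
                    isomirs = data.frame(), hits = hits,
                    verdicts = data.frame())
  if (nrow(hits) == 0) return(empty_out)
  idx <- match(hits$sequence, eligible$sequence)
  hits$total <- eligible$total[idx]
  for (cc in count_cols) hits[[cc]] <- eligible[[cc]][idx]

  fb <- find_blocks(hits, min_reads, max_blocks, chain_gap)
  passing <- fb$verdicts$contig_id[fb$verdicts$pass]
  if (length(passing) == 0) {
    empty_out$verdicts <- fb$verdicts
    return(empty_out)
  }

  cands <- list()
  loci_all <- list()
  iso_all <- list()
  serial <- 0L
  ## fold all windows in one external call
  wins <- list()
  for (cid in passing) {
    strand <- fb$verdicts$strand[fb$verdicts$contig_id == cid]
    b <- fb$blocks[fb$blocks$contig_id == cid &
                     fb$blocks$strand == strand, , drop = FALSE]
    wins[[cid]] <- extract_window(contigs[[cid]], b, flank, max_window)
  }
  folded <- fold_many(vapply(wins, `[[`, character(1), "sequence"))

  for (cid in passing) {
    serial <- serial + 1L
    strand <- fb$verdicts$strand[fb$verdicts$contig_id == cid]
    b <- fb$blocks[fb$blocks$contig_id == cid &
                     fb$blocks$strand == strand, , drop = FALSE]
    win <- wins[[cid]]
    fr <- folded[folded$id == cid, ]
    met <- hairpin_metrics(fr$mfe, win$sequence)

    dom_block <- b[which.max(b$reads), ]
    dbw <- to_window(dom_block$start, dom_block$end, win)
    val <- validate_hairpin(fr$dot_bracket, met$mfei, dbw$wstart, dbw$wend,
                            min_mfei, min_paired_frac, max_loop_overlap)

    ch <- hits[hits$contig_id == cid & hits$strand == strand, , drop = FALSE]
    chw <- to_window(ch$start, ch$end, win)
    ch$wstart <- chw$wstart
    ch$wend <- chw$wend

    status <- if (val$pass) "full_length" else "partial"
    if (!val$pass) {
      dom_tag <- dominant_row(ch[ch$wstart >= dbw$wstart - isomir_window &
                                   ch$wend <= dbw$wend + isomir_window, ,
                                 drop = FALSE])
      if (nrow(dom_tag) == 0 ||
          !dom_tag$sequence %in% normalize_dna(bna_matures)) {
        next   # rejected candidate
      }
      category <- "known_bna"
      loci <- data.frame(arm = NA_character_, sequence = dom_tag$sequence,
                         wstart = dom_tag$wstart, wend = dom_tag$wend,
                         dom_tag[, c("total", count_cols), drop = FALSE],
                         n_isomirs = 0L,
                         first_nt = chartr("T", "U",
                                           substr(dom_tag$sequence, 1, 1)),
                         star = NA_character_, stringsAsFactors = FALSE)
      isom <- data.frame()
    } else {
      called <- call_mature_star_isomirs(ch, val$loop_start, val$loop_end,
                                         isomir_window)
      loci <- called$loci
      isom <- called$isomirs
      dom_arm <- loci[which.max(loci$total), ]
      category <- classify_precursor(dom_arm$sequence, bna_matures,
                                     plant_matures)
      if (category == "novel") {
        star_present <- nrow(loci) == 2 &&
          sum(loci$total[loci$sequence != dom_arm$sequence]) > 0
        mc <- as.numeric(dom_arm[, count_cols])
        if (!novel_family_filter(mc, star_present)) next
      }
    }
    cand_id <- sprintf("cand%03d", serial)
    ## contig coordinates of each locus (round-trip through the window)
    if (win$strand == "+") {
      loci$start <- win$start + loci$wstart
      loci$end <- win$start + loci$wend
    } else {
      loci$start <- win$end - loci$wend
      loci$end <- win$end - loci$wstart
    }
    loci$precursor_id <- cand_id
    loci$contig_id <- cid
    loci$strand <- win$strand
    if (nrow(isom) > 0) {
      isom$precursor_id <- cand_id
      isom$contig_id <- cid
    }
    cands[[cand_id]] <- data.frame(
      id = cand_id, contig_id = cid, strand = win$strand,
      window_start = win$start, window_end = win$end,
      sequence = win$sequence, dot_bracket = fr$dot_bracket,
      mfe = fr$mfe, length = met$length, gc = met$gc, amfe = met$amfe,
      mfei = met$mfei, n_blocks = nrow(b), reads = sum(b$reads),
      category = category, status = status,
      mfe_band_warn = !(fr$mfe <= -40 && fr$mfe >= -100),
      paired_frac = val$paired_frac, stringsAsFactors = FALSE)
    loci_all[[cand_id]] <- loci
    if (nrow(isom) > 0) iso_all[[cand_id]] <- isom
  }
  list(candidates = if (length(cands)) do.call(rbind, c(cands,
         make.row.names = FALSE)) else data.frame(),
       loci = if (length(loci_all)) do.call(rbind, c(loci_all,
         make.row.names = FALSE)) else data.frame(),
       isomirs = if (length(iso_all)) do.call(rbind, c(iso_all,
         make.row.names = FALSE)) else data.frame(),
       hits = hits, verdicts = fb$verdicts)
}

#' Serialize candidates to GFF3-style features
#'
#' @param disc result of [discover_precursors()].
#' @return data.frame of GFF3 columns (1-based inclusive).
#' @export
candidates_to_gff <- function(disc) {
  cand <- disc$candidates
  loci <- disc$loci
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    c1 <- cand[i, ]
    rows[[length(rows) + 1]] <- data.frame(
      seqid = c1$contig_id, source = "seedmir", type = "pre_miRNA",
      start = c1$window_start + 1L, end = c1$window_end,
      score = c1$mfe, strand = c1$strand,
      attributes = sprintf("ID=%s;category=%s;status=%s;MFEI=%.3f",
                           c1$id, c1$category, c1$status, c1$mfei),
      stringsAsFactors = FALSE)
    lc <- loci[loci$precursor_id == c1$id, , drop = FALSE]
    for (j in seq_len(nrow(lc))) {
      l1 <- lc[j, ]
      rows[[length(rows) + 1]] <- data.frame(
        seqid = l1$contig_id, source = "seedmir", type = "miRNA",
        start = l1$start + 1L, end = l1$end, score = l1$total,
        strand = l1$strand,
        attributes = sprintf("ID=%s-%s;Parent=%s;arm=%s", c1$id,
                             ifelse(is.na(l1$arm), "m", l1$arm), c1$id,
                             ifelse(is.na(l1$arm), "NA", l1$arm)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(seqid = character(0)))
  }
  do.call(rbind, rows)
}

#' Write candidate structures in RNAfold dialect
#'
#' For each candidate: a header line, the sequence line and the
#' dot-bracket line suffixed with "(MFE)".
#'
#' @param disc result of [discover_precursors()].
#' @param path output file.
#' @export
write_structure_file <- function(disc, path) {
  cand <- disc$candidates
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cand))) {
    writeLines(c(paste0(">", cand$id[i]),
                 chartr("T", "U", cand$sequence[i]),
                 sprintf("%s (%.2f)", cand$dot_bracket[i], cand$mfe[i])),
               con)
  }
  invisible(path)
}
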