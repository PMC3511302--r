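test_that("folding returns valid structures and energies", {
  f <- fold(strrep("A", 60))
  expect_identical(f$dot_bracket, strrep(".", 60))
  expect_identical(f$mfe, 0)
  hp <- simulate_hairpin(seed = 2, arm_len = 21, loop_len = 8,
                         star_mismatches = 0)
  f2 <- fold(hp$sequence)
  expect_identical(nchar(f2$dot_bracket), nchar(hp$sequence))
  pt <- pair_table(f2$dot_bracket)            # errors if unbalanced
  expect_gte(sum(!is.na(pt[1:21])), 17)
  expect_lte(f2$mfe, 0)
  expect_error(fold("ACGTXACGT"), "non-nucleotide")
  # batch folding matches single calls
  many <- fold_many(c(a = strrep("A", 50), h = hp$sequence))
  expect_identical(many$mfe[2], f2$mfe)
})

test_that("tags map exactly on both strands with half-open coordinates", {
  tag <- "TGACAGAAGAGAGTGAGCACA"
  ctg <- paste0(strrep("C", 100), tag, strrep("A", 50),
                revcomp(tag), strrep("C", 30))
  absent <- "GATTACAGATTACAGATTAC"
  tags <- data.frame(sequence = c(tag, absent),
                     total = c(5L, 1L), class = "unassigned",
                     stringsAsFactors = FALSE)
  hits <- map_tags(tags, c(ctg1 = ctg))
  h <- hits[hits$sequence == tag, ]
  expect_identical(nrow(h), 2L)
  plus <- h[h$strand == "+", ]
  expect_identical(c(plus$start, plus$end), c(100L, 121L))
  minus <- h[h$strand == "-", ]
  expect_identical(c(minus$start, minus$end), c(171L, 192L))
  expect_false(absent %in% hits$sequence)
})

test_that("block anchoring applies the 11-read / two-block / one-strand rules", {
  mk_hits <- function(starts, totals, strand = "+") {
    data.frame(sequence = sprintf("t%02d", seq_along(starts)),
               contig_id = "c1", start = starts, end = starts + 21L,
               strand = strand, total = totals, stringsAsFactors = FALSE)
  }
  # 12 reads stacked in one block -> pass
  v <- find_blocks(mk_hits(c(100, 101, 102), c(6, 4, 2)))$verdicts
  expect_true(v$pass)
  expect_identical(v$n_blocks, 1L)
  # 10 reads -> fail
  expect_false(find_blocks(mk_hits(c(100, 101), c(6, 4)))$verdicts$pass)
  # 12 reads over 3 separated blocks -> fail
  v3 <- find_blocks(mk_hits(c(100, 200, 300), c(4, 4, 4)))$verdicts
  expect_false(v3$pass)
  expect_identical(v3$n_blocks, 3L)
  # opposite strands on one contig -> fail
  both <- rbind(mk_hits(c(100, 101), c(8, 8)),
                mk_hits(150, 8, strand = "-"))
  expect_false(find_blocks(both)$verdicts$pass)
  # chain gap: starts 3 apart chain, 4 apart do not
  expect_identical(
    find_blocks(mk_hits(c(100, 103), c(30, 30)))$verdicts$n_blocks, 1L)
  expect_identical(
    find_blocks(mk_hits(c(100, 125), c(30, 30)))$verdicts$n_blocks, 2L)
})

test_that("window extraction follows block span, clipping and strand", {
  ctg <- paste(rep(c("A", "C", "G", "T"), 100), collapse = "")  # 400 nt
  blocks <- data.frame(contig_id = "c", strand = "+",
                       start = c(50L, 120L), end = c(71L, 141L))
  w <- extract_window(ctg, blocks, flank = 20)
  expect_identical(c(w$start, w$end), c(30L, 161L))
  expect_identical(w$sequence, substr(ctg, 31, 161))
  # clipping at the contig start
  b2 <- data.frame(contig_id = "c", strand = "+", start = 5L, end = 26L)
  expect_identical(extract_window(ctg, b2, flank = 20)$start, 0L)
  # short contigs are used whole
  short <- substr(ctg, 1, 200)
  w3 <- extract_window(short, b2, flank = 20, max_window = 300)
  expect_identical(c(w3$start, w3$end), c(0L, 200L))
  # minus-strand window is the reverse complement of the plus extraction
  bm <- blocks
  bm$strand <- "-"
  wm <- extract_window(ctg, bm, flank = 20)
  expect_identical(wm$sequence, revcomp(w$sequence))
})

test_that("hairpin metrics implement AMFE and MFEI arithmetic", {
  m <- hairpin_metrics(-42.5, random_seq <- paste(
    rep(c("G", "C", "A", "T"), 25), collapse = ""))   # L=100, GC=50
  expect_equal(m$amfe, -42.5)
  expect_equal(m$mfei, -0.85)
  m2 <- hairpin_metrics(-42.5, strrep(random_seq, 2)) # L=200
  expect_equal(m2$amfe, -21.25)
  expect_equal(m2$mfei, -0.425)
  m0 <- hairpin_metrics(0, "ATATATAT")
  expect_identical(m0$mfei, 0)
  expect_error(hairpin_metrics(-5, strrep("AT", 30)), "MFEI undefined")
})

test_that("hairpin validation enforces MFEI, arm pairing and loop exclusion", {
  hp <- simulate_hairpin(seed = 6, arm_len = 21, loop_len = 10,
                         star_mismatches = 2)
  f <- fold(hp$sequence)
  met <- hairpin_metrics(f$mfe, hp$sequence)
  ok <- validate_hairpin(f$dot_bracket, met$mfei, 0L, 21L)
  expect_true(ok$pass)
  expect_identical(ok$arm, "5p")
  # mature placed inside the terminal loop -> fail
  bad <- validate_hairpin(f$dot_bracket, met$mfei, 21L, 31L,
                          max_loop_overlap = 3)
  expect_false(bad$pass)
  expect_true("in_loop" %in% bad$reasons)
  # weak MFEI -> fail even with good pairing
  weak <- validate_hairpin(f$dot_bracket, -0.5, 0L, 21L)
  expect_false(weak$pass)
  expect_true("mfei_below_threshold" %in% weak$reasons)
})

test_that("mature, star and isomiR calling follows dominance and offsets", {
  mk <- function(seq, ws, tot) {
    data.frame(sequence = seq, wstart = ws, wend = ws + nchar(seq),
               total = tot, count_A = tot, stringsAsFactors = FALSE)
  }
  whits <- rbind(mk(strrep("A", 21), 10L, 50L),       # dominant 5p
                 mk(strrep("C", 21), 11L, 10L),       # isomiR +1
                 mk(strrep("G", 20), 9L, 5L),         # isomiR -1/-2
                 mk(strrep("T", 21), 60L, 8L))        # 3p star
  out <- call_mature_star_isomirs(whits, loop_start = 40, loop_end = 50,
                                  isomir_window = 3)
  l5 <- out$loci[out$loci$arm == "5p", ]
  expect_identical(l5$sequence, strrep("A", 21))
  expect_identical(l5$n_isomirs, 2L)
  expect_identical(l5$star, strrep("T", 21))
  expect_identical(out$loci$star[out$loci$arm == "3p"], strrep("A", 21))
  expect_setequal(out$isomirs$offset5, c(1L, -1L))
  # count tie breaks to the lexicographically smallest sequence
  tie <- rbind(mk("TTTTTTTTTTTTTTTTTTTTT", 10L, 30L),
               mk("AAAAAAAAAAAAAAAAAAAAA", 11L, 30L))
  t_out <- call_mature_star_isomirs(tie, 40, 50)
  expect_identical(t_out$loci$sequence[1], strrep("A", 21))
})

test_that("category assignment and the novel-family filter follow identity rules", {
  bna <- c("bna-miR159" = "TTTGGATTGAAGGGAGCTCTA")
  plant <- c(bna, "ath-miR172a" = "AGAATCTTGATGATGCTGCAT")
  expect_identical(classify_precursor(unname(bna), bna, plant),
                   "known_bna")
  expect_identical(classify_precursor("AGAATCTTGATGATGCTGCAT", bna, plant),
                   "known_plant")
  mm <- "AGAATCTTGATGATGCTGCAA"  # one mismatch vs everything
  expect_identical(classify_precursor(mm, bna, plant), "novel")

  expect_true(novel_family_filter(c(3, 1), star_present = FALSE))
  expect_true(novel_family_filter(c(3, 0), star_present = TRUE))
  expect_false(novel_family_filter(c(3, 0), star_present = FALSE))
})

test_that("first-nucleotide profiles count U bias", {
  expect_identical(first_nucleotide_profile(c("TAGCT", "TGGA", "AAGT")),
                   c(A = 1L, C = 0L, G = 0L, U = 2L))
  expect_identical(sum(first_nucleotide_profile(character(0))), 0L)
  # simulated U-start bias lands in the binomial 99% interval
  set.seed(40)
  n <- 50
  firsts <- sample(c("T", "A"), n, replace = TRUE, prob = c(0.8, 0.2))
  prof <- first_nucleotide_profile(paste0(firsts, strrep("G", 20)))
  ci <- qbinom(c(0.005, 0.995), n, 0.8)
  expect_gte(prof[["U"]], ci[1])
  expect_lte(prof[["U"]], ci[2])
})

test_that("end-to-end discovery recovers planted precursors and skips decoys", {
  sd <- small_discovery()
  truth <- sd$ds$truth
  cand <- sd$disc$candidates
  expect_gte(sum(truth$contig_id %in% cand$contig_id),
             ceiling(0.9 * nrow(truth)))
  expect_identical(sum(grepl("decoy", cand$contig_id)), 0L)
  # reported candidates re-satisfy their serialized validation metrics
  expect_true(all(abs(cand$mfei[cand$status == "full_length"]) >= 0.85))
  expect_true(all(cand$mfe <= 0))
  expect_equal(cand$amfe, cand$mfe / cand$length * 100)
  expect_equal(cand$mfei, cand$amfe / cand$gc)
  # categories match the planted truth
  m <- merge(cand, truth, by = "contig_id")
  expect_true(all(m$category.x == m$category.y))
  # coordinate round-trip: locus contig interval contains the called tag
  loci <- sd$disc$loci
  for (i in seq_len(nrow(loci))) {
    ctg <- sd$ds$contigs[[loci$contig_id[i]]]
    seg <- substr(ctg, loci$start[i] + 1, loci$end[i])
    if (loci$strand[i] == "-") seg <- revcomp(seg)
    expect_identical(seg, loci$sequence[i])
  }
})

test_that("discovery is invariant under reverse-complementing a contig", {
  sd <- small_discovery()
  truth <- sd$ds$truth
  cid <- truth$contig_id[1]
  contigs2 <- sd$ds$contigs
  contigs2[[cid]] <- revcomp(contigs2[[cid]])
  disc2 <- discover_precursors(sd$ann$tags, contigs2,
                               sd$ds$refs$bna_mature,
                               sd$ds$refs$plant_mature)
  c1 <- sd$disc$candidates[sd$disc$candidates$contig_id == cid, ]
  c2 <- disc2$candidates[disc2$candidates$contig_id == cid, ]
  expect_identical(nrow(c2), nrow(c1))
  expect_identical(c2$strand, "-")
  expect_identical(c2$sequence, c1$sequence)   # same folded window
  l1 <- sd$disc$loci[sd$disc$loci$contig_id == cid, ]
  l2 <- disc2$loci[disc2$loci$contig_id == cid, ]
  expect_setequal(l2$sequence, l1$sequence)
  expect_identical(sort(l2$arm), sort(l1$arm))
})
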