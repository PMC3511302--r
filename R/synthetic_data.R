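## Synthetic small-RNA study generator.
##
## Emulates a two-condition plant seed small-RNA experiment: transcript
## contigs carrying planted pre-miRNA hairpins, reference sets (ncRNA
## classes, plant/Bna mature miRNAs), and per-library FASTQ reads with
## mature, star, isomiR and contaminant components. Every operation is
## deterministic under a fixed seed so downstream stages can be validated
## against the planted truth.

WC_PAIR <- c(A = "T", C = "G", G = "C", T = "A")

## bases that neither Watson-Crick pair nor G:U wobble with `base`
non_pairing_bases <- function(base) {
  forbid <- WC_PAIR[[base]]
  if (base == "G") forbid <- c(forbid, "T")
  if (base == "T") forbid <- c(forbid, "G")
  setdiff(c("A", "C", "G", "T"), c(base, forbid))
}

#' Library profile for the read simulator
#'
#' @param name library label.
#' @param total_reads total reads written for this library.
#' @param per_locus_abundance relative expected abundance per planted locus
#'   (recycled to the number of loci).
#' @param fold_change per-locus multiplicative factor applied in this
#'   library (recycled); 1 means no change.
#' @return a `library_profile` list.
#' @export
library_profile <- function(name, total_reads = 50000,
                            per_locus_abundance = 1, fold_change = 1) {
  check_that(total_reads > 0, "total_reads must be positive")
  check_that(all(per_locus_abundance > 0), "abundances must be positive")
  check_that(all(fold_change > 0), "fold changes must be positive")
  structure(list(name = name, total_reads = as.integer(total_reads),
                 per_locus_abundance = per_locus_abundance,
                 fold_change = fold_change),
            class = "library_profile")
}

#' Simulation configuration
#'
#' Defaults describe the emulated study: two libraries (`mature` vs
#' `developing` seeds), 20 planted hairpin precursors among 20 decoy
#' contigs, 21-nt mature arms, a 24-nt-biased contaminant background that
#' reproduces the 21/24-nt bimodal length profile typical of plant seed
#' small-RNA libraries, and eight loci with an 8-fold abundance change in
#' the developing library.
#'
#' @param seed integer RNG seed.
#' @param n_precursors number of planted hairpin precursors.
#' @param n_decoy_contigs number of contigs without any planted hairpin.
#' @param arm_len mature/arm length in nt (18-25).
#' @param loop_range loop length range sampled per precursor.
#' @param gc_target target GC fraction of the 5p arm.
#' @param star_mismatches substitutions between the 3p arm and the perfect
#'   reverse complement of the 5p arm.
#' @param libraries list of [library_profile()] objects.
#' @param adapter3 3' adapter appended to every read.
#' @param contaminant_fraction fraction of reads drawn from ncRNA
#'   references.
#' @param sirna_fraction fraction of reads that are random siRNA-like
#'   sequences (24-nt biased) matching no reference.
#' @param isomir_rate fraction of a locus's mature-arm reads emitted as
#'   5'/3' offset isomiRs.
#' @param star_rate fraction of a locus's reads drawn from the star arm.
#' @param u_start_bias probability that a planted mature starts with U.
#' @param low_quality_fraction fraction of reads written with Phred 8
#'   qualities to exercise the quality filter.
#' @param category_fractions named numeric, fractions of loci whose mature
#'   is planted into the Bna reference set (`known_bna`), only the plant
#'   set (`known_plant`), or neither (`novel`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_precursors = 20L,
                       n_decoy_contigs = 20L,
                       arm_len = 21L,
                       loop_range = c(8L, 15L),
                       gc_target = 0.45,
                       star_mismatches = 2L,
                       libraries = list(
                         library_profile("mature", 50000),
                         library_profile("developing", 50000,
                                         fold_change = rep(c(8, 1 / 8, 1),
                                                           c(4, 4, 12)))
                       ),
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       contaminant_fraction = 0.15,
                       sirna_fraction = 0.25,
                       isomir_rate = 0.2,
                       star_rate = 0.1,
                       u_start_bias = 0.8,
                       low_quality_fraction = 0,
                       category_fractions = c(known_bna = 0.3,
                                              known_plant = 0.3,
                                              novel = 0.4)) {
  check_that(arm_len >= 18 && arm_len <= 25, "arm_len must be in [18,25]")
  fracs <- c(contaminant_fraction, sirna_fraction, isomir_rate, star_rate,
             u_start_bias, low_quality_fraction)
  check_that(all(fracs >= 0 & fracs <= 1), "fractions must lie in [0,1]")
  check_that(contaminant_fraction + sirna_fraction < 1,
             "contaminant + siRNA fractions must leave room for signal")
  check_that(length(libraries) >= 1, "at least one library profile needed")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one pre-miRNA hairpin
#'
#' Builds `arm5p + loop + arm3p` where `arm3p` is the reverse complement of
#' `arm5p` carrying exactly `star_mismatches` pairing-breaking
#' substitutions, so that folding the result yields a stem-loop with the
#' mature sequence on one arm and a near-complementary star on the other.
#' The loop is drawn from A/C so it cannot extend the stem.
#'
#' @param seed optional RNG seed.
#' @param arm_len arm length (>= 18).
#' @param loop_len loop length (>= 3).
#' @param gc_target target GC fraction of the 5p arm (achieved within
#'   +/- 0.1).
#' @param star_mismatches number of substitutions on the 3p arm.
#' @param first_nt optional fixed first base of the 5p arm (e.g. "T" for a
#'   5' U mature).
#' @return list with `sequence`, `arm5p`, `loop`, `arm3p`.
#' @export
simulate_hairpin <- function(seed = NULL, arm_len = 21L, loop_len = 8L,
                             gc_target = 0.45, star_mismatches = 2L,
                             first_nt = NULL) {
  check_that(arm_len >= 18, "arm_len must be >= 18")
  check_that(loop_len >= 3, "loop_len must be >= 3")
  check_that(star_mismatches >= 0 && star_mismatches <= arm_len,
             "star_mismatches must be in [0, arm_len]")
  if (!is.null(seed)) set.seed(seed)

  ## exact GC count keeps the arm within +/-0.1 of the target
  n_gc <- round(arm_len * gc_target)
  bases <- character(arm_len)
  gc_pos <- sample.int(arm_len, n_gc)
  bases[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  bases[-gc_pos] <- sample(c("A", "T"), arm_len - n_gc, replace = TRUE)
  if (!is.null(first_nt)) bases[1] <- first_nt
  arm5p <- paste(bases, collapse = "")

  star <- strsplit(revcomp(arm5p), "")[[1]]
  if (star_mismatches > 0) {
    ## avoid the outermost positions so the stem ends stay clamped
    pool <- seq(2L, arm_len - 1L)
    mm_pos <- sample(pool, star_mismatches)
    for (i in mm_pos) {
      partner <- bases[arm_len - i + 1L]
      star[i] <- sample(non_pairing_bases(partner), 1)
    }
  }
  arm3p <- paste(star, collapse = "")
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE,
                       prob = c(0.6, 0.4)), collapse = "")
  list(sequence = paste0(arm5p, loop, arm3p),
       arm5p = arm5p, loop = loop, arm3p = arm3p)
}

## lower (basal) stem surrounding the mature/star duplex, as in pri-miRNAs:
## a stem segment before the 5p arm whose imperfect reverse complement
## follows the 3p arm, so the folded precursor is stem-dominated
lower_stem <- function(len, gc, mismatches = 2L) {
  up <- random_dna(len, gc)
  down <- strsplit(revcomp(up), "")[[1]]
  if (mismatches > 0 && len > 2) {
    pos <- sample(seq(2L, len - 1L), min(mismatches, len - 2L))
    for (i in pos) {
      partner <- substr(up, len - i + 1L, len - i + 1L)
      down[i] <- sample(non_pairing_bases(partner), 1)
    }
  }
  list(up = up, down = paste(down, collapse = ""))
}

#' Plant hairpin precursors into synthetic contigs
#'
#' Each precursor consists of the mature/star duplex from
#' [simulate_hairpin()] extended by an imperfect basal stem on both sides
#' (as in genuine pri-miRNA fold-backs), embedded in a contig with long
#' random flanks; decoy contigs carry no hairpin. Coordinates in the truth
#' table are 0-based half-open on the contig plus strand.
#'
#' @param config a [sim_config()].
#' @return list with `contigs` (named character vector) and `truth`
#'   (data.frame, one row per planted precursor).
#' @export
plant_precursors <- function(config) {
  check_that(inherits(config, "sim_config"), "config must be a sim_config")
  check_that(config$n_decoy_contigs >= 0, "n_decoy_contigs must be >= 0")
  set.seed(config$seed)

  n <- config$n_precursors
  cats <- rep(names(config$category_fractions),
              diff(round(cumsum(c(0, config$category_fractions)) * n)))
  cats <- c(cats, rep("novel", n - length(cats)))

  contigs <- character(0)
  rows <- list()
  seen_mature <- character(0)
  for (i in seq_len(n)) {
    repeat {
      loop_len <- sample(seq(config$loop_range[1], config$loop_range[2]), 1)
      first_nt <- if (stats::runif(1) < config$u_start_bias) "T" else NULL
      hp <- simulate_hairpin(seed = NULL, arm_len = config$arm_len,
                             loop_len = loop_len,
                             gc_target = config$gc_target,
                             star_mismatches = config$star_mismatches,
                             first_nt = first_nt)
      if (!hp$arm5p %in% seen_mature) break
    }
    seen_mature <- c(seen_mature, hp$arm5p)
    basal <- lower_stem(sample(18:25, 1), config$gc_target)
    ## short upper stem between the mature/star duplex and the terminal
    ## loop, as in genuine pre-miRNAs (the processed duplex does not abut
    ## the loop)
    upper <- lower_stem(sample(5:8, 1), config$gc_target, mismatches = 1L)
    hairpin_seq <- paste0(hp$arm5p, upper$up, hp$loop, upper$down,
                          hp$arm3p)
    precursor <- paste0(basal$up, hairpin_seq, basal$down)
    lflank <- sample(120:250, 1)
    rflank <- sample(120:250, 1)
    contig <- paste0(random_dna(lflank, config$gc_target), precursor,
                     random_dna(rflank, config$gc_target))
    cid <- sprintf("contig%04d", i)
    pid <- sprintf("prec%03d", i)
    contigs[cid] <- contig
    a <- config$arm_len
    m5_start <- lflank + nchar(basal$up)
    mid_len <- nchar(upper$up) + nchar(hp$loop) + nchar(upper$down)
    rows[[i]] <- data.frame(
      precursor_id = pid, contig_id = cid,
      start = lflank, end = lflank + nchar(precursor),
      mature5p = hp$arm5p,
      mature5p_start = m5_start, mature5p_end = m5_start + a,
      mature3p = hp$arm3p,
      mature3p_start = m5_start + a + mid_len,
      mature3p_end = m5_start + 2L * a + mid_len,
      category = cats[i], stringsAsFactors = FALSE)
  }
  for (j in seq_len(config$n_decoy_contigs)) {
    cid <- sprintf("decoy%04d", j)
    contigs[cid] <- random_dna(sample(150:400, 1), config$gc_target)
  }
  truth <- do.call(rbind, rows)
  list(contigs = contigs, truth = truth)
}

#' Truth table as GFF3-like features
#'
#' @param truth truth table from [plant_precursors()].
#' @return data.frame of GFF3 columns (1-based inclusive coordinates).
#' @export
truth_to_gff <- function(truth) {
  gff_row <- function(seqid, type, start0, end0, id, arm) {
    data.frame(seqid = seqid, source = "seedmir_sim", type = type,
               start = start0 + 1L, end = end0, score = ".", strand = "+",
               attributes = paste0("ID=", id,
                                   if (nzchar(arm)) paste0(";arm=", arm)
                                   else ""),
               stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    rbind(gff_row(t$contig_id, "pre_miRNA", t$start, t$end,
                  t$precursor_id, ""),
          gff_row(t$contig_id, "miRNA", t$mature5p_start, t$mature5p_end,
                  paste0(t$precursor_id, "-5p"), "5p"),
          gff_row(t$contig_id, "miRNA", t$mature3p_start, t$mature3p_end,
                  paste0(t$precursor_id, "-3p"), "3p"))
  })
  do.call(rbind, out)
}

## realistic plant miRNA family numbers used for reference naming
FAMILY_POOL <- c(156, 157, 158, 159, 160, 162, 164, 165, 166, 167, 168,
                 169, 170, 171, 172, 319, 390, 391, 393, 394, 395, 396,
                 398, 399, 400, 403, 408, 824, 827, 858, 1140, 1885, 2111)

#' Simulate reference sets matched to a planted truth table
#'
#' Produces the reference FASTA contents the annotation stage expects:
#' ncRNA classes (rRNA, tRNA, snRNA, snoRNA, mtRNA, cpRNA), a Bna mature
#' miRNA set containing the matures of `known_bna` loci, and a plant mature
#' set containing Bna plus `known_plant` matures plus unrelated decoy
#' matures. All sequences are synthetic stand-ins generated under the
#' config seed.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [plant_precursors()].
#' @return list with `ncrna` (data.frame id/seq/class), `bna_mature`,
#'   `plant_mature` (named character vectors), and `families` (named
#'   character vector mapping precursor_id to family label).
#' @export
simulate_references <- function(config, truth) {
  set.seed(config$seed + 1L)
  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA", "mtRNA", "cpRNA")
  lens <- list(rRNA = c(500, 1500), tRNA = c(70, 90), snRNA = c(100, 200),
               snoRNA = c(60, 120), mtRNA = c(300, 800),
               cpRNA = c(300, 800))
  nc <- do.call(rbind, lapply(classes, function(cl) {
    k <- if (cl %in% c("rRNA", "mtRNA", "cpRNA")) 4L else 6L
    data.frame(
      id = sprintf("%s_%02d", tolower(cl), seq_len(k)),
      seq = vapply(seq_len(k), function(i)
        random_dna(sample(lens[[cl]][1]:lens[[cl]][2], 1), 0.5),
        character(1)),
      class = cl, stringsAsFactors = FALSE)
  }))

  fams <- sample(FAMILY_POOL, nrow(truth), replace = nrow(truth) >
                   length(FAMILY_POOL))
  names(fams) <- truth$precursor_id
  letters_idx <- stats::setNames(rep(1L, length(FAMILY_POOL)),
                                 as.character(FAMILY_POOL))
  bna <- character(0)
  plant <- character(0)
  for (i in seq_len(nrow(truth))) {
    fam <- as.character(fams[i])
    suffix <- letters[letters_idx[fam]]
    letters_idx[fam] <- letters_idx[fam] + 1L
    mat <- truth$mature5p[i]
    if (truth$category[i] == "known_bna") {
      bna[sprintf("bna-miR%s%s", fam, suffix)] <- mat
      plant[sprintf("bna-miR%s%s", fam, suffix)] <- mat
    } else if (truth$category[i] == "known_plant") {
      plant[sprintf("ath-miR%s%s", fam, suffix)] <- mat
    }
  }
  ## unrelated plant matures never expected to be seen in the libraries
  extra_fams <- sample(FAMILY_POOL, 10, replace = TRUE)
  for (f in seq_along(extra_fams)) {
    fam <- as.character(extra_fams[f])
    suffix <- letters[letters_idx[fam]]
    letters_idx[fam] <- letters_idx[fam] + 1L
    plant[sprintf("osa-miR%s%s", fam, suffix)] <- random_dna(21, 0.45)
  }
  list(ncrna = nc, bna_mature = bna, plant_mature = plant,
       families = stats::setNames(paste0("MIR", fams), names(fams)))
}

## draw an isomiR variant of a mature interval on its contig
isomir_variant <- function(contig, start0, end0) {
  side <- sample(c("start", "end"), 1)
  off <- sample(c(-2L, -1L, 1L, 2L), 1)
  s <- start0
  e <- end0
  if (side == "start") s <- s + off else e <- e + off
  s <- max(0L, s)
  e <- min(nchar(contig), e)
  substr(contig, s + 1L, e)
}

#' Simulate per-library FASTQ reads from a planted truth
#'
#' Each library's `total_reads` are allocated multinomially across planted
#' loci (probability proportional to `per_locus_abundance` times the
#' library's `fold_change`), ncRNA contaminants and siRNA-like background.
#' Locus reads are emitted as exact 5p matures, 3p star reads
#' (`star_rate`), or offset isomiRs (`isomir_rate`); every read carries the
#' full 3' adapter and constant Phred 30 qualities (a `low_quality_fraction`
#' is written at Phred 8 instead).
#'
#' @param truth truth table from [plant_precursors()].
#' @param contigs named contig sequences.
#' @param refs references from [simulate_references()].
#' @param config a [sim_config()].
#' @return list with `reads` (named list of read data.frames, one per
#'   library) and `expected` (data.frame of per-locus expected and realized
#'   mature-arm counts per library).
#' @export
simulate_reads <- function(truth, contigs, refs, config) {
  check_that(nrow(truth) > 0, "truth table is empty")
  check_that(length(config$libraries) > 0, "profiles non-empty")
  set.seed(config$seed + 2L)
  n_loci <- nrow(truth)

  reads_by_lib <- list()
  expected <- list()
  for (prof in config$libraries) {
    ab <- rep_len(prof$per_locus_abundance, n_loci)
    fc <- rep_len(prof$fold_change, n_loci)
    w <- ab * fc
    total <- prof$total_reads
    n_contam <- round(config$contaminant_fraction * total)
    n_sirna <- round(config$sirna_fraction * total)
    n_signal <- total - n_contam - n_sirna
    locus_counts <- as.integer(stats::rmultinom(1, n_signal, w / sum(w)))

    seqs <- character(0)
    origin <- character(0)
    for (i in seq_len(n_loci)) {
      ci <- locus_counts[i]
      if (ci == 0) next
      contig <- contigs[[truth$contig_id[i]]]
      kind <- sample(c("star", "isomir", "mature"), ci, replace = TRUE,
                     prob = c(config$star_rate,
                              (1 - config$star_rate) * config$isomir_rate,
                              (1 - config$star_rate) *
                                (1 - config$isomir_rate)))
      s <- character(ci)
      s[kind == "mature"] <- truth$mature5p[i]
      s[kind == "star"] <- truth$mature3p[i]
      n_iso <- sum(kind == "isomir")
      if (n_iso > 0) {
        s[kind == "isomir"] <- vapply(seq_len(n_iso), function(z)
          isomir_variant(contig, truth$mature5p_start[i],
                         truth$mature5p_end[i]), character(1))
      }
      seqs <- c(seqs, s)
      origin <- c(origin, paste0(truth$precursor_id[i], ":", kind))
    }
    if (n_contam > 0) {
      ref_idx <- sample.int(nrow(refs$ncrna), n_contam, replace = TRUE)
      clen <- sample(c(21L, 22L, 23L, 24L), n_contam, replace = TRUE,
                     prob = c(0.2, 0.1, 0.1, 0.6))
      cseq <- vapply(seq_len(n_contam), function(z) {
        rs <- refs$ncrna$seq[ref_idx[z]]
        start <- sample.int(nchar(rs) - clen[z] + 1L, 1)
        substr(rs, start, start + clen[z] - 1L)
      }, character(1))
      seqs <- c(seqs, cseq)
      origin <- c(origin, paste0("ncrna:", refs$ncrna$class[ref_idx]))
    }
    if (n_sirna > 0) {
      slen <- sample(c(21L, 24L), n_sirna, replace = TRUE,
                     prob = c(0.15, 0.85))
      seqs <- c(seqs, vapply(slen, random_dna, character(1),
                             gc = config$gc_target))
      origin <- c(origin, rep("sirna", n_sirna))
    }
    ord <- sample.int(length(seqs))
    seqs <- seqs[ord]
    origin <- origin[ord]
    full <- paste0(seqs, config$adapter3)
    q30 <- strrep("?", nchar(full))          # Phred 30
    q8 <- strrep(")", nchar(full))           # Phred 8
    low <- stats::runif(length(full)) < config$low_quality_fraction
    reads_by_lib[[prof$name]] <- data.frame(
      id = sprintf("%s_%07d %s", prof$name, seq_along(full), origin),
      seq = full,
      qual = ifelse(low, q8, q30),
      stringsAsFactors = FALSE)
    expected[[prof$name]] <- data.frame(
      precursor_id = truth$precursor_id,
      library = prof$name,
      expected_locus_reads = n_signal * w / sum(w),
      realized_locus_reads = locus_counts,
      fold_change = fc, stringsAsFactors = FALSE)
  }
  list(reads = reads_by_lib, expected = do.call(rbind, expected))
}

#' Generate a complete synthetic study
#'
#' One call producing contigs, truth, references and per-library reads
#' under a single seed.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `contigs`, `truth`, `refs`, `reads`,
#'   `expected`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  planted <- plant_precursors(config)
  refs <- simulate_references(config, planted$truth)
  sim <- simulate_reads(planted$truth, planted$contigs, refs, config)
  list(config = config, contigs = planted$contigs, truth = planted$truth,
       refs = refs, reads = sim$reads, expected = sim$expected)
}
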