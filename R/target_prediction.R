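## miRNA target prediction on transcript contigs with a complementarity
## expectation score: Watson-Crick pair 0, G:U wobble 0.5, mismatch 1,
## gap/bulge 2, penalties doubled over the core region (miRNA positions
## 2-13 from the 5' end); lower E is better, default cutoff E <= 4.

TARGET_PENALTY <- local({
  b <- c("A", "C", "G", "T")
  p <- matrix(1, 4, 4, dimnames = list(b, b))     # mismatch
  p["A", "T"] <- p["T", "A"] <- 0                 # Watson-Crick
  p["G", "C"] <- p["C", "G"] <- 0
  p["G", "T"] <- p["T", "G"] <- 0.5               # G:U wobble
  p
})

## core-region doubling of penalties at miRNA positions 2..13
core_weight <- function(m, core = c(2, 13)) {
  w <- rep(1, m)
  w[seq(min(core[1], m), min(core[2], m))] <- 2
  w
}

## penalty of miRNA base (5'->3' position i) against an aligned target
## base; sequences given as integer codes 1..4 over A,C,G,T
pair_penalty <- function(mir_code, targ_code) {
  TARGET_PENALTY[cbind(mir_code, targ_code)]
}

encode_dna <- function(x) {
  match(strsplit(normalize_dna(x), "")[[1]], c("A", "C", "G", "T"))
}

#' Score one miRNA/target-site duplex
#'
#' The site is the target subsequence, 5'->3', that the miRNA binds
#' antiparallel; its length may differ from the miRNA by at most one
#' (a single bulge on either side, penalty 2). The best placement of the
#' bulge is chosen.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param site target site sequence (5'->3').
#' @param e_core core region of doubled penalties, miRNA positions.
#' @return list with `e`, `mismatches`, `gu`, `gaps`, and `alignment`
#'   (character triple: miRNA 3'->5', pairing row, target 5'->3').
#' @export
score_duplex <- function(mirna, site, e_core = c(2, 13)) {
  mir <- encode_dna(mirna)
  tgt <- encode_dna(site)
  check_that(!anyNA(mir) && !anyNA(tgt),
             "non-nucleotide symbols in input")
  m <- length(mir)
  L <- length(tgt)
  check_that(abs(L - m) <= 1, "site length must be within miRNA +/- 1")
  w <- core_weight(m, e_core)
  rt <- rev(tgt)   # rt[j] aligns with miRNA position j
  best <- NULL
  if (L == m) {
    pen <- pair_penalty(mir, rt)
    best <- list(e = sum(pen * w), pen = pen, gap_at = NA_integer_,
                 gap_side = "none")
  } else if (L == m + 1) {
    ## one bulged (unpaired) target base
    for (g in seq_len(m + 1)) {
      idx <- c(seq_len(g - 1), if (g <= m) seq(g + 1, m + 1))
      pen <- pair_penalty(mir, rt[idx])
      gw <- w[min(g, m)]
      e <- sum(pen * w) + 2 * gw
      if (is.null(best) || e < best$e) {
        best <- list(e = e, pen = pen, gap_at = g, gap_side = "target")
      }
    }
  } else {
    ## one unpaired miRNA base (bulge in the miRNA)
    for (g in seq_len(m)) {
      keep <- setdiff(seq_len(m), g)
      pen <- pair_penalty(mir[keep], rt)
      e <- sum(pen * w[keep]) + 2 * w[g]
      if (is.null(best) || e < best$e) {
        best <- list(e = e, pen = pen, gap_at = g, gap_side = "mirna")
      }
    }
  }
  mism <- sum(best$pen == 1)
  gu <- sum(best$pen == 0.5)
  gaps <- as.integer(L != m)
  list(e = best$e, mismatches = mism, gu = gu, gaps = gaps,
       alignment = duplex_alignment(mirna, site, best))
}

## render the duplex: miRNA 3'->5' over the site 5'->3'
duplex_alignment <- function(mirna, site, best) {
  mir <- strsplit(chartr("T", "U", normalize_dna(mirna)), "")[[1]]
  tgt <- strsplit(chartr("T", "U", normalize_dna(site)), "")[[1]]
  m <- length(mir)
  rt <- rev(tgt)
  if (best$gap_side == "none") {
    top <- mir
    bot <- rt
  } else if (best$gap_side == "target") {
    top <- append(mir, "-", after = best$gap_at - 1)
    bot <- rt
  } else {
    top <- mir
    bot <- append(rt, "-", after = best$gap_at - 1)
  }
  sym <- vapply(seq_along(top), function(i) {
    a <- top[i]
    b <- bot[i]
    if (a == "-" || b == "-") return(" ")
    key <- paste0(chartr("U", "T", a), chartr("U", "T", b))
    p <- TARGET_PENALTY[chartr("U", "T", a), chartr("U", "T", b)]
    if (p == 0) "|" else if (p == 0.5) "o" else " "
  }, character(1))
  c(paste(rev(top), collapse = ""),
    paste(rev(sym), collapse = ""),
    paste(rev(bot), collapse = ""))
}

## Vectorised scan of all windows of length L on a coded strand sequence;
## returns the best achievable E per window start (minimised over the
## single bulge position when L differs from the miRNA length by one).
## miRNA position j (5'->3') pairs the j-th base of the reversed window.
scan_len <- function(mir, codes, w, L) {
  n <- length(codes)
  m <- length(mir)
  if (n < L) return(numeric(0))
  nwin <- n - L + 1
  p <- seq_len(nwin)
  pen <- function(j, idx) w[j] * TARGET_PENALTY[cbind(mir[j], codes[idx])]
  if (L == m) {
    e <- numeric(nwin)
    for (j in seq_len(m)) e <- e + pen(j, p + L - j)
    return(e)
  }
  if (L == m + 1) {
    ## bulged target base at reversed-window position g
    B <- lapply(seq_len(m), function(j) pen(j, p + L - j - 1))
    suffix <- vector("list", m + 2)
    suffix[[m + 1]] <- numeric(nwin)
    for (g in rev(seq_len(m))) suffix[[g]] <- B[[g]] + suffix[[g + 1]]
    best <- rep(Inf, nwin)
    prefA <- numeric(nwin)
    for (g in seq_len(m + 1)) {
      best <- pmin(best, prefA + suffix[[g]] + 2 * w[min(g, m)])
      if (g <= m) prefA <- prefA + pen(g, p + L - g)
    }
    return(best)
  }
  if (L == m - 1) {
    ## unpaired miRNA base g
    B <- lapply(seq_len(m), function(j)
      if (j >= 2) pen(j, p + L - j + 1) else numeric(nwin))
    suffix <- vector("list", m + 2)
    suffix[[m + 1]] <- numeric(nwin)
    for (g in rev(seq_len(m))) suffix[[g]] <- B[[g]] + suffix[[g + 1]]
    best <- rep(Inf, nwin)
    prefA <- numeric(nwin)
    for (g in seq_len(m)) {
      best <- pmin(best, prefA + suffix[[g + 1]] + 2 * w[g])
      if (g <= m - 1) prefA <- prefA + pen(g, p + L - g)
    }
    return(best)
  }
  stop("window length must be within one of the miRNA length")
}

#' Scan contigs for miRNA target sites
#'
#' Every window on either contig strand with length within one of the
#' miRNA (at most one bulge) is scored; hits with E <= `e_max` are
#' returned sorted by E then coordinate. With `dedupe = TRUE` (default)
#' overlapping hits of the same miRNA on the same contig strand are
#' reduced to the best-scoring site.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param contigs named character vector of contigs.
#' @param e_max expectation cutoff.
#' @param dedupe collapse overlapping windows to the best site.
#' @param e_core core region of doubled penalties.
#' @return data.frame: mirna_id, mirna_seq, contig_id, start, end
#'   (0-based half-open, plus strand), strand, e, mismatches, gu, gaps.
#' @export
scan_targets <- function(mirnas, contigs, e_max = 4, dedupe = TRUE,
                         e_core = c(2, 13)) {
  check_that(length(contigs) > 0, "contigs non-empty")
  out <- list()
  for (mi in seq_along(mirnas)) {
    mir <- encode_dna(mirnas[[mi]])
    m <- length(mir)
    w <- core_weight(m, e_core)
    for (ci in seq_along(contigs)) {
      cseq <- normalize_dna(contigs[[ci]])
      n <- nchar(cseq)
      for (strand in c("+", "-")) {
        s <- if (strand == "+") cseq else revcomp(cseq)
        codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
        hits_here <- list()
        for (L in c(m, m - 1L, m + 1L)) {
          ev <- scan_len(mir, codes, w, L)
          for (p in which(ev <= e_max)) {
            ## full per-site annotation only for passing windows
            sc <- score_duplex(mirnas[[mi]], substr(s, p, p + L - 1),
                               e_core)
            st <- if (strand == "+") p - 1L else n - (p - 1L) - L
            hits_here[[length(hits_here) + 1]] <- data.frame(
              mirna_id = names(mirnas)[mi], mirna_seq = mirnas[[mi]],
              contig_id = names(contigs)[ci],
              start = st, end = st + L, strand = strand,
              e = sc$e, mismatches = sc$mismatches, gu = sc$gu,
              gaps = sc$gaps, stringsAsFactors = FALSE)
          }
        }
        out <- c(out, hits_here)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), mirna_seq = character(0),
                      contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      e = numeric(0), mismatches = integer(0),
                      gu = integer(0), gaps = integer(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$e, hits$contig_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  if (dedupe) hits <- dedupe_hits(hits)
  hits
}

## greedy reduction: accept hits in (E, gaps, coordinate) order, dropping
## any later hit overlapping an accepted one for the same miRNA on the
## same contig strand
dedupe_hits <- function(hits) {
  hits <- hits[order(hits$e, hits$gaps, hits$contig_id, hits$start), ,
               drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    prior <- which(keep &
                     hits$mirna_id == hits$mirna_id[i] &
                     hits$contig_id == hits$contig_id[i] &
                     hits$strand == hits$strand[i])
    overlap <- any(hits$start[prior] < hits$end[i] &
                     hits$end[prior] > hits$start[i])
    keep[i] <- !overlap
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$e, hits$contig_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-miRNA target counts
#'
#' @param hits data.frame from [scan_targets()].
#' @return data.frame with `mirna_id`, `n_targets` (distinct contigs) and
#'   `n_sites`.
#' @export
target_summary <- function(hits) {
  ids <- unique(hits$mirna_id)
  data.frame(
    mirna_id = ids,
    n_targets = vapply(ids, function(i)
      length(unique(hits$contig_id[hits$mirna_id == i])), integer(1)),
    n_sites = vapply(ids, function(i) sum(hits$mirna_id == i),
                     integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
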