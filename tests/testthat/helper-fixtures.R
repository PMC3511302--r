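# Shared fixtures (built in code, memoised per session) and independent
# oracles used across test files.

small_sim_config <- function(seed = 5, ...) {
  sim_config(
    seed = seed,
    n_precursors = 6, n_decoy_contigs = 6,
    libraries = list(
      library_profile("A", 8000),
      library_profile("B", 8000, fold_change = rep(c(8, 1), c(2, 4)))),
    ...)
}

.fixture_env <- new.env(parent = emptyenv())

memoised <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, expr, .fixture_env)
  get(key, .fixture_env)
}

small_dataset <- function() {
  memoised("small_dataset", simulate_dataset(small_sim_config()))
}

# preprocessed + collapsed + annotated small dataset
small_annotated <- function() {
  memoised("small_annotated", {
    ds <- small_dataset()
    pp <- lapply(ds$reads, function(r)
      preprocess_library(r, adapter3 = ds$config$adapter3))
    tags <- collapse_tags(lapply(pp, `[[`, "reads"))
    ann <- annotate_tags(tags, ds$refs)
    list(ds = ds, pp = pp, tags = tags, ann = ann)
  })
}

small_discovery <- function() {
  memoised("small_discovery", {
    sa <- small_annotated()
    disc <- discover_precursors(sa$ann$tags, sa$ds$contigs,
                                sa$ds$refs$bna_mature,
                                sa$ds$refs$plant_mature)
    c(sa, list(disc = disc))
  })
}

# make a read table with constant quality
make_reads <- function(seqs, phred = 30, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(id = ids, seq = seqs,
             qual = vapply(nchar(seqs), function(n)
               intToUtf8(rep(phred + 33L, n)), character(1)),
             stringsAsFactors = FALSE)
}

# ---- independent target-scoring oracle --------------------------------
# Naive re-derivation of the expectation score: explicit base-by-base
# loops, no shared code with the package's vectorised scanner.

.ORACLE_WC <- list(A = "T", C = "G", G = "C", T = "A")

oracle_pair_pen <- function(mir_b, targ_b) {
  if (.ORACLE_WC[[mir_b]] == targ_b) return(0)
  if ((mir_b == "G" && targ_b == "T") ||
      (mir_b == "T" && targ_b == "G")) return(0.5)
  1
}

# score one alignment of miRNA (5'->3') vs target site (5'->3'),
# minimising over a single bulge placement; core positions 2..13 doubled
oracle_duplex_e <- function(mirna, site) {
  mir <- strsplit(toupper(mirna), "")[[1]]
  tgt <- rev(strsplit(toupper(site), "")[[1]])
  m <- length(mir)
  L <- length(tgt)
  wt <- function(j) if (j >= 2 && j <= 13) 2 else 1
  if (L == m) {
    e <- 0
    for (j in seq_len(m)) e <- e + wt(j) * oracle_pair_pen(mir[j], tgt[j])
    return(e)
  }
  best <- Inf
  if (L == m + 1) {
    for (g in seq_len(m + 1)) {
      e <- 2 * wt(min(g, m))
      for (j in seq_len(m)) {
        tj <- if (j < g) j else j + 1
        e <- e + wt(j) * oracle_pair_pen(mir[j], tgt[tj])
      }
      best <- min(best, e)
    }
  } else if (L == m - 1) {
    for (g in seq_len(m)) {
      e <- 2 * wt(g)
      for (j in seq_len(m)) {
        if (j == g) next
        tj <- if (j < g) j else j - 1
        e <- e + wt(j) * oracle_pair_pen(mir[j], tgt[tj])
      }
      best <- min(best, e)
    }
  } else {
    stop("bad site length")
  }
  best
}

oracle_revcomp <- function(x) {
  paste(rev(vapply(strsplit(toupper(x), "")[[1]],
                   function(b) .ORACLE_WC[[b]], character(1))),
        collapse = "")
}

# exhaustive all-window scan on both strands; returns plus-strand
# half-open coordinates like scan_targets
oracle_scan <- function(mirna, contig, e_max) {
  m <- nchar(mirna)
  n <- nchar(contig)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(contig) else oracle_revcomp(contig)
    for (L in c(m - 1, m, m + 1)) {
      if (n < L) next
      for (p in seq_len(n - L + 1)) {
        e <- oracle_duplex_e(mirna, substr(s, p, p + L - 1))
        if (e <= e_max) {
          st <- if (strand == "+") p - 1 else n - (p - 1) - L
          rows[[length(rows) + 1]] <-
            data.frame(start = st, end = st + L, strand = strand, e = e)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), e = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$e, out$start, out$strand), ]
}
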