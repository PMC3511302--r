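## Per-miRNA abundance and two-library differential expression.
##
## Counts are TMM-normalised (trimmed mean of M-values) and each locus is
## tested with two independent statistics: a negative-binomial exact test
## conditioning on the pairwise total, and the Audic-Claverie test for
## digital counts. A locus is called differentially abundant only when
## both p-values fall at or below alpha (default 0.001).

#' Count per-locus miRNA abundance
#'
#' A tag contributes its full per-library count to every mature locus on
#' whose precursor it maps exactly within `isomir_window` nt of the mature
#' interval. Per-family aggregates count every distinct tag once.
#'
#' @param tags tag data.frame with `count_*` columns.
#' @param loci locus data.frame (from [discover_precursors()] or built by
#'   hand) with `precursor_id`, `arm`, `contig_id`, `start`, `end`,
#'   `strand` and optionally `family`.
#' @param contigs named contig sequences.
#' @param isomir_window nt of slack around the mature interval.
#' @return list with `counts` (matrix, loci x libraries) and `families`
#'   (matrix of per-family counts, each tag counted once per family) --
#'   `families` is NULL when `loci` has no family column.
#' @export
count_abundance <- function(tags, loci, contigs, isomir_window = 3) {
  count_cols <- grep("^count_", names(tags), value = TRUE)
  libs <- sub("^count_", "", count_cols)
  hits <- map_tags(tags, contigs)
  ids <- paste0(loci$precursor_id, "-",
                ifelse(is.na(loci$arm), "m", loci$arm))
  counts <- matrix(0, nrow = nrow(loci), ncol = length(libs),
                   dimnames = list(ids, libs))
  tag_sets <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    h <- hits[hits$contig_id == loci$contig_id[i] &
                hits$strand == loci$strand[i] &
                hits$start >= loci$start[i] - isomir_window &
                hits$end <= loci$end[i] + isomir_window, , drop = FALSE]
    if (nrow(h) == 0) next
    tseq <- unique(h$sequence)
    tag_sets[[i]] <- tseq
    ti <- match(tseq, tags$sequence)
    for (k in seq_along(libs)) {
      counts[i, k] <- sum(tags[[count_cols[k]]][ti])
    }
  }
  families <- NULL
  if ("family" %in% names(loci)) {
    fams <- unique(loci$family)
    families <- matrix(0, nrow = length(fams), ncol = length(libs),
                       dimnames = list(fams, libs))
    for (f in seq_along(fams)) {
      tseq <- unique(unlist(tag_sets[loci$family == fams[f]]))
      ti <- match(tseq, tags$sequence)
      for (k in seq_along(libs)) {
        families[f, k] <- sum(tags[[count_cols[k]]][ti])
      }
    }
  }
  list(counts = counts, families = families)
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalisation: per library, the weighted mean
#' of per-locus log2 ratios against a reference library (after library
#' size division), doubly trimmed on M (log-ratio) and A (absolute
#' intensity); weights are inverse asymptotic binomial variances. Rows
#' containing zeros are excluded. Factors are rescaled so their geometric
#' mean is 1. The reference library is the one whose upper-quartile
#' size-scaled count is closest to the mean upper quartile.
#'
#' @param counts matrix, loci x libraries.
#' @param lib_sizes library sizes; defaults to column sums.
#' @param trim_M log-ratio trim fraction per side.
#' @param trim_A intensity trim fraction per side.
#' @return named numeric vector of scaling factors.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        trim_M = 0.30, trim_A = 0.05) {
  check_that(ncol(counts) >= 2, "need >= 2 libraries")
  check_that(all(lib_sizes > 0), "all-zero library")
  nlib <- ncol(counts)
  uq <- apply(counts, 2, function(x) {
    x <- x[x > 0]
    if (length(x) == 0) return(0)
    stats::quantile(x, 0.75)
  }) / lib_sizes
  ref <- which.min(abs(uq - mean(uq)))

  f <- numeric(nlib)
  for (k in seq_len(nlib)) {
    if (k == ref) {
      f[k] <- 1
      next
    }
    x <- counts[, k]
    r <- counts[, ref]
    keep <- x > 0 & r > 0
    x <- x[keep]
    r <- r[keep]
    if (length(x) == 0) {
      f[k] <- 1
      next
    }
    px <- x / lib_sizes[k]
    pr <- r / lib_sizes[ref]
    M <- log2(px / pr)
    A <- 0.5 * log2(px * pr)
    w <- 1 / ((lib_sizes[k] - x) / (lib_sizes[k] * x) +
                (lib_sizes[ref] - r) / (lib_sizes[ref] * r))
    keepM <- rank(M, ties.method = "first") > floor(length(M) * trim_M) &
      rank(-M, ties.method = "first") > floor(length(M) * trim_M)
    keepA <- rank(A, ties.method = "first") > floor(length(A) * trim_A) &
      rank(-A, ties.method = "first") > floor(length(A) * trim_A)
    sel <- keepM & keepA
    f[k] <- if (any(sel)) 2^(sum(w[sel] * M[sel]) / sum(w[sel])) else 1
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Audic-Claverie posterior probability
#'
#' p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)), the
#' probability of observing `y` counts in a library of size N2 given `x`
#' counts in a library of size N1 under equal underlying abundance.
#' Computed in log space.
#'
#' @param x,y observed counts.
#' @param N1,N2 library sizes.
#' @return numeric probability (vectorised over `y`).
#' @export
ac_probability <- function(x, y, N1, N2) {
  check_that(all(c(x, y) >= 0), "counts must be non-negative")
  check_that(N1 > 0 && N2 > 0, "library sizes must be positive")
  r <- N2 / N1
  exp(y * log(r) + lchoose(x + y, y) - (x + y + 1) * log1p(r))
}

#' Audic-Claverie test
#'
#' One-sided p is the smaller tail sum of p(y' | x) over y' >= y or
#' y' <= y; the two-sided p doubles the smaller tail (capped at 1). The
#' pair is internally put in a canonical orientation (the smaller library
#' conditions the tail) so the result does not depend on which library is
#' passed first.
#'
#' @param x,y observed counts in the two libraries.
#' @param N1,N2 library sizes.
#' @return list with `p_one_sided`, `p_two_sided`.
#' @export
ac_test <- function(x, y, N1, N2) {
  check_that(x >= 0 && y >= 0, "counts must be non-negative")
  if (N2 < N1 || (N2 == N1 && y < x)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- N1; N1 <- N2; N2 <- tmp
  }
  lower <- sum(ac_probability(x, 0:y, N1, N2))
  upper <- 1 - sum(ac_probability(x, seq_len(y) - 1, N1, N2))
  ## guard against cancellation: both tails include y itself
  upper <- max(upper, ac_probability(x, y, N1, N2))
  one <- min(lower, upper, 1)
  list(p_one_sided = one, p_two_sided = min(1, 2 * one))
}

#' Negative-binomial exact test for two libraries
#'
#' Conditions on the pairwise total s = x + y: under the null the split
#' follows the conditional distribution of two independent NB variables
#' with means proportional to the effective library sizes and common
#' dispersion; the p-value sums the probabilities of all splits at most
#' as likely as the observed one. At dispersion 0 this is the exact
#' binomial test with success probability N1 / (N1 + N2).
#'
#' @param x,y observed counts (after any TMM scaling of library sizes).
#' @param N1,N2 effective library sizes.
#' @param dispersion NB dispersion (squared BCV); 0 gives the
#'   Poisson/binomial limit.
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(x, y, N1, N2, dispersion = 0) {
  check_that(x >= 0 && y >= 0, "counts must be non-negative")
  check_that(dispersion >= 0, "dispersion must be >= 0")
  s <- x + y
  if (s == 0) return(1)
  k <- 0:s
  p1 <- N1 / (N1 + N2)
  if (dispersion == 0) {
    logp <- stats::dbinom(k, s, p1, log = TRUE)
  } else {
    size <- 1 / dispersion
    mu1 <- s * p1
    mu2 <- s * (1 - p1)
    logp <- stats::dnbinom(k, size = size, mu = mu1, log = TRUE) +
      stats::dnbinom(s - k, size = size, mu = mu2, log = TRUE)
    logp <- logp - logsumexp(logp)
  }
  obs <- logp[x + 1]
  min(1, sum(exp(logp[logp <= obs + 1e-10])))
}

## numerically stable log-sum-exp
logsumexp <- function(lx) {
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

#' Differential abundance across two libraries
#'
#' Runs TMM normalisation, both tests per locus and the dual-test rule:
#' a locus is differentially abundant iff both p-values are <= alpha.
#' Fold change is the ratio of TMM-scaled counts-per-million with a
#' pseudocount of 1; `highlight` flags fold changes beyond `min_fold` in
#' either direction.
#'
#' @param counts matrix with exactly two library columns.
#' @param lib_sizes total library sizes (defaults to column sums).
#' @param dispersion NB dispersion for the exact test.
#' @param alpha significance threshold applied to both tests.
#' @param min_fold highlight threshold on fold change.
#' @return data.frame: id, counts, cpm, fold_change (library 2 over
#'   library 1), p_exact, p_ac, is_de, highlight.
#' @export
call_de <- function(counts, lib_sizes = colSums(counts), dispersion = 0.1,
                    alpha = 0.001, min_fold = 2.0) {
  check_that(ncol(counts) == 2, "call_de expects two libraries")
  f <- tmm_factors(counts, lib_sizes)
  eff <- lib_sizes * f
  cpm <- sweep(counts, 2, eff / 1e6, "/")
  x <- counts[, 1]
  y <- counts[, 2]
  p_ac <- vapply(seq_along(x), function(i)
    ac_test(x[i], y[i], eff[1], eff[2])$p_two_sided, numeric(1))
  p_exact <- vapply(seq_along(x), function(i)
    nb_exact_test(x[i], y[i], eff[1], eff[2], dispersion), numeric(1))
  fold <- (cpm[, 2] + 1) / (cpm[, 1] + 1)
  data.frame(id = rownames(counts),
             count_1 = x, count_2 = y,
             cpm_1 = cpm[, 1], cpm_2 = cpm[, 2],
             norm_factor_1 = f[1], norm_factor_2 = f[2],
             fold_change = fold,
             p_exact = p_exact, p_ac = p_ac,
             is_de = p_exact <= alpha & p_ac <= alpha,
             highlight = fold > min_fold | fold < 1 / min_fold,
             stringsAsFactors = FALSE, row.names = NULL)
}
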