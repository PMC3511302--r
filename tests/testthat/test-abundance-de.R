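test_that("abundance counting credits tags within the isomiR window", {
  ctg <- paste0(strrep("C", 60), "TGACAGAAGAGAGTGAGCACA", strrep("A", 60))
  loci <- data.frame(precursor_id = "p1", arm = "5p", contig_id = "c1",
                     start = 60L, end = 81L, strand = "+",
                     family = "MIRX", stringsAsFactors = FALSE)
  tags <- data.frame(
    sequence = c("TGACAGAAGAGAGTGAGCACA",       # exact
                 "GACAGAAGAGAGTGAGCACAA",       # +1 shifted
                 strrep("C", 21)),              # elsewhere
    count_A = c(50L, 5L, 99L), count_B = c(10L, 1L, 99L),
    total = c(60L, 6L, 198L), class = "unassigned",
    stringsAsFactors = FALSE)
  ca <- count_abundance(tags, loci, c(c1 = ctg))
  expect_identical(ca$counts["p1-5p", "A"], 55)
  expect_identical(ca$counts["p1-5p", "B"], 11)
  # family aggregate counts a shared tag once
  loci2 <- rbind(loci, transform(loci, precursor_id = "p2"))
  ca2 <- count_abundance(tags, loci2, c(c1 = ctg))
  expect_identical(unname(ca2$counts[, "A"]), c(55, 55))
  expect_identical(ca2$families["MIRX", "A"], 55)
  # no tags -> zero matrix
  z <- count_abundance(tags[0, ], loci, c(c1 = ctg))
  expect_true(all(z$counts == 0))
})

test_that("TMM factors behave under identity, scaling and outliers", {
  set.seed(7)
  base <- rpois(1000, 100)
  m <- cbind(A = base, B = base)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  # doubling a whole library is absorbed by library-size division
  m2 <- cbind(A = base, B = 2L * base)
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-8)
  # a single extreme outlier row is trimmed away (equal library sizes,
  # so the factors reduce to the trimmed mean of raw log ratios)
  m3 <- cbind(A = c(base, 10L), B = c(base, 100000L))
  ls <- c(A = 2e5, B = 2e5)
  f3 <- tmm_factors(m3, lib_sizes = ls)
  expect_lt(abs(f3[["B"]] / f3[["A"]] - 1), 0.01)
  # brute-force doubly-trimmed weighted mean oracle
  keep <- m3[, 1] > 0 & m3[, 2] > 0
  px <- m3[keep, 2] / ls[2]
  pr <- m3[keep, 1] / ls[1]
  M <- log2(px / pr)
  A <- 0.5 * log2(px * pr)
  qM <- quantile(M, c(0.3, 0.7), type = 1)
  qA <- quantile(A, c(0.05, 0.95), type = 1)
  sel <- M >= qM[1] & M <= qM[2] & A >= qA[1] & A <= qA[2]
  w <- 1 / ((ls[2] - m3[keep, 2]) / (ls[2] * m3[keep, 2]) +
              (ls[1] - m3[keep, 1]) / (ls[1] * m3[keep, 1]))
  oracle <- 2^(sum((w * M)[sel]) / sum(w[sel]))
  expect_lt(abs(log2(f3[["B"]] / f3[["A"]]) - log2(oracle)), 0.05)
  expect_error(tmm_factors(cbind(A = 0L, B = 5L),
                           lib_sizes = c(0, 5)), "all-zero")
})

test_that("TMM agrees with the reference implementation on random counts", {
  set.seed(11)
  m <- cbind(A = rpois(2000, exp(rnorm(2000, 4, 1))),
             B = rpois(2000, exp(rnorm(2000, 4.5, 1))))
  ours <- tmm_factors(m)
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("the Audic-Claverie statistic matches closed forms and sums to 1", {
  expect_identical(ac_probability(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_probability(5, 0, 1e6, 1e6), 2^-6)
  # probabilities over the support sum to 1
  for (x in c(0, 3, 25)) {
    s <- sum(ac_probability(x, 0:5000, 2e6, 1e6))
    expect_lt(abs(s - 1), 1e-9)
  }
  # tail matches the negative-binomial identity p(y|x) = NB(x+1, N1/(N1+N2))
  for (cse in list(c(4, 9, 1e6, 1e6), c(12, 3, 2e6, 5e5))) {
    x <- cse[1]; y <- cse[2]; n1 <- cse[3]; n2 <- cse[4]
    lower <- sum(ac_probability(x, 0:y, n1, n2))
    expect_equal(lower, pnbinom(y, size = x + 1, prob = n1 / (n1 + n2)),
                 tolerance = 1e-12)
  }
  # the verdict does not depend on which library is passed first
  p1 <- ac_test(7, 19, 1e6, 3e6)$p_one_sided
  p2 <- ac_test(19, 7, 3e6, 1e6)$p_one_sided
  expect_equal(p1, p2, tolerance = 1e-12)
  p3 <- ac_test(4, 21, 2e6, 2e6)$p_one_sided
  expect_equal(p3, ac_test(21, 4, 2e6, 2e6)$p_one_sided,
               tolerance = 1e-12)
  expect_error(ac_test(-1, 2, 10, 10), "non-negative")
})

test_that("the NB exact test reduces to the exact binomial at dispersion 0", {
  expect_equal(nb_exact_test(8, 2, 1e6, 1e6, dispersion = 0), 0.109375)
  for (s in c(1, 7, 23, 50)) {
    for (x in 0:s) {
      expect_equal(nb_exact_test(x, s - x, 1e6, 1e6, 0),
                   binom.test(x, s, 0.5)$p.value, tolerance = 1e-12)
    }
  }
  # unequal library sizes shift the null split
  expect_equal(nb_exact_test(10, 2, 3e6, 1e6, 0),
               binom.test(10, 12, 0.75)$p.value, tolerance = 1e-12)
  # balanced split is the mode
  expect_identical(nb_exact_test(5, 5, 1e6, 1e6, 0.2), 1)
  # p decreases monotonically in |x - y| at fixed total
  p <- vapply(5:10, function(x) nb_exact_test(x, 10 - x, 1e6, 1e6, 0),
              numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("NB exact test with dispersion agrees with the reference implementation", {
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(1, 200)
    y <- rpois(1, 600)
    phi <- runif(1, 0.01, 0.4)
    ours <- nb_exact_test(x, y, 1e6, 1e6, phi)
    ref <- edgeR::exactTestBySmallP(matrix(x, 1), matrix(y, 1),
                                    dispersion = phi)
    expect_equal(ours, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("DE calling applies the dual-test rule at the inclusive boundary", {
  res <- data.frame(p_exact = c(5e-4, 5e-4, 1e-3, 2e-3),
                    p_ac = c(9e-4, 2e-3, 1e-3, 1e-4))
  is_de <- res$p_exact <= 0.001 & res$p_ac <= 0.001
  expect_identical(is_de, c(TRUE, FALSE, TRUE, FALSE))
  # through call_de: a strong planted change is called, a null one is not
  set.seed(5)
  counts <- cbind(A = c(rpois(200, 100), 200),
                  B = c(rpois(200, 100), 1600))
  rownames(counts) <- c(sprintf("null%03d", 1:200), "planted")
  de <- call_de(counts, dispersion = 0)
  expect_true(de$is_de[de$id == "planted"])
  expect_true(de$highlight[de$id == "planted"])
  expect_gt(de$fold_change[de$id == "planted"], 2)
  # scale invariance: x10 on counts and sizes leaves fold change alone
  de10 <- call_de(counts * 10L, dispersion = 0)
  expect_equal(de10$fold_change, de$fold_change, tolerance = 1e-6)
})
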