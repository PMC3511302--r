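test_that("quality filter drops reads below the mean-Phred threshold", {
  reads <- rbind(make_reads("ACGTACGTACGTACGTACGTA", phred = 30),
                 make_reads("ACGTACGTACGTACGTACGTA", phred = 2),
                 make_reads("TTTTACGTACGTACGTACGTA", phred = 12),
                 make_reads("GGGGACGTACGTACGTACGTA", phred = 13))
  kept <- quality_filter(reads, qmin = 13)
  expect_identical(nrow(kept), 2L)
  # counting oracle on a mixed library: k low + m high -> m survivors
  k <- 7L; m <- 11L
  lib <- rbind(make_reads(rep("ACGTACGTACGTACGTAC", m), phred = 30),
               make_reads(rep("ACGTACGTACGTACGTAC", k), phred = 5))
  expect_identical(nrow(quality_filter(lib)), m)
  # min-base rule is stricter
  mixed <- make_reads("ACGTACGT", phred = 30)
  mixed$qual <- paste0(substr(mixed$qual, 1, 7), "+")  # one base at Phred 10
  expect_identical(nrow(quality_filter(mixed, rule = "mean")), 1L)
  expect_identical(nrow(quality_filter(mixed, rule = "min")), 0L)
})

test_that("adapter trimming removes the longest exact 3' overlap", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "TACGATCGATCGATCGATCGA"
  full <- make_reads(paste0(insert, adapter))
  expect_identical(trim_adapters(full, adapter)$seq, insert)
  # partial adapter at the read end
  part <- make_reads(paste0(insert, substr(adapter, 1, 10)))
  expect_identical(trim_adapters(part, adapter)$seq, insert)
  # overlap below min_overlap stays; brute-force suffix check agrees
  seven <- make_reads(paste0(insert, substr(adapter, 1, 7)))
  expect_identical(trim_adapters(seven, adapter)$seq, seven$seq)
  suffix_hits <- vapply(8:nchar(seven$seq), function(k)
    substr(seven$seq, nchar(seven$seq) - k + 1, nchar(seven$seq)) ==
      substr(adapter, 1, k), logical(1))
  expect_false(any(suffix_hits))
  # read without any adapter is untouched; qualities track the sequence
  none <- make_reads("ACGTACGTACGTACGTACGTACG")
  out <- trim_adapters(none, adapter)
  expect_identical(out$seq, none$seq)
  tr <- trim_adapters(full, adapter)
  expect_identical(nchar(tr$qual), nchar(tr$seq))
  # 5' adapter trimming is symmetric
  five <- make_reads(paste0("GTTCAGAGTT", insert))
  out5 <- trim_adapters(five, adapter, adapter5 = "ACACGTTCAGAGTT")
  expect_identical(out5$seq, insert)
})

test_that("ambiguous-base and length filters partition correctly", {
  reads <- make_reads(c("ACGNACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT",
                        "acgtnacgtacgtacgtacg"))
  expect_identical(nrow(drop_ambiguous(reads)), 1L)
  j <- 5L
  lib <- rbind(make_reads(rep("ACGTNCGT", j)),
               make_reads(rep("ACGTACGT", 3)))
  expect_identical(nrow(lib) - nrow(drop_ambiguous(lib)), j)

  lens <- c(17, 18, 25, 26)
  reads <- make_reads(vapply(lens, function(n)
    paste(rep("A", n), collapse = ""), character(1)))
  lf <- length_filter(reads)
  expect_identical(sort(nchar(lf$reads$seq)), c(18L, 25L))
  expect_identical(lf$summary$reads,
                   c(4L, 2L, 1L, 1L))
  empty <- length_filter(make_reads(character(0)))
  expect_identical(nrow(empty$reads), 0L)
  expect_true(all(empty$summary$reads == 0))
})

test_that("the cleaning cascade partitions every input read", {
  cfg <- small_sim_config(seed = 31, low_quality_fraction = 0.05)
  ds <- simulate_dataset(cfg)
  for (lib in names(ds$reads)) {
    pp <- preprocess_library(ds$reads[[lib]], cfg$adapter3)
    acc <- pp$accounting
    expect_identical(acc[["input"]],
                     acc[["quality_removed"]] + acc[["n_removed"]] +
                       acc[["short"]] + acc[["long"]] + acc[["retained"]])
    # idempotence: rerunning the cascade on its output changes nothing
    again <- preprocess_library(pp$reads, cfg$adapter3)
    expect_identical(again$reads$seq, pp$reads$seq)
    expect_identical(again$accounting[["retained"]], acc[["retained"]])
  }
})

test_that("tag collapsing conserves counts and matches a sort-unique oracle", {
  a <- make_reads(c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                    "ACGTACGTACGTACGTAC", "TTTTACGTACGTACGTAC"))
  b <- make_reads(c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC"))
  tags <- collapse_tags(list(A = a, B = b))
  one <- tags[tags$sequence == "ACGTACGTACGTACGTAC", ]
  expect_identical(one$count_A, 3L)
  expect_identical(one$count_B, 2L)
  # U is normalised to T
  u <- make_reads("ACGUACGUACGUACGUAC")
  expect_identical(collapse_tags(list(A = u))$sequence,
                   "ACGTACGTACGTACGTAC")

  sa <- small_annotated()
  for (lib in names(sa$pp)) {
    col <- paste0("count_", lib)
    expect_identical(sum(sa$tags[[col]]),
                     as.integer(sa$pp[[lib]]$accounting[["retained"]]))
    # distinct-tag oracle: sort-unique over the cleaned reads
    expect_identical(sum(sa$tags[[col]] > 0),
                     length(unique(sa$pp[[lib]]$reads$seq)))
  }
  # collapse/expand round-trip preserves per-library multisets
  expanded <- rep(sa$tags$sequence, sa$tags$count_A)
  expect_identical(sort(expanded), sort(sa$pp$A$reads$seq))
})

test_that("length distribution recovers the bimodal 21/24 profile", {
  tags <- data.frame(sequence = c("AAAAAAAAAAAAAAAAAAAAA"),
                     count_A = 5L, total = 5L, class = "unassigned",
                     stringsAsFactors = FALSE)
  ld <- length_distribution(tags)
  expect_identical(ld$total_reads[ld$length == 21], 5)
  expect_identical(ld$distinct_tags[ld$length == 21], 1L)
  expect_true(all(length_distribution(tags[0, ])$total_reads == 0))

  sa <- small_annotated()
  ld <- length_distribution(sa$tags)
  top2 <- ld$length[order(-ld$total_reads)][1:2]
  expect_setequal(top2, c(21, 24))
})
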