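---
title: "seedmir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedmir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Plant seeds remodel their small-RNA population as they mature, and miRNAs
are central post-transcriptional regulators of embryogenesis and storage
metabolism. For crops without a finished genome, the miRNA repertoire has
to be characterised directly from sequencing data: small-RNA libraries
supply the 18–25 nt tags, and assembled mRNA-seq contigs stand in for the
genome as the substrate on which precursor hairpins and target sites are
sought. `seedmir` implements that workflow end to end — read cleaning, tag
classification, conserved-miRNA identification, novel pre-miRNA discovery,
isomiR cataloguing, two-library differential abundance, and target
prediction — together with a seeded synthetic-data generator so every stage
can be validated offline against a planted ground truth.

## Preprocessing model

Reads pass a fixed cascade: mean-Phred quality filter (default threshold
13), exact 3′-adapter trimming (longest read suffix matching an adapter
prefix, minimum overlap 8 nt), removal of reads containing N, and an
18–25 nt length window. The cascade partitions every input read into
exactly one of five bins (quality-removed, N-removed, too short, too long,
retained), which the tests assert as a conservation law. Two deliberate
interpretations:

* The quality rule is *mean* Phred < 13 over the read; a `rule = "min"`
  switch applies the stricter any-base rule instead. Vendor pipelines do
  not document their exact rule, so both are provided.
* Adapter matching is exact. Small-RNA inserts are short and the adapter
  is ligated directly, so an exact-prefix model with an 8 nt floor is the
  conservative choice; reads without a qualifying match pass through.

Distinct-sequence tags carry per-library counts after collapsing; U is
normalised to T internally so RNA- and DNA-alphabet inputs mix safely.

Percentages in the summary tables follow two rounding dialects —
half-up to one decimal for length tallies and half-up to two decimals for
class tallies — implemented in one place (`percent_of()`) because base R's
`round()` rounds half to even.

## Annotation model

A tag is assigned a non-miRNA class (rRNA, tRNA, snRNA, snoRNA, mtRNA,
cpRNA) when its full sequence occurs as an exact substring of a reference
of that class on either strand. Conserved miRNAs require full-length,
equal-length, zero-mismatch identity to a known plant mature miRNA; this
is intentionally strict so that one substitution (a candidate novel
variant) is never silently absorbed. Classification precedence puts miRNA
first so a conserved miRNA can never be swallowed by the exclusion set;
the remainder is reported as "other sRNA" (in seed libraries this residue
is dominated by siRNAs). Families are parsed from reference identifiers
(species prefix, paralog letters and arm suffixes stripped) and the
evolutionarily linked pairs MIR156/157, MIR165/166 and MIR170/171 are
merged.

## Precursor discovery

Discovery follows the read-anchoring logic: tags that survived annotation
are mapped exactly (both strands) onto contigs; per contig, hits are
chained into blocks (two hits share a block if their intervals overlap or
their starts differ by ≤ 3 nt, transitively). A contig qualifies when its
hits form one or two blocks, all in one orientation, with ≥ 11 summed
reads — the footprint of a processed mature (and optionally its star). A
folding window spanning the blocks ± 20 nt is extracted (whole contigs up
to 300 nt are folded as-is) and folded with ViennaRNA's `RNAfold`.
Candidates must satisfy:

* |MFEI| ≥ 0.85, where MFEI = AMFE / GC% and AMFE = MFE/L × 100
  (kcal/mol per 100 nt) — the standard plant pre-miRNA plausibility
  index;
* the dominant block sits on one arm with ≥ 75% of its bases paired
  across the terminal loop to the opposite arm, and at most 3 of its
  bases inside the loop. The terminal loop is taken as the hairpin loop
  with the deepest enclosing stem, which makes the rule robust to
  incidental side-hairpins in the flanks.

The MFE plausibility band (−40 to −100 kcal/mol) is reported as a warning
flag rather than a hard filter, since genuine precursors fall outside it
in both directions. Candidates on qualifying contigs whose window fails
structural validation are kept with status `"partial"` only when the
dominant tag is identical to a known organism mature (mirroring how
truncated known precursors are rescued); everything else is rejected.

Per arm, the most abundant tag is the mature (ties break to the
lexicographically smallest sequence — a documented, deterministic rule);
same-arm tags within ±3 nt of the mature's ends are its isomiRs; the
opposite arm's dominant is the star. Categories are assigned by exact
identity of the dominant mature: known in the organism, known in plants,
or novel. Novel candidates additionally require the mature in every
library or a star in at least one — the dual-evidence rule that guards
against single-library artefacts.

## Differential abundance

Counts per mature locus credit each tag mapping within ±3 nt of the
mature interval; family aggregates count every distinct tag once. Library
scaling uses TMM (trimmed mean of M-values): per-locus log2 ratios
against a reference library after size division, doubly trimmed (30% on
M, 5% on A per side), weighted by inverse asymptotic binomial variances,
rescaled to geometric mean 1. The reference library is the one whose
upper-quartile size-scaled count is closest to the mean upper quartile.

Two independent tests are computed per locus:

* the Audic–Claverie statistic
  p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)),
  evaluated in log space; the one-sided p is the smaller tail sum and the
  two-sided p doubles it (capped at 1). The tail is *not* symmetric under
  exchanging libraries of unequal size (the pmf picks up a factor
  N2/N1), so the pair is put in a canonical orientation internally — the
  smaller library conditions the tail — making the result independent of
  argument order.
* a negative-binomial exact test conditioning on the pairwise total
  s = x + y: the p-value sums the probabilities of all splits at most as
  likely as the observed one under two independent NB variables with
  means proportional to the effective library sizes and common
  dispersion. At dispersion 0 this is exactly the binomial test with
  success probability N1/(N1+N2); the suite verifies agreement with an
  exact-binomial oracle to 10⁻¹² over all totals up to 50.

A locus is differentially abundant only when **both** p-values are ≤ α
(default 0.001, boundary inclusive). With one library per condition,
dispersion cannot be estimated tagwise, so it is a configuration
parameter: 0.1 as a squared-BCV analogue for conservative calling, 0 for
the Poisson limit. Fold changes are ratios of TMM-scaled counts-per-million
with a pseudocount of 1 (zero-count protection); a separate highlight flag
marks fold changes beyond 2 in either direction.

## Target prediction

Target sites are scored with the classical plant expectation scheme:
Watson–Crick pair 0, G:U wobble 0.5, mismatch 1, gap/bulge 2, all
penalties doubled over the miRNA core (positions 2–13 from the 5′ end);
at most one bulge per duplex, placed optimally. Every window within one
nucleotide of the miRNA length on either contig strand is scored, and
hits with E ≤ 4 are reported. The scanner is vectorised by gap position
(prefix/suffix accumulation) and is verified against an exhaustive naive
rescoring — identical hit sets and E values. Overlapping windows of one
true site are reduced to the best-scoring one by default (`dedupe`);
the raw all-window mode is retained for exact comparisons.

## What the generator emulates — and what it does not

`sim_config()` describes a two-condition seed experiment: two libraries
(default 50,000 reads each), 20 hairpin precursors planted in contigs
among 20 decoys, 21-nt mature arms, star arms carrying 2 pairing-breaking
substitutions, ±1–2 nt isomiRs at rate 0.2, star reads at rate 0.1, an
ncRNA contaminant fraction of 0.15 and a siRNA-like random background of
0.25 biased to 24 nt (these two backgrounds reproduce the bimodal 21/24 nt
length profile of seed libraries), 80% 5′-U mature bias, a single
full-length 3′ adapter and constant Phred-30 qualities (with an optional
low-quality fraction to exercise the filter). Eight loci carry an 8-fold
abundance change in the second library.

Planted precursors are composed as a mature/star duplex extended by an
imperfect basal stem (18–25 nt, 2 mismatches) and a short upper stem
(5–8 nt, 1 mismatch) between the duplex and the terminal loop. Both
extensions mirror genuine pri-miRNA fold-backs — the processed duplex
neither abuts the loop nor floats in unstructured sequence — and they are
what makes MFEI a meaningful discriminator on windows that include
flanking sequence. Contig flanks are 120–250 nt so the block-window
folding mode is the one exercised by default.

Per-library totals are allocated multinomially across loci and
backgrounds (probabilities proportional to abundance × fold change).
This is a Poisson model conditioned on the exact library total, so read
conservation holds exactly while per-locus counts remain Poisson-like;
the alternative of free Poisson draws per locus cannot conserve the
stated library size.

Passing tests on this generator demonstrate correct mechanics — exact
mapping, block logic, folding thresholds, arm assignment, count
statistics — not performance on real data: the generator has no
sequencing-error model, no paralogous repeat structure, no expression
correlation between loci, uniform isomiR offsets, and synthetic
(randomly drawn) reference sequences with realistic naming only.

## Numerical and reporting choices

* Rounding: half-up dialects as above; category percentages are checked
  to re-sum to 100 ± 0.05 after rounding.
* Tie-breaks: dominant tags by count then lexicographic order; TMM
  trimming uses first-occurrence ranks.
* The A–C tail uses the complement of the lower cumulative sum guarded
  against cancellation; the NB exact test normalises conditional log
  probabilities with log-sum-exp and treats ties with a 10⁻¹⁰ log-space
  slack.
* Degenerate inputs: empty read sets, all-zero count columns, GC-0
  windows and unbalanced dot-brackets raise explicit errors; MFE 0 yields
  MFEI 0 by convention.
* The identification tally's size-class totals are column sums of its
  category rows, so every number in the table is recomputable from the
  rows themselves.

## Problem sizes used in validation

The shipped validation suite runs the full pipeline on the default
20-precursor, 2 × 50,000-read configuration (planted recovery, decoy
specificity, arm assignment), a 2,000-locus null simulation and 20
replicated 10-locus power simulations for the dual-test operating
characteristics, exhaustive agreement of the target scanner on ~600 nt
contigs (with the all-window oracle also exercised at 2 kb in the test
suite), and the closed-form checks described above. These sizes were
chosen to give stable operating-characteristic estimates from a
laptop-scale run.

## Known limitations

* One library per condition: no replicate-based dispersion estimation or
  FDR control — raw dual-test p-value cut-offs follow the single-library
  study design this pipeline reproduces.
* Discovery assumes simple stem-loops; multi-branched precursors are
  rejected by the arm-pairing rule.
* ncRNA classification is containment-based with zero mismatches; it
  will under-exclude degraded or edited fragments.
* Target prediction scores complementarity only; no accessibility or
  conservation terms, and no degradome support.
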