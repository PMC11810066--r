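ref <- synthetic_amplicon()

test_that("the packaged fixture satisfies the amplicon invariants", {
  chars <- strsplit(ref$sequence, "")[[1]]
  expect_true(all(chars[ref$cpg_offsets + 1] == "C"))
  expect_true(all(chars[ref$cpg_offsets + 2] == "G"))
  expect_false(is.unsorted(ref$cpg_offsets, strictly = TRUE))
  expect_identical(length(ref$cpg_offsets), 13L)
  expect_identical(ref$cpg_ids[1:3],
                   c("cg16867657", "cg21572722", "cg24724428"))
  # no unannotated CpGs anywhere on the top strand
  all_cg <- gregexpr("CG", ref$sequence, fixed = TRUE)[[1]] - 1L
  expect_identical(as.integer(all_cg), ref$cpg_offsets)
})

test_that("amplicon construction rejects broken annotations", {
  expect_error(amplicon_reference("x", "ACGTA", 2L), "no CpG dinucleotide")
  expect_error(amplicon_reference("x", "ACGTA", c(1L, 1L)), "increasing")
  expect_error(amplicon_reference("x", "ACGTA", 10L), "outside")
})

test_that("clean high-quality reads pass trimming unchanged", {
  p <- read_pairs("r", "ACGTACGT", qual_string(rep(30, 8)),
                  "TTTTAAAA", qual_string(rep(30, 8)))
  t <- trim_read_pair(p, quality_cutoff = 20)
  expect_identical(t$r1_seq, "ACGTACGT")
  expect_identical(t$r2_seq, "TTTTAAAA")
})

test_that("a full 3' adapter and everything beyond it is removed", {
  adapter <- "AGATCGGAAGAGC"
  insert <- "TTACCTGGTT"
  p <- read_pairs("r", paste0(insert, adapter),
                  qual_string(rep(35, nchar(insert) + nchar(adapter))),
                  "AAAA", qual_string(rep(35, 4)))
  t <- trim_read_pair(p, quality_cutoff = 0, adapter = adapter)
  expect_identical(t$r1_seq, insert)
  # partial adapter prefix (>= 3 bases) at the end is also removed
  p2 <- read_pairs("r", paste0(insert, substr(adapter, 1, 4)),
                   qual_string(rep(35, nchar(insert) + 4)),
                   "AAAA", qual_string(rep(35, 4)))
  t2 <- trim_read_pair(p2, quality_cutoff = 0, adapter = adapter)
  expect_identical(t2$r1_seq, insert)
  # a 2-base suffix match is below the minimum and stays
  p3 <- read_pairs("r", paste0(insert, substr(adapter, 1, 2)),
                   qual_string(rep(35, nchar(insert) + 2)),
                   "AAAA", qual_string(rep(35, 4)))
  t3 <- trim_read_pair(p3, quality_cutoff = 0, adapter = adapter)
  expect_identical(t3$r1_seq, paste0(insert, substr(adapter, 1, 2)))
})

test_that("quality trimming matches the brute-force cut-point oracle", {
  p <- read_pairs("r", "ACGT", qual_string(c(40, 40, 5, 5)),
                  "ACGT", qual_string(rep(40, 4)))
  t <- trim_read_pair(p, quality_cutoff = 20)
  expect_identical(t$r1_seq, "AC")
  set.seed(21)
  for (i in 1:50) {
    L <- sample(5:40, 1)
    q <- sample(2:40, L, replace = TRUE)
    cutoff <- sample(5:30, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    p <- read_pairs("r", seq, qual_string(q), "AAAA", qual_string(rep(40, 4)))
    t <- trim_read_pair(p, quality_cutoff = cutoff)
    expect_identical(nchar(t$r1_seq), L - brute_force_qtrim(q, cutoff))
  }
})

test_that("trimming never cuts into the protected UMI region of read 1", {
  p <- read_pairs("r", "ACGTACGT", qual_string(rep(2, 8)),
                  "ACGT", qual_string(rep(40, 4)))
  t <- trim_read_pair(p, quality_cutoff = 30, umi_length = 8)
  expect_identical(t$r1_seq, "ACGTACGT")
  t2 <- trim_read_pair(p, quality_cutoff = 30, umi_length = 0)
  expect_identical(t2$r1_seq, "")
})

test_that("malformed quality strings are rejected", {
  expect_error(read_pairs("r", "ACGT", "!!", "ACGT", "!!!!"),
               "differ in length")
  p <- data.frame(read_id = "r", r1_seq = "ACGT", r1_qual = "!! ",
                  r2_seq = "ACGT", r2_qual = "!!!!",
                  stringsAsFactors = FALSE)
  expect_error(trim_read_pair(p, 20), "malformed")
})

test_that("UMI parsing strips the prefix and round-trips simulator truth", {
  p <- read_pairs("r", "ACGTNNNNTTTT", qual_string(rep(30, 12)),
                  "ACGT", qual_string(rep(30, 4)))
  ref4 <- synthetic_amplicon(umi_length = 4L)
  u <- parse_umi(p, ref4)
  expect_identical(u$umi, "ACGT")
  expect_identical(u$r1_seq, "NNNNTTTT")

  ref0 <- synthetic_amplicon(umi_length = 0L)
  u0 <- parse_umi(p, ref0)
  expect_identical(u0$umi, "")
  expect_identical(u0$r1_seq, "ACGTNNNNTTTT")

  short <- read_pairs("r", "ACG", qual_string(rep(30, 3)),
                      "ACGT", qual_string(rep(30, 4)))
  expect_error(parse_umi(short, ref4), "read too short")

  sim <- simulate_reads(ref, 40, meth_probs = 0.5, duplication_rate = 2,
                        seed = 91)
  parsed <- parse_umi(sim$pairs, ref)
  mol <- sub(":.*", "", parsed$read_id)
  expect_identical(parsed$umi,
                   sim$truth$molecules$umi[match(mol,
                     sim$truth$molecules$molecule_id)])
})

test_that("conversion-consistent perfect reads align at their true offset", {
  conv <- converted_strand(ref)                  # fully unmethylated strand
  read <- substr(conv, 41, 140)                  # true start offset 40
  p <- read_pairs("r", read, qual_string(rep(37, 100)),
                  rc_str(substr(conv, 200, 299)), qual_string(rep(37, 100)))
  p$umi <- ""
  a <- bisulfite_align(p, ref)
  expect_true(a$mapped)
  expect_identical(a$r1_start, 40L)
  expect_identical(a$r1_mm, 0L)
})

test_that("random same-length sequences fail the mismatch threshold", {
  set.seed(33)
  rand <- paste(sample(c("A", "C", "G", "T"), nchar(ref$sequence), TRUE),
                collapse = "")
  p <- read_pairs("r", rand, qual_string(rep(37, nchar(rand))),
                  rand, qual_string(rep(37, nchar(rand))))
  p$umi <- ""
  a <- bisulfite_align(p, ref, max_mismatch_frac = 0.1)
  expect_false(a$mapped)
  expect_identical(a$flag, "")
  # empty reads are unmapped and flagged
  pe <- p; pe$r1_seq <- ""; pe$r1_qual <- ""
  ae <- bisulfite_align(pe, ref)
  expect_false(ae$mapped)
  expect_identical(ae$flag, "empty")
})

test_that("production alignment equals the exhaustive brute-force scan on 200 simulated pairs", {
  sim <- simulate_reads(ref, 200, meth_probs = runif(13), seed = 57,
                        duplication_rate = 1, conversion_efficiency = 0.99,
                        error_rate = 0.002)
  pp <- parse_umi(sim$pairs, ref)
  al <- bisulfite_align(pp, ref)
  expect_true(all(al$mapped))
  for (i in seq_len(nrow(al))) {
    o1 <- brute_force_align(al$r1_seq[i], ref$sequence)
    expect_identical(al$r1_start[i], o1$start)
    expect_identical(al$r1_mm[i], o1$mm)
    o2 <- brute_force_align(al$r2_rc[i], ref$sequence)
    expect_identical(al$r2_start[i], o2$start)
    expect_identical(al$r2_mm[i], o2$mm)
  }
})

test_that("deduplication keeps one representative per (UMI, start) group", {
  conv <- converted_strand(ref)
  mk <- function(id, umi, qual) {
    p <- read_pairs(id, substr(conv, 1, 100), qual_string(rep(qual, 100)),
                    rc_str(substr(conv, 200, 299)),
                    qual_string(rep(qual, 100)))
    p$umi <- umi
    p
  }
  trio <- rbind(mk("a", "AAAA", 20), mk("b", "AAAA", 35), mk("c", "AAAA", 30))
  al <- bisulfite_align(trio, ref)
  kept <- dedup_pairs(al)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$read_id, "b")          # highest mean quality wins
  expect_identical(unname(as.integer(attr(kept, "group_sizes"))), 3L)

  distinct <- rbind(mk("a", "AAAA", 30), mk("b", "CCCC", 30),
                    mk("c", "GGGG", 30))
  ald <- bisulfite_align(distinct, ref)
  expect_identical(nrow(dedup_pairs(ald)), 3L)

  # ties by first-seen order
  tie <- rbind(mk("x", "TTTT", 30), mk("y", "TTTT", 30))
  alt <- bisulfite_align(tie, ref)
  expect_identical(dedup_pairs(alt)$read_id, "x")
})

test_that("dedup is idempotent and recovers the simulator's molecule count", {
  sim <- simulate_reads(ref, 120, meth_probs = 0.5, duplication_rate = 3,
                        seed = 77)
  expect_gt(nrow(sim$pairs), 120)
  pp <- bisulfite_align(parse_umi(sim$pairs, ref), ref)
  once <- dedup_pairs(pp)
  expect_identical(nrow(once), 120L)
  twice <- dedup_pairs(once)
  expect_identical(twice$read_id, once$read_id)
})

test_that("methylation calls follow base identity with full coverage", {
  # all methylated: every CpG C stays C
  sim <- simulate_reads(ref, 150, meth_probs = 1, seed = 3)
  res <- call_amplicon_sample(sim$pairs, ref)
  expect_true(all(res$calls$beta == 1))
  expect_true(attr(res$calls, "passed_depth_filter"))
  expect_identical(attr(res$calls, "total_deduplicated_reads"), 150L)
  # all unmethylated: every CpG C reads T
  sim0 <- simulate_reads(ref, 150, meth_probs = 0, seed = 3)
  res0 <- call_amplicon_sample(sim0$pairs, ref)
  expect_true(all(res0$calls$beta == 0))
})

test_that("the depth filter fails below the documented 100-pair threshold", {
  sim <- simulate_reads(ref, 99, meth_probs = 0.5, seed = 13)
  res <- call_amplicon_sample(sim$pairs, ref, min_reads = 100)
  expect_identical(res$qc$deduplicated, 99L)
  expect_false(res$qc$passed_depth_filter)
  expect_false(attr(res$calls, "passed_depth_filter"))
  # betas are still reported
  expect_true(all(is.finite(res$calls$beta)))
  res2 <- call_amplicon_sample(sim$pairs, ref, min_reads = 99)
  expect_true(res2$qc$passed_depth_filter)
})

test_that("mate overlap contributes exactly one call per pair per CpG", {
  # construct a molecule methylated at one overlap CpG; both mates cover it
  o <- 198L                                     # inside [150,250) overlap
  conv <- converted_strand(ref, methylated_offsets = o)
  r1 <- substr(conv, 1, 250)
  r2_top <- substr(conv, 151, 400)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r2 <- paste(rev(unname(comp[strsplit(r2_top, "")[[1]]])), collapse = "")
  p <- read_pairs("r", r1, qual_string(rep(37, 250)),
                  r2, qual_string(rep(37, 250)))
  p$umi <- "ACGTACGT"
  al <- bisulfite_align(p, ref)
  expect_identical(al$r1_start, 0L)
  expect_identical(al$r2_start, 150L)
  calls <- call_methylation(al, ref, min_reads = 1)
  row <- calls[calls$offset == o, ]
  expect_identical(row$methylated, 1L)          # one call, not two
  expect_identical(row$coverage, 1L)
  # counting conservation: per-CpG calls never exceed retained pairs
  expect_true(all(calls$coverage <= nrow(al)))
  # every covered CpG got exactly one contribution from this single pair
  expect_true(all(calls$coverage == 1L))
})

test_that("called beta lands in the binomial 99% CI of the truth methylation", {
  sim <- simulate_reads(ref, 600, meth_probs = 0.7, seed = 29)
  res <- call_amplicon_sample(sim$pairs, ref)
  n <- attr(res$calls, "total_deduplicated_reads")
  lo <- qbinom(0.005, n, 0.7) / n
  hi <- qbinom(0.995, n, 0.7) / n
  expect_true(all(res$calls$beta >= lo & res$calls$beta <= hi))
  # and the calls match the simulator's per-molecule truth exactly at error 0
  truth_beta <- colMeans(sim$truth$states)
  expect_equal(unname(res$calls$beta), unname(truth_beta), tolerance = 1e-12)
})

test_that("CpG offsets outside the reference are a config error", {
  p <- read_pairs("r", "ACGT", qual_string(rep(30, 4)),
                  "ACGT", qual_string(rep(30, 4)))
  bad <- ref
  bad$cpg_offsets <- c(bad$cpg_offsets, 2000L)
  expect_error(call_methylation(p, bad, 1), "config error")
})
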