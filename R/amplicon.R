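#' Amplicon reference for targeted bisulfite sequencing
#'
#' Describes a single PCR amplicon on its own coordinate system: the
#' top-strand sequence (primer to primer), the 0-based offsets of the CpG
#' cytosines on that strand, and the read geometry (UMI length at the 5' end
#' of read 1, primer lengths).
#'
#' @param name Amplicon name (used as the "chromosome" in coverage output).
#' @param sequence Upper-case DNA string, top strand.
#' @param cpg_offsets Integer vector of 0-based offsets with `C` at the
#'   offset and `G` immediately after; strictly increasing.
#' @param cpg_ids Optional CpG identifiers, same length as `cpg_offsets`.
#' @param umi_length UMI bases at the 5' of read 1 (>= 0).
#' @param fwd_primer_len,rev_primer_len Primer lengths in bases.
#' @return An object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(name, sequence, cpg_offsets, cpg_ids = NULL,
                               umi_length = 8L, fwd_primer_len = 0L,
                               rev_primer_len = 0L) {
  sequence <- toupper(as.character(sequence)[1])
  if (!grepl("^[ACGTN]+$", sequence))
    stop("reference sequence must be ACGTN", call. = FALSE)
  cpg_offsets <- as.integer(cpg_offsets)
  if (is.unsorted(cpg_offsets, strictly = TRUE))
    stop("cpg_offsets must be strictly increasing", call. = FALSE)
  if (any(cpg_offsets < 0L) || any(cpg_offsets + 2L > nchar(sequence)))
    stop("CpG offset outside the reference", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- cpg_offsets[chars[cpg_offsets + 1L] != "C" |
                     chars[cpg_offsets + 2L] != "G"]
  if (length(bad))
    stop("no CpG dinucleotide at offset ", bad[1], call. = FALSE)
  if (is.null(cpg_ids))
    cpg_ids <- sprintf("%s_cpg_%02d", name, seq_along(cpg_offsets))
  if (length(cpg_ids) != length(cpg_offsets))
    stop("cpg_ids must match cpg_offsets in length", call. = FALSE)
  if (umi_length < 0L)
    stop("umi_length must be >= 0", call. = FALSE)
  structure(
    list(name = as.character(name)[1], sequence = sequence,
         cpg_offsets = cpg_offsets, cpg_ids = as.character(cpg_ids),
         umi_length = as.integer(umi_length),
         fwd_primer_len = as.integer(fwd_primer_len),
         rev_primer_len = as.integer(rev_primer_len)),
    class = "amplicon_reference"
  )
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("<amplicon_reference> %s: %d bp, %d CpGs, UMI %d bp\n",
              x$name, nchar(x$sequence), length(x$cpg_offsets), x$umi_length))
  invisible(x)
}

#' Packaged synthetic ELOVL2-like amplicon fixture
#'
#' A deterministic 400 bp synthetic amplicon carrying 13 CpG sites, emulating
#' the geometry of the targeted ELOVL2 assay (one short amplicon, 13 CpGs, a
#' UMI at the start of read 1). The sequence is synthetic — the real assay's
#' amplicon boundaries and primers are not public — and the first three CpGs
#' are labelled with the clock's site ids (cg16867657, cg21572722,
#' cg24724428) so pipeline output can be fed straight into [predict_age()].
#'
#' @param umi_length UMI length in bases (default 8; the real assay's UMI
#'   length is not published).
#' @return An [amplicon_reference()].
#' @export
synthetic_amplicon <- function(umi_length = 8L) {
  seq <- paste0(
    "CACAAAACTAATTAGAAAAGTAGGCATCTCACCTCGCTTATAGATAGGATTCATAAGTGG",
    "CCGATGCACTACAACATAAAATCAGCCTCGCTCATTTATACTACAAGGATCACGTCCATG",
    "TTGTAGTTGTTGATGGCATATTACGAACTGCAAGGTTTGCTGATTTGGATCGTATTGGCA",
    "TACAGCCTGTGAGTTGACCGTCACAGAGAGTAAAAATTAATTCTCACGTGTTTACCCTTC",
    "ATACCAGCCTATCCTCGCTCTGTTTATCATAAGAATATATTCCTCGAATCCTACAAGTAA",
    "TGAATCAACTCTCGAGGTGCAGGTCCAATATCTAATGTACTCGTAGGTGTTGAACTAGAT",
    "CCTAAGGACGGTCACTTAGAAAACAGCCATGGCAGGGATA")
  offs <- c(34L, 61L, 88L, 112L, 143L, 170L, 198L, 226L, 255L, 284L,
            312L, 341L, 368L)
  ids <- c("cg16867657", "cg21572722", "cg24724428",
           sprintf("syn_cpg_%02d", 4:13))
  amplicon_reference("synthetic_elovl2", seq, offs, cpg_ids = ids,
                     umi_length = umi_length,
                     fwd_primer_len = 20L, rev_primer_len = 20L)
}

#' Build a read-pair table
#'
#' Read pairs flow through the pipeline as a data frame with one row per
#' pair; trimming, UMI parsing, alignment and deduplication add or modify
#' columns on it.
#'
#' @param read_id Character vector of pair ids.
#' @param r1_seq,r1_qual,r2_seq,r2_qual Sequences and phred+33 quality
#'   strings, equal length per mate.
#' @return Data frame of class `read_pairs`.
#' @export
read_pairs <- function(read_id, r1_seq, r1_qual, r2_seq, r2_qual) {
  df <- data.frame(read_id = as.character(read_id),
                   r1_seq = toupper(as.character(r1_seq)),
                   r1_qual = as.character(r1_qual),
                   r2_seq = toupper(as.character(r2_seq)),
                   r2_qual = as.character(r2_qual),
                   stringsAsFactors = FALSE)
  .check_qual(df$r1_seq, df$r1_qual)
  .check_qual(df$r2_seq, df$r2_qual)
  class(df) <- c("read_pairs", "data.frame")
  df
}

.check_qual <- function(seq, qual) {
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence and quality strings differ in length", call. = FALSE)
  if (any(grepl("[^\\x21-\\x7e]", qual, perl = TRUE)))
    stop("malformed phred+33 quality string", call. = FALSE)
  invisible(NULL)
}

.phred <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

# BWA-style 3' quality trim: over the reversed (cutoff - Q) partial sums,
# cut the suffix attaining the maximal positive sum.
.qual_trim_len <- function(q, cutoff) {
  if (!length(q)) return(0L)
  cs <- cumsum(cutoff - rev(q))
  m <- max(cs)
  if (m > 0L) which.max(cs) else 0L
}

# 3' adapter trim: drop the read tail that exactly matches a prefix of the
# adapter, minimum 3 matching bases; the longest such tail wins.
.adapter_trim_len <- function(seq, adapter) {
  L <- nchar(seq); A <- nchar(adapter)
  if (L < 3L || A < 3L) return(0L)
  for (k in seq(min(L, A), 3L)) {
    if (substr(seq, L - k + 1L, L) == substr(adapter, 1L, k)) return(k)
  }
  0L
}

#' Trim adapters and low-quality 3' ends from read pairs
#'
#' Per mate, first removes a 3' tail that exactly matches a prefix (>= 3
#' bases) of the adapter, then applies BWA-style quality trimming at the
#' cutoff (cut at the suffix maximising the running sum of `cutoff - Q`).
#' The 5' UMI region of read 1 is never touched: quality/adapter trimming
#' cannot shorten read 1 below `umi_length` bases.
#'
#' @param pairs A [read_pairs()] table.
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 20).
#' @param adapter Adapter sequence, or `NULL` to skip adapter trimming.
#' @param umi_length Protected 5' bases on read 1 (default 0; pass the
#'   reference's `umi_length` when trimming before [parse_umi()]).
#' @return The trimmed `read_pairs` table.
#' @export
trim_read_pair <- function(pairs, quality_cutoff = 20L, adapter = NULL,
                           umi_length = 0L) {
  .check_qual(pairs$r1_seq, pairs$r1_qual)
  .check_qual(pairs$r2_seq, pairs$r2_qual)
  trim_one <- function(seq, qual, keep_min) {
    n <- length(seq)
    new_len <- nchar(seq)
    if (!is.null(adapter)) {
      alen <- vapply(seq_len(n), function(i)
        .adapter_trim_len(substr(seq[i], 1L, new_len[i]), adapter), integer(1))
      new_len <- new_len - alen
    }
    phreds <- .phred(qual)
    qlen <- vapply(seq_len(n), function(i)
      .qual_trim_len(phreds[[i]][seq_len(new_len[i])], quality_cutoff),
      integer(1))
    new_len <- pmax(keep_min, new_len - qlen)
    list(seq = substr(seq, 1L, new_len), qual = substr(qual, 1L, new_len))
  }
  r1 <- trim_one(pairs$r1_seq, pairs$r1_qual, keep_min = umi_length)
  r2 <- trim_one(pairs$r2_seq, pairs$r2_qual, keep_min = 0L)
  pairs$r1_seq <- r1$seq; pairs$r1_qual <- r1$qual
  pairs$r2_seq <- r2$seq; pairs$r2_qual <- r2$qual
  pairs
}

#' Parse the UMI off read 1
#'
#' Moves the first `umi_length` bases of read 1 into a `umi` column and
#' strips them (and their qualities) from the read.
#'
#' @param pairs A [read_pairs()] table.
#' @param reference An [amplicon_reference()] supplying `umi_length`.
#' @return The table with a `umi` column and shortened read 1.
#' @export
parse_umi <- function(pairs, reference) {
  k <- reference$umi_length
  if (any(nchar(pairs$r1_seq) <= k))
    stop("read too short: read 1 must exceed the UMI length (", k, ")",
         call. = FALSE)
  pairs$umi <- substr(pairs$r1_seq, 1L, k)
  pairs$r1_seq <- substr(pairs$r1_seq, k + 1L, nchar(pairs$r1_seq))
  pairs$r1_qual <- substr(pairs$r1_qual, k + 1L, nchar(pairs$r1_qual))
  pairs
}

# Count conversion-tolerant mismatches of a read (top-strand orientation,
# character vector) at every feasible start; reference C may be read as T.
.scan_offsets <- function(read_chars, ref_chars) {
  L <- length(read_chars); R <- length(ref_chars)
  if (L == 0L || L > R) return(integer(0))
  n_starts <- R - L + 1L
  mm <- integer(n_starts)
  for (s in seq_len(n_starts)) {
    refc <- ref_chars[s:(s + L - 1L)]
    mm[s] <- sum(refc != read_chars & !(refc == "C" & read_chars == "T"))
  }
  mm
}

.align_one <- function(read, ref_chars, max_mm_frac) {
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  mm <- .scan_offsets(chars, ref_chars)
  if (!length(mm))
    return(list(start = NA_integer_, mm = NA_integer_, mapped = FALSE))
  best <- which.min(mm)                      # ties -> smallest start
  mapped <- mm[best] <= max_mm_frac * length(chars)
  list(start = if (mapped) best - 1L else NA_integer_,
       mm = if (mapped) mm[best] else NA_integer_, mapped = mapped)
}

#' Conversion-aware ungapped alignment of read pairs to the amplicon
#'
#' Both mates are scored in top-strand orientation (read 2 is
#' reverse-complemented first) against every feasible start on the reference
#' under the bisulfite rule that a reference `C` may be read as `C` or `T`;
#' conversion-consistent positions are not mismatches. The minimal-mismatch
#' start wins, ties broken by the smallest start, and a mate maps iff its
#' mismatch fraction is at most `max_mismatch_frac`. The amplicon is short, so
#' the exhaustive scan is exact — there is no heuristic seeding and indels are
#' not modelled (indel-bearing reads exceed the mismatch threshold and drop
#' out).
#'
#' @param pairs A trimmed, UMI-parsed [read_pairs()] table.
#' @param reference An [amplicon_reference()].
#' @param max_mismatch_frac Maximum mismatch fraction per mate (default 0.1).
#' @return The table with columns `r1_start`, `r1_mm`, `r2_start`, `r2_mm`
#'   (0-based starts and mismatch counts), `r2_rc`/`r2_rc_qual` (read 2 in
#'   top-strand orientation), `mapped`, and `flag` ("empty" for reads empty
#'   after trimming).
#' @export
bisulfite_align <- function(pairs, reference, max_mismatch_frac = 0.1) {
  ref_chars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ifelse(nchar(pairs$r2_seq) > 0, pairs$r2_seq, "A"))))
  rc[nchar(pairs$r2_seq) == 0] <- ""
  pairs$r2_rc <- rc
  pairs$r2_rc_qual <- vapply(pairs$r2_qual, function(q)
    paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)

  n <- nrow(pairs)
  r1_start <- r1_mm <- r2_start <- r2_mm <- rep(NA_integer_, n)
  mapped <- logical(n)
  flag <- rep("", n)
  for (i in seq_len(n)) {
    if (nchar(pairs$r1_seq[i]) == 0L || nchar(pairs$r2_rc[i]) == 0L) {
      flag[i] <- "empty"
      next
    }
    a1 <- .align_one(pairs$r1_seq[i], ref_chars, max_mismatch_frac)
    a2 <- .align_one(pairs$r2_rc[i], ref_chars, max_mismatch_frac)
    if (a1$mapped && a2$mapped) {
      r1_start[i] <- a1$start; r1_mm[i] <- a1$mm
      r2_start[i] <- a2$start; r2_mm[i] <- a2$mm
      mapped[i] <- TRUE
    }
  }
  pairs$r1_start <- r1_start; pairs$r1_mm <- r1_mm
  pairs$r2_start <- r2_start; pairs$r2_mm <- r2_mm
  pairs$mapped <- mapped; pairs$flag <- flag
  pairs
}

#' Collapse PCR duplicates by UMI and alignment start
#'
#' Mapped pairs are grouped by the key `(UMI, read-1 alignment start)` and
#' exactly one representative per group is retained: the pair with the
#' highest mean base quality over both mates, ties broken by first-seen
#' order. The operation is idempotent.
#'
#' @param pairs An aligned [read_pairs()] table (only `mapped` rows are
#'   considered).
#' @return The retained pairs, with attribute `group_sizes` (named integer
#'   vector of duplicate-family sizes).
#' @export
dedup_pairs <- function(pairs) {
  pairs <- pairs[isTRUE_vec(pairs$mapped), , drop = FALSE]
  if (!nrow(pairs)) {
    attr(pairs, "group_sizes") <- integer(0)
    return(pairs)
  }
  key <- paste(pairs$umi, pairs$r1_start, sep = "@")
  meanq <- vapply(seq_len(nrow(pairs)), function(i) {
    q <- c(as.integer(charToRaw(pairs$r1_qual[i])),
           as.integer(charToRaw(pairs$r2_qual[i]))) - 33L
    if (length(q)) mean(q) else 0
  }, numeric(1))
  keep <- vapply(split(seq_len(nrow(pairs)), key), function(idx) {
    idx[which.max(meanq[idx])]          # which.max: first max = first seen
  }, integer(1))
  out <- pairs[sort(keep), , drop = FALSE]
  attr(out, "group_sizes") <- table(key)[unique(key)]
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Per-CpG methylation calling with mate-overlap exclusion
#'
#' At each reference CpG cytosine covered by a retained pair, the observed
#' base (top-strand orientation) is scored `C` = methylated, `T` =
#' unmethylated, anything else = other. Where the mates overlap, only read 1
#' contributes; read 2 contributes only at positions read 1 does not cover,
#' so each pair yields at most one call per CpG. Beta is
#' methylated / (methylated + unmethylated), undefined (NA) when the
#' denominator is zero. The sample passes the depth filter when the number
#' of deduplicated pairs is at least `min_reads`; when it fails, betas are
#' still reported but flagged excluded.
#'
#' @param pairs Deduplicated, aligned [read_pairs()].
#' @param reference An [amplicon_reference()].
#' @param min_reads Depth threshold on deduplicated read pairs (default 100).
#' @return A `methylation_calls` data frame with columns `cpg_id`, `offset`,
#'   `methylated`, `unmethylated`, `other`, `coverage`, `beta`; attributes
#'   `total_deduplicated_reads`, `passed_depth_filter`, `min_reads`,
#'   `amplicon`.
#' @export
call_methylation <- function(pairs, reference, min_reads = 100L) {
  offs <- reference$cpg_offsets
  if (any(offs + 2L > nchar(reference$sequence)))
    stop("config error: CpG offset outside reference", call. = FALSE)
  n_cpg <- length(offs)
  meth <- unmeth <- other <- integer(n_cpg)
  n_pairs <- nrow(pairs)
  if (n_pairs) {
    r1s <- pairs$r1_start; r1e <- r1s + nchar(pairs$r1_seq)
    r2s <- pairs$r2_start; r2e <- r2s + nchar(pairs$r2_rc)
    for (j in seq_len(n_cpg)) {
      o <- offs[j]
      in1 <- isTRUE_vec(o >= r1s & o < r1e)
      in2 <- isTRUE_vec(o >= r2s & o < r2e) & !in1   # read 1 wins in overlap
      base <- rep(NA_character_, n_pairs)
      base[in1] <- substr(pairs$r1_seq[in1], o - r1s[in1] + 1L,
                          o - r1s[in1] + 1L)
      base[in2] <- substr(pairs$r2_rc[in2], o - r2s[in2] + 1L,
                          o - r2s[in2] + 1L)
      meth[j] <- sum(base == "C", na.rm = TRUE)
      unmeth[j] <- sum(base == "T", na.rm = TRUE)
      other[j] <- sum(!is.na(base)) - meth[j] - unmeth[j]
    }
  }
  denom <- meth + unmeth
  out <- data.frame(cpg_id = reference$cpg_ids, offset = offs,
                    methylated = meth, unmethylated = unmeth, other = other,
                    coverage = meth + unmeth + other,
                    beta = ifelse(denom > 0, meth / denom, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "total_deduplicated_reads") <- n_pairs
  attr(out, "passed_depth_filter") <- n_pairs >= min_reads
  attr(out, "min_reads") <- as.integer(min_reads)
  attr(out, "amplicon") <- reference$name
  class(out) <- c("methylation_calls", "data.frame")
  out
}

#' @export
print.methylation_calls <- function(x, ...) {
  cat(sprintf("<methylation_calls> %s: %d CpGs, %d deduplicated pairs, depth filter %s\n",
              attr(x, "amplicon"), nrow(x),
              attr(x, "total_deduplicated_reads"),
              if (attr(x, "passed_depth_filter")) "PASS" else
                sprintf("FAIL (< %d)", attr(x, "min_reads"))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Run the full amplicon methylation pipeline on one sample
#'
#' Convenience wrapper: trim, parse UMIs, align, deduplicate, call
#' methylation.
#'
#' @param pairs Raw [read_pairs()] (read 1 still carrying its UMI).
#' @param reference An [amplicon_reference()].
#' @param quality_cutoff,adapter Passed to [trim_read_pair()].
#' @param max_mismatch_frac Passed to [bisulfite_align()].
#' @param min_reads Passed to [call_methylation()].
#' @return List with `calls` (the [call_methylation()] table) and `qc`
#'   (reads in / trimmed / mapped / deduplicated counts and filter status).
#' @export
call_amplicon_sample <- function(pairs, reference, quality_cutoff = 20L,
                                 adapter = NULL, max_mismatch_frac = 0.1,
                                 min_reads = 100L) {
  n_in <- nrow(pairs)
  pairs <- trim_read_pair(pairs, quality_cutoff, adapter,
                          umi_length = reference$umi_length)
  pairs <- parse_umi(pairs, reference)
  pairs <- bisulfite_align(pairs, reference, max_mismatch_frac)
  n_mapped <- sum(pairs$mapped)
  kept <- dedup_pairs(pairs)
  calls <- call_methylation(kept, reference, min_reads)
  list(calls = calls,
       qc = list(reads_in = n_in, mapped = n_mapped,
                 deduplicated = nrow(kept),
                 passed_depth_filter = attr(calls, "passed_depth_filter"),
                 min_reads = as.integer(min_reads)))
}
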