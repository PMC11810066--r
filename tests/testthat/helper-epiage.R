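# Shared fixture builders. Everything is generated in code; no binary files.

published_betas <- function(b1, b2, b3) {
  c(cg16867657 = b1, cg21572722 = b2, cg24724428 = b3)
}

# Brute-force OLS oracle: explicit normal-equations solve, independent of lm.
normal_equations_fit <- function(X, y) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

# Brute-force conversion-tolerant alignment oracle: try every offset, count
# mismatches with reference C allowed to read as T; min mismatches wins,
# ties by smallest start.
brute_force_align <- function(read, ref) {
  rc <- strsplit(read, "")[[1]]
  fc <- strsplit(ref, "")[[1]]
  L <- length(rc)
  if (L == 0 || L > length(fc)) return(list(start = NA, mm = NA))
  mm <- sapply(0:(length(fc) - L), function(s) {
    refc <- fc[(s + 1):(s + L)]
    sum(refc != rc & !(refc == "C" & rc == "T"))
  })
  list(start = which.min(mm) - 1L, mm = min(mm))
}

# Brute-force BWA-style 3' quality trim: evaluate the running objective at
# every cut point and keep the best positive one.
brute_force_qtrim <- function(q, cutoff) {
  L <- length(q)
  if (L == 0) return(0L)
  best <- 0; best_k <- 0L
  for (k in seq_len(L)) {           # trim the last k bases
    s <- sum(cutoff - q[(L - k + 1):L])
    if (s > best) { best <- s; best_k <- k }
  }
  best_k
}

# Hand-rolled phred string from integer qualities.
qual_string <- function(q) rawToChar(as.raw(q + 33L))

rc_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Minimal read-pair builder around a reference substring with full bisulfite
# conversion applied outside the methylated CpG set.
converted_strand <- function(reference, methylated_offsets = integer(0)) {
  chars <- strsplit(reference$sequence, "")[[1]]
  c_pos <- which(chars == "C")
  keep <- methylated_offsets + 1L
  chars[setdiff(c_pos, keep)] <- "T"
  paste(chars, collapse = "")
}
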