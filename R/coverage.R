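#' Write methylation calls as bedGraph and Bismark-style coverage files
#'
#' Emits the two standard per-CpG text outputs of a bisulfite pipeline:
#' bedGraph (`chrom  start0  end0  methylation%`, 0-based half-open) and the
#' Bismark coverage (".cov") dialect (`chrom  start1  end1  methylation%
#' count_methylated  count_unmethylated`, 1-based inclusive). Only CpGs with
#' at least one methylated or unmethylated call are written; reading a .cov
#' file back reproduces the counts exactly.
#'
#' @param calls A [call_methylation()] table.
#' @param bedgraph_path,cov_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_coverage <- function(calls, bedgraph_path = NULL, cov_path = NULL) {
  chrom <- attr(calls, "amplicon") %||% "amplicon"
  keep <- calls$methylated + calls$unmethylated > 0
  x <- calls[keep, , drop = FALSE]
  pct <- 100 * x$methylated / (x$methylated + x$unmethylated)
  # trim trailing zeros so 70 prints as "70", 20.4081... keeps 10 decimals
  pct_s <- sub("\\.$", "", sub("0+$", "", sprintf("%.10f", pct)))
  if (!is.null(bedgraph_path)) {
    lines <- if (nrow(x))
      sprintf("%s\t%d\t%d\t%s", chrom, x$offset, x$offset + 1L, pct_s)
    else character(0)
    writeLines(lines, bedgraph_path)
  }
  if (!is.null(cov_path)) {
    lines <- if (nrow(x))
      sprintf("%s\t%d\t%d\t%s\t%d\t%d", chrom, x$offset + 1L, x$offset + 1L,
              pct_s, x$methylated, x$unmethylated)
    else character(0)
    writeLines(lines, cov_path)
  }
  invisible(c(bedgraph = bedgraph_path, cov = cov_path))
}

#' Read a bedGraph or Bismark-style coverage file
#'
#' Parses per-CpG methylation output back into a table on the internal
#' 0-based coordinate system. For the .cov dialect (6 columns, 1-based
#' inclusive) betas are recomputed from the counts; bedGraph (4 columns,
#' 0-based half-open) carries no counts, so beta comes from the percentage
#' and the count columns are `NA`.
#'
#' @param path File to read.
#' @param dialect `"bedgraph"` or `"cov"`.
#' @return Data frame with columns `chrom`, `offset` (0-based), `methylated`,
#'   `unmethylated`, `beta`.
#' @export
read_coverage <- function(path, dialect = c("bedgraph", "cov")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(0), offset = integer(0),
                      methylated = integer(0), unmethylated = integer(0),
                      beta = numeric(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- if (dialect == "cov") 6L else 4L
  if (any(nf != want))
    stop("mixed or wrong dialect: expected ", want, " columns for ", dialect,
         ", found ", nf[which(nf != want)[1]], " on line ",
         which(nf != want)[1], call. = FALSE)
  m <- do.call(rbind, fields)
  if (dialect == "cov") {
    meth <- as.integer(m[, 5]); unmeth <- as.integer(m[, 6])
    data.frame(chrom = m[, 1], offset = as.integer(m[, 2]) - 1L,
               methylated = meth, unmethylated = unmeth,
               beta = ifelse(meth + unmeth > 0, meth / (meth + unmeth),
                             NA_real_),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = m[, 1], offset = as.integer(m[, 2]),
               methylated = NA_integer_, unmethylated = NA_integer_,
               beta = as.numeric(m[, 4]) / 100,
               stringsAsFactors = FALSE)
  }
}
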