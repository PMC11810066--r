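.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a beta-value matrix
#'
#' Delimited text (tab or comma, auto-detected), header row of CpG ids,
#' first column sample ids. Cells must be numeric in \[0,1\]; empty cells
#' become missing values (never zeros). Errors name the offending cell.
#'
#' @param path File to read.
#' @return Numeric samples x CpG matrix with sample ids as row names.
#' @export
read_beta_matrix <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L)
    stop("beta matrix needs a sample_id column plus CpG columns",
         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", ids[duplicated(ids)][1], call. = FALSE)
  cells <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                  dimnames = dimnames(cells)))
  bad <- which(is.na(vals) & !(is.na(cells) | cells == "" | cells == "NA"),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric beta in row '", ids[bad[1, 1]], "', column '",
         colnames(vals)[bad[1, 2]], "'", call. = FALSE)
  out_of_range <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(out_of_range))
    stop("beta outside [0,1] in row '", ids[out_of_range[1, 1]],
         "', column '", colnames(vals)[out_of_range[1, 2]], "' (",
         vals[out_of_range[1, , drop = FALSE]], ")", call. = FALSE)
  rownames(vals) <- ids
  vals
}

#' Write a beta-value matrix
#'
#' @param beta Samples x CpG matrix with row and column names.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(beta, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Delimited text with columns `sample_id`, optionally `age`, `sex`, `group`,
#' and any further covariate columns (e.g. cell-composition fractions).
#'
#' @param path File to read.
#' @return Data frame; `age`, when present, validated numeric and `>= 0`.
#' @export
read_sample_sheet <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (!"sample_id" %in% names(df))
    stop("sample sheet needs a sample_id column", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  if ("age" %in% names(df)) {
    df$age <- as.numeric(df$age)
    if (any(!is.na(df$age) & df$age < 0))
      stop("negative age in sample sheet", call. = FALSE)
  }
  df
}

#' Read / write a clock model as JSON
#'
#' The JSON schema is `{name, cpg_ids, weights, intercept}` with weights in
#' `cpg_ids` order.
#'
#' @param path File path.
#' @return [read_clock_json()]: an [epiage_clock()].
#' @export
read_clock_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("cpg_ids", "weights", "intercept"))
    if (is.null(x[[f]])) stop("clock JSON missing field: ", f, call. = FALSE)
  epiage_clock(x$cpg_ids, x$weights, x$intercept,
               name = x$name %||% "from-json")
}

#' @rdname read_clock_json
#' @param model An [epiage_clock()].
#' @export
write_clock_json <- function(model, path) {
  stopifnot(inherits(model, "epiage_clock"))
  jsonlite::write_json(
    list(name = model$name, cpg_ids = model$cpg_ids,
         weights = unname(model$weights), intercept = model$intercept),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write paired FASTQ files
#'
#' Thin wrappers over Biostrings FASTQ IO keeping mates paired by position.
#' `.gz` paths are compressed/decompressed transparently.
#'
#' @param r1_path,r2_path FASTQ paths for read 1 and read 2.
#' @return [read_fastq_pair()]: a [read_pairs()] table.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("read 1 and read 2 FASTQ differ in read count", call. = FALSE)
  read_pairs(
    read_id = sub(" .*", "", names(r1)),
    r1_seq = as.character(r1),
    r1_qual = as.character(S4Vectors::mcols(r1)$qualities),
    r2_seq = as.character(r2),
    r2_qual = as.character(S4Vectors::mcols(r2)$qualities)
  )
}

#' @rdname read_fastq_pair
#' @param pairs A [read_pairs()] table.
#' @export
write_fastq_pair <- function(pairs, r1_path, r2_path) {
  gz1 <- grepl("\\.gz$", r1_path); gz2 <- grepl("\\.gz$", r2_path)
  s1 <- Biostrings::DNAStringSet(pairs$r1_seq)
  s2 <- Biostrings::DNAStringSet(pairs$r2_seq)
  names(s1) <- names(s2) <- pairs$read_id
  Biostrings::writeXStringSet(s1, r1_path, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$r1_qual),
                              compress = gz1)
  Biostrings::writeXStringSet(s2, r2_path, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$r2_qual),
                              compress = gz2)
  invisible(c(r1_path, r2_path))
}

#' Read a CpG annotation (BED or JSON) on amplicon coordinates
#'
#' BED: 3+ columns, 0-based half-open, optional 4th column of CpG ids.
#' JSON: `{offsets: [...], ids: [...]}` with 0-based offsets.
#'
#' @param path Annotation file; `.json` is parsed as JSON, anything else as
#'   BED.
#' @return List with `offsets` (0-based integer) and `ids` (character or
#'   `NULL`).
#' @export
read_cpg_annotation <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(x$offsets)) stop("CpG JSON missing 'offsets'", call. = FALSE)
    return(list(offsets = as.integer(x$offsets),
                ids = if (!is.null(x$ids)) as.character(x$ids) else NULL))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list(offsets = integer(0), ids = NULL))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("BED lines need at least 3 columns", call. = FALSE)
  starts <- as.integer(vapply(fields, `[[`, character(1), 2L))
  ends <- as.integer(vapply(fields, `[[`, character(1), 3L))
  if (any(is.na(starts)) || any(ends <= starts))
    stop("malformed BED intervals", call. = FALSE)
  ids <- if (all(lengths(fields) >= 4L))
    vapply(fields, `[[`, character(1), 4L) else NULL
  list(offsets = starts, ids = ids)
}

#' Write a machine-readable provenance record
#'
#' Every CLI run drops a JSON provenance record (configuration, package
#' version, R version, seed) next to its outputs.
#'
#' @param path Output JSON path.
#' @param config Named list of run configuration.
#' @return Invisibly, `path`.
#' @export
write_provenance <- function(path, config) {
  jsonlite::write_json(
    list(package = "epiage",
         version = as.character(utils::packageVersion("epiage")),
         r_version = R.version.string,
         config = config),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
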