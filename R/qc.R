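#' Per-CpG coefficient of variation across technical replicates
#'
#' CV is the sample (n-1) standard deviation of a CpG's replicate betas
#' divided by their mean, as a percent.
#'
#' @param replicate_betas Replicates x CpG numeric matrix, a `replicate_set`
#'   from [simulate_replicates()], or (with `cpg_id = NULL`) a plain numeric
#'   vector of one CpG's replicate values.
#' @param cpg_id Column to summarise when a matrix is given; `NULL` returns
#'   the CV of every column.
#' @return CV in percent (named vector over CpGs when `cpg_id` is `NULL` and
#'   the input is a matrix).
#' @export
cpg_cv <- function(replicate_betas, cpg_id = NULL) {
  if (inherits(replicate_betas, "replicate_set"))
    replicate_betas <- replicate_betas$betas
  one <- function(x) {
    if (length(x) < 2L)
      stop("need at least 2 replicates for a CV", call. = FALSE)
    m <- mean(x)
    if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
    100 * stats::sd(x) / abs(m)
  }
  if (is.null(dim(replicate_betas))) return(one(replicate_betas))
  if (!is.null(cpg_id)) {
    if (!cpg_id %in% colnames(replicate_betas))
      stop("missing site: ", cpg_id, call. = FALSE)
    return(one(replicate_betas[, cpg_id]))
  }
  apply(replicate_betas, 2L, one)
}

#' Bin a CI range into the precision grades
#'
#' Left-closed bins over the full CI width in years: `<1`, `[1,1.5)`,
#' `[1.5,2)`, `[2,3)`, `>=3` (labelled `">3"`). An exact boundary value falls
#' in the higher bin.
#'
#' @param range Non-negative CI full widths, years.
#' @return Character vector over `{"<1","1-1.5","1.5-2","2-3",">3"}`.
#' @export
ci_bin <- function(range) {
  if (any(range < 0)) stop("CI range must be >= 0", call. = FALSE)
  cut(range, breaks = c(-Inf, 1, 1.5, 2, 3, Inf), right = FALSE,
      labels = c("<1", "1-1.5", "1.5-2", "2-3", ">3")) |> as.character()
}

.ci_bin_levels <- c("<1", "1-1.5", "1.5-2", "2-3", ">3")

#' Confidence interval of mean EpiAge across technical replicates
#'
#' Mean and confidence interval of a sample's epigenetic age over repeated
#' measurements: `mean +/- q * SD / sqrt(n)` with `q` the Student-t quantile
#' `t(n-1, (1+confidence)/2)` (default) or the normal quantile. The reported
#' "CI range" is the full interval width (twice the halfwidth), binned by
#' [ci_bin()].
#'
#' @param replicate_epiages Numeric vector of per-replicate EpiAge, years
#'   (>= 2 values).
#' @param confidence Confidence level (default 0.95).
#' @param method `"t"` (Student-t, appropriate at n = 4) or `"normal"`.
#' @return List with `mean`, `sd`, `cv` (percent), `halfwidth`, `range`,
#'   `bin`, `n`, `confidence`, `method`.
#' @export
epiage_ci <- function(replicate_epiages, confidence = 0.95,
                      method = c("t", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(replicate_epiages)
  n <- length(x)
  if (n < 2L) stop("need at least 2 replicates", call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  q <- if (method == "t") stats::qt((1 + confidence) / 2, df = n - 1)
       else stats::qnorm((1 + confidence) / 2)
  half <- q * s / sqrt(n)
  list(mean = m, sd = s,
       cv = if (m != 0) 100 * s / abs(m) else NA_real_,
       halfwidth = half, range = 2 * half, bin = ci_bin(2 * half),
       n = n, confidence = confidence, method = method)
}

#' Replicate-precision summary of a cohort
#'
#' Per sample: mean, SD, CV and CI range of EpiAge across its technical
#' replicates, plus the count of samples per CI-range precision bin. EpiAges
#' are taken directly from each set when present, otherwise computed from the
#' replicate betas with `model`.
#'
#' @param sets List of `replicate_set` objects (fields `sample_id` and
#'   `betas` and/or `epiages`).
#' @param model An [epiage_clock()]; required when any set carries only
#'   betas.
#' @param confidence,method Passed to [epiage_ci()].
#' @return List with `per_sample` (data frame: `sample_id`, `n_replicates`,
#'   `mean_epiage`, `sd_epiage`, `cv_epiage`, `ci_range`, `ci_bin`) and
#'   `bin_counts` (named integer over the five bins; sums to `length(sets)`).
#' @export
summarize_replicate_cohort <- function(sets, model = NULL, confidence = 0.95,
                                       method = c("t", "normal")) {
  method <- match.arg(method)
  empty <- data.frame(sample_id = character(0), n_replicates = integer(0),
                      mean_epiage = numeric(0), sd_epiage = numeric(0),
                      cv_epiage = numeric(0), ci_range = numeric(0),
                      ci_bin = character(0), stringsAsFactors = FALSE)
  if (!length(sets))
    return(list(per_sample = empty,
                bin_counts = stats::setNames(integer(5), .ci_bin_levels)))
  rows <- lapply(sets, function(s) {
    epi <- s$epiages
    if (is.null(epi)) {
      if (is.null(model))
        stop("model required to compute EpiAge from replicate betas",
             call. = FALSE)
      epi <- predict_age(model, s$betas)
    }
    ci <- epiage_ci(epi, confidence = confidence, method = method)
    data.frame(sample_id = s$sample_id %||% NA_character_,
               n_replicates = ci$n, mean_epiage = ci$mean,
               sd_epiage = ci$sd, cv_epiage = ci$cv, ci_range = ci$range,
               ci_bin = ci$bin, stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  counts <- table(factor(per_sample$ci_bin, levels = .ci_bin_levels))
  list(per_sample = per_sample,
       bin_counts = stats::setNames(as.integer(counts), .ci_bin_levels))
}
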