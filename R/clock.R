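#' Construct an epigenetic clock model
#'
#' An `epiage_clock` is a linear model mapping methylation beta values at a
#' fixed, ordered set of CpG sites to a predicted age in years:
#' `epiage = sum(weights * beta[cpg_ids]) + intercept`. Weights are in years
#' per unit beta and are always applied in `cpg_ids` order; beta lookup is by
#' CpG id, never by column position.
#'
#' @param cpg_ids Character vector of unique CpG site identifiers.
#' @param weights Numeric vector of coefficients, one per CpG, in years per
#'   unit beta.
#' @param intercept Numeric scalar, years.
#' @param name Label for the model.
#' @return An object of class `epiage_clock`.
#' @seealso [elovl2_clock()] for the published three-CpG default.
#' @export
epiage_clock <- function(cpg_ids, weights, intercept, name = "custom") {
  cpg_ids <- as.character(cpg_ids)
  weights <- as.numeric(weights)
  if (length(weights) != length(cpg_ids))
    stop("weights and cpg_ids must have equal length", call. = FALSE)
  if (anyDuplicated(cpg_ids))
    stop("cpg_ids must be unique", call. = FALSE)
  if (length(cpg_ids) == 0L)
    stop("a clock needs at least one CpG site", call. = FALSE)
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("intercept must be a single finite number", call. = FALSE)
  structure(
    list(cpg_ids = cpg_ids, weights = stats::setNames(weights, cpg_ids),
         intercept = as.numeric(intercept), name = as.character(name)[1]),
    class = "epiage_clock"
  )
}

#' The published EpiAgePublic three-CpG ELOVL2 clock
#'
#' The packaged default clock over cg16867657, cg21572722 and cg24724428
#' (all in the ELOVL2 promoter region), with weights 122.70, 24.45 and
#' -30.44 years per unit beta and intercept -42.91 years. Beta values are
#' fractions in \[0,1\].
#'
#' @return An `epiage_clock`.
#' @examples
#' clock <- elovl2_clock()
#' predict_age(clock, c(cg16867657 = 0, cg21572722 = 0, cg24724428 = 0))
#' @export
elovl2_clock <- function() {
  epiage_clock(
    cpg_ids = c("cg16867657", "cg21572722", "cg24724428"),
    weights = c(122.70, 24.45, -30.44),
    intercept = -42.91,
    name = "EpiAgePublic"
  )
}

# Normalise beta input (named vector or matrix/data.frame with CpG columns)
# into a samples x cpg numeric matrix restricted to the model's sites, in
# model order. Errors name the first missing site.
.beta_matrix_for <- function(model, betas) {
  if (is.null(dim(betas))) {
    if (is.null(names(betas)))
      stop("betas must be named by CpG id", call. = FALSE)
    betas <- matrix(betas, nrow = 1L, dimnames = list(NULL, names(betas)))
  }
  betas <- as.matrix(betas)
  if (is.null(colnames(betas)))
    stop("beta matrix must have CpG ids as column names", call. = FALSE)
  missing <- setdiff(model$cpg_ids, colnames(betas))
  if (length(missing))
    stop("missing site: ", missing[1], call. = FALSE)
  m <- betas[, model$cpg_ids, drop = FALSE]
  storage.mode(m) <- "double"
  m
}

.check_beta_scale <- function(m, strict = TRUE) {
  finite <- m[is.finite(m)]
  if (any(finite > 1.5))
    stop("beta values above 1.5 detected; betas must be fractions in [0,1] ",
         "(percent-scale input? divide by 100)", call. = FALSE)
  if (strict && any(finite < 0 | finite > 1))
    stop("beta values outside [0,1]; pass strict = FALSE to override",
         call. = FALSE)
  invisible(m)
}

#' Predict epigenetic age from methylation beta values
#'
#' Evaluates the clock's linear formula. For the published default this is
#' `(beta_cg16867657 * 122.70 + beta_cg21572722 * 24.45 +
#' beta_cg24724428 * (-30.44)) - 42.91`. The output is not clamped: negative
#' predictions are model extrapolations and are returned as-is.
#'
#' @param model An [epiage_clock()].
#' @param betas Named numeric vector (one sample) or a samples x CpG numeric
#'   matrix / data.frame with CpG ids as column names. Every model CpG must
#'   be present and non-missing; lookup is by id, so extra columns and
#'   arbitrary column order are fine.
#' @param strict If `TRUE` (default), betas outside \[0,1\] are rejected.
#'   Values above 1.5 are always rejected as percent-scale input.
#' @return Numeric vector of predicted ages in years, named by sample when
#'   the input carries row names.
#' @export
predict_age <- function(model, betas, strict = TRUE) {
  stopifnot(inherits(model, "epiage_clock"))
  m <- .beta_matrix_for(model, betas)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1]
    miss <- model$cpg_ids[which(is.na(m[bad, ]))[1]]
    stop("missing site: ", miss, " (NA beta in sample ",
         rownames(m)[bad] %||% bad, ")", call. = FALSE)
  }
  .check_beta_scale(m, strict = strict)
  drop(m %*% model$weights) + model$intercept
}

#' @rdname predict_age
#' @param object,newdata,... `predict` method arguments; `newdata` as `betas`.
#' @export
predict.epiage_clock <- function(object, newdata, strict = TRUE, ...) {
  predict_age(object, newdata, strict = strict)
}

#' Epigenetic age acceleration
#'
#' EAA is the difference between DNA methylation age and chronological age;
#' positive values indicate accelerated epigenetic aging.
#'
#' @param epiage Predicted epigenetic age(s), years.
#' @param chronological_age Chronological age(s), years, each `>= 0`.
#' @return `epiage - chronological_age`, recycled per base arithmetic rules.
#' @export
compute_eaa <- function(epiage, chronological_age) {
  if (any(!is.na(chronological_age) & chronological_age < 0))
    stop("chronological age must be >= 0", call. = FALSE)
  epiage - chronological_age
}

#' Assign lifespan age-group labels
#'
#' Bins chronological ages into the lifespan groups used for age-acceleration
#' scatter summaries: newborns ("0", age below 1 year), then decade-style
#' brackets from 19 upward. Ages in \[1, 19) fall in no published bracket and
#' are labelled "unassigned" rather than guessed.
#'
#' @param age Numeric vector of ages in years, each `>= 0`.
#' @return Character vector over `{"0", "19-30", "31-40", "41-50", "51-60",
#'   "61-70", "71+", "unassigned"}`. Bins are left-closed: `[19,31)`,
#'   `[31,41)`, `[41,51)`, `[51,61)`, `[61,71)`, `[71,Inf)`.
#' @export
assign_age_group <- function(age) {
  if (any(!is.na(age) & age < 0))
    stop("age must be >= 0", call. = FALSE)
  out <- rep(NA_character_, length(age))
  out[which(age < 1)] <- "0"
  out[which(age >= 1 & age < 19)] <- "unassigned"
  out[which(age >= 19 & age < 31)] <- "19-30"
  out[which(age >= 31 & age < 41)] <- "31-40"
  out[which(age >= 41 & age < 51)] <- "41-50"
  out[which(age >= 51 & age < 61)] <- "51-60"
  out[which(age >= 61 & age < 71)] <- "61-70"
  out[which(age >= 71)] <- "71+"
  out
}

#' Per-sample age estimates with EAA and age group
#'
#' Convenience wrapper joining predictions to a sample sheet.
#'
#' @param model An [epiage_clock()].
#' @param betas Samples x CpG beta matrix (row names = sample ids).
#' @param samples Optional data frame with columns `sample_id` and `age`;
#'   when ages are present, EAA and age-group labels are added.
#' @param strict Passed to [predict_age()].
#' @return Data frame with columns `sample_id`, `epiage`, and (when ages are
#'   available) `eaa` and `age_group`.
#' @export
estimate_ages <- function(model, betas, samples = NULL, strict = TRUE) {
  epi <- predict_age(model, betas, strict = strict)
  ids <- rownames(as.matrix(betas)) %||% as.character(seq_along(epi))
  out <- data.frame(sample_id = ids, epiage = as.numeric(epi),
                    stringsAsFactors = FALSE)
  if (!is.null(samples) && "age" %in% names(samples)) {
    age <- samples$age[match(out$sample_id, samples$sample_id)]
    out$eaa <- compute_eaa(out$epiage, age)
    out$age_group <- assign_age_group(age)
  }
  out
}

#' @export
print.epiage_clock <- function(x, ...) {
  cat(sprintf("<epiage_clock> %s: %d CpG sites\n", x$name, length(x$cpg_ids)))
  cat(sprintf("  %s  %+9.2f y per unit beta\n", x$cpg_ids, x$weights), sep = "")
  cat(sprintf("  intercept   %+9.2f y\n", x$intercept))
  invisible(x)
}

#' @export
coef.epiage_clock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
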