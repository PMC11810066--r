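#' Refit the clock by ordinary least squares
#'
#' Fits `age ~ beta_1 + ... + beta_k` with intercept by plain OLS — no
#' regularisation, no covariates, no beta transformation; betas enter
#' untransformed exactly as the published formula uses them. The solution is
#' the unique minimiser of the residual sum of squares under a full-rank
#' design and is invariant to row order and to beta-matrix column order
#' (sites are looked up by CpG id).
#'
#' @param betas Samples x CpG numeric matrix (or data frame) of beta values
#'   with CpG ids as column names; row names identify samples.
#' @param age Numeric vector of chronological ages, one per row of `betas`.
#' @param cpg_ids CpG sites to fit; defaults to all columns of `betas`.
#' @param name Name for the refitted clock.
#' @return An object of class `c("epiage_fit", "epiage_fit_report")` with
#'   components `model` (the refitted [epiage_clock()]), `r_squared`,
#'   `pearson_r`, `mae` (years), `n`, `se` (per-coefficient standard errors,
#'   intercept first) and `fit` (the underlying `lm`).
#' @seealso [evaluate_fit()] to score a clock on (held-out) data.
#' @export
fit_clock <- function(betas, age, cpg_ids = NULL, name = "refit") {
  betas <- as.matrix(betas)
  if (is.null(cpg_ids)) cpg_ids <- colnames(betas)
  if (is.null(cpg_ids))
    stop("beta matrix must have CpG ids as column names", call. = FALSE)
  missing <- setdiff(cpg_ids, colnames(betas))
  if (length(missing))
    stop("missing site: ", missing[1], call. = FALSE)
  age <- as.numeric(age)
  if (length(age) != nrow(betas))
    stop("age must have one value per sample", call. = FALSE)
  if (anyNA(age) || anyNA(betas[, cpg_ids]))
    stop("every profile must carry age and all fitted CpG betas",
         call. = FALSE)
  p <- length(cpg_ids) + 1L   # coefficients incl. intercept
  n <- length(age)
  if (n < p + 1L)
    stop("need at least ", p + 1L, " samples to fit ", p, " coefficients",
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1, betas[, cpg_ids, drop = FALSE])
  if (qr(X)$rank < p)
    stop("degenerate design: beta columns are collinear (rank ",
         qr(X)$rank, " < ", p, ")", call. = FALSE)

  df <- data.frame(.age = age, betas[, cpg_ids, drop = FALSE],
                   check.names = FALSE)
  fit <- stats::lm(.age ~ ., data = df)
  cf <- stats::coef(fit)
  model <- epiage_clock(cpg_ids, cf[cpg_ids], cf[["(Intercept)"]],
                        name = name)

  pred <- stats::fitted(fit)
  ss_res <- sum((age - pred)^2)
  ss_tot <- sum((age - mean(age))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  pr <- if (ss_tot > 0 && stats::sd(pred) > 0) stats::cor(pred, age) else NA_real_
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))  # warns on exact fits

  structure(
    list(model = model, r_squared = r2, pearson_r = pr,
         mae = mean(abs(pred - age)), n = n,
         se = se[c("(Intercept)", cpg_ids)], fit = fit),
    class = c("epiage_fit", "epiage_fit_report")
  )
}

#' Evaluate a clock against observed ages
#'
#' Scores predictions from an existing clock on a cohort:
#' `r_squared = 1 - SS_res / SS_tot` of predicted vs observed age (which can
#' be negative for a badly mis-calibrated clock on held-out data),
#' `pearson_r` between predictions and ages, and the mean absolute error in
#' years.
#'
#' @param model An [epiage_clock()].
#' @param betas Samples x CpG beta matrix containing all model sites.
#' @param age Observed chronological ages, one per sample.
#' @return An `epiage_fit_report` with `model`, `r_squared`, `pearson_r`,
#'   `mae`, `n`.
#' @export
evaluate_fit <- function(model, betas, age) {
  stopifnot(inherits(model, "epiage_clock"))
  age <- as.numeric(age)
  if (length(age) < 2L)
    stop("r_squared undefined: need at least 2 samples", call. = FALSE)
  if (stats::sd(age) == 0)
    stop("r_squared undefined: zero variance in observed age", call. = FALSE)
  pred <- predict_age(model, betas)
  if (length(pred) != length(age))
    stop("age must have one value per sample", call. = FALSE)
  ss_res <- sum((age - pred)^2)
  ss_tot <- sum((age - mean(age))^2)
  structure(
    list(model = model, r_squared = 1 - ss_res / ss_tot,
         pearson_r = if (stats::sd(pred) > 0) stats::cor(pred, age) else NA_real_,
         mae = mean(abs(pred - age)), n = length(age)),
    class = "epiage_fit_report"
  )
}

#' @export
print.epiage_fit_report <- function(x, ...) {
  cat(sprintf("<%s> clock '%s' on n = %d samples\n",
              class(x)[1], x$model$name, x$n))
  cat(sprintf("  R-squared %.4f | Pearson r %s | MAE %.2f y\n",
              x$r_squared,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.4f", x$pearson_r),
              x$mae))
  invisible(x)
}

#' @export
coef.epiage_fit <- function(object, ...) coef(object$model)

#' @export
predict.epiage_fit <- function(object, newdata, ...) {
  predict_age(object$model, newdata, ...)
}

#' @export
summary.epiage_fit <- function(object, ...) {
  tab <- data.frame(
    term = names(object$se),
    estimate = coef(object$model)[names(object$se)],
    se = object$se,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 mae = object$mae, n = object$n,
                 name = object$model$name),
            class = "summary.epiage_fit")
}

#' @export
print.summary.epiage_fit <- function(x, ...) {
  cat(sprintf("OLS clock refit '%s' (n = %d)\n", x$name, x$n))
  print(x$coefficients, digits = 6)
  cat(sprintf("R-squared %.4f, MAE %.2f y\n", x$r_squared, x$mae))
  invisible(x)
}
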