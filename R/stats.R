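#' Two-group comparison with normality screening
#'
#' Compares two groups of EAA (or any continuous) values. Unless
#' `force_test` is given, a Shapiro-Wilk screen at alpha = 0.05 on each
#' group selects the test: both groups pass, an unpaired (or paired)
#' two-tailed t-test; otherwise a two-tailed Mann-Whitney U (Wilcoxon)
#' test. Groups too small to screen (n < 3) default to the t-test.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @param paired Paired comparison (requires equal lengths).
#' @param force_test `"t"` or `"mann-whitney"` to bypass the screen.
#' @return A `group_comparison` list: `test`, `statistic`, `p_value`,
#'   `mean_difference` (`mean(a) - mean(b)`), `n` (per group),
#'   `shapiro_p` (screen p-values, `NA` when skipped).
#' @export
compare_groups <- function(a, b, paired = FALSE, force_test = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal group sizes", call. = FALSE)
  shap <- c(a = NA_real_, b = NA_real_)
  if (is.null(force_test)) {
    screen <- function(x) {
      if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
      stats::shapiro.test(x)$p.value
    }
    shap <- c(a = screen(a), b = screen(b))
    normal <- all(is.na(shap) | shap > 0.05)
    test <- if (normal) "t" else "mann-whitney"
  } else {
    test <- match.arg(force_test, c("t", "mann-whitney"))
  }
  res <- if (test == "t")
    stats::t.test(a, b, paired = paired, alternative = "two.sided")
  else
    suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                        alternative = "two.sided"))
  structure(
    list(test = test, statistic = unname(res$statistic),
         p_value = res$p.value, mean_difference = mean(a) - mean(b),
         n = c(a = length(a), b = length(b)), shapiro_p = shap),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s test: statistic %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  cat(sprintf("  mean difference (a - b) %.4g y; n = %d vs %d\n",
              x$mean_difference, x$n[1], x$n[2]))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors, n >= 4, each with nonzero variance.
#' @param confidence Confidence level for the Fisher z-transform interval.
#' @return List with `r`, `ci_low`, `ci_high`, `p` (two-tailed), `n`.
#' @export
pearson_with_ci <- function(x, y, confidence = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must match in length", call. = FALSE)
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = confidence)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], p = ct$p.value, n = length(x))
}

#' ROC analysis with sensitivity at full specificity
#'
#' AUC by the Mann-Whitney identity (probability a random case scores beyond
#' a random control, ties counting one half). The case-enriched direction is
#' auto-detected (AUC >= 0.5) and recorded; the reported sensitivity at 100%
#' specificity is the fraction of cases strictly beyond the most extreme
#' control on that side, with the control extremum as the threshold. The
#' p-value for AUC = 0.5 is the two-sided Mann-Whitney p (normal
#' approximation under ties), labelled as such.
#'
#' @param scores_cases,scores_controls Numeric score vectors, both non-empty.
#' @return A `roc_result` list: `auc`, `sensitivity_at_full_specificity`,
#'   `threshold`, `direction` (`"cases-high"` / `"cases-low"`), `p_value`,
#'   `p_method`, `n`.
#' @export
roc_analysis <- function(scores_cases, scores_controls) {
  ca <- as.numeric(scores_cases); co <- as.numeric(scores_controls)
  if (!length(ca) || !length(co)) stop("empty group", call. = FALSE)
  n1 <- length(ca); n0 <- length(co)
  r <- rank(c(ca, co))
  auc_high <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc_high >= 0.5) {
    direction <- "cases-high"
    auc <- auc_high
    threshold <- max(co)
    sens <- mean(ca > threshold)
  } else {
    direction <- "cases-low"
    auc <- 1 - auc_high
    threshold <- min(co)
    sens <- mean(ca < threshold)
  }
  p <- suppressWarnings(stats::wilcox.test(ca, co)$p.value)
  structure(
    list(auc = auc, sensitivity_at_full_specificity = sens,
         threshold = threshold, direction = direction, p_value = p,
         p_method = "mann-whitney (normal approximation under ties)",
         n = c(cases = n1, controls = n0)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%s), sensitivity %.2f%% at 100%% specificity (threshold %.4g), p = %.4g\n",
              x$auc, x$direction, 100 * x$sensitivity_at_full_specificity,
              x$threshold, x$p_value))
  invisible(x)
}

#' Covariate-adjusted association by multiple linear regression
#'
#' OLS of `outcome ~ predictor + covariates` with intercept; per-term
#' two-tailed t-test p-values. Used to re-test clock associations while
#' controlling for cell-composition fractions, sex and similar confounders.
#'
#' @param outcome Numeric response (e.g. EAA).
#' @param predictor Numeric predictor of interest.
#' @param covariates Optional data frame of additional numeric/factor
#'   covariates.
#' @param predictor_name Label for the predictor term.
#' @return An `adjusted_association`: data frame with `term`, `estimate`,
#'   `se`, `t`, `p`, plus attributes `n` and `r_squared`.
#' @export
covariate_adjusted_association <- function(outcome, predictor,
                                           covariates = NULL,
                                           predictor_name = "predictor") {
  df <- data.frame(.outcome = as.numeric(outcome),
                   .predictor = as.numeric(predictor))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(df))
      stop("covariates must have one row per observation", call. = FALSE)
    df <- cbind(df, covariates)
  }
  n_terms <- ncol(df)  # predictor + covariates + intercept ~ outcome
  if (nrow(df) <= n_terms + 1L)
    stop("need n > number of terms + 1", call. = FALSE)
  X <- stats::model.matrix(.outcome ~ ., data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(.outcome ~ ., data = df)
  fit_summary <- suppressWarnings(summary(fit))  # warns on exact fits
  sm <- fit_summary$coefficients
  terms <- rownames(sm)
  terms[terms == ".predictor"] <- predictor_name
  out <- data.frame(term = terms, estimate = sm[, 1], se = sm[, 2],
                    t = sm[, 3], p = sm[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(df)
  attr(out, "r_squared") <- fit_summary$r.squared
  class(out) <- c("adjusted_association", "data.frame")
  out
}

#' Bin scores into labelled categories
#'
#' The `"stress"` preset maps perceived-stress scores (integers 0-15) to
#' severity groups: 0 = NoStress, 1-4 = Low, 5-7 = Moderate, 8-10 = High,
#' 11-15 = Severe. Custom left-closed bins are available via `edges`.
#'
#' @param scores Numeric scores.
#' @param preset `"stress"` or `"custom"`.
#' @param edges For `"custom"`: increasing break points (left-closed bins,
#'   as in `cut(right = FALSE)` including both boundaries).
#' @param labels For `"custom"`: one label per bin.
#' @return Character vector of labels.
#' @export
bin_scores <- function(scores, preset = c("stress", "custom"), edges = NULL,
                       labels = NULL) {
  preset <- match.arg(preset)
  if (preset == "stress") {
    s <- as.numeric(scores)
    if (any(is.na(s)) || any(s != round(s)) || any(s < 0 | s > 15))
      stop("stress scores must be integers in 0..15", call. = FALSE)
    out <- character(length(s))
    out[s == 0] <- "NoStress"
    out[s >= 1 & s <= 4] <- "Low"
    out[s >= 5 & s <= 7] <- "Moderate"
    out[s >= 8 & s <= 10] <- "High"
    out[s >= 11] <- "Severe"
    return(out)
  }
  if (is.null(edges) || is.null(labels) || length(labels) != length(edges) - 1L)
    stop("custom binning needs edges and length(edges) - 1 labels",
         call. = FALSE)
  if (any(scores < edges[1] | scores > edges[length(edges)]))
    stop("score outside the binning domain", call. = FALSE)
  as.character(cut(scores, breaks = edges, labels = labels, right = FALSE,
                   include.lowest = TRUE))
}

#' One-way ANOVA with Dunnett contrasts against a reference group
#'
#' Ordinary one-way ANOVA across groups followed by Dunnett's multiple
#' comparisons of every group against the reference (the design used for
#' stress-level group analyses). Repeated-measures ANOVA with sphericity
#' correction is out of scope.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @param reference Reference level compared against (default: first level).
#' @return List with `anova_p` (overall F-test p), `dunnett` (data frame of
#'   contrast estimates, SE, adjusted p).
#' @export
anova_dunnett <- function(values, groups, reference = NULL) {
  g <- factor(groups)
  if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  df <- data.frame(y = as.numeric(values), g = g)
  fit <- stats::aov(y ~ g, data = df)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(glht)
  list(anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
       dunnett = data.frame(contrast = names(sm$test$coefficients),
                            estimate = unname(sm$test$coefficients),
                            se = unname(sm$test$sigma),
                            p_adjusted = unname(sm$test$pvalues),
                            stringsAsFactors = FALSE))
}
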