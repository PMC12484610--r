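#' Welch two-sample t-test
#'
#' Two-sided Welch test with the Welch-Satterthwaite (fractional) degrees
#' of freedom, as used throughout treatment-vs-control comparisons. Thin
#' wrapper over [stats::t.test()] with explicit handling of the degenerate
#' zero-variance cases: both groups constant and equal gives `t = 0, p = 1`;
#' both constant and unequal gives `p = 0` with a warning.
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @return List of class `welch_result` with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    gm_stop("each group needs at least 2 values")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 1),
                       class = "welch_result"))
    }
    gm_warn("both groups have zero variance with unequal means; p = 0")
    return(structure(list(t = sign(mean(x) - mean(y)) * Inf,
                          df = length(x) + length(y) - 2, p = 0),
                     class = "welch_result"))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat("Welch two-sample t-test: t = ", format(x$t, digits = 5),
      ", df = ", format(x$df, digits = 5), ", p = ",
      format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons with studentized-range adjusted p-values using the
#' pooled within-group variance (Tukey-Kramer for unequal group sizes), via
#' [stats::aov()] + [stats::TukeyHSD()].
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; at least 2 groups with at
#'   least 2 values each.
#' @return Data frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`
#'   (one row per unordered pair).
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) gm_stop("at least 2 groups required")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    gm_stop("group(s) with fewer than 2 values: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  fit <- stats::aov(values ~ groups, data = data.frame(values = values,
                                                       groups = groups))
  td <- stats::TukeyHSD(fit)$groups
  data.frame(comparison = rownames(td), diff = td[, "diff"],
             lwr = td[, "lwr"], upr = td[, "upr"], p_adj = td[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fluorescence-to-cell-count standard curve
#'
#' Ordinary least-squares line relating plate-reader fluorescence to known
#' seeded cell counts, used to convert transwell-migration fluorescence
#' readings into migrated cell numbers.
#'
#' @param fluorescence Calibration fluorescence readings (>= 3 points, not
#'   all equal).
#' @param cell_counts Matching known cell counts (>= 0).
#' @return List of class `standard_curve` with `slope` (cells per
#'   fluorescence unit), `intercept` (cells), `r_squared`.
#' @export
fit_standard_curve <- function(fluorescence, cell_counts) {
  if (length(fluorescence) < 3L || length(cell_counts) != length(fluorescence)) {
    gm_stop("at least 3 matched calibration points required")
  }
  if (any(cell_counts < 0)) gm_stop("cell counts must be >= 0")
  if (stats::sd(fluorescence) == 0) {
    gm_stop("constant fluorescence across calibration points; slope undefined")
  }
  fit <- stats::lm(cell_counts ~ fluorescence)
  tss <- sum((cell_counts - mean(cell_counts))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = min(max(r2, 0), 1)),
            class = "standard_curve")
}

#' Convert fluorescence readings to cell counts via a standard curve
#'
#' Applies the fitted line and clips predictions at zero (a reading below
#' the zero-count intercept cannot mean negative cells).
#'
#' @param curve A [fit_standard_curve()] result.
#' @param fluorescence Fluorescence reading(s).
#' @return Predicted cell count(s), >= 0.
#' @export
predict_cell_count <- function(curve, fluorescence) {
  stopifnot(inherits(curve, "standard_curve"))
  pmax(0, curve$intercept + curve$slope * fluorescence)
}
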