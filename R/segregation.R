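#' Observed class-count table
#'
#' @param class character vector of class labels (>= 2).
#' @param observed non-negative integer counts.
#' @param ratio theoretical expected ratio (e.g. \code{c(1, 2, 1)}), or NULL
#'   when probabilities are given directly.
#' @param prob expected class probabilities summing to 1 (alternative to
#'   \code{ratio}).
#' @return A \code{"class_count_table"} data frame with columns \code{class},
#'   \code{observed} and \code{expected_prob}.
#' @examples
#' class_count_table(c("large", "small"), c(134, 52), ratio = c(3, 1))
#' @export
class_count_table <- function(class, observed, ratio = NULL, prob = NULL) {
  if (length(class) < 2L)
    abort("a class-count table needs at least two classes",
          "seglethal_invalid_table")
  if (length(observed) != length(class) || any(observed < 0) ||
      any(observed != round(observed)))
    abort("observed counts must be non-negative integers, one per class",
          "seglethal_invalid_table")
  if (is.null(prob)) {
    if (is.null(ratio))
      abort("either ratio or prob must be given", "seglethal_invalid_table")
    if (length(ratio) != length(class) || any(ratio <= 0))
      abort("expected ratio entries must be positive", "seglethal_invalid_table")
    prob <- ratio / sum(ratio)
  } else {
    if (length(prob) != length(class) || any(prob < 0) ||
        abs(sum(prob) - 1) > 1e-8)
      abort("expected probabilities must be non-negative and sum to 1",
            "seglethal_invalid_table")
  }
  structure(data.frame(class = class, observed = as.integer(observed),
                       expected_prob = prob, stringsAsFactors = FALSE),
            class = c("class_count_table", "data.frame"))
}

#' Bracket an exact p-value on a 0.05 grid
#'
#' Reports \code{"0.35 < P < 0.40"}-style brackets alongside the exact
#' p-value, the presentation convention of classical segregation tables.
#' @param p exact p-value.
#' @return A single character string.
#' @export
bracket_p <- function(p) {
  if (p < 0.05) return("P < 0.05")
  if (p > 0.95) return("P > 0.95")
  lo <- floor(p / 0.05) * 0.05
  sprintf("%.2f < P < %.2f", lo, lo + 0.05)
}

#' Chi-square goodness-of-fit test of segregation counts
#'
#' Pearson chi-square of observed class counts against expected counts
#' \code{n * prob}, without continuity correction. Degrees of freedom default
#' to classes - 1; pass \code{df} to subtract estimated parameters.
#'
#' @param table a \code{\link{class_count_table}}.
#' @param df degrees-of-freedom override.
#' @return A \code{"gof_result"} list: \code{statistic}, \code{df}, \code{p},
#'   \code{p_bracket}, per-class \code{contributions}, \code{n}.
#' @examples
#' tab <- class_count_table(c("large", "small"), c(134, 52), ratio = c(3, 1))
#' chi_square_gof(tab)  # statistic 0.87, df 1
#' @export
chi_square_gof <- function(table, df = NULL) {
  n <- sum(table$observed)
  if (n <= 0) abort("total observed count must be positive",
                    "seglethal_empty_class")
  expected <- n * table$expected_prob
  if (any(expected == 0))
    abort("zero expected count: degenerate expectation",
          "seglethal_degenerate_expectation")
  contrib <- (table$observed - expected)^2 / expected
  stat <- sum(contrib)
  if (is.null(df)) df <- nrow(table) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p, p_bracket = bracket_p(p),
                 contributions = stats::setNames(contrib, table$class),
                 expected = stats::setNames(expected, table$class), n = n),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Chi-square = %.2f, df = %d, %s (exact P = %.4g), n = %d\n",
              x$statistic, x$df, x$p_bracket, x$p, x$n))
  invisible(x)
}

#' Threshold rule for continuous traits
#'
#' Half-open intervals \code{[low, high)} defined by strictly increasing cut
#' points; one label per interval. Optional outer \code{bounds} restrict the
#' classified range, in which case out-of-range values are counted separately
#' by \code{\link{classify_counts}} rather than silently dropped.
#'
#' @param trait trait name.
#' @param cuts strictly increasing interior cut points.
#' @param labels one label per interval (\code{length(cuts) + 1}).
#' @param bounds optional c(low, high) outer limits.
#' @return A \code{"threshold_rule"}.
#' @examples
#' grain_threshold_rule()
#' @export
threshold_rule <- function(trait, cuts, labels, bounds = c(-Inf, Inf)) {
  if (is.unsorted(cuts, strictly = TRUE))
    abort("cut points must be strictly increasing", "seglethal_invalid_rule")
  if (length(labels) != length(cuts) + 1L)
    abort("need one label per interval", "seglethal_invalid_rule")
  if (anyDuplicated(labels))
    abort("class labels must be unique", "seglethal_invalid_rule")
  structure(list(trait = trait, cuts = cuts, labels = labels, bounds = bounds),
            class = "threshold_rule")
}

#' Default grain-area threshold rule
#'
#' Cut points at the midpoints between the default class means of
#' \code{\link{phenotype_model}} (small 20.0, medium 22.0, large 24.6 mm^2):
#' 21.0 and 23.3 mm^2.
#' @return A \code{"threshold_rule"} with classes small/medium/large.
#' @export
grain_threshold_rule <- function()
  threshold_rule("grain_area", c(21.0, 23.3), c("small", "medium", "large"))

#' Count trait measurements into threshold classes
#'
#' @param values numeric trait measurements (finite).
#' @param rule a \code{\link{threshold_rule}}.
#' @param ratio optional expected ratio attached to the resulting table.
#' @return A \code{\link{class_count_table}} (expected probabilities uniform
#'   unless \code{ratio} given) with attribute \code{n_outside}, the number of
#'   values outside the rule's bounds.
#' @examples
#' classify_counts(c(20.1, 22.3, 24.9, 21.9), grain_threshold_rule(),
#'                 ratio = c(1, 2, 1))
#' @export
classify_counts <- function(values, rule, ratio = NULL) {
  if (any(!is.finite(values)))
    abort("trait values must be finite", "seglethal_invalid_table")
  inside <- values >= rule$bounds[1] & values < rule$bounds[2]
  idx <- findInterval(values[inside], rule$cuts) + 1L
  counts <- tabulate(idx, nbins = length(rule$labels))
  tab <- class_count_table(rule$labels, counts,
                           ratio = ratio,
                           prob = if (is.null(ratio))
                             rep(1 / length(rule$labels), length(rule$labels)))
  attr(tab, "n_outside") <- sum(!inside)
  attr(tab, "outside_values") <- values[!inside]
  tab
}

#' Test observed counts against a transmission-model expectation
#'
#' Convenience wrapper: derives expected class probabilities from a cross
#' design via \code{\link{expected_class_probabilities}} and runs the
#' chi-square test. Observed classes must be a subset of the classifier's
#' labels; classifier classes with no observed entry contribute observed 0.
#'
#' @param observed a \code{\link{class_count_table}} (its expected column is
#'   ignored) or a named vector of counts.
#' @param cross a \code{\link{cross_design}} or \code{"zygote_dist"}.
#' @param classifier a \code{"phenotype_classifier"}.
#' @param df degrees-of-freedom override.
#' @return A \code{"gof_result"}.
#' @examples
#' fit_vs_model(c(semidwarf = 11, partially_sterile = 26, long_culm = 75),
#'              design_bc1f2(), culm_classifier())  # chi-square 0.22
#' @export
fit_vs_model <- function(observed, cross, classifier, df = NULL) {
  if (inherits(observed, "class_count_table"))
    observed <- stats::setNames(observed$observed, observed$class)
  exp_p <- expected_class_probabilities(cross, classifier)
  bad <- setdiff(names(observed), exp_p$class)
  if (length(bad))
    abort(sprintf("observed class(es) %s not produced by the classifier",
                  paste(bad, collapse = ", ")), "seglethal_classification")
  obs <- stats::setNames(rep(0L, nrow(exp_p)), exp_p$class)
  obs[names(observed)] <- observed
  keep <- exp_p$prob > 0 | obs > 0
  chi_square_gof(class_count_table(exp_p$class[keep], obs[keep],
                                   prob = exp_p$prob[keep] /
                                     sum(exp_p$prob[keep])),
                 df = df)
}
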