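# Significance testing as reported in the assay figures: two-sample
# t-tests with */** star annotation at 0.05 / 0.01.

#' Two-sample t-test with star annotation
#'
#' Two-sided two-sample t-test, pooled-variance by default (the classic
#' equal-variance test); `variant = "welch"` switches to the
#' unequal-variance form. The degenerate case of zero pooled variance is
#' handled explicitly: equal means give `t = 0, p = 1`, unequal means
#' `t = Inf` (signed), `p = 0`.
#'
#' @param a,b numeric sample vectors (each of length >= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A one-row tibble of class `comparison_result`: `t`, `df`,
#'   `p`, `stars`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' two_sample_t_test(c(1, 2, 3), c(11, 12, 13))
two_sample_t_test <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) {
    abort_validation("each sample needs at least 2 values")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort_validation("samples must be finite")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(
      statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
      parameter = length(a) + length(b) - 2,
      p.value = if (equal) 1 else 0
    )
  } else {
    res <- t.test(a, b, var.equal = (variant == "pooled"))
  }
  p <- unname(res$p.value)
  out <- tibble(
    t = unname(res$statistic),
    df = unname(res$parameter),
    p = p,
    stars = annotate_stars(p),
    mean_a = mean(a),
    mean_b = mean(b)
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Star annotation of a p value
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise (strict
#' inequalities).
#'
#' @param p p value(s) in \[0, 1\].
#' @return Character vector of star strings.
#' @export
#' @examples
#' annotate_stars(c(0.5, 0.04, 0.009))  # "", "*", "**"
annotate_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_validation("`p` must lie in [0, 1]")
  }
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Annotate pairwise comparisons of a summary table
#'
#' Runs [two_sample_t_test()] between a reference group and every other
#' group of per-replicate values.
#'
#' @param values data frame with a numeric `value` column and a `group`
#'   column.
#' @param reference reference group label.
#' @param variant passed to [two_sample_t_test()].
#' @return Tibble with `group`, `t`, `df`, `p`, `stars`.
#' @export
compare_to_reference <- function(values, reference, variant = "pooled") {
  if (!all(c("value", "group") %in% names(values))) {
    abort_validation("`values` needs `value` and `group` columns")
  }
  if (!reference %in% values$group) {
    abort_config(sprintf("reference group '%s' not present", reference))
  }
  ref <- values$value[values$group == reference]
  others <- setdiff(unique(values$group), reference)
  dplyr::bind_rows(lapply(others, function(g) {
    res <- two_sample_t_test(values$value[values$group == g], ref,
                             variant = variant)
    tibble(group = g, t = res$t, df = res$df, p = res$p, stars = res$stars)
  }))
}
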