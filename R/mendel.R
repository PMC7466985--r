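# Mendelian segregation analysis: chi-square goodness of fit of two
# phenotype classes against an expected ratio, with the Yates continuity
# correction that segregation tables in the crop-genetics literature use.

#' Chi-square test of a two-class segregation ratio
#'
#' Tests observed counts of two phenotype classes (wild-type-like vs
#' mutant-like) against an expected Mendelian ratio `a:b`. By default the
#' Yates continuity correction is applied:
#' `chi2 = sum((max(|O - E| - 0.5, 0))^2 / E)` with df = 1. The verdict is
#' "fits" when `chi2 < qchisq(0.95, 1) = 3.84`.
#'
#' @param n_class_a,n_class_b Non-negative observed counts (class a first,
#'   e.g. wild-type-like; total must be >= 1).
#' @param ratio Expected ratio as `c(a, b)` (default `c(3, 1)` for an F2
#'   recessive segregation; use `c(1, 1)` for a backcross).
#' @param correct Apply the Yates continuity correction (default TRUE).
#' @param cross Optional label for the cross.
#' @return An object of class `seg_test` with fields `observed`, `expected`,
#'   `ratio`, `chi2`, `df`, `p_value`, `verdict`, `ratio_ab`, `correct`,
#'   `cross`. Methods: [tidy.seg_test()], [glance.seg_test()], `print`.
#' @export
#' @examples
#' chi_square_segregation(719, 208, ratio = c(3, 1))  # chi2 = 3.11
#' chi_square_segregation(75, 84, ratio = c(1, 1))    # chi2 = 0.40
chi_square_segregation <- function(n_class_a, n_class_b, ratio = c(3, 1),
                                   correct = TRUE, cross = NA_character_) {
  obs <- c(n_class_a, n_class_b)
  if (any(obs < 0) || any(obs != floor(obs))) {
    abort("counts must be non-negative integers")
  }
  total <- sum(obs)
  if (total < 1) abort("total count must be >= 1")
  if (length(ratio) != 2 || any(ratio <= 0)) {
    abort("`ratio` must be two positive numbers (a, b)")
  }
  expected <- total * ratio / sum(ratio)
  dev <- abs(obs - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(
    list(observed = obs, expected = expected, ratio = ratio,
         chi2 = chi2, df = 1L, p_value = p,
         verdict = if (chi2 < qchisq(0.95, 1)) "fits" else "deviates",
         ratio_ab = if (obs[2] > 0) obs[1] / obs[2] else NA_real_,
         correct = correct, cross = cross),
    class = "seg_test"
  )
}

#' Observed segregation ratio
#'
#' @param n_class_a,n_class_b Observed counts; `n_class_b` must be > 0.
#' @return `n_class_a / n_class_b`.
#' @export
#' @examples
#' segregation_ratio(261, 85)  # 3.07
segregation_ratio <- function(n_class_a, n_class_b) {
  if (any(n_class_b <= 0)) abort("class-b count must be > 0 to form a ratio")
  n_class_a / n_class_b
}

#' Segregation tests over a table of crosses
#'
#' Data-frame-first convenience: one chi-square segregation test per row.
#'
#' @param data A data frame of observed counts.
#' @param a_col,b_col Column names holding the class-a / class-b counts.
#' @param ratio_col Optional column holding the expected ratio as a string
#'   `"a:b"`; `ratio` is used for all rows when absent.
#' @param ratio Fallback expected ratio.
#' @param cross_col Optional column with cross labels.
#' @param correct Apply the continuity correction.
#' @return A tibble with one tidied test per row (see [tidy.seg_test()]).
#' @export
segregation_table <- function(data, a_col = "n_class_a", b_col = "n_class_b",
                              ratio_col = NULL, ratio = c(3, 1),
                              cross_col = NULL, correct = TRUE) {
  data <- as_tibble(data)
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    r <- if (!is.null(ratio_col)) {
      as.numeric(strsplit(data[[ratio_col]][i], ":")[[1]])
    } else ratio
    lbl <- if (!is.null(cross_col)) data[[cross_col]][i] else NA_character_
    tidy(chi_square_segregation(data[[a_col]][i], data[[b_col]][i],
                                ratio = r, correct = correct, cross = lbl))
  })
}

#' Tidy a segregation test
#'
#' @param x A `seg_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `cross`, `n_class_a`, `n_class_b`, `total`,
#'   `ratio_ab`, `expected`, `statistic`, `df`, `p.value`, `verdict`.
#' @export
tidy.seg_test <- function(x, ...) {
  tibble(
    cross = x$cross,
    n_class_a = x$observed[1], n_class_b = x$observed[2],
    total = sum(x$observed),
    ratio_ab = x$ratio_ab,
    expected = paste0(x$ratio[1], ":", x$ratio[2]),
    statistic = x$chi2, df = x$df, p.value = x$p_value,
    verdict = x$verdict
  )
}

#' Glance at a segregation test
#'
#' @param x A `seg_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `verdict`.
#' @export
glance.seg_test <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p_value,
         verdict = x$verdict)
}

#' @export
print.seg_test <- function(x, ...) {
  cat(sprintf(
    "Segregation test%s: %d : %d vs %s:%s -> chi2 = %.2f (df 1), P = %.3f [%s]\n",
    if (is.na(x$cross)) "" else paste0(" (", x$cross, ")"),
    x$observed[1], x$observed[2], x$ratio[1], x$ratio[2],
    x$chi2, x$p_value, x$verdict))
  invisible(x)
}

#' Turn a fitted object into a tidy tibble
#'
#' Generic in the style of broom; this package provides methods for its own
#' result objects.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' Generic in the style of broom.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @importFrom stats qchisq
NULL
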