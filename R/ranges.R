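#' Bounded parameter range
#'
#' Most model inputs (failure probabilities, failure trajectory costs, cohort
#' complication rates) are published as bounded ranges rather than point
#' estimates. A `bounded_range` holds the two bounds plus an `open_upper`
#' marker for ranges quoted with a trailing "+" (e.g. the catastrophic cost
#' tier, "$800,000--$1,000,000+"). The marker affects display only;
#' deterministic arithmetic and Monte Carlo sampling use `upper` as the
#' numeric bound.
#'
#' @param lower,upper Numeric scalars, `lower <= upper`.
#' @param open_upper Logical; `TRUE` when the published range is open above.
#' @return An object of class `bounded_range`.
#' @examples
#' bounded_range(0.15, 0.25)
#' bounded_range(800000, 1000000, open_upper = TRUE)
#' @export
bounded_range <- function(lower, upper, open_upper = FALSE) {
  if (!is.numeric(lower) || length(lower) != 1L || is.na(lower)) {
    stop("`lower` must be a single non-missing number", call. = FALSE)
  }
  if (!is.numeric(upper) || length(upper) != 1L || is.na(upper)) {
    stop("`upper` must be a single non-missing number", call. = FALSE)
  }
  if (lower > upper) {
    stop("`lower` (", lower, ") must not exceed `upper` (", upper, ")",
         call. = FALSE)
  }
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper),
         open_upper = isTRUE(open_upper)),
    class = "bounded_range"
  )
}

#' Coerce to a bounded range
#'
#' Accepts an existing `bounded_range`, a length-2 numeric `c(lower, upper)`,
#' a single number (degenerate point range), or a list with `lower`/`upper`
#' fields (as produced by config deserialization).
#'
#' @param x Object to coerce.
#' @return A `bounded_range`.
#' @export
as_bounded_range <- function(x) {
  if (inherits(x, "bounded_range")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(bounded_range(x[[1L]], x[[2L]]))
  if (is.numeric(x) && length(x) == 1L) return(bounded_range(x, x))
  if (is.list(x) && all(c("lower", "upper") %in% names(x))) {
    return(bounded_range(x$lower, x$upper, isTRUE(x$open_upper)))
  }
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a bounded range", call. = FALSE)
}

#' Midpoint of a bounded range
#'
#' Exact arithmetic mean of the two bounds, no rounding. For the open-ended
#' catastrophic cost tier the nominal upper bound is used, so its midpoint is
#' $900,000.
#'
#' @param x A [bounded_range()] or anything [as_bounded_range()] accepts.
#' @return Numeric scalar.
#' @export
midpoint <- function(x) {
  x <- as_bounded_range(x)
  (x$lower + x$upper) / 2
}

#' Resolve a bounded range to a point value under a bound policy
#'
#' The recommended convention is the midpoint for typical cases, the upper
#' bound when high-risk features cluster, and the lower bound for borderline
#' presentations. Explicit values are supplied through the `override`
#' arguments of [resolve_probabilities()] / [resolve_cost()], not here.
#'
#' @param x A bounded range (or coercible).
#' @param policy One of `"midpoint"`, `"lower"`, `"upper"`.
#' @return Numeric scalar.
#' @export
resolve_bound <- function(x, policy = c("midpoint", "lower", "upper")) {
  x <- as_bounded_range(x)
  policy <- match.arg(policy)
  switch(policy,
    lower = x$lower,
    upper = x$upper,
    midpoint = midpoint(x)
  )
}

#' @export
format.bounded_range <- function(x, ...) {
  paste0("[", format(x$lower, big.mark = ",", scientific = FALSE), ", ",
         format(x$upper, big.mark = ",", scientific = FALSE),
         if (x$open_upper) "+" else "", "]")
}

#' @export
print.bounded_range <- function(x, ...) {
  cat("<bounded_range> ", format(x), "\n", sep = "")
  invisible(x)
}

# warn (never fail) when an explicit override falls outside its published
# range -- actual costs and rates vary by year, geography and payer mix
warn_if_outside <- function(value, range, what) {
  range <- as_bounded_range(range)
  if (value < range$lower || value > range$upper) {
    warning(sprintf("explicit %s (%s) lies outside the published range %s",
                    what, format(value, big.mark = ","), format(range)),
            call. = FALSE)
  }
  invisible(value)
}
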