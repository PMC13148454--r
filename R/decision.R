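#' Decision inputs
#'
#' Bundle and validate the point inputs of the expected-value comparison
#' between routine closure (S1) and definitive reconstruction (S2):
#' incremental reconstruction cost `delta_c` (facility/operative; physician
#' professional fees are structurally excluded -- no field exists for them),
#' failure probabilities `p1` (routine closure) and `p2` (reconstruction),
#' failure trajectory cost `c`, and an optional baseline episode cost `c0`
#' that shifts both expected totals equally and cancels from the comparison.
#'
#' @param delta_c Incremental reconstruction cost in USD, `>= 0`.
#' @param p1,p2 Failure probabilities with `0 <= p2 < p1 <= 1`.
#' @param c Failure trajectory cost in USD, `>= 0`.
#' @param c0 Baseline episode cost in USD (default 0).
#' @return A `decision_inputs` list.
#' @export
decision_inputs <- function(delta_c, p1, p2, c, c0 = 0) {
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      stop("`", what, "` must be a single non-missing number", call. = FALSE)
    }
    as.numeric(x)
  }
  delta_c <- num1(delta_c, "delta_c"); p1 <- num1(p1, "p1")
  p2 <- num1(p2, "p2"); c <- num1(c, "c"); c0 <- num1(c0, "c0")
  if (delta_c < 0) stop("`delta_c` must be non-negative", call. = FALSE)
  if (c < 0) stop("`c` must be non-negative", call. = FALSE)
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p2 >= p1) {
    stop("`p2` must be strictly below `p1`: no absolute risk reduction",
         call. = FALSE)
  }
  structure(list(delta_c = delta_c, p1 = p1, p2 = p2, c = c, c0 = c0),
            class = "decision_inputs")
}

#' Expected total episode costs under both strategies
#'
#' E\[Cost | S1\] = C0 + P1 x C for routine closure and
#' E\[Cost | S2\] = C0 + dC + P2 x C for definitive reconstruction. The
#' difference S2 - S1 equals dC - dP x C regardless of C0.
#'
#' @param inputs A [decision_inputs()].
#' @return Named numeric vector `c(s1 = , s2 = )` in USD.
#' @examples
#' expected_costs(decision_inputs(50000, 0.20, 0.07, 600000))
#' @export
expected_costs <- function(inputs) {
  stopifnot(inherits(inputs, "decision_inputs"))
  c(s1 = inputs$c0 + inputs$p1 * inputs$c,
    s2 = inputs$c0 + inputs$delta_c + inputs$p2 * inputs$c)
}

#' Decision threshold dP x C
#'
#' The maximum incremental reconstruction cost justified on expected-value
#' grounds: reconstruction is favored exactly when dC < (P1 - P2) x C.
#'
#' @param p1,p2 Failure probabilities with `0 <= p2 <= p1 <= 1`.
#' @param c Failure trajectory cost in USD, `>= 0`.
#' @return Threshold in USD, computed exactly as `(p1 - p2) * c`.
#' @examples
#' decision_threshold(0.07, 0.04, 175000)  # 5250
#' decision_threshold(0.20, 0.07, 600000)  # 78000
#' @export
decision_threshold <- function(p1, p2, c) {
  if (any(p1 < 0) || any(p1 > 1) || any(p2 < 0) || any(p2 > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p2 > p1)) stop("`p2` must not exceed `p1`", call. = FALSE)
  if (any(c < 0)) stop("`c` must be non-negative", call. = FALSE)
  (p1 - p2) * c
}

.cascade_verdicts <- c("reconstruction_favored", "indeterminate", "closure_favored")

#' Three-way decision verdict
#'
#' Compares the incremental reconstruction cost against the threshold dP x C:
#' below the threshold reconstruction is economically justified, above it it
#' is not, and at the threshold the result is indeterminate and requires
#' clinical judgment. Because exact real-valued equality is meaningless in
#' floating point, the indeterminate band has a configurable width, by
#' default `max(1e-9 * threshold, $0.005)` -- i.e. agreement to well below
#' one cent counts as equality.
#'
#' @param delta_c Incremental reconstruction cost in USD.
#' @param threshold Decision threshold in USD (see [decision_threshold()]).
#' @param tolerance Half-width of the indeterminate band in USD; `NULL` for
#'   the default.
#' @return One of `"reconstruction_favored"`, `"indeterminate"`,
#'   `"closure_favored"`.
#' @export
decide <- function(delta_c, threshold, tolerance = NULL) {
  if (is.null(tolerance)) tolerance <- max(1e-9 * abs(threshold), 0.005)
  if (tolerance < 0) stop("`tolerance` must be non-negative", call. = FALSE)
  if (abs(delta_c - threshold) <= tolerance) return("indeterminate")
  if (delta_c < threshold) "reconstruction_favored" else "closure_favored"
}

#' Full case-level decision analysis
#'
#' Runs the five-step pipeline for one case: (1) Clinical Risk Score and
#' risk tier from the factors present, with the applicability gate; (2)
#' failure probabilities resolved from the tier table under the case's bound
#' policy or explicit overrides; (3) failure trajectory cost resolved from
#' the failure cost tier; (4) decision threshold dP x C; (5) verdict from
#' comparing dC with the threshold, alongside the expected total episode
#' costs of both strategies. A "not applicable" gate annotates the result
#' but never blocks it.
#'
#' @param case A `cascade_case` (see [cascade_case()] / [read_case()]).
#' @param catalog Risk factor catalog.
#' @param prob_table Probability tier table.
#' @param cost_tiers Failure cost tier table.
#' @param tolerance Indeterminate-band tolerance passed to [decide()].
#' @return A `cascade_decision`: list with `case_id`, `crs`, `applicability`,
#'   `p1`, `p2`, `dp`, `c`, `delta_c`, `c0`, `threshold`,
#'   `expected_cost_s1`, `expected_cost_s2`, `verdict`.
#' @examples
#' case <- cascade_case(factors = c("hardware", "perfusion", "soft_tissue",
#'                                  "operative", "comorbidity"),
#'                      fct = 3, delta_c = 50000,
#'                      overrides = list(p1 = 0.20, p2 = 0.07))
#' cascade_decide(case)
#' @export
cascade_decide <- function(case,
                           catalog = default_crs_catalog(),
                           prob_table = default_probability_table(),
                           cost_tiers = default_cost_tiers(),
                           tolerance = NULL) {
  if (is.character(case) && length(case) == 1L) case <- read_case(case)
  stopifnot(inherits(case, "cascade_case"))

  crs <- compute_crs(case$factors, catalog)
  applicability <- check_applicability(crs, case$applicability_flags)
  # [[ with exact = TRUE: `$c` would partial-match `c0` when `c` is absent
  ov <- function(nm) case$overrides[[nm, exact = TRUE]]
  probs <- resolve_probabilities(crs$tier, policy = case$policy,
                                 p1 = ov("p1"), p2 = ov("p2"),
                                 table = prob_table)
  cost <- resolve_cost(case$fct, policy = case$policy,
                       override = ov("c"), tiers = cost_tiers)
  c0 <- if (is.null(ov("c0"))) 0 else ov("c0")
  inputs <- decision_inputs(case$delta_c, probs$p1, probs$p2, cost, c0)
  ec <- expected_costs(inputs)
  threshold <- decision_threshold(probs$p1, probs$p2, cost)
  verdict <- decide(case$delta_c, threshold, tolerance)

  structure(list(
    case_id = case$case_id,
    crs = crs,
    applicability = applicability,
    p1 = probs$p1, p2 = probs$p2, dp = probs$dp,
    c = cost, delta_c = case$delta_c, c0 = c0,
    threshold = threshold,
    expected_cost_s1 = unname(ec["s1"]),
    expected_cost_s2 = unname(ec["s2"]),
    verdict = verdict
  ), class = "cascade_decision")
}

usd <- function(x) paste0("$", formatC(round(x, 2), format = "f", digits = 2,
                                       big.mark = ","))

#' @export
print.cascade_decision <- function(x, ...) {
  cat("== Wound reconstruction decision analysis ==\n")
  if (!is.null(x$case_id)) cat("Case: ", x$case_id, "\n", sep = "")
  cat(sprintf("CRS %d (%s tier); factors: %s\n", x$crs$score, x$crs$tier,
              if (length(x$crs$contributing_factors))
                paste(x$crs$contributing_factors, collapse = ", ") else "none"))
  if (!x$applicability$applicable) {
    cat("NOTE: analysis flagged not applicable (",
        paste(x$applicability$reasons, collapse = "; "), ")\n", sep = "")
  }
  cat(sprintf("P1 = %.4g, P2 = %.4g, dP = %.4g\n", x$p1, x$p2, x$dp))
  cat("Failure trajectory cost C = ", usd(x$c), "\n", sep = "")
  cat("Threshold dP x C = ", usd(x$threshold),
      "; incremental cost dC = ", usd(x$delta_c), "\n", sep = "")
  cat("Expected episode cost: S1 (closure) ", usd(x$expected_cost_s1),
      "  S2 (reconstruction) ", usd(x$expected_cost_s2), "\n", sep = "")
  cat("Verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Flatten a decision result for serialization
#'
#' @param x A `cascade_decision`.
#' @param ... Unused.
#' @return A plain named list with stable field order, suitable for JSON
#'   output.
#' @export
as.list.cascade_decision <- function(x, ...) {
  list(
    case_id = x$case_id,
    crs = x$crs$score,
    tier = x$crs$tier,
    applicability = list(applicable = x$applicability$applicable,
                         reasons = x$applicability$reasons),
    p1 = x$p1, p2 = x$p2, dp = x$dp,
    c = x$c, delta_c = x$delta_c, c0 = x$c0,
    threshold = x$threshold,
    e_s1 = x$expected_cost_s1, e_s2 = x$expected_cost_s2,
    verdict = x$verdict
  )
}
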