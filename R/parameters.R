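#' Default tier-conditional failure probability table
#'
#' Literature-informed failure probability ranges by risk tier: P1 is the
#' probability of wound failure under routine closure, P2 under definitive
#' reconstruction, and dP = P1 - P2 the absolute risk reduction. The
#' published dP columns are carried as reference data only (`dp_lower`,
#' `dp_upper`); resolved dP is always computed exactly as P1 - P2, because
#' the published dP ranges are not the elementwise differences of the P1 and
#' P2 ranges.
#'
#' @return A `probability_tier_table` (data frame with one row per tier and
#'   columns `tier`, `p1_lower`, `p1_upper`, `p2_lower`, `p2_upper`,
#'   `dp_lower`, `dp_upper`).
#' @export
default_probability_table <- function() {
  tbl <- data.frame(
    tier = .cascade_tiers,
    p1_lower = c(0.05, 0.10, 0.15, 0.25),
    p1_upper = c(0.10, 0.15, 0.25, 0.40),
    p2_lower = c(0.02, 0.03, 0.05, 0.07),
    p2_upper = c(0.05, 0.07, 0.10, 0.15),
    dp_lower = c(0.03, 0.05, 0.10, 0.15),
    dp_upper = c(0.05, 0.10, 0.15, 0.25),
    stringsAsFactors = FALSE
  )
  probability_tier_table(tbl)
}

#' Validate a probability tier table
#'
#' @param tbl Data frame with the columns of [default_probability_table()].
#' @return A validated `probability_tier_table`.
#' @export
probability_tier_table <- function(tbl) {
  if (!is.data.frame(tbl)) stop("`tbl` must be a data frame", call. = FALSE)
  needed <- c("tier", "p1_lower", "p1_upper", "p2_lower", "p2_upper",
              "dp_lower", "dp_upper")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols)) {
    stop("probability table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tbl[needed]
  if (!setequal(tbl$tier, .cascade_tiers) || nrow(tbl) != 4L) {
    stop("probability table must have exactly one row per tier (",
         paste(.cascade_tiers, collapse = ", "), ")", call. = FALSE)
  }
  tbl <- tbl[match(.cascade_tiers, tbl$tier), ]
  rownames(tbl) <- NULL
  prob_cols <- setdiff(needed, "tier")
  vals <- unlist(tbl[prob_cols])
  if (any(vals < 0 | vals > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(tbl$p1_lower > tbl$p1_upper) || any(tbl$p2_lower > tbl$p2_upper)) {
    stop("range lower bounds must not exceed upper bounds", call. = FALSE)
  }
  if (any(tbl$p2_upper > tbl$p1_upper)) {
    stop("P2 upper bound must not exceed P1 upper bound within a tier",
         call. = FALSE)
  }
  if (is.unsorted(tbl$p1_lower) || is.unsorted(tbl$p1_upper)) {
    stop("P1 ranges must be non-decreasing across tiers Low -> Extreme",
         call. = FALSE)
  }
  class(tbl) <- c("probability_tier_table", "data.frame")
  tbl
}

#' Default failure cost tiers
#'
#' Four failure trajectory scenarios with total-episode cost ranges and a
#' representative (midpoint) cost: Tier 1 limited failure
#' ($100,000--$250,000, representative $175,000), Tier 2 moderate
#' ($250,000--$400,000, $325,000), Tier 3 severe ($400,000--$800,000,
#' $600,000) and Tier 4 catastrophic ($800,000--$1,000,000+, $900,000). The
#' Tier 4 "+" is display-only; deterministic arithmetic and default sampling
#' use $1,000,000 as the upper bound.
#'
#' @return A `failure_cost_tiers` data frame with columns `fct`, `scenario`,
#'   `clinical_events`, `cost_lower`, `cost_upper`, `open_upper`,
#'   `representative`.
#' @export
default_cost_tiers <- function() {
  tbl <- data.frame(
    fct = 1:4,
    scenario = c("Limited failure", "Moderate failure trajectory",
                 "Severe failure trajectory", "Catastrophic failure trajectory"),
    clinical_events = c(
      "SSI, minor reoperation, prolonged LOS",
      "Washout, VAC therapy, delayed closure",
      "Multiple reoperations, readmission, SNF",
      "Free flap salvage, prolonged hospitalization, rehabilitation"
    ),
    cost_lower = c(100000, 250000, 400000, 800000),
    cost_upper = c(250000, 400000, 800000, 1000000),
    open_upper = c(FALSE, FALSE, FALSE, TRUE),
    representative = c(175000, 325000, 600000, 900000),
    stringsAsFactors = FALSE
  )
  failure_cost_tiers(tbl)
}

#' Validate a failure cost tier table
#'
#' @param tbl Data frame with the columns of [default_cost_tiers()].
#' @return A validated `failure_cost_tiers`.
#' @export
failure_cost_tiers <- function(tbl) {
  if (!is.data.frame(tbl)) stop("`tbl` must be a data frame", call. = FALSE)
  needed <- c("fct", "scenario", "clinical_events", "cost_lower", "cost_upper",
              "open_upper", "representative")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols)) {
    stop("cost tier table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tbl[needed]
  tbl$fct <- as.integer(tbl$fct)
  if (!identical(sort(tbl$fct), 1:4)) {
    stop("cost tiers must be numbered 1 through 4", call. = FALSE)
  }
  tbl <- tbl[order(tbl$fct), ]
  rownames(tbl) <- NULL
  bad <- tbl$representative < tbl$cost_lower | tbl$representative > tbl$cost_upper
  if (any(tbl$cost_lower > tbl$cost_upper) || any(tbl$cost_lower < 0)) {
    stop("cost ranges must be non-negative with lower <= upper", call. = FALSE)
  }
  if (any(bad)) {
    stop("representative cost must lie within the tier cost range (tier ",
         paste(tbl$fct[bad], collapse = ", "), ")", call. = FALSE)
  }
  class(tbl) <- c("failure_cost_tiers", "data.frame")
  tbl
}

#' Resolve tier probabilities to point values
#'
#' Given a risk tier, resolve (P1, P2) from the tier's published ranges under
#' a bound policy and return the absolute risk reduction dP = P1 - P2,
#' computed exactly. Explicit overrides take precedence over policy
#' resolution; overrides outside the tier's published range trigger a
#' warning, not an error. An override pair with P2 >= P1 is rejected ("no
#' absolute risk reduction").
#'
#' Note: under the default `"midpoint"` policy the resolved values are exact
#' arithmetic means (e.g. High-tier P2 = 0.075, Low-tier P2 = 0.035).
#' Published worked examples that quote rounded midpoints (0.07, 0.04) are
#' reproduced by passing those values as explicit overrides.
#'
#' @param tier One of `"Low"`, `"Moderate"`, `"High"`, `"Extreme"`.
#' @param policy Bound policy, see [resolve_bound()].
#' @param p1,p2 Optional explicit probabilities in \[0, 1\].
#' @param table A [probability_tier_table()].
#' @return List with numeric `p1`, `p2`, `dp`.
#' @examples
#' resolve_probabilities("High", p1 = 0.20, p2 = 0.07)  # dp = 0.13
#' resolve_probabilities("High", policy = "midpoint")   # exact midpoints
#' @export
resolve_probabilities <- function(tier, policy = "midpoint",
                                  p1 = NULL, p2 = NULL,
                                  table = default_probability_table()) {
  table <- probability_tier_table(table)
  if (!is.character(tier) || length(tier) != 1L || !tier %in% .cascade_tiers) {
    stop("`tier` must be one of: ", paste(.cascade_tiers, collapse = ", "),
         call. = FALSE)
  }
  row <- table[table$tier == tier, ]
  p1_range <- bounded_range(row$p1_lower, row$p1_upper)
  p2_range <- bounded_range(row$p2_lower, row$p2_upper)

  check_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("explicit ", what, " must be a single probability in [0, 1]",
           call. = FALSE)
    }
    p
  }
  if (!is.null(p1)) {
    p1 <- check_prob(p1, "P1")
    warn_if_outside(p1, p1_range, paste0("P1 (", tier, " tier)"))
  } else {
    p1 <- resolve_bound(p1_range, policy)
  }
  if (!is.null(p2)) {
    p2 <- check_prob(p2, "P2")
    warn_if_outside(p2, p2_range, paste0("P2 (", tier, " tier)"))
  } else {
    p2 <- resolve_bound(p2_range, policy)
  }
  if (p2 >= p1) {
    stop("P2 (", p2, ") must be strictly below P1 (", p1,
         "): no absolute risk reduction", call. = FALSE)
  }
  list(p1 = p1, p2 = p2, dp = p1 - p2)
}

#' Resolve a failure cost tier to a point cost
#'
#' Under the `"midpoint"` policy this returns the tier's representative cost
#' (which equals the arithmetic midpoint of its range for all default tiers).
#' An explicit `override` takes precedence; values outside the tier range
#' warn rather than fail.
#'
#' @param fct Failure cost tier, integer 1--4.
#' @param policy Bound policy, see [resolve_bound()].
#' @param override Optional explicit cost in USD, must be non-negative.
#' @param tiers A [failure_cost_tiers()] table.
#' @return Numeric cost in USD.
#' @examples
#' resolve_cost(3)                  # 600000
#' resolve_cost(3, override = 800000)
#' @export
resolve_cost <- function(fct, policy = "midpoint", override = NULL,
                         tiers = default_cost_tiers()) {
  tiers <- failure_cost_tiers(tiers)
  if (!is.numeric(fct) || length(fct) != 1L || !fct %in% 1:4) {
    stop("`fct` must be an integer between 1 and 4", call. = FALSE)
  }
  row <- tiers[tiers$fct == as.integer(fct), ]
  rng <- bounded_range(row$cost_lower, row$cost_upper, row$open_upper)
  if (!is.null(override)) {
    if (!is.numeric(override) || length(override) != 1L || is.na(override) ||
        override < 0) {
      stop("cost override must be a single non-negative number", call. = FALSE)
    }
    warn_if_outside(override, rng, paste0("failure cost (tier ", fct, ")"))
    return(as.numeric(override))
  }
  if (identical(policy, "midpoint")) return(row$representative)
  resolve_bound(rng, policy)
}

#' Write / read the parameter tables as JSON or YAML
#'
#' Serializes the probability tier table and cost tier table into one config
#' file; `read_parameter_tables()` restores and re-validates them, so the
#' default tables round-trip unchanged.
#'
#' @param path Destination (`.json`, `.yaml` or `.yml`).
#' @param probabilities A [probability_tier_table()].
#' @param costs A [failure_cost_tiers()].
#' @return `read_parameter_tables()` returns
#'   `list(probabilities = , costs = )`; the writer returns `path`
#'   invisibly.
#' @export
write_parameter_tables <- function(path,
                                   probabilities = default_probability_table(),
                                   costs = default_cost_tiers()) {
  probabilities <- probability_tier_table(probabilities)
  costs <- failure_cost_tiers(costs)
  payload <- list(
    probabilities = lapply(seq_len(nrow(probabilities)), function(i) {
      as.list(as.data.frame(probabilities)[i, , drop = FALSE])
    }),
    costs = lapply(seq_len(nrow(costs)), function(i) {
      as.list(as.data.frame(costs)[i, , drop = FALSE])
    })
  )
  write_config_file(payload, path)
  invisible(path)
}

#' @rdname write_parameter_tables
#' @export
read_parameter_tables <- function(path) {
  raw <- read_config_file(path)
  bind_rows_list <- function(rows) {
    as.data.frame(do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    })))
  }
  list(
    probabilities = probability_tier_table(bind_rows_list(raw$probabilities)),
    costs = failure_cost_tiers(bind_rows_list(raw$costs))
  )
}
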