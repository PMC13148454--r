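.case_fields <- c("case_id", "factors", "applicability_flags", "fct",
                  "delta_c", "policy", "overrides", "documentation")
.override_fields <- c("p1", "p2", "c", "c0")

.doc_elements <- data.frame(
  element = c("crs_drivers", "expected_failure_trajectory",
              "reason_routine_closure_inadequate", "reconstructive_mechanism",
              "anticipated_prevented_events"),
  label = c("CRS drivers documented",
            "Expected failure trajectory documented",
            "Reason routine closure is inadequate",
            "Reconstructive mechanism selected",
            "Anticipated prevented downstream events"),
  model_function = c(
    "Defines baseline risk tier and assigns failure probability inputs (P1, P2, dP)",
    "Defines failure cost tier (FCT) and associated total episode cost range (C)",
    "Establishes clinical necessity for reconstruction (debridement, vascularized coverage, tension-free closure requirements)",
    "Defines incremental intervention (dC) and confirms strategy (e.g., flap, graft, staged reconstruction)",
    "Links intervention to reduction in failure trajectory and expected total episode cost differential"
  ),
  stringsAsFactors = FALSE
)

#' Construct a case profile
#'
#' A `cascade_case` describes one patient-case: the risk factors present,
#' the selected failure cost tier, the incremental reconstruction cost, the
#' bound policy used to resolve published ranges, optional explicit
#' overrides (`p1`, `p2`, `c`, `c0`), applicability flags, and an optional
#' clinical documentation checklist. All invariants are checked on
#' construction, so no case with out-of-range values can reach the
#' computation layer.
#'
#' @param factors Character vector of risk factor ids (validated against
#'   `catalog`).
#' @param fct Failure cost tier, integer 1--4.
#' @param delta_c Incremental reconstruction cost in USD, `>= 0`.
#' @param case_id Optional identifier string.
#' @param applicability_flags Named list of logical exclusion flags (see
#'   [check_applicability()]).
#' @param policy Bound policy: `"midpoint"`, `"lower"` or `"upper"`.
#' @param overrides Named list, any of `p1`, `p2`, `c`, `c0`.
#' @param documentation Named list of logicals over the five documentation
#'   elements (see [documentation_report()]); missing names count as not
#'   documented.
#' @param catalog Catalog used to validate factor ids.
#' @return A `cascade_case`.
#' @export
cascade_case <- function(factors = character(), fct, delta_c,
                         case_id = NULL,
                         applicability_flags = list(),
                         policy = "midpoint",
                         overrides = list(),
                         documentation = list(),
                         catalog = default_crs_catalog()) {
  raw <- list(case_id = case_id, factors = as.character(factors),
              applicability_flags = applicability_flags, fct = fct,
              delta_c = delta_c, policy = policy, overrides = overrides,
              documentation = documentation)
  raw <- raw[!vapply(raw, is.null, logical(1L))]
  validate_case(raw, catalog = catalog)
}

#' Validate a raw case description
#'
#' Checks a raw list (typically parsed from a JSON/YAML case file) against
#' the case schema and returns a typed `cascade_case`. All violations are
#' collected and reported together, not just the first; unknown top-level
#' keys are rejected by name.
#'
#' @param raw Named list as parsed from a case file.
#' @param catalog Catalog used to validate factor ids.
#' @return A `cascade_case`, or an error listing every violation.
#' @export
validate_case <- function(raw, catalog = default_crs_catalog()) {
  if (!is.list(raw)) stop("case must be a named list/object", call. = FALSE)
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  unknown <- setdiff(names(raw), .case_fields)
  if (length(unknown)) {
    note(paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  }

  factors <- unique(as.character(unlist(raw$factors)))
  bad_ids <- setdiff(factors, catalog$id)
  if (length(bad_ids)) {
    note(paste0("unknown risk factor id(s): ", paste(bad_ids, collapse = ", ")))
  }

  fct <- raw$fct
  if (is.null(fct)) {
    note("`fct` is required")
  } else if (!is.numeric(fct) || length(fct) != 1L || is.na(fct) ||
             !fct %in% 1:4) {
    note("`fct` must be 1-4")
  }

  delta_c <- raw$delta_c
  if (is.null(delta_c)) {
    note("`delta_c` is required")
  } else if (!is.numeric(delta_c) || length(delta_c) != 1L || is.na(delta_c) ||
             delta_c < 0) {
    note("`delta_c` must be a single non-negative number")
  }

  policy <- if (is.null(raw$policy)) "midpoint" else raw$policy
  if (!is.character(policy) || length(policy) != 1L ||
      !policy %in% c("midpoint", "lower", "upper")) {
    note("`policy` must be one of: midpoint, lower, upper")
  }

  flags <- as.list(raw$applicability_flags)
  bad_flags <- setdiff(names(flags), names(.applicability_flags))
  if (length(bad_flags)) {
    note(paste0("unknown applicability flag(s): ",
                paste(bad_flags, collapse = ", ")))
  }
  if (length(flags) && !all(vapply(flags, is.logical, logical(1L)))) {
    note("applicability flags must be true/false")
  }

  overrides <- as.list(raw$overrides)
  bad_over <- setdiff(names(overrides), .override_fields)
  if (length(bad_over)) {
    note(paste0("unknown override(s): ", paste(bad_over, collapse = ", ")))
  }
  for (nm in intersect(names(overrides), .override_fields)) {
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      note(paste0("override `", nm, "` must be a single number"))
    } else if (nm %in% c("p1", "p2") && (v < 0 || v > 1)) {
      note(paste0("override `", nm, "` must lie in [0, 1]"))
    } else if (nm %in% c("c", "c0") && v < 0) {
      note(paste0("override `", nm, "` must be non-negative"))
    }
  }
  if (!is.null(overrides$p1) && !is.null(overrides$p2) &&
      is.numeric(overrides$p1) && is.numeric(overrides$p2) &&
      length(overrides$p1) == 1L && length(overrides$p2) == 1L &&
      !any(is.na(c(overrides$p1, overrides$p2))) &&
      overrides$p2 >= overrides$p1) {
    note("override `p2` must be strictly below `p1` (no absolute risk reduction)")
  }

  documentation <- as.list(raw$documentation)
  bad_doc <- setdiff(names(documentation), .doc_elements$element)
  if (length(bad_doc)) {
    note(paste0("unknown documentation element(s): ",
                paste(bad_doc, collapse = ", ")))
  }
  if (length(documentation) &&
      !all(vapply(documentation, is.logical, logical(1L)))) {
    note("documentation entries must be true/false")
  }

  if (length(problems)) {
    stop("invalid case:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  }

  structure(list(
    case_id = if (is.null(raw$case_id)) NULL else as.character(raw$case_id),
    factors = factors,
    applicability_flags = flags,
    fct = as.integer(fct),
    delta_c = as.numeric(delta_c),
    policy = policy,
    overrides = overrides,
    documentation = documentation
  ), class = "cascade_case")
}

#' Read / write case files
#'
#' Case files are JSON or YAML documents matching the [cascade_case()]
#' schema; reading validates every field and reports all violations at once.
#'
#' @param path File path (`.json`, `.yaml`, `.yml`).
#' @param case A `cascade_case` to write.
#' @return `read_case()` returns a `cascade_case`; `write_case()` returns
#'   `path` invisibly.
#' @export
read_case <- function(path) {
  validate_case(read_config_file(path))
}

#' @rdname read_case
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "cascade_case"))
  payload <- unclass(case)
  payload <- payload[!vapply(payload, is.null, logical(1L))]
  # keep empty collections as objects/arrays, not nulls
  payload$factors <- as.list(payload$factors)
  write_config_file(payload, path)
  invisible(path)
}

#' @export
print.cascade_case <- function(x, ...) {
  cat("<cascade_case", if (!is.null(x$case_id)) paste0(" ", x$case_id), ">\n",
      sep = "")
  cat("  factors: ",
      if (length(x$factors)) paste(x$factors, collapse = ", ") else "none",
      "\n", sep = "")
  cat("  fct: ", x$fct, "; delta_c: ", usd(x$delta_c),
      "; policy: ", x$policy, "\n", sep = "")
  if (length(x$overrides)) {
    cat("  overrides: ",
        paste(names(x$overrides), unlist(x$overrides), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Clinical documentation report
#'
#' Maps the five required documentation elements that link clinical
#' decision-making to model inputs (risk drivers, expected failure
#' trajectory, reason routine closure is inadequate, reconstructive
#' mechanism, anticipated prevented events) to present/missing status for a
#' case, annotated with the model function each element feeds. Purely
#' informational: a sparse checklist never blocks the decision computation.
#'
#' @param case A `cascade_case`.
#' @return A `documentation_report`: data frame with columns `element`,
#'   `label`, `model_function`, `present`; attribute `n_present` counts
#'   documented elements (out of 5).
#' @export
documentation_report <- function(case) {
  stopifnot(inherits(case, "cascade_case"))
  present <- vapply(.doc_elements$element, function(el) {
    isTRUE(case$documentation[[el]])
  }, logical(1L))
  out <- cbind(.doc_elements, present = unname(present))
  structure(out, n_present = sum(present),
            class = c("documentation_report", "data.frame"))
}

#' @export
print.documentation_report <- function(x, ...) {
  cat("Documentation elements: ", attr(x, "n_present"), "/", nrow(x),
      " present\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s\n        -> %s\n",
                if (x$present[i]) "x" else " ", x$label[i],
                x$model_function[i]))
  }
  invisible(x)
}
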