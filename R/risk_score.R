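#' @importFrom stats quantile runif rbinom qnorm rnorm sd
#' @importFrom utils write.csv modifyList
NULL

.cascade_tiers <- c("Low", "Moderate", "High", "Extreme")

#' Risk factor catalog
#'
#' Build a Clinical Risk Score (CRS) catalog from a data frame with columns
#' `id`, `label`, `criteria`, `points`. Weights are data, not code: the
#' default catalog can be replaced from a config file (see
#' [read_crs_catalog()]) so re-weighted score variants can be evaluated
#' without code changes.
#'
#' @param factors Data frame of factor definitions. Points must be 1 or 2;
#'   ids must be unique.
#' @return A `crs_catalog` (a validated data frame).
#' @seealso [default_crs_catalog()], [compute_crs()]
#' @export
crs_catalog <- function(factors) {
  if (!is.data.frame(factors)) stop("`factors` must be a data frame", call. = FALSE)
  needed <- c("id", "label", "criteria", "points")
  missing_cols <- setdiff(needed, names(factors))
  if (length(missing_cols)) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  factors <- factors[needed]
  factors$id <- as.character(factors$id)
  factors$points <- as.integer(factors$points)
  if (anyDuplicated(factors$id)) {
    stop("duplicate factor id(s): ",
         paste(unique(factors$id[duplicated(factors$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(factors$points %in% c(1L, 2L))) {
    stop("factor points must be 1 or 2", call. = FALSE)
  }
  class(factors) <- c("crs_catalog", "data.frame")
  factors
}

#' Default Clinical Risk Score catalog
#'
#' The eight scored wound/patient risk factors: five wound- or
#' reconstruction-specific 2-point factors (perfusion compromise, hardware
#' present, closure tension, soft tissue destruction, prior failure) and
#' three contextual 1-point amplifiers (contamination, operative factors,
#' comorbidity). The maximum attainable score is 13 points (5 x 2 + 3 x 1);
#' scores of 9 or more all fall in the open-ended Extreme tier.
#'
#' @return A `crs_catalog`.
#' @export
default_crs_catalog <- function() {
  crs_catalog(data.frame(
    id = c("perfusion", "hardware", "tension", "soft_tissue", "prior_failure",
           "contamination", "operative", "comorbidity"),
    label = c("Perfusion compromise", "Hardware present", "Closure tension",
              "Soft tissue destruction", "Prior failure", "Contamination",
              "Operative factors", "Comorbidity"),
    criteria = c(
      "Ischemia, radiation history, tenuous tissue",
      "Instrumentation, prosthetics, implants",
      "Inability to achieve tension-free closure",
      "Dead space, muscle loss, tissue deficit",
      "Prior wound breakdown or revision",
      "Non-sterile field, colonization, open wound",
      "Prolonged surgery, reoperation field",
      "Diabetes, obesity, immunosuppression, malnutrition"
    ),
    points = c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  ))
}

#' Read / write a CRS catalog as JSON or YAML
#'
#' @param path File path; format inferred from the `.json` / `.yaml` / `.yml`
#'   extension.
#' @param catalog A `crs_catalog` to write.
#' @return `read_crs_catalog()` returns a `crs_catalog`;
#'   `write_crs_catalog()` returns `path` invisibly.
#' @export
read_crs_catalog <- function(path) {
  raw <- read_config_file(path)
  crs_catalog(as.data.frame(do.call(rbind, lapply(raw$factors, function(f) {
    data.frame(id = f$id, label = f$label, criteria = f$criteria,
               points = f$points, stringsAsFactors = FALSE)
  }))))
}

#' @rdname read_crs_catalog
#' @export
write_crs_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "crs_catalog"))
  payload <- list(factors = lapply(seq_len(nrow(catalog)), function(i) {
    as.list(catalog[i, , drop = FALSE])
  }))
  write_config_file(payload, path)
  invisible(path)
}

#' Map a Clinical Risk Score to its risk tier
#'
#' Tier bands: 0--2 Low, 3--5 Moderate, 6--8 High, 9 and above Extreme.
#' The Extreme band is open-ended, so scores above 12 (the default catalog
#' reaches 13) are accepted.
#'
#' @param score Non-negative integer score(s); vectorized.
#' @return Character vector of tiers, one of
#'   `"Low"`, `"Moderate"`, `"High"`, `"Extreme"`.
#' @examples
#' assign_tier(c(0, 2, 3, 6, 9, 13))
#' @export
assign_tier <- function(score) {
  if (!is.numeric(score) || any(is.na(score))) {
    stop("`score` must be numeric and non-missing", call. = FALSE)
  }
  if (any(score < 0)) stop("`score` must be non-negative", call. = FALSE)
  if (any(score != floor(score))) stop("`score` must be integer-valued", call. = FALSE)
  out <- ifelse(score <= 2, "Low",
         ifelse(score <= 5, "Moderate",
         ifelse(score <= 8, "High", "Extreme")))
  out
}

#' Compute the Clinical Risk Score for one case
#'
#' Additive scoring: the CRS is the sum of the point weights of the risk
#' factors present. Duplicated ids in the input are deduplicated (set
#' semantics). The score is then banded into a risk tier via [assign_tier()].
#' No interaction terms are modeled.
#'
#' @param present_factors Character vector of factor ids present in the case
#'   (may be empty).
#' @param catalog A [crs_catalog()]; defaults to the standard eight-factor
#'   catalog.
#' @return A `crs_result`: list with `score`, `tier` and
#'   `contributing_factors`.
#' @examples
#' compute_crs(c("hardware", "perfusion", "soft_tissue", "operative", "comorbidity"))
#' @export
compute_crs <- function(present_factors = character(),
                        catalog = default_crs_catalog()) {
  stopifnot(inherits(catalog, "crs_catalog"))
  present_factors <- unique(as.character(present_factors))
  unknown <- setdiff(present_factors, catalog$id)
  if (length(unknown)) {
    stop("unknown risk factor id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  score <- sum(catalog$points[catalog$id %in% present_factors])
  structure(
    list(score = as.integer(score), tier = assign_tier(score),
         contributing_factors = present_factors),
    class = "crs_result"
  )
}

#' @export
print.crs_result <- function(x, ...) {
  cat("Clinical Risk Score: ", x$score, " (", x$tier, " tier)\n", sep = "")
  if (length(x$contributing_factors)) {
    cat("Factors: ", paste(x$contributing_factors, collapse = ", "), "\n", sep = "")
  } else {
    cat("Factors: none\n")
  }
  invisible(x)
}

.applicability_flags <- c(
  tension_free_closure_achievable =
    "reliable tension-free closure achievable without advanced technique",
  no_contamination_hardware_perfusion =
    "no contamination, hardware, or perfusion compromise present",
  standard_comorbidity_burden =
    "standard comorbidity burden with no additional risk amplifiers"
)

#' Applicability gate for the decision analysis
#'
#' The framework targets high-risk wound environments where entry into a
#' failure trajectory is clinically meaningful. It is flagged not applicable
#' when the CRS falls in the Low tier (0--2) or when any explicit exclusion
#' flag is set: tension-free closure achievable, no
#' contamination/hardware/perfusion compromise, or standard comorbidity
#' burden. The flags are deliberate clinical judgments recorded in the case
#' file, not inferred from the absence of scored factors. A "not applicable"
#' verdict annotates downstream results; it never blocks them.
#'
#' @param crs A `crs_result` from [compute_crs()].
#' @param flags Named list of logical exclusion flags; unknown names are an
#'   error. Recognized: `tension_free_closure_achievable`,
#'   `no_contamination_hardware_perfusion`, `standard_comorbidity_burden`.
#' @return A `cascade_applicability`: list with logical `applicable` and a
#'   character vector `reasons` (empty when applicable).
#' @export
check_applicability <- function(crs, flags = list()) {
  stopifnot(inherits(crs, "crs_result"))
  flags <- as.list(flags)
  unknown <- setdiff(names(flags), names(.applicability_flags))
  if (length(unknown)) {
    stop("unknown applicability flag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  reasons <- character()
  if (crs$tier == "Low") {
    reasons <- c(reasons, "CRS 0-2 (low-risk wound environment)")
  }
  for (nm in names(flags)) {
    if (isTRUE(flags[[nm]])) reasons <- c(reasons, .applicability_flags[[nm]])
  }
  structure(list(applicable = length(reasons) == 0L, reasons = reasons),
            class = "cascade_applicability")
}

#' @export
print.cascade_applicability <- function(x, ...) {
  if (x$applicable) {
    cat("Decision analysis applicable\n")
  } else {
    cat("Decision analysis NOT applicable:\n")
    for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  }
  invisible(x)
}
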