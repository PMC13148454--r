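#' Synthetic case generator configuration
#'
#' Seeded generator of plausible case profiles so the whole pipeline is
#' testable end-to-end without patient data. Each risk factor is drawn as an
#' independent Bernoulli with its configured prevalence; an optional
#' exchangeable latent correlation (Gaussian-copula thresholding) is
#' available for stress tests, since in practice high-risk factors tend to
#' coexist. The failure cost tier is assigned from the resulting risk tier
#' (default mapping Low to tier 1 through Extreme to tier 4, mirroring how
#' worked examples pair risk environment with expected trajectory), and the
#' incremental reconstruction cost is drawn uniformly from `delta_c_range`.
#'
#' @param n_cases Number of cases to generate.
#' @param prevalence Either a single prevalence applied to all eight factors
#'   or a named vector over catalog factor ids; values in \[0, 1\].
#' @param fct_rule Named integer vector mapping risk tier to failure cost
#'   tier.
#' @param delta_c_range Range (USD) for the uniform incremental-cost draw.
#' @param seed Integer seed; mandatory.
#' @param correlation Exchangeable latent correlation in \[0, 1) between
#'   factor indicators (0 = independent).
#' @param catalog Risk factor catalog.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases, prevalence = 0.3,
                             fct_rule = c(Low = 1L, Moderate = 2L,
                                          High = 3L, Extreme = 4L),
                             delta_c_range = c(20000, 80000),
                             seed, correlation = 0,
                             catalog = default_crs_catalog()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  }
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases < 1) {
    stop("`n_cases` must be a positive integer", call. = FALSE)
  }
  if (length(prevalence) == 1L && is.null(names(prevalence))) {
    prevalence <- stats::setNames(rep(as.numeric(prevalence), nrow(catalog)),
                                  catalog$id)
  }
  if (!setequal(names(prevalence), catalog$id)) {
    stop("`prevalence` must be a single number or named over all catalog ids",
         call. = FALSE)
  }
  prevalence <- prevalence[catalog$id]
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(fct_rule), .cascade_tiers) ||
      !all(fct_rule %in% 1:4)) {
    stop("`fct_rule` must map each tier to a cost tier 1-4", call. = FALSE)
  }
  dc <- as_bounded_range(delta_c_range)
  if (dc$lower < 0) stop("`delta_c_range` must be non-negative", call. = FALSE)
  if (!is.numeric(correlation) || correlation < 0 || correlation >= 1) {
    stop("`correlation` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(
    n_cases = as.integer(n_cases), prevalence = prevalence,
    fct_rule = fct_rule, delta_c_range = dc, seed = as.integer(seed),
    correlation = as.numeric(correlation), catalog = catalog
  ), class = "generator_config")
}

#' Generate synthetic cases
#'
#' @param config A [generator_config()].
#' @return A list of [cascade_case()] objects with a `manifest` attribute: a
#'   data frame of case id, score, tier, cost tier, incremental cost and
#'   the factors present.
#' @examples
#' cases <- generate_cases(generator_config(5, prevalence = 0.5, seed = 7))
#' attr(cases, "manifest")
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  catalog <- config$catalog
  n <- config$n_cases
  k <- nrow(catalog)

  present <- with_preserved_seed(config$seed, {
    if (config$correlation > 0) {
      # one-factor Gaussian copula: z_ij = sqrt(rho) z_i + sqrt(1-rho) e_ij,
      # thresholded at the marginal quantile so prevalences are preserved
      common <- rnorm(n)
      z <- sqrt(config$correlation) * matrix(common, n, k) +
        sqrt(1 - config$correlation) * matrix(rnorm(n * k), n, k)
      sweep(z, 2, qnorm(config$prevalence), "<")
    } else {
      matrix(runif(n * k), n, k) <
        matrix(config$prevalence, n, k, byrow = TRUE)
    }
  })
  delta_c <- with_preserved_seed(config$seed + 1L, {
    if (config$delta_c_range$lower == config$delta_c_range$upper) {
      rep(config$delta_c_range$lower, n)
    } else {
      runif(n, config$delta_c_range$lower, config$delta_c_range$upper)
    }
  })

  cases <- vector("list", n)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    factors <- catalog$id[present[i, ]]
    crs <- compute_crs(factors, catalog)
    fct <- unname(config$fct_rule[[crs$tier]])
    id <- sprintf("case_%04d", i)
    cases[[i]] <- cascade_case(
      factors = factors, fct = fct, delta_c = delta_c[i], case_id = id,
      catalog = catalog
    )
    manifest[[i]] <- data.frame(
      case_id = id, crs = crs$score, tier = crs$tier, fct = fct,
      delta_c = delta_c[i],
      factors = paste(factors, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  structure(cases, manifest = do.call(rbind, manifest))
}

#' Write generated cases to a directory
#'
#' Writes one JSON case file per case plus a `manifest.csv` index.
#'
#' @param cases Output of [generate_cases()].
#' @param dir Destination directory (created if absent).
#' @return The manifest data frame, invisibly.
#' @export
write_cases <- function(cases, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- attr(cases, "manifest")
  for (case in cases) {
    write_case(case, file.path(dir, paste0(case$case_id, ".json")))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
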