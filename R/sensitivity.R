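#' Two-way deterministic threshold grid
#'
#' Outer product of failure trajectory costs and absolute risk reductions:
#' each cell is the decision threshold C x dP, the maximum incremental
#' reconstruction cost justified by that combination. The default axes are
#' the four representative tier costs ($175,000 / $325,000 / $600,000 /
#' $900,000) crossed with dP in {0.05, 0.10, 0.13, 0.20, 0.25}. Costs are
#' sorted ascending so thresholds are non-decreasing down each column and
#' rightward along each row.
#'
#' @param costs Numeric vector of failure trajectory costs (USD, `>= 0`).
#'   Names, if present, are kept as row labels.
#' @param dps Numeric vector of absolute risk reductions in \[0, 1\].
#' @return A `threshold_grid`: numeric matrix of thresholds with costs as
#'   rows and dP values as columns, plus `costs` and `dps` attributes.
#' @examples
#' two_way_grid()["Tier 3 ($600,000)", "dP=0.13"]  # 78000
#' @export
two_way_grid <- function(costs = NULL, dps = c(0.05, 0.10, 0.13, 0.20, 0.25)) {
  if (is.null(costs)) {
    tiers <- default_cost_tiers()
    costs <- tiers$representative
    names(costs) <- sprintf("Tier %d ($%s)", tiers$fct,
                            formatC(costs, format = "d", big.mark = ","))
  }
  if (length(costs) == 0L || length(dps) == 0L) {
    stop("`costs` and `dps` must be non-empty", call. = FALSE)
  }
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  if (any(dps < 0 | dps > 1)) stop("dP values must lie in [0, 1]", call. = FALSE)
  ord <- order(costs)
  costs <- costs[ord]
  if (is.null(names(costs))) {
    names(costs) <- paste0("$", formatC(costs, format = "d", big.mark = ","))
  }
  grid <- outer(costs, dps)
  dimnames(grid) <- list(names(costs), paste0("dP=", format(dps)))
  structure(grid, costs = unname(costs), dps = dps,
            class = c("threshold_grid", class(grid)))
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat("Decision thresholds C x dP (USD):\n")
  print(unclass(structure(x, costs = NULL, dps = NULL)), ...)
  invisible(x)
}

#' One-way sensitivity analysis
#'
#' Re-runs the full decision for each value of a single swept parameter
#' (`p1`, `p2`, `c` or `delta_c`), holding the others at their base values.
#'
#' @param inputs Base-case [decision_inputs()].
#' @param parameter Which input to sweep: `"p1"`, `"p2"`, `"c"` or
#'   `"delta_c"`.
#' @param values Numeric vector of substituted values, each within the
#'   parameter's valid domain.
#' @param tolerance Passed to [decide()].
#' @return Data frame with columns `parameter`, `value`, `p1`, `p2`, `c`,
#'   `delta_c`, `threshold`, `e_s1`, `e_s2`, `verdict`, one row per value.
#' @examples
#' base <- decision_inputs(50000, 0.20, 0.07, 600000)
#' one_way(base, "c", c(600000, 800000))  # thresholds 78000 and 104000
#' @export
one_way <- function(inputs, parameter, values, tolerance = NULL) {
  stopifnot(inherits(inputs, "decision_inputs"))
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% c("p1", "p2", "c", "delta_c")) {
    stop("`parameter` must be one of: p1, p2, c, delta_c", call. = FALSE)
  }
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    args <- unclass(inputs)
    args[[parameter]] <- v
    mod <- do.call(decision_inputs, args)  # revalidates the substituted value
    ec <- expected_costs(mod)
    thr <- decision_threshold(mod$p1, mod$p2, mod$c)
    data.frame(parameter = parameter, value = v,
               p1 = mod$p1, p2 = mod$p2, c = mod$c, delta_c = mod$delta_c,
               threshold = thr, e_s1 = unname(ec["s1"]), e_s2 = unname(ec["s2"]),
               verdict = decide(mod$delta_c, thr, tolerance),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Configuration for probabilistic sensitivity analysis
#'
#' Each of `p1`, `p2` and `c` may be a single number (point mass) or a range
#' ([bounded_range()] or `c(lower, upper)`); `dist` selects the sampling
#' distribution applied to non-degenerate ranges: `"uniform"` over the range
#' or `"triangular"` with mode at the range midpoint (reflecting the
#' guidance that the midpoint is the typical case). The ordering constraint
#' P2 < P1 is enforced draw-wise by resampling P2 (see [run_psa()]).
#'
#' @param delta_c Fixed incremental reconstruction cost in USD.
#' @param p1,p2 Probability specs (scalar or range, values in \[0, 1\]).
#' @param c Cost spec (scalar or range, USD). For the catastrophic tier the
#'   default sampling range is \[$800,000, $1,000,000\]; pass a larger upper
#'   bound explicitly to explore an extended tail.
#' @param n_samples Number of Monte Carlo draws, `>= 1`.
#' @param seed Integer seed; mandatory, results are bit-reproducible per
#'   seed.
#' @param dist `"uniform"` or `"triangular"`.
#' @return A `psa_config` list.
#' @export
psa_config <- function(delta_c, p1, p2, c, n_samples = 10000, seed,
                       dist = c("uniform", "triangular")) {
  dist <- match.arg(dist)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  }
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("`n_samples` must be at least 1", call. = FALSE)
  }
  if (!is.numeric(delta_c) || length(delta_c) != 1L || delta_c < 0) {
    stop("`delta_c` must be a single non-negative number", call. = FALSE)
  }
  check_range <- function(x, what, lo = -Inf, hi = Inf) {
    r <- as_bounded_range(x)
    if (r$lower < lo || r$upper > hi) {
      stop("`", what, "` range must lie in [", lo, ", ", hi, "]", call. = FALSE)
    }
    r
  }
  structure(list(
    delta_c = as.numeric(delta_c),
    p1 = check_range(p1, "p1", 0, 1),
    p2 = check_range(p2, "p2", 0, 1),
    c = check_range(c, "c", 0),
    n_samples = as.integer(n_samples),
    seed = as.integer(seed),
    dist = dist
  ), class = "psa_config")
}

# triangular sampler, mode at m; degenerates gracefully when a == b
rtriangular <- function(n, a, b, m = (a + b) / 2) {
  if (a == b) return(rep(a, n))
  u <- runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

sample_range <- function(n, range, dist) {
  if (range$lower == range$upper) return(rep(range$lower, n))
  switch(dist,
    uniform = runif(n, range$lower, range$upper),
    triangular = rtriangular(n, range$lower, range$upper)
  )
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Run a probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of the parameter ranges through the decision
#' rule: draws (P1, P2, C) per the configured distributions, computes the
#' threshold dP x C per draw, and reports the fraction of draws in which
#' reconstruction is favored (threshold strictly above the fixed dC),
#' together with its Monte Carlo standard error and summaries of the
#' threshold and of the expected-cost difference S2 - S1 = dC - dP x C.
#'
#' P1 and P2 are sampled independently from their marginal ranges; draws
#' violating P2 < P1 are rejected and P2 is resampled (up to 1000 rounds),
#' which preserves both marginals' supports while enforcing the ordering.
#' The overall rejection rate is reported; draws that never satisfy the
#' constraint are dropped from `n_effective`, and an all-rejected
#' configuration is an error.
#'
#' @param config A [psa_config()].
#' @return A `psa_result`: list with `probability_favored`, `mc_se`,
#'   `n_effective`, `rejection_rate`, `threshold` and `cost_diff` summary
#'   lists (mean + quantiles), `delta_c`, `seed`.
#' @examples
#' cfg <- psa_config(delta_c = 78000, p1 = 0.20, p2 = 0.07,
#'                   c = c(400000, 800000), n_samples = 2000, seed = 42)
#' run_psa(cfg)$probability_favored  # ~0.5: P(0.13 C > 78000) = P(C > 600000)
#' @export
run_psa <- function(config) {
  stopifnot(inherits(config, "psa_config"))
  n <- config$n_samples
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)

  draws <- with_preserved_seed(config$seed, {
    p1 <- sample_range(n, config$p1, config$dist)
    p2 <- sample_range(n, config$p2, config$dist)
    rejections <- 0L
    bad <- p2 >= p1
    # point-mass p2 can never be repaired by resampling; skip the loop then
    resamplable <- config$p2$lower < config$p2$upper
    iter <- 0L
    while (any(bad) && resamplable && iter < 1000L) {
      rejections <- rejections + sum(bad)
      p2[bad] <- sample_range(sum(bad), config$p2, config$dist)
      bad <- p2 >= p1
      iter <- iter + 1L
    }
    if (any(bad)) rejections <- rejections + sum(bad)
    c_draw <- sample_range(n, config$c, config$dist)
    list(p1 = p1[!bad], p2 = p2[!bad], c = c_draw[!bad],
         rejections = rejections, dropped = sum(bad))
  })

  n_eff <- length(draws$p1)
  if (n_eff == 0L) {
    stop(sprintf(
      "all %d draws violated the P2 < P1 constraint (rejection rate %.3f); check the probability ranges",
      n, draws$rejections / (n + draws$rejections)), call. = FALSE)
  }
  threshold <- (draws$p1 - draws$p2) * draws$c
  cost_diff <- config$delta_c - threshold        # E[S2] - E[S1] per draw
  favored <- config$delta_c < threshold
  p_fav <- mean(favored)

  structure(list(
    probability_favored = p_fav,
    mc_se = sqrt(p_fav * (1 - p_fav) / n_eff),
    n_effective = n_eff,
    rejection_rate = draws$rejections / (n + draws$rejections),
    threshold = list(mean = mean(threshold),
                     quantiles = quantile(threshold, qs, names = TRUE)),
    cost_diff = list(mean = mean(cost_diff),
                     quantiles = quantile(cost_diff, qs, names = TRUE)),
    delta_c = config$delta_c,
    n_samples = n,
    seed = config$seed,
    dist = config$dist
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis (", x$dist, ", n = ", x$n_samples,
      ", seed = ", x$seed, ")\n", sep = "")
  cat(sprintf("P(reconstruction favored at dC = %s): %.4f (MC SE %.4f, n_eff %d)\n",
              usd(x$delta_c), x$probability_favored, x$mc_se, x$n_effective))
  cat(sprintf("Threshold dP x C: mean %s, median %s\n",
              usd(x$threshold$mean), usd(x$threshold$quantiles[["50%"]])))
  if (x$rejection_rate > 0) {
    cat(sprintf("P2 resampling rejection rate: %.4f\n", x$rejection_rate))
  }
  invisible(x)
}

#' Directional robustness of high-risk thresholds
#'
#' Checks the grid assertion that for high-risk and extreme-risk wound
#' environments paired with severe-or-worse failure trajectories (cost tiers
#' 3--4), the decision threshold exceeds $50,000 at every dP at or above
#' 0.10. The stated claim presumes high-risk cases select cost tiers 3--4;
#' the moderate cost tier ($325,000) yields $32,500 at dP = 0.10, so the
#' assertion is evaluated over tiers 3--4 only.
#'
#' @param grid A [two_way_grid()] (defaults to the standard grid).
#' @param floor Threshold floor in USD (default $50,000).
#' @param min_dp Minimum dP included (default 0.10).
#' @param fct_rows Integer cost-tier rows the claim covers (default 3:4).
#' @return Logical scalar; attribute `"cells"` holds the checked sub-grid.
#' @export
directional_robustness <- function(grid = two_way_grid(), floor = 50000,
                                   min_dp = 0.10, fct_rows = 3:4) {
  dps <- attr(grid, "dps")
  cells <- unclass(grid)[fct_rows, dps >= min_dp, drop = FALSE]
  structure(all(cells > floor), cells = cells)
}
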