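#' Specify an uncertainty distribution for a parameter
#'
#' Tariff-valued costs are given Normal distributions; event probabilities
#' and utilities are given Beta distributions parameterised by the method
#' of moments from a mean and standard error.  The published analysis does
#' not report dispersions, so the default standard error is 20% of the
#' mean (matching the one-way perturbation magnitude) and is configurable.
#'
#' A Beta specification degenerates to a point mass when the mean is 0 or
#' 1 (with a warning) or when the implied variance is infeasible
#' (`v >= m(1-m)`).
#'
#' @param mean Distribution mean; in (0, 1) for a proper Beta.
#' @param kind `"beta"` or `"normal"`.
#' @param se Standard error; default `0.2 * mean`.
#' @return A list of class `param_distribution` with the method-of-moments
#'   parameters (`alpha`, `beta` or `sd`) and a `point_mass` flag.
#' @export
#' @examples
#' make_distribution(0.5, "beta", se = 0.1) # alpha = beta = 12
make_distribution <- function(mean, kind = c("beta", "normal"),
                              se = 0.2 * mean) {
  kind <- match.arg(kind)
  out <- list(kind = kind, mean = mean, se = se, point_mass = FALSE)
  if (kind == "beta") {
    if (mean < 0 || mean > 1) stop("beta mean must lie in [0, 1]", call. = FALSE)
    v <- se^2
    if (mean == 0 || mean == 1) {
      if (se > 0) warning("beta with mean ", mean, " treated as a point mass")
      out$point_mass <- TRUE
    } else if (v <= 0 || v >= mean * (1 - mean)) {
      out$point_mass <- v <= 0
      if (v >= mean * (1 - mean)) {
        warning("requested variance infeasible for a beta; using point mass")
        out$point_mass <- TRUE
      }
    } else {
      nu <- mean * (1 - mean) / v - 1
      out$alpha <- mean * nu
      out$beta <- (1 - mean) * nu
    }
  } else {
    out$sd <- se
    out$point_mass <- se <= 0
  }
  structure(out, class = "param_distribution")
}

# quantile of a distribution spec (used so that one uniform draw can move a
# whole parameter group coherently)
.dist_quantile <- function(dist, u) {
  if (dist$point_mass) return(dist$mean)
  if (dist$kind == "beta") {
    stats::qbeta(u, dist$alpha, dist$beta)
  } else {
    stats::qnorm(u, dist$mean, dist$sd)
  }
}

# ---------------------------------------------------------------------------
# parameter registry shared by OWSA and PSA

# ids: prob:<arm>:<event> (one multiplier per event-arm pair),
#      cost:<item>, util:<arm>:<state>
.parameter_registry <- function(params) {
  arms <- c(params$settings$intervention, params$settings$comparator)
  ev <- params$events[params$events$arm %in% arms, c("arm", "event")]
  ev <- dplyr::distinct(ev)
  u <- params$utilities[params$utilities$arm %in% arms, , drop = FALSE]
  c(paste0("prob:", ev$arm, ":", ev$event),
    paste0("cost:", params$costs$item),
    paste0("util:", u$arm, ":", u$state))
}

# return a copy of params with one registry entry multiplied by `factor`
# (probabilities and utilities clamped to [0, 1]); perturbed sets are used
# directly without re-validation
.perturb <- function(params, id, factor) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  clamped <- FALSE
  if (parts[1] == "prob") {
    sel <- params$events$arm == parts[2] & params$events$event == parts[3]
    p <- params$events$probability[sel] * factor
    clamped <- any(p > 1)
    params$events$probability[sel] <- pmin(1, pmax(0, p))
  } else if (parts[1] == "cost") {
    sel <- params$costs$item == parts[2]
    params$costs$euros[sel] <- params$costs$euros[sel] * factor
  } else if (parts[1] == "util") {
    sel <- params$utilities$arm == parts[2] & params$utilities$state == parts[3]
    uu <- params$utilities$utility[sel] * factor
    clamped <- any(uu > 1)
    params$utilities$utility[sel] <- pmin(1, pmax(0, uu))
  } else {
    stop("unknown parameter id '", id, "'", call. = FALSE)
  }
  attr(params, "clamped") <- clamped
  params
}

.run_ce <- function(params) {
  s <- params$settings
  compute_ce(run_arm(params, s$intervention, keep_trace = FALSE),
             run_arm(params, s$comparator, keep_trace = FALSE))
}

#' One-way sensitivity analysis with tornado ranking
#'
#' Reruns the full model with each registered input multiplied by
#' `1 - perturbation` and `1 + perturbation` (default +/-20%), everything
#' else held at base.  Registered inputs are one multiplier per event-arm
#' probability group, each unit cost, and each state utility;
#' probabilities and utilities are clamped to \[0, 1\] and clamping is
#' flagged.  Entries are ranked by the absolute range of the incremental
#' cost-utility ratio.
#'
#' @param params A validated `parameter_set`.
#' @param perturbation Relative perturbation (default 0.20).
#' @param top_n Number of entries returned (default 20).
#' @return An object of class `owsa_result`: a tibble with columns
#'   `parameter`, `low_input`, `high_input`, `icur_low`, `icur_high`,
#'   `icer_low`, `icer_high`, `range`, `clamped`, sorted by descending
#'   `range`, with the base-case `ce_result` in attribute `"base"`.
#' @export
owsa <- function(params, perturbation = 0.20, top_n = 20) {
  base <- .run_ce(params)
  ids <- .parameter_registry(params)
  rows <- purrr::map_dfr(ids, function(id) {
    lo <- .perturb(params, id, 1 - perturbation)
    hi <- .perturb(params, id, 1 + perturbation)
    ce_lo <- .run_ce(lo)
    ce_hi <- .run_ce(hi)
    tibble::tibble(
      parameter = id,
      low_input = 1 - perturbation, high_input = 1 + perturbation,
      icur_low = ce_lo$icur, icur_high = ce_hi$icur,
      icer_low = ce_lo$icer, icer_high = ce_hi$icer,
      range = abs(ce_hi$icur - ce_lo$icur),
      clamped = isTRUE(attr(lo, "clamped")) || isTRUE(attr(hi, "clamped")))
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$range))
  out <- utils::head(rows, top_n)
  attr(out, "base") <- base
  class(out) <- c("owsa_result", class(out))
  out
}

# ---------------------------------------------------------------------------
# probabilistic sensitivity analysis

# draw one sampled parameter set; event probabilities move as a group per
# event-arm pair (mode "multiplier") or independently per interval
# (mode "individual")
.sample_params <- function(params, se_frac, mode, max_retries) {
  arms <- c(params$settings$intervention, params$settings$comparator)
  ev <- params$events
  groups <- dplyr::distinct(ev[ev$arm %in% arms, c("arm", "event")])
  for (g in seq_len(nrow(groups))) {
    sel <- which(ev$arm == groups$arm[g] & ev$event == groups$event[g])
    u_common <- stats::runif(1)
    for (i in sel) {
      p <- ev$probability[i]
      if (p <= 0) next
      d <- suppressWarnings(make_distribution(p, "beta", se = se_frac * p))
      u <- if (mode == "multiplier") u_common else stats::runif(1)
      ev$probability[i] <- .dist_quantile(d, u)
    }
  }
  params$events <- ev
  cs <- params$costs
  for (i in seq_len(nrow(cs))) {
    if (cs$euros[i] <= 0) next
    d <- make_distribution(cs$euros[i], "normal", se = se_frac * cs$euros[i])
    x <- .dist_quantile(d, stats::runif(1))
    tries <- 0
    while (x < 0 && tries < max_retries) {
      x <- .dist_quantile(d, stats::runif(1))
      tries <- tries + 1
    }
    cs$euros[i] <- max(x, 0)
  }
  params$costs <- cs
  ut <- params$utilities
  for (i in which(ut$arm %in% arms)) {
    if (ut$utility[i] <= 0) next
    d <- suppressWarnings(
      make_distribution(min(ut$utility[i], 1), "beta",
                        se = se_frac * ut$utility[i]))
    ut$utility[i] <- .dist_quantile(d, stats::runif(1))
  }
  params$utilities <- ut
  params
}

#' Probabilistic sensitivity analysis
#'
#' Samples every uncertain input from its distribution (Beta for event
#' probabilities and utilities, Normal for tariff costs), reruns both arms
#' per draw, and records the incremental cost, QALYs and life years.
#' Interval probabilities of one event-arm pair move together through a
#' shared quantile by default (`mode = "multiplier"`); `"individual"`
#' samples each interval independently.  Fully reproducible from `seed`.
#'
#' @param params A validated `parameter_set`.
#' @param n_draws Number of simulation runs (default 1000).
#' @param seed Integer seed.
#' @param se_frac Standard error as a fraction of each mean (default 0.2;
#'   0 makes every distribution a point mass).
#' @param mode `"multiplier"` or `"individual"` (see above).
#' @param max_retries Resampling cap for invalid draws (negative costs).
#' @return An object of class `psa_result`: list with `draws` (tibble
#'   `draw, delta_cost, delta_qaly, delta_ly`), `n_draws`, `seed`,
#'   `se_frac`, `mode` and the base-case `ce_result`.
#' @export
psa <- function(params, n_draws = 1000, seed = 1L, se_frac = 0.2,
                mode = c("multiplier", "individual"), max_retries = 100L) {
  mode <- match.arg(mode)
  base <- .run_ce(params)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draws <- purrr::map_dfr(seq_len(n_draws), function(k) {
    ps_k <- .sample_params(params, se_frac, mode, max_retries)
    ce <- .run_ce(ps_k)
    tibble::tibble(draw = k, delta_cost = ce$delta_cost,
                   delta_qaly = ce$delta_qaly, delta_ly = ce$delta_ly)
  })
  structure(list(draws = draws, n_draws = n_draws, seed = seed,
                 se_frac = se_frac, mode = mode, base = base),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_draws, " draws (seed ", x$seed, ", se ",
      x$se_frac * 100, "% of mean, ", x$mode, " mode)\n", sep = "")
  cat(sprintf("  mean Δcost %0.0f, mean ΔQALY %0.3f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the
#' intervention is cost-effective: the fraction of PSA draws with positive
#' net monetary benefit `lambda * delta_effect - delta_cost`.
#'
#' @param psa_result A [psa()] result.
#' @param wtp_grid Willingness-to-pay grid in euros per unit effect
#'   (default 0 to 100,000 in steps of 1,000).
#' @param effect `"qaly"` (default) or `"ly"`.
#' @return An object of class `ceac_curve`: tibble with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 100000, by = 1000),
                 effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  if (nrow(psa_result$draws) == 0L) stop("no PSA draws", call. = FALSE)
  de <- if (effect == "qaly") psa_result$draws$delta_qaly else
    psa_result$draws$delta_ly
  dc <- psa_result$draws$delta_cost
  prob <- vapply(wtp_grid, function(l) mean(l * de - dc > 0), numeric(1))
  out <- tibble::tibble(wtp = wtp_grid, probability = prob)
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Cost-effectiveness plane points
#'
#' @param psa_result A [psa()] result.
#' @return Tibble with one row per draw: `draw`, `delta_qaly`,
#'   `delta_cost` and the plane `quadrant` (`NE` dearer and more
#'   effective, `SE` cheaper and more effective, `NW` dearer and less
#'   effective, `SW` cheaper and less effective).
#' @export
ce_plane <- function(psa_result) {
  if (nrow(psa_result$draws) == 0L) stop("no PSA draws", call. = FALSE)
  psa_result$draws |>
    dplyr::transmute(
      .data$draw, .data$delta_qaly, .data$delta_cost,
      quadrant = dplyr::case_when(
        .data$delta_qaly >= 0 & .data$delta_cost >= 0 ~ "NE",
        .data$delta_qaly >= 0 & .data$delta_cost < 0 ~ "SE",
        .data$delta_qaly < 0 & .data$delta_cost >= 0 ~ "NW",
        TRUE ~ "SW"))
}
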