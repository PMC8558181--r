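#' Discount factor at a given cycle
#'
#' Monthly-cycle discounting at an annual rate:
#' `(1 + annual_rate)^(-cycle/12)`.
#'
#' @param cycle Cycle number (integer >= 0, vectorised).
#' @param annual_rate Annual discount rate (>= 0).
#' @return Discount factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(12, 0.03) # one year out
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0)) stop("cycle must be >= 0", call. = FALSE)
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

# occupancy weights used for accrual: end-of-cycle by default, the average
# of cycle start and end under the half-cycle correction
.accrual_occupancy <- function(trace, half_cycle) {
  H <- nrow(trace$occupancy) - 1L
  if (H == 0L) return(trace$occupancy[0, , drop = FALSE])
  if (half_cycle) {
    (trace$occupancy[1:H, , drop = FALSE] +
       trace$occupancy[2:(H + 1L), , drop = FALSE]) / 2
  } else {
    trace$occupancy[2:(H + 1L), , drop = FALSE]
  }
}

#' Accrue (discounted) life years from a trace
#'
#' Sums the living cohort fraction over cycles, at one twelfth of a year
#' per monthly cycle, weighted by the discount factor of the cycle.
#'
#' @param trace A `cohort_trace`.
#' @param rate Annual discount rate.
#' @param half_cycle Average start- and end-of-cycle occupancy.
#' @return Named list with `discounted` and `undiscounted` life years.
#' @export
accrue_life_years <- function(trace, rate, half_cycle = FALSE) {
  occ <- .accrual_occupancy(trace, half_cycle)
  H <- nrow(occ)
  alive <- if (H == 0L) numeric(0) else rowSums(occ[, 1:8, drop = FALSE])
  t <- seq_len(H)
  list(discounted = sum(alive / 12 * discount_factor(t, rate)),
       undiscounted = sum(alive / 12))
}

#' Accrue (discounted) QALYs from a trace
#'
#' Weights each living state's occupancy by its per-year utility (death
#' contributes 0) and accrues one twelfth of that utility per monthly
#' cycle, discounted.
#'
#' @param trace A `cohort_trace`.
#' @param utilities Tibble `state, arm, utility` covering the eight living
#'   states for the trace's arm.
#' @param rate Annual discount rate.
#' @param half_cycle Average start- and end-of-cycle occupancy.
#' @return Named list with `discounted` and `undiscounted` QALYs.
#' @export
accrue_qalys <- function(trace, utilities, rate, half_cycle = FALSE) {
  ua <- utilities[utilities$arm == trace$arm, , drop = FALSE]
  u <- ua$utility[match(living_states(), ua$state)]
  if (anyNA(u)) {
    stop("missing utility for state '",
         living_states()[which(is.na(u))[1]], "', arm '", trace$arm, "'",
         call. = FALSE)
  }
  occ <- .accrual_occupancy(trace, half_cycle)
  H <- nrow(occ)
  qw <- if (H == 0L) numeric(0) else
    as.numeric(occ[, 1:8, drop = FALSE] %*% u)
  t <- seq_len(H)
  list(discounted = sum(qw / 12 * discount_factor(t, rate)),
       undiscounted = sum(qw / 12))
}

# index procedure (and, in the scenario, rehabilitation) cost for an arm
.index_cost <- function(params, arm, scenario_mode) {
  if (scenario_mode) {
    idx <- unname(.micro_index_costs[arm])
    if (is.null(params$rehab_cost)) {
      stop("scenario mode needs a rehabilitation unit cost; pass rehab_cost ",
           "to load_parameter_set()", call. = FALSE)
    }
    uptake <- params$rehab$uptake[match(arm, params$rehab$arm)]
    c(index_procedure = idx,
      rehabilitation = unname(uptake * params$rehab_cost))
  } else {
    item <- switch(arm, tavi = "tavi_procedure", savr = "savr_procedure", NA)
    idx <- if (is.na(item)) 0 else params$costs$euros[match(item, params$costs$item)]
    c(index_procedure = unname(idx), rehabilitation = 0)
  }
}

#' Accrue (discounted) costs from a trace
#'
#' Total cost is the index procedure cost (billed undiscounted at model
#' start; under the micro-costing scenario the micro-cost value plus the
#' rehabilitation uptake times its unit cost) plus, per cycle, expected
#' event incidences times unit costs times the cycle's discount factor.
#' Repeat procedures are billed at the respective index procedure tariff.
#'
#' @param trace A `cohort_trace`.
#' @param params A validated `parameter_set`.
#' @param arm Arm label.
#' @param rate Annual discount rate.
#' @param scenario_mode Use micro-costing index costs and bill
#'   rehabilitation.
#' @return Named list: `discounted`, `undiscounted`, and `breakdown`
#'   (tibble `item, euros` of the discounted components, summing to the
#'   discounted total).
#' @export
accrue_costs <- function(trace, params, arm, rate,
                         scenario_mode = params$settings$scenario) {
  idx <- .index_cost(params, arm, scenario_mode)
  evs <- colnames(trace$events)
  H <- nrow(trace$events)
  t <- seq_len(H)
  df <- discount_factor(t, rate)
  unit <- vapply(evs, function(e) {
    cost <- params$costs$euros[match(.billing_map(e), params$costs$item)]
    if (is.na(cost)) {
      stop("no unit cost for event '", e, "'", call. = FALSE)
    }
    if (e == "hosp_hf" && isTRUE(params$settings$oedema_with_hf)) {
      oed <- params$costs$euros[match("acute_pulmonary_oedema", params$costs$item)]
      if (!is.na(oed)) cost <- cost + oed
    }
    cost
  }, numeric(1))
  disc_by_event <- as.numeric(df %*% trace$events) * unit
  undisc_by_event <- colSums(trace$events) * unit
  breakdown <- tibble::tibble(
    item = c(names(idx), evs),
    euros = c(unname(idx), unname(disc_by_event)))
  list(discounted = sum(breakdown$euros),
       undiscounted = sum(idx) + sum(undisc_by_event),
       breakdown = breakdown)
}

#' Run one arm of the model end to end
#'
#' Builds the arm's transition matrices, iterates the cohort, and accrues
#' discounted and undiscounted costs, life years and QALYs.
#'
#' @param params A validated `parameter_set`.
#' @param arm Arm label.
#' @param keep_trace Attach the cohort trace to the result.
#' @return An object of class `arm_result`.
#' @export
#' @examples
#' ps <- load_parameter_set("inoperable_base")
#' run_arm(ps, "tavi")
run_arm <- function(params, arm, keep_trace = TRUE) {
  s <- params$settings
  model <- build_transition_matrices(params, arm)
  trace <- run_cohort(model, horizon_cycles = s$horizon_cycles,
                      initial_nyha = s$initial_nyha)
  ly <- accrue_life_years(trace, s$annual_discount_rate, s$half_cycle)
  qaly <- accrue_qalys(trace, params$utilities, s$annual_discount_rate,
                       s$half_cycle)
  cost <- accrue_costs(trace, params, arm, s$annual_discount_rate)
  structure(
    list(arm = arm, risk_group = s$risk_group,
         discounted_cost = cost$discounted,
         undiscounted_cost = cost$undiscounted,
         discounted_qaly = qaly$discounted,
         undiscounted_qaly = qaly$undiscounted,
         discounted_ly = ly$discounted,
         undiscounted_ly = ly$undiscounted,
         cost_breakdown = cost$breakdown,
         warnings = model$cycle_probs$warnings,
         trace = if (keep_trace) trace else NULL),
    class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf(
    "<arm_result> %s (%s risk): cost %0.0f, QALY %0.2f, LY %0.2f (discounted)\n",
    x$arm, x$risk_group, x$discounted_cost, x$discounted_qaly,
    x$discounted_ly))
  invisible(x)
}

#' Incremental cost-effectiveness of intervention versus comparator
#'
#' Differences all discounted quantities (intervention minus comparator)
#' and forms the incremental cost-utility ratio (euros per QALY) and
#' cost-effectiveness ratio (euros per life year gained) on the unrounded
#' deltas.  Ratios are `NA` (flagged undefined) when their denominator is
#' not positive; dominance is flagged when the deltas have opposite
#' beneficial signs.
#'
#' @param intervention,comparator `arm_result` objects from the same
#'   settings.
#' @return An object of class `ce_result` with fields `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icur`, `icer`, `dominance`, and the two
#'   arm results.
#' @export
compute_ce <- function(intervention, comparator) {
  dc <- intervention$discounted_cost - comparator$discounted_cost
  dq <- intervention$discounted_qaly - comparator$discounted_qaly
  dl <- intervention$discounted_ly - comparator$discounted_ly
  dominance <- "none"
  if ((dc < 0 && dq >= 0) || (dc <= 0 && dq > 0)) {
    dominance <- "intervention_dominant"
  } else if ((dc > 0 && dq <= 0) || (dc >= 0 && dq < 0)) {
    dominance <- "intervention_dominated"
  }
  structure(
    list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
         icur = if (dq > 0) dc / dq else NA_real_,
         icer = if (dl > 0) dc / dl else NA_real_,
         dominance = dominance,
         intervention = intervention, comparator = comparator),
    class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf(
    "<ce_result> %s vs %s: Δcost %0.0f, ΔQALY %0.3f, ΔLY %0.3f\n",
    x$intervention$arm, x$comparator$arm, x$delta_cost, x$delta_qaly,
    x$delta_ly))
  cat(sprintf("  ICUR %s /QALY, ICER %s /LYG, dominance: %s\n",
              format(round(x$icur)), format(round(x$icer)), x$dominance))
  invisible(x)
}

#' Tidy an incremental cost-effectiveness result
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return A tibble with one row per arm: discounted and undiscounted
#'   cost, QALY and LY.
#' @method tidy ce_result
#' @export
tidy.ce_result <- function(x, ...) {
  dplyr::bind_rows(lapply(list(x$intervention, x$comparator), function(a) {
    tibble::tibble(arm = a$arm, risk_group = a$risk_group,
                   cost = a$discounted_cost, qaly = a$discounted_qaly,
                   ly = a$discounted_ly,
                   undiscounted_cost = a$undiscounted_cost,
                   undiscounted_qaly = a$undiscounted_qaly,
                   undiscounted_ly = a$undiscounted_ly)
  }))
}

#' One-row summary of an incremental cost-effectiveness result
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return A one-row tibble with the incremental quantities, ratios and
#'   dominance flag.
#' @method glance ce_result
#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(risk_group = x$intervention$risk_group,
                 intervention = x$intervention$arm,
                 comparator = x$comparator$arm,
                 delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
                 delta_ly = x$delta_ly, icur = x$icur, icer = x$icer,
                 dominance = x$dominance)
}
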