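#' Model settings
#'
#' Assembles the run-level settings of the cohort model: the patient risk
#' group, the two strategies compared, the time horizon in monthly cycles
#' and the annual discount rate, plus the numerical switches that the
#' methods vignette documents (half-cycle correction, mortality
#' extrapolation mode, initial NYHA distribution).
#'
#' @param risk_group One of `"intermediate"`, `"high"`, `"inoperable"`.
#' @param comparator Comparator strategy; defaults to surgical replacement
#'   (`"savr"`) for operable groups and `"medical"` therapy for the
#'   inoperable group.
#' @param horizon_cycles Number of monthly cycles (default 180, i.e. 15
#'   years).
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   outcomes (default 0.03).
#' @param scenario Logical; use micro-costing procedure costs and bill
#'   rehabilitation (default `FALSE`).
#' @param half_cycle Logical; average start- and end-of-cycle occupancy
#'   when accruing life years and QALYs (default `FALSE`).
#' @param extrapolation_mode `"interval"` (default) fits the linear
#'   mortality trend to the annual interval probabilities of the fit
#'   years; `"cumulative"` fits it to the cumulative death probability.
#' @param extrapolation_fit_years Years whose annual mortality enters the
#'   linear fit (default `2:5`).
#' @param initial_nyha Length-4 distribution of the cohort over NYHA I-IV
#'   at model start (no stroke history); defaults to uniform over classes
#'   II-IV.
#' @param oedema_with_hf Logical; bill the acute pulmonary oedema tariff on
#'   top of each heart-failure hospitalisation (default `FALSE`, i.e. the
#'   tariff is loaded but unbilled because no incidence input exists for
#'   it).
#'
#' @return A list of class `model_settings`.
#' @export
#' @examples
#' model_settings("inoperable")
model_settings <- function(risk_group = c("intermediate", "high", "inoperable"),
                           comparator = NULL,
                           horizon_cycles = 180L,
                           annual_discount_rate = 0.03,
                           scenario = FALSE,
                           half_cycle = FALSE,
                           extrapolation_mode = c("interval", "cumulative"),
                           extrapolation_fit_years = 2:5,
                           initial_nyha = c(0, 1, 1, 1) / 3,
                           oedema_with_hf = FALSE) {
  risk_group <- match.arg(risk_group)
  if (is.null(comparator)) {
    comparator <- if (risk_group == "inoperable") "medical" else "savr"
  }
  expected <- if (risk_group == "inoperable") "medical" else "savr"
  if (!identical(comparator, expected)) {
    stop("comparator for the ", risk_group, " group must be '", expected, "'",
         call. = FALSE)
  }
  horizon_cycles <- as.integer(horizon_cycles)
  if (is.na(horizon_cycles) || horizon_cycles < 0L) {
    stop("horizon_cycles must be a non-negative integer", call. = FALSE)
  }
  if (annual_discount_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (length(initial_nyha) != 4L || any(initial_nyha < 0) ||
      abs(sum(initial_nyha) - 1) > 1e-9) {
    stop("initial_nyha must be a length-4 distribution summing to 1",
         call. = FALSE)
  }
  structure(
    list(risk_group = risk_group,
         intervention = "tavi",
         comparator = comparator,
         cycle_length = 1L,
         horizon_cycles = horizon_cycles,
         annual_discount_rate = annual_discount_rate,
         scenario = scenario,
         half_cycle = half_cycle,
         extrapolation_mode = match.arg(extrapolation_mode),
         extrapolation_fit_years = extrapolation_fit_years,
         initial_nyha = initial_nyha,
         oedema_with_hf = oedema_with_hf),
    class = "model_settings")
}

#' Convert an interval probability to a constant per-cycle probability
#'
#' Given the probability `p_interval` that an event occurs at least once
#' during an interval of `n_cycles` model cycles, returns the constant
#' per-cycle probability `1 - (1 - p_interval)^(1/n_cycles)` that
#' compounds back to the interval probability exactly.
#'
#' `p_interval = 1` returns 1 regardless of `n_cycles`: a certain event
#' stays certain at any time resolution.
#'
#' @param p_interval Probability in \[0, 1\] (vectorised).
#' @param n_cycles Interval length in cycles (positive integer, recycled).
#' @return Per-cycle probability of the same length as `p_interval`.
#' @export
#' @examples
#' interval_to_cycle_probability(0.039, 5)
interval_to_cycle_probability <- function(p_interval, n_cycles) {
  if (any(p_interval < 0 | p_interval > 1)) {
    stop("p_interval must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_cycles < 1)) stop("n_cycles must be >= 1", call. = FALSE)
  # single-cycle intervals are returned unchanged (exact identity)
  ifelse(n_cycles == 1, p_interval, 1 - (1 - p_interval)^(1 / n_cycles))
}

# expand one event's interval table to a per-cycle vector over 1..n_months,
# without carry-forward (bands must cover the range requested)
.bands_to_monthly <- function(tbl, n_months) {
  p <- rep(NA_real_, n_months)
  for (i in seq_len(nrow(tbl))) {
    if (tbl$start_month[i] > n_months) next
    n <- tbl$end_month[i] - tbl$start_month[i] + 1L
    idx <- tbl$start_month[i]:min(tbl$end_month[i], n_months)
    p[idx] <- interval_to_cycle_probability(tbl$probability[i], n)
  }
  p
}

#' Extrapolate mortality beyond the observed follow-up
#'
#' Interval mortality data (monthly bands through 60 months) are converted
#' to per-cycle probabilities; beyond month 60 the annual mortality
#' probability is extended on a straight line fitted by ordinary least
#' squares to the annual interval probabilities of the fit years (default
#' years 2-5), evaluated at each later year and converted to a monthly
#' probability.  Fitted annual values are clamped to \[0, 1\]; clamping is
#' recorded as a warning attribute rather than an error.
#'
#' In `"cumulative"` mode the line is instead fitted to the cumulative
#' death probability at the end of each fit year, and later interval
#' probabilities are recovered as conditional probabilities from the
#' extended cumulative curve.
#'
#' @param mortality_table Data frame with columns `start_month`,
#'   `end_month`, `probability` covering months 1-60 contiguously.
#' @param horizon_cycles Length of the returned per-cycle sequence.
#' @param fit_years Years whose annual values enter the linear fit.
#' @param mode `"interval"` (default) or `"cumulative"`.
#' @return Numeric vector of length `horizon_cycles` of per-cycle death
#'   probabilities, with a character attribute `"warnings"` listing any
#'   clamping that occurred.
#' @export
extrapolate_mortality <- function(mortality_table, horizon_cycles,
                                  fit_years = 2:5,
                                  mode = c("interval", "cumulative")) {
  mode <- match.arg(mode)
  tbl <- mortality_table[order(mortality_table$start_month), , drop = FALSE]
  if (max(tbl$end_month) < 60L) {
    stop("mortality table must cover months 1-60", call. = FALSE)
  }
  horizon_cycles <- as.integer(horizon_cycles)
  observed_months <- min(max(tbl$end_month), horizon_cycles)
  p <- numeric(horizon_cycles)
  if (observed_months > 0) {
    p[seq_len(observed_months)] <- .bands_to_monthly(tbl, observed_months)
  }
  warnings <- character()
  last_year <- max(tbl$end_month) %/% 12L
  n_years <- ceiling(horizon_cycles / 12)

  # annual interval probability of each observed year y (months 12y-11..12y)
  annual_interval <- function(y) {
    row <- which(tbl$start_month == (y - 1L) * 12L + 1L & tbl$end_month == y * 12L)
    if (length(row) != 1L) {
      stop("mortality table has no single band for year ", y, call. = FALSE)
    }
    tbl$probability[row]
  }

  if (n_years > last_year) {
    if (mode == "interval") {
      fit <- stats::lm(p ~ y, data = data.frame(
        y = fit_years, p = vapply(fit_years, annual_interval, numeric(1))))
      for (y in (last_year + 1L):n_years) {
        pa <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * y)
        if (pa < 0 || pa > 1) {
          warnings <- c(warnings, sprintf(
            "extrapolated annual mortality %.3f at year %d clamped to [0, 1]",
            pa, y))
          pa <- min(max(pa, 0), 1)
        }
        idx <- ((y - 1L) * 12L + 1L):min(y * 12L, horizon_cycles)
        p[idx] <- interval_to_cycle_probability(pa, 12L)
      }
    } else {
      surv <- 1
      cum <- numeric(last_year)
      for (y in seq_len(last_year)) {
        # survival through year y from the per-cycle sequence already built
        surv <- prod(1 - p[seq_len(min(y * 12L, observed_months))])
        cum[y] <- 1 - surv
      }
      fit <- stats::lm(c ~ y, data = data.frame(y = fit_years, c = cum[fit_years]))
      prev_cum <- cum[last_year]
      for (y in (last_year + 1L):n_years) {
        cy <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * y)
        if (cy < prev_cum || cy > 1) {
          warnings <- c(warnings, sprintf(
            "extrapolated cumulative mortality %.3f at year %d clamped", cy, y))
          cy <- min(max(cy, prev_cum), 1)
        }
        pa <- if (prev_cum >= 1) 1 else (cy - prev_cum) / (1 - prev_cum)
        idx <- ((y - 1L) * 12L + 1L):min(y * 12L, horizon_cycles)
        p[idx] <- interval_to_cycle_probability(pa, 12L)
        prev_cum <- cy
      }
    }
  }
  p <- p[seq_len(horizon_cycles)]
  attr(p, "warnings") <- warnings
  p
}

#' Extend event rates to the horizon by carrying the last band forward
#'
#' Converts an event's interval probabilities to per-cycle probabilities
#' and holds the last observed band's per-cycle value constant for all
#' later cycles, reflecting the assumption that the last available data
#' remain representative for the rest of the time horizon.
#'
#' @param event_table Data frame with columns `start_month`, `end_month`,
#'   `probability`, contiguous from month 1.
#' @param horizon_cycles Length of the returned sequence.
#' @return Numeric vector of length `horizon_cycles`.
#' @export
extend_event_rates <- function(event_table, horizon_cycles) {
  if (nrow(event_table) == 0L) stop("empty event table", call. = FALSE)
  tbl <- event_table[order(event_table$start_month), , drop = FALSE]
  horizon_cycles <- as.integer(horizon_cycles)
  last <- max(tbl$end_month)
  p <- numeric(horizon_cycles)
  upto <- min(last, horizon_cycles)
  if (upto > 0) p[seq_len(upto)] <- .bands_to_monthly(tbl, upto)
  if (horizon_cycles > last) {
    n_last <- tbl$end_month[nrow(tbl)] - tbl$start_month[nrow(tbl)] + 1L
    p[(last + 1L):horizon_cycles] <-
      interval_to_cycle_probability(tbl$probability[nrow(tbl)], n_last)
  }
  p
}

# ---------------------------------------------------------------------------
# Parameter-set assembly

.micro_index_costs <- c(tavi = 26985, savr = 14802, medical = 0)
.rehab_uptake_default <- c(tavi = 0.062, savr = 0.64, medical = 0)

.fixture_path <- function(file) {
  system.file("extdata", file, package = "tavicea", mustWork = TRUE)
}

#' Load and validate a complete parameter set
#'
#' Builds the full input bundle for one risk group: interval event
#' probabilities per arm, unit costs, NYHA transition matrices, state
#' utilities, rehabilitation inputs and the run settings, validated as a
#' whole before any model run.
#'
#' Packaged fixtures carry the published interval probabilities and tariff
#' costs for all three risk groups; `"<group>_base"` uses tariff procedure
#' costs and `"<group>_micro"` the micro-costing procedure costs together
#' with rehabilitation billing.  The NYHA transition matrices and state
#' utilities are not published in the main text: by default they are
#' generated by the synthetic-data module (clearly labelled synthetic) and
#' can be replaced by user CSVs in the standard schemas.
#'
#' @param fixture Fixture name (`"intermediate_base"`, `"high_micro"`,
#'   ...), or `NULL` when `events_file` and `costs_file` are given.
#' @param events_file,costs_file Optional CSV paths overriding the
#'   packaged tables.  `events.csv` has columns `risk_group, arm, event,
#'   start_month, end_month, probability`; `costs.csv` has `item, euros`.
#' @param utilities_file Optional CSV (`state, arm, utility`) of per-year
#'   utilities for the eight living states; default synthetic.
#' @param transitions_file Optional CSV (`arm, cycle, from, to,
#'   probability`) of monthly NYHA transition matrices (`cycle = 0` rows
#'   apply to all cycles not otherwise specified); default synthetic.
#' @param settings A [model_settings()] object; defaults to the fixture's
#'   risk group with standard settings (scenario mode for `_micro`
#'   fixtures).
#' @param rehab_cost Rehabilitation unit cost in euros; required when the
#'   scenario is run (the tariff value is not published and must be
#'   supplied).
#' @param percent Logical; read the event probabilities as percent rather
#'   than decimal fractions.
#' @param synthetic Optional [synthetic_config()] used when utilities or
#'   transitions are generated rather than read.
#'
#' @return A validated object of class `parameter_set`.
#' @export
#' @examples
#' ps <- load_parameter_set("inoperable_base")
#' ps$costs
load_parameter_set <- function(fixture = NULL,
                               events_file = NULL, costs_file = NULL,
                               utilities_file = NULL, transitions_file = NULL,
                               settings = NULL, rehab_cost = NULL,
                               percent = FALSE, synthetic = NULL) {
  scenario <- FALSE
  if (!is.null(fixture)) {
    parts <- strsplit(fixture, "_", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% c("intermediate", "high", "inoperable") ||
        !parts[2] %in% c("base", "micro")) {
      stop("unknown fixture '", fixture, "'; expected <risk_group>_<base|micro>",
           call. = FALSE)
    }
    risk_group <- parts[1]
    scenario <- parts[2] == "micro"
    if (is.null(events_file)) events_file <- .fixture_path("events.csv")
    if (is.null(costs_file)) costs_file <- .fixture_path("costs.csv")
  } else if (is.null(events_file) || is.null(costs_file)) {
    stop("either a fixture name or both events_file and costs_file are required",
         call. = FALSE)
  }
  if (is.null(settings)) {
    settings <- model_settings(risk_group, scenario = scenario)
  }

  events <- readr::read_csv(events_file, show_col_types = FALSE,
                            progress = FALSE)
  required <- c("risk_group", "arm", "event", "start_month", "end_month",
                "probability")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0L) {
    stop("events file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (percent) events$probability <- events$probability / 100
  events <- dplyr::filter(events, .data$risk_group == settings$risk_group)

  costs <- readr::read_csv(costs_file, show_col_types = FALSE, progress = FALSE)
  if (!all(c("item", "euros") %in% names(costs))) {
    stop("costs file must have columns item, euros", call. = FALSE)
  }

  if (is.null(synthetic)) synthetic <- synthetic_config()
  utilities <- if (is.null(utilities_file)) {
    generate_utilities(synthetic)
  } else {
    readr::read_csv(utilities_file, show_col_types = FALSE, progress = FALSE)
  }
  arms <- c(settings$intervention, settings$comparator)
  nyha <- if (is.null(transitions_file)) {
    stats::setNames(lapply(arms, function(a) {
      generate_nyha_transitions(synthetic, a,
                                horizon_cycles = settings$horizon_cycles)
    }), arms)
  } else {
    .read_transitions(transitions_file, arms, settings$horizon_cycles)
  }

  index_costs <- if (settings$scenario) {
    .micro_index_costs
  } else {
    c(tavi = costs$euros[match("tavi_procedure", costs$item)],
      savr = costs$euros[match("savr_procedure", costs$item)],
      medical = 0)
  }

  ps <- structure(
    list(settings = settings,
         events = tibble::as_tibble(events),
         costs = tibble::as_tibble(costs),
         index_costs = index_costs,
         utilities = tibble::as_tibble(utilities),
         nyha = nyha,
         rehab = tibble::tibble(
           arm = names(.rehab_uptake_default),
           uptake = unname(.rehab_uptake_default)),
         rehab_cost = rehab_cost),
    class = "parameter_set")
  validate_parameter_set(ps)
}

# transitions.csv: arm, cycle (0 = all unspecified cycles), from, to, probability
.read_transitions <- function(path, arms, horizon_cycles) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("arm", "cycle", "from", "to", "probability") %in% names(tr))) {
    stop("transitions file must have columns arm, cycle, from, to, probability",
         call. = FALSE)
  }
  out <- list()
  for (a in arms) {
    ta <- tr[tr$arm == a, , drop = FALSE]
    if (nrow(ta) == 0L) stop("no NYHA transitions for arm '", a, "'", call. = FALSE)
    base <- matrix(0, 4, 4)
    b <- ta[ta$cycle == 0L, , drop = FALSE]
    base[cbind(b$from, b$to)] <- b$probability
    mats <- array(rep(base, horizon_cycles), dim = c(4, 4, horizon_cycles))
    for (cy in unique(ta$cycle[ta$cycle > 0L])) {
      if (cy > horizon_cycles) next
      m <- matrix(0, 4, 4)
      s <- ta[ta$cycle == cy, , drop = FALSE]
      m[cbind(s$from, s$to)] <- s$probability
      mats[, , cy] <- m
    }
    out[[a]] <- mats
  }
  out
}

#' Validate a parameter set
#'
#' Runs every structural and numerical check the model requires: both
#' arms present with contiguous, in-range interval probability tables
#' (mortality through at least 60 months, events through at least 24),
#' non-negative costs covering every event category with non-zero
#' incidence, row-stochastic NYHA matrices, utilities in \[0, 1\] with the
#' stroke variant of a class never above its no-stroke variant.  Errors
#' name the offending cell.
#'
#' @param params A `parameter_set`.
#' @return `params` invisibly restored (classed), after all checks pass.
#' @export
validate_parameter_set <- function(params) {
  s <- params$settings
  arms <- c(s$intervention, s$comparator)
  ev <- params$events
  bad <- which(ev$probability < 0 | ev$probability > 1)
  if (length(bad) > 0L) {
    stop(sprintf(
      "probability %.4g outside [0, 1] for event '%s', arm '%s', months %d-%d",
      ev$probability[bad[1]], ev$event[bad[1]], ev$arm[bad[1]],
      ev$start_month[bad[1]], ev$end_month[bad[1]]), call. = FALSE)
  }
  unknown <- setdiff(unique(ev$event), event_categories())
  if (length(unknown) > 0L) {
    stop("unknown event category '", unknown[1], "'", call. = FALSE)
  }
  for (a in arms) {
    ea <- ev[ev$arm == a, , drop = FALSE]
    if (nrow(ea) == 0L) stop("no event inputs for arm '", a, "'", call. = FALSE)
    for (e in unique(ea$event)) {
      tbl <- ea[ea$event == e, , drop = FALSE]
      tbl <- tbl[order(tbl$start_month), , drop = FALSE]
      if (tbl$start_month[1] != 1L) {
        stop("event '", e, "', arm '", a, "': intervals must start at month 1",
             call. = FALSE)
      }
      if (any(tbl$end_month < tbl$start_month)) {
        stop("event '", e, "', arm '", a, "': interval with end before start",
             call. = FALSE)
      }
      gaps <- tbl$start_month[-1] != tbl$end_month[-nrow(tbl)] + 1L
      if (nrow(tbl) > 1L && any(gaps)) {
        stop(sprintf(
          "event '%s', arm '%s': intervals not contiguous at month %d",
          e, a, tbl$end_month[which(gaps)[1]]), call. = FALSE)
      }
      need <- if (e == "mortality") 60L else 24L
      if (max(tbl$end_month) < need) {
        stop(sprintf("event '%s', arm '%s': coverage ends at month %d, need %d",
                     e, a, max(tbl$end_month), need), call. = FALSE)
      }
    }
    if (!"mortality" %in% ea$event) {
      stop("no mortality inputs for arm '", a, "'", call. = FALSE)
    }
    if (is.null(params$nyha[[a]])) {
      stop("no NYHA transition matrices for arm '", a, "'", call. = FALSE)
    }
    mats <- params$nyha[[a]]
    rs <- apply(mats, 3, rowSums)
    if (any(abs(rs - 1) > 1e-9) || any(mats < 0)) {
      stop("NYHA transition matrices for arm '", a,
           "' are not row-stochastic", call. = FALSE)
    }
  }
  if (any(params$costs$euros < 0)) {
    stop("negative unit cost for item '",
         params$costs$item[which(params$costs$euros < 0)[1]], "'",
         call. = FALSE)
  }
  incident <- unique(ev$event[ev$probability > 0 & ev$event != "mortality"])
  billed <- .billing_map(incident)
  missing_cost <- setdiff(billed, params$costs$item)
  if (length(missing_cost) > 0L) {
    stop("no unit cost for billed item '", missing_cost[1], "'", call. = FALSE)
  }
  u <- params$utilities
  if (!all(c("state", "arm", "utility") %in% names(u))) {
    stop("utilities must have columns state, arm, utility", call. = FALSE)
  }
  if (any(u$utility < 0 | u$utility > 1)) {
    stop("utility outside [0, 1] for state '",
         u$state[which(u$utility < 0 | u$utility > 1)[1]], "'", call. = FALSE)
  }
  for (a in intersect(arms, unique(u$arm))) {
    for (k in 1:4) {
      ns <- u$utility[u$arm == a & u$state == paste0("nyha", k)]
      st <- u$utility[u$arm == a & u$state == paste0("nyha", k, "_stroke")]
      if (length(ns) == 1L && length(st) == 1L && st > ns + 1e-12) {
        stop(sprintf(
          "utility of nyha%d_stroke (%.3f) exceeds nyha%d (%.3f) for arm '%s'",
          k, st, k, ns, a), call. = FALSE)
      }
    }
  }
  if (any(params$rehab$uptake < 0 | params$rehab$uptake > 1)) {
    stop("rehabilitation uptake outside [0, 1]", call. = FALSE)
  }
  invisible(params)
}

# unit-cost item billed for each event category; repeat procedures reuse the
# index procedure tariffs
.billing_map <- function(events) {
  vapply(events, function(e) switch(e,
    re_tavi = "tavi_procedure",
    re_savr = "savr_procedure",
    e), character(1))
}

#' Per-cycle event probabilities for one arm
#'
#' Expands an arm's interval probability tables to per-cycle sequences over
#' the full horizon: mortality via [extrapolate_mortality()], every other
#' event via [extend_event_rates()].
#'
#' @param params A validated `parameter_set`.
#' @param arm Arm label present in the parameter set.
#' @return A list with `mortality` (numeric vector of length
#'   `horizon_cycles`) and `events` (matrix `horizon_cycles` x events,
#'   named columns), plus `warnings` from the extrapolation.
#' @export
cycle_probabilities <- function(params, arm) {
  s <- params$settings
  ev <- params$events[params$events$arm == arm, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no inputs for arm '", arm, "'", call. = FALSE)
  mort <- extrapolate_mortality(ev[ev$event == "mortality", , drop = FALSE],
                                s$horizon_cycles,
                                fit_years = s$extrapolation_fit_years,
                                mode = s$extrapolation_mode)
  others <- setdiff(unique(ev$event), "mortality")
  em <- matrix(0, nrow = s$horizon_cycles, ncol = length(others),
               dimnames = list(NULL, others))
  for (e in others) {
    em[, e] <- extend_event_rates(ev[ev$event == e, , drop = FALSE],
                                  s$horizon_cycles)
  }
  list(mortality = as.numeric(mort), events = em,
       warnings = attr(mort, "warnings"))
}

#' @export
print.parameter_set <- function(x, ...) {
  s <- x$settings
  cat("<parameter_set> ", s$risk_group, " risk: ", s$intervention, " vs ",
      s$comparator, "\n", sep = "")
  cat("  horizon: ", s$horizon_cycles, " monthly cycles; discount ",
      s$annual_discount_rate * 100, "% per annum",
      if (s$scenario) "; micro-costing scenario" else "", "\n", sep = "")
  cat("  events: ", length(unique(x$events$event)), " categories, ",
      nrow(x$events), " interval rows\n", sep = "")
  invisible(x)
}
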