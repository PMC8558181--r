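#' Configuration for the synthetic supplementary inputs
#'
#' The NYHA-transition matrices and health-state utilities the model needs
#' are published only in supplementary tables that are not part of the
#' packaged inputs.  This module generates clearly labelled synthetic
#' stand-ins with the qualitative structure the model description implies:
#' valve replacement shifts patients toward NYHA I (more strongly in the
#' first year), medical therapy lets them progress, utilities decrease
#' with NYHA class and carry a stroke decrement.  The numbers are NOT the
#' published supplementary values; runs that need those values should
#' supply them as CSVs through [load_parameter_set()].
#'
#' @param seed Integer seed recorded with the configuration (generation is
#'   deterministic in the configuration).
#' @param improvement Named improvement strengths per arm in \[0, 1\]: the
#'   monthly probability of moving one NYHA class toward I.
#' @param progression Named progression strengths per arm in \[0, 1\]: the
#'   monthly probability of moving one class toward IV.
#' @param early_boost Multiplier (>= 1) on the improvement strength during
#'   cycles 1-12, capturing the stronger post-procedural recovery.
#' @param utility_gradient Strictly decreasing utilities for NYHA I-IV.
#' @param stroke_decrement Utility decrement in \[0, 1\] applied to
#'   stroke-history states (floored at 0).
#' @param arm_offset Named additive utility offset per arm (clamped to
#'   \[0, 1\]); no sign is asserted.
#' @param event_rate_scale Scale factor applied when synthetic event
#'   tables are generated.
#' @return A list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config()
#' generate_utilities(cfg)
synthetic_config <- function(seed = 1203L,
                             improvement = c(tavi = 0.25, savr = 0.22, medical = 0.02),
                             progression = c(tavi = 0.03, savr = 0.03, medical = 0.15),
                             early_boost = 1.5,
                             utility_gradient = c(0.85, 0.74, 0.62, 0.50),
                             stroke_decrement = 0.12,
                             arm_offset = c(tavi = 0, savr = 0, medical = 0),
                             event_rate_scale = 1) {
  if (any(diff(utility_gradient) >= 0)) {
    stop("utility_gradient must be strictly decreasing over NYHA I-IV",
         call. = FALSE)
  }
  if (any(improvement < 0 | improvement > 1) ||
      any(progression < 0 | progression > 1)) {
    stop("improvement and progression strengths must lie in [0, 1]",
         call. = FALSE)
  }
  if (stroke_decrement < 0 || stroke_decrement > 1) {
    stop("stroke_decrement must lie in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), improvement = improvement,
                 progression = progression, early_boost = early_boost,
                 utility_gradient = utility_gradient,
                 stroke_decrement = stroke_decrement,
                 arm_offset = arm_offset,
                 event_rate_scale = event_rate_scale),
            class = "synthetic_config")
}

# one monthly 4x4 NYHA matrix from improvement strength s and progression w
.nyha_matrix <- function(s, w) {
  if (s + w > 1) { f <- s + w; s <- s / f; w <- w / f }
  m <- matrix(0, 4, 4)
  for (k in 1:4) {
    up <- if (k > 1) s else 0      # toward NYHA I
    down <- if (k < 4) w else 0    # toward NYHA IV
    m[k, k] <- max(0, 1 - up - down)
    if (k > 1) m[k, k - 1] <- up
    if (k < 4) m[k, k + 1] <- down
    m[k, ] <- m[k, ] / sum(m[k, ])  # exact row-stochasticity
  }
  m
}

#' Generate monthly NYHA transition matrices for an arm
#'
#' Produces a `4 x 4 x horizon_cycles` array of row-stochastic monthly
#' transition matrices over NYHA I-IV.  Movement is at most one class per
#' month; the improvement strength is multiplied by `early_boost` during
#' cycles 1-12 so intervention arms improve fastest right after the
#' procedure.  Generation is deterministic given the configuration.
#'
#' @param config A [synthetic_config()].
#' @param arm Arm label with entries in `config$improvement` /
#'   `config$progression`.
#' @param horizon_cycles Number of monthly matrices to produce.
#' @return Array of dimension `c(4, 4, horizon_cycles)`.
#' @export
generate_nyha_transitions <- function(config, arm, horizon_cycles = 180L) {
  if (!arm %in% names(config$improvement)) {
    stop("no improvement strength configured for arm '", arm, "'",
         call. = FALSE)
  }
  s <- unname(config$improvement[arm])
  w <- unname(config$progression[arm])
  early <- .nyha_matrix(min(1, s * config$early_boost), w)
  late <- .nyha_matrix(s, w)
  out <- array(0, dim = c(4, 4, horizon_cycles))
  for (t in seq_len(horizon_cycles)) {
    out[, , t] <- if (t <= 12L) early else late
  }
  out
}

#' Generate a synthetic utility table
#'
#' Utility per year for each living state and arm: the NYHA gradient plus
#' the arm offset, with stroke-history states reduced by the stroke
#' decrement and floored at 0.  Death has utility 0 by construction and is
#' not listed.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `state`, `arm`, `utility`.
#' @export
generate_utilities <- function(config) {
  arms <- names(config$arm_offset)
  tidyr::crossing(arm = arms, nyha = 1:4, stroke = c(FALSE, TRUE)) |>
    dplyr::mutate(
      state = paste0("nyha", .data$nyha,
                     ifelse(.data$stroke, "_stroke", "")),
      utility = pmin(1, pmax(0,
        config$utility_gradient[.data$nyha] +
          config$arm_offset[.data$arm] -
          ifelse(.data$stroke, config$stroke_decrement, 0)))) |>
    dplyr::select("state", "arm", "utility")
}

#' Write the synthetic supplementary inputs as standard CSVs
#'
#' Writes `utilities.csv` (`state, arm, utility`) and `transitions.csv`
#' (`arm, cycle, from, to, probability`; `cycle = 0` rows hold from month
#' 13 onward, explicit rows cover months 1-12) in the same schemas
#' [load_parameter_set()] reads, so synthetic and user-supplied inputs are
#' interchangeable.  File names are prefixed `synthetic_` to keep their
#' provenance visible.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @param horizon_cycles Horizon used for the time-varying transitions.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_inputs <- function(config, dir, horizon_cycles = 180L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  upath <- file.path(dir, "synthetic_utilities.csv")
  readr::write_csv(generate_utilities(config), upath)
  rows <- list()
  for (a in names(config$improvement)) {
    mats <- generate_nyha_transitions(config, a, horizon_cycles)
    for (cy in c(1:12, 0L)) {
      m <- if (cy == 0L) mats[, , min(13L, horizon_cycles)] else mats[, , cy]
      idx <- which(m > 0, arr.ind = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        arm = a, cycle = cy, from = idx[, 1], to = idx[, 2],
        probability = m[idx])
    }
  }
  tpath <- file.path(dir, "synthetic_transitions.csv")
  readr::write_csv(dplyr::bind_rows(rows), tpath)
  invisible(c(utilities = upath, transitions = tpath))
}

#' Ground-truth parameter set with closed-form expectations
#'
#' Builds a degenerate parameter set - constant monthly hazards, a single
#' NYHA class with identity transitions, flat utilities - whose discounted
#' life years, QALYs and costs have exact geometric-series closed forms,
#' and returns both the set and those expectations.  The full pipeline
#' must reproduce them to numerical precision; this regime exists to
#' verify the engine, not to emulate any published inputs.
#'
#' @param monthly_mortality Constant per-cycle death probability.
#' @param utility Flat utility of every living state.
#' @param event_rate Constant per-cycle probability of the single costed
#'   event (heart-failure hospitalisation).
#' @param event_cost Unit cost of that event in euros.
#' @param index_cost Index procedure cost billed at model start, both arms.
#' @param annual_discount_rate Annual discount rate.
#' @param horizon_cycles Model horizon.
#' @return A list with elements `params` (a validated `parameter_set`
#'   whose two arms are identical) and `expected` (named list with
#'   `discounted_ly`, `discounted_qaly`, `discounted_cost`,
#'   `undiscounted_ly`).
#' @export
#' @examples
#' gt <- generate_ground_truth_set(monthly_mortality = 0.02,
#'                                 annual_discount_rate = 0,
#'                                 horizon_cycles = 120)
#' gt$expected$discounted_ly
generate_ground_truth_set <- function(monthly_mortality = 0.02,
                                      utility = 1,
                                      event_rate = 0,
                                      event_cost = 0,
                                      index_cost = 10000,
                                      annual_discount_rate = 0,
                                      horizon_cycles = 120L) {
  horizon_cycles <- as.integer(horizon_cycles)
  m <- monthly_mortality
  # interval tables that convert back to the constant monthly hazard
  bands <- tibble::tibble(start_month = c(1L, 2L, 7L, 13L, 25L, 37L, 49L),
                          end_month = c(1L, 6L, 12L, 24L, 36L, 48L, 60L))
  band_p <- function(p_monthly) {
    1 - (1 - p_monthly)^(bands$end_month - bands$start_month + 1L)
  }
  arms <- c("tavi", "savr")
  events <- dplyr::bind_rows(lapply(arms, function(a) {
    dplyr::bind_rows(
      tibble::tibble(risk_group = "intermediate", arm = a,
                     event = "mortality", start_month = bands$start_month,
                     end_month = bands$end_month,
                     probability = band_p(m)),
      tibble::tibble(risk_group = "intermediate", arm = a,
                     event = "hosp_hf", start_month = bands$start_month[1:4],
                     end_month = bands$end_month[1:4],
                     probability = band_p(event_rate)[1:4]))
  }))
  settings <- model_settings("intermediate",
                             horizon_cycles = horizon_cycles,
                             annual_discount_rate = annual_discount_rate,
                             initial_nyha = c(0, 1, 0, 0))
  utilities <- tidyr::crossing(arm = c(arms, "medical"),
                               state = living_states()) |>
    dplyr::mutate(utility = utility)
  identity_nyha <- array(rep(diag(4), horizon_cycles),
                         dim = c(4, 4, max(1L, horizon_cycles)))
  params <- structure(
    list(settings = settings, events = events,
         costs = tibble::tibble(
           item = c("tavi_procedure", "savr_procedure", "hosp_hf"),
           euros = c(index_cost, index_cost, event_cost)),
         index_costs = c(tavi = index_cost, savr = index_cost, medical = 0),
         utilities = utilities,
         nyha = list(tavi = identity_nyha, savr = identity_nyha),
         rehab = tibble::tibble(arm = c("tavi", "savr", "medical"),
                                uptake = c(0, 0, 0)),
         rehab_cost = NULL),
    class = "parameter_set")
  params <- validate_parameter_set(params)

  d <- (1 + annual_discount_rate)^(-1 / 12)
  x <- (1 - m) * d
  geom <- function(q, n) if (abs(q - 1) < 1e-15) n else q * (1 - q^n) / (1 - q)
  discounted_ly <- geom(x, horizon_cycles) / 12
  # events are billed on the population at risk at cycle start
  at_risk_sum <- if (horizon_cycles == 0L) 0 else {
    d * (if (abs(x - 1) < 1e-15) horizon_cycles else (1 - x^horizon_cycles) / (1 - x))
  }
  expected <- list(
    discounted_ly = discounted_ly,
    undiscounted_ly = geom(1 - m, horizon_cycles) / 12,
    discounted_qaly = utility * discounted_ly,
    discounted_cost = index_cost + event_cost * event_rate * at_risk_sum)
  list(params = params, expected = expected)
}
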