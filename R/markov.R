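#' Build per-cycle transition matrices for one arm
#'
#' Composes, for every cycle, the 9 x 9 transition matrix over the model's
#' state space from three sequential steps in a fixed, documented order:
#'
#' 1. death, with the cycle's mortality probability, from every living
#'    state;
#' 2. among survivors, major stroke moves the corresponding cohort
#'    fraction from a no-stroke state to the stroke-history state of the
#'    same NYHA class (the flag flips, the class is kept);
#' 3. among survivors, NYHA classes are redistributed by the arm's monthly
#'    NYHA matrix, applied within each stroke stratum.
#'
#' Stroke history is never lost: no transition leads from a stroke-history
#' state back to a no-stroke state.
#'
#' @param params A validated `parameter_set`.
#' @param arm Arm label.
#' @return An object of class `transition_model`: list with `arm`,
#'   `matrices` (array `9 x 9 x horizon_cycles`) and the per-cycle
#'   probabilities used (`cycle_probs`).
#' @export
build_transition_matrices <- function(params, arm) {
  if (is.null(params$nyha[[arm]])) {
    stop("no NYHA transition matrices for arm '", arm, "'", call. = FALSE)
  }
  cp <- cycle_probabilities(params, arm)
  H <- params$settings$horizon_cycles
  nyha <- params$nyha[[arm]]
  if (dim(nyha)[3] < H) {
    stop("NYHA matrices cover ", dim(nyha)[3], " cycles, need ", H,
         call. = FALSE)
  }
  has_stroke <- "major_stroke" %in% colnames(cp$events)
  mats <- array(0, dim = c(9, 9, max(1L, H)),
                dimnames = list(health_states(), health_states(), NULL))
  for (t in seq_len(H)) {
    pm <- cp$mortality[t]
    ps <- if (has_stroke) cp$events[t, "major_stroke"] else 0
    M <- nyha[, , t]
    P <- matrix(0, 9, 9)
    # no-stroke k -> {no-stroke k', stroke k', death}
    P[.state_nostroke, .state_nostroke] <- (1 - pm) * (1 - ps) * M
    P[.state_nostroke, .state_stroke] <- (1 - pm) * ps * M
    # stroke k -> {stroke k', death}
    P[.state_stroke, .state_stroke] <- (1 - pm) * M
    P[1:8, .state_death] <- pm
    P[.state_death, .state_death] <- 1
    mats[, , t] <- P
  }
  structure(list(arm = arm, matrices = mats, cycle_probs = cp),
            class = "transition_model")
}

#' Run the cohort through the model
#'
#' Iterates the cohort occupancy distribution through the per-cycle
#' transition matrices: `occupancy(t) = occupancy(t-1) %*% matrix(t)`.
#' Expected event incidences are recorded per cycle as the living fraction
#' at cycle start times the cycle's per-event probability.
#'
#' @param model A `transition_model` from [build_transition_matrices()].
#' @param initial Length-9 initial distribution over the states (sums to
#'   1); default puts the whole cohort alive without stroke history,
#'   spread over NYHA classes by `initial_nyha`.
#' @param horizon_cycles Number of cycles to run (default: all matrices in
#'   the model).
#' @param initial_nyha Length-4 NYHA distribution used when `initial` is
#'   not given.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (matrix `(horizon_cycles + 1) x 9`, row 1 = cycle 0) and `events`
#'   (matrix `horizon_cycles x` events of expected incidences per cohort
#'   member).
#' @export
run_cohort <- function(model, initial = NULL, horizon_cycles = NULL,
                       initial_nyha = c(0, 1, 1, 1) / 3) {
  mats <- model$matrices
  if (is.null(horizon_cycles)) horizon_cycles <- dim(mats)[3]
  if (dim(mats)[3] < horizon_cycles) {
    stop("model holds ", dim(mats)[3], " matrices, need ", horizon_cycles,
         call. = FALSE)
  }
  if (is.null(initial)) {
    initial <- c(initial_nyha, rep(0, 5))
  }
  if (length(initial) != 9L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    stop("initial distribution must be length 9, non-negative, summing to 1",
         call. = FALSE)
  }
  occ <- matrix(0, nrow = horizon_cycles + 1L, ncol = 9,
                dimnames = list(NULL, health_states()))
  occ[1, ] <- initial
  ev_probs <- model$cycle_probs$events
  ev <- matrix(0, nrow = horizon_cycles, ncol = ncol(ev_probs),
               dimnames = list(NULL, colnames(ev_probs)))
  for (t in seq_len(horizon_cycles)) {
    at_risk <- sum(occ[t, 1:8])
    ev[t, ] <- at_risk * ev_probs[t, ]
    occ[t + 1L, ] <- occ[t, ] %*% mats[, , t]
  }
  structure(list(occupancy = occ, events = ev, arm = model$arm),
            class = "cohort_trace")
}

#' Tidy a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A tibble with one row per cycle and state
#'   (`cycle`, `state`, `occupancy`).
#' @method tidy cohort_trace
#' @export
tidy.cohort_trace <- function(x, ...) {
  tibble::as_tibble(x$occupancy) |>
    dplyr::mutate(cycle = 0:(nrow(x$occupancy) - 1L), .before = 1) |>
    tidyr::pivot_longer(-"cycle", names_to = "state",
                        values_to = "occupancy")
}

#' Export a cohort trace as CSV
#'
#' One row per cycle with the nine state occupancies and the expected
#' per-event incidences (events are attributed to the cycle in which they
#' occur; cycle 0 carries the initial distribution and no events).
#'
#' @param trace A `cohort_trace`.
#' @param path File to write.
#' @return Invisibly, the exported tibble.
#' @export
export_trace <- function(trace, path) {
  H <- nrow(trace$occupancy) - 1L
  tab <- dplyr::bind_cols(
    tibble::tibble(cycle = 0:H),
    tibble::as_tibble(trace$occupancy),
    tibble::as_tibble(rbind(matrix(0, 1, ncol(trace$events),
                                   dimnames = list(NULL, colnames(trace$events))),
                            trace$events)))
  readr::write_csv(tab, path)
  invisible(tab)
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy) - 1L
  cat("<cohort_trace> arm '", x$arm, "', ", H, " cycles; final survival ",
      sprintf("%.1f%%", 100 * sum(x$occupancy[H + 1L, 1:8])), "\n", sep = "")
  invisible(x)
}
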