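# Independent oracles used across the suite.  Each recomputes a quantity by
# a different route than the package (exhaustive enumeration, closed forms,
# textbook formulas) so agreement is evidence, not tautology.

# occupancy of a finite Markov chain by exhaustive path enumeration:
# `mats` is a list of n x n transition matrices (one per cycle); returns a
# (cycles + 1) x n occupancy matrix.  Exponential in cycles - keep tiny.
enumerate_occupancy <- function(mats, initial) {
  n <- length(initial)
  cycles <- length(mats)
  occ <- matrix(0, cycles + 1L, n)
  occ[1L, ] <- initial
  recurse <- function(state, prob, t) {
    if (prob == 0) return(invisible())
    if (t > cycles) return(invisible())
    for (nxt in seq_len(n)) {
      p <- prob * mats[[t]][state, nxt]
      if (p > 0) {
        occ[t + 1L, nxt] <<- occ[t + 1L, nxt] + p
        recurse(nxt, p, t + 1L)
      }
    }
  }
  for (s in seq_len(n)) {
    if (initial[s] > 0) recurse(s, initial[s], 1L)
  }
  occ
}

# textbook least squares on (x, y): returns c(intercept, slope)
hand_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(mean(y) - slope * mean(x), slope)
}

# geometric series sum_{t=1..n} q^t without loops over the package code
geom_sum <- function(q, n) {
  if (abs(q - 1) < 1e-15) return(n)
  q * (1 - q^n) / (1 - q)
}

# a small randomised but valid parameter set: random interval tables and
# NYHA dynamics around the ground-truth scaffold
random_params <- function(seed, horizon_cycles = 60L) {
  set.seed(seed)
  gt <- generate_ground_truth_set(monthly_mortality = runif(1, 0.005, 0.05),
                                  event_rate = runif(1, 0, 0.05),
                                  event_cost = runif(1, 100, 5000),
                                  utility = runif(1, 0.4, 1),
                                  annual_discount_rate = runif(1, 0, 0.05),
                                  horizon_cycles = horizon_cycles)
  params <- gt$params
  # randomise the interval probabilities (keeping them valid) and add a
  # stroke event so both strata are exercised
  params$events$probability <- pmin(0.95, pmax(
    0, params$events$probability * runif(nrow(params$events), 0.2, 1.8)))
  stroke <- params$events[params$events$event == "hosp_hf", , drop = FALSE]
  stroke$event <- "major_stroke"
  stroke$probability <- runif(nrow(stroke), 0, 0.05)
  params$events <- rbind(params$events, stroke)
  params$costs <- rbind(params$costs,
                        data.frame(item = "major_stroke", euros = 19624))
  cfg <- synthetic_config(improvement = c(tavi = runif(1), savr = runif(1),
                                          medical = 0.1),
                          progression = c(tavi = runif(1, 0, 0.3),
                                          savr = runif(1, 0, 0.3),
                                          medical = 0.2))
  params$nyha <- list(tavi = generate_nyha_transitions(cfg, "tavi", horizon_cycles),
                      savr = generate_nyha_transitions(cfg, "savr", horizon_cycles))
  validate_parameter_set(params)
}

# interval bands used by the packaged tables
mortality_bands <- data.frame(start = c(1, 2, 7, 13, 25, 37, 49),
                              end = c(1, 6, 12, 24, 36, 48, 60))
event_bands <- data.frame(start = c(1, 2, 7, 13), end = c(1, 6, 12, 24))

# bare interval table constructor
interval_table <- function(bands, probability) {
  data.frame(start_month = bands$start, end_month = bands$end,
             probability = probability)
}
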