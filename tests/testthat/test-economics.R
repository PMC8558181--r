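test_that("discount factors follow annual compounding on a monthly grid", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(0:100, 0), rep(1, 101))
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(6, 0.03), 1.03^(-0.5), tolerance = 1e-12)
  expect_error(discount_factor(-1, 0.03), ">= 0")
})

test_that("life years and QALYs match geometric closed forms", {
  # full survival, 12 cycles, no discounting: exactly one year
  gt0 <- generate_ground_truth_set(monthly_mortality = 0, horizon_cycles = 12,
                                   annual_discount_rate = 0)
  trace <- run_cohort(build_transition_matrices(gt0$params, "tavi"))
  ly <- accrue_life_years(trace, 0)
  expect_equal(ly$discounted, 1, tolerance = 1e-12)
  expect_equal(ly$undiscounted, 1, tolerance = 1e-12)

  # constant monthly survival s at rate r: sum s^t (1+r)^(-t/12) / 12
  s <- 0.98
  r <- 0.03
  gt <- generate_ground_truth_set(monthly_mortality = 1 - s,
                                  annual_discount_rate = r,
                                  horizon_cycles = 120)
  trace <- run_cohort(build_transition_matrices(gt$params, "tavi"))
  ly <- accrue_life_years(trace, r)
  expect_equal(ly$discounted, geom_sum(s * (1 + r)^(-1 / 12), 120) / 12,
               tolerance = 1e-9)
  expect_equal(ly$undiscounted, geom_sum(s, 120) / 12, tolerance = 1e-9)

  # utilities scale QALYs linearly against LYs
  u1 <- generate_utilities(synthetic_config(
    utility_gradient = c(1, 0.999999, 0.999998, 0.999997),
    stroke_decrement = 0))
  u1$utility <- 1
  q <- accrue_qalys(trace, u1, r)
  expect_equal(q$discounted, ly$discounted, tolerance = 1e-12)
  u1$utility <- 0.5
  q2 <- accrue_qalys(trace, u1, r)
  expect_equal(q2$discounted, ly$discounted / 2, tolerance = 1e-12)

  expect_error(accrue_qalys(trace, u1[u1$state != "nyha3", ], r),
               "missing utility")
})

test_that("cost accrual bills the index procedure, events and the scenario extras", {
  # no events: the tariff alone
  gt <- generate_ground_truth_set(monthly_mortality = 0.02, event_rate = 0,
                                  index_cost = 30634, horizon_cycles = 60)
  trace <- run_cohort(build_transition_matrices(gt$params, "tavi"))
  cost <- accrue_costs(trace, gt$params, "tavi", 0.03, scenario_mode = FALSE)
  expect_equal(cost$discounted, 30634)
  expect_equal(cost$undiscounted, 30634)

  # one expected stroke per member at cycle 1, undiscounted: adds 19,624
  trace1 <- trace
  trace1$events <- matrix(c(1, rep(0, 59)), 60, 1,
                          dimnames = list(NULL, "major_stroke"))
  params1 <- gt$params
  params1$costs <- rbind(params1$costs,
                         data.frame(item = "major_stroke", euros = 19624))
  cost1 <- accrue_costs(trace1, params1, "tavi", 0, scenario_mode = FALSE)
  expect_equal(cost1$discounted, 30634 + 19624)

  # scenario mode: micro-cost plus uptake x rehabilitation unit cost
  mic <- load_parameter_set("intermediate_micro", rehab_cost = 3000)
  tr0 <- run_cohort(build_transition_matrices(mic, "tavi"))
  tr0$events[] <- 0
  cmic <- accrue_costs(tr0, mic, "tavi", 0.03, scenario_mode = TRUE)
  expect_equal(cmic$discounted, 26985 + 0.062 * 3000, tolerance = 1e-9)
  csavr <- accrue_costs(structure(list(occupancy = tr0$occupancy,
                                       events = tr0$events, arm = "savr"),
                                  class = "cohort_trace"),
                        mic, "savr", 0.03, scenario_mode = TRUE)
  breakdown <- csavr$breakdown
  expect_equal(breakdown$euros[breakdown$item == "rehabilitation"],
               0.64 * 3000)

  # scenario without a configured rehabilitation cost is an error
  base <- load_parameter_set("intermediate_base")
  expect_error(accrue_costs(tr0, base, "tavi", 0.03, scenario_mode = TRUE),
               "rehab")

  # repeat procedures are billed at the index tariffs
  gtc <- generate_ground_truth_set(monthly_mortality = 0, horizon_cycles = 2)
  trc <- run_cohort(build_transition_matrices(gtc$params, "tavi"))
  trc$events <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "re_savr"))
  prc <- gtc$params
  prc$costs <- rbind(prc$costs,
                     data.frame(item = "unused", euros = 1))
  crc <- accrue_costs(trc, prc, "tavi", 0, scenario_mode = FALSE)
  expect_equal(crc$discounted,
               prc$index_costs[["tavi"]] +
                 prc$costs$euros[prc$costs$item == "savr_procedure"])
})

test_that("the cost breakdown sums to the total", {
  for (fx in c("intermediate_base", "inoperable_base")) {
    ps <- load_parameter_set(fx)
    for (arm in c(ps$settings$intervention, ps$settings$comparator)) {
      res <- run_arm(ps, arm)
      expect_equal(sum(res$cost_breakdown$euros), res$discounted_cost,
                   tolerance = 1e-6)
    }
  }
})

test_that("discounting can only lower totals and QALYs stay below LYs", {
  ps <- load_parameter_set("high_base")
  res <- run_arm(ps, "tavi")
  expect_lte(res$discounted_cost, res$undiscounted_cost)
  expect_lte(res$discounted_qaly, res$undiscounted_qaly)
  expect_lte(res$discounted_ly, res$undiscounted_ly)
  expect_lte(res$discounted_qaly, res$discounted_ly)

  # explicit rate ordering, all else equal
  gt <- generate_ground_truth_set(monthly_mortality = 0.02, event_rate = 0.01,
                                  event_cost = 1000, horizon_cycles = 60)
  trace <- run_cohort(build_transition_matrices(gt$params, "tavi"))
  ly0 <- accrue_life_years(trace, 0)$discounted
  ly3 <- accrue_life_years(trace, 0.03)$discounted
  ly6 <- accrue_life_years(trace, 0.06)$discounted
  expect_true(ly0 > ly3 && ly3 > ly6)
})

test_that("incremental results, ratios and dominance behave as specified", {
  mk <- function(cost, qaly, ly) {
    structure(list(arm = "x", risk_group = "high", discounted_cost = cost,
                   discounted_qaly = qaly, discounted_ly = ly,
                   undiscounted_cost = cost, undiscounted_qaly = qaly,
                   undiscounted_ly = ly,
                   cost_breakdown = tibble::tibble(item = "index_procedure",
                                                   euros = cost)),
              class = "arm_result")
  }
  # quotient of printed-scale deltas
  ce <- compute_ce(mk(36623, 4.21, 6.08), mk(36623 - 3593, 4.21 - 0.43, 6.08))
  expect_equal(ce$icur, 3593 / 0.43, tolerance = 1e-12)
  expect_equal(round(ce$icur), 8356)
  expect_equal(ce$dominance, "none")

  dom <- compute_ce(mk(99, 1.1, 2), mk(100, 1.0, 2))
  expect_equal(dom$dominance, "intervention_dominant")
  expect_true(is.na(compute_ce(mk(99, 1, 2), mk(100, 1.1, 2))$icur))

  same <- compute_ce(mk(100, 1, 2), mk(100, 1, 2))
  expect_equal(same$delta_cost, 0)
  expect_equal(same$dominance, "none")
  expect_true(is.na(same$icur) && is.na(same$icer))

  # zero QALY delta with a cost delta: flagged undefined, no exception
  flat <- compute_ce(mk(200, 1, 2.5), mk(100, 1, 2))
  expect_true(is.na(flat$icur))
  expect_equal(flat$icer, 100 / 0.5)

  g <- glance(ce)
  expect_s3_class(g, "tbl_df")
  expect_named(g, c("risk_group", "intervention", "comparator", "delta_cost",
                    "delta_qaly", "delta_ly", "icur", "icer", "dominance"))
  expect_equal(nrow(tidy(ce)), 2)
})

test_that("costs are currency-equivariant: scaling every price scales the ratios", {
  ps <- load_parameter_set("high_base")
  ce1 <- compute_ce(run_arm(ps, "tavi"), run_arm(ps, "savr"))
  k <- 1.37
  ps2 <- ps
  ps2$costs$euros <- ps2$costs$euros * k
  ps2$index_costs <- ps2$index_costs * k
  ce2 <- compute_ce(run_arm(ps2, "tavi"), run_arm(ps2, "savr"))
  expect_equal(ce2$delta_cost, k * ce1$delta_cost, tolerance = 1e-12)
  expect_equal(ce2$icur, k * ce1$icur, tolerance = 1e-12)
  expect_equal(ce2$icer, k * ce1$icer, tolerance = 1e-12)
  expect_equal(ce2$delta_qaly, ce1$delta_qaly, tolerance = 1e-15)
})

test_that("ICER does not exceed ICUR when the QALY gain trails the LY gain", {
  for (fx in c("intermediate_base", "high_base", "inoperable_base")) {
    ps <- load_parameter_set(fx)
    ce <- compute_ce(run_arm(ps, ps$settings$intervention),
                     run_arm(ps, ps$settings$comparator))
    if (!is.na(ce$icer) && !is.na(ce$icur) &&
        ce$delta_qaly <= ce$delta_ly && ce$delta_qaly > 0) {
      expect_lte(ce$icer, ce$icur)
    }
  }
})
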