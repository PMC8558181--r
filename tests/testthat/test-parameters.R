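test_that("interval-to-cycle conversion matches the closed form and round-trips", {
  # 5-month band at 3.9%: hand value of 1 - (1 - p)^(1/n)
  expect_equal(interval_to_cycle_probability(0.039, 5),
               1 - exp(log(1 - 0.039) / 5), tolerance = 1e-12)
  expect_equal(interval_to_cycle_probability(0.039, 5), 0.00792460742187,
               tolerance = 1e-9)
  expect_identical(interval_to_cycle_probability(0, 7), 0)
  for (p in c(0.001, 0.3, 0.67, 1)) {
    expect_identical(interval_to_cycle_probability(p, 1), p)
  }
  expect_equal(interval_to_cycle_probability(1, 12), 1)
  expect_error(interval_to_cycle_probability(-0.1, 5), "\\[0, 1\\]")
  expect_error(interval_to_cycle_probability(1.2, 5), "\\[0, 1\\]")
  # round trip: compounding the monthly probability recovers the interval
  set.seed(11)
  for (i in 1:50) {
    p <- runif(1)
    n <- sample(1:24, 1)
    pc <- interval_to_cycle_probability(p, n)
    expect_equal(1 - (1 - pc)^n, p, tolerance = 1e-12)
  }
})

test_that("mortality extrapolation fits OLS to years 2-5 annual probabilities", {
  # published intermediate-risk TAVI mortality: years 2-5 are the four
  # 12-month bands
  p7 <- c(0.010, 0.039, 0.041, 0.076, 0.083, 0.090, 0.099)
  tbl <- interval_table(mortality_bands, p7)
  out <- extrapolate_mortality(tbl, 180)
  expect_length(out, 180)
  expect_true(all(out >= 0 & out <= 1))
  # observed months use the band conversion
  expect_equal(out[1], 0.010)
  expect_equal(out[4], interval_to_cycle_probability(0.039, 5))
  expect_equal(out[60], interval_to_cycle_probability(0.099, 12))
  # year 6 onward: hand least-squares line on (2:5, annual p)
  coefs <- hand_ols(2:5, p7[4:7])
  for (y in c(6, 10, 15)) {
    pa <- coefs[1] + coefs[2] * y
    expect_equal(out[(y - 1) * 12 + 3],
                 interval_to_cycle_probability(pa, 12), tolerance = 1e-12)
  }
})

test_that("a flat mortality trend extrapolates flat and a rising one clamps at 1", {
  flat <- interval_table(mortality_bands,
                         c(0.02, 0.05, 0.06, rep(0.10, 4)))
  out <- extrapolate_mortality(flat, 180)
  expect_equal(out[61:180],
               rep(interval_to_cycle_probability(0.10, 12), 120),
               tolerance = 1e-12)
  expect_length(attr(out, "warnings"), 0)

  steep <- interval_table(mortality_bands,
                          c(0.02, 0.05, 0.06, 0.30, 0.50, 0.70, 0.90))
  out2 <- extrapolate_mortality(steep, 180)
  expect_true(length(attr(out2, "warnings")) > 0)
  expect_true(all(out2 <= 1))
  # once the annual trend passes 1, the monthly probability is that of a
  # certain annual event
  expect_equal(out2[179], 1)
})

test_that("cumulative-mode extrapolation is monotone and matches a hand fit", {
  p7 <- c(0.02, 0.085, 0.094, 0.245, 0.253, 0.258, 0.260)
  tbl <- interval_table(mortality_bands, p7)
  out <- extrapolate_mortality(tbl, 120, mode = "cumulative")
  surv <- cumprod(1 - out)
  expect_true(all(diff(surv) <= 1e-12))
  # hand: cumulative death at end of years 2-5, linear fit, year 6 interval
  cum <- 1 - cumprod(1 - extrapolate_mortality(tbl, 60))[c(24, 36, 48, 60)]
  coefs <- hand_ols(2:5, cum)
  c6 <- coefs[1] + coefs[2] * 6
  pa6 <- (c6 - cum[4]) / (1 - cum[4])
  expect_equal(out[65], interval_to_cycle_probability(pa6, 12),
               tolerance = 1e-12)
})

test_that("event rates carry the last band forward to the horizon", {
  tbl <- interval_table(event_bands, c(0.101, 0.005, 0.001, 0.001))
  out <- extend_event_rates(tbl, 180)
  expect_length(out, 180)
  expect_equal(out[1], 0.101)
  expect_equal(out[25:180],
               rep(interval_to_cycle_probability(0.001, 12), 156),
               tolerance = 1e-15)
  # degenerate single interval: month-1 value carried to every later cycle
  single <- data.frame(start_month = 1, end_month = 1, probability = 0.05)
  expect_equal(extend_event_rates(single, 10), rep(0.05, 10))
  # all-zero table stays zero
  expect_equal(extend_event_rates(interval_table(event_bands, rep(0, 4)), 50),
               rep(0, 50))
  expect_error(extend_event_rates(tbl[0, ], 50), "empty")
})

test_that("packaged fixtures load with the published costs and probabilities", {
  ps <- load_parameter_set("intermediate_base")
  expect_s3_class(ps, "parameter_set")
  expect_equal(ps$costs$euros[ps$costs$item == "tavi_procedure"], 30634)
  expect_equal(ps$costs$euros[ps$costs$item == "savr_procedure"], 24675)
  expect_equal(unname(ps$index_costs["tavi"]), 30634)

  inop <- load_parameter_set("inoperable_base")
  bv <- inop$events[inop$events$arm == "medical" &
                      inop$events$event == "balloon_valvuloplasty" &
                      inop$events$start_month == 1, ]
  expect_equal(bv$probability, 0.67)
  # micro-costing variant swaps the index costs
  mic <- load_parameter_set("high_micro", rehab_cost = 3000)
  expect_equal(unname(mic$index_costs["tavi"]), 26985)
  expect_equal(unname(mic$index_costs["savr"]), 14802)
  expect_true(mic$settings$scenario)
})

test_that("validation rejects perturbed inputs and names the offending cell", {
  expect_error(load_parameter_set("lowrisk_base"), "unknown fixture")

  base <- load_parameter_set("intermediate_base")
  # out-of-range probability
  bad <- base
  i <- which(bad$events$event == "mortality")[1]
  bad$events$probability[i] <- 1.2
  expect_error(validate_parameter_set(bad), "outside \\[0, 1\\]")
  expect_error(validate_parameter_set(bad), "mortality")
  # non-contiguous intervals
  bad <- base
  i <- which(bad$events$event == "tia" & bad$events$arm == "tavi" &
               bad$events$start_month == 7)
  bad$events$start_month[i] <- 8L
  expect_error(validate_parameter_set(bad), "not contiguous")
  # negative cost
  bad <- base
  bad$costs$euros[3] <- -10
  expect_error(validate_parameter_set(bad), "negative unit cost")
  # stroke utility above the no-stroke variant
  bad <- base
  i <- which(bad$utilities$state == "nyha2_stroke" & bad$utilities$arm == "tavi")
  bad$utilities$utility[i] <- 0.99
  expect_error(validate_parameter_set(bad), "nyha2_stroke")
  # random violations: any single probability pushed out of range is caught
  set.seed(7)
  for (k in 1:10) {
    bad <- base
    i <- sample(nrow(bad$events), 1)
    bad$events$probability[i] <- sample(c(-0.2, 1.01, 2), 1)
    expect_error(validate_parameter_set(bad), "outside")
  }
})

test_that("per-cycle sequences span the horizon and stay in [0, 1]", {
  for (fx in c("intermediate_base", "high_base", "inoperable_base")) {
    ps <- load_parameter_set(fx)
    for (arm in c(ps$settings$intervention, ps$settings$comparator)) {
      cp <- cycle_probabilities(ps, arm)
      expect_length(cp$mortality, 180)
      expect_equal(nrow(cp$events), 180)
      expect_true(all(cp$mortality >= 0 & cp$mortality <= 1))
      expect_true(all(cp$events >= 0 & cp$events <= 1))
    }
  }
})

test_that("the loader accepts percent-scaled event files", {
  events <- readr::read_csv(system.file("extdata", "events.csv",
                                        package = "tavicea"),
                            show_col_types = FALSE)
  events$probability <- events$probability * 100
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(events, tmp)
  ps <- load_parameter_set("high_base", events_file = tmp, percent = TRUE)
  ref <- load_parameter_set("high_base")
  expect_equal(ps$events$probability, ref$events$probability)
})
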