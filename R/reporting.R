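#' @keywords internal
.run_manifest <- function(fixtures, settings_list, seed = NULL,
                          warnings = character()) {
  list(package = "tavicea",
       version = as.character(utils::packageVersion("tavicea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       fixtures = fixtures,
       seed = seed,
       settings = settings_list,
       warnings = warnings)
}

.groups_arg <- function(risk_group) {
  if (identical(risk_group, "all")) c("intermediate", "high", "inoperable")
  else match.arg(risk_group, c("intermediate", "high", "inoperable"),
                 several.ok = TRUE)
}

.ce_to_rows <- function(ce) {
  arms <- tidy(ce)
  inc <- glance(ce)
  arms |>
    dplyr::mutate(
      delta_cost = ifelse(.data$arm == inc$intervention, inc$delta_cost, NA),
      delta_qaly = ifelse(.data$arm == inc$intervention, inc$delta_qaly, NA),
      delta_ly = ifelse(.data$arm == inc$intervention, inc$delta_ly, NA),
      icur = ifelse(.data$arm == inc$intervention, inc$icur, NA),
      icer = ifelse(.data$arm == inc$intervention, inc$icer, NA),
      dominance = ifelse(.data$arm == inc$intervention, inc$dominance, NA))
}

#' Run the base-case analysis
#'
#' Runs the full model for one or all risk groups with tariff procedure
#' costs and returns the per-arm discounted totals, incremental
#' quantities and ratios in one tidy table (the layout of a standard
#' base-case results table).  The full `ce_result` objects and the run
#' manifest are attached as attributes.
#'
#' @param risk_group `"all"` (default) or any of `"intermediate"`,
#'   `"high"`, `"inoperable"`.
#' @param utilities_file,transitions_file Optional CSVs replacing the
#'   synthetic utility and NYHA-transition inputs (see
#'   [load_parameter_set()]).
#' @param synthetic Optional [synthetic_config()].
#' @param settings_fn Optional function `risk_group -> model_settings`
#'   overriding the defaults (horizon 180 cycles, 3% discounting).
#' @return A tibble with one row per arm and group, with attributes
#'   `"ce"` (named list of `ce_result`) and `"manifest"`.
#' @export
#' @examples
#' run_base_case("inoperable")
run_base_case <- function(risk_group = "all",
                          utilities_file = NULL, transitions_file = NULL,
                          synthetic = NULL, settings_fn = NULL) {
  groups <- .groups_arg(risk_group)
  ces <- list()
  warnings <- character()
  for (g in groups) {
    st <- if (is.null(settings_fn)) NULL else settings_fn(g)
    ps <- load_parameter_set(paste0(g, "_base"),
                             utilities_file = utilities_file,
                             transitions_file = transitions_file,
                             settings = st, synthetic = synthetic)
    ce <- .run_ce(ps)
    warnings <- c(warnings, ce$intervention$warnings, ce$comparator$warnings)
    ces[[g]] <- ce
  }
  out <- dplyr::bind_rows(lapply(ces, .ce_to_rows))
  attr(out, "ce") <- ces
  attr(out, "manifest") <- .run_manifest(paste0(groups, "_base"),
                                         list(horizon_cycles = 180,
                                              annual_discount_rate = 0.03,
                                              scenario = FALSE),
                                         warnings = unique(warnings))
  out
}

#' Run the micro-costing scenario analysis
#'
#' As [run_base_case()], but with the micro-costing procedure costs for
#' the index intervention and rehabilitation billed at its uptake fraction
#' per arm.  The rehabilitation unit cost is a required input: the tariff
#' the published analysis used is not printed, so no default is asserted.
#'
#' @inheritParams run_base_case
#' @param rehab_cost Rehabilitation unit cost in euros (required).
#' @return A tibble as in [run_base_case()], with the scenario flag in the
#'   manifest.
#' @export
run_scenario <- function(risk_group = "all", rehab_cost,
                         utilities_file = NULL, transitions_file = NULL,
                         synthetic = NULL, settings_fn = NULL) {
  if (missing(rehab_cost) || is.null(rehab_cost)) {
    stop("the scenario analysis needs rehab_cost (euros); the tariff value ",
         "is not published and must be supplied", call. = FALSE)
  }
  groups <- .groups_arg(risk_group)
  ces <- list()
  for (g in groups) {
    st <- if (is.null(settings_fn)) {
      model_settings(g, scenario = TRUE)
    } else {
      settings_fn(g)
    }
    ps <- load_parameter_set(paste0(g, "_micro"),
                             utilities_file = utilities_file,
                             transitions_file = transitions_file,
                             settings = st, rehab_cost = rehab_cost,
                             synthetic = synthetic)
    ces[[g]] <- .run_ce(ps)
  }
  out <- dplyr::bind_rows(lapply(ces, .ce_to_rows))
  attr(out, "ce") <- ces
  attr(out, "manifest") <- .run_manifest(paste0(groups, "_micro"),
                                         list(horizon_cycles = 180,
                                              annual_discount_rate = 0.03,
                                              scenario = TRUE,
                                              rehab_cost = rehab_cost))
  out
}

#' Run the sensitivity analyses
#'
#' One-way (tornado) and probabilistic sensitivity analyses with the
#' acceptability curve for one risk group, optionally writing
#' `tornado.csv`, `psa_draws.csv`, `ceac.csv` and `manifest.json` to a
#' directory.
#'
#' @param risk_group One of `"intermediate"`, `"high"`, `"inoperable"`.
#' @param n_draws PSA simulation runs (default 1000).
#' @param seed PSA seed.
#' @param top_n Tornado entries kept (default 20).
#' @param perturbation One-way perturbation (default 0.20).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @param out_dir Optional output directory.
#' @param params Optional `parameter_set` overriding the packaged
#'   base-case fixture for the group.
#' @return List with `tornado` (an `owsa_result`), `psa` (a
#'   `psa_result`), `ceac` (a `ceac_curve`) and `manifest`.
#' @export
run_sensitivity <- function(risk_group = "intermediate", n_draws = 1000,
                            seed = 1L, top_n = 20, perturbation = 0.20,
                            wtp_grid = seq(0, 100000, by = 1000),
                            out_dir = NULL, params = NULL) {
  if (is.null(params)) {
    params <- load_parameter_set(paste0(.groups_arg(risk_group)[1], "_base"))
  }
  tor <- owsa(params, perturbation = perturbation, top_n = top_n)
  ps <- psa(params, n_draws = n_draws, seed = seed)
  cc <- ceac(ps, wtp_grid = wtp_grid)
  manifest <- .run_manifest(params$settings$risk_group,
                            list(horizon_cycles = params$settings$horizon_cycles,
                                 annual_discount_rate = params$settings$annual_discount_rate,
                                 n_draws = n_draws, perturbation = perturbation,
                                 top_n = top_n),
                            seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(tibble::as_tibble(tor), file.path(out_dir, "tornado.csv"))
    readr::write_csv(ps$draws, file.path(out_dir, "psa_draws.csv"))
    readr::write_csv(tibble::as_tibble(cc), file.path(out_dir, "ceac.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(tornado = tor, psa = ps, ceac = cc, manifest = manifest)
}

#' Export base-case or scenario results
#'
#' Writes `results.csv` and `results.json` (per-arm totals, deltas and
#' ratios), `cost_breakdown.csv` (discounted cost per item and arm) and
#' `manifest.json` for a table produced by [run_base_case()] or
#' [run_scenario()].
#'
#' @param results Tibble from [run_base_case()] / [run_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(results, file.path(dir, "results.csv"))
  jsonlite::write_json(results, file.path(dir, "results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ces <- attr(results, "ce")
  breakdown <- dplyr::bind_rows(lapply(names(ces), function(g) {
    dplyr::bind_rows(lapply(list(ces[[g]]$intervention, ces[[g]]$comparator),
                            function(a) {
      dplyr::mutate(a$cost_breakdown, risk_group = g, arm = a$arm,
                    .before = 1)
    }))
  }))
  readr::write_csv(breakdown, file.path(dir, "cost_breakdown.csv"))
  jsonlite::write_json(attr(results, "manifest"),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
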