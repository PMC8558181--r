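#' Health-state space
#'
#' The model tracks nine mutually exclusive health states: NYHA functional
#' classes I-IV without stroke history, the same four classes with stroke
#' history, and death (the single absorbing state).
#'
#' @return A character vector of the nine state labels, in the canonical
#'   order used by every occupancy vector and transition matrix in the
#'   package: `nyha1` ... `nyha4`, `nyha1_stroke` ... `nyha4_stroke`,
#'   `death`.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c(paste0("nyha", 1:4), paste0("nyha", 1:4, "_stroke"), "death")
}

#' Living health states
#'
#' @return The eight living state labels (NYHA I-IV crossed with stroke
#'   history), in canonical order.
#' @export
living_states <- function() health_states()[1:8]

# index helpers used throughout the engine
.state_death <- 9L
.state_nostroke <- 1:4
.state_stroke <- 5:8

#' Event categories tracked by the model
#'
#' Fifteen event categories are modelled: all-cause mortality plus fourteen
#' clinical events and procedures (major stroke, transient ischaemic
#' attack, atrial fibrillation, renal replacement therapy, myocardial
#' infarction, pacemaker implantation, major bleeding, major vascular
#' complication, hospitalisation for aortic-stenosis symptoms,
#' hospitalisation for heart failure, balloon valvuloplasty, repeat TAVI,
#' repeat surgical replacement, endocarditis).  Only major stroke changes
#' health state; the other events are costed incidences.
#'
#' @return Character vector of the fifteen event labels.
#' @export
event_categories <- function() {
  c("mortality", "major_stroke", "tia", "atrial_fibrillation",
    "renal_replacement", "myocardial_infarction", "new_pacemaker",
    "major_bleeding", "major_vascular", "hosp_as", "hosp_hf",
    "balloon_valvuloplasty", "re_tavi", "re_savr", "endocarditis")
}

# non-mortality events, i.e. those that can carry a unit cost
.costed_events <- function() setdiff(event_categories(), "mortality")
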