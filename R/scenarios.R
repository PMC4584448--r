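#' Trial-type bookkeeping
#'
#' The task crosses three contexts (`Ch`, `Cm`, `Cw`) with two responses
#' (`Rf`, `Rn`), giving six scenarios; each trial additionally carries a
#' perception condition (`Cplus` if the context stimulus was looked at,
#' `Cminus` otherwise), for twelve trial types in total.
#'
#' @return A tibble with one row per trial type and columns `context`,
#'   `response`, `condition`, `scenario` (e.g. `"ChRf"`) and `type`
#'   (e.g. `"ChRf.Cplus"`).
#' @export
#' @examples
#' trial_types()
trial_types <- function() {
  g <- tidyr::expand_grid(
    condition = c("Cplus", "Cminus"),
    response = c("Rf", "Rn"),
    context = c("Ch", "Cm", "Cw")
  )
  tibble::tibble(
    context = g$context,
    response = g$response,
    condition = g$condition,
    scenario = paste0(g$context, g$response),
    type = paste0(g$context, g$response, ".", g$condition)
  )
}

contexts <- function() c("Ch", "Cm", "Cw")
responses <- function() c("Rf", "Rn")
conditions <- function() c("Cplus", "Cminus")

#' Task timeline
#'
#' A trial is a Waiting period (still image, no couplings planted by the
#' generator), a Context period and a Response period. The baseline
#' interval used for causality normalization must lie inside Waiting.
#'
#' @param waiting,context,response Period durations in seconds.
#' @param baseline Numeric length-2, `[start, end]` of the baseline
#'   interval in trial-relative seconds; defaults to the Waiting period
#'   minus a 0.25 s guard at each edge.
#' @param trial_length Total trial duration in seconds (may exceed the sum
#'   of the periods; the tail belongs to the next Waiting period).
#' @return An object of class `ercnet_timeline`.
#' @export
task_timeline <- function(waiting = 2.5, context = 1.5, response = 3,
                          baseline = NULL, trial_length = NULL) {
  if (any(c(waiting, context, response) <= 0)) {
    abort_config("all timeline durations must be > 0")
  }
  baseline <- baseline %||% c(0.25, waiting - 0.25)
  if (baseline[1] < 0 || baseline[2] > waiting || baseline[1] >= baseline[2]) {
    abort_config("baseline interval must lie entirely within the Waiting period")
  }
  trial_length <- trial_length %||% (waiting + context + response + 1)
  structure(
    list(
      waiting = waiting, context = context, response = response,
      baseline = baseline, trial_length = trial_length,
      context_on = waiting,
      response_on = waiting + context,
      response_off = waiting + context + response
    ),
    class = "ercnet_timeline"
  )
}

#' @export
print.ercnet_timeline <- function(x, ...) {
  cat(sprintf(
    "<ercnet_timeline> Waiting %.2gs | Context %.2gs | Response %.2gs (trial %.2gs, baseline [%.2g, %.2g]s)\n",
    x$waiting, x$context, x$response, x$trial_length,
    x$baseline[1], x$baseline[2]
  ))
  invisible(x)
}

#' The eighteen condition-contrast specifications
#'
#' Nine ordered scenario pairs are compared, each separately within the
#' `Cplus` and `Cminus` conditions: three context contrasts under `Rf`
#' (ChRf-CmRf, CmRf-CwRf, CwRf-ChRf), three under `Rn`, and three
#' response contrasts (ChRf-ChRn, CmRf-CmRn, CwRf-CwRn).
#'
#' @return A tibble with 18 rows and columns `comparison` (label),
#'   `family` (`context_Rf`, `context_Rn`, `response`), `minuend`,
#'   `subtrahend` (scenario labels) and `condition`.
#' @export
#' @examples
#' build_comparisons()
build_comparisons <- function() {
  pairs <- tibble::tribble(
    ~family, ~minuend, ~subtrahend,
    "context_Rf", "ChRf", "CmRf",
    "context_Rf", "CmRf", "CwRf",
    "context_Rf", "CwRf", "ChRf",
    "context_Rn", "ChRn", "CmRn",
    "context_Rn", "CmRn", "CwRn",
    "context_Rn", "CwRn", "ChRn",
    "response", "ChRf", "ChRn",
    "response", "CmRf", "CmRn",
    "response", "CwRf", "CwRn"
  )
  out <- tidyr::expand_grid(condition = conditions(), pairs)
  out <- out[, c("family", "minuend", "subtrahend", "condition")]
  out$comparison <- paste0(out$minuend, "-", out$subtrahend, ".", out$condition)
  out[, c("comparison", "family", "minuend", "subtrahend", "condition")]
}
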