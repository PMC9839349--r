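#' Population code
#'
#' Container for a deterministic population code: an `N x M` matrix of
#' baseline-subtracted responses `r_i(theta_m)` (N neurons, M stimuli),
#' an optional length-N vector of spontaneous rates `delta`, and the
#' stimulus grid. The baseline-subtracted responses define the code's
#' inner-product kernel and hence its inductive bias; the total activity
#' `s = r + delta` (which must be nonnegative) is what metabolic-cost
#' analyses operate on.
#'
#' @param responses numeric `N x M` matrix of baseline-subtracted rates.
#' @param grid a [stimulus_grid()] with M stimuli.
#' @param baseline optional length-N spontaneous-rate vector `delta`.
#' @return an object of class `population_code`.
#' @export
population_code <- function(responses, grid, baseline = NULL) {
  check_finite_matrix(responses, "responses")
  stopifnot(inherits(grid, "stimulus_grid"))
  if (ncol(responses) != n_stimuli(grid)) {
    stop_invalid("responses has ", ncol(responses), " columns but the grid has ",
                 n_stimuli(grid), " stimuli")
  }
  if (!is.null(baseline)) {
    baseline <- as.numeric(baseline)
    if (length(baseline) != nrow(responses) || !all(is.finite(baseline))) {
      stop_invalid("baseline must be a finite vector of length N")
    }
    if (min(responses + baseline) < -1e-10) {
      stop_invalid("total activity (responses + baseline) must be nonnegative")
    }
  }
  structure(
    list(responses = responses, baseline = baseline, grid = grid),
    class = "population_code"
  )
}

#' Total spiking activity of a code
#'
#' Returns `s = r + delta`, the nonnegative total activity matrix. Codes
#' without a stored baseline must already be nonnegative.
#'
#' @param code a [population_code()].
#' @return `N x M` nonnegative matrix.
#' @export
total_activity <- function(code) {
  s <- code$responses
  if (!is.null(code$baseline)) s <- s + code$baseline
  if (min(s) < -1e-10) {
    stop_invalid("code has no baseline making total activity nonnegative")
  }
  pmax(s, 0)
}

n_neurons <- function(code) nrow(code$responses)

#' @export
print.population_code <- function(x, ...) {
  cat(sprintf(
    "<population_code: %d neurons x %d stimuli%s>\n",
    nrow(x$responses), ncol(x$responses),
    if (is.null(x$baseline)) "" else ", with baseline"
  ))
  invisible(x)
}
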