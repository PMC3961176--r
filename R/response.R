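# The response measure: percentage increase of the peak target level over
# the control peak, under chronic percentage parameter perturbations.

#' Build a cached response function for a model under a protocol
#'
#' Returns a closure `f(deltas)` mapping named percentage parameter changes
#' to the simulated response.  For three-node motifs the response is the
#' percentage increase of the peak level of T over the control peak; for
#' the CREB model it is the percentage increase of the HIGH-state
#' `[CREB1]/[CREB2]` ratio over control.  The control is computed once when
#' the closure is built.  Perturbations are chronic: parameters are changed
#' at t = 0 and held throughout.
#'
#' The initial state of every three-node run is the *unperturbed* model's
#' pre-stimulus steady state.  Motifs without a finite resting state
#' (mutual excitation, positive auto-regulation, positive feedback from T)
#' fall back to the resting
#' state of the canonical model with the same parameters, i.e. the state
#' the pathway occupies before the motif's feedback and the drug take
#' effect.
#'
#' @param model A `motif_model` or `creb_model`.
#' @param protocol A [stimulus_protocol] (three-node models; the CREB model
#'   always uses its 5-HT protocol).
#' @param t_end Simulation horizon, minutes (default 3000; automatically
#'   doubled, up to 24000, when the peak falls in the final 5% of samples).
#' @param dt Integration step, minutes.
#' @param b_delay Delay of the stimulus seen by B, minutes.
#' @param init Optional fixed initial state overriding the defaults above.
#' @param ... Passed to methods.
#' @return A function `f(deltas)`; `f(numeric())` is exactly 0.  The
#'   control peak (or ratio) is available as `attr(f, "control")` and the
#'   initial state as `attr(f, "init")`.
#' @export
make_response_fn <- function(model, protocol = NULL, t_end = 3000,
                             dt = 0.05, b_delay = 0, init = NULL, ...) {
  UseMethod("make_response_fn")
}

#' @rdname make_response_fn
#' @param extend,t_cap Horizon-extension policy: when `extend` is `TRUE`
#'   the horizon doubles (up to `t_cap`) until the peak is interior.
#' @export
make_response_fn.motif_model <- function(model, protocol = NULL,
                                         t_end = 3000, dt = 0.05,
                                         b_delay = 0, init = NULL,
                                         extend = TRUE, t_cap = 24000, ...) {
  if (is.null(protocol)) stop("a stimulus protocol is required")
  if (is.null(init)) init <- .resting_state(model, dt = dt)
  control <- .peak_T(model, protocol, init, t_end = t_end, dt = dt,
                     b_delay = b_delay, extend = extend, t_cap = t_cap)$peak
  if (control <= 0) stop("control peak must be positive")
  f <- function(deltas = numeric()) {
    if (length(deltas) == 0) return(0)
    pert <- apply_deltas(model, deltas)
    pk <- .peak_T(pert, protocol, init, t_end = t_end, dt = dt,
                  b_delay = b_delay, extend = extend, t_cap = t_cap)$peak
    100 * (pk - control) / control
  }
  attr(f, "control") <- control
  attr(f, "init") <- init
  f
}

# Resting state with fallback: motifs whose basal dynamics do not settle
# (no finite fixed point under the regulated-rate dialect) start from the
# canonical resting state with the same parameters and variant.
.resting_state <- function(model, dt = 0.05) {
  tryCatch(find_presimulus_steady_state(model, dt = dt),
           error = function(e) {
             fallback <- model
             fallback$overrides <- list()
             find_presimulus_steady_state(fallback, dt = dt)
           })
}

#' Response to a set of parameter changes
#'
#' One-shot convenience wrapper around [make_response_fn()]: the percentage
#' increase of the peak level of T (three-node motifs) over the control
#' peak under the given chronic percentage parameter changes.
#'
#' @inheritParams make_response_fn
#' @param deltas Named numeric vector of signed percentage changes.
#' @return Percentage increase over control (0 for empty `deltas`).
#' @examples
#' \donttest{
#' response(motif_model("canonical_m"), square_pulse(1), c(k_dA = -45))
#' }
#' @export
response <- function(model, protocol = NULL, deltas = numeric(), ...) {
  make_response_fn(model, protocol, ...)(deltas)
}

#' Direction of a single-parameter perturbation
#'
#' Each swept parameter is perturbed in the direction that increases the
#' response (the peak level of T, or the CREB ratio): the full-budget
#' response is simulated for both signs and the larger one wins.  Ties
#' break toward +1 with a warning.  If both directions decrease the
#' response the less harmful sign is returned, flagged with attribute
#' `ineffective = TRUE` (the pair pipeline still runs).
#'
#' @param model A `motif_model` or `creb_model`, or a response closure
#'   from [make_response_fn()].
#' @param protocol Stimulus protocol (models only).
#' @param param Parameter name.
#' @param budget Perturbation budget, percent (default 90).
#' @param ... Passed to [make_response_fn()].
#' @return +1 or -1, possibly with attribute `ineffective`.
#' @export
determine_direction <- function(model, protocol = NULL, param,
                                budget = 90, ...) {
  resp <- if (is.function(model)) model
          else make_response_fn(model, protocol, ...)
  .direction(resp, param, budget)
}

.direction <- function(resp, param, budget) {
  up <- as.numeric(resp(setNames(+budget, param)))
  dn <- as.numeric(resp(setNames(-budget, param)))
  if (up == dn) {
    warning("both directions of '", param,
            "' give the same response; choosing +1")
    sgn <- +1
  } else {
    sgn <- if (up > dn) +1 else -1
  }
  if (max(up, dn) <= 0) attr(sgn, "ineffective") <- TRUE
  sgn
}
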