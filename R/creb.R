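# The two-gene CREB1/CREB2 interlocked-feedback model: bistable LOW/HIGH
# states, the 5-HT pulse-train protocol, and the [CREB1]/[CREB2] response.

#' Build the CREB1/CREB2 model
#'
#' Two ODEs for the levels of the transcription activator CREB1 (`x`) and
#' the repressor CREB2 (`y`), which bind competitively, as dimers, to
#' shared CRE sites: `dx/dt = r_bas_x + V_x_eff*occ - k_dx*x` and
#' `dy/dt = r_bas_y + V_y*occ - k_dy*y`, with CRE occupancy by CREB1
#' `occ = (x^2/K_x) / (1 + x^2/K_x + y^2/K_y)` (`K_x`, `K_y` are dimer-DNA
#' dissociation constants in squared-concentration units).  The quadratic
#' self-activation makes the switch bistable at standard parameters (LOW
#' and HIGH states); a 5-HT pulse train transiently raises the effective
#' `V_x` and switches the system LOW to HIGH.
#'
#' @param params Named vector of the 8 parameters; defaults to
#'   [creb_params()].
#' @return An object of class `creb_model`.
#' @export
creb_model <- function(params = creb_params()) {
  params <- .validate_params(params, .creb_param_order)
  structure(list(params = params), class = "creb_model")
}

#' @export
print.creb_model <- function(x, ...) {
  cat("CREB1/CREB2 interlocked-feedback model\n")
  cat("  parameters:", paste(sprintf("%s=%g", names(x$params), x$params),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Right-hand side of the CREB1/CREB2 model
#'
#' @param state Numeric vector `(x, y)` = (CREB1, CREB2), non-negative.
#' @param t Time (unused).
#' @param params The 8 CREB parameters.
#' @param V_x_effective Effective maximal CREB1 synthesis rate (min^-1);
#'   the stimulus protocol elevates this above `V_x`.
#' @return Named derivative vector `(CREB1, CREB2)`.
#' @export
creb_rhs <- function(state, t = 0, params = creb_params(),
                     V_x_effective = params[["V_x"]]) {
  if (any(!is.finite(state))) stop("non-finite state")
  x <- state[[1]]; y <- state[[2]]
  occ <- (x^2 / params[["K_x"]]) /
    (1 + x^2 / params[["K_x"]] + y^2 / params[["K_y"]])
  c(CREB1 = params[["r_bas_x"]] + V_x_effective * occ - params[["k_dx"]] * x,
    CREB2 = params[["r_bas_y"]] + params[["V_y"]] * occ - params[["k_dy"]] * y)
}

#' The 5-HT stimulation protocol
#'
#' Five 5-min pulses with a 20-min interstimulus gap, during which the
#' effective `V_x` is elevated; at the standard `V_x` of 0.4 min^-1 the
#' elevated value is 3.7 min^-1.  When `V_x` is perturbed the elevated
#' value scales proportionally (5-HT is treated as a fold-induction of
#' CREB1 synthesis capacity, so a chronic change of `V_x` scales both the
#' basal and the induced rate).
#'
#' @param params CREB parameter vector (the baseline is its `V_x`).
#' @param fold Elevation factor (default 3.7/0.4 = 9.25).
#' @param n_pulses,pulse_duration,interstimulus_interval,onset Protocol
#'   geometry, minutes; defaults are the standard 5 x 5-min / 20-min-gap
#'   protocol.
#' @return A [stimulus_protocol] over the effective `V_x`.
#' @examples
#' apply_5ht_protocol()  # amplitude 3.7, baseline 0.4
#' @export
apply_5ht_protocol <- function(params = creb_params(), fold = 3.7 / 0.4,
                               n_pulses = 5, pulse_duration = 5,
                               interstimulus_interval = 20, onset = 0) {
  vx <- params[["V_x"]]
  pulse_train(amplitude = vx * fold, baseline = vx, n_pulses = n_pulses,
              pulse_duration = pulse_duration,
              interstimulus_interval = interstimulus_interval, onset = onset)
}

#' LOW and HIGH steady states of the CREB model
#'
#' The LOW state is located by basal relaxation from the origin (stimulus
#' at baseline `V_x`); the HIGH state by running the 5-HT protocol from the
#' LOW state and relaxing until the derivative norm falls below `tol`.
#'
#' @param model A `creb_model`.
#' @param protocol Protocol used to reach the HIGH state; defaults to
#'   [apply_5ht_protocol()] for the model's parameters.
#' @param dt Integration step, minutes.
#' @param tol Convergence tolerance, per minute.
#' @param t_max Maximum relaxation horizon, minutes.
#' @return For `creb_low_state`/`creb_high_state`: a named state vector
#'   with attribute `residual`.  For `creb_steady_states`: list with
#'   elements `low` and `high`.
#' @export
creb_low_state <- function(model = creb_model(), dt = 0.05, tol = 1e-9,
                           t_max = 5e4) {
  p <- unname(model$params[.creb_param_order])
  res <- .settle_creb_cpp(p, model$params[["V_x"]], c(0, 0), dt, tol, t_max)
  if (!res$converged)
    stop(sprintf("CREB basal state did not converge (residual %.3g/min)",
                 res$residual))
  structure(setNames(res$state, c("CREB1", "CREB2")),
            residual = res$residual)
}

#' @rdname creb_low_state
#' @export
creb_high_state <- function(model = creb_model(),
                            protocol = apply_5ht_protocol(model$params),
                            dt = 0.05, tol = 1e-9, t_max = 5e4) {
  low <- creb_low_state(model, dt = dt, tol = tol, t_max = t_max)
  p <- unname(model$params[.creb_param_order])
  span <- protocol_span(protocol)
  sim <- .sim_creb_cpp(p, .proto_vec(protocol), as.numeric(low), span, dt,
                       FALSE)
  res <- .settle_creb_cpp(p, model$params[["V_x"]], sim$final_state, dt,
                          tol, t_max)
  if (!res$converged)
    stop(sprintf(
      "CREB post-stimulus state did not converge (residual %.3g/min)",
      res$residual))
  structure(setNames(res$state, c("CREB1", "CREB2")),
            residual = res$residual)
}

#' @rdname creb_low_state
#' @export
creb_steady_states <- function(model = creb_model(), dt = 0.05, tol = 1e-9,
                               t_max = 5e4) {
  list(low = creb_low_state(model, dt = dt, tol = tol, t_max = t_max),
       high = creb_high_state(model, dt = dt, tol = tol, t_max = t_max))
}

#' CREB response to parameter perturbations
#'
#' Applies percentage parameter changes (a chronic perturbation, present
#' before and throughout the protocol), starts the perturbed system from
#' its LOW state, runs the 5-HT protocol, relaxes to the post-stimulus
#' steady state and returns the percentage increase of the HIGH-state
#' `[CREB1]/[CREB2]` ratio over the unperturbed control.
#'
#' @param deltas Named vector of signed percentage changes of the 8
#'   parameters (empty for the control).
#' @param model A `creb_model` (standard parameters by default).
#' @param dt,tol,t_max Passed to the relaxation (see [creb_low_state()]).
#' @param require_switch If `TRUE`, raise an error when the perturbed
#'   system fails to leave its LOW state.
#' @return Percentage increase of the ratio over control (0 for empty
#'   `deltas`), with attribute `switched`.
#' @export
creb_response <- function(deltas = numeric(), model = creb_model(),
                          dt = 0.05, tol = 1e-9, t_max = 5e4,
                          require_switch = TRUE) {
  resp <- make_response_fn(model, dt = dt, tol = tol, t_max = t_max,
                           require_switch = require_switch)
  resp(deltas)
}

# Ratio after protocol + relaxation for one (possibly perturbed) model.
.creb_ratio_run <- function(model, dt, tol, t_max, require_switch) {
  protocol <- apply_5ht_protocol(model$params)
  low <- creb_low_state(model, dt = dt, tol = tol, t_max = t_max)
  p <- unname(model$params[.creb_param_order])
  span <- protocol_span(protocol)
  sim <- .sim_creb_cpp(p, .proto_vec(protocol), as.numeric(low), span, dt,
                       FALSE)
  res <- .settle_creb_cpp(p, model$params[["V_x"]], sim$final_state, dt,
                          tol, t_max)
  if (!res$converged)
    stop(sprintf(
      "perturbed CREB system failed to reach a steady state (residual %.3g/min)",
      res$residual))
  switched <- abs(res$state[1] - low[["CREB1"]]) > 1e-3 * (1 + low[["CREB1"]])
  if (require_switch && !switched)
    stop("perturbed CREB system failed to switch out of the LOW state")
  structure(res$state[1] / res$state[2], switched = switched)
}

#' @rdname make_response_fn
#' @param tol,t_max,require_switch CREB relaxation settings, see
#'   [creb_response()].
#' @export
make_response_fn.creb_model <- function(model, protocol = NULL,
                                        t_end = NULL, dt = 0.05,
                                        b_delay = 0, init = NULL,
                                        tol = 1e-9, t_max = 5e4,
                                        require_switch = FALSE, ...) {
  control <- as.numeric(.creb_ratio_run(model, dt, tol, t_max,
                                        require_switch = TRUE))
  function(deltas = numeric()) {
    if (length(deltas) == 0) return(0)
    pert <- apply_deltas(model, deltas)
    r <- .creb_ratio_run(pert, dt, tol, t_max, require_switch)
    structure(100 * (as.numeric(r) - control) / control,
              switched = attr(r, "switched"))
  }
}
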