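# Fixed-step RK4 integration, pre-stimulus equilibration and peak extraction.

.new_time_course <- function(times, states, variable_names, dt) {
  colnames(states) <- variable_names
  structure(list(times = times, states = states,
                 variable_names = variable_names, dt = dt),
            class = "time_course")
}

#' Integrate a model with fixed-step fourth-order Runge-Kutta
#'
#' Classical RK4 with a fixed step `dt` (default 0.05 min, i.e. 3 s), the
#' reference integration method for all models in this package.  The
#' stimulus protocol is evaluated at the sub-stage times `t`, `t + dt/2`
#' and `t + dt`; pulse edges that are multiples of `dt` are therefore
#' handled without ambiguity.
#'
#' @param model A `motif_model`, a `creb_model`, or a plain R function
#'   `f(t, y)` returning the derivative vector (for test problems).
#' @param protocol A [stimulus_protocol] (ignored for function models).
#'   For `motif_model`s the protocol drives the stimulus S; for
#'   `creb_model`s it drives the effective `V_x`.
#' @param init Initial state.  For `motif_model`s, defaults to the
#'   pre-stimulus steady state ([find_presimulus_steady_state()]); for
#'   `creb_model`s, to the LOW state.  Required for function models.
#' @param t_end Simulation horizon, minutes (default 3000 for three-node
#'   motifs, 5000 for CREB).
#' @param dt Time step, minutes (default 0.05).
#' @param b_delay Delay (minutes) of the stimulus seen by element B only;
#'   used by the delayed-B sensitivity scenario (three-node models only).
#' @return An object of class `time_course`: uniformly sampled trajectory
#'   with elements `times`, `states` (matrix, one column per variable),
#'   `variable_names` and `dt`.
#' @examples
#' tc <- integrate_rk4(function(t, y) -0.2 * y, init = c(A = 1), t_end = 5)
#' tail(as.data.frame(tc), 1)  # exp(-1)
#' @export
integrate_rk4 <- function(model, protocol = NULL, init = NULL,
                          t_end = NULL, dt = 0.05, b_delay = 0) {
  stopifnot(dt > 0)
  if (is.function(model)) {
    if (is.null(init)) stop("init is required for a function model")
    if (is.null(t_end)) stop("t_end is required for a function model")
    res <- .rk4_generic_cpp(function(t, y) as.numeric(model(t, y)),
                            as.numeric(init), t_end, dt)
    nms <- names(init)
    if (is.null(nms)) nms <- paste0("y", seq_along(init))
    return(.new_time_course(res$times, res$states, nms, dt))
  }
  UseMethod("integrate_rk4")
}

#' @export
integrate_rk4.motif_model <- function(model, protocol = NULL, init = NULL,
                                      t_end = 3000, dt = 0.05, b_delay = 0) {
  if (is.null(protocol)) protocol <- constant_stimulus(0)
  if (is.null(t_end)) t_end <- 3000
  if (is.null(init)) init <- find_presimulus_steady_state(model, dt = dt)
  if (length(init) != 3) stop("initial state must have length 3 (A, B, T)")
  a <- .tn_cpp_args(model)
  res <- .sim_three_node_cpp(a$params, a$variant, a$ovA, a$ovAk, a$ovB,
                             a$ovBk, .proto_vec(protocol), b_delay,
                             as.numeric(init), t_end, dt, TRUE)
  .new_time_course(res$times, res$states, c("A", "B", "T"), dt)
}

#' @export
integrate_rk4.creb_model <- function(model, protocol = NULL, init = NULL,
                                     t_end = 5000, dt = 0.05, b_delay = 0) {
  if (is.null(protocol)) protocol <- constant_stimulus(model$params[["V_x"]])
  if (is.null(t_end)) t_end <- 5000
  if (is.null(init)) init <- creb_low_state(model, dt = dt)
  if (length(init) != 2) stop("initial state must have length 2 (CREB1, CREB2)")
  res <- .sim_creb_cpp(unname(model$params[.creb_param_order]),
                       .proto_vec(protocol), as.numeric(init), t_end, dt, TRUE)
  .new_time_course(res$times, res$states, c("CREB1", "CREB2"), dt)
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: %d samples, t = 0..%g min (dt = %g), variables: %s\n",
              length(x$times), max(x$times), x$dt,
              paste(x$variable_names, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  data.frame(time_min = x$times, x$states, check.names = FALSE)
}

#' @export
plot.time_course <- function(x, variables = x$variable_names,
                             xlab = "time (min)", ylab = "level",
                             col = seq_along(variables), lty = 1, ...) {
  graphics::matplot(x$times, x$states[, variables, drop = FALSE],
                    type = "l", xlab = xlab, ylab = ylab, col = col,
                    lty = lty, ...)
  graphics::legend("topright", legend = variables, col = col, lty = lty,
                   bty = "n")
  invisible(x)
}

#' Pre-stimulus steady state
#'
#' Locates the resting state of a model with the stimulus held at baseline
#' (S = 0 for three-node motifs) by long basal integration from the origin,
#' stopping when the maximum absolute time-derivative falls below `tol`.
#' This state is the default initial condition for all three-node
#' simulations.  Motifs whose regulated deactivation cannot balance basal
#' activation (mutual excitation, positive auto-regulation and positive
#' feedback from T, under the hyperbolic rate forms) have no finite
#' resting state; for these the function raises an error reporting the
#' residual, and the simulation pipeline falls back to the canonical
#' resting state (see [make_response_fn()]).
#'
#' @param model A `motif_model`.
#' @param dt Integration step, minutes.
#' @param tol Convergence tolerance on the derivative, per minute.
#' @param t_max Maximum equilibration horizon, minutes.
#' @param init Starting point of the relaxation (default: origin).
#' @return Named state vector `(A, B, T)` with attributes `residual` and
#'   `t` (time at which convergence was reached).
#' @examples
#' find_presimulus_steady_state(motif_model("canonical_m"))  # A = B = 1
#' @export
find_presimulus_steady_state <- function(model, dt = 0.05, tol = 1e-9,
                                         t_max = 2e5, init = c(0, 0, 0)) {
  stopifnot(inherits(model, "motif_model"))
  a <- .tn_cpp_args(model)
  res <- .settle_three_node_cpp(a$params, a$variant, a$ovA, a$ovAk, a$ovB,
                                a$ovBk, 0, as.numeric(init), dt, tol, t_max)
  if (!res$converged)
    stop(sprintf(paste0("basal steady state did not converge for motif '%s' ",
                        "within %g min (residual %.3g/min)"),
                 model$motif, t_max, res$residual))
  structure(setNames(res$state, c("A", "B", "T")),
            residual = res$residual, t = res$t)
}

#' Peak response of a trajectory variable
#'
#' The global maximum of a state variable over the sampled trajectory and
#' the time at which it occurs.  The peak of the target T is the response
#' measure of the three-node models.  Warns when the maximum falls on the
#' final sample (the horizon was too short to bracket the peak).
#'
#' @param tc A `time_course`.
#' @param variable Variable label (default `"T"`).
#' @return List with elements `peak` and `time`.
#' @examples
#' tc <- integrate_rk4(motif_model("canonical_m"), square_pulse(1),
#'                     t_end = 500)
#' peak_response(tc)
#' @export
peak_response <- function(tc, variable = "T") {
  stopifnot(inherits(tc, "time_course"))
  if (!variable %in% tc$variable_names)
    stop("unknown variable '", variable, "'; trajectory has: ",
         paste(tc$variable_names, collapse = ", "))
  v <- tc$states[, variable]
  i <- which.max(v)
  if (i == length(v))
    warning("peak of '", variable,
            "' occurs at the final sample; horizon may be too short")
  list(peak = v[[i]], time = tc$times[[i]])
}

# Fast path used by the perturbation pipeline: peak of T without storing the
# trajectory, with automatic horizon doubling (up to t_cap) when the peak
# falls in the final 5% of samples.  Divergent perturbed systems (where T
# drifts upward throughout) run to t_cap and report the end-of-window peak.
.peak_T <- function(model, protocol, init, t_end = 3000, dt = 0.05,
                    b_delay = 0, extend = TRUE, t_cap = 24000) {
  a <- .tn_cpp_args(model)
  pv <- .proto_vec(protocol)
  y0 <- as.numeric(init)
  repeat {
    res <- .sim_three_node_cpp(a$params, a$variant, a$ovA, a$ovAk, a$ovB,
                               a$ovBk, pv, b_delay, y0, t_end, dt, FALSE)
    interior <- res$peak_index < 0.95 * (res$n_samples - 1)
    if (interior || !extend || t_end >= t_cap)
      return(list(peak = res$peak, time = res$peak_time, t_end = t_end,
                  interior = interior))
    t_end <- min(2 * t_end, t_cap)
  }
}

#' Write a time course as tidy CSV
#'
#' One row per sample with columns `time_min` and one per state variable.
#'
#' @param tc A `time_course`.
#' @param path Output file.
#' @param every Keep every `every`-th sample (1 = all samples).
#' @return The path, invisibly.
#' @export
write_time_course <- function(tc, path, every = 1L) {
  df <- as.data.frame(tc)
  if (every > 1L) df <- df[seq(1, nrow(df), by = every), , drop = FALSE]
  df[] <- lapply(df, function(col) sprintf("%.8g", col))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
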