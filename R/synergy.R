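# Nonlinear-blending (NB) and additive-effect (AE) curves for a parameter
# pair under a fixed total perturbation budget, and the degrees of NB and
# additive synergism derived from them.

#' Enumerate unordered parameter pairs
#'
#' All distinct unordered pairs of the supplied parameter names, in
#' lexicographic canonical order (14 names give 91 pairs, 8 give 28).
#'
#' @param params Character vector of at least two distinct names, or a
#'   model (its sweep-eligible names are used).
#' @return Data frame with columns `param_1`, `param_2` and a `pair` label.
#' @examples
#' nrow(enumerate_pairs(sweep_parameters()))   # 91
#' @export
enumerate_pairs <- function(params) {
  if (!is.character(params)) params <- sweep_parameters(params)
  if (anyDuplicated(params)) stop("duplicate parameter names")
  if (length(params) < 2) stop("need at least two parameter names")
  # radix = C-locale byte order, so pair labels are locale-independent
  nm <- sort(params, method = "radix")
  cmb <- utils::combn(nm, 2)
  data.frame(param_1 = cmb[1, ], param_2 = cmb[2, ],
             pair = paste(cmb[1, ], cmb[2, ], sep = "/"),
             stringsAsFactors = FALSE)
}

#' Allocation grid for blending curves
#'
#' `n_points` evenly spaced fractions f in [0, 1] (endpoints included).
#' At each point parameter 1 takes `f * budget` percent of the change and
#' parameter 2 takes `(1 - f) * budget`, so the sum of absolute percentage
#' changes is the budget everywhere on the grid.
#'
#' @param n_points Number of grid points (default 30).
#' @param budget Total budget in percent (default 90; must be in (0, 100)).
#' @return Data frame with columns `f`, `delta1_pct`, `delta2_pct`.
#' @export
allocation_grid <- function(n_points = 30, budget = 90) {
  if (n_points < 3) stop("need at least 3 grid points")
  if (budget <= 0 || budget >= 100) stop("budget must be in (0, 100)")
  f <- seq(0, 1, length.out = n_points)
  data.frame(f = f, delta1_pct = f * budget, delta2_pct = (1 - f) * budget)
}

#' Blending analysis of one parameter pair
#'
#' Builds the nonlinear-blending (NB) and additive-effect (AE) curves for a
#' pair of parameters under the budget constraint.  The NB value at grid
#' fraction f is the response to the *joint* change (f of the budget on
#' parameter 1, the rest on parameter 2); the AE value is the sum of the
#' two single-parameter responses at the same allocations.  Directions are
#' chosen per parameter to increase the response unless supplied.
#'
#' @param model A `motif_model` or `creb_model`.
#' @param protocol Stimulus protocol (three-node models).
#' @param pair Character vector of two parameter names.
#' @param budget Total perturbation budget in percent (default 90).
#' @param n_grid Number of allocation grid points (default 30).
#' @param directions Optional numeric vector of two signs; determined
#'   automatically when `NULL`.
#' @param resp Optional response closure from [make_response_fn()] (reused
#'   across pairs by the sweep machinery).
#' @param ... Passed to [make_response_fn()].
#' @return An object of class `blending_curves`: list with `pair`,
#'   `directions`, `grid` (data frame `f`, `delta1_pct`, `delta2_pct`),
#'   `nb`, `ae` (percent increase over control per grid point),
#'   `control_peak`, `budget`, and `degrees` (see [synergy_degrees()]).
#' @examples
#' \donttest{
#' bc <- blending(motif_model("canonical_m"), square_pulse(1),
#'                c("k_dA", "k_dB"))
#' bc$degrees
#' }
#' @export
blending <- function(model, protocol = NULL, pair, budget = 90,
                     n_grid = 30, directions = NULL, resp = NULL, ...) {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  if (is.null(resp)) resp <- make_response_fn(model, protocol, ...)
  if (is.null(directions))
    directions <- c(.direction(resp, pair[1], budget),
                    .direction(resp, pair[2], budget))
  grid <- allocation_grid(n_grid, budget)
  d1 <- directions[[1]] * grid$delta1_pct
  d2 <- directions[[2]] * grid$delta2_pct
  single1 <- vapply(d1, function(d)
    if (d == 0) 0 else as.numeric(resp(setNames(d, pair[1]))), numeric(1))
  single2 <- vapply(d2, function(d)
    if (d == 0) 0 else as.numeric(resp(setNames(d, pair[2]))), numeric(1))
  nb <- vapply(seq_len(n_grid), function(i) {
    if (grid$f[i] == 0) return(single2[i])
    if (grid$f[i] == 1) return(single1[i])
    as.numeric(resp(setNames(c(d1[i], d2[i]), pair)))
  }, numeric(1))
  ae <- single1 + single2
  structure(list(pair = pair, directions = as.numeric(directions),
                 grid = grid, nb = nb, ae = ae,
                 control_peak = attr(resp, "control"), budget = budget,
                 degrees = synergy_degrees(nb, ae, grid$f)),
            class = "blending_curves")
}

#' Degrees of NB and additive synergism
#'
#' `degree_nb()` implements the nonlinear-blending rule: with
#' `E = max(NB(0), NB(1))` the maximal single-parameter effect, the degree
#' of strong NB synergism is `max(NB) - E` when positive.  Otherwise, if
#' the curve nowhere falls below the straight chord between its endpoints
#' (within `tol`) the pair shows weak NB synergism, degree 0; if it does
#' fall below the chord (concave up) the degree is the most negative
#' deviation below the chord (antagonism).  `degree_additive()` uses the
#' maximal difference between the NB and AE curves as a signed quantity:
#' the degree is the value of `NB - AE` at the grid point where the
#' absolute gap `|NB - AE|` is largest.  (The curves coincide at the
#' endpoints by construction, so an unsigned maximum could never be
#' negative; the signed rule lets a pair whose AE curve lies above its NB
#' curve show additive antagonism with a negative degree.)  A degree > 1
#' is classified synergistic and a negative degree antagonistic.  The
#' largest and most negative differences are both recorded so that
#' intertwined curves (simultaneous additive synergism and antagonism)
#' remain reportable.
#'
#' @param nb,ae Numeric vectors of NB and AE responses on the grid.
#' @param f Grid fractions (defaults to an even grid over the curve).
#' @param tol Numerical tolerance for the classification (default 1e-6).
#' @return `degree_nb`: list `(degree, class)` with class one of
#'   `"strong"`, `"weak"`, `"antagonistic"`.  `degree_additive`: list
#'   `(degree, class, degree_max, degree_min)` with class
#'   `"synergistic"`, `"neutral"` or `"antagonistic"`.
#'   `synergy_degrees`: both, flattened into a list `(degree_nb, class_nb,
#'   degree_add, degree_add_max, degree_add_min, class_add)`.
#' @examples
#' degree_nb(c(10, 30, 12), f = c(0, 0.5, 1))   # strong, degree 18
#' degree_nb(c(10, 5, 12), f = c(0, 0.5, 1))    # antagonistic, degree -6
#' @export
degree_nb <- function(nb, f = seq(0, 1, length.out = length(nb)),
                      tol = 1e-6) {
  if (length(nb) < 3) stop("need at least 3 grid points")
  stopifnot(length(f) == length(nb))
  e <- max(nb[1], nb[length(nb)])
  d <- max(nb) - e
  if (d > tol) return(list(degree = d, class = "strong"))
  chord <- nb[1] + (nb[length(nb)] - nb[1]) * (f - f[1]) / (f[length(f)] - f[1])
  below <- min(nb - chord)
  if (below >= -tol) list(degree = 0, class = "weak")
  else list(degree = below, class = "antagonistic")
}

#' @rdname degree_nb
#' @export
degree_additive <- function(nb, ae, tol = 1e-6) {
  stopifnot(length(nb) == length(ae))
  gap <- nb - ae
  d <- gap[[which.max(abs(gap))]]
  cls <- if (d > 1) "synergistic" else if (d < 0) "antagonistic" else "neutral"
  list(degree = d, class = cls, degree_max = max(gap), degree_min = min(gap))
}

#' @rdname degree_nb
#' @export
synergy_degrees <- function(nb, ae, f = seq(0, 1, length.out = length(nb)),
                            tol = 1e-6) {
  dn <- degree_nb(nb, f, tol)
  da <- degree_additive(nb, ae, tol)
  list(degree_nb = dn$degree, class_nb = dn$class,
       degree_add = da$degree, degree_add_max = da$degree_max,
       degree_add_min = da$degree_min, class_add = da$class)
}

#' @export
print.blending_curves <- function(x, ...) {
  d <- x$degrees
  cat(sprintf("Blending curves for pair %s/%s (directions %+d/%+d, budget %g%%)\n",
              x$pair[1], x$pair[2], x$directions[1], x$directions[2],
              x$budget))
  cat(sprintf("  control peak: %.6g\n", x$control_peak))
  cat(sprintf("  NB synergism: degree %.4g (%s)\n", d$degree_nb, d$class_nb))
  cat(sprintf("  additive synergism: degree %.4g (%s; min NB-AE %.4g)\n",
              d$degree_add, d$class_add, d$degree_add_min))
  invisible(x)
}

#' @export
as.data.frame.blending_curves <- function(x, ...) {
  data.frame(pair = paste(x$pair, collapse = "/"), f = x$grid$f,
             delta1_pct = x$directions[1] * x$grid$delta1_pct,
             delta2_pct = x$directions[2] * x$grid$delta2_pct,
             nb_pct = x$nb, ae_pct = x$ae, stringsAsFactors = FALSE)
}

#' @export
plot.blending_curves <- function(x, xlab = NULL, ylab = "response (% increase of peak)",
                                 main = NULL, ...) {
  if (is.null(xlab))
    xlab <- sprintf("fraction of budget on %s", x$pair[1])
  if (is.null(main))
    main <- sprintf("%s / %s", x$pair[1], x$pair[2])
  ylim <- range(x$nb, x$ae)
  plot(x$grid$f, x$nb, type = "b", pch = 16, col = "black", xlab = xlab,
       ylab = ylab, ylim = ylim, main = main, ...)
  graphics::lines(x$grid$f, x$ae, type = "b", pch = 1, col = "red3")
  graphics::legend("bottomright", legend = c("NB", "AE"),
                   col = c("black", "red3"), pch = c(16, 1), lty = 1,
                   bty = "n")
  invisible(x)
}

#' NB curve / AE curve of a pair
#'
#' Thin accessors computing only one of the two blending curves; see
#' [blending()] for the full analysis.
#'
#' @inheritParams blending
#' @return Numeric vector of responses on the allocation grid.
#' @export
nb_curve <- function(model, protocol = NULL, pair, budget = 90,
                     n_grid = 30, directions = NULL, resp = NULL, ...) {
  blending(model, protocol, pair, budget, n_grid, directions, resp, ...)$nb
}

#' @rdname nb_curve
#' @export
ae_curve <- function(model, protocol = NULL, pair, budget = 90,
                     n_grid = 30, directions = NULL, resp = NULL, ...) {
  blending(model, protocol, pair, budget, n_grid, directions, resp, ...)$ae
}
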