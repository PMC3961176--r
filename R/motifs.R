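# The motif catalogue: the canonical convergence model (Variants M and A)
# and nine extensions built by replacing k_dA and/or k_dB with regulated
# rates driven by a state variable.

# direction: "decreasing" k*K/(K+X) or "increasing" k*X/(K+X);
# regulator: which state variable drives the rate; k is the maximal rate
# replacing the canonical k_d, K the half-saturation constant.
.override <- function(direction, regulator, k, K) {
  list(direction = direction, regulator = regulator, k = k, K = K)
}

.motif_catalogue <- list(
  canonical_m = list(variant = "M", overrides = list()),
  canonical_a = list(variant = "A", overrides = list()),
  # coherent positive feed-forward loop: A slows deactivation of B
  p_ffl = list(variant = "M", overrides = list(
    k_dB = .override("decreasing", "A", 0.22, 3))),
  # incoherent negative feed-forward loop: A accelerates deactivation of B
  n_ffl = list(variant = "M", overrides = list(
    k_dB = .override("increasing", "A", 0.4, 1))),
  # mutual excitation: each element slows the other's deactivation
  me = list(variant = "M", overrides = list(
    k_dA = .override("decreasing", "B", 0.22, 3),
    k_dB = .override("decreasing", "A", 0.22, 3))),
  # mutual inhibition: each element accelerates the other's deactivation
  mi = list(variant = "M", overrides = list(
    k_dA = .override("increasing", "B", 0.4, 1),
    k_dB = .override("increasing", "A", 0.4, 1))),
  # positive auto-regulation of A (auto-excitation)
  auto_pos = list(variant = "M", overrides = list(
    k_dA = .override("decreasing", "A", 0.22, 3))),
  # negative auto-regulation of A (auto-inhibition)
  auto_neg = list(variant = "M", overrides = list(
    k_dA = .override("increasing", "A", 0.4, 1))),
  # negative feedback between A and B: A protects B, B degrades A
  nf_ba = list(variant = "M", overrides = list(
    k_dA = .override("increasing", "B", 0.4, 1),
    k_dB = .override("decreasing", "A", 0.22, 3))),
  # negative feedback from the target to both elements
  nf_tab = list(variant = "M", overrides = list(
    k_dA = .override("increasing", "T", 0.4, 0.05),
    k_dB = .override("increasing", "T", 0.4, 0.05))),
  # positive feedback from the target to both elements
  pf_tab = list(variant = "M", overrides = list(
    k_dA = .override("decreasing", "T", 0.22, 0.15),
    k_dB = .override("decreasing", "T", 0.22, 0.15)))
)

#' Valid motif identifiers
#' @return Character vector of the eleven motif ids.
#' @export
motif_ids <- function() names(.motif_catalogue)

#' Build a three-node motif model
#'
#' Constructs the ODE system for one of the ten motifs (eleven ids: the
#' canonical model comes in a multiplicative Variant M and an additive
#' Variant A).  All motifs share the canonical equations for A, B and T;
#' the extensions replace the deactivation rate constants `k_dA` and/or
#' `k_dB` with hyperbolic regulated rates driven by a state variable (see
#' [regulated_rate()]), using the motif constants of the catalogue.  When a
#' motif regulates `k_dA` (or `k_dB`), percentage perturbations of that
#' parameter apply to the regulated form's maximal rate.
#'
#' @param motif One of [motif_ids()]: `"canonical_m"`, `"canonical_a"`,
#'   `"p_ffl"`, `"n_ffl"`, `"me"`, `"mi"`, `"auto_pos"`, `"auto_neg"`,
#'   `"nf_ba"`, `"nf_tab"`, `"pf_tab"` (case-insensitive).
#' @param params Named vector of the 14 canonical parameters; defaults to
#'   [standard_params()].
#' @return An object of class `motif_model`: list with elements `motif`,
#'   `variant` (`"M"` or `"A"`), `params`, `overrides`.
#' @examples
#' m <- motif_model("canonical_m")
#' m
#' motif_model("mi")$overrides
#' @export
motif_model <- function(motif = motif_ids(), params = standard_params()) {
  motif <- tolower(motif[1])
  if (!motif %in% names(.motif_catalogue))
    stop("unknown motif id '", motif, "'; valid ids: ",
         paste(motif_ids(), collapse = ", "))
  params <- .validate_params(params, .param_order)
  entry <- .motif_catalogue[[motif]]
  structure(list(motif = motif, variant = entry$variant, params = params,
                 overrides = entry$overrides),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("Three-node motif '%s' (Variant %s)\n", x$motif, x$variant))
  if (length(x$overrides)) {
    for (nm in names(x$overrides)) {
      ov <- x$overrides[[nm]]
      cat(sprintf("  %s replaced by %s regulated rate in %s (k = %g, K = %g)\n",
                  nm, ov$direction, ov$regulator, ov$k, ov$K))
    }
  } else {
    cat("  no regulated-rate overrides\n")
  }
  cat("  parameters:", paste(sprintf("%s=%g", names(x$params), x$params),
                             collapse = ", "), "\n")
  invisible(x)
}

#' The motif catalogue
#'
#' @return A named list (one entry per motif id) with the variant and the
#'   regulated-rate overrides (direction, regulator, constants) of each
#'   motif.  Convert with `jsonlite::toJSON()` for export.
#' @export
motif_catalogue <- function() .motif_catalogue

#' Hyperbolic regulated rate
#'
#' The regulated forms that replace a deactivation rate constant in the
#' motif extensions: `decreasing` gives `k*K/(K + X)` (equals `k` at
#' `X = 0`, falls toward 0) and `increasing` gives `k*X/(K + X)` (0 at
#' `X = 0`, saturates at `k`).
#'
#' @param direction `"decreasing"` or `"increasing"`.
#' @param k Maximal rate (min^-1), positive.
#' @param K Half-saturation constant, positive.
#' @param X Regulator level(s), non-negative.
#' @return Effective rate(s), same length as `X`.
#' @examples
#' regulated_rate("decreasing", k = 0.22, K = 3, X = 3)   # half-saturation
#' regulated_rate("increasing", k = 0.4, K = 1, X = 1)    # recovers 0.2
#' @export
regulated_rate <- function(direction = c("decreasing", "increasing"), k, K, X) {
  direction <- match.arg(direction)
  stopifnot(k > 0, K > 0)
  if (any(X < 0)) stop("regulator level X must be non-negative")
  if (direction == "decreasing") k * K / (K + X) else k * X / (K + X)
}

#' Right-hand side of the canonical convergence model
#'
#' Pure derivative evaluation of the canonical three-node system:
#' `dA/dt = k_basal_A + k_sA*S - k_dA*A/(K_A + A)` (B symmetric), and for
#' the target `dT/dt = k_basal_T + k_ST*act - k_dT*T/(K_T + T)` where `act`
#' is the product (Variant M) or sum (Variant A) of the saturable effects
#' `A/(K_TA + A)` and `B/(K_TB + B)`.
#'
#' @param state Numeric vector `(A, B, T)`, non-negative.
#' @param t Time (unused; present for solver-interface symmetry).
#' @param params The 14 canonical parameters.
#' @param S Stimulus value.
#' @param variant `"M"` or `"A"`.
#' @return Numeric vector of the three derivatives.
#' @export
canonical_rhs <- function(state, t = 0, params = standard_params(), S = 0,
                          variant = c("M", "A")) {
  variant <- match.arg(variant)
  model <- motif_model(if (variant == "M") "canonical_m" else "canonical_a",
                       params)
  motif_rhs(model, state, S = S)
}

#' Right-hand side of any three-node motif model
#'
#' Reference (R-level) derivative evaluation including the motif's
#' regulated-rate overrides.  Used for steady-state residual checks; the
#' integrator uses an equivalent compiled form.
#'
#' @param model A `motif_model`.
#' @param state Numeric vector `(A, B, T)`.
#' @param S Stimulus value seen by A.
#' @param S_B Stimulus value seen by B (defaults to `S`; differs only under
#'   a delayed-B scenario).
#' @return Numeric vector of the three derivatives, named `A`, `B`, `T`.
#' @export
motif_rhs <- function(model, state, S = 0, S_B = S) {
  stopifnot(inherits(model, "motif_model"), length(state) == 3)
  if (any(!is.finite(state))) stop("non-finite state")
  p <- model$params
  A <- state[[1]]; B <- state[[2]]; T_ <- state[[3]]
  lev <- c(A = A, B = B, T = T_)
  eff <- function(slot, default) {
    ov <- model$overrides[[slot]]
    if (is.null(ov)) default
    else regulated_rate(ov$direction, ov$k, ov$K, lev[[ov$regulator]])
  }
  kdA <- eff("k_dA", p[["k_dA"]])
  kdB <- eff("k_dB", p[["k_dB"]])
  fA <- A / (p[["K_TA"]] + A)
  fB <- B / (p[["K_TB"]] + B)
  act <- if (model$variant == "M") fA * fB else fA + fB
  c(A = p[["k_basal_A"]] + p[["k_sA"]] * S - kdA * A / (p[["K_A"]] + A),
    B = p[["k_basal_B"]] + p[["k_sB"]] * S_B - kdB * B / (p[["K_B"]] + B),
    T = p[["k_basal_T"]] + p[["k_ST"]] * act - p[["k_dT"]] * T_ / (p[["K_T"]] + T_))
}

# Arguments for the C++ cores.
.tn_cpp_args <- function(model) {
  code <- c(none = 0L, decreasing = 1L, increasing = 2L)
  regi <- c(A = 0L, B = 1L, T = 2L)
  ov <- function(slot) {
    o <- model$overrides[[slot]]
    if (is.null(o)) list(cr = c(0L, 0L), kk = c(0, 1))
    else list(cr = c(code[[o$direction]], regi[[o$regulator]]),
              kk = c(o$k, o$K))
  }
  a <- ov("k_dA"); b <- ov("k_dB")
  list(params = unname(model$params[.param_order]),
       variant = if (model$variant == "M") 0L else 1L,
       ovA = a$cr, ovAk = a$kk, ovB = b$cr, ovBk = b$kk)
}

#' Apply percentage perturbations to a model's parameters
#'
#' Multiplies each named parameter by `1 + delta/100`.  For a motif whose
#' `k_dA` (or `k_dB`) is replaced by a regulated rate, a perturbation of
#' that name scales the regulated form's maximal rate instead.  For the
#' CREB model the 8 parameter names apply directly.
#'
#' @param model A `motif_model` or `creb_model`.
#' @param deltas Named numeric vector of signed percentage changes; each
#'   must be `> -100` so parameters stay positive.
#' @return A model of the same class with perturbed parameters.
#' @examples
#' m <- apply_deltas(motif_model("canonical_m"), c(k_dA = -45, k_ST = 45))
#' m$params[c("k_dA", "k_ST")]
#' @export
apply_deltas <- function(model, deltas) {
  if (length(deltas) == 0) return(model)
  if (is.null(names(deltas)) || any(!nzchar(names(deltas))))
    stop("deltas must be a named vector of percentage changes")
  if (any(deltas <= -100))
    stop("percentage changes must be > -100 so parameters stay positive")
  UseMethod("apply_deltas")
}

#' @export
apply_deltas.motif_model <- function(model, deltas) {
  bad <- setdiff(names(deltas), .param_order)
  if (length(bad))
    stop("not sweep-eligible parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(deltas)) {
    fac <- 1 + deltas[[nm]] / 100
    if (nm %in% names(model$overrides)) {
      model$overrides[[nm]]$k <- model$overrides[[nm]]$k * fac
    } else {
      model$params[[nm]] <- model$params[[nm]] * fac
    }
  }
  model
}

#' @export
apply_deltas.creb_model <- function(model, deltas) {
  bad <- setdiff(names(deltas), .creb_param_order)
  if (length(bad))
    stop("not sweep-eligible parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(deltas))
    model$params[[nm]] <- model$params[[nm]] * (1 + deltas[[nm]] / 100)
  model
}
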