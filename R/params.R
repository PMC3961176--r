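# Canonical parameter sets.  Order matters: the C++ cores receive plain
# numeric vectors in exactly this order.

.param_order <- c("k_sA", "k_basal_A", "k_dA", "K_A",
                  "k_sB", "k_basal_B", "k_dB", "K_B",
                  "k_basal_T", "k_ST", "K_TA", "K_TB", "k_dT", "K_T")

.creb_param_order <- c("V_x", "V_y", "K_x", "K_y",
                       "k_dx", "k_dy", "r_bas_x", "r_bas_y")

#' Standard parameter values of the canonical three-node model
#'
#' The 14 rate and binding constants governing the dynamics of the two
#' upstream elements A and B and the target T.  These are the sweep-eligible
#' parameters: every pairwise perturbation analysis enumerates pairs from
#' this set (91 unordered pairs).  Units: rates in min^-1, dissociation-like
#' constants in the model's non-dimensional concentration units.
#'
#' @return Named numeric vector of length 14.
#' @examples
#' standard_params()
#' @export
standard_params <- function() {
  setNames(c(0.1, 0.1, 0.2, 1,
             0.1, 0.1, 0.2, 1,
             0.0001, 0.01, 2.5, 2.5, 0.01, 0.5),
           .param_order)
}

#' Sweep-eligible parameter names
#'
#' @param model Either a `motif_model` or a `creb_model`; defaults to the
#'   three-node set.
#' @return Character vector: the 14 canonical names for three-node motifs or
#'   the 8 CREB parameter names.
#' @export
sweep_parameters <- function(model = NULL) {
  if (inherits(model, "creb_model")) .creb_param_order else .param_order
}

#' Standard parameter values of the CREB1/CREB2 model
#'
#' Maximal induced synthesis rates (`V_x`, `V_y`), dissociation constants of
#' CREB1 and CREB2 from the shared CRE sites (`K_x`, `K_y`), first-order
#' degradation rates (`k_dx`, `k_dy`) and basal synthesis rates
#' (`r_bas_x`, `r_bas_y`).  Rates are in min^-1.
#'
#' @return Named numeric vector of length 8.
#' @export
creb_params <- function() {
  setNames(c(0.4, 0.01, 5, 10, 0.04, 0.01, 0.003, 0.002),
           .creb_param_order)
}

#' Read or write a parameter set as flat key-value JSON or YAML
#'
#' @param params Named numeric vector (14 canonical or 8 CREB parameters).
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return `write_params()` returns the path invisibly; `read_params()`
#'   a validated named numeric vector.
#' @export
write_params <- function(params, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML output")
    yaml::write_yaml(as.list(params), path)
  } else {
    jsonlite::write_json(as.list(params), path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  params <- unlist(lst)
  expected <- if (setequal(names(params), .creb_param_order))
    .creb_param_order else .param_order
  .validate_params(params, expected)
}

# Check a named parameter vector: right names, all positive and finite.
.validate_params <- function(params, expected) {
  if (is.null(names(params)) || !setequal(names(params), expected))
    stop("parameters must be a named vector with names: ",
         paste(expected, collapse = ", "))
  params <- params[expected]
  if (any(!is.finite(params)) || any(params <= 0))
    stop("all parameter values must be positive and finite")
  params
}
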