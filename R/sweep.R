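# Batch execution: all-pairs sweeps, threshold counts, histograms,
# dose-effect scans over stimulus strength, and sensitivity scenarios.

# Memoize a response closure on the delta set.  Single-parameter responses
# recur across the AE curves of every pair sharing a parameter, so caching
# cuts a full sweep roughly threefold.
.memoize_resp <- function(resp) {
  cache <- new.env(parent = emptyenv())
  f <- function(deltas = numeric()) {
    if (length(deltas) == 0) return(0)
    key <- paste(names(deltas), sprintf("%.12g", deltas),
                 sep = "=", collapse = ";")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- resp(deltas)
      cache[[key]] <- got
    }
    got
  }
  attributes(f) <- attributes(resp)
  f
}

#' Sensitivity-analysis scenario
#'
#' A named set of parameter multipliers applied to the standard values
#' before direction determination, plus an optional delay (minutes) of the
#' stimulus seen by element B.
#'
#' @param multipliers Named positive multipliers (empty for none).
#' @param b_delay Delay of B's stimulus, minutes (>= 0).
#' @param name Scenario label.
#' @return Object of class `scenario`.
#' @examples
#' scenario(c(k_sB = 0.5, k_basal_B = 0.5, k_dB = 0.5), name = "slower_b")
#' @export
scenario <- function(multipliers = numeric(), b_delay = 0,
                     name = "scenario") {
  if (length(multipliers) && (is.null(names(multipliers)) ||
                              any(multipliers <= 0)))
    stop("multipliers must be a named vector of positive values")
  if (b_delay < 0) stop("b_delay must be >= 0")
  structure(list(multipliers = multipliers, b_delay = b_delay, name = name),
            class = "scenario")
}

.apply_scenario <- function(model, scen) {
  if (is.null(scen)) return(model)
  for (nm in names(scen$multipliers)) {
    if (nm %in% names(model$overrides))
      model$overrides[[nm]]$k <- model$overrides[[nm]]$k * scen$multipliers[[nm]]
    else model$params[[nm]] <- model$params[[nm]] * scen$multipliers[[nm]]
  }
  model
}

# Shared sweep core: enumerate pairs, determine directions, build single-
# parameter response curves once, then NB curves and degrees per pair.
.sweep_core <- function(resp, param_names, budget, n_grid, motif_label,
                        s_label, pairs = NULL, keep_curves = FALSE) {
  all_pairs <- enumerate_pairs(param_names)
  if (!is.null(pairs)) {
    keep <- if (is.data.frame(pairs)) {
      vapply(seq_len(nrow(pairs)), function(i)
        paste(sort(c(pairs$param_1[i], pairs$param_2[i]), method = "radix"),
              collapse = "/"), character(1))
    } else pairs
    all_pairs <- all_pairs[all_pairs$pair %in% keep, , drop = FALSE]
    if (!nrow(all_pairs)) stop("no requested pair matches the catalogue")
  }
  used <- sort(unique(c(all_pairs$param_1, all_pairs$param_2)))
  resp <- .memoize_resp(resp)
  dirs <- vapply(used, function(p) as.numeric(.direction(resp, p, budget)),
                 numeric(1))
  curves <- if (keep_curves) vector("list", nrow(all_pairs))
  rows <- lapply(seq_len(nrow(all_pairs)), function(i) {
    p1 <- all_pairs$param_1[i]; p2 <- all_pairs$param_2[i]
    out <- tryCatch({
      bc <- blending(NULL, NULL, c(p1, p2), budget = budget,
                     n_grid = n_grid, directions = c(dirs[[p1]], dirs[[p2]]),
                     resp = resp)
      if (keep_curves) curves[[i]] <<- bc
      d <- bc$degrees
      data.frame(motif = motif_label, S = s_label, pair = all_pairs$pair[i],
                 param_1 = p1, param_2 = p2,
                 dir_1 = dirs[[p1]], dir_2 = dirs[[p2]],
                 degree_nb = d$degree_nb, class_nb = d$class_nb,
                 degree_add = d$degree_add,
                 degree_add_max = d$degree_add_max,
                 degree_add_min = d$degree_add_min,
                 class_add = d$class_add, flag = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(motif = motif_label, S = s_label, pair = all_pairs$pair[i],
                 param_1 = p1, param_2 = p2,
                 dir_1 = dirs[[p1]], dir_2 = dirs[[p2]],
                 degree_nb = NA_real_, class_nb = NA_character_,
                 degree_add = NA_real_, degree_add_max = NA_real_,
                 degree_add_min = NA_real_,
                 class_add = NA_character_, flag = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    out
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("sweep_table", "data.frame")
  if (keep_curves) {
    names(curves) <- all_pairs$pair
    attr(tab, "curves") <- curves
  }
  tab
}

#' All-pairs synergism sweep
#'
#' Enumerates every unordered pair of sweep-eligible parameters (91 for the
#' three-node motifs, 28 for the CREB model), determines each parameter's
#' favourable direction, computes NB and AE blending curves under the
#' budget, and tabulates the degrees of NB and additive synergism with
#' their classifications.  A pair whose integration fails is recorded as a
#' flagged row rather than aborting the sweep.
#'
#' @param model A `motif_model` or `creb_model`.
#' @param protocol Stimulus protocol (three-node models; the CREB model
#'   uses its 5-HT protocol).
#' @param pairs Optional subset: a character vector of `"p1/p2"` labels
#'   (lexicographic order) or a data frame with `param_1`, `param_2`.
#' @param scenario Optional [scenario()] applied before direction
#'   determination.
#' @param budget,n_grid Budget (percent) and allocation grid size.
#' @param b_delay Delay of B's stimulus, minutes (three-node models).
#' @param keep_curves If `TRUE`, attach the per-pair [blending()] objects
#'   as `attr(table, "curves")`.
#' @param ... Passed to [make_response_fn()] (e.g. `t_end`, `dt`).
#' @return A `sweep_table` data frame: one row per pair with columns
#'   `motif`, `S`, `pair`, `param_1`, `param_2`, `dir_1`, `dir_2`,
#'   `degree_nb`, `class_nb`, `degree_add`, `degree_add_min`, `class_add`,
#'   `flag`.
#' @examples
#' \donttest{
#' tab <- sweep_all_pairs(motif_model("canonical_m"), square_pulse(1),
#'                        pairs = c("k_dA/k_dB"))
#' }
#' @export
sweep_all_pairs <- function(model, protocol = NULL, pairs = NULL,
                            scenario = NULL, budget = 90, n_grid = 30, ...) {
  UseMethod("sweep_all_pairs")
}

#' @export
sweep_all_pairs.motif_model <- function(model, protocol = NULL, pairs = NULL,
                                        scenario = NULL, budget = 90,
                                        n_grid = 30, b_delay = 0,
                                        keep_curves = FALSE, ...) {
  if (is.null(protocol)) stop("a stimulus protocol is required")
  if (!is.null(scenario)) {
    model <- .apply_scenario(model, scenario)
    b_delay <- b_delay + scenario$b_delay
  }
  resp <- make_response_fn(model, protocol, b_delay = b_delay, ...)
  .sweep_core(resp, .param_order, budget, n_grid, model$motif,
              protocol$amplitude, pairs = pairs, keep_curves = keep_curves)
}

#' @export
sweep_all_pairs.creb_model <- function(model, protocol = NULL, pairs = NULL,
                                       scenario = NULL, budget = 90,
                                       n_grid = 30, keep_curves = FALSE,
                                       ...) {
  if (!is.null(scenario)) model <- .apply_scenario(model, scenario)
  resp <- make_response_fn(model, ...)
  .sweep_core(resp, .creb_param_order, budget, n_grid, "creb", "5ht",
              pairs = pairs, keep_curves = keep_curves)
}

#' Count pairs whose degree strictly exceeds a threshold
#'
#' @param table A `sweep_table`.
#' @param metric `"nb"` or `"add"`.
#' @param threshold Threshold; the comparison is a strict `>`.
#' @return Integer count (flagged rows with missing degrees never count).
#' @export
count_exceeding <- function(table, metric = c("nb", "add"), threshold) {
  metric <- match.arg(metric)
  v <- table[[if (metric == "nb") "degree_nb" else "degree_add"]]
  sum(v > threshold, na.rm = TRUE)
}

#' Histogram of synergism degrees
#'
#' Half-open bins `[lo, hi)` of width `bin_width` covering the observed
#' degrees; counts sum to the number of non-missing rows.
#'
#' @param table A `sweep_table`.
#' @param metric `"nb"` or `"add"`.
#' @param bin_width Bin width in degree units.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
synergy_histogram <- function(table, metric = c("nb", "add"),
                              bin_width = 10) {
  metric <- match.arg(metric)
  if (bin_width <= 0) stop("bin_width must be positive")
  v <- table[[if (metric == "nb") "degree_nb" else "degree_add"]]
  v <- v[!is.na(v)]
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- floor(max(v) / bin_width) * bin_width + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- vapply(seq_len(length(edges) - 1), function(i)
    sum(v >= edges[i] & v < edges[i + 1]), integer(1))
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = counts)
}

#' Dose-effect of stimulus strength on synergism degrees
#'
#' Recomputes the control peak, directions, blending curves and both
#' degrees of one parameter pair for each stimulus amplitude.
#'
#' @param model A `motif_model`.
#' @param pair Character vector of two parameter names.
#' @param S_values Positive stimulus amplitudes (square 10-min pulse).
#' @param pulse_duration Pulse width, minutes.
#' @param budget,n_grid Budget (percent) and grid size.
#' @param ... Passed to [make_response_fn()].
#' @return Data frame with columns `S`, `degree_nb`, `degree_add` (plus
#'   classes).
#' @export
dose_effect_vs_stimulus <- function(model, pair, S_values,
                                    pulse_duration = 10, budget = 90,
                                    n_grid = 30, ...) {
  stopifnot(all(S_values > 0))
  rows <- lapply(S_values, function(S) {
    resp <- .memoize_resp(make_response_fn(model,
                                           square_pulse(S, pulse_duration),
                                           ...))
    bc <- blending(NULL, NULL, pair, budget = budget, n_grid = n_grid,
                   resp = resp)
    d <- bc$degrees
    data.frame(S = S, degree_nb = d$degree_nb, class_nb = d$class_nb,
               degree_add = d$degree_add, class_add = d$class_add,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standard sensitivity-analysis scenarios
#'
#' The named scenarios of the canonical-model sensitivity analysis: the
#' B-pathway parameters (`k_sB`, `k_basal_B`, `k_dB`) jointly reduced by
#' 50/70/90%, a 60-min delay of B's activation, and each of the six
#' T-dynamics parameters altered by -25% or +25%.
#'
#' @return Named list of [scenario()] objects.
#' @export
sensitivity_scenarios <- function() {
  b3 <- function(f) setNames(rep(f, 3), c("k_sB", "k_basal_B", "k_dB"))
  out <- list(
    slower_b_50 = scenario(b3(0.5), name = "slower_b_50"),
    slower_b_70 = scenario(b3(0.3), name = "slower_b_70"),
    slower_b_90 = scenario(b3(0.1), name = "slower_b_90"),
    delayed_b   = scenario(b_delay = 60, name = "delayed_b"))
  tpar <- c("k_basal_T", "k_ST", "K_TA", "K_TB", "k_dT", "K_T")
  for (p in tpar) {
    for (f in c(0.75, 1.25)) {
      nm <- sprintf("%s_x%.2f", p, f)
      out[[nm]] <- scenario(setNames(f, p), name = nm)
    }
  }
  out
}

#' Run the sensitivity-analysis suite
#'
#' One all-pairs sweep of the canonical Variant M model per scenario, plus
#' threshold summaries (counts of pairs with degree > 10, > 20, > 40 for
#' both metrics).  The full suite over all 16 scenarios and 91 pairs is a
#' long desk-scale computation; restrict `scenarios` and/or `pairs` for
#' quick looks.
#'
#' @param S Stimulus amplitude (default 1).
#' @param scenarios Named list of [scenario()] objects (default
#'   [sensitivity_scenarios()]).
#' @param pairs Optional pair subset, as in [sweep_all_pairs()].
#' @param ... Passed to [sweep_all_pairs()].
#' @return List with elements `tables` (one `sweep_table` per scenario)
#'   and `summary` (data frame of threshold counts).
#' @export
run_sensitivity_suite <- function(S = 1, scenarios = sensitivity_scenarios(),
                                  pairs = NULL, ...) {
  model <- motif_model("canonical_m")
  protocol <- square_pulse(S)
  tables <- lapply(scenarios, function(sc)
    sweep_all_pairs(model, protocol, pairs = pairs, scenario = sc, ...))
  summary <- do.call(rbind, lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    data.frame(scenario = nm,
               nb_gt_10 = count_exceeding(tb, "nb", 10),
               nb_gt_20 = count_exceeding(tb, "nb", 20),
               nb_gt_40 = count_exceeding(tb, "nb", 40),
               add_gt_10 = count_exceeding(tb, "add", 10),
               add_gt_20 = count_exceeding(tb, "add", 20),
               add_gt_40 = count_exceeding(tb, "add", 40),
               stringsAsFactors = FALSE)
  }))
  list(tables = tables, summary = summary)
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf("Synergism sweep: %d pairs (motif %s, S = %s)\n", nrow(x),
              x$motif[1], format(x$S[1])))
  cat(sprintf("  NB degree > 0: %d; additive degree > 1: %d; flagged: %d\n",
              count_exceeding(x, "nb", 0), count_exceeding(x, "add", 1),
              sum(nzchar(x$flag))))
  NextMethod()
}
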