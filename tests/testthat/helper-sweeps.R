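# Shared, lazily computed objects for the expensive full-sweep tests.
# Computed once per test run and cached in this environment.

.sweep_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  got <- .sweep_cache[[key]]
  if (is.null(got)) {
    got <- force(expr)
    .sweep_cache[[key]] <- got
  }
  got
}

# Full 91-pair sweep of canonical Variant M at S = 1 with curves attached.
sweep_m_s1 <- function() {
  cached("m_s1", sweep_all_pairs(motif_model("canonical_m"), square_pulse(1),
                                 keep_curves = TRUE))
}

# Full 91-pair sweep of canonical Variant A at S = 1.
sweep_a_s1 <- function() {
  cached("a_s1", sweep_all_pairs(motif_model("canonical_a"), square_pulse(1)))
}

# Focal-pair blending for a motif under a square pulse, study conditions.
focal_blend <- function(motif, S, pair) {
  cached(paste(motif, S, paste(pair, collapse = "_"), sep = "|"), {
    blending(motif_model(motif), square_pulse(S), pair)
  })
}

# Quick response closure on a short fixed horizon for structural tests
# where the study-condition horizon is irrelevant.
quick_resp <- function(motif = "canonical_m", S = 1, t_end = 300) {
  cached(paste("resp", motif, S, t_end, sep = "|"), {
    motifsynergy:::.memoize_resp(
      make_response_fn(motif_model(motif), square_pulse(S), t_end = t_end,
                       extend = FALSE))
  })
}
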