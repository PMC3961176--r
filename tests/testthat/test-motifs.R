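test_that("canonical right-hand side matches hand-computed values", {
  # all saturable terms vanish at the origin
  expect_equal(unname(canonical_rhs(c(0, 0, 0), S = 0, variant = "M")),
               c(0.1, 0.1, 0.0001))
  # basal balance at A = B = 1: production 0.1 equals deactivation 0.2/2
  d <- canonical_rhs(c(1, 1, 0), S = 0, variant = "M")
  expect_equal(unname(d[c("A", "B")]), c(0, 0))
  # variant A: sum of saturable effects >= their product when both <= 1
  dM <- canonical_rhs(c(1, 1, 0.2), S = 0, variant = "M")
  dA <- canonical_rhs(c(1, 1, 0.2), S = 0, variant = "A")
  expect_gte(dA[["T"]], dM[["T"]])
})

test_that("regulated rates take the hyperbolic forms with the right limits", {
  expect_equal(regulated_rate("decreasing", k = 0.22, K = 3, X = 0), 0.22)
  expect_equal(regulated_rate("decreasing", k = 0.22, K = 3, X = 3), 0.11)
  expect_equal(regulated_rate("increasing", k = 0.4, K = 1, X = 1), 0.2)
  expect_equal(regulated_rate("increasing", k = 0.4, K = 1, X = 0), 0)
  # monotone, bounded by k
  X <- seq(0, 50, by = 0.5)
  dec <- regulated_rate("decreasing", 0.22, 3, X)
  inc <- regulated_rate("increasing", 0.4, 1, X)
  expect_true(all(diff(dec) < 0) && all(dec <= 0.22) && all(dec > 0))
  expect_true(all(diff(inc) > 0) && all(inc < 0.4) && all(inc >= 0))
  expect_error(regulated_rate("decreasing", 0.22, 3, -1), "non-negative")
})

test_that("the motif catalogue wires the regulated overrides correctly", {
  m <- motif_model("canonical_m")
  expect_length(m$overrides, 0)
  expect_length(m$params, 14)
  expect_equal(m$params[["k_ST"]], 0.01)

  mi <- motif_model("mi")
  expect_setequal(names(mi$overrides), c("k_dA", "k_dB"))
  expect_equal(mi$overrides$k_dA[c("direction", "regulator", "k", "K")],
               list(direction = "increasing", regulator = "B", k = 0.4, K = 1))
  expect_equal(mi$overrides$k_dB$regulator, "A")

  wiring <- list(
    p_ffl = list(k_dB = c("decreasing", "A")),
    n_ffl = list(k_dB = c("increasing", "A")),
    me = list(k_dA = c("decreasing", "B"), k_dB = c("decreasing", "A")),
    auto_pos = list(k_dA = c("decreasing", "A")),
    auto_neg = list(k_dA = c("increasing", "A")),
    nf_ba = list(k_dA = c("increasing", "B"), k_dB = c("decreasing", "A")),
    nf_tab = list(k_dA = c("increasing", "T"), k_dB = c("increasing", "T")),
    pf_tab = list(k_dA = c("decreasing", "T"), k_dB = c("decreasing", "T")))
  for (mo in names(wiring)) {
    ov <- motif_model(mo)$overrides
    expect_setequal(names(ov), names(wiring[[mo]]))
    for (slot in names(wiring[[mo]])) {
      expect_equal(ov[[slot]]$direction, wiring[[mo]][[slot]][1],
                   label = paste(mo, slot, "direction"))
      expect_equal(ov[[slot]]$regulator, wiring[[mo]][[slot]][2],
                   label = paste(mo, slot, "regulator"))
    }
  }
  # feedback-from-T constants differ between the negative and positive loops
  expect_equal(motif_model("nf_tab")$overrides$k_dA[c("k", "K")],
               list(k = 0.4, K = 0.05))
  expect_equal(motif_model("pf_tab")$overrides$k_dA[c("k", "K")],
               list(k = 0.22, K = 0.15))
  expect_error(motif_model("nonsense"), "valid ids")
})

test_that("positive auto-regulation leaves the full maximal rate at A = 0", {
  m <- motif_model("auto_pos")
  # at A = 0 the decreasing form equals its maximal rate k = 0.22, so the
  # A-derivative at (0, 1, 0) has no deactivation (A/(K_A+A) = 0) and at
  # (1, 1, 0) uses k_eff = 0.22 * 3/4 = 0.165
  d <- motif_rhs(m, c(1, 1, 0), S = 0)
  expect_equal(d[["A"]], 0.1 - 0.165 * 0.5)
})

test_that("percentage perturbations scale the regulated maximal rate", {
  m <- apply_deltas(motif_model("mi"), c(k_dA = -50, k_ST = 10))
  expect_equal(m$overrides$k_dA$k, 0.2)
  expect_equal(m$params[["k_dA"]], 0.2)  # the unused slot is untouched
  expect_equal(m$params[["k_ST"]], 0.011)
  expect_error(apply_deltas(motif_model("mi"), c(K_B_A = 10)),
               "not sweep-eligible")
  expect_error(apply_deltas(motif_model("mi"), c(k_dA = -100)), "> -100")
})

test_that("identical pathways give identical A and B trajectories", {
  m <- motif_model("canonical_m")
  tc <- integrate_rk4(m, square_pulse(1), t_end = 500)
  expect_equal(tc$states[, "A"], tc$states[, "B"])
})

test_that("regulation signs move the peak response in the expected direction", {
  pk <- function(motif) {
    m <- motif_model(motif)
    init <- motifsynergy:::.resting_state(m)
    motifsynergy:::.peak_T(m, square_pulse(1), init, t_end = 1500,
                           extend = FALSE)$peak
  }
  base <- pk("canonical_m")
  expect_gt(pk("me"), base)
  expect_gt(pk("auto_pos"), base)
  expect_lt(pk("mi"), base)
  expect_lt(pk("auto_neg"), base)
})

test_that("the compiled motif right-hand side matches the R reference", {
  for (mo in c("canonical_m", "canonical_a", "mi", "me", "nf_tab")) {
    m <- motif_model(mo)
    a <- motifsynergy:::.tn_cpp_args(m)
    for (state in list(c(0.5, 1.2, 0.1), c(2, 0.3, 1.5))) {
      # one tiny RK4 step against an R-side RK4 step built on motif_rhs
      S <- 0.7
      dt <- 1e-3
      sim <- motifsynergy:::.sim_three_node_cpp(
        a$params, a$variant, a$ovA, a$ovAk, a$ovB, a$ovBk,
        motifsynergy:::.proto_vec(constant_stimulus(S)), 0, state, dt, dt,
        FALSE)
      k1 <- motif_rhs(m, state, S)
      k2 <- motif_rhs(m, state + dt / 2 * k1, S)
      k3 <- motif_rhs(m, state + dt / 2 * k2, S)
      k4 <- motif_rhs(m, state + dt * k3, S)
      manual <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      expect_equal(sim$final_state, unname(manual), tolerance = 1e-12)
    }
  }
})
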