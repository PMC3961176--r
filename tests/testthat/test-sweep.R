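test_that("a restricted sweep returns one row per requested pair", {
  m <- motif_model("canonical_m")
  tab <- sweep_all_pairs(m, square_pulse(1),
                         pairs = c("k_dA/k_dB", "k_ST/k_dA"),
                         t_end = 300, extend = FALSE)
  expect_s3_class(tab, "sweep_table")
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$pair, c("k_dA/k_dB", "k_ST/k_dA"))
  expect_true(all(tab$flag == ""))
  expect_true(all(is.finite(tab$degree_nb)))
  # degree columns are consistent with their classes
  expect_true(all((tab$degree_nb > 0) == (tab$class_nb == "strong")))
  expect_error(sweep_all_pairs(m, square_pulse(1), pairs = "no/pe",
                               t_end = 300), "no requested pair")
})

test_that("threshold counts use strict inequalities", {
  tab <- data.frame(degree_nb = c(0, 0.5, 21, NA),
                    degree_add = c(1, 1.01, -3, 50))
  expect_equal(count_exceeding(tab, "nb", 0), 2)
  expect_equal(count_exceeding(tab, "nb", 21), 0)
  expect_equal(count_exceeding(tab, "add", 1), 2)
  expect_equal(count_exceeding(tab, "add", Inf), 0)
  expect_error(count_exceeding(tab, "both", 1), "arg")
})

test_that("histograms conserve the pair count in half-open bins", {
  tab <- data.frame(degree_nb = c(-5, 0, 0, 9.99, 10, 35),
                    degree_add = rep(1, 6))
  h <- synergy_histogram(tab, "nb", bin_width = 10)
  expect_equal(sum(h$count), 6)
  expect_equal(h$bin_hi - h$bin_lo, rep(10, nrow(h)))
  # 10 falls in [10, 20), not [0, 10)
  expect_equal(h$count[h$bin_lo == 0], 3)
  expect_equal(h$count[h$bin_lo == 10], 1)
  single <- synergy_histogram(data.frame(degree_nb = rep(2, 4),
                                         degree_add = 0), "nb", 1)
  expect_equal(sum(single$count > 0), 1)
  expect_error(synergy_histogram(tab, "nb", 0), "positive")
})

test_that("an empty scenario reproduces the base sweep exactly", {
  m <- motif_model("canonical_m")
  pairs <- c("k_dA/k_dB", "K_T/k_dA")
  base <- sweep_all_pairs(m, square_pulse(1), pairs = pairs, t_end = 300,
                          extend = FALSE)
  same <- sweep_all_pairs(m, square_pulse(1), pairs = pairs, t_end = 300,
                          extend = FALSE,
                          scenario = scenario(c(k_dB = 1), b_delay = 0))
  expect_identical(base, same)
  # determinism: re-running is bit-identical
  again <- sweep_all_pairs(m, square_pulse(1), pairs = pairs, t_end = 300,
                           extend = FALSE)
  expect_identical(base, again)
})

test_that("scenario multipliers rescale parameters before the sweep", {
  sc <- scenario(c(k_sB = 0.5, k_basal_B = 0.5, k_dB = 0.5), name = "slow_b")
  m2 <- motifsynergy:::.apply_scenario(motif_model("canonical_m"), sc)
  expect_equal(unname(m2$params[c("k_sB", "k_basal_B", "k_dB")]),
               c(0.05, 0.05, 0.1))
  # on a regulated motif the multiplier reaches the override's maximal rate
  m3 <- motifsynergy:::.apply_scenario(motif_model("mi"), sc)
  expect_equal(m3$overrides$k_dB$k, 0.2)
  expect_error(scenario(c(0.5)), "named")
  expect_error(scenario(b_delay = -1), "b_delay")
  # the standard catalogue covers the B-pathway and T-dynamics analyses
  scs <- sensitivity_scenarios()
  expect_true(all(c("slower_b_50", "slower_b_70", "slower_b_90",
                    "delayed_b") %in% names(scs)))
  expect_equal(length(scs), 16)
})

test_that("delaying B's activation shifts only the B trajectory", {
  m <- motif_model("canonical_m")
  init <- find_presimulus_steady_state(m)
  tc <- integrate_rk4(m, square_pulse(1), init = init, t_end = 200,
                      b_delay = 60)
  # B sees no stimulus before 60 min, so it stays at rest
  expect_equal(tc$states[tc$times <= 59, "B"],
               rep(1, sum(tc$times <= 59)), tolerance = 1e-6)
  # and then traces A's response with a 60-min lag (up to a one-stage
  # boundary effect: the step ending exactly at the delayed onset already
  # samples the pulse in its final RK4 stage)
  iA <- round(30 / tc$dt) + 1L
  iB <- round(90 / tc$dt) + 1L
  expect_equal(unname(tc$states[iB, "B"]), unname(tc$states[iA, "A"]),
               tolerance = 1e-3)
})

test_that("dose-effect scans recompute degrees per stimulus amplitude", {
  m <- motif_model("canonical_m")
  de <- dose_effect_vs_stimulus(m, c("k_dA", "k_dB"), S_values = c(1, 10),
                                t_end = 300, extend = FALSE)
  expect_equal(de$S, c(1, 10))
  expect_true(all(is.finite(de$degree_nb)))
  expect_true(all(is.finite(de$degree_add)))
})

test_that("a sensitivity scenario subset runs end to end with summaries", {
  out <- run_sensitivity_suite(
    scenarios = sensitivity_scenarios()["delayed_b"],
    pairs = c("k_dA/k_dB"), t_end = 300, extend = FALSE)
  expect_named(out, c("tables", "summary"))
  expect_equal(nrow(out$tables$delayed_b), 1)
  expect_equal(out$summary$scenario, "delayed_b")
  expect_true(all(c("nb_gt_10", "add_gt_40") %in% names(out$summary)))
})

test_that("CREB sweep machinery enumerates its 8 parameters", {
  tab <- sweep_all_pairs(creb_model(), pairs = c("V_x/k_dy"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$motif, "creb")
  expect_equal(tab$dir_1, 1)   # raising V_x raises the ratio
  expect_equal(tab$dir_2, 1)   # raising k_dy raises the ratio
  expect_true(is.finite(tab$degree_nb))
})

test_that("tables, time courses and manifests round-trip deterministically", {
  m <- motif_model("canonical_m")
  tab <- sweep_all_pairs(m, square_pulse(1), pairs = "k_dA/k_dB",
                         t_end = 300, extend = FALSE)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_sweep_table(tab, f1)
  write_sweep_table(tab, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  header <- readLines(f1, n = 1)
  expect_match(header, "^motif,S,pair,")

  tc <- integrate_rk4(m, square_pulse(1), t_end = 50)
  f3 <- tempfile(fileext = ".csv")
  write_time_course(tc, f3, every = 20L)
  df <- read.csv(f3)
  expect_equal(names(df), c("time_min", "A", "B", "T"))
  expect_equal(df$time_min[1:2], c(0, 1))

  mf <- run_manifest(m, square_pulse(1), budget = 90, n_grid = 30)
  f4 <- tempfile(fileext = ".json")
  write_manifest(mf, f4)
  back <- jsonlite::read_json(f4)
  expect_equal(back$model, "canonical_m")
  expect_equal(back$parameters$k_ST, 0.01)
  expect_equal(back$protocol$amplitude, 1)
})

test_that("parameter sets round-trip through flat JSON", {
  f <- tempfile(fileext = ".json")
  write_params(standard_params(), f)
  expect_equal(read_params(f), standard_params())
  p <- creb_params()
  write_params(p, f)
  expect_equal(read_params(f), p)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(k_sA = -1), bad, auto_unbox = TRUE)
  expect_error(read_params(bad), "named vector|positive")
})

test_that("fixture regeneration is byte-stable", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  f1 <- make_fixtures(d1)
  f2 <- make_fixtures(d2)
  expect_length(f1, 3)
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  # shipped fixtures match regeneration
  shipped <- system.file("extdata", basename(f1), package = "motifsynergy")
  if (all(nzchar(shipped))) {
    for (i in seq_along(f1))
      expect_identical(readLines(f1[i]), readLines(shipped[i]))
  }
})
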