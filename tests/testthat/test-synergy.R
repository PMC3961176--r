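test_that("pair enumeration yields all unordered pairs in canonical order", {
  expect_equal(nrow(enumerate_pairs(sweep_parameters())), 91)
  expect_equal(nrow(enumerate_pairs(creb_params() |> names())), 28)
  expect_equal(nrow(enumerate_pairs(c("a", "b"))), 1)
  p <- enumerate_pairs(c("c", "a", "b"))
  expect_equal(p$pair, c("a/b", "a/c", "b/c"))
  expect_error(enumerate_pairs(c("a", "a")), "duplicate")
  expect_error(enumerate_pairs("a"), "at least two")
})

test_that("the allocation grid keeps the total budget constant", {
  g <- allocation_grid()
  expect_equal(nrow(g), 30)
  expect_equal(g$f[c(1, 30)], c(0, 1))
  expect_equal(g$delta1_pct + g$delta2_pct, rep(90, 30))
  expect_equal(diff(g$f), rep(1 / 29, 29))
  expect_error(allocation_grid(2), "3 grid points")
  expect_error(allocation_grid(30, budget = 100), "budget")
})

test_that("NB degree follows the endpoint/chord classification rules", {
  # linear curve: no curvature, weak, degree 0
  d <- degree_nb(c(10, 11, 12), f = c(0, 0.5, 1))
  expect_equal(d$degree, 0)
  expect_equal(d$class, "weak")
  # interior max above both endpoints: strong, degree = max - best endpoint
  d <- degree_nb(c(10, 30, 12), f = c(0, 0.5, 1))
  expect_equal(d$degree, 18)
  expect_equal(d$class, "strong")
  # sagging below the endpoint chord: antagonistic, most negative deviation
  d <- degree_nb(c(10, 5, 12), f = c(0, 0.5, 1))
  expect_equal(d$degree, -6)
  expect_equal(d$class, "antagonistic")
  # concave down with the max at an endpoint: weak, degree 0
  d <- degree_nb(c(10, 12, 12.5), f = c(0, 0.5, 1))
  expect_equal(d$degree, 0)
  expect_equal(d$class, "weak")
  expect_error(degree_nb(c(1, 2)), "3 grid points")
})

test_that("additive degree is the signed extreme NB-AE gap", {
  nb <- c(0, 10, 12, 5)
  expect_equal(degree_additive(nb, nb)$degree, 0)
  expect_equal(degree_additive(nb, nb)$class, "neutral")
  d <- degree_additive(nb + 5, nb)
  expect_equal(d$degree, 5)
  expect_equal(d$class, "synergistic")
  d <- degree_additive(nb - 2, nb)
  expect_equal(d$degree, -2)
  expect_equal(d$class, "antagonistic")
  # intertwined curves keep both extremes on record
  d <- degree_additive(nb + c(0, 4, -7, 0), nb)
  expect_equal(d$degree, -7)
  expect_equal(d$degree_max, 4)
  expect_equal(d$degree_min, -7)
})

test_that("favourable directions match the known signs of the canonical model", {
  resp <- quick_resp()
  expect_equal(as.numeric(motifsynergy:::.direction(resp, "k_dA", 90)), -1)
  expect_equal(as.numeric(motifsynergy:::.direction(resp, "k_ST", 90)), +1)
  expect_equal(as.numeric(motifsynergy:::.direction(resp, "K_T", 90)), +1)
  expect_equal(as.numeric(motifsynergy:::.direction(resp, "k_basal_A", 90)), +1)
})

test_that("the response measure is zero at no change and symmetric in A/B", {
  resp <- quick_resp()
  expect_identical(resp(numeric()), 0)
  r1 <- resp(c(k_dA = -45, k_dB = -45))
  r2 <- resp(c(k_dB = -45, k_dA = -45))
  expect_equal(r1, r2)
  r3 <- resp(c(k_dA = -30))
  r4 <- resp(c(k_dB = -30))
  expect_equal(r3, r4, tolerance = 1e-9)
  expect_gt(r3, 0)
})

test_that("blending curves meet at the endpoints and respect A/B symmetry", {
  resp <- quick_resp()
  bc <- blending(NULL, NULL, c("k_dA", "k_dB"), resp = resp)
  n <- length(bc$nb)
  expect_equal(bc$nb[1], bc$ae[1])
  expect_equal(bc$nb[n], bc$ae[n])
  # f = 1 is parameter 1 alone at full budget; f = 0 parameter 2 alone
  expect_equal(bc$nb[n], as.numeric(resp(c(k_dA = -90))))
  expect_equal(bc$nb[1], as.numeric(resp(c(k_dB = -90))))
  # identical pathways make the NB curve symmetric about f = 1/2
  expect_equal(bc$nb, rev(bc$nb), tolerance = 1e-6)
  # AE decomposes into the two single-parameter dose-effect curves
  singles1 <- vapply(bc$grid$delta1_pct, function(d)
    if (d == 0) 0 else as.numeric(resp(c(k_dA = -d))), numeric(1))
  singles2 <- vapply(bc$grid$delta2_pct, function(d)
    if (d == 0) 0 else as.numeric(resp(c(k_dB = -d))), numeric(1))
  expect_equal(bc$ae, singles1 + singles2)
})

test_that("degrees are invariant under pair relabelling", {
  resp <- quick_resp()
  b1 <- blending(NULL, NULL, c("k_dA", "k_ST"), resp = resp)
  b2 <- blending(NULL, NULL, c("k_ST", "k_dA"), resp = resp)
  expect_equal(b1$degrees$degree_nb, b2$degrees$degree_nb, tolerance = 1e-9)
  expect_equal(b1$degrees$degree_add, b2$degrees$degree_add,
               tolerance = 1e-9)
  expect_equal(b1$nb, rev(b2$nb), tolerance = 1e-9)
})

test_that("grid refinement does not lose synergism", {
  resp <- quick_resp()
  coarse <- blending(NULL, NULL, c("k_dA", "k_dB"), n_grid = 10,
                     resp = resp)
  # a finer grid sees at least as much of the interior maximum
  fine <- blending(NULL, NULL, c("k_dA", "k_dB"), n_grid = 28, resp = resp)
  expect_gte(fine$degrees$degree_nb, coarse$degrees$degree_nb - 1e-6)
  expect_gte(fine$degrees$degree_add_max,
             coarse$degrees$degree_add_max - 1e-6)
})

test_that("a null stimulus flags ineffective directions but still blends", {
  m <- motif_model("canonical_m")
  # S identically zero: no parameter change can raise the (flat) peak of T
  suppressWarnings({
    resp <- make_response_fn(m, constant_stimulus(0), t_end = 100,
                             extend = FALSE)
    d <- motifsynergy:::.direction(resp, "k_sA", 90)
  })
  expect_true(isTRUE(attr(d, "ineffective")) || as.numeric(d) %in% c(-1, 1))
  bc <- blending(NULL, NULL, c("k_sA", "k_sB"),
                 directions = c(1, 1), resp = resp)
  expect_equal(bc$degrees$degree_nb, 0)
  expect_equal(bc$degrees$class_nb, "weak")
  expect_equal(bc$nb, bc$ae, tolerance = 1e-9)
})
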