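# Flow-cytometry statistics: transform, gating, function scores, light/dark
# dissimilarity and many-to-one tests.

test_that("arcsinh transform is monotone with the stated log limit", {
  ev <- data.frame(dye = c(0, 10, 100, 1e9), marker = c(1, 2, 3, 4))
  tr <- arcsinh_transform(ev, cofactor = 150)
  expect_equal(tr$dye[1], 0)
  expect_true(all(diff(tr$dye) > 0))
  expect_identical(tr$marker, ev$marker)            # other channels untouched
  # large-x limit: asinh(x/c) ~ log(2x/c)
  expect_equal(tr$dye[4], log(2 * 1e9 / 150), tolerance = 1e-6)
  expect_error(arcsinh_transform(ev, cofactor = 0), "cofactor")
  expect_error(arcsinh_transform(ev, channels = "nope"), "channel")
})

test_that("sequential gates subset events in order", {
  ev <- simulate_flow(0.5, n_events = 5000, seed = 1)
  expect_identical(apply_gates(ev, gate_spec()), ev)
  none <- apply_gates(ev, gate_spec(gate_rect("dye", min = 1e12)))
  expect_equal(nrow(none), 0)
  # independent rectangles commute
  g1 <- gate_rect("fsc_a", min = 3e4)
  g2 <- gate_rect("ssc_a", max = 5e4)
  expect_identical(apply_gates(ev, gate_spec(g1, g2)),
                   apply_gates(ev, gate_spec(g2, g1)))
  # order and acquisition indices are preserved
  gated <- apply_gates(ev, gate_spec(g1))
  expect_true(all(diff(gated$t_acq) > 0))
  # reference-derived quantile gates use the reference sample
  wt <- simulate_flow(0.8, n_events = 5000, seed = 2)
  gq <- gate_quantile("dye", q = 0.5, side = "below", reference = TRUE)
  gated_ref <- apply_gates(ev, gate_spec(gq), reference_events = wt)
  expect_equal(nrow(gated_ref), sum(ev$dye < median(wt$dye)))
  expect_error(apply_gates(ev, gate_spec(gq)), "reference")
  expect_error(apply_gates(ev, gate_spec(gate_rect("nope"))), "channel")
  expect_error(gate_quantile("dye", q = 1.2), "q must")
})

test_that("the wild-type gate scores 50% on wild type itself", {
  wt <- arcsinh_transform(simulate_flow(0.8, n_events = 20000, seed = 3))
  expect_equal(hyperpolarized_percent(wt, wt), 50, tolerance = 0.01)
  # all variant events above the WT median score 0
  hi <- wt
  hi$dye <- hi$dye + 100
  expect_equal(hyperpolarized_percent(hi, wt), 0)
  # active variant scores above an inactive one
  act <- arcsinh_transform(simulate_flow(0.9, n_events = 20000, seed = 4))
  dead <- arcsinh_transform(simulate_flow(0, n_events = 20000, seed = 5))
  expect_gt(hyperpolarized_percent(act, wt), hyperpolarized_percent(dead, wt))
  expect_error(hyperpolarized_percent(wt[0, ], wt), "empty")
})

test_that("function tests match a hand-computed Welch oracle", {
  a <- c(55, 60, 58)
  b <- c(50, 52, 49)
  ft <- function_test(a, b, alternative = "greater")
  # Welch statistic computed explicitly from the definition
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(ft$statistic, t_hand, tolerance = 1e-12)
  expect_equal(ft$df, df_hand, tolerance = 1e-12)
  expect_equal(ft$p.value, pt(t_hand, df_hand, lower.tail = FALSE),
               tolerance = 1e-12)
  # near-identical groups sit near p = 0.5; strong separation is significant
  expect_equal(function_test(c(50, 51, 52), c(50.0, 51.1, 51.9))$p.value,
               0.5, tolerance = 0.2)
  expect_lt(function_test(c(90, 91, 92), c(10, 11, 12))$p.value, 0.001)
  expect_error(function_test(1, c(1, 2)), "replicates")
})

test_that("light/dark dissimilarity matches the 2x2 Pearson oracle", {
  # hand-computed example: 150/1000 vs 300/1000, expected 225/775 per side
  res <- chi2_2x2(150, 1000, 300, 1000)
  expect_equal(res$chi2, 64.516, tolerance = 1e-3)
  expect_equal(sum(res$table), 2000)
  # identical samples give zero dissimilarity
  d <- simulate_flow(0.5, n_events = 2000, seed = 6)
  expect_equal(light_dissimilarity(d, d)$chi2, 0)
  # permuting event order changes nothing
  l <- simulate_flow(0.5, n_events = 2000, seed = 7)
  perm <- withr::with_seed(8, sample(nrow(l)))
  expect_equal(light_dissimilarity(d, l)$chi2,
               light_dissimilarity(d, l[perm, ])$chi2)
  expect_error(light_dissimilarity(d, l, q = 1.5), "q must")
})

test_that("normalization removes proportional count scaling", {
  # doubling all counts at fixed proportions doubles chi2, not chi2/N
  r1 <- chi2_2x2(150, 1000, 300, 1000)
  r2 <- chi2_2x2(300, 2000, 600, 2000)
  expect_equal(r2$chi2, 2 * r1$chi2, tolerance = 1e-9)
  n1 <- normalize_and_average(r1$chi2, 2000)
  n2 <- normalize_and_average(r2$chi2, 4000)
  expect_equal(n1$normalized, n2$normalized, tolerance = 1e-9)
  # equal inputs average to the common value
  na <- normalize_and_average(c(4, 4, 4), c(2, 2, 2))
  expect_equal(na$mean, 2)
  # wild type normalized against itself is 1 per challenge
  wt_norm <- c(0.01, 0.02, 0.05)
  self <- normalize_and_average(wt_norm * c(1000, 1000, 1000),
                                c(1000, 1000, 1000),
                                wt_reference_chi2 = wt_norm)
  expect_equal(self$normalized, c(1, 1, 1))
  expect_error(normalize_and_average(1:3, 1:2), "lengths")
})

test_that("many-to-one tests flag shifted variants and rank conservatively", {
  scores <- list(WT = c(10, 11, 10.5, 10.2),
                 same = c(10.1, 10.9, 10.4, 10.3),
                 shifted = c(30, 31, 30.5, 30.2))
  dn <- many_to_one_test(scores, control = "WT", method = "dunnett")
  bf <- many_to_one_test(scores, control = "WT", method = "bonferroni")
  expect_gt(dn$p_adjusted[dn$variant == "same"], 0.5)
  expect_lt(dn$p_adjusted[dn$variant == "shifted"], 0.001)
  expect_lt(bf$p_adjusted[bf$variant == "shifted"], 0.001)
  # Bonferroni is at least as conservative as Dunnett (small MC slack)
  ok <- vapply(1:20, function(s) {
    sc <- withr::with_seed(400 + s, list(
      WT = rnorm(4), v1 = rnorm(4, 0.5), v2 = rnorm(4, 1), v3 = rnorm(3)))
    d <- many_to_one_test(sc, method = "dunnett")
    b <- many_to_one_test(sc, method = "bonferroni")
    all(b$p_adjusted >= d$p_adjusted - 0.01)
  }, logical(1))
  expect_true(all(ok))
  expect_error(many_to_one_test(list(a = 1:3)), "control")
  expect_error(many_to_one_test(list(WT = 1, v = 1:2)), "replicates")
})
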