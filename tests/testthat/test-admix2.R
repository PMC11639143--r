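test_that("admixture_config2 validates its inputs", {
  expect_error(admixture_config2("x", "a", "x", c("i", "j")), "disjoint")
  expect_error(admixture_config2("x", "a", "b", "i"), "k = 2")
  cfg <- admixture_config2("x", "a", "b", c("j", "i"))
  expect_equal(cfg$auxiliaries, c("i", "j"))  # lexicographic order
})

test_that("alpha_full_space recovers exact hybrids and matches a generic LS oracle", {
  sc <- scenario2(s = 500, alpha = 0.3)
  est <- alpha_full_space(sc$panel, sc$config)
  expect_equal(est$alpha, 0.3, tolerance = 1e-12)

  # x identical to donor a -> alpha = 1
  p <- sc$panel
  p1 <- frequency_panel(cbind(unclass(p)[, setdiff(pop_names(p), "x")],
                              x = p[, "a"]))
  expect_equal(alpha_full_space(p1, sc$config)$alpha, 1.0)

  # noisy hybrid: equals the slope from R's generic no-intercept lm
  scn <- scenario2(s = 800, alpha = 0.3, eps = 0.15, seed = 21)
  est2 <- alpha_full_space(scn$panel, scn$config)
  xv <- scn$panel[, "a"] - scn$panel[, "b"]
  yv <- scn$panel[, "x"] - scn$panel[, "b"]
  oracle <- lm(yv ~ xv + 0)
  expect_equal(est2$alpha, unname(coef(oracle)), tolerance = 1e-10)
  expect_equal(unname(est2$ci),
               unname(confint(oracle)[1, ]), tolerance = 1e-8)

  same <- frequency_panel(cbind(a = c(.2, .4), b = c(.2, .4),
                                x = c(.2, .4), i = c(.1, .9), j = c(.3, .3)))
  expect_error(alpha_full_space(same, sc$config), "degenerate donors")
})

test_that("angle_phi matches direct vector geometry", {
  # x strictly inside the (a, b) segment -> 180 degrees
  sc <- scenario2(s = 300, alpha = 0.6)
  expect_equal(angle_phi(sc$panel, sc$config), 180)

  # right angle by construction: (x-a) orthogonal to (x-b)
  p <- frequency_panel(cbind(a = c(0.6, 0.2, 0.2), b = c(0.2, 0.6, 0.2),
                             x = c(0.2, 0.2, 0.2),
                             i = c(0.5, 0.5, 0.5), j = c(0.1, 0.9, 0.4)))
  cfg <- admixture_config2("x", "a", "b", c("i", "j"))
  expect_equal(angle_phi(p, cfg), 90)

  # random triangle vs dot-product/norm oracle
  rp <- random_panel(s = 3, seed = 31)
  cfg2 <- admixture_config2("x", "a", "b", c("i", "j"))
  u <- rp[, "a"] - rp[, "x"]; v <- rp[, "b"] - rp[, "x"]
  oracle <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(angle_phi(rp, cfg2), oracle)

  px <- frequency_panel(cbind(a = c(.2, .4), b = c(.5, .1),
                              x = c(.2, .4), i = c(.1, .9), j = c(.3, .3)))
  expect_error(angle_phi(px, cfg2), "undefined angle")
})

test_that("admixture_test_full follows the sign of f3", {
  sc <- scenario2(s = 300, alpha = 0.5)
  res <- admixture_test_full(sc$panel, sc$config)
  expect_true(res$passed)
  expect_equal(res$f3, -f2(sc$panel, "a", "b") / 4)
  expect_gt(res$phi_deg, 90)

  # x = a is the boundary: f3 = 0 is not admixture
  p <- sc$panel
  p1 <- frequency_panel(cbind(unclass(p)[, setdiff(pop_names(p), "x")],
                              x = p[, "a"]))
  expect_false(admixture_test_full(p1, sc$config)$passed)

  # verdict matches the brute-force f3 sign on a drifted scenario
  scn <- scenario2(s = 500, alpha = 0.4, eps = 0.3, seed = 41)
  res2 <- admixture_test_full(scn$panel, scn$config)
  expect_equal(res2$passed, bf_f3(scn$panel, "a", "b", "x") < 0)
})

test_that("build_f4_point_set enumerates pairs and excludes degenerate ones", {
  sc <- scenario2(s = 200, n_aux = 5, seed = 51)
  ps <- build_f4_point_set(sc$panel, sc$config)
  expect_equal(nrow(ps), choose(5, 2))
  expect_true(all(ps$pair_i < ps$pair_j))
  expect_true(all(ps$weight >= 0))
  expect_identical(attr(ps, "n_excluded"), 0L)

  # entries equal the individually recomputed renormalized statistics
  for (r in c(1L, 4L, nrow(ps))) {
    expect_equal(ps$predictor[r],
                 n_snps(sc$panel) *
                   bf_f4(sc$panel, "a", "b", ps$pair_i[r], ps$pair_j[r]) /
                   bf_f2(sc$panel, ps$pair_i[r], ps$pair_j[r]))
    expect_equal(ps$response[r],
                 n_snps(sc$panel) *
                   bf_f4(sc$panel, "x", "b", ps$pair_i[r], ps$pair_j[r]) /
                   bf_f2(sc$panel, ps$pair_i[r], ps$pair_j[r]))
  }

  # duplicated auxiliary vector -> C(5,2) - 1 usable pairs
  p <- sc$panel
  aux <- sc$config$auxiliaries
  dup <- unclass(p)
  dup[, aux[2]] <- dup[, aux[1]]
  pdup <- frequency_panel(dup)
  expect_message(ps2 <- build_f4_point_set(pdup, sc$config),
                 "excluded 1 degenerate")
  expect_equal(nrow(ps2), choose(5, 2) - 1L)
  expect_identical(attr(ps2, "n_excluded"), 1L)

  # k = 2 -> a subspace of dimension one
  cfg2 <- admixture_config2("x", "a", "b", aux[1:2])
  expect_equal(nrow(build_f4_point_set(sc$panel, cfg2)), 1L)
})

test_that("alpha_jl: exactness, slope identity, weighted-average identity", {
  sc <- scenario2(s = 1000, alpha = 0.25, seed = 61)
  ps <- build_f4_point_set(sc$panel, sc$config)
  expect_equal(alpha_jl(ps)$alpha, 0.25, tolerance = 1e-10)

  scn <- scenario2(s = 1000, alpha = 0.25, eps = 0.2, seed = 62)
  psn <- build_f4_point_set(scn$panel, scn$config)
  est <- alpha_jl(psn)
  # generic through-origin LS oracle
  oracle <- lm(response ~ predictor + 0, data = as.data.frame(psn))
  expect_equal(est$alpha, unname(coef(oracle)), tolerance = 1e-10)
  expect_equal(unname(est$ci), unname(confint(oracle)[1, ]),
               tolerance = 1e-8)
  # weighted average of single-pair ratios with weights predictor^2
  m <- psn$response / psn$predictor
  expect_equal(est$alpha, sum(m * psn$weight) / sum(psn$weight),
               tolerance = 1e-10)

  # k = 2 collapses to the classical f4-ratio
  aux <- sc$config$auxiliaries
  cfg2 <- admixture_config2("x", "a", "b", aux[1:2])
  ps2 <- build_f4_point_set(scn$panel, cfg2)
  expect_equal(alpha_jl(ps2)$alpha,
               f4_ratio(scn$panel, "x", "a", "b", aux[1], aux[2]),
               tolerance = 1e-10)
})

test_that("angle_varphi is 180 for noiseless hybrids and guards degeneracy", {
  sc <- scenario2(s = 500, alpha = 0.35, seed = 71)
  expect_equal(angle_varphi(sc$panel, sc$config), 180)

  p <- sc$panel
  p1 <- frequency_panel(cbind(unclass(p)[, setdiff(pop_names(p), "x")],
                              x = p[, "a"]))
  expect_error(angle_varphi(p1, sc$config), "undefined angle")
})

test_that("f4_ratio equals the ratio of brute-force f4 values", {
  sc <- scenario2(s = 400, alpha = 0.3, eps = 0.1, seed = 81)
  aux <- sc$config$auxiliaries
  # a cross-clade pair has shared drift with the donors
  i <- grep("^s", aux, value = TRUE)[1]
  j <- grep("^d", aux, value = TRUE)[1]
  expect_equal(f4_ratio(sc$panel, "x", "a", "b", i, j),
               bf_f4(sc$panel, "x", "b", i, j) /
                 bf_f4(sc$panel, "a", "b", i, j))
  # zero shared drift -> unreliable-ratio error
  p <- frequency_panel(cbind(a = c(.2, .8), b = c(.8, .2), x = c(.5, .5),
                             i = c(.3, .3), j = c(.6, .6)))
  expect_error(f4_ratio(p, "x", "a", "b", "i", "j"), "unreliable ratio")
})

test_that("pair_diagnostics decomposes the fit into weighted ratios", {
  sc <- scenario2(s = 2000, n_aux = 8, alpha = 0.4, eps = 0.1, seed = 91)
  ps <- build_f4_point_set(sc$panel, sc$config)
  d <- pair_diagnostics(ps)
  expect_equal(sum(d$weight_share), 1)
  expect_equal(d$cum_weight_share[nrow(d)], 1)
  expect_true(!is.unsorted(rev(d$weight)))
  # pooled estimate = weighted average of the tabulated ratios
  ok <- !is.na(d$m)
  expect_equal(sum(d$m[ok] * d$weight[ok]) / sum(d$weight[ok]),
               alpha_jl(ps)$alpha, tolerance = 1e-6)
  # cross-clade pairs (one s-tip, one d-tip) carry more weight than
  # within-clade pairs: compare the mean weights of the two groups
  # (lexicographic pair order puts the d-tip first in cross-clade pairs)
  straddle <- grepl("^d", d$pair_i) & grepl("^s", d$pair_j)
  within <- (grepl("^s", d$pair_i) & grepl("^s", d$pair_j)) |
    (grepl("^d", d$pair_i) & grepl("^d", d$pair_j))
  expect_gt(mean(d$weight[straddle]), 10 * mean(d$weight[within]))

  # a pair holding ~99.99% of the weight pins the pooled estimate to its
  # own ratio (weighted-average limit)
  dom <- structure(
    data.frame(pair_i = c("p", "q", "r"), pair_j = c("q", "r", "s"),
               predictor = c(100, 0.5, 0.3), response = c(41, 0.1, 0.2),
               weight = c(100, 0.5, 0.3)^2),
    class = c("f4_point_set", "data.frame"))
  expect_equal(alpha_jl(dom)$alpha, 0.41, tolerance = 1e-4)
  eq <- pair_diagnostics(dom)
  expect_equal(eq$weight_share[1], 100^2 / sum(dom$weight))

  # equal-weight point set -> equal weight shares
  flat <- structure(
    data.frame(pair_i = c("p", "q"), pair_j = c("q", "r"),
               predictor = c(2, -2), response = c(1, -1),
               weight = c(4, 4)),
    class = c("f4_point_set", "data.frame"))
  expect_equal(pair_diagnostics(flat)$weight_share, c(0.5, 0.5))
})

test_that("swapping donors maps alpha to 1 - alpha for all estimators", {
  sc <- scenario2(s = 2000, alpha = 0.3, eps = 0.15, seed = 101)
  cfg <- sc$config
  swapped <- admixture_config2("x", cfg$donor_b, cfg$donor_a,
                               cfg$auxiliaries)
  expect_equal(alpha_full_space(sc$panel, swapped)$alpha,
               1 - alpha_full_space(sc$panel, cfg)$alpha, tolerance = 1e-10)
  expect_equal(alpha_jl(build_f4_point_set(sc$panel, swapped))$alpha,
               1 - alpha_jl(build_f4_point_set(sc$panel, cfg))$alpha,
               tolerance = 1e-10)
  aux <- cfg$auxiliaries
  i <- grep("^s", aux, value = TRUE)[1]
  j <- grep("^d", aux, value = TRUE)[1]
  expect_equal(f4_ratio(sc$panel, "x", cfg$donor_b, cfg$donor_a, i, j),
               1 - f4_ratio(sc$panel, "x", cfg$donor_a, cfg$donor_b, i, j),
               tolerance = 1e-10)
})

test_that("fit_admixture2 assembles the full report and warns out of range", {
  sc <- scenario2(s = 2000, alpha = 0.4, eps = 0.1, seed = 111)
  fit <- fit_admixture2(sc$panel, sc$config)
  expect_s3_class(fit, "admixture_fit2")
  expect_true(fit$phi_deg >= 0 && fit$phi_deg <= 180)
  expect_true(fit$varphi_deg >= 0 && fit$varphi_deg <= 180)
  expect_identical(fit$test_passed_full, fit$f3_test < 0)
  expect_identical(fit$test_passed_full,
                   fit$phi_deg > 90 && fit$phi_deg < 180)
  expect_equal(fit$n_pairs_used, choose(8, 2))
  expect_output(print(fit), "alpha \\(subspace fit\\)")

  # hybrid beyond donor a -> alpha > 1 with a warning
  p <- sc$panel
  beyond <- frequency_panel(cbind(
    unclass(p)[, setdiff(pop_names(p), "x")],
    x = pmin(pmax(1.3 * p[, "a"] - 0.3 * p[, "b"], 0), 1)))
  expect_warning(fit_admixture2(beyond, sc$config), "outside \\[0, 1\\]")
})
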