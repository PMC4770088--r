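test_that("gaussian summary: degenerate, i.i.d. closed form, correlated series", {
  g <- gaussian_summary(rep(2.5, 1000), frame_interval = 4.8,
                        block_length = 0.48)
  expect_identical(g$sd, 0)
  expect_identical(g$se_mean, 0)
  expect_identical(g$se_sd, 0)

  # i.i.d. N(3, 1.5): block se_mean approximates sd/sqrt(n)
  set.seed(21)
  n <- 1e5
  x <- rnorm(n, 3, 1.5)
  # 10 blocks of 1e4 frames: 48 ns blocks at 4.8 ps spacing
  g <- gaussian_summary(x, frame_interval = 4.8, block_length = 48)
  expect_identical(g$n_blocks, 10)
  expect_lt(abs(g$mean - 3), 3 * 1.5 / sqrt(n))
  expect_lt(abs(g$se_mean - 1.5 / sqrt(n)) / (1.5 / sqrt(n)), 0.5)
  expect_lt(abs(g$sd - 1.5), 3 * 1.5 / sqrt(2 * n))

  # for i.i.d. data with many blocks the block estimate converges to
  # sd/sqrt(n) (within 20% at M >= 50 blocks)
  g2 <- gaussian_summary(x, frame_interval = 4.8, block_length = 4.8)
  expect_identical(g2$n_blocks, 100)
  expect_lt(abs(g2$se_mean - g2$sd / sqrt(n)) / (g2$sd / sqrt(n)), 0.2)

  # AR(1) series with long correlation time: block se exceeds the naive
  # i.i.d. estimate several-fold
  d <- small_cpg_duplex()
  ear <- generate_parameter_ensemble(
    ensemble_spec(d, n_frames = 2e4L, parameters = "roll",
                  ar1_tau = 480, seed = 22))
  y <- ear$values$roll[, 1]
  gar <- gaussian_summary(y, frame_interval = 4.8, block_length = 9.6)
  expect_gt(gar$se_mean, 3 * sd(y) / sqrt(length(y)))

  expect_error(gaussian_summary(rnorm(100), 4.8, 20), "fewer than 2")
})

test_that("difference errors propagate in quadrature", {
  expect_identical(propagate_difference_se(0, 2.5), 2.5)
  expect_identical(propagate_difference_se(3, 4), 5)
  expect_error(propagate_difference_se(-1, 2), ">= 0")

  # resampling oracle: sd of a difference of independent noises
  set.seed(23)
  for (i in 1:5) {
    se_a <- runif(1, 0.1, 2)
    se_b <- runif(1, 0.1, 2)
    diffs <- rnorm(2e4, 0, se_a) - rnorm(2e4, 0, se_b)
    expect_lt(abs(sd(diffs) - propagate_difference_se(se_a, se_b)) /
                propagate_difference_se(se_a, se_b), 0.05)
  }
})

test_that("delta profile: null contrast, antisymmetry, kernel recovery", {
  d0 <- small_cpg_duplex()
  dm <- small_cpg_duplex("5fC")

  e <- generate_parameter_ensemble(
    ensemble_spec(d0, n_frames = 1000L, parameters = "roll", seed = 31))
  null_prof <- delta_profile(e, e, "roll", 8L, block_length = 0.48)
  expect_lt(max(abs(null_prof$dmean)), 1e-14)
  expect_lt(max(abs(null_prof$dsd)), 1e-14)

  em <- generate_parameter_ensemble(
    ensemble_spec(dm, n_frames = 4000L, parameters = "roll", seed = 32))
  eu <- generate_parameter_ensemble(
    ensemble_spec(d0, n_frames = 4000L, parameters = "roll", seed = 33))
  pr <- delta_profile(em, eu, "roll", 8L, block_length = 2.4)
  pr_rev <- delta_profile(eu, em, "roll", 8L, block_length = 2.4)
  expect_equal(pr$dmean, -pr_rev$dmean)
  expect_equal(pr$dsd, -pr_rev$dsd)
  expect_equal(pr$se_dsd, pr_rev$se_dsd)

  # recovered profile matches the generative kernel within error bounds
  kernel <- c(0, 1 / 3, 2 / 3, 1, 2 / 3, 1 / 3, 0)
  eff <- default_modification_effects()
  dsd_true <- kernel * eff$dsd[eff$condition == "5fC" &
                                 eff$parameter == "roll"]
  dmean_true <- kernel * eff$dmean[eff$condition == "5fC" &
                                     eff$parameter == "roll"]
  expect_true(all(abs(pr$dsd - dsd_true) < 4 * pr$se_dsd + 1e-12))
  expect_true(all(abs(pr$dmean - dmean_true) < 4 * pr$se_dmean + 1e-12))
  # 5fC-like ensembles broaden roll at the CpG centre
  expect_gt(pr$dsd[pr$distance == 0], 0)

  # intra-base-pair parameters pool the two central pairs at d = 0
  ei <- generate_parameter_ensemble(
    ensemble_spec(dm, n_frames = 500L, parameters = "propeller", seed = 34))
  eui <- generate_parameter_ensemble(
    ensemble_spec(d0, n_frames = 500L, parameters = "propeller", seed = 35))
  pri <- delta_profile(ei, eui, "propeller", 8L, block_length = 0.48)
  expect_identical(pri$n_pooled[pri$distance == 0], 2L)
  expect_identical(pri$n_pooled[pri$distance == 1], 1L)

  # missing coverage errors with the offending positions
  e_small <- generate_parameter_ensemble(
    ensemble_spec(modified_duplex("AACGTT"), n_frames = 500L,
                  parameters = "roll", seed = 36))
  expect_error(delta_profile(e_small, e_small, "roll", 3L,
                             block_length = 0.48),
               "do not cover position")
})

test_that("window average over the 3 bp centred at a CpG step", {
  mk <- function(dsd, se = rep(0.1, 7)) {
    p <- data.frame(parameter = "roll", distance = -3:3,
                    dmean = 0, se_dmean = se, dsd = dsd, se_dsd = se,
                    n_pooled = 1L)
    class(p) <- c("delta_profile", class(p))
    p
  }
  flat <- window_average_delta_sd(mk(rep(0.7, 7)))
  expect_equal(flat$estimate, 0.7)
  tri <- window_average_delta_sd(mk(c(0, 0, 1, 2, 1, 0, 0)))
  expect_equal(tri$estimate, 4 / 3)
  set.seed(41)
  for (i in 1:10) {
    v <- rnorm(7)
    se <- runif(7, 0.01, 1)
    w <- window_average_delta_sd(mk(v, se))
    expect_equal(w$estimate, mean(v[3:5]))
    expect_equal(w$se, sqrt(sum(se[3:5]^2)) / 3)
  }
})

test_that("ranking renders strict and similar orderings, order-invariant", {
  # estimates and errors shaped like the reported window-averaged s.d.
  # changes: clear fC > (hmC ~ caC ~ C) > mC tie structure
  est <- c(`5-fC` = 1.0, `5-hmC` = 0.40, `5-caC` = 0.35,
           `unmodified C` = 0.30, `5-mC` = -0.50)
  se <- c(`5-fC` = 0.05, `5-hmC` = 0.05, `5-caC` = 0.05,
          `unmodified C` = 0.05, `5-mC` = 0.05)
  r <- rank_modifications(est, se)
  expect_identical(r$string, "5-fC>5-hmC≳5-caC≳unmodified C>5-mC")

  # invariant to the order conditions are supplied in
  perm <- sample(names(est))
  r2 <- rank_modifications(est[perm], se[perm])
  expect_identical(r2$string, r$string)

  # all conditions identical: all ties
  r3 <- rank_modifications(c(a = 1, b = 1, c = 1), c(a = .1, b = .1, c = .1))
  expect_identical(r3$string, "a≳b≳c")

  # separation far beyond the errors: strict
  r4 <- rank_modifications(c(hi = 10, lo = 0), c(hi = 0.1, lo = 0.1))
  expect_identical(r4$string, "hi>lo")

  expect_error(rank_modifications(c(a = 1), c(a = 0.1)), "at least 2")
  expect_error(rank_modifications(c(a = 1, b = NaN), c(a = .1, b = .1)),
               "finite")
})

test_that("generate -> profile -> rank recovers the generative ordering", {
  d <- modified_duplex(cyclization_core_70mer())
  steps <- interior_cpg_steps(d$top)
  suite <- condition_suite(d, cpg_steps = steps, seed = 55,
                           n_frames = 3000L, parameters = "roll")
  others <- setdiff(names(suite), "unmodified")
  wa <- lapply(others, function(cond) {
    window_average_delta_sd(delta_profile(suite[[cond]], suite$unmodified,
                                          "roll", steps, block_length = 2.4))
  })
  est <- c(vapply(wa, `[[`, numeric(1), "estimate"), unmodified = 0)
  se <- c(vapply(wa, `[[`, numeric(1), "se"), unmodified = 0)
  names(est)[seq_along(others)] <- others
  names(se)[seq_along(others)] <- others
  r <- rank_modifications(est, se)
  expect_identical(r$order, c("5fC", "5hmC", "5caC", "unmodified", "5mC"))
})
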