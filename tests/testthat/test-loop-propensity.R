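test_that("a rigid straight rod never closes; sampling is deterministic", {
  rigid <- chain_fluctuation_spec(n_samples = 500L,
                                  sds = setNames(rep(0, 6),
                                                 parameter_names("step")),
                                  seed = 71)
  e <- estimate_closure_propensity(rigid)
  expect_identical(e$count, 0)
  expect_identical(e$propensity, 0)

  spec <- chain_fluctuation_spec(n_steps = 30L, n_samples = 2000L,
                                 sds = c(shift = 0, slide = 0, rise = 0,
                                         tilt = 8, roll = 8, twist = 4.5),
                                 r_c = 200, theta_c = 120, seed = 72)
  e1 <- estimate_closure_propensity(spec)
  e2 <- estimate_closure_propensity(spec)
  expect_identical(e1$count, e2$count)
  expect_gt(e1$count, 0)
})

test_that("C++ sampler and R reference agree draw-for-draw", {
  spec <- chain_fluctuation_spec(n_steps = 20L, n_samples = 400L,
                                 sds = c(shift = 0, slide = 0, rise = 0,
                                         tilt = 9, roll = 9, twist = 5),
                                 r_c = 300, theta_c = 45, seed = 73)
  fast <- estimate_closure_propensity(spec)
  slow <- modflex:::.closure_mc_r(spec)
  expect_identical(fast$count, as.numeric(slow$count))
  expect_gt(fast$count, 0)
  expect_lt(fast$count, spec$n_samples)
})

test_that("estimator is unbiased against exhaustive enumeration (toy chain)", {
  # 3-step chain, roll discretized to {-20, 0, +20} deg with equal weights,
  # other parameters rigid B-DNA
  rolls <- c(-20, 0, 20)
  grid <- expand.grid(r1 = rolls, r2 = rolls, r3 = rolls)
  mk_steps <- function(r) {
    cbind(shift = 0, slide = 0, rise = 3.38, tilt = 0, roll = r, twist = 36)
  }
  all_confs <- lapply(seq_len(nrow(grid)), function(i)
    mk_steps(as.numeric(grid[i, ])))
  closed <- closure_fraction(all_confs, r_c = 1000, theta_c = 35)
  p_exact <- mean(closed)
  expect_gt(p_exact, 0)
  expect_lt(p_exact, 1)

  set.seed(74)
  n <- 3000L
  draws <- matrix(sample(rolls, 3 * n, replace = TRUE), n, 3)
  sampled <- lapply(seq_len(n), function(i) mk_steps(draws[i, ]))
  p_hat <- mean(closure_fraction(sampled, r_c = 1000, theta_c = 35))
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / n))
})

test_that("propensity is monotone in the capture criteria", {
  spec <- chain_fluctuation_spec(n_steps = 40L, n_samples = 5000L,
                                 sds = c(shift = 0, slide = 0, rise = 0,
                                         tilt = 8, roll = 8, twist = 4.5),
                                 r_c = 150, theta_c = 90, seed = 75)
  e <- estimate_closure_propensity(spec, return_samples = TRUE)
  s <- e$samples
  count_at <- function(rc, th) sum(s[, 1] < rc & s[, 2] < th)
  for (rc in c(50, 100, 150)) {
    expect_lte(count_at(rc, 90), count_at(rc + 25, 90))
  }
  for (th in c(30, 60, 90)) {
    expect_lte(count_at(150, th), count_at(150, th + 20))
  }
  # enabling the twist-register criterion can only reduce the count
  reg_count <- sum(s[, 1] < 150 & s[, 2] < 90 & s[, 3] <= 30)
  expect_lte(reg_count, count_at(150, 90))
})

test_that("closure propensity rises with bend fluctuations (90-step chain)", {
  # bend s.d. at the ends of the 4-8 degree range, 1e6 samples each
  mk <- function(bend_sd, seed) {
    chain_fluctuation_spec(
      n_samples = 1e6,
      sds = c(shift = 0.5, slide = 0.5, rise = 0.3,
              tilt = bend_sd, roll = bend_sd, twist = 4.5),
      seed = seed)
  }
  stiff <- estimate_closure_propensity(mk(4, 76))
  soft <- estimate_closure_propensity(mk(8, 77))
  expect_gt(soft$propensity, stiff$propensity)
  expect_gt(soft$ci["lower"], stiff$ci["upper"])
})

test_that("binomial CI width scales as 1/sqrt(n)", {
  mk <- function(n, seed) {
    chain_fluctuation_spec(n_steps = 40L, n_samples = n,
                           sds = c(shift = 0, slide = 0, rise = 0,
                                   tilt = 8, roll = 8, twist = 4.5),
                           r_c = 150, theta_c = 90, seed = seed)
  }
  e1 <- estimate_closure_propensity(mk(10000L, 78))
  e4 <- estimate_closure_propensity(mk(40000L, 79))
  w1 <- diff(e1$ci)
  w4 <- diff(e4$ci)
  expect_lt(abs(w4 / w1 - 0.5), 0.2)
})

test_that("condition comparison reports unit ratios for identical specs", {
  mk <- function(seed) {
    chain_fluctuation_spec(n_steps = 40L, n_samples = 20000L,
                           sds = c(shift = 0, slide = 0, rise = 0,
                                   tilt = 8, roll = 8, twist = 4.5),
                           r_c = 150, theta_c = 90, seed = seed)
  }
  cmp <- compare_conditions(list(unmodified = mk(80), `5fC` = mk(81)))
  tab <- cmp$table
  r <- tab$ratio[tab$condition == "5fC"]
  expect_gt(r, tab$ratio_lower[tab$condition == "5fC"] / 1.0001)
  expect_true(tab$ratio_lower[tab$condition == "5fC"] <= 1 &&
                tab$ratio_upper[tab$condition == "5fC"] >= 1)
  expect_identical(tab$ratio[tab$condition == "unmodified"], 1)

  expect_error(compare_conditions(list(`5fC` = mk(1))), "unmodified")
})
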