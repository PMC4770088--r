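test_that("generator is deterministic and degenerate cases collapse to means", {
  d <- small_cpg_duplex("5fC")
  spec <- ensemble_spec(d, n_frames = 200L, seed = 42)
  e1 <- generate_parameter_ensemble(spec)
  e2 <- generate_parameter_ensemble(spec)
  expect_identical(e1$values, e2$values)

  # zero baseline sd and zero effects: every frame equals the baseline mean
  b0 <- default_baseline()
  b0$sd <- 0
  eff0 <- default_modification_effects()
  eff0$dmean <- 0
  eff0$dsd <- 0
  e0 <- generate_parameter_ensemble(
    ensemble_spec(d, n_frames = 10L, baseline = b0, effects = eff0,
                  sd_floor = 0, seed = 1))
  expect_lt(max(abs(e0$values$twist - 36)), 1e-12)
  expect_lt(max(abs(e0$values$roll)), 1e-12)
  expect_lt(max(abs(e0$values$rise - 3.38)), 1e-12)
})

test_that("sampled sd at the CpG centre matches the spec'd effect", {
  # roll baseline (0, 5 deg), 5fC +1 deg at the CpG centre -> sd 6 deg there
  d <- small_cpg_duplex("5fC")
  b <- default_baseline()
  b$sd[b$parameter == "roll"] <- 5
  eff <- data.frame(condition = "5fC", parameter = "roll", dmean = 0, dsd = 1)
  n <- 1e5L
  e <- generate_parameter_ensemble(
    ensemble_spec(d, n_frames = n, baseline = b, effects = eff,
                  parameters = "roll", seed = 13))
  s_hat <- sd(e$values$roll[, "8"])   # CpG step position
  se_sd <- 6 / sqrt(2 * n)
  expect_lt(abs(s_hat - 6), 3 * se_sd)
  # far position keeps the baseline sd
  s_far <- sd(e$values$roll[, "2"])
  expect_lt(abs(s_far - 5), 3 * 5 / sqrt(2 * n))
})

test_that("generator moments converge at the 1/sqrt(n) rate", {
  d <- small_cpg_duplex()
  for (n in c(2000L, 32000L)) {
    e <- generate_parameter_ensemble(
      ensemble_spec(d, n_frames = n, parameters = c("roll", "twist"),
                    seed = 101))
    for (p in c("roll", "twist")) {
      mu <- e$generative$mean[[p]]
      sg <- e$generative$sd[[p]]
      m_hat <- colMeans(e$values[[p]])
      s_hat <- apply(e$values[[p]], 2, sd)
      expect_true(all(abs(m_hat - mu) < 4.5 * sg / sqrt(n)))
      expect_true(all(abs(s_hat - sg) < 4.5 * sg / sqrt(2 * n)))
    }
  }
})

test_that("paired seeds localize effects to the kernel support", {
  d0 <- small_cpg_duplex()
  suite <- condition_suite(d0, conditions = c("unmodified", "5fC"),
                           cpg_steps = 8L, seed = 77, paired_seeds = TRUE,
                           n_frames = 300L)
  u <- suite$unmodified$values$roll
  m <- suite$`5fC`$values$roll
  # kernel support: steps within |d| <= 2 of the CpG step at 8
  inside <- as.character(6:10)
  outside <- setdiff(colnames(u), as.character(5:11))
  expect_identical(m[, outside], u[, outside])
  expect_true(all(abs(m[, "8"] - u[, "8"]) > 0))
})

test_that("positions with zero kernel weight are distributionally baseline", {
  d0 <- small_cpg_duplex()
  suite <- condition_suite(d0, conditions = c("unmodified", "5fC"),
                           cpg_steps = 8L, seed = 31, n_frames = 2000L,
                           parameters = "roll")
  u <- suite$unmodified$values$roll
  m <- suite$`5fC`$values$roll
  outside <- setdiff(colnames(u), as.character(5:11))
  pvals <- vapply(outside, function(j)
    suppressWarnings(stats::ks.test(m[, j], u[, j])$p.value), numeric(1))
  # two-sample test at alpha = 0.01 with Bonferroni multiplicity control
  expect_true(all(pvals > 0.01 / length(pvals)))
})

test_that("condition suite has matched shapes and rejects unknown labels", {
  d0 <- modified_duplex(cyclization_core_70mer())
  suite <- condition_suite(d0, seed = 3, n_frames = 20L,
                           parameters = c("roll", "twist"))
  expect_named(suite, c("unmodified", "5mC", "5hmC", "5fC", "5caC"))
  dims <- lapply(suite, function(e) dim(e$values$roll))
  expect_true(all(vapply(dims, identical, logical(1), dims[[1]])))

  one <- condition_suite(d0, conditions = "unmodified", seed = 3,
                         n_frames = 5L, parameters = "roll")
  expect_named(one, "unmodified")
  expect_error(condition_suite(d0, conditions = c("unmodified", "6mA")),
               "unknown condition")
})

test_that("realize -> extract recovers the generated parameters exactly", {
  d <- small_cpg_duplex("5hmC")

  # deterministic ideal B-DNA chain extracts to the baseline means
  b0 <- default_baseline()
  b0$sd <- 0
  eff0 <- default_modification_effects()
  eff0$dmean <- 0
  eff0$dsd <- 0
  e0 <- generate_parameter_ensemble(
    ensemble_spec(d, n_frames = 2L, baseline = b0, effects = eff0,
                  sd_floor = 0, seed = 2))
  ex0 <- extract_parameters(realize_coordinates(e0, d))
  expect_lt(max(abs(ex0$values$twist - 36)), 1e-6)
  expect_lt(max(abs(ex0$values$rise - 3.38)), 1e-6)
  expect_lt(max(abs(ex0$values$propeller)), 1e-6)

  # fluctuating ensemble: extraction is an exact inverse of realization
  e <- generate_parameter_ensemble(ensemble_spec(d, n_frames = 120L, seed = 8))
  ex <- extract_parameters(realize_coordinates(e, d))
  err <- max(vapply(parameter_names(), function(p)
    max(abs(e$values[[p]] - ex$values[[p]])), numeric(1)))
  expect_lt(err, 1e-6)
})

test_that("PDB write/read round trip preserves coordinates to format precision", {
  d <- small_cpg_duplex()
  e <- generate_parameter_ensemble(ensemble_spec(d, n_frames = 4L, seed = 5))
  tr <- realize_coordinates(e, d)
  f <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, f)
  tr2 <- read_trajectory_pdb(f)
  expect_identical(dim(tr2$xyz), dim(tr$xyz))
  expect_lt(max(abs(tr2$xyz - tr$xyz)), 1e-3 + 1e-9)
  expect_identical(tr2$atoms$base, tr$atoms$base)
})

test_that("long-format ensemble TSV round trips", {
  d <- small_cpg_duplex("5caC")
  e <- generate_parameter_ensemble(ensemble_spec(d, n_frames = 15L, seed = 6))
  f <- tempfile(fileext = ".tsv")
  write_ensemble_tsv(e, f)
  e2 <- read_ensemble_tsv(f)
  expect_identical(e2$condition, e$condition)
  expect_equal(e2$frame_interval, e$frame_interval)
  err <- max(vapply(names(e$values), function(p)
    max(abs(e$values[[p]] - e2$values[[p]])), numeric(1)))
  expect_lt(err, 1e-12)
})
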