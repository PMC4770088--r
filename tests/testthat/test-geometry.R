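test_that("base-frame fitting recovers known rigid transforms", {
  std <- standard_base_geometry("C")

  f <- fit_base_frame(std, "C")
  expect_lt(max(abs(f$axes - diag(3))), 1e-9)
  expect_lt(max(abs(f$origin)), 1e-9)

  # apply a known transform; the fitted frame must be its image
  a <- 30 * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  obs <- std %*% t(R) + matrix(rep(c(1, 2, 3), each = nrow(std)), nrow(std))
  f <- fit_base_frame(obs, "C")
  expect_lt(max(abs(f$axes - R)), 1e-9)
  expect_lt(max(abs(f$origin - c(1, 2, 3))), 1e-9)

  # exact covariance under random rigid motions, for all base types
  set.seed(5)
  for (b in c("A", "C", "G", "T", "5fC")) {
    g <- standard_base_geometry(b)
    f0 <- fit_base_frame(g, b)
    for (i in 1:5) {
      Q <- random_rotation()
      t0 <- rnorm(3, sd = 10)
      f1 <- fit_base_frame(g %*% t(Q) + matrix(rep(t0, each = nrow(g)),
                                               nrow(g)), b)
      expect_lt(max(abs(f1$axes - Q %*% f0$axes)), 1e-9)
      expect_lt(max(abs(f1$origin - (drop(Q %*% f0$origin) + t0))), 1e-9)
    }
  }

  expect_error(fit_base_frame(std[1:2, ], "C"), "at least 3")
  collinear <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, byrow = TRUE,
                      dimnames = list(c("N1", "C2", "N3"), NULL))
  expect_error(fit_base_frame(collinear, "C"), "collinear")
})

test_that("intra-base-pair decomposition is exact and zero for an ideal pair", {
  # ideal Watson-Crick pair: flipped complementary frame coincides with W
  w <- reference_frame(c(1, -2, 5), diag(3))
  cfl <- reference_frame(c(1, -2, 5), diag(c(1, -1, -1)))
  bp <- base_pair_frame(w, cfl)
  expect_lt(max(abs(bp$params)), 1e-12)
  expect_lt(max(abs(bp$bp_frame$axes - diag(3))), 1e-12)

  # single-parameter build-then-measure round trips
  for (par in c("propeller", "shear")) {
    p <- setNames(numeric(6), parameter_names("intra"))
    p[par] <- if (par == "propeller") 10 else 0.5
    pair <- base_pair_from_frame(reference_frame(), p)
    back <- base_pair_frame(pair$frame_W, pair$frame_C)
    expect_equal(unname(back$params[par]), unname(p[par]), tolerance = 1e-10)
    expect_lt(max(abs(back$params[setdiff(names(p), par)])), 1e-10)
  }

  # full random round trips through an arbitrary base-pair frame
  set.seed(6)
  for (i in 1:40) {
    bpf <- reference_frame(rnorm(3, sd = 5), random_rotation())
    p <- random_intra_params()
    pair <- base_pair_from_frame(bpf, p)
    back <- base_pair_frame(pair$frame_W, pair$frame_C)
    expect_lt(max(abs(back$params - p)), 1e-8)
    expect_lt(max(abs(back$bp_frame$axes - bpf$axes)), 1e-9)
    expect_lt(max(abs(back$bp_frame$origin - bpf$origin)), 1e-9)
  }

  bad <- reference_frame()
  bad$axes <- matrix(1:9, 3)
  expect_error(base_pair_frame(bad, reference_frame()), "orthonormal")
})

test_that("step parameters: null step, pure twist, oracle equivalence", {
  f0 <- reference_frame()
  expect_lt(max(abs(step_params(f0, f0))), 1e-12)

  fr <- rebuild_frames(f0, matrix(c(0, 0, 3.4, 0, 0, 36), 1))
  sp <- step_params(fr[[1]], fr[[2]])
  expect_equal(unname(sp["twist"]), 36, tolerance = 1e-9)
  expect_equal(unname(sp["rise"]), 3.4, tolerance = 1e-9)
  expect_lt(max(abs(sp[c("shift", "slide", "tilt", "roll")])), 1e-9)

  # closed-form extraction agrees with the numerical-minimization oracle
  set.seed(7)
  for (i in 1:20) {
    p <- random_step_params()
    fr <- rebuild_frames(reference_frame(rnorm(3), random_rotation()),
                         matrix(p, 1))
    got <- step_params(fr[[1]], fr[[2]])
    orc <- oracle_step_params(fr[[1]], fr[[2]])
    expect_lt(max(abs(got - orc)), 1e-6)
  }
})

test_that("reversing a step negates tilt and shift only", {
  FLIP <- diag(c(1, -1, -1))
  set.seed(8)
  for (i in 1:40) {
    f1 <- reference_frame(rnorm(3), random_rotation())
    fr <- rebuild_frames(f1, matrix(random_step_params(), 1))
    p <- step_params(fr[[1]], fr[[2]])
    # swap the two frames with a strand flip
    g1 <- reference_frame(fr[[2]]$origin, fr[[2]]$axes %*% FLIP)
    g2 <- reference_frame(fr[[1]]$origin, fr[[1]]$axes %*% FLIP)
    q <- step_params(g1, g2)
    expect_lt(max(abs(q - p * c(-1, 1, 1, -1, 1, 1))), 1e-9)
  }
})

test_that("rebuild and extract are exact inverses; B-DNA has period 10", {
  f0 <- reference_frame()

  # null chain
  fr <- rebuild_frames(f0, matrix(0, 5, 6))
  for (f in fr) {
    expect_lt(max(abs(f$axes - diag(3))), 1e-12)
    expect_lt(max(abs(f$origin)), 1e-12)
  }

  # one helical turn of ideal B-DNA
  fr <- rebuild_frames(f0, matrix(rep(c(0, 0, 3.4, 0, 0, 36), 10), 10,
                                  byrow = TRUE))
  expect_lt(max(abs(fr[[11]]$axes - diag(3))), 1e-9)
  expect_lt(max(abs(fr[[11]]$origin - c(0, 0, 34))), 1e-9)

  # random chains round-trip within 1e-8 and stay orthonormal
  set.seed(9)
  for (i in 1:20) {
    steps <- t(replicate(12, random_step_params()))
    colnames(steps) <- parameter_names("step")
    fr <- rebuild_frames(f0, steps)
    for (k in 1:12) {
      expect_lt(max(abs(crossprod(fr[[k + 1]]$axes) - diag(3))), 1e-9)
      got <- step_params(fr[[k]], fr[[k + 1]])
      expect_lt(max(abs(got - steps[k, ])), 1e-8)
    }
  }

  expect_error(rebuild_frames(f0, matrix(c(NA, 0, 0, 0, 0, 0), 1)),
               "non-finite")
})
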