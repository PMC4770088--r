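# Independent oracles and fixture builders used across the test files.

# exhaustive character-by-character CpG scan (independent of the package's
# regex-based implementation)
brute_cpg_scan <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- integer(0)
  for (p in seq_len(length(ch) - 1L)) {
    if (ch[p] == "C" && ch[p + 1L] == "G") out <- c(out, p)
  }
  out
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# explicit rotation builders for the oracle forward model (written from the
# rotation-matrix definition, no package code)
oracle_rz <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
oracle_ry <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# Brute-force recovery of the six step parameters between two frames by
# numerical minimization over the mid-frame factorization, independent of
# the closed-form extraction path.
oracle_step_params <- function(f1, f2) {
  A_obs <- t(f1$axes) %*% f2$axes
  d_obs <- f2$origin - f1$origin
  obj <- function(p) {
    # p = (shift, slide, rise, tilt, roll, twist), angles in degrees
    ax <- p[4] * pi / 180
    ay <- p[5] * pi / 180
    w <- p[6] * pi / 180
    G <- sqrt(ax^2 + ay^2)
    phi <- if (G == 0) 0 else atan2(ax, ay)
    A <- oracle_rz(w / 2 - phi) %*% oracle_ry(G) %*% oracle_rz(w / 2 + phi)
    Rm <- f1$axes %*% oracle_rz(w / 2 - phi) %*% oracle_ry(G / 2) %*%
      oracle_rz(phi)
    sum((A - A_obs)^2) + sum((drop(Rm %*% p[1:3]) - d_obs)^2)
  }
  fit <- stats::optim(rep(0, 6), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  fit2 <- stats::optim(fit$par, obj, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-16))
  stats::setNames(fit2$par, c("shift", "slide", "rise", "tilt", "roll",
                              "twist"))
}

# moderate random step parameters (bend within the oracle's basin)
random_step_params <- function() {
  c(shift = runif(1, -2, 2), slide = runif(1, -2, 2),
    rise = runif(1, 1, 5), tilt = runif(1, -25, 25),
    roll = runif(1, -25, 25), twist = runif(1, -60, 80))
}

random_intra_params <- function() {
  stats::setNames(c(runif(2, -1, 1), runif(1, -0.8, 0.8),
                    runif(2, -15, 15), runif(1, -20, 20)),
                  c("shear", "stretch", "stagger", "buckle", "propeller",
                    "opening"))
}

# small duplex with a single interior CpG step (start position 8 of 16)
small_cpg_duplex <- function(mod = NULL) {
  d <- modified_duplex("ATTAGCACGTGCTAAT")
  if (!is.null(mod)) d <- apply_modifications(d, 8L, mod)
  d
}
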