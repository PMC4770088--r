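# Single-molecule cyclization kinetics: two-state (looped/unlooped) Markov
# simulation of a population of surface-tethered molecules after a salt
# jump, exponential fitting of the looped fraction versus time, and
# fold-changes of the apparent looping time between constructs.
#
# Two-state kinetics with rates k_loop (unlooped -> looped) and k_unloop:
# starting all-unlooped, the expected looped fraction is
#   f(t) = f_eq * (1 - exp(-t / tau)),
# with f_eq = k_loop / (k_loop + k_unloop) and tau = 1 / (k_loop + k_unloop).
# The apparent looping time tau is the operational flexibility measure:
# more flexible DNA loops faster.

#' Default salt-jump sampling grid
#'
#' Dense early, log-spaced time grid mimicking a salt-jump experiment:
#' `t = 0` plus `n - 1` log-spaced points from `tau_scale / 20` to
#' `5 * tau_scale` seconds.
#'
#' @param tau_scale Expected looping time scale in seconds.
#' @param n Number of points.
#' @return Numeric vector of times (s).
#' @export
default_sample_times <- function(tau_scale = 600, n = 25L) {
  c(0, exp(seq(log(tau_scale / 20), log(5 * tau_scale), length.out = n - 1L)))
}

#' Simulate a looping time course
#'
#' Each molecule evolves as an independent two-state Markov chain, starting
#' unlooped at `t = 0` (salt-jump start); the recorded value at each sample
#' time is the binomial fraction of looped molecules. An optional
#' per-molecule dropout rate (photobleaching surrogate) removes molecules
#' permanently from the count; it defaults to 0.
#'
#' @param n_molecules Number of molecules.
#' @param k_loop,k_unloop Rates in 1/s (> 0).
#' @param sample_times Strictly increasing sample times in seconds.
#' @param seed RNG seed.
#' @param dropout_rate Per-second rate at which molecules drop out.
#' @param condition Condition label.
#' @return Object of class `looping_timecourse`: data.frame with columns
#'   `time_s`, `looped_fraction`, `n_molecules`, plus attributes recording
#'   the generative rates.
#' @export
#' @examples
#' tc <- simulate_looping(200, 0.008, 0.002, default_sample_times(100), seed = 1)
simulate_looping <- function(n_molecules, k_loop, k_unloop, sample_times,
                             seed = NULL, dropout_rate = 0,
                             condition = "unmodified") {
  if (k_loop <= 0 || k_unloop <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  sample_times <- as.numeric(sample_times)
  if (any(diff(sample_times) <= 0) || any(sample_times < 0)) {
    stop("sample_times must be non-negative and strictly increasing",
         call. = FALSE)
  }
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) stop("need at least one molecule", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ksum <- k_loop + k_unloop
  feq <- k_loop / ksum
  state <- rep(FALSE, n_molecules)   # FALSE = unlooped at t = 0
  alive <- rep(TRUE, n_molecules)
  states <- matrix(FALSE, n_molecules, length(sample_times))
  alives <- matrix(TRUE, n_molecules, length(sample_times))
  t_prev <- 0
  frac <- numeric(length(sample_times))
  nmol <- integer(length(sample_times))
  for (i in seq_along(sample_times)) {
    dt <- sample_times[i] - t_prev
    if (dt > 0) {
      decay <- exp(-dt * ksum)
      p_loop <- feq + (as.numeric(state) - feq) * decay
      state <- runif(n_molecules) < p_loop
      if (dropout_rate > 0) {
        alive <- alive & (runif(n_molecules) > 1 - exp(-dropout_rate * dt))
      }
      t_prev <- sample_times[i]
    }
    nmol[i] <- sum(alive)
    frac[i] <- if (nmol[i] > 0) mean(state[alive]) else NA_real_
    states[, i] <- state
    alives[, i] <- alive
  }
  out <- data.frame(time_s = sample_times, looped_fraction = frac,
                    n_molecules = nmol)
  attr(out, "k_loop") <- k_loop
  attr(out, "k_unloop") <- k_unloop
  attr(out, "condition") <- condition
  attr(out, "states") <- states
  attr(out, "alive") <- alives
  class(out) <- c("looping_timecourse", class(out))
  out
}

#' Fit the apparent looping time
#'
#' Unweighted least-squares fit of `f(t) = f_eq * (1 - exp(-t / tau))` to a
#' looped-fraction time course. The plateau `f_eq` floats by default
#' (bounded to `[0, 1]`); pass `fix_plateau` to fit only `tau` with the
#' plateau held at a known equilibrium value. A binomially weighted fit is
#' available via `weighted = TRUE`.
#'
#' Standard errors: because a time course tracks the same molecules over
#' time, its residuals are strongly correlated and the asymptotic
#' regression errors understate the true uncertainty several-fold. When the
#' time course carries per-molecule trajectories (as produced by
#' [simulate_looping()]), errors are therefore computed by a
#' molecule-level bootstrap (resample molecules with replacement, recompute
#' the fraction curve, refit); otherwise the asymptotic errors are
#' reported.
#'
#' @param tc A `looping_timecourse` (or data.frame with columns `time_s`,
#'   `looped_fraction`).
#' @param fix_plateau Optional fixed equilibrium looped fraction.
#' @param weighted Weight residuals by inverse binomial variance?
#' @param se_method `"auto"` (bootstrap when per-molecule states are
#'   available), `"bootstrap"` or `"asymptotic"`.
#' @param n_boot Bootstrap resamples.
#' @return Object of class `looping_fit`: list with `tau`, `f_eq`,
#'   `se_tau`, `se_f_eq`, `se_method`, `residual_sd`, `fit`.
#' @export
fit_looping <- function(tc, fix_plateau = NULL, weighted = FALSE,
                        se_method = c("auto", "bootstrap", "asymptotic"),
                        n_boot = 200L) {
  se_method <- match.arg(se_method)
  d <- as.data.frame(tc)[, c("time_s", "looped_fraction")]
  d <- d[complete.cases(d), ]
  if (nrow(d) < 4L) stop("need at least 4 time points", call. = FALSE)
  fmax <- max(d$looped_fraction)
  f0 <- min(max(fmax, 0.05), 0.999)
  t63 <- d$time_s[which(d$looped_fraction >= 0.632 * f0)[1]]
  tau0 <- if (is.na(t63) || t63 <= 0) median(d$time_s[d$time_s > 0]) else t63
  w <- if (weighted) {
    nm <- if ("n_molecules" %in% names(tc)) tc$n_molecules[complete.cases(tc)]
          else rep(1, nrow(d))
    v <- pmax(d$looped_fraction * (1 - d$looped_fraction), 1e-4) / pmax(nm, 1)
    1 / v
  } else rep(1, nrow(d))
  fit <- tryCatch({
    if (is.null(fix_plateau)) {
      minpack.lm::nlsLM(looped_fraction ~ f_eq * (1 - exp(-time_s / tau)),
                        data = d, weights = w,
                        start = list(f_eq = f0, tau = tau0),
                        lower = c(f_eq = 0, tau = 1e-9),
                        upper = c(f_eq = 1, tau = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      if (fix_plateau < 0 || fix_plateau > 1) {
        stop("fix_plateau must lie in [0, 1]", call. = FALSE)
      }
      f_eq <- fix_plateau
      minpack.lm::nlsLM(looped_fraction ~ f_eq * (1 - exp(-time_s / tau)),
                        data = d, weights = w, start = list(tau = tau0),
                        lower = c(tau = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop("looping fit failed to converge: ", conditionMessage(e),
         "\n  time range ", min(d$time_s), "-", max(d$time_s),
         " s, fraction range ", round(min(d$looped_fraction), 3), "-",
         round(max(d$looped_fraction), 3), call. = FALSE)
  })
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tau <- unname(cf["tau"])
  if (tau <= 0) stop("fitted tau is non-positive", call. = FALSE)
  se_tau <- unname(se["tau"])
  se_f_eq <- if (is.null(fix_plateau)) unname(se["f_eq"]) else 0
  used <- "asymptotic"
  states <- attr(tc, "states")
  alive <- attr(tc, "alive")
  if (se_method != "asymptotic" && !is.null(states)) {
    used <- "bootstrap"
    nm <- nrow(states)
    all_times <- as.data.frame(tc)$time_s
    refit <- function(frac) {
      db <- data.frame(time_s = all_times, looped_fraction = frac)
      db <- db[complete.cases(db), ]
      if (nrow(db) != length(w)) return(c(NA_real_, NA_real_))
      ft <- tryCatch(
        if (is.null(fix_plateau)) {
          minpack.lm::nlsLM(looped_fraction ~ f_eq * (1 - exp(-time_s / tau)),
                            data = db, weights = w,
                            start = as.list(cf),
                            lower = c(f_eq = 0, tau = 1e-9),
                            upper = c(f_eq = 1, tau = Inf))
        } else {
          f_eq <- fix_plateau
          minpack.lm::nlsLM(looped_fraction ~ f_eq * (1 - exp(-time_s / tau)),
                            data = db, weights = w, start = as.list(cf),
                            lower = c(tau = 1e-9))
        }, error = function(e) NULL)
      if (is.null(ft)) c(NA_real_, NA_real_) else {
        cb <- coef(ft)
        c(unname(cb["tau"]),
          if (is.null(fix_plateau)) unname(cb["f_eq"]) else fix_plateau)
      }
    }
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nm, nm, replace = TRUE)
      st <- states[idx, , drop = FALSE]
      al <- alive[idx, , drop = FALSE]
      frac <- colSums(st & al) / pmax(colSums(al), 1L)
      refit(frac)
    }, numeric(2))
    se_tau <- sd(boots[1, ], na.rm = TRUE)
    if (is.null(fix_plateau)) se_f_eq <- sd(boots[2, ], na.rm = TRUE)
  } else if (se_method == "bootstrap" && is.null(states)) {
    stop("bootstrap errors need per-molecule states ",
         "(a time course from simulate_looping)", call. = FALSE)
  }
  structure(list(
    tau = tau,
    f_eq = if (is.null(fix_plateau)) unname(cf["f_eq"]) else fix_plateau,
    se_tau = se_tau,
    se_f_eq = se_f_eq,
    se_method = used,
    residual_sd = sd(residuals(fit)),
    fit = fit), class = "looping_fit")
}

#' @export
print.looping_fit <- function(x, ...) {
  cat(sprintf("looping_fit: tau = %.4g +/- %.2g s, f_eq = %.3f +/- %.3f\n",
              x$tau, x$se_tau, x$f_eq, x$se_f_eq))
  invisible(x)
}

#' Fold change of the apparent looping time
#'
#' Ratio `tau_a / tau_b` with first-order propagated standard error.
#'
#' @param fit_a,fit_b `looping_fit` objects.
#' @return List with `ratio` and `se`.
#' @export
fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "looping_fit"), inherits(fit_b, "looping_fit"))
  if (fit_b$tau <= 0) stop("denominator tau must be positive", call. = FALSE)
  r <- fit_a$tau / fit_b$tau
  se <- r * sqrt((fit_a$se_tau / fit_a$tau)^2 + (fit_b$se_tau / fit_b$tau)^2)
  list(ratio = r, se = se)
}

#' Write / read looping time-course TSV
#'
#' Columns `time_s`, `looped_fraction`, `n_molecules`.
#'
#' @param tc A `looping_timecourse`.
#' @param path File path.
#' @export
write_timecourse_tsv <- function(tc, path) {
  utils::write.table(as.data.frame(tc)[, c("time_s", "looped_fraction",
                                           "n_molecules")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_tsv
#' @export
read_timecourse_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("time_s", "looped_fraction", "n_molecules")
  if (!all(need %in% names(d))) {
    stop("time-course TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(d) <- c("looping_timecourse", class(d))
  d
}
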