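# Single-molecule FRET force spectroscopy of nucleosome unwrapping:
# ratiometric FRET efficiency, Gaussian histogram peak fitting, synthetic
# stretching traces exhibiting the three unwrapping behaviours, change-point
# trace classification, trace averaging and class percentages.
#
# Trace classes (exhaustive, mutually exclusive per trace):
#   high_force_drop   - stable high FRET, single major drop at high force
#                       (~15 pN), the unmodified-nucleosome behaviour;
#   gradual_then_drop - an additional gradual FRET decline before the final
#                       high-force drop;
#   low_force_drop    - the major drop already at low force (~5 pN).
# The published observations do not define the classification rule; the
# change-point + pre-drop-slope procedure here is this package's
# operationalization, with its thresholds exposed as arguments.

TRACE_CLASSES <- c("high_force_drop", "gradual_then_drop", "low_force_drop")

#' Ratiometric FRET efficiency
#'
#' `E = IA / (IA + gamma * ID)` with detection-correction factor `gamma`
#' (default 1). Vectorized over paired intensities.
#'
#' @param donor_intensity,acceptor_intensity Non-negative intensities
#'   (arbitrary units).
#' @param gamma Detection-correction factor.
#' @return Efficiency in `[0, 1]`.
#' @export
#' @examples
#' fret_efficiency(500, 500, gamma = 1.25)  # 4/9
fret_efficiency <- function(donor_intensity, acceptor_intensity, gamma = 1) {
  if (any(donor_intensity < 0) || any(acceptor_intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  tot <- acceptor_intensity + gamma * donor_intensity
  if (any(tot <= 0)) stop("total intensity must be positive", call. = FALSE)
  acceptor_intensity / tot
}

#' Fit a Gaussian peak to a FRET-efficiency histogram
#'
#' Bins the efficiencies and least-squares fits `A * exp(-(x - mu)^2 /
#' (2 * width^2))` to the bin counts; returns the peak position with the
#' standard error of the fitted mean.
#'
#' @param efficiencies Numeric vector (>= 100 values).
#' @param n_bins Number of histogram bins.
#' @param n_components Number of Gaussian components (only 1 supported).
#' @return List with `mean`, `se_mean`, `width`, `fit`.
#' @export
fit_fret_histogram <- function(efficiencies, n_bins = 40L, n_components = 1L) {
  if (length(efficiencies) < 100L) {
    stop("need at least 100 efficiency values", call. = FALSE)
  }
  if (n_components != 1L) {
    stop("only single-component fits are implemented", call. = FALSE)
  }
  if (sd(efficiencies) < 1e-12) {
    stop("degenerate histogram: all efficiencies identical", call. = FALSE)
  }
  h <- hist(efficiencies, breaks = n_bins, plot = FALSE)
  d <- data.frame(x = h$mids, y = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * width^2)), data = d,
                      start = list(A = max(d$y), mu = mean(efficiencies),
                                   width = sd(efficiencies)),
                      lower = c(A = 0, mu = -Inf, width = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("histogram fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  list(mean = unname(cf["mu"]), se_mean = unname(se["mu"]),
       width = abs(unname(cf["width"])), fit = fit)
}

#' Simulate nucleosome stretching traces
#'
#' Generates FRET-versus-force stretch traces of the three unwrapping
#' classes: `high_force_drop` traces hold high FRET until a sigmoidal drop
#' centred at `drop_force_high`; `gradual_then_drop` traces add a linear
#' FRET decline before that final drop; `low_force_drop` traces drop
#' already at `drop_force_low`. Gaussian noise is added per point.
#'
#' @param n_traces Number of traces.
#' @param class_mix Proportions over
#'   `c(high_force_drop, gradual_then_drop, low_force_drop)`; must sum
#'   to 1.
#' @param drop_force_low,drop_force_high Drop centres in pN (defaults 5
#'   and 15).
#' @param noise_sd Per-point Gaussian noise s.d. (default 0.05).
#' @param force_grid Stretch-segment force grid in pN, non-decreasing,
#'   within the instrument range 0.4-30 pN.
#' @param fret_high,fret_low Plateau FRET levels.
#' @param gradual_slope Linear decline rate (FRET per pN) of the
#'   `gradual_then_drop` class.
#' @param drop_width Sigmoid width in pN.
#' @param dwell_ms Dwell time per point in ms (metadata; default 20).
#' @param seed RNG seed.
#' @return List of `stretch_trace` objects: data.frames with columns
#'   `force_pN`, `fret`, plus attributes `class`, `molecule_id`,
#'   `dwell_ms`.
#' @export
simulate_stretch_traces <- function(n_traces,
                                    class_mix = c(1 / 3, 1 / 3, 1 / 3),
                                    drop_force_low = 5, drop_force_high = 15,
                                    noise_sd = 0.05,
                                    force_grid = seq(0.4, 20, by = 0.2),
                                    fret_high = 0.8, fret_low = 0.1,
                                    gradual_slope = 0.02, drop_width = 0.4,
                                    dwell_ms = 20, seed = NULL) {
  class_mix <- as.numeric(class_mix)
  if (length(class_mix) != 3L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (any(force_grid < 0.4 - 1e-9) || any(force_grid > 30 + 1e-9)) {
    stop("force_grid must lie within the instrument range 0.4-30 pN",
         call. = FALSE)
  }
  if (any(diff(force_grid) < 0)) {
    stop("force_grid must be non-decreasing (stretch segment)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_per <- drop(stats::rmultinom(1, n_traces, class_mix))
  classes <- rep(TRACE_CLASSES, n_per)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    cl <- classes[i]
    # pre-drop plateau (optionally declining) blended into the final drop
    plateau <- switch(cl,
      high_force_drop = rep(fret_high, length(force_grid)),
      gradual_then_drop = fret_high -
        gradual_slope * pmin(force_grid, drop_force_high),
      low_force_drop = rep(fret_high, length(force_grid)))
    centre <- if (cl == "low_force_drop") drop_force_low else drop_force_high
    base <- fret_low + (plateau - fret_low) /
      (1 + exp((force_grid - centre) / drop_width))
    fret <- base + rnorm(length(force_grid), 0, noise_sd)
    tr <- data.frame(force_pN = force_grid, fret = fret)
    attr(tr, "class_label") <- cl
    attr(tr, "molecule_id") <- i
    attr(tr, "dwell_ms") <- dwell_ms
    class(tr) <- c("stretch_trace", class(tr))
    traces[[i]] <- tr
  }
  traces
}

#' Classify a stretching trace
#'
#' Locates the largest windowed FRET decrease along the force axis (change
#' point by maximum drop over a sliding force window). If the drop force is
#' below `force_boundary` the trace is `low_force_drop`; otherwise the
#' pre-drop segment's fitted slope decides between `gradual_then_drop`
#' (slope below `-gradual_slope_threshold`) and `high_force_drop`.
#' Classification is differential, hence invariant to adding a constant to
#' all FRET values.
#'
#' @param trace A `stretch_trace` (data.frame with `force_pN`, `fret`).
#' @param force_boundary Boundary between low- and high-force drop regimes
#'   in pN; default 8, midway between the ~5 and ~15 pN landmarks.
#' @param gradual_slope_threshold Minimum pre-drop decline (FRET per pN) to
#'   call the gradual class; default 0.01.
#' @param window Sliding window half-width in pN.
#' @param min_drop Smallest windowed decrease accepted as a drop; traces
#'   with no such decrease raise an unclassifiable error.
#' @return One of `"high_force_drop"`, `"gradual_then_drop"`,
#'   `"low_force_drop"`.
#' @export
classify_trace <- function(trace, force_boundary = 8,
                           gradual_slope_threshold = 0.01,
                           window = 1.5, min_drop = 0.2) {
  d <- as.data.frame(trace)[, c("force_pN", "fret")]
  if (nrow(d) < 10L) stop("need at least 10 points", call. = FALSE)
  if (min(d$force_pN) > force_boundary || max(d$force_pN) < force_boundary) {
    stop("force range must span the low/high boundary of ", force_boundary,
         " pN", call. = FALSE)
  }
  f <- d$force_pN
  centres <- f[f >= min(f) + window & f <= max(f) - window]
  if (length(centres) < 3L) stop("force grid too narrow for the window",
                                 call. = FALSE)
  drop_at <- vapply(centres, function(fc) {
    before <- d$fret[f >= fc - window & f < fc]
    after <- d$fret[f > fc & f <= fc + window]
    if (length(before) < 2L || length(after) < 2L) return(NA_real_)
    mean(before) - mean(after)
  }, numeric(1))
  if (all(is.na(drop_at)) || max(drop_at, na.rm = TRUE) < min_drop) {
    stop("no detectable FRET drop: trace is unclassifiable", call. = FALSE)
  }
  drop_force <- centres[which.max(drop_at)]
  if (drop_force < force_boundary) return("low_force_drop")
  pre <- d[f <= drop_force - window, ]
  if (nrow(pre) >= 5L) {
    slope <- unname(coef(lm(fret ~ force_pN, data = pre))["force_pN"])
    if (slope < -gradual_slope_threshold) return("gradual_then_drop")
  }
  "high_force_drop"
}

#' Average stretching traces over force bins
#'
#' Per force bin, each trace contributes its in-bin mean once; the result
#' is the across-trace mean with its standard error. Bins covered by fewer
#' than two traces are flagged (`ok = FALSE`), never silently dropped.
#'
#' @param traces List of `stretch_trace`s.
#' @param force_bins Bin edges in pN.
#' @return data.frame with `force_mid`, `mean_fret`, `se_fret`, `n_traces`,
#'   `ok`.
#' @export
average_traces <- function(traces, force_bins = seq(0, 20, by = 1)) {
  if (length(traces) < 2L) stop("need at least 2 traces", call. = FALSE)
  k <- length(force_bins) - 1L
  mids <- (force_bins[-1L] + force_bins[-(k + 1L)]) / 2
  per_trace <- vapply(traces, function(tr) {
    d <- as.data.frame(tr)
    idx <- findInterval(d$force_pN, force_bins, rightmost.closed = TRUE)
    out <- rep(NA_real_, k)
    for (b in unique(idx[idx >= 1L & idx <= k])) {
      out[b] <- mean(d$fret[idx == b])
    }
    out
  }, numeric(k))
  per_trace <- matrix(per_trace, nrow = k)
  n <- rowSums(!is.na(per_trace))
  m <- rowMeans(per_trace, na.rm = TRUE)
  s <- apply(per_trace, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2L) sd(x) / sqrt(length(x)) else NA_real_
  })
  data.frame(force_mid = mids, mean_fret = ifelse(n > 0, m, NA_real_),
             se_fret = s, n_traces = n, ok = n >= 2L)
}

# round half away from zero (display convention for percentages)
round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Class percentages of counted traces
#'
#' `100 * count / total`, rounded half away from zero to `digits` decimals
#' (default one; `digits = 0` reproduces whole-percent reporting).
#'
#' @param counts Named non-negative integer vector of per-class counts.
#' @param digits Decimals to report.
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' class_percentages(c(high_force_drop = 13, gradual_then_drop = 13,
#'                     low_force_drop = 7))
class_percentages <- function(counts, digits = 1L) {
  counts <- unlist(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  round_half_away(100 * counts / total, digits)
}

#' Write / read stretch-trace TSV
#'
#' Long format with columns `molecule_id`, `force_pN`, `fret`.
#'
#' @param traces List of `stretch_trace`s.
#' @param path File path.
#' @export
write_traces_tsv <- function(traces, path) {
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(molecule_id = attr(tr, "molecule_id"),
               force_pN = tr$force_pN, fret = tr$fret)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_tsv
#' @export
read_traces_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("molecule_id", "force_pN", "fret")
  if (!all(need %in% names(d))) {
    stop("trace TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(d, d$molecule_id), function(g) {
    tr <- data.frame(force_pN = g$force_pN, fret = g$fret)
    attr(tr, "molecule_id") <- g$molecule_id[1]
    class(tr) <- c("stretch_trace", class(tr))
    tr
  })
}
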