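# Fluctuation statistics: per-position Gaussian summaries with
# block-averaged standard errors, change-in-mean / change-in-s.d. profiles
# versus distance from the CpG-step centre, window averages and condition
# ranking.
#
# "Gaussian fit" is implemented as the sample moments of the full series
# (the maximum-likelihood Gaussian fit); standard errors treat fixed-length
# block averages as independent measurements. No multiplicity correction is
# applied anywhere: the profiles are descriptive, not hypothesis tests.

#' Gaussian summary of a parameter time series with block-averaged errors
#'
#' Mean and s.d. are the sample moments of the full series. Standard errors
#' treat one `block_length` block as an independent measurement: the series
#' is cut into `M` complete blocks (incomplete trailing block discarded),
#' `se_mean` is the s.d. of the block means over `sqrt(M)` and `se_sd` the
#' s.d. of the block s.d.'s over `sqrt(M)`.
#'
#' @param series Numeric vector (one frame per entry).
#' @param frame_interval Frame spacing in ps.
#' @param block_length Block length in ns; default 20.
#' @return Object of class `gaussian_summary`: list with `mean`, `sd`, `n`,
#'   `se_mean`, `se_sd`, `n_blocks`.
#' @export
#' @examples
#' gaussian_summary(rnorm(5000, 0, 5), frame_interval = 4.8, block_length = 2.4)
gaussian_summary <- function(series, frame_interval = 4.8, block_length = 20) {
  series <- as.numeric(series)
  if (any(!is.finite(series))) stop("series must be finite", call. = FALSE)
  if (frame_interval <= 0 || block_length <= 0) {
    stop("frame_interval and block_length must be positive", call. = FALSE)
  }
  fpb <- floor(block_length * 1000 / frame_interval)
  if (fpb < 1L) stop("block shorter than one frame", call. = FALSE)
  M <- floor(length(series) / fpb)
  if (M < 2L) {
    stop("series of ", length(series), " frames holds fewer than 2 complete ",
         block_length, "-ns blocks; shorten block_length or extend the series",
         call. = FALSE)
  }
  used <- series[seq_len(M * fpb)]
  blocks <- matrix(used, fpb, M)
  bm <- colMeans(blocks)
  bs <- apply(blocks, 2, sd)
  structure(list(mean = mean(series), sd = sd(series), n = length(series),
                 se_mean = sd(bm) / sqrt(M), se_sd = sd(bs) / sqrt(M),
                 n_blocks = M),
            class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf("gaussian_summary: mean %.4g +/- %.2g, sd %.4g +/- %.2g (n = %d, %d blocks)\n",
              x$mean, x$se_mean, x$sd, x$se_sd, x$n, x$n_blocks))
  invisible(x)
}

#' Per-position Gaussian summaries of an ensemble
#'
#' @param ensemble A `parameter_ensemble`.
#' @param block_length Block length in ns.
#' @param parameters Parameters to summarize (default: all present).
#' @return data.frame with one row per (parameter, position): `mean`, `sd`,
#'   `se_mean`, `se_sd`, `n`, `n_blocks`.
#' @export
ensemble_summary <- function(ensemble, block_length = 20,
                             parameters = names(ensemble$values)) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  rows <- list()
  for (p in parameters) {
    v <- ensemble$values[[p]]
    for (j in seq_len(ncol(v))) {
      g <- gaussian_summary(v[, j], ensemble$frame_interval, block_length)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, position = as.integer(colnames(v)[j]),
        mean = g$mean, sd = g$sd, se_mean = g$se_mean, se_sd = g$se_sd,
        n = g$n, n_blocks = g$n_blocks)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard error of a difference
#'
#' Conventional error propagation for a difference of two independent
#' estimates: `sqrt(se_a^2 + se_b^2)`. Vectorized.
#'
#' @param se_a,se_b Non-negative standard errors.
#' @return Propagated standard error(s).
#' @export
#' @examples
#' propagate_difference_se(3, 4)  # 5
propagate_difference_se <- function(se_a, se_b) {
  if (any(se_a < 0) || any(se_b < 0)) {
    stop("standard errors must be >= 0", call. = FALSE)
  }
  sqrt(se_a^2 + se_b^2)
}

.profile_positions <- function(step, d, is_step_param, L) {
  if (is_step_param) {
    step + d
  } else {
    # bp positions whose truncated half-integer offset equals d
    if (d == 0L) c(step, step + 1L) else if (d > 0L) step + 1L + d
    else step + d
  }
}

#' Change-in-mean and change-in-s.d. profile around CpG steps
#'
#' For each distance `d` in `-max_d .. max_d` bp from the CpG-step centre,
#' the difference (modified minus unmodified) of the per-position mean and
#' s.d., averaged over all supplied CpG steps. Distances are measured from
#' the step centre (midpoint between the step's two base pairs): step
#' parameters use integer offsets from the central step, base-pair
#' parameters map their half-integer offsets to integer bins by truncation
#' toward zero, so the two central pairs are pooled in the d = 0 bin.
#' Standard errors are propagated per pair and averaged with the same
#' pooling.
#'
#' @param modified,unmodified `parameter_ensemble`s with the same frame
#'   interval, covering every position within `max_d` bp of each step.
#' @param parameter_name One of the 12 canonical parameter names.
#' @param cpg_steps Top-strand start positions of the CpG steps to pool.
#' @param block_length Block length in ns for the standard errors.
#' @param max_d Profile half-width in bp (default 3).
#' @return data.frame of class `delta_profile`: `parameter`, `distance`,
#'   `dmean`, `se_dmean`, `dsd`, `se_dsd`, `n_pooled`.
#' @export
delta_profile <- function(modified, unmodified, parameter_name, cpg_steps,
                          block_length = 20, max_d = 3L) {
  stopifnot(inherits(modified, "parameter_ensemble"),
            inherits(unmodified, "parameter_ensemble"))
  if (!identical(modified$frame_interval, unmodified$frame_interval)) {
    stop("ensembles must share frame_interval", call. = FALSE)
  }
  if (!parameter_name %in% names(modified$values) ||
      !parameter_name %in% names(unmodified$values)) {
    stop("parameter ", parameter_name, " missing from an ensemble",
         call. = FALSE)
  }
  is_step <- parameter_name %in% STEP_PARAMS
  L <- modified$duplex_length
  vm <- modified$values[[parameter_name]]
  vu <- unmodified$values[[parameter_name]]
  cpg_steps <- as.integer(cpg_steps)
  # precondition: full coverage of every step's +/- max_d neighbourhood
  want <- unique(unlist(lapply(cpg_steps, function(s)
    unlist(lapply(seq(-max_d, max_d), function(d)
      .profile_positions(s, d, is_step, L))))))
  have <- intersect(as.integer(colnames(vm)), as.integer(colnames(vu)))
  miss <- setdiff(want, have)
  if (length(miss)) {
    stop("ensembles do not cover position(s) ",
         paste(sort(miss), collapse = ", "), " for parameter ",
         parameter_name, call. = FALSE)
  }
  sum_cache_m <- new.env(parent = emptyenv())
  sum_cache_u <- new.env(parent = emptyenv())
  get_sum <- function(v, pos, cache, fi) {
    k <- as.character(pos)
    if (is.null(cache[[k]])) {
      cache[[k]] <- gaussian_summary(v[, k], fi, block_length)
    }
    cache[[k]]
  }
  rows <- list()
  for (d in seq(-max_d, max_d)) {
    dm <- c(); sm <- c(); ds <- c(); ss <- c()
    for (s in cpg_steps) {
      for (pos in .profile_positions(s, d, is_step, L)) {
        gm <- get_sum(vm, pos, sum_cache_m, modified$frame_interval)
        gu <- get_sum(vu, pos, sum_cache_u, unmodified$frame_interval)
        dm <- c(dm, gm$mean - gu$mean)
        sm <- c(sm, propagate_difference_se(gm$se_mean, gu$se_mean))
        ds <- c(ds, gm$sd - gu$sd)
        ss <- c(ss, propagate_difference_se(gm$se_sd, gu$se_sd))
      }
    }
    n <- length(dm)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = parameter_name, distance = d,
      dmean = mean(dm), se_dmean = sqrt(sum(sm^2)) / n,
      dsd = mean(ds), se_dsd = sqrt(sum(ss^2)) / n,
      n_pooled = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("delta_profile", class(out))
  out
}

#' Window-averaged change in s.d.
#'
#' Mean of the `dsd` profile over a window of `2 * half_width + 1` bins
#' centred at the CpG step (default 3 bp), with propagated standard error.
#'
#' @param profile A [delta_profile()].
#' @param half_width Window half-width in bp (default 1, i.e. 3 bp).
#' @return List with `estimate` and `se`.
#' @export
window_average_delta_sd <- function(profile, half_width = 1L) {
  stopifnot(inherits(profile, "delta_profile"))
  w <- profile[abs(profile$distance) <= half_width, ]
  if (nrow(w) != 2L * half_width + 1L) {
    stop("profile does not cover the +/-", half_width, " bp window",
         call. = FALSE)
  }
  list(estimate = mean(w$dsd), se = sqrt(sum(w$se_dsd^2)) / nrow(w))
}

#' Rank conditions by a scalar estimate with tie notation
#'
#' Conditions are ordered by descending point estimate; an adjacent pair
#' whose difference is below `tie_threshold` times the propagated standard
#' error of the difference is rendered with a greater-or-similar sign
#' (`≳`), otherwise with `>`. The result is invariant to the order in
#' which conditions are supplied.
#'
#' @param estimates Named numeric vector (one per condition).
#' @param ses Standard errors, same names/order.
#' @param tie_threshold Multiple of the propagated SE below which adjacent
#'   conditions are treated as similar; default 1.
#' @return List with `order` (condition names, descending), `string`
#'   (e.g. `"5-fC>5-hmC≳5-caC"`) and `comparisons` (data.frame of the
#'   adjacent differences).
#' @export
rank_modifications <- function(estimates, ses, tie_threshold = 1) {
  if (length(estimates) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (any(!is.finite(estimates)) || any(!is.finite(ses))) {
    stop("estimates and ses must be finite", call. = FALSE)
  }
  if (is.null(names(estimates))) stop("estimates must be named", call. = FALSE)
  ses <- ses[names(estimates)]
  ord <- order(estimates, decreasing = TRUE)
  est <- estimates[ord]
  se <- ses[ord]
  k <- length(est)
  sep <- character(k - 1L)
  comp <- data.frame(higher = names(est)[-k], lower = names(est)[-1L],
                     difference = est[-k] - est[-1L],
                     se_difference = propagate_difference_se(se[-k], se[-1L]))
  for (i in seq_len(k - 1L)) {
    tied <- comp$difference[i] < tie_threshold * comp$se_difference[i]
    sep[i] <- if (tied) "≳" else ">"
  }
  s <- names(est)[1]
  for (i in seq_len(k - 1L)) s <- paste0(s, sep[i], names(est)[i + 1L])
  rownames(comp) <- NULL
  list(order = names(est), string = s, comparisons = comp)
}
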