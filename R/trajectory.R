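# Synthetic conformational ensembles: Gaussian fluctuations of the twelve
# base-pair parameters around B-DNA means, with modification-dependent shifts
# of mean and s.d. localized at CpG steps and decaying over neighbouring
# base pairs, plus realization of an ensemble as 3-D coordinates and the
# inverse extraction from coordinates.

#' Baseline B-DNA parameter moments
#'
#' Default per-parameter (mean, sd) for unmodified B-DNA: twist 36 deg, rise
#' 3.38 A, all other means zero; s.d.'s of 4.5-5 deg for angles and
#' 0.25-0.5 A for translations, typical of room-temperature B-DNA ensembles.
#' These are generator calibration constants, not measured values.
#'
#' @return data.frame with columns `parameter`, `mean`, `sd`.
#' @export
default_baseline <- function() {
  data.frame(
    parameter = ALL_PARAMS,
    mean = c(0, 0, 3.38, 0, 0, 36, 0, 0, 0, 0, 0, 0),
    sd = c(0.5, 0.5, 0.3, 4.5, 4.5, 4.5, 0.25, 0.25, 0.4, 5, 5, 5)
  )
}

#' Default modification effects at CpG steps
#'
#' Synthetic calibration of the per-modification shifts of parameter mean
#' and s.d. at the centre of a CpG step. The roll mean shifts are +5, +2,
#' -1 and +1 deg for 5fC, 5hmC, 5caC and 5mC; the s.d. shifts follow the
#' ordering 5fC > 5hmC > 5caC > unmodified > 5mC for all parameters except
#' tilt and shift, whose fluctuations are slightly damped by every
#' modification (unmodified largest). Magnitudes other than the roll mean
#' shifts are generator calibration, chosen once to give that ordering at a
#' realistic fraction of the baseline s.d.
#'
#' @return data.frame with columns `condition`, `parameter`, `dmean`, `dsd`.
#' @export
default_modification_effects <- function() {
  sd_scale <- c(`5fC` = 1.0, `5hmC` = 0.4, `5caC` = 0.25, `5mC` = -0.6)
  angle_up <- c("roll", "twist", "buckle", "propeller", "opening")
  trans_up <- c("slide", "rise", "shear", "stretch", "stagger")
  rows <- list()
  for (m in names(sd_scale)) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = m, parameter = angle_up, dmean = 0, dsd = sd_scale[[m]])
    rows[[length(rows) + 1L]] <- data.frame(
      condition = m, parameter = trans_up, dmean = 0,
      dsd = 0.08 * sd_scale[[m]])
    rows[[length(rows) + 1L]] <- data.frame(
      condition = m, parameter = c("tilt", "shift"), dmean = 0,
      dsd = c(-0.2, -0.02))
  }
  eff <- do.call(rbind, rows)
  roll_mean <- c(`5fC` = 5, `5hmC` = 2, `5caC` = -1, `5mC` = 1)
  for (m in names(roll_mean)) {
    eff$dmean[eff$condition == m & eff$parameter == "roll"] <- roll_mean[[m]]
  }
  rownames(eff) <- NULL
  eff
}

#' Specification of a synthetic conformational ensemble
#'
#' @param duplex A [modified_duplex()]; its annotations determine where
#'   modification effects apply (see [modification_effect_centers()]).
#' @param n_frames Number of frames; default 52083, i.e. 250 ns recorded
#'   every 4.8 ps.
#' @param frame_interval Time between frames in ps.
#' @param baseline Per-parameter (mean, sd) defaults, see
#'   [default_baseline()].
#' @param effects Per-condition, per-parameter (dmean, dsd) at the CpG step
#'   centre, see [default_modification_effects()].
#' @param neighbour_kernel Weights at distance `|d| = 0, 1, 2, ...` bp from
#'   the CpG-step centre; weight 1 at d = 0, values in `[0, 1]`, zero beyond
#'   the vector. Default linear decay to 0 at `|d| = 3`.
#' @param parameters Subset of parameter names to generate (default all 12).
#' @param ar1_tau Optional correlation time in ps; when set, each series is
#'   AR(1) with that correlation time instead of i.i.d. (used to exercise
#'   block averaging).
#' @param sd_floor Smallest admissible s.d. after applying effects.
#' @param seed RNG seed for reproducible generation.
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(duplex, n_frames = 52083L, frame_interval = 4.8,
                          baseline = default_baseline(),
                          effects = default_modification_effects(),
                          neighbour_kernel = c(1, 2 / 3, 1 / 3, 0),
                          parameters = ALL_PARAMS,
                          ar1_tau = NULL, sd_floor = 1e-6, seed = NULL) {
  stopifnot(inherits(duplex, "modified_duplex"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be positive", call. = FALSE)
  if (any(baseline$sd < 0)) stop("baseline sds must be >= 0", call. = FALSE)
  if (!all(ALL_PARAMS %in% baseline$parameter)) {
    stop("baseline must cover all 12 parameters", call. = FALSE)
  }
  k <- as.numeric(neighbour_kernel)
  if (length(k) < 1L || abs(k[1] - 1) > 1e-12 || any(k < 0 | k > 1)) {
    stop("neighbour_kernel weights must lie in [0, 1] with weight 1 at d = 0",
         call. = FALSE)
  }
  parameters <- match.arg(parameters, ALL_PARAMS, several.ok = TRUE)
  structure(list(duplex = duplex, n_frames = n_frames,
                 frame_interval = frame_interval, baseline = baseline,
                 effects = effects, neighbour_kernel = k,
                 parameters = parameters, ar1_tau = ar1_tau,
                 sd_floor = sd_floor, seed = seed),
            class = "ensemble_spec")
}

#' Effect centres of a modified duplex
#'
#' Maps the duplex's annotations to the CpG steps (top-strand start
#' positions) at which modification effects are centred. Annotations on
#' either strand of the same CpG step collapse to one centre; a fully
#' modified step therefore contributes a single effect.
#'
#' @param duplex A [modified_duplex()].
#' @return data.frame with columns `step` (top-strand start position) and
#'   `condition` (mod type).
#' @export
modification_effect_centers <- function(duplex) {
  stopifnot(inherits(duplex, "modified_duplex"))
  ann <- duplex$annotations
  if (nrow(ann) == 0L) {
    return(data.frame(step = integer(0), condition = character(0)))
  }
  L <- duplex$length
  top_pos <- ifelse(ann$strand == "top", ann$position, L - ann$position + 1L)
  step <- integer(nrow(ann))
  for (i in seq_along(top_pos)) {
    q <- top_pos[i]
    if (q < L && substr(duplex$top, q, q) == "C" &&
        substr(duplex$top, q + 1L, q + 1L) == "G") {
      step[i] <- q
    } else if (q > 1L && substr(duplex$top, q, q) == "G" &&
               substr(duplex$top, q - 1L, q - 1L) == "C") {
      step[i] <- q - 1L
    } else {
      stop("annotation at top-strand position ", q,
           " is not part of a CpG step", call. = FALSE)
    }
  }
  out <- unique(data.frame(step = step, condition = ann$mod_type))
  out[order(out$step), , drop = FALSE]
}

# distance (in integer bins) of a parameter position from a CpG step centre;
# the step centre sits between bp p and p + 1, so base-pair positions map to
# half-integer offsets which are rounded toward zero (the two central pairs
# share the d = 0 bin), while inter-bp steps use integer offsets directly.
.cpg_distance <- function(position, step, is_step_param) {
  if (is_step_param) position - step else trunc(position - step - 0.5)
}

#' Generative per-position moments of an ensemble spec
#'
#' The mean and s.d. surface the generator samples from: for each parameter
#' and position, mean = baseline mean + sum over CpG centres of
#' kernel(d) * dmean, and likewise for the s.d. (floored at `sd_floor`).
#'
#' @param spec An [ensemble_spec()].
#' @return List with elements `mean` and `sd`, each a named list of numeric
#'   vectors (one per parameter; step parameters have `L - 1` entries,
#'   intra-base-pair parameters `L`).
#' @export
ensemble_moments <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  L <- spec$duplex$length
  centers <- modification_effect_centers(spec$duplex)
  k <- spec$neighbour_kernel
  kmax <- length(k) - 1L
  mu <- list()
  sg <- list()
  floored <- FALSE
  for (par in spec$parameters) {
    is_step <- par %in% STEP_PARAMS
    npos <- if (is_step) L - 1L else L
    b <- spec$baseline[spec$baseline$parameter == par, ]
    m <- rep(b$mean, npos)
    s <- rep(b$sd, npos)
    if (nrow(centers)) {
      for (i in seq_len(nrow(centers))) {
        e <- spec$effects[spec$effects$condition == centers$condition[i] &
                            spec$effects$parameter == par, ]
        if (nrow(e) == 0L) next
        d <- .cpg_distance(seq_len(npos), centers$step[i], is_step)
        w <- ifelse(abs(d) > kmax, 0, k[pmin(abs(d), kmax) + 1L])
        m <- m + w * sum(e$dmean)
        s <- s + w * sum(e$dsd)
      }
    }
    if (any(s < spec$sd_floor)) floored <- TRUE
    s <- pmax(s, spec$sd_floor)
    mu[[par]] <- m
    sg[[par]] <- s
  }
  if (floored) {
    warning("some effect-adjusted s.d. values fell below the floor of ",
            spec$sd_floor, " and were clipped", call. = FALSE)
  }
  list(mean = mu, sd = sg)
}

new_parameter_ensemble <- function(values, frame_interval, condition,
                                   duplex_length, seed = NULL,
                                   generative = NULL) {
  structure(list(values = values, frame_interval = frame_interval,
                 condition = condition, duplex_length = duplex_length,
                 seed = seed, generative = generative),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  nf <- nrow(x$values[[1]])
  cat("parameter_ensemble: condition '", x$condition, "', ", nf,
      " frames x ", x$duplex_length, " bp, ", length(x$values),
      " parameters, frame interval ", x$frame_interval, " ps\n", sep = "")
  invisible(x)
}

#' Generate a synthetic parameter ensemble
#'
#' Each (position, parameter) series is sampled i.i.d. Gaussian (or AR(1)
#' when `ar1_tau` is set) from the moments of [ensemble_moments()].
#' Reproducible under a fixed `seed`. Sampling is written as
#' `mean + sd * eps` with a condition-independent noise stream, so two specs
#' generated with the same seed share their noise and differ exactly where
#' their moments differ.
#'
#' @param spec An [ensemble_spec()].
#' @param condition Condition label stored in the ensemble; default derived
#'   from the duplex annotations.
#' @return A `parameter_ensemble`: named list of `n_frames x positions`
#'   matrices, one per parameter, plus metadata (and the generative moments
#'   as the `generative` element).
#' @export
generate_parameter_ensemble <- function(spec, condition = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  mom <- ensemble_moments(spec)
  if (is.null(condition)) {
    mods <- unique(spec$duplex$annotations$mod_type)
    condition <- if (length(mods) == 0L) "unmodified"
                 else paste(mods, collapse = "+")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  phi <- if (is.null(spec$ar1_tau)) 0 else
    exp(-spec$frame_interval / spec$ar1_tau)
  nf <- spec$n_frames
  values <- list()
  for (par in spec$parameters) {
    m <- mom$mean[[par]]
    s <- mom$sd[[par]]
    npos <- length(m)
    eps <- matrix(rnorm(nf * npos), nf, npos)
    if (phi > 0) {
      # stationary AR(1) with unit marginal variance
      eps[1, ] <- eps[1, ]
      w <- sqrt(1 - phi^2)
      for (t in 2:nf) eps[t, ] <- phi * eps[t - 1L, ] + w * eps[t, ]
    }
    x <- sweep(sweep(eps, 2, s, `*`), 2, m, `+`)
    colnames(x) <- as.character(seq_len(npos))
    values[[par]] <- x
  }
  new_parameter_ensemble(values, spec$frame_interval, condition,
                         spec$duplex$length, spec$seed, mom)
}

#' Generate the five-condition ensemble suite
#'
#' One ensemble per condition with identical baselines, differing only in
#' the modification effects placed at the duplex's CpG steps; emulates a set
#' of matched simulations of the same construct.
#'
#' @param duplex Unannotated [modified_duplex()] (the construct sequence).
#' @param conditions Condition labels, a subset of
#'   `c("unmodified", "5mC", "5hmC", "5fC", "5caC")`.
#' @param cpg_steps CpG steps to modify; default the interior CpG steps of
#'   the top strand.
#' @param seed Base seed; condition `i` uses `seed + i - 1` unless
#'   `paired_seeds` is set, in which case all conditions share `seed` (and
#'   hence the same noise stream).
#' @param paired_seeds Use one shared seed for every condition?
#' @param ... Passed to [ensemble_spec()] (`n_frames`, `baseline`, ...).
#' @return Named list of `parameter_ensemble` objects.
#' @export
condition_suite <- function(duplex, conditions = CONDITIONS,
                            cpg_steps = interior_cpg_steps(duplex$top),
                            seed = NULL, paired_seeds = FALSE, ...) {
  stopifnot(inherits(duplex, "modified_duplex"))
  if (any(!conditions %in% CONDITIONS)) {
    stop("unknown condition label(s): ",
         paste(setdiff(conditions, CONDITIONS), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    d <- if (cond == "unmodified") duplex
         else apply_modifications(duplex, cpg_steps, cond, both_strands = TRUE)
    s <- if (is.null(seed)) NULL else if (paired_seeds) seed else seed + i - 1L
    spec <- ensemble_spec(d, seed = s, ...)
    out[[cond]] <- generate_parameter_ensemble(spec, condition = cond)
  }
  out
}

# ---- coordinate realization and extraction --------------------------------

.base_atom_count <- function(b) nrow(standard_base_geometry(b))

.traj_atom_table <- function(duplex) {
  L <- duplex$length
  rows <- list()
  for (i in seq_len(L)) {
    bt <- substr(duplex$top, i, i)
    bb <- complement_base(bt)
    for (ch in c("A", "B")) {
      b <- if (ch == "A") bt else bb
      resno <- if (ch == "A") i else L - i + 1L
      nm <- rownames(standard_base_geometry(b))
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = resno, base = b, atom = nm)
    }
  }
  at <- do.call(rbind, rows)
  at$index <- seq_len(nrow(at))
  at
}

#' Realize a parameter ensemble as 3-D coordinates
#'
#' For every frame, base-pair frames are chained from the step parameters
#' (starting at the identity frame), split into the two base frames via the
#' intra-base-pair parameters, and the standard ring-atom geometry of each
#' base is placed through its frame. Writing, re-reading and re-extracting
#' recovers the generated parameter values.
#'
#' @param ensemble A `parameter_ensemble` covering all 12 parameters for
#'   every pair/step of the duplex.
#' @param duplex The [modified_duplex()] the ensemble describes.
#' @return Object of class `bp_trajectory`: list with `atoms` (atom table:
#'   chain, resno, base, atom) and `xyz` (array `frames x atoms x 3`, A).
#' @export
realize_coordinates <- function(ensemble, duplex) {
  stopifnot(inherits(ensemble, "parameter_ensemble"),
            inherits(duplex, "modified_duplex"))
  L <- duplex$length
  missing <- setdiff(ALL_PARAMS, names(ensemble$values))
  if (length(missing)) {
    stop("ensemble lacks parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (par in STEP_PARAMS) {
    if (ncol(ensemble$values[[par]]) != L - 1L) {
      stop("step parameter ", par, " does not cover all ", L - 1L, " steps",
           call. = FALSE)
    }
  }
  for (par in INTRA_PARAMS) {
    if (ncol(ensemble$values[[par]]) != L) {
      stop("intra parameter ", par, " does not cover all ", L, " base pairs",
           call. = FALSE)
    }
  }
  atoms <- .traj_atom_table(duplex)
  nf <- nrow(ensemble$values[[1]])
  natoms <- nrow(atoms)
  xyz <- array(NA_real_, c(nf, natoms, 3L))
  # per-bp standard geometries and atom index slices, precomputed
  std_top <- lapply(seq_len(L), function(i)
    standard_base_geometry(substr(duplex$top, i, i)))
  std_bot <- lapply(seq_len(L), function(i)
    standard_base_geometry(complement_base(substr(duplex$top, i, i))))
  idx_top <- lapply(seq_len(L), function(i)
    atoms$index[atoms$chain == "A" & atoms$resno == i])
  idx_bot <- lapply(seq_len(L), function(i)
    atoms$index[atoms$chain == "B" & atoms$resno == L - i + 1L])
  sv <- ensemble$values
  for (f in seq_len(nf)) {
    steps <- matrix(vapply(STEP_PARAMS, function(p) sv[[p]][f, ],
                           numeric(L - 1L)), L - 1L, 6L,
                    dimnames = list(NULL, STEP_PARAMS))
    R <- diag(3)
    o <- c(0, 0, 0)
    for (i in seq_len(L)) {
      intra <- vapply(INTRA_PARAMS, function(p) sv[[p]][f, i], numeric(1))
      sp <- .frames_from_mid(R, o, intra)
      # W base (top strand) is the "2" side, complementary base the flipped "1"
      xyz[f, idx_top[[i]], ] <- std_top[[i]] %*% t(sp$R2) +
        matrix(sp$o2, nrow(std_top[[i]]), 3, byrow = TRUE)
      Rc <- sp$R1 %*% .FLIP
      xyz[f, idx_bot[[i]], ] <- std_bot[[i]] %*% t(Rc) +
        matrix(sp$o1, nrow(std_bot[[i]]), 3, byrow = TRUE)
      if (i < L) {
        cs <- .compose_frames(R, o, steps[i, ])
        R <- cs$R2
        o <- cs$o2
      }
    }
  }
  structure(list(atoms = atoms[, c("chain", "resno", "base", "atom")],
                 xyz = xyz, frame_interval = ensemble$frame_interval,
                 condition = ensemble$condition),
            class = "bp_trajectory")
}

#' Extract base-pair parameters from a coordinate trajectory
#'
#' The inverse of [realize_coordinates()]: per frame, a reference frame is
#' fitted to the ring atoms of every base, complementary frames are paired
#' (chain A residue `i` with chain B residue `L - i + 1` by default) into
#' base-pair frames and intra-base-pair parameters, and step parameters are
#' taken between consecutive base-pair frames.
#'
#' @param traj A `bp_trajectory` (from [realize_coordinates()] or
#'   [read_trajectory_pdb()]).
#' @param frame_interval Frame spacing in ps recorded in the result.
#' @param condition Condition label for the result.
#' @return A `parameter_ensemble`.
#' @export
extract_parameters <- function(traj, frame_interval = traj$frame_interval,
                               condition = traj$condition) {
  stopifnot(inherits(traj, "bp_trajectory"))
  atoms <- traj$atoms
  L <- max(atoms$resno)
  nf <- dim(traj$xyz)[1]
  if (is.null(frame_interval)) frame_interval <- 4.8
  if (is.null(condition)) condition <- "unknown"
  # precompute per-base fitting inputs
  key <- paste(atoms$chain, atoms$resno)
  groups <- split(seq_len(nrow(atoms)), key)
  base_of <- vapply(groups, function(ix) atoms$base[ix[1]], character(1))
  values <- lapply(setNames(ALL_PARAMS, ALL_PARAMS), function(p) {
    npos <- if (p %in% STEP_PARAMS) L - 1L else L
    matrix(NA_real_, nf, npos, dimnames = list(NULL, seq_len(npos)))
  })
  for (f in seq_len(nf)) {
    fr <- list()
    for (g in names(groups)) {
      ix <- groups[[g]]
      obs <- traj$xyz[f, ix, , drop = TRUE]
      rownames(obs) <- atoms$atom[ix]
      fr[[g]] <- fit_base_frame(obs, base_of[[g]])
    }
    bpR <- vector("list", L)
    for (i in seq_len(L)) {
      w <- fr[[paste("A", i)]]
      cc <- fr[[paste("B", L - i + 1L)]]
      bp <- base_pair_frame(w, cc)
      bpR[[i]] <- bp$bp_frame
      for (p in INTRA_PARAMS) values[[p]][f, i] <- bp$params[[p]]
    }
    for (i in seq_len(L - 1L)) {
      st <- step_params(bpR[[i]], bpR[[i + 1L]])
      for (p in STEP_PARAMS) values[[p]][f, i] <- st[[p]]
    }
  }
  new_parameter_ensemble(values, frame_interval, condition, L)
}

# ---- trajectory I/O -------------------------------------------------------

.pdb_resid <- function(b) paste0("D", b)

#' Write a trajectory as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; residues named DA/DC/DG/DT, chains A
#' (top strand, 5'->3') and B (bottom strand, 5'->3'). Coordinates are
#' written at the format's 0.001 A precision. Header REMARKs record the
#' 1-based coordinate convention and condition label.
#'
#' @param traj A `bp_trajectory`.
#' @param path Output PDB file.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "bp_trajectory"))
  atoms <- traj$atoms
  nf <- dim(traj$xyz)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "REMARK   1 modflex synthetic base-pair trajectory (ring atoms only)",
    "REMARK   1 residue numbering 1-based along each strand 5'->3'",
    paste0("REMARK   1 condition ", traj$condition %||% "unknown")), con)
  elem <- substr(atoms$atom, 1, 1)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL %8d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(atoms)), atoms$atom, .pdb_resid(atoms$base), atoms$chain,
      atoms$resno, traj$xyz[f, , 1], traj$xyz[f, , 2], traj$xyz[f, , 3], elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multi-model PDB trajectory
#'
#' MODEL/ENDMDL records are frames. Reading goes through
#' [bio3d::read.pdb()].
#'
#' @param path PDB file.
#' @param frame_interval Frame spacing in ps to record.
#' @param condition Condition label to record.
#' @return A `bp_trajectory`.
#' @export
read_trajectory_pdb <- function(path, frame_interval = 4.8,
                                condition = "unknown") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      base = sub("^D", "", at$resid), atom = at$elety)
  xyzm <- pdb$xyz
  if (is.null(dim(xyzm))) xyzm <- matrix(xyzm, nrow = 1)
  nf <- nrow(xyzm)
  natoms <- nrow(atoms)
  xyz <- array(NA_real_, c(nf, natoms, 3L))
  xyz[, , 1] <- xyzm[, seq(1, 3 * natoms, 3), drop = FALSE]
  xyz[, , 2] <- xyzm[, seq(2, 3 * natoms, 3), drop = FALSE]
  xyz[, , 3] <- xyzm[, seq(3, 3 * natoms, 3), drop = FALSE]
  structure(list(atoms = atoms, xyz = xyz, frame_interval = frame_interval,
                 condition = condition),
            class = "bp_trajectory")
}

#' Write a parameter ensemble as long-format TSV
#'
#' Columns `frame_index`, `position`, `parameter_name`, `value`; a `#`
#' header comment records the condition, frame interval, seed and the
#' 1-based coordinate convention.
#'
#' @param ensemble A `parameter_ensemble`.
#' @param path Output TSV.
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  hdr <- c(
    "# modflex parameter ensemble (long format); positions 1-based",
    paste0("# condition=", ensemble$condition,
           " frame_interval_ps=", ensemble$frame_interval,
           " seed=", ensemble$seed %||% "NA"))
  writeLines(hdr, path)
  tabs <- lapply(names(ensemble$values), function(p) {
    v <- ensemble$values[[p]]
    data.table::data.table(
      frame_index = rep(seq_len(nrow(v)), ncol(v)),
      position = rep(as.integer(colnames(v)), each = nrow(v)),
      parameter_name = p,
      value = as.vector(v))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, sep = "\t",
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a long-format parameter ensemble TSV
#'
#' @param path TSV written by [write_ensemble_tsv()] (or equivalent long
#'   table with columns `frame_index`, `position`, `parameter_name`,
#'   `value`).
#' @param frame_interval,condition Metadata when absent from the header.
#' @return A `parameter_ensemble`.
#' @export
read_ensemble_tsv <- function(path, frame_interval = 4.8,
                              condition = "unknown") {
  hdr <- readLines(path, n = 5L)
  hdr <- hdr[startsWith(hdr, "#")]
  m <- regmatches(hdr, regexec("condition=(\\S+) frame_interval_ps=(\\S+)", hdr))
  for (mm in m) {
    if (length(mm) == 3L) {
      condition <- mm[2]
      frame_interval <- as.numeric(mm[3])
    }
  }
  dt <- data.table::fread(path, sep = "\t", skip = "frame_index")
  need <- c("frame_index", "position", "parameter_name", "value")
  if (!all(need %in% names(dt))) {
    stop("ensemble TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  values <- list()
  L <- NA_integer_
  for (p in unique(dt$parameter_name)) {
    sub <- dt[dt$parameter_name == p, ]
    nf <- max(sub$frame_index)
    npos <- max(sub$position)
    v <- matrix(NA_real_, nf, npos, dimnames = list(NULL, seq_len(npos)))
    v[cbind(sub$frame_index, sub$position)] <- sub$value
    values[[p]] <- v
    if (p %in% INTRA_PARAMS) L <- npos
  }
  if (is.na(L) && length(values)) L <- ncol(values[[1]]) + 1L
  new_parameter_ensemble(values, frame_interval, condition, L)
}
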