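# Rigid base-pair geometry: reference-frame fitting, the mid-frame (CEHS
# style) decomposition of the relative transform between frames into the six
# rigid-body parameters, and its exact inverse.
#
# Conventions: right-handed frames, z along the helix advance, negative roll
# opens towards the minor groove. For two frames (R1, o1) -> (R2, o2) the
# relative rotation is factored as
#
#   t(R1) %*% R2 = Rz(w/2 - phi) %*% Ry(Gamma) %*% Rz(w/2 + phi)
#
# with twist w about the mid-frame z axis and a bend Gamma about a hinge in
# the mid-frame xy plane at phase phi, giving roll = Gamma cos(phi) (about
# y) and tilt = Gamma sin(phi) (about x). Translations (shift, slide, rise)
# are o2 - o1 expressed in the mid frame. The mid frame has origin
# (o1 + o2) / 2 and orientation half way along the same factorization.
# Angles are degrees and distances Angstrom everywhere in the public API.

.deg <- 180 / pi

.rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

.rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

.is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Construct a reference frame
#'
#' A rigid-body frame: an origin (Angstrom) and a proper rotation matrix
#' whose columns are the frame's x, y, z unit vectors.
#'
#' @param origin Numeric 3-vector.
#' @param axes 3x3 rotation matrix, orthonormal within 1e-9, determinant +1.
#' @return Object of class `reference_frame` (list with `origin`, `axes`).
#' @export
#' @examples
#' reference_frame(c(0, 0, 0), diag(3))
reference_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop("origin must be a finite 3-vector", call. = FALSE)
  }
  if (!.is_rotation(axes)) {
    stop("axes must be a proper rotation matrix (orthonormal within 1e-9, ",
         "determinant +1)", call. = FALSE)
  }
  structure(list(origin = origin, axes = axes), class = "reference_frame")
}

.check_frame <- function(f, what = "frame") {
  if (!inherits(f, "reference_frame")) stop(what, " must be a reference_frame",
                                            call. = FALSE)
  if (!.is_rotation(f$axes)) stop(what, " axes are not orthonormal",
                                  call. = FALSE)
  f
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("reference_frame\n  origin:", format(x$origin, digits = 4), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

# Core decomposition between raw (R, o) pairs; angles returned in degrees.
# Returns the six parameters in (x, y, z, about-x, about-y, about-z) order
# plus the mid frame.
.decompose_frames <- function(R1, o1, R2, o2) {
  A <- crossprod(R1, R2)
  sb <- sqrt(A[1, 3]^2 + A[2, 3]^2)
  if (sb < 1e-12) {
    if (A[3, 3] < 0) {
      stop("degenerate step: 180 degree bend between frames", call. = FALSE)
    }
    Gam <- 0
    phi <- 0
    omega <- atan2(A[2, 1], A[1, 1])
  } else {
    beta <- atan2(sb, A[3, 3])
    alpha <- atan2(A[2, 3], A[1, 3])
    gam2 <- atan2(A[3, 2], -A[3, 1])
    omega <- alpha + gam2
    Gam <- beta
    phi <- (gam2 - alpha) / 2
    # keep twist in (-pi, pi]; the compensating sign flip of Gamma preserves
    # the factorization exactly
    if (omega > pi) {
      omega <- omega - 2 * pi
      Gam <- -Gam
    } else if (omega <= -pi) {
      omega <- omega + 2 * pi
      Gam <- -Gam
    }
  }
  Rm <- R1 %*% .rot_z(omega / 2 - phi) %*% .rot_y(Gam / 2) %*% .rot_z(phi)
  v <- drop(crossprod(Rm, o2 - o1))
  c(v,
    Gam * sin(phi) * .deg,   # about x (tilt slot)
    Gam * cos(phi) * .deg,   # about y (roll slot)
    omega * .deg) -> p
  list(params = p, mid_R = Rm, mid_o = (o1 + o2) / 2)
}

# Exact inverse of .decompose_frames: advance (R1, o1) by the six parameters
# (x, y, z, about-x deg, about-y deg, about-z deg).
.compose_frames <- function(R1, o1, p) {
  if (!all(is.finite(p))) stop("non-finite step parameters", call. = FALSE)
  ax <- p[4] / .deg
  ay <- p[5] / .deg
  omega <- p[6] / .deg
  Gam <- sqrt(ax^2 + ay^2)
  phi <- if (Gam == 0) 0 else atan2(ax, ay)
  Rm <- R1 %*% .rot_z(omega / 2 - phi) %*% .rot_y(Gam / 2) %*% .rot_z(phi)
  R2 <- R1 %*% .rot_z(omega / 2 - phi) %*% .rot_y(Gam) %*%
    .rot_z(omega / 2 + phi)
  o2 <- o1 + drop(Rm %*% p[1:3])
  list(R2 = R2, o2 = o2, mid_R = Rm, mid_o = (o1 + o2) / 2)
}

# Split a mid frame into its two flanking frames given the six parameters.
.frames_from_mid <- function(Rm, om, p) {
  ax <- p[4] / .deg
  ay <- p[5] / .deg
  omega <- p[6] / .deg
  Gam <- sqrt(ax^2 + ay^2)
  phi <- if (Gam == 0) 0 else atan2(ax, ay)
  H1 <- .rot_z(omega / 2 - phi) %*% .rot_y(Gam / 2) %*% .rot_z(phi)
  R1 <- Rm %*% t(H1)
  R2 <- R1 %*% .rot_z(omega / 2 - phi) %*% .rot_y(Gam) %*%
    .rot_z(omega / 2 + phi)
  tv <- drop(Rm %*% p[1:3])
  list(R1 = R1, o1 = om - tv / 2, R2 = R2, o2 = om + tv / 2)
}

.kabsch <- function(S, O) {
  # rotation R and translation t with O ~= S %*% t(R) + t (rowwise points)
  sc <- colMeans(S)
  oc <- colMeans(O)
  H <- crossprod(sweep(S, 2, sc), sweep(O, 2, oc))
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-30)) {
    stop("degenerate (collinear) atom set: frame is underdetermined",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = drop(oc - R %*% sc))
}

#' Fit a base reference frame to observed atoms
#'
#' Least-squares superposition of the standard ring-atom geometry of
#' `base_type` onto the observed coordinates; the returned frame is the
#' image of the standard reference frame under the fitted rigid transform.
#' Only ring atoms are matched, so exocyclic substituents (including the
#' 5-position modifications) never influence the fit.
#'
#' @param observed_atoms Numeric matrix (atoms x 3) with atom-name rownames.
#' @param base_type Base type, see [standard_base_geometry()].
#' @return A [reference_frame()].
#' @export
fit_base_frame <- function(observed_atoms, base_type) {
  std <- standard_base_geometry(base_type)
  if (is.null(rownames(observed_atoms))) {
    stop("observed_atoms must have atom-name rownames", call. = FALSE)
  }
  common <- intersect(rownames(std), rownames(observed_atoms))
  if (length(common) < 3L) {
    stop("need at least 3 matched ring atoms, got ", length(common),
         call. = FALSE)
  }
  fit <- .kabsch(std[common, , drop = FALSE],
                 observed_atoms[common, , drop = FALSE])
  reference_frame(fit$t, fit$R)
}

.FLIP <- diag(c(1, -1, -1))

#' Base-pair frame and intra-base-pair parameters
#'
#' The complementary-strand frame is flipped (y and z axes negated) to
#' co-align with the strand-W frame; the base-pair frame is the half-way
#' frame between the flipped complementary frame and the W frame, and the
#' six intra-base-pair parameters (shear, stretch, stagger in Angstrom;
#' buckle, propeller, opening in degrees) are the mid-frame decomposition of
#' the relative transform, taken from the flipped complementary frame to the
#' W frame.
#'
#' @param frame_W Frame of the Watson (top) strand base.
#' @param frame_C Frame of the complementary (anti-parallel) base.
#' @return List with `bp_frame` ([reference_frame()]) and `params` (named
#'   numeric vector of the six intra-base-pair parameters).
#' @export
base_pair_frame <- function(frame_W, frame_C) {
  frame_W <- .check_frame(frame_W, "frame_W")
  frame_C <- .check_frame(frame_C, "frame_C")
  Rc <- frame_C$axes %*% .FLIP
  dec <- .decompose_frames(Rc, frame_C$origin, frame_W$axes, frame_W$origin)
  list(bp_frame = reference_frame(dec$mid_o, dec$mid_R),
       params = setNames(dec$params, INTRA_PARAMS))
}

#' Rebuild the two base frames of a pair from its frame and parameters
#'
#' Exact inverse of [base_pair_frame()]: given a base-pair frame and the six
#' intra-base-pair parameters, returns the Watson and complementary base
#' frames (the complementary frame un-flipped to its own strand convention).
#'
#' @param bp_frame Base-pair [reference_frame()].
#' @param params Named vector of the six intra-base-pair parameters.
#' @return List with `frame_W` and `frame_C`.
#' @export
base_pair_from_frame <- function(bp_frame, params) {
  bp_frame <- .check_frame(bp_frame, "bp_frame")
  p <- as.numeric(params[INTRA_PARAMS])
  if (any(!is.finite(p))) stop("non-finite intra-base-pair parameters",
                               call. = FALSE)
  sp <- .frames_from_mid(bp_frame$axes, bp_frame$origin, p)
  list(frame_W = reference_frame(sp$o2, sp$R2),
       frame_C = reference_frame(sp$o1, sp$R1 %*% .FLIP))
}

#' Inter-base-pair (step) parameters between stacked base-pair frames
#'
#' Mid-step-frame decomposition of the transform from base-pair frame `i` to
#' its 3' neighbour `j`: twist about the mid-frame z axis, a bend angle
#' factored into (tilt, roll) hinge components, and (shift, slide, rise) as
#' the origin displacement in the mid-step frame.
#'
#' @param bp_frame_i Frame of base pair i.
#' @param bp_frame_j Frame of the 3' neighbouring base pair.
#' @return Named numeric vector `shift`, `slide`, `rise` (Angstrom),
#'   `tilt`, `roll`, `twist` (degrees).
#' @export
#' @examples
#' f <- reference_frame()
#' g <- rebuild_frames(f, matrix(c(0, 0, 3.4, 0, 0, 36), 1))[[2]]
#' step_params(f, g)
step_params <- function(bp_frame_i, bp_frame_j) {
  bp_frame_i <- .check_frame(bp_frame_i, "bp_frame_i")
  bp_frame_j <- .check_frame(bp_frame_j, "bp_frame_j")
  dec <- .decompose_frames(bp_frame_i$axes, bp_frame_i$origin,
                           bp_frame_j$axes, bp_frame_j$origin)
  setNames(dec$params, STEP_PARAMS)
}

#' Mid-step frame between two base-pair frames
#'
#' @inheritParams step_params
#' @return The mid-step [reference_frame()].
#' @export
mid_step_frame <- function(bp_frame_i, bp_frame_j) {
  bp_frame_i <- .check_frame(bp_frame_i, "bp_frame_i")
  bp_frame_j <- .check_frame(bp_frame_j, "bp_frame_j")
  dec <- .decompose_frames(bp_frame_i$axes, bp_frame_i$origin,
                           bp_frame_j$axes, bp_frame_j$origin)
  reference_frame(dec$mid_o, dec$mid_R)
}

#' Rebuild a chain of frames from step parameters
#'
#' Exact inverse of [step_params()]: starting from `start`, each row of
#' `steps` advances the chain by one step, so
#' `step_params(frames[[k]], frames[[k + 1]])` reproduces `steps[k, ]`.
#'
#' @param start Starting [reference_frame()].
#' @param steps Matrix or data.frame with columns `shift`, `slide`, `rise`,
#'   `tilt`, `roll`, `twist` (unnamed input is taken in that order).
#' @return List of `nrow(steps) + 1` frames.
#' @export
rebuild_frames <- function(start, steps) {
  start <- .check_frame(start, "start")
  steps <- as.matrix(steps)
  if (ncol(steps) != 6L) stop("steps must have 6 columns", call. = FALSE)
  if (!is.null(colnames(steps))) {
    if (!all(STEP_PARAMS %in% colnames(steps))) {
      stop("steps columns must be named ", paste(STEP_PARAMS, collapse = ", "),
           call. = FALSE)
    }
    steps <- steps[, STEP_PARAMS, drop = FALSE]
  }
  if (any(!is.finite(steps))) stop("non-finite step parameters", call. = FALSE)
  n <- nrow(steps)
  out <- vector("list", n + 1L)
  out[[1L]] <- start
  R <- start$axes
  o <- start$origin
  for (k in seq_len(n)) {
    cs <- .compose_frames(R, o, steps[k, ])
    R <- cs$R2
    o <- cs$o2
    out[[k + 1L]] <- reference_frame(o, R)
  }
  out
}
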