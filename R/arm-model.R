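#' Seven-degree-of-freedom kinematic arm model
#'
#' Constructs the geometric model of a right arm used throughout the package:
#' a 3-DOF shoulder (abduction, flexion, rotation), a 2-DOF elbow (flexion,
#' pronation) and a 2-DOF wrist (flexion, abduction), with the endpoint at the
#' fingertip of the middle finger.
#'
#' The frame convention is right-handed with x forward, y left, z up, shoulder
#' at `shoulder_origin`. The zero pose is the arm extended along +x with the
#' palm facing down (palm normal -z). The shoulder composes flexion (about
#' +y, positive lowering the extended arm), then abduction (about the rotated
#' z axis), then internal rotation about the humerus axis; flexion leads so
#' that the decomposition stays regular with the upper arm pointing down, the
#' dominant direction in desk-height reaching. Internal rotation and elbow
#' pronation are reported on the continuous `[0, 360)` branch occupied by
#' this workspace. All public interfaces use degrees.
#'
#' @param upper_arm_len,forearm_len,hand_len Segment lengths in metres.
#' @param shoulder_origin Numeric 3-vector, metres.
#' @param joint_limits 7 x 2 matrix of per-joint `[min, max]` limits in
#'   degrees, rows ordered as `joint_order(arm)`. Defaults to permissive
#'   anatomical limits.
#' @return An object of class `arm_model`.
#' @examples
#' arm <- arm_model()
#' forward_kinematics(arm, rep(0, 7))$fingertip
#' @export
arm_model <- function(upper_arm_len = 0.30,
                      forearm_len = 0.25,
                      hand_len = 0.18,
                      shoulder_origin = c(0, 0, 0),
                      joint_limits = default_joint_limits()) {
  lens <- c(upper_arm_len, forearm_len, hand_len)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort_reachclone("all segment lengths must be positive and finite",
                     "reachclone_invalid_input")
  }
  joint_limits <- as.matrix(joint_limits)
  if (!identical(dim(joint_limits), c(7L, 2L)) ||
      any(joint_limits[, 1] >= joint_limits[, 2])) {
    abort_reachclone("joint_limits must be a 7 x 2 matrix with min < max",
                     "reachclone_invalid_input")
  }
  rownames(joint_limits) <- joint_order()
  colnames(joint_limits) <- c("min", "max")
  structure(
    list(
      upper_arm_len = upper_arm_len,
      forearm_len = forearm_len,
      hand_len = hand_len,
      shoulder_origin = as.numeric(shoulder_origin),
      joint_limits = joint_limits
    ),
    class = "arm_model"
  )
}

#' Canonical joint ordering of the arm model
#'
#' @return Character vector of the seven joint names in model order:
#'   shoulder abduction, shoulder flexion, shoulder rotation, elbow flexion,
#'   elbow pronation, wrist flexion, wrist abduction.
#' @export
joint_order <- function() {
  c("S_abd", "S_flex", "S_rot", "E_flex", "E_pron", "W_flex", "W_abd")
}

#' @rdname arm_model
#' @export
default_joint_limits <- function() {
  m <- rbind(
    S_abd  = c(-90, 90),
    S_flex = c(-60, 180),
    S_rot  = c(0, 360),
    E_flex = c(0, 150),
    E_pron = c(0, 360),
    W_flex = c(-70, 70),
    W_abd  = c(-70, 70)
  )
  colnames(m) <- c("min", "max")
  m
}

#' @export
print.arm_model <- function(x, ...) {
  cat("<arm_model> 7-DOF, reach",
      format(arm_reach(x), digits = 3), "m;",
      "segments", x$upper_arm_len, x$forearm_len, x$hand_len, "m\n")
  invisible(x)
}

#' Total reach of the arm (sum of segment lengths)
#' @param arm An `arm_model`.
#' @export
arm_reach <- function(arm) {
  arm$upper_arm_len + arm$forearm_len + arm$hand_len
}

as_joint_vector <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 7) {
    abort_reachclone("a joint vector must have exactly 7 angles",
                     "reachclone_invalid_input")
  }
  if (any(!is.finite(q))) {
    abort_reachclone("joint angles must be finite", "reachclone_invalid_input")
  }
  names(q) <- joint_order()
  q
}

# Rotation of the shoulder block: flexion about y, then abduction about z,
# then internal rotation about x (intrinsic composition, radians). Flexion
# leads so that the decomposition stays regular with the upper arm pointing
# down — the dominant direction in desk-height reaching; the singular
# directions are straight left/right, far outside the task workspace.
shoulder_rotation <- function(q_rad) {
  rot_y(q_rad[["S_flex"]]) %*% rot_z(q_rad[["S_abd"]]) %*% rot_x(q_rad[["S_rot"]])
}

#' Forward kinematics of the 7-DOF arm
#'
#' Composes the seven joint rotations along the segment chain and returns the
#' fingertip position, elbow position and palm normal.
#'
#' @param arm An `arm_model`.
#' @param q Joint vector: 7 angles in degrees, ordered as `joint_order()`.
#' @return A list with elements `fingertip`, `elbow_point`, `wrist_point`
#'   (3-vectors, metres) and `palm_normal` (unit 3-vector).
#' @export
forward_kinematics <- function(arm, q) {
  q <- as_joint_vector(q)
  qr <- deg2rad(q)
  x_hat <- c(1, 0, 0)
  r_sh <- shoulder_rotation(qr)
  elbow <- arm$shoulder_origin + arm$upper_arm_len * as.numeric(r_sh %*% x_hat)
  r_el <- r_sh %*% rot_y(qr[["E_flex"]]) %*% rot_x(qr[["E_pron"]])
  wrist <- elbow + arm$forearm_len * as.numeric(r_el %*% x_hat)
  r_wr <- r_el %*% rot_y(qr[["W_flex"]]) %*% rot_z(qr[["W_abd"]])
  fingertip <- wrist + arm$hand_len * as.numeric(r_wr %*% x_hat)
  palm_normal <- as.numeric(r_wr %*% c(0, 0, -1))
  list(fingertip = fingertip, elbow_point = elbow, wrist_point = wrist,
       palm_normal = palm_normal)
}

#' Redundancy-resolved inverse kinematics with an explicit swivel angle
#'
#' Places the fingertip at `fingertip_target` with the elbow on the
#' redundancy circle at `swivel_deg` from the vertical reference plane
#' (0 = elbow directly below the shoulder-fingertip axis, positive per the
#' right-hand rule about that axis).
#'
#' When `palm_down` is set, elbow pronation follows the task-determined
#' palm-flat profile: the pronation that levels the palm for the reference
#' swivel at the same fingertip point (and is therefore identical across
#' swivel styles, the way forearm rotation in tabletop reaching is set by the
#' task rather than by elbow elevation), while wrist flexion supplies the
#' residual palm tilt for the actual elbow elevation. A short outer fixed
#' point iteration restores exact fingertip placement under the bent wrist.
#'
#' @param arm An `arm_model`.
#' @param fingertip_target 3-vector, metres.
#' @param swivel_deg Elbow swivel angle in degrees.
#' @param palm_down Logical; orient the palm downwards (default `TRUE`).
#' @param reference_swivel_deg Swivel defining the shared pronation profile.
#' @return Joint vector (7 angles, degrees) satisfying
#'   `forward_kinematics(arm, q)$fingertip == fingertip_target` to well below
#'   1e-6 m.
#' @export
inverse_kinematics_swivel <- function(arm, fingertip_target, swivel_deg = 25,
                                      palm_down = TRUE,
                                      reference_swivel_deg = 27) {
  p <- as.numeric(fingertip_target) - arm$shoulder_origin
  phi <- deg2rad(swivel_deg)
  if (!isTRUE(palm_down)) {
    sol <- ik_two_link(arm, p, phi)
    q <- rad2deg(c(sol$s_abd, sol$s_flex, sol$s_rot, sol$e_flex, 0, 0, 0))
    return(check_joint_limits(arm, q))
  }
  Q <- ik_path(arm, matrix(as.numeric(fingertip_target), 1, 3), swivel_deg,
               reference_swivel_deg)
  stats::setNames(Q[1, ], joint_order())
}

# Vectorized two-link solve over a path of fingertip points (rows of P,
# relative to the shoulder), elbow on the swivel circle at `phi` radians.
ik_two_link_vec <- function(arm, P, phi) {
  l1 <- arm$upper_arm_len
  l2 <- arm$forearm_len + arm$hand_len
  d <- sqrt(rowSums(P^2))
  if (any(!is.finite(d)) || any(d >= l1 + l2 - 1e-12) ||
      any(d <= abs(l1 - l2) + 1e-12)) {
    i <- which(!is.finite(d) | d >= l1 + l2 - 1e-12 |
                 d <= abs(l1 - l2) + 1e-12)[1]
    abort_reachclone(
      sprintf("fingertip target at %.3f m is outside the reachable annulus (%.3f, %.3f) m",
              d[i], abs(l1 - l2), l1 + l2),
      "reachclone_unreachable")
  }
  n_hat <- P / d
  u_ref <- cbind(-n_hat[, 1] * (-n_hat[, 3]), -n_hat[, 2] * (-n_hat[, 3]),
                 -1 - n_hat[, 3] * (-n_hat[, 3]))
  u_norm <- sqrt(rowSums(u_ref^2))
  if (any(u_norm < 1e-9)) {
    abort_reachclone("fingertip target is vertically aligned with the shoulder; swivel reference undefined",
                     "reachclone_unreachable")
  }
  u_hat <- u_ref / u_norm
  v_hat <- cbind(n_hat[, 2] * u_hat[, 3] - n_hat[, 3] * u_hat[, 2],
                 n_hat[, 3] * u_hat[, 1] - n_hat[, 1] * u_hat[, 3],
                 n_hat[, 1] * u_hat[, 2] - n_hat[, 2] * u_hat[, 1])
  cos_beta <- clamp((l1^2 + d^2 - l2^2) / (2 * l1 * d), -1, 1)
  sin_beta <- sqrt(pmax(0, 1 - cos_beta^2))
  elbow <- l1 * cos_beta * n_hat +
    l1 * sin_beta * (cos(phi) * u_hat + sin(phi) * v_hat)
  u1 <- elbow / l1
  s_abd <- asin(clamp(u1[, 2], -1, 1))
  s_flex <- atan2(-u1[, 3], u1[, 1])
  f_hat <- (P - elbow) / l2
  e_flex <- acos(clamp(rowSums(u1 * f_hat), -1, 1))
  # w = Rz(-abd) Ry(-flex) f_hat
  w <- vrot_z(-s_abd, vrot_y(-s_flex, f_hat))
  s_rot <- ifelse(abs(e_flex) < 1e-9, 0, atan2(w[, 2], -w[, 3]))
  s_rot <- ifelse(s_rot < 0, s_rot + 2 * pi, s_rot)
  list(s_abd = s_abd, s_flex = s_flex, s_rot = s_rot, e_flex = e_flex,
       elbow = elbow)
}

# z components of columns 2 and 3 of M = Ry(f) Rz(a) Rx(c) Ry(ef), vectorized.
palm_frame_z <- function(sol) {
  n <- length(sol$s_abd)
  apply_chain <- function(V) {
    V <- vrot_y(sol$e_flex, V)
    V <- vrot_x(sol$s_rot, V)
    V <- vrot_z(sol$s_abd, V)
    vrot_y(sol$s_flex, V)
  }
  e2 <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  e3 <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  list(m2z = apply_chain(e2)[, 3], m3z = apply_chain(e3)[, 3])
}

# Columns 1 and 3 of R_el = Ry(f) Rz(a) Rx(c) Ry(ef) Rx(ep), vectorized.
elbow_frame_cols <- function(sol, e_pron) {
  n <- length(sol$s_abd)
  apply_chain <- function(V) {
    V <- vrot_x(e_pron, V)
    V <- vrot_y(sol$e_flex, V)
    V <- vrot_x(sol$s_rot, V)
    V <- vrot_z(sol$s_abd, V)
    vrot_y(sol$s_flex, V)
  }
  e1 <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  e3 <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  list(c1 = apply_chain(e1), c3 = apply_chain(e3))
}

# Solve an entire fingertip path (n x 3 matrix, world frame) at one swivel.
# Pronation follows the reference-swivel palm-flat profile; wrist flexion
# supplies the residual tilt; a fixed-point iteration restores the fingertip.
ik_path <- function(arm, path, swivel_deg, reference_swivel_deg = 27) {
  P <- sweep(matrix(as.numeric(path), ncol = 3), 2, arm$shoulder_origin)
  phi <- deg2rad(swivel_deg)
  ref <- ik_two_link_vec(arm, P, deg2rad(reference_swivel_deg))
  pz <- palm_frame_z(ref)
  e_pron <- atan2(-pz$m2z, pz$m3z)
  e_pron <- ifelse(e_pron < 0, e_pron + 2 * pi, e_pron)
  l2f <- arm$forearm_len
  l3 <- arm$hand_len
  w_max <- deg2rad(arm$joint_limits["W_flex", "max"])
  V <- P
  sol <- NULL; w_flex <- NULL
  for (iter in seq_len(25)) {
    sol <- ik_two_link_vec(arm, V, phi)
    fc <- elbow_frame_cols(sol, e_pron)
    w_flex <- clamp(atan2(fc$c1[, 3], fc$c3[, 3]), -w_max, w_max)
    tip <- sol$elbow + l2f * fc$c1 +
      l3 * (cos(w_flex) * fc$c1 - sin(w_flex) * fc$c3)
    err <- P - tip
    if (max(abs(err)) < 1e-10) break
    V <- V + err
  }
  Q <- rad2deg(cbind(sol$s_abd, sol$s_flex, sol$s_rot, sol$e_flex, e_pron,
                     w_flex, 0))
  colnames(Q) <- joint_order()
  lim <- arm$joint_limits
  for (j in seq_len(7)) {
    bad <- which(Q[, j] < lim[j, "min"] - 1e-9 | Q[, j] > lim[j, "max"] + 1e-9)
    if (length(bad) > 0) {
      abort_reachclone(
        sprintf("no inverse-kinematics solution within joint limits (violated: %s)",
                joint_order()[j]),
        "reachclone_joint_limits")
    }
  }
  Q
}

# Closed-form two-link solve (straight wrist): shoulder angles, elbow flexion
# and the elbow point for a fingertip target `p` relative to the shoulder,
# with the elbow on the swivel circle at `phi` radians. Radians in and out.
ik_two_link <- function(arm, p, phi) {
  d <- vec_norm(p)
  l1 <- arm$upper_arm_len
  l2 <- arm$forearm_len + arm$hand_len
  if (!is.finite(d) || d >= l1 + l2 - 1e-12 || d <= abs(l1 - l2) + 1e-12) {
    abort_reachclone(
      sprintf("fingertip target at %.3f m is outside the reachable annulus (%.3f, %.3f) m",
              d, abs(l1 - l2), l1 + l2),
      "reachclone_unreachable")
  }
  n_hat <- p / d
  down <- c(0, 0, -1)
  u_ref <- down - sum(down * n_hat) * n_hat
  if (vec_norm(u_ref) < 1e-9) {
    abort_reachclone("fingertip target is vertically aligned with the shoulder; swivel reference undefined",
                     "reachclone_unreachable")
  }
  u_hat <- u_ref / vec_norm(u_ref)
  v_hat <- cross3(n_hat, u_hat)
  cos_beta <- clamp((l1^2 + d^2 - l2^2) / (2 * l1 * d), -1, 1)
  sin_beta <- sqrt(max(0, 1 - cos_beta^2))
  elbow <- l1 * cos_beta * n_hat +
    l1 * sin_beta * (cos(phi) * u_hat + sin(phi) * v_hat)
  u1 <- elbow / l1
  # u1 = Ry(flex) Rz(abd) x = (cos f cos a, sin a, -sin f cos a)
  s_abd <- asin(clamp(u1[2], -1, 1))
  s_flex <- atan2(-u1[3], u1[1])
  f_hat <- (p - elbow) / l2
  e_flex <- acos(clamp(sum(u1 * f_hat), -1, 1))
  r0 <- rot_y(s_flex) %*% rot_z(s_abd)
  w <- as.numeric(t(r0) %*% f_hat)
  s_rot <- if (abs(e_flex) < 1e-9) 0 else atan2(w[2], -w[3])
  # internal rotation lives on the continuous [0, 360) branch occupied by
  # desk-height reaching (the principal branch would cut the workspace)
  if (s_rot < 0) s_rot <- s_rot + 2 * pi
  list(s_abd = s_abd, s_flex = s_flex, s_rot = s_rot, e_flex = e_flex,
       elbow = elbow)
}

check_joint_limits <- function(arm, q) {
  names(q) <- joint_order()
  lim <- arm$joint_limits
  if (any(q < lim[, "min"] - 1e-9) || any(q > lim[, "max"] + 1e-9)) {
    bad <- joint_order()[q < lim[, "min"] - 1e-9 | q > lim[, "max"] + 1e-9]
    abort_reachclone(
      sprintf("no inverse-kinematics solution within joint limits (violated: %s)",
              paste(bad, collapse = ", ")),
      "reachclone_joint_limits")
  }
  q
}

#' Serialize / restore an arm model through a YAML config
#'
#' @param arm An `arm_model`.
#' @param path File path for the YAML document.
#' @return `write_arm_config()` returns `path` invisibly;
#'   `read_arm_config()` returns an `arm_model`.
#' @export
write_arm_config <- function(arm, path) {
  cfg <- list(
    segment_lengths = c(arm$upper_arm_len, arm$forearm_len, arm$hand_len),
    shoulder_origin = arm$shoulder_origin,
    joint_limits_deg = stats::setNames(
      lapply(seq_len(7), function(i) as.numeric(arm$joint_limits[i, ])),
      joint_order())
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_arm_config
#' @export
read_arm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lims <- do.call(rbind, cfg$joint_limits_deg[joint_order()])
  arm_model(
    upper_arm_len = cfg$segment_lengths[[1]],
    forearm_len = cfg$segment_lengths[[2]],
    hand_len = cfg$segment_lengths[[3]],
    shoulder_origin = as.numeric(cfg$shoulder_origin),
    joint_limits = lims
  )
}
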