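# Internal numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Elementary rotation matrices, radians, right-handed, active rotations.
rot_x <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}
rot_y <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}
rot_z <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

vec_norm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

abort_reachclone <- function(msg, class) {
  rlang::abort(msg, class = c(class, "reachclone_error"))
}

# Vectorized application of elementary rotations to n x 3 row-vector matrices
# (each row rotated by the corresponding angle in `a`).
vrot_x <- function(a, V) {
  cbind(V[, 1], cos(a) * V[, 2] - sin(a) * V[, 3],
        sin(a) * V[, 2] + cos(a) * V[, 3])
}
vrot_y <- function(a, V) {
  cbind(cos(a) * V[, 1] + sin(a) * V[, 3], V[, 2],
        -sin(a) * V[, 1] + cos(a) * V[, 3])
}
vrot_z <- function(a, V) {
  cbind(cos(a) * V[, 1] - sin(a) * V[, 2],
        sin(a) * V[, 1] + cos(a) * V[, 2], V[, 3])
}
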