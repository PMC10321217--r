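# Quaternion helpers (w, x, y, z convention). Internal.

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_rotate <- function(q, v) as.numeric(quat_to_matrix(q) %*% v)

# Shoemake's uniform random unit quaternions, n x 4.
random_quats <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}
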