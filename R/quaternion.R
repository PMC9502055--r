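# Minimal unit-quaternion utilities. Quaternions are n x 4 matrices with
# columns (w, x, y, z), scalar part first, Hamilton convention.

quat_norm <- function(q) sqrt(rowSums(q^2))

quat_normalize <- function(q) q / quat_norm(q)

quat_conjugate <- function(q) {
  q[, 2:4] <- -q[, 2:4]
  q
}

quat_multiply <- function(a, b) {
  cbind(a[, 1]*b[, 1] - a[, 2]*b[, 2] - a[, 3]*b[, 3] - a[, 4]*b[, 4],
        a[, 1]*b[, 2] + a[, 2]*b[, 1] + a[, 3]*b[, 4] - a[, 4]*b[, 3],
        a[, 1]*b[, 3] - a[, 2]*b[, 4] + a[, 3]*b[, 1] + a[, 4]*b[, 2],
        a[, 1]*b[, 4] + a[, 2]*b[, 3] - a[, 3]*b[, 2] + a[, 4]*b[, 1])
}

# rotation of angle_deg about a fixed 3-vector axis; vectorized over angle
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  cbind(cos(half), sin(half) %o% axis)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

as_quat_matrix <- function(q, arg = "quaternion input") {
  if (is.data.frame(q)) q <- as.matrix(q)
  if (is.numeric(q) && is.null(dim(q)) && length(q) == 4L) q <- matrix(q, 1)
  if (!is.matrix(q) || ncol(q) != 4L)
    stop(arg, " must be an n x 4 matrix (w, x, y, z)")
  storage.mode(q) <- "double"
  q
}
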