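# Vectorised internal geometry kernels. All functions accept n x 3 matrices
# (or length-3 vectors, recycled) and return length-n vectors. Angles in
# radians; dihedrals in (-pi, pi].

.as_mat3 <- function(x, n = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (!is.null(n) && nrow(x) == 1 && n > 1) {
    x <- x[rep(1, n), , drop = FALSE]
  }
  x
}

.row_dot <- function(a, b) rowSums(a * b)

.row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

.row_norm <- function(a) sqrt(rowSums(a^2))

# Wrap angles into (-pi, pi].
wrap_angle <- function(x) {
  w <- atan2(sin(x), cos(x))
  w[w <= -pi + 1e-15] <- pi
  w
}

# Bond angle p1-p2-p3 (at p2), in [0, pi].
.row_angle <- function(p1, p2, p3) {
  n <- max(nrow(.as_mat3(p1)), nrow(.as_mat3(p2)), nrow(.as_mat3(p3)))
  v1 <- .as_mat3(p1, n) - .as_mat3(p2, n)
  v2 <- .as_mat3(p3, n) - .as_mat3(p2, n)
  # atan2 form is accurate near 0 and pi, unlike acos of the cosine
  atan2(.row_norm(.row_cross(v1, v2)), .row_dot(v1, v2))
}

# Dihedral p1-p2-p3-p4: atan2 formulation on the two plane normals, positive
# for a right-handed rotation about the p2->p3 axis viewed from p2 toward p3.
.row_dihedral <- function(p1, p2, p3, p4) {
  n <- max(
    nrow(.as_mat3(p1)), nrow(.as_mat3(p2)),
    nrow(.as_mat3(p3)), nrow(.as_mat3(p4))
  )
  b1 <- .as_mat3(p2, n) - .as_mat3(p1, n)
  b2 <- .as_mat3(p3, n) - .as_mat3(p2, n)
  b3 <- .as_mat3(p4, n) - .as_mat3(p3, n)
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  b2n <- b2 / .row_norm(b2)
  m <- .row_cross(n1, b2n)
  wrap_angle(atan2(.row_dot(m, n2), .row_dot(n1, n2)))
}

# Rotation matrix for intrinsic z-y'-z'' Euler angles (phi about z, then
# theta about the new y, then psi about the new z). Equals
# Rz(phi) %*% Ry(theta) %*% Rz(psi) in fixed axes.
euler_zyz <- function(phi, theta, psi) {
  cf <- cos(phi); sf <- sin(phi)
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(psi); sp <- sin(psi)
  matrix(c(
    cf * ct * cp - sf * sp, -cf * ct * sp - sf * cp, cf * st,
    sf * ct * cp + cf * sp, -sf * ct * sp + cf * cp, sf * st,
    -st * cp, st * sp, ct
  ), nrow = 3, byrow = TRUE)
}
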