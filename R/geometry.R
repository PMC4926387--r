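# Rotation utilities: quaternions, rotation matrices, deterministic
# quasi-uniform orientation sets for rigid-body search.

#' Check that a matrix is a proper rotation
#'
#' @param m numeric 3x3 matrix.
#' @param tol numeric tolerance on orthonormality and determinant.
#' @return `TRUE` or `FALSE`.
#' @keywords internal
is_rotation_matrix <- function(m, tol = 1e-6) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) && all(is.finite(m)) &&
    max(abs(crossprod(m) - diag(3))) <= tol && abs(det(m) - 1) <= tol
}

quat_normalize <- function(q) q / sqrt(sum(q * q))

# Unit quaternion (w, x, y, z) -> 3x3 rotation matrix.
quat_to_mat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

axis_angle_quat <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis)
}

# Spherical linear interpolation between unit quaternions (u in [0, 1]).
quat_slerp <- function(a, b, u) {
  a <- quat_normalize(a); b <- quat_normalize(b)
  d <- sum(a * b)
  if (d < 0) { b <- -b; d <- -d }
  if (d > 1 - 1e-10) return(quat_normalize(a + u * (b - a)))
  th <- acos(min(1, d))
  quat_normalize((sin((1 - u) * th) * a + sin(u * th) * b) / sin(th))
}

# Geodesic rotation angle (radians) between two rotations given as unit
# quaternions: angle of the relative rotation.
quat_geodesic <- function(a, b) {
  d <- min(1, abs(sum(a * b)))
  2 * acos(d)
}

# Uniform random unit quaternion (Shoemake's map from three uniforms).
random_quat <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

# --- finite rotation groups -------------------------------------------------
# Unit quaternions of the binary tetrahedral / octahedral / icosahedral
# groups; q and -q give the same rotation, deduplicated downstream.

quat_group_tetra <- function() {
  q <- matrix(0, 0, 4)
  for (i in 1:4) for (s in c(1, -1)) {
    v <- numeric(4); v[i] <- s; q <- rbind(q, v)
  }
  half <- as.matrix(expand.grid(c(-.5, .5), c(-.5, .5), c(-.5, .5), c(-.5, .5)))
  rbind(q, half)
}

quat_group_octa <- function() {
  q <- quat_group_tetra()
  s <- 1 / sqrt(2)
  idx <- utils::combn(4, 2)
  for (k in seq_len(ncol(idx))) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      v <- numeric(4); v[idx[1, k]] <- s1 * s; v[idx[2, k]] <- s2 * s
      q <- rbind(q, v)
    }
  }
  q
}

quat_group_icosa <- function() {
  phi <- (1 + sqrt(5)) / 2
  q <- quat_group_tetra()
  vals <- c(0, 0.5, 1 / (2 * phi), phi / 2)
  even_perms <- list(c(1,2,3,4), c(1,3,4,2), c(1,4,2,3), c(2,1,4,3),
                     c(2,3,1,4), c(2,4,3,1), c(3,1,2,4), c(3,2,4,1),
                     c(3,4,1,2), c(4,1,3,2), c(4,2,1,3), c(4,3,2,1))
  for (p in even_perms) {
    base <- vals[order(p)]  # place vals into positions given by perm p
    nz <- which(base != 0)
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), length(nz))))
    for (r in seq_len(nrow(signs))) {
      v <- base; v[nz] <- v[nz] * signs[r, ]
      q <- rbind(q, v)
    }
  }
  q
}

dedup_rotations <- function(q, tol = 1e-6) {
  # identify q with -q; canonicalise sign on first nonzero component
  q <- t(apply(q, 1, function(v) {
    v <- quat_normalize(v)
    nz <- which(abs(v) > 1e-9)[1]
    if (v[nz] < 0) v <- -v
    v
  }))
  q[!duplicated(round(q, 6)), , drop = FALSE]
}

# Deterministic super-Fibonacci spiral of n unit quaternions.
super_fibonacci <- function(n) {
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041
  i <- seq_len(n) - 0.5
  t <- i / n
  d <- 2 * pi * i
  r <- sqrt(t); rr <- sqrt(1 - t)
  a <- d / phi; b <- d / psi
  cbind(r * sin(a), r * cos(a), rr * sin(b), rr * cos(b))
}

#' Deterministic quasi-uniform rotation set
#'
#' Returns `n` rotation matrices spread quasi-uniformly over SO(3) for the
#' orientation stage of rigid-body docking. For `n` equal to the order of an
#' exact rotation group (1, 12, 24, 60: identity, tetrahedral, octahedral,
#' icosahedral) the group itself is returned, which is the optimal uniform
#' arrangement; otherwise a super-Fibonacci quaternion pool is subsampled by
#' greedy farthest-point selection seeded at the identity. The result is
#' identical across calls.
#'
#' @param n integer number of orientations (>= 1).
#' @return list of 3x3 rotation matrices; the first is always the identity.
#' @export
orientation_set <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 1L) return(list(diag(3)))
  qset <- switch(as.character(n),
    "12" = dedup_rotations(quat_group_tetra()),
    "24" = dedup_rotations(quat_group_octa()),
    "60" = dedup_rotations(quat_group_icosa()),
    NULL)
  if (is.null(qset)) {
    pool <- rbind(c(1, 0, 0, 0), super_fibonacci(8L * n))
    pool <- t(apply(pool, 1, quat_normalize))
    # greedy farthest-point subsample, seeded at the identity
    chosen <- 1L
    dmin <- apply(pool, 1, function(v) quat_geodesic(pool[1, ], v))
    while (length(chosen) < n) {
      nxt <- which.max(dmin)
      chosen <- c(chosen, nxt)
      dn <- apply(pool, 1, function(v) quat_geodesic(pool[nxt, ], v))
      dmin <- pmin(dmin, dn)
    }
    qset <- pool[chosen, , drop = FALSE]
  } else {
    # put identity first, keep deterministic order for the rest
    idn <- which.max(abs(qset[, 1]))
    qset <- rbind(qset[idn, ], qset[-idn, , drop = FALSE])
  }
  stopifnot(nrow(qset) == n)
  lapply(seq_len(n), function(i) quat_to_mat(qset[i, ]))
}

# Kabsch least-squares rotation aligning mobile onto fixed (both centred,
# row-major: apply as mobile %*% R). Reflections are disallowed.
kabsch_rotation <- function(fixed, mobile) {
  h <- crossprod(mobile, fixed)      # M^T F
  s <- svd(h)
  d <- sign(det(tcrossprod(s$u, s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}
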