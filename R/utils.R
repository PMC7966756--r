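# Internal geometry and RNG helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
as_xyz_matrix <- function(x) {
  if (inherits(x, "water_set")) {
    m <- as.matrix(x[, c("x", "y", "z")])
  } else if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    m <- as.matrix(x[, c("x", "y", "z")])
  } else {
    m <- as.matrix(x)
  }
  if (ncol(m) != 3L) stop("coordinates must be an n x 3 matrix")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

# All pairwise Euclidean distances between rows of A and rows of B.
pairwise_dist <- function(A, B = A) {
  A <- as_xyz_matrix(A)
  B <- as_xyz_matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Angle (degrees) at pj in the triple pi-pj-pk.
triplet_angle <- function(pi_, pj, pk) {
  u <- pi_ - pj
  v <- pk - pj
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cs <- min(1, max(-1, cs))
  acos(cs) * 180 / pi
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never disturb user RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Uniform random rotation matrix (Shoemake quaternion method).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  quat_to_rot(q)
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Proper rotation by `theta` degrees about unit `axis`.
rotation_about_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  th <- theta * pi / 180
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation carrying unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
  s <- sqrt(sum(v^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate 180 degrees about any axis perpendicular to a
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * a) * a
    return(rotation_about_axis(perp, 180))
  }
  K <- matrix(c(
    0, -v[3], v[2],
    v[3], 0, -v[1],
    -v[2], v[1], 0
  ), nrow = 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

assert_finite_coords <- function(m, ids = NULL) {
  bad <- which(!is.finite(rowSums(m)))
  if (length(bad)) {
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else
      paste(bad, collapse = ", ")
    stop("non-finite coordinates for: ", lab)
  }
  invisible(TRUE)
}
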