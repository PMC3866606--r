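# Low-level 3-D vector utilities shared by the builder, QA and alignment code.
# All coordinates are in Angstroms, all angles in degrees unless noted.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle a-b-c-d using the IUPAC convention (trans = 180).
#'
#' @param a,b,c,d numeric 3-vectors, Angstroms.
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# bond angle at b in degrees
angle3 <- function(a, b, c) {
  v1 <- unitv(a - b)
  v2 <- unitv(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) / DEG
}

#' Place an atom by internal coordinates (NeRF)
#'
#' Given three placed atoms a-b-c, returns the position d such that
#' |c-d| = bond, angle(b,c,d) = theta and dihedral(a,b,c,d) = chi.
#'
#' @param a,b,c numeric 3-vectors of the three reference atoms.
#' @param bond bond length c-d in Angstroms.
#' @param theta bond angle b-c-d in degrees.
#' @param chi dihedral a-b-c-d in degrees.
#' @return numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, theta, chi) {
  th <- theta * DEG
  ch <- -chi * DEG
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ch),
          bond * sin(th) * sin(ch))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Rotation matrix from axis (unit 3-vector) and angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  rbind(
    c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st),
    c(uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st),
    c(uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)))
}

# Minimal rotation carrying unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  c <- sum(a * b)
  if (s < 1e-9) {
    if (c > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about_axis(perp, 180))
  }
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx * ((1 - c) / s^2)
}

# Uniform random rotation matrix (uses the current RNG stream).
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# Apply rigid transform (rotation R then translation t) to an n x 3 matrix.
apply_rigid <- function(xyz, rotation, translation) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  sweep(xyz %*% t(rotation), 2, translation, `+`)
}

# Pairwise squared-distance matrix between rows of n x 3 matrices.
distsq_matrix <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d <- outer(an, bn, `+`) - 2 * (a %*% t(b))
  d[d < 0] <- 0
  d
}

# Run an expression with a private, restored RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
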