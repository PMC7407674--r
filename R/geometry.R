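# Rigid-body poses, periodic minimum-image distances and rotation sampling.

#' Create a rigid-body pose
#'
#' A pose places a coarse protein (whose reference coordinates are stored
#' centered at its center of mass) in the simulation box: current
#' coordinates are `ref %*% t(R) + t`.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation (the center-of-mass position, Angstrom).
#' @return An object of class `cg_pose`.
#' @export
cg_pose <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)), length(t) == 3)
  structure(list(R = R, t = as.numeric(t)), class = "cg_pose")
}

#' Apply a pose to a coarse protein
#'
#' @param protein a `coarse_protein`.
#' @param pose a `cg_pose` (defaults to the protein's stored pose).
#' @return n_sites x 3 matrix of site coordinates (Angstrom).
#' @export
placed_xyz <- function(protein, pose = protein$pose) {
  xyz <- protein$xyz %*% t(pose$R)
  xyz[, 1] <- xyz[, 1] + pose$t[1]
  xyz[, 2] <- xyz[, 2] + pose$t[2]
  xyz[, 3] <- xyz[, 3] + pose$t[3]
  xyz
}

# Pairwise squared distances between rows of A and rows of B, with the
# minimum-image convention when `box` (cubic edge, Angstrom) is given.
pair_dist_sq <- function(A, B, box = NULL) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box * round(dx / box)
    dy <- dy - box * round(dy / box)
    dz <- dz - box * round(dz / box)
  }
  dx * dx + dy * dy + dz * dz
}

# Elementwise minimum-image distances for matched rows of A and B.
row_dist <- function(A, B, box = NULL) {
  d <- A - B
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(rowSums(d * d))
}

# Minimum-image displacement of b relative to a (vectors length 3).
min_image_disp <- function(a, b, box = NULL) {
  d <- b - a
  if (!is.null(box)) d <- d - box * round(d / box)
  d
}

#' Uniform random rotation matrix
#'
#' Samples uniformly over SO(3) via a random unit quaternion (four iid
#' normals, normalized). Used for initial orientations; naive independent
#' Euler-angle sampling would bias orientations.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    nrow = 3, byrow = TRUE)
}

# Rotation by `angle` (rad) about unit `axis` (Rodrigues formula).
axis_angle_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis * axis))
  c0 <- cos(angle); s0 <- sin(angle); C <- 1 - c0
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c0 + ux * ux * C,      ux * uy * C - uz * s0, ux * uz * C + uy * s0,
    uy * ux * C + uz * s0, c0 + uy * uy * C,      uy * uz * C - ux * s0,
    uz * ux * C - uy * s0, uz * uy * C + ux * s0, c0 + uz * uz * C),
    nrow = 3, byrow = TRUE)
}

# Uniform random point on the unit sphere.
random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v * v))
}

# Wrap a position into [0, box).
wrap_position <- function(t, box) t - box * floor(t / box)

# Least-squares rigid superposition (Kabsch, SVD form): rotation +
# translation taking `mobile_fit` onto `fixed_fit` with minimal RMSD,
# proper rotation enforced via the determinant sign correction.
kabsch_transform <- function(mobile_fit, fixed_fit) {
  cm <- colMeans(mobile_fit)
  cf <- colMeans(fixed_fit)
  H <- crossprod(sweep(mobile_fit, 2, cm), sweep(fixed_fit, 2, cf))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cm = cm, cf = cf)
}

# Apply a kabsch_transform to an n x 3 coordinate matrix (row vectors).
apply_kabsch <- function(tr, xyz) {
  out <- sweep(xyz, 2, tr$cm) %*% t(tr$R)
  sweep(out, 2, tr$cf, "+")
}
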