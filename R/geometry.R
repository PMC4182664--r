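# Planar geometry substrate: points, rotations, rigid transforms, angle
# measurement, chord displacement, circle fitting and point-line distance.
#
# Conventions (used everywhere in the package):
#   * sagittal plane, +x anterior (the skull faces right), +y dorsal;
#   * all interface angles in degrees, counterclockwise positive;
#   * a "ventral" rotation of the anterior-facing skull is clockwise,
#     i.e. a negative internal angle -- user-facing functions take
#     positive ventral/anterior degrees and handle the sign internally;
#   * all lengths in millimetres.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Normalize an angle in degrees to (-180, 180].
norm_angle_deg <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

# Coerce to a finite length-2 numeric point.
as_pt <- function(p, what = "point") {
  p <- unname(as.numeric(p))
  if (length(p) != 2L || !all(is.finite(p)))
    stop_domain(sprintf("%s must be a pair of finite coordinates", what))
  p
}

# Coerce to an n x 2 coordinate matrix (row names preserved).
as_pts <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop_domain("coordinate matrix must have 2 columns")
    storage.mode(p) <- "double"
    return(p)
  }
  matrix(as_pt(p), nrow = 1L)
}

vnorm <- function(v) sqrt(sum(v^2))

# 2D cross product (scalar z-component).
cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

unit_vec <- function(v, what = "direction") {
  v <- as_pt(v, what)
  n <- vnorm(v)
  if (n == 0) stop_domain(sprintf("%s vector must be nonzero", what))
  v / n
}

rot_mat <- function(angle_deg) {
  th <- deg2rad(angle_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Rotate points about a center
#'
#' Rotates one point (length-2 vector) or a matrix of points (n x 2) about
#' `center` by `angle_deg` degrees, counterclockwise positive.
#'
#' @param p A length-2 numeric vector or an n x 2 coordinate matrix (mm).
#' @param center Length-2 numeric vector, the center of rotation.
#' @param angle_deg Rotation angle in degrees, counterclockwise positive.
#' @return The rotated point(s), same shape as `p`.
#' @examples
#' rotate_about(c(1, 0), c(0, 0), 90) # c(0, 1)
#' @export
rotate_about <- function(p, center, angle_deg) {
  if (!is.finite(angle_deg)) stop_domain("rotation angle must be finite")
  center <- as_pt(center, "center")
  single <- !is.matrix(p)
  m <- as_pts(p)
  R <- rot_mat(angle_deg)
  out <- sweep(sweep(m, 2L, center) %*% t(R), 2L, center, "+")
  dimnames(out) <- dimnames(m)
  if (single) drop(out) else out
}

#' Chord displacement of a point on a rotating arc
#'
#' Straight-line distance travelled by a point at distance `radius` from
#' the center when rotated by `angle_deg`: `2 * radius * sin(|angle| / 2)`.
#' This is the ventral translation suffered by the jaw joint when the
#' neck-and-skull unit rotates about a pivot at that distance.
#'
#' @param radius Distance from the rotation center, mm (non-negative).
#' @param angle_deg Arc of rotation in degrees.
#' @return Displacement in mm; zero iff `radius == 0` or the angle is a
#'   multiple of 360 degrees.
#' @examples
#' chord_displacement(100, 15) # ~26.105 mm
#' @export
chord_displacement <- function(radius, angle_deg) {
  if (!is.finite(radius) || radius < 0)
    stop_domain("radius must be finite and non-negative")
  if (!is.finite(angle_deg)) stop_domain("angle must be finite")
  2 * radius * abs(sin(deg2rad(angle_deg) / 2))
}

#' Unsigned angle at a vertex
#'
#' Angle in `[0, 180]` degrees between rays `vertex -> a` and
#' `vertex -> b`, computed with `atan2` of cross and dot products for
#' numerical stability near 0 and 180 degrees.  The gape angle, for
#' example, is the angle at the jaw joint subtended by the two incisor
#' tips.
#'
#' @param vertex,a,b Length-2 numeric points (mm).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angle_at_vertex(c(0, 0), c(1, 0), c(0, -1)) # 90
#' @export
angle_at_vertex <- function(vertex, a, b) {
  vertex <- as_pt(vertex, "vertex")
  va <- as_pt(a, "a") - vertex
  vb <- as_pt(b, "b") - vertex
  if (vnorm(va) == 0 || vnorm(vb) == 0)
    stop_domain("degenerate geometry: ray endpoint coincides with the vertex")
  unname(rad2deg(atan2(abs(cross2(va, vb)), sum(va * vb))))
}

#' Perpendicular distance from a point to an infinite line
#'
#' The shortest (unsigned) distance from `point` to the line through
#' `line_point` with direction `line_dir`.  This is the primitive behind
#' lever in-/out-lever lengths.
#'
#' @param point Length-2 numeric point (mm).
#' @param line_point A point on the line.
#' @param line_dir Nonzero direction vector of the line.
#' @return Distance in mm.
#' @export
perpendicular_distance <- function(point, line_point, line_dir) {
  point <- as_pt(point, "point")
  line_point <- as_pt(line_point, "line point")
  d <- unit_vec(line_dir, "line direction")
  unname(abs(cross2(point - line_point, d)))
}

#' Fit a circle to planar points
#'
#' For exactly three points returns the circumcircle; for more, the
#' algebraic (Kasa) least-squares circle minimizing
#' `sum((x^2 + y^2 + a x + b y + c)^2)`.  Used to recover the virtual
#' center of the maxillary canine curvature from canine landmarks.
#'
#' @param pts An n x 2 coordinate matrix, n >= 3, not all collinear.
#' @param tol Collinearity tolerance relative to the largest pairwise
#'   distance among the points; defaults to `1e-9`.
#' @return An object of class `circle_fit`: list with `center` (length-2),
#'   `radius` (mm) and `residuals` (signed distance of each point to the
#'   fitted circle).
#' @examples
#' fit_circle(rbind(c(1, 0), c(0, 1), c(-1, 0))) # unit circle at origin
#' @export
fit_circle <- function(pts, tol = 1e-9) {
  m <- as_pts(pts)
  if (nrow(m) < 3L) stop_domain("circle fit needs at least 3 points")
  if (!all(is.finite(m))) stop_domain("circle fit: non-finite coordinates")
  char_len <- max(stats::dist(m))
  if (char_len == 0) stop_domain("circle fit: all points coincide")
  # collinearity: maximal perpendicular offset from the longest-span line
  dd <- as.matrix(stats::dist(m))
  ij <- which(dd == max(dd), arr.ind = TRUE)[1L, ]
  axis <- unit_vec(m[ij[2L], ] - m[ij[1L], ])
  offs <- apply(m, 1L, function(p) abs(cross2(p - m[ij[1L], ], axis)))
  if (max(offs) <= tol * char_len)
    stop_domain("cannot fit a circle: points are collinear")
  A <- cbind(2 * m[, 1L], 2 * m[, 2L], 1)
  b <- rowSums(m^2)
  sol <- qr.solve(A, b)
  center <- sol[1:2]
  radius <- sqrt(sol[3L] + sum(center^2))
  res <- sqrt(rowSums(sweep(m, 2L, center)^2)) - radius
  structure(list(center = unname(center), radius = unname(radius),
                 residuals = unname(res)),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: center (%.6g, %.6g), radius %.6g mm, RMS residual %.3g mm\n",
              x$center[1], x$center[2], x$radius,
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

# ---- rigid transforms -------------------------------------------------

#' Planar rigid transform
#'
#' A rotation by `angle_deg` about `center` followed by `translation`.
#' Stored internally as a rotation matrix plus offset so transforms
#' compose and invert exactly.
#'
#' @param angle_deg Rotation angle, degrees CCW.
#' @param center Center of rotation, length-2 (mm).
#' @param translation Additional displacement, length-2 (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angle_deg = 0, center = c(0, 0),
                            translation = c(0, 0)) {
  if (!is.finite(angle_deg)) stop_domain("transform angle must be finite")
  center <- as_pt(center, "center")
  translation <- as_pt(translation, "translation")
  R <- rot_mat(angle_deg)
  t_off <- center - as.numeric(R %*% center) + translation
  structure(list(R = R, t = t_off), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf A `rigid_transform`.
#' @param p A length-2 point or n x 2 matrix.
#' @return Transformed point(s), same shape as `p`.
#' @export
apply_transform <- function(tf, p) {
  stopifnot(inherits(tf, "rigid_transform"))
  single <- !is.matrix(p)
  m <- as_pts(p)
  out <- sweep(m %*% t(tf$R), 2L, tf$t, "+")
  dimnames(out) <- dimnames(m)
  if (single) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(after, first)` applies `first`, then `after`.
#'
#' @param after,first `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(after, first) {
  stopifnot(inherits(after, "rigid_transform"),
            inherits(first, "rigid_transform"))
  structure(list(R = after$R %*% first$R,
                 t = as.numeric(after$R %*% first$t) + after$t),
            class = "rigid_transform")
}

#' Invert a rigid transform
#'
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform` (composition with `tf` is the
#'   identity).
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  Rt <- t(tf$R)
  structure(list(R = Rt, t = -as.numeric(Rt %*% tf$t)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rad2deg(atan2(x$R[2, 1], x$R[1, 1]))
  cat(sprintf("Rigid transform: rotation %.6g deg, offset (%.6g, %.6g) mm\n",
              ang, x$t[1], x$t[2]))
  invisible(x)
}
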