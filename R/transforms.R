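# 2D transforms in physical (mm) coordinates.
#
# Convention: every transform maps FIXED-image coordinates to MOVING-image
# coordinates, i.e. it is a resampling map: warped(x) = moving(T(x)).
# A point (x, y) has x running along matrix columns and y along rows;
# pixel centres sit at (col - 1) * spacing, (row - 1) * spacing.

#' Create a 2D rigid transform
#'
#' Rotation about a centre followed by a translation:
#' \code{T(p) = c + R(theta) (p - c) + t}.
#'
#' @param angle_deg Rotation angle in degrees (counter-clockwise in the
#'   x-right / y-down pixel frame).
#' @param tx,ty Translation in mm.
#' @param cx,cy Centre of rotation in mm.
#' @return An object of class \code{c("rigid2d", "tf2d")}.
#' @export
rigid2d <- function(angle_deg = 0, tx = 0, ty = 0, cx = 0, cy = 0) {
  stopifnot(is.finite(angle_deg), is.finite(tx), is.finite(ty))
  structure(list(angle_deg = normalize_angle(angle_deg),
                 t = unname(c(tx, ty)), center = unname(c(cx, cy))),
            class = c("rigid2d", "tf2d"))
}

#' Create a 2D affine transform
#'
#' \code{T(p) = c + A (p - c) + t} with an invertible 2x2 matrix \code{A}.
#'
#' @param A 2x2 linear matrix.
#' @param t Translation, length-2 (mm).
#' @param center Centre, length-2 (mm).
#' @return An object of class \code{c("affine2d", "tf2d")}.
#' @export
affine2d <- function(A = diag(2), t = c(0, 0), center = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < 1e-12) stop("affine2d: matrix is singular")
  structure(list(A = A, t = unname(as.numeric(t)),
                 center = unname(as.numeric(center))),
            class = c("affine2d", "tf2d"))
}

normalize_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  if (identical(a, -180)) a <- 180
  a
}

rotmat <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Homogeneous 3x3 matrix of a rigid or affine transform
#' @param tf A \code{rigid2d} or \code{affine2d}.
#' @return 3x3 matrix acting on column vectors \code{(x, y, 1)}.
#' @export
tf_matrix <- function(tf) {
  if (inherits(tf, "rigid2d")) A <- rotmat(tf$angle_deg) else A <- tf$A
  c0 <- tf$center
  off <- c0 - A %*% c0 + tf$t
  rbind(cbind(A, off), c(0, 0, 1))
}

#' Build an affine transform from a 3x3 homogeneous matrix
#' @param M 3x3 matrix.
#' @return An \code{affine2d} with centre at the origin.
#' @export
affine_from_matrix <- function(M) {
  affine2d(A = M[1:2, 1:2], t = M[1:2, 3], center = c(0, 0))
}

#' Apply a transform to points
#'
#' @param tf A \code{tf2d} (rigid, affine, B-spline field, or
#'   \code{slice_chain} forward map).
#' @param x,y Numeric vectors of coordinates in mm.
#' @return \code{list(x =, y =)} of transformed coordinates.
#' @export
tf_apply <- function(tf, x, y) UseMethod("tf_apply")

#' @export
tf_apply.rigid2d <- function(tf, x, y) apply_linear(rotmat(tf$angle_deg), tf$t, tf$center, x, y)

#' @export
tf_apply.affine2d <- function(tf, x, y) apply_linear(tf$A, tf$t, tf$center, x, y)

apply_linear <- function(A, t, c0, x, y) {
  dx <- x - c0[1]; dy <- y - c0[2]
  list(x = A[1, 1] * dx + A[1, 2] * dy + c0[1] + t[1],
       y = A[2, 1] * dx + A[2, 2] * dy + c0[2] + t[2])
}

#' Invert a rigid or affine transform
#' @param tf Transform to invert.
#' @return Transform of the same family mapping in the opposite direction.
#' @export
tf_invert <- function(tf) UseMethod("tf_invert")

#' @export
tf_invert.rigid2d <- function(tf) {
  M <- solve(tf_matrix(tf))
  rigid_from_matrix(M)
}

#' @export
tf_invert.affine2d <- function(tf) affine_from_matrix(solve(tf_matrix(tf)))

rigid_from_matrix <- function(M) {
  ang <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  rigid2d(angle_deg = ang, tx = M[1, 3], ty = M[2, 3], cx = 0, cy = 0)
}

#' Compose two transforms
#'
#' Returns \code{a} composed with \code{b}: \code{(a \%o\% b)(p) = a(b(p))}.
#' Composition of two rigids is returned as a rigid; anything else involving
#' only rigid/affine as an affine.
#'
#' @param a,b Rigid or affine transforms.
#' @return Composed transform.
#' @export
tf_compose <- function(a, b) {
  M <- tf_matrix(a) %*% tf_matrix(b)
  if (inherits(a, "rigid2d") && inherits(b, "rigid2d")) rigid_from_matrix(M)
  else affine_from_matrix(M)
}

#' Rotation angle of the linear part of a transform
#'
#' Extracts the rotation component via the polar decomposition of the
#' 2x2 linear part (rotation of the closest rotation+scale map), in degrees.
#' Used to compare a recovered composite map with a ground-truth similarity.
#'
#' @param tf Rigid or affine transform.
#' @return Angle in degrees in (-180, 180].
#' @export
tf_rotation_deg <- function(tf) {
  A <- tf_matrix(tf)[1:2, 1:2]
  s <- svd(A)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { # reflection present; report rotation of the flip-corrected map
    s$v[, 2] <- -s$v[, 2]
    R <- s$u %*% t(s$v)
  }
  normalize_angle(atan2(R[2, 1], R[1, 1]) * 180 / pi)
}

# ---------------------------------------------------------------------------
# Cubic B-spline free-form deformation field

# Cubic B-spline basis values for fractional offsets u in [0, 1): weights for
# control points i-1, i, i+1, i+2 where i = floor(t), u = t - i.
bspline3_weights <- function(u) {
  u2 <- u * u; u3 <- u2 * u
  cbind((1 - 3 * u + 3 * u2 - u3) / 6,
        (4 - 6 * u2 + 3 * u3) / 6,
        (1 + 3 * u + 3 * u2 - 3 * u3) / 6,
        u3 / 6)
}

# Derivatives of the four basis weights with respect to t.
bspline3_dweights <- function(u) {
  u2 <- u * u
  cbind(-(1 - 2 * u + u2) / 2,
        (-4 * u + 3 * u2) / 2,
        (1 + 2 * u - 3 * u2) / 2,
        u2 / 2)
}

#' Create a free-form B-spline displacement field
#'
#' A tensor-product cubic B-spline over a regular control-point mesh covering
#' the rectangle \code{[0, domain[1]] x [0, domain[2]]} (mm) of the fixed
#' image. The transform is \code{T(p) = p + u(p)} where \code{u} interpolates
#' the control-point displacements. Zero control points give the identity map.
#'
#' @param mesh Number of mesh cells along (x, y); control grid is
#'   \code{mesh + 3} per axis (cubic support).
#' @param domain Physical extent (mm) along (x, y).
#' @param cpx,cpy Control-point displacement matrices, \code{(mesh[2]+3) x
#'   (mesh[1]+3)} (rows index y), in mm. Default zero.
#' @return Object of class \code{c("bspline2d", "tf2d")}.
#' @export
bspline2d <- function(mesh, domain, cpx = NULL, cpy = NULL) {
  mesh <- rep(as.integer(mesh), length.out = 2)
  stopifnot(all(mesh >= 1), all(domain > 0))
  nr <- mesh[2] + 3L; nc <- mesh[1] + 3L
  if (is.null(cpx)) cpx <- matrix(0, nr, nc)
  if (is.null(cpy)) cpy <- matrix(0, nr, nc)
  stopifnot(all(dim(cpx) == c(nr, nc)), all(dim(cpy) == c(nr, nc)))
  structure(list(mesh = mesh, domain = as.numeric(domain),
                 cpx = cpx, cpy = cpy),
            class = c("bspline2d", "tf2d"))
}

# Evaluate the displacement at arbitrary points (mm). Points outside the
# domain take the clamped-edge field value.
bspline_displacement <- function(tf, x, y) {
  cellx <- tf$domain[1] / tf$mesh[1]
  celly <- tf$domain[2] / tf$mesh[2]
  txc <- pmin(pmax(x / cellx, 0), tf$mesh[1] - 1e-9)
  tyc <- pmin(pmax(y / celly, 0), tf$mesh[2] - 1e-9)
  ix <- floor(txc); iy <- floor(tyc)
  wx <- bspline3_weights(txc - ix)
  wy <- bspline3_weights(tyc - iy)
  ux <- numeric(length(x)); uy <- numeric(length(x))
  nr <- nrow(tf$cpx)
  for (a in 1:4) {
    for (b in 1:4) {
      idx <- (iy + a) + nr * (ix + b - 1)  # control (iy+a-1+1, ix+b-1+1), 1-based
      w <- wy[, a] * wx[, b]
      ux <- ux + w * tf$cpx[idx]
      uy <- uy + w * tf$cpy[idx]
    }
  }
  list(x = ux, y = uy)
}

#' @export
tf_apply.bspline2d <- function(tf, x, y) {
  u <- bspline_displacement(tf, x, y)
  list(x = x + u$x, y = y + u$y)
}

#' Invert a B-spline map at given points
#'
#' Solves \code{p + u(p) = q} for \code{p} by fixed-point iteration
#' \code{p <- q - u(p)}.
#'
#' @param tf A \code{bspline2d}.
#' @param x,y Target coordinates (mm).
#' @param tol Convergence tolerance in mm.
#' @param max_iter Iteration cap.
#' @return \code{list(x, y, converged)} where \code{converged} is a logical
#'   vector per point.
#' @export
bspline_invert_points <- function(tf, x, y, tol = 0.04, max_iter = 50) {
  px <- x; py <- y
  for (k in seq_len(max_iter)) {
    u <- bspline_displacement(tf, px, py)
    nx <- x - u$x; ny <- y - u$y
    delta <- pmax(abs(nx - px), abs(ny - py))
    px <- nx; py <- ny
    if (max(delta) < tol) break
  }
  u <- bspline_displacement(tf, px, py)
  err <- sqrt((px + u$x - x)^2 + (py + u$y - y)^2)
  list(x = px, y = py, converged = err < 10 * tol + 1e-6)
}

# Basis matrices for all points of a regular image grid: B such that the
# dense field is  U = By %*% CP %*% t(Bx)  (rows = image rows). Returned as
# sparse-in-structure dense matrices (small control counts keep this cheap).
bspline_basis_matrix <- function(n_pix, spacing, n_cells, extent) {
  coord <- (seq_len(n_pix) - 1) * spacing
  cell <- extent / n_cells
  tt <- pmin(pmax(coord / cell, 0), n_cells - 1e-9)
  i0 <- floor(tt)
  W <- bspline3_weights(tt - i0)
  B <- matrix(0, n_pix, n_cells + 3)
  for (b in 1:4) B[cbind(seq_len(n_pix), i0 + b)] <- W[, b]
  B
}
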