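## Cubic tensor-product B-spline deformation fields.  A field stores the
## *absolute* target position g(x, y) = sum_kl C_kl B3(x/sx - k) B3(y/sy - l)
## with knots k = -1 .. K+1 (K = ceiling((W-1)/sx)), so the coefficient grid
## is (L+3) x (K+3) per component; the identity field has C_kl = (k sx, l sy)
## exactly (cubic B-splines reproduce linear functions).  Coefficient
## matrices cx, cy are indexed [l, k] (rows follow y).

n_knots <- function(extent, spacing) ceiling((extent - 1) / spacing) + 3L

#' Create an identity B-spline deformation field
#'
#' @param width,height domain size in pixels.
#' @param sx,sy control-point spacings in pixels.
#' @return object of class `bspline_field`.
#' @export
identity_field <- function(width, height, sx, sy = sx) {
  nk <- n_knots(width, sx); nl <- n_knots(height, sy)
  kx <- (seq_len(nk) - 2) * sx     # knot k = -1 .. K+1
  ly <- (seq_len(nl) - 2) * sy
  structure(list(cx = matrix(rep(kx, each = nl), nl, nk),
                 cy = matrix(rep(ly, nk), nl, nk),
                 sx = sx, sy = sy, width = width, height = height),
            class = "bspline_field")
}

#' @export
print.bspline_field <- function(x, ...) {
  cat(sprintf("<bspline_field> %d x %d domain, spacing (%g, %g), %d x %d coefficients\n",
              x$width, x$height, x$sx, x$sy, nrow(x$cx), ncol(x$cx)))
  invisible(x)
}

#' Evaluate a deformation field at points
#'
#' @param f a `bspline_field`.
#' @param points n x 2 matrix of (x, y) coordinates inside the domain.
#' @return n x 2 matrix of mapped (x, y) positions.
#' @export
eval_field <- function(f, points) {
  points <- rbind(points)
  if (any(points[, 1] < 0 | points[, 1] > f$width - 1 |
          points[, 2] < 0 | points[, 2] > f$height - 1))
    stop_data("domain error: point outside field domain")
  cpp_field_eval_points(f$cx, f$cy, f$sx, f$sy, points[, 1], points[, 2])
}

field_grid <- function(f) cpp_field_grid(f$cx, f$cy, f$sx, f$sy, f$width, f$height)

#' Displacement statistics of a field
#'
#' Mean Euclidean geometric distance `||g(x,y) - (x,y)||` over all domain
#' pixels: the quantity the validation model thresholds against alpha.
#'
#' @param f a `bspline_field`.
#' @return mean displacement in pixels.
#' @export
mean_deformation <- function(f) {
  cpp_mean_deformation(f$cx, f$cy, f$sx, f$sy, f$width, f$height)
}

#' Warp an image through a deformation field
#'
#' Backward warping: `out(x, y) = img(g(x, y))` with bilinear sampling;
#' samples outside the source domain are black (0).
#'
#' @param img gray matrix or RGB array whose shape matches the field domain.
#' @param f a `bspline_field`.
#' @return warped image of the same mode.
#' @export
warp_image <- function(img, f) {
  if (img_height(img) != f$height || img_width(img) != f$width)
    stop_data("domain error: field/image shape mismatch")
  g <- field_grid(f)
  if (img_mode(img) == "gray") return(cpp_warp_bilinear(img, g$gx, g$gy))
  out <- img
  for (c in 1:3) out[, , c] <- cpp_warp_bilinear(img[, , c], g$gx, g$gy)
  out
}

# Least-squares fit of a B-spline field to target maps vx, vy (H x W).
# The tensor-product design factorizes, so the normal equations solve
# per axis; a tiny ridge keeps edge knots (with little support inside the
# domain) well-conditioned.
fit_field <- function(vx, vy, sx, sy = sx, lambda = 1e-6) {
  H <- nrow(vx); W <- ncol(vx)
  nk <- n_knots(W, sx); nl <- n_knots(H, sy)
  Bx <- outer(0:(W - 1), seq_len(nk) - 2, function(x, k) bspline3((x / sx) - k))
  By <- outer(0:(H - 1), seq_len(nl) - 2, function(y, l) bspline3((y / sy) - l))
  # second-difference penalty: fixes the weakly determined edge knots
  # without biasing them (linear/affine coefficient patterns lie in its
  # null space, so affine maps are reproduced exactly)
  d2 <- function(n) if (n < 3) matrix(0, 0, n) else
    diff(diag(n), differences = 2)
  Dx <- d2(nk); Dy <- d2(nl)
  Ax <- solve(crossprod(Bx) + lambda * crossprod(Dx) + diag(1e-10, nk))
  Ay <- solve(crossprod(By) + lambda * crossprod(Dy) + diag(1e-10, nl))
  proj <- function(V) Ay %*% crossprod(By, V) %*% Bx %*% Ax
  structure(list(cx = proj(vx), cy = proj(vy), sx = sx, sy = sy,
                 width = W, height = H),
            class = "bspline_field")
}

#' Cubic B-spline basis function
#'
#' @param t evaluation points; support is `|t| < 2`.
#' @return basis values.
#' @export
bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Refit a field computed as x -> fun(x) on the full pixel grid.
refit_field_fun <- function(fun, width, height, sx, sy = sx) {
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), width), height, width)
  v <- fun(as.vector(xs), as.vector(ys))
  fit_field(matrix(v[, 1], height, width), matrix(v[, 2], height, width), sx, sy)
}

# evaluate a field at arbitrary points, extending it outside the domain by
# the displacement at the nearest boundary point (identity + edge
# displacement), so compositions stay well-behaved near the border
eval_field_extended <- function(f, pts) {
  qx <- pmin(pmax(pts[, 1], 0), f$width - 1)
  qy <- pmin(pmax(pts[, 2], 0), f$height - 1)
  v <- eval_field(f, cbind(qx, qy))
  v + (pts - cbind(qx, qy))
}

#' Compose a global transform with a B-spline field
#'
#' Returns a field whose evaluation equals `f(T(x))` at every pixel,
#' refitted on the same control grid (where `T(x)` leaves the domain, `f`
#' is extended by its boundary displacement).  For affine `T` the
#' composition is exact up to the refit tolerance (cubic B-splines
#' reproduce affine maps).
#'
#' @param T a `global_transform` (see [ransac_transform()]).
#' @param f a `bspline_field`.
#' @return a `bspline_field` on the same grid.
#' @export
compose_with_global <- function(T, f) {
  A <- T$matrix
  refit_field_fun(function(x, y)
    eval_field_extended(f, cbind(A[1, 1] * x + A[1, 2] * y + A[1, 3],
                                 A[2, 1] * x + A[2, 2] * y + A[2, 3])),
    f$width, f$height, f$sx, f$sy)
}

# field from an affine map (2x3 matrix), exact for B-splines
field_from_affine <- function(A, width, height, sx, sy = sx) {
  refit_field_fun(function(x, y)
    cbind(A[1, 1] * x + A[1, 2] * y + A[1, 3],
          A[2, 1] * x + A[2, 2] * y + A[2, 3]),
    width, height, sx, sy)
}

# resample a field onto a domain scaled by `s` (coordinates multiply by s):
# g'(x) = s * g(x / s), refit with spacing sx_new.
rescale_field <- function(f, s, width, height, sx, sy = sx) {
  refit_field_fun(function(x, y)
    s * eval_field_extended(f, cbind(x / s, y / s)),
    width, height, sx, sy)
}
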