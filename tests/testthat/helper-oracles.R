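options(stackreg.quiet = TRUE)

# ---- independent oracles (deliberately naive implementations) -------------

# brute-force tensor-product B-spline sum over ALL coefficients
bf_eval_field <- function(f, x, y) {
  nk <- ncol(f$cx); nl <- nrow(f$cx)
  gx <- 0; gy <- 0
  for (k in seq_len(nk)) for (l in seq_len(nl)) {
    w <- bspline3(x / f$sx - (k - 2)) * bspline3(y / f$sy - (l - 2))
    gx <- gx + f$cx[l, k] * w
    gy <- gy + f$cy[l, k] * w
  }
  c(gx, gy)
}

# per-pixel mean displacement by explicit loop
bf_mean_deformation <- function(f) {
  acc <- 0
  for (x in 0:(f$width - 1)) for (y in 0:(f$height - 1)) {
    g <- bf_eval_field(f, x, y)
    acc <- acc + sqrt((g[1] - x)^2 + (g[2] - y)^2)
  }
  acc / (f$width * f$height)
}

# cumulative-sum loop for the saturation bounds
bf_saturation_bounds <- function(hist, p_low, p_high) {
  n <- sum(hist)
  x_low <- NA
  for (l in 0:255) if (sum(hist[1:(l + 1)]) > p_low * n) { x_low <- l; break }
  x_high <- NA
  for (l in 255:0) if (sum(hist[(l + 1):256]) > p_high * n) { x_high <- l; break }
  c(x_low, max(x_high, x_low))
}

# set-enumeration pair accuracy on plain matrices (no hole filling:
# callers supply images whose foreground has no enclosed holes)
bf_pair_accuracy <- function(a, b, t) {
  M <- (a > 0) & (b > 0)
  wi <- which(M & (a >= t)); wj <- which(M & (b >= t))
  if (length(wi) == 0) return(if (length(wj) > 0) 0 else 1)
  length(intersect(wi, wj)) / length(wi)
}

# ---- shared fixtures ------------------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

texture128 <- function() {
  if (is.null(.fixture_cache$t128))
    .fixture_cache$t128 <- generate_base_texture(128, seed = 11)
  .fixture_cache$t128
}
texture256 <- function() {
  if (is.null(.fixture_cache$t256))
    .fixture_cache$t256 <- generate_base_texture(256, seed = 11)
  .fixture_cache$t256
}

rand_img <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, h * w, TRUE), h, w) * 1.0
}

rand_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, TRUE), c(h, w, 3)) * 1.0
}

shift_image <- function(img, dx, dy) {
  f <- identity_field(ncol(img), nrow(img), 16)
  f$cx <- f$cx + dx; f$cy <- f$cy + dy
  warp_image(img, f)
}

displacement_grid <- function(f) {
  g <- stackreg:::field_grid(f)
  xs <- matrix(rep(0:(f$width - 1), each = f$height), f$height, f$width)
  ys <- matrix(rep(0:(f$height - 1), f$width), f$height, f$width)
  list(ux = g$gx - xs, uy = g$gy - ys)
}
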