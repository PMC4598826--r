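## Synthetic deformed-sequence generator: one textured base section is
## duplicated n times and every copy (except the first) is independently
## warped by a random smooth B-spline field on a black background.  Ground
## truth fields are retained so registration can also be judged by endpoint
## error, not only by the overlap score.

#' Generate a deterministic tissue-like base texture
#'
#' A band-passed Gaussian random field restricted to an elliptical
#' foreground on black: mid-gray ridged texture with the brightest 20% of
#' the foreground lifted above 200 (blob-like "white" structures for the
#' accuracy metric), and a black frame of at least 8 px.
#'
#' @param size image side in pixels (square, >= 128).
#' @param seed RNG seed.
#' @return gray matrix in \[0, 255\].
#' @export
generate_base_texture <- function(size = 512, seed = 0) {
  if (size < 128) stop_usage("base texture needs size >= 128")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  noise <- matrix(rnorm(size * size), size, size)
  band <- cpp_gaussian_blur(noise, size / 128) - cpp_gaussian_blur(noise, size / 42)
  cx <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1), each = size), size, size)
  ys <- matrix(rep(0:(size - 1), size), size, size)
  a <- (size / 2) - 12 # semi-axes keep a black frame of >= 8 px
  b <- 0.82 * a
  inside <- ((xs - cx) / a)^2 + ((ys - cx) / b)^2 <= 1
  v <- band[inside]
  lo <- quantile(v, 0.02); mid <- quantile(v, 0.80); hi <- quantile(v, 0.999)
  img <- matrix(0, size, size)
  base_val <- 30 + 130 * pmin(pmax((band - lo) / (mid - lo), 0), 0.999)
  bright <- band > mid
  bright_val <- 200 + 55 * pmin(pmax((band - mid) / (hi - mid), 0), 1)
  img[inside] <- ifelse(bright[inside], bright_val[inside], base_val[inside])
  round(img)
}

#' Random smooth B-spline deformation field
#'
#' Control-point displacements are drawn i.i.d. Gaussian and globally
#' rescaled so the mean geometric displacement over the domain equals
#' `magnitude` exactly; `smoothness` is the control-point spacing.
#'
#' @param width,height domain size.
#' @param magnitude target mean displacement, pixels (0 gives the exact
#'   identity field).
#' @param smoothness control spacing, pixels.
#' @param seed RNG seed.
#' @return a `bspline_field`.
#' @export
random_field <- function(width, height = width, magnitude = 8, smoothness = 48,
                         seed = 0) {
  if (magnitude < 0) stop_usage("magnitude must be >= 0")
  f <- identity_field(width, height, smoothness)
  if (magnitude == 0) return(f)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  dx <- matrix(rnorm(length(f$cx)), nrow(f$cx), ncol(f$cx))
  dy <- matrix(rnorm(length(f$cy)), nrow(f$cy), ncol(f$cy))
  g <- f; g$cx <- f$cx + dx; g$cy <- f$cy + dy
  # displacement is linear in the coefficient perturbation, so one global
  # rescale sets the mean geometric displacement exactly
  s <- magnitude / mean_deformation(g)
  g$cx <- f$cx + s * dx
  g$cy <- f$cy + s * dy
  g
}

#' Generate a synthetic deformed serial sequence
#'
#' Section 0 is the undeformed base (identity truth field); sections
#' 1..n-1 are the base warped by independent [random_field()]s, all on a
#' black background.  Deterministic per seed.
#'
#' @param n number of sections (>= 2; the reference construction uses 10).
#' @param size image side in pixels.
#' @param magnitude target mean displacement per deformed section, pixels.
#' @param smoothness deformation control spacing, pixels.
#' @param seed master seed; per-section seeds are derived from it.
#' @param base optional user-supplied base image (gray matrix); defaults to
#'   [generate_base_texture()].
#' @return list of class `synthetic_sequence`: `stack`, `truth_fields`,
#'   `spec`.
#' @export
generate_sequence <- function(n = 10, size = 512, magnitude = 8,
                              smoothness = 48, seed = 0, base = NULL) {
  if (n < 2) stop_usage("need n >= 2 sections")
  if (is.null(base)) base <- generate_base_texture(size, seed)
  H <- nrow(base); W <- ncol(base)
  fields <- vector("list", n)
  sections <- vector("list", n)
  fields[[1]] <- identity_field(W, H, smoothness)
  sections[[1]] <- base
  for (i in 2:n) {
    fields[[i]] <- random_field(W, H, magnitude, smoothness,
                                seed = seed * 1000 + i)
    sections[[i]] <- warp_image(base, fields[[i]])
  }
  structure(list(stack = section_stack(sections),
                 truth_fields = fields,
                 spec = list(n = n, size = size, magnitude = magnitude,
                             smoothness = smoothness, seed = seed)),
            class = "synthetic_sequence")
}
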