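## Data normalization (percentile saturation stretch) and stain color
## deconvolution in optical-density space.  The eosin concentration channel
## of H&E sections (or the normalized image itself for grayscale data) is
## the "feature image" that both the keypoint matcher and the elastic
## refinement operate on.

#' 256-bin intensity histogram of a single-channel image
#'
#' @param img single-channel matrix, values in \[0, 255\].
#' @return integer vector of length 256; element `x + 1` counts pixels with
#'   intensity level `x`.
#' @export
channel_histogram <- function(img) {
  tabulate(as.integer(round(img)) + 1L, nbins = 256L)
}

#' Saturation bounds of a histogram
#'
#' `x_low` is the smallest level whose cumulative count (from 0 up to and
#' including it) strictly exceeds `p_low * n`; `x_high` the largest level
#' whose cumulative count from it upward strictly exceeds `p_high * n`.
#' Saturating a small fixed percentage at both ends excludes extreme pixel
#' values that are not representative of the tissue content.
#'
#' @param hist 256-bin count vector.
#' @param p_low,p_high saturated fractions in \[0, 0.5).
#' @return list with `x_low`, `x_high`, `p_low`, `p_high`.
#' @export
saturation_bounds <- function(hist, p_low = 0.01, p_high = 0.01) {
  n <- sum(hist)
  if (n <= 0) stop_data("empty histogram")
  if (p_low < 0 || p_low >= 0.5 || p_high < 0 || p_high >= 0.5)
    stop_usage("saturation fractions must lie in [0, 0.5)")
  lo_cum <- cumsum(hist)
  hi_cum <- rev(cumsum(rev(hist)))
  x_low <- which(lo_cum > p_low * n)[1] - 1L
  x_high <- tail(which(hi_cum > p_high * n), 1) - 1L
  x_high <- max(x_high, x_low)
  list(x_low = x_low, x_high = x_high, p_low = p_low, p_high = p_high)
}

#' Linear contrast stretch of one channel
#'
#' Maps `x_low -> 0` and `x_high -> 255` linearly, rounding and clamping to
#' \[0, 255\].  A constant channel (`x_low == x_high`) maps to all zeros: it
#' carries no registration signal and is kept in the background.
#'
#' @param img single-channel matrix.
#' @param b bounds from [saturation_bounds()].
#' @return stretched matrix.
#' @export
stretch_channel <- function(img, b) {
  if (b$x_high == b$x_low) return(img * 0)
  clamp255(round(255 * (img - b$x_low) / (b$x_high - b$x_low)))
}

#' Histogram-based brightness/contrast normalization
#'
#' Each channel is independently stretched between its own saturation
#' bounds, reducing stain variation across sections before feature
#' extraction.
#'
#' @param img gray matrix or RGB array.
#' @param p_low,p_high saturated fractions (default 1\% each end).
#' @return normalized image of the same mode.
#' @export
normalize_image <- function(img, p_low = 0.01, p_high = 0.01) {
  one <- function(ch) stretch_channel(ch, saturation_bounds(channel_histogram(ch), p_low, p_high))
  if (img_mode(img) == "gray") return(one(img))
  out <- img
  for (c in 1:3) out[, , c] <- one(img[, , c])
  out
}

#' RGB to optical density
#'
#' `od_c = -log10(max(v_c, 1) / 255)` per channel; stain amounts mix
#' linearly in OD space.  White (255) maps to OD 0; a zero channel is
#' clamped to 1 before the log so the OD stays finite.
#'
#' @param img RGB array.
#' @return H x W x 3 array of optical densities (>= 0).
#' @export
rgb_to_od <- function(img) {
  if (img_mode(img) != "rgb") stop_data("rgb_to_od needs an RGB image")
  -log10(pmax(img, 1) / 255)
}

#' Build a row-normalized stain matrix
#'
#' Rows 1-2 are the unit-normalized OD vectors of the two stains; row 3 is
#' the residual channel: the cross product of rows 1-2 with negative
#' components zeroed, renormalized.  Rows are stains, columns are the OD
#' detected in R, G, B.
#'
#' @param stain1_od,stain2_od nonnegative, non-parallel OD triples.
#' @param names row names (default hematoxylin / eosin / residual).
#' @return 3 x 3 matrix of class `stain_matrix`.
#' @export
build_stain_matrix <- function(stain1_od, stain2_od,
                               names = c("hematoxylin", "eosin", "residual")) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop_data("degenerate stain system: zero stain vector")
    v / n
  }
  r1 <- unit(stain1_od); r2 <- unit(stain2_od)
  cr <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  if (sqrt(sum(cr^2)) < 1e-9) stop_data("degenerate stain system: parallel stains")
  r3 <- pmax(cr, 0)                      # residual: nonnegative part of the normal
  if (sum(r3^2) < 1e-12) r3 <- pmax(-cr, 0)
  r3 <- unit(r3)
  M <- rbind(r1, r2, r3)
  rownames(M) <- names
  colnames(M) <- c("od_red", "od_green", "od_blue")
  if (abs(det(M)) < 1e-9) stop_data("degenerate stain system: singular matrix")
  class(M) <- c("stain_matrix", class(M))
  M
}

#' Default H&E stain matrix
#'
#' The widely published hematoxylin/eosin OD vectors; override via
#' `stains.hematoxylin` / `stains.eosin` in the configuration when the
#' slide's color system is known.
#' @return a `stain_matrix`.
#' @export
default_stain_matrix <- function() {
  build_stain_matrix(c(0.650, 0.704, 0.286), c(0.072, 0.990, 0.105))
}

#' Stain deconvolution
#'
#' With `C` the per-pixel stain amounts and `M` the row-normalized stain
#' matrix, the forward model is `OD = t(M) %*% C`; deconvolution inverts it,
#' `C = solve(t(M)) %*% OD`.
#'
#' @param img RGB array.
#' @param M a `stain_matrix`.
#' @return list with `concentrations` (H x W x 3 raw float stain amounts)
#'   and `channels` (list of three 8-bit min-max rescaled matrices, one per
#'   stain row).
#' @export
deconvolve <- function(img, M) {
  od <- rgb_to_od(img)
  H <- dim(od)[1]; W <- dim(od)[2]
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  Minv <- tryCatch(solve(t(unclass(M))),
                   error = function(e) stop_data("degenerate stain system: singular matrix"))
  C <- Minv %*% odm
  conc <- array(0, dim = c(H, W, 3L))
  channels <- vector("list", 3L)
  for (s in 1:3) {
    m <- matrix(C[s, ], H, W)
    conc[, , s] <- m
    rng <- range(m)
    span <- rng[2] - rng[1]
    channels[[s]] <- if (span < 1e-12) m * 0 else round(255 * (m - rng[1]) / span)
  }
  names(channels) <- rownames(M)
  list(concentrations = conc, channels = channels)
}

# forward OD rendering used by the deconvolution round-trip tests
render_od_image <- function(conc, M) {
  H <- dim(conc)[1]; W <- dim(conc)[2]
  Cm <- rbind(as.vector(conc[, , 1]), as.vector(conc[, , 2]), as.vector(conc[, , 3]))
  od <- t(unclass(M)) %*% Cm
  img <- array(0, dim = c(H, W, 3L))
  for (c in 1:3) img[, , c] <- matrix(round(255 * 10^(-od[c, ])), H, W)
  clamp255(img)
}

#' Extract the feature image used for registration
#'
#' RGB sections are deconvolved and the configured stain channel (eosin by
#' default: eosinophilic, protein-rich structures) is returned; grayscale
#' sections pass through unchanged.  RGB input with `channel = "luminance"`
#' (or a missing stain matrix) falls back to the intensity maximum.
#'
#' @param img a *normalized* image (see [normalize_image()]).
#' @param M a `stain_matrix`, or `NULL`.
#' @param channel `"eosin"`, `"hematoxylin"` or `"luminance"`.
#' @return list with `pixels` (8-bit matrix) and `provenance`.
#' @export
extract_feature_image <- function(img, M = default_stain_matrix(),
                                  channel = c("eosin", "hematoxylin", "luminance")) {
  channel <- match.arg(channel)
  if (img_mode(img) == "gray")
    return(list(pixels = img, provenance = "gray_normalized"))
  if (is.null(M) || channel == "luminance") {
    if (is.null(M) && channel != "luminance")
      log_info("no stain matrix supplied; falling back to luminance features")
    return(list(pixels = img_intensity(img), provenance = "luminance"))
  }
  dec <- deconvolve(img, M)
  list(pixels = dec$channels[[channel]], provenance = paste0(channel, "_channel"))
}
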