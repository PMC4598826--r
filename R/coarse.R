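## Feature-based coarse global registration: difference-of-Gaussian
## interest points with gradient descriptors, Lowe-ratio matching with a
## symmetric cross-check, and RANSAC geometric consensus.

#' Detect difference-of-Gaussian keypoints
#'
#' Local extrema of the DoG scale space above a contrast threshold, with
#' edge responses suppressed by the Hessian trace/determinant ratio test;
#' each keypoint carries a dominant orientation and a 128-d unit gradient
#' descriptor.  Deterministic for fixed input and parameters.
#'
#' @param feature a feature image (list with `pixels`, from
#'   [extract_feature_image()]) or a plain matrix in \[0, 255\].
#' @param nspo scales per octave.
#' @param sigma0 base scale in pixels.
#' @param contrast DoG contrast threshold (on intensities scaled to \[0,1\]).
#' @param edge_r edge-response ratio limit.
#' @param max_keypoints hard cap.
#' @return list with `points` (n x 4: x, y, scale, orientation) and
#'   `descriptors` (n x 128, unit rows).
#' @export
detect_keypoints <- function(feature, nspo = 3, sigma0 = 1.6, contrast = 0.015,
                             edge_r = 10, max_keypoints = 5000) {
  img <- if (is.list(feature)) feature$pixels else feature
  if (img_height(img) < 32 || img_width(img) < 32)
    stop_data("insufficient extent: keypoint detection needs at least 32 x 32")
  cpp_detect_dog(img, as.integer(nspo), sigma0, contrast, edge_r,
                 as.integer(max_keypoints))
}

#' Match keypoint descriptors
#'
#' Nearest-neighbor descriptor matches passing the Lowe ratio test
#' (nearest / second-nearest Euclidean distance < `ratio`), kept only when
#' mutual (symmetric cross-check).
#'
#' @param k1,k2 keypoint sets from [detect_keypoints()].
#' @param ratio Lowe ratio threshold.
#' @return list of class `correspondence_set`: `p1`, `p2` (n x 2 positions),
#'   `distance`, `inlier_mask` (filled by [ransac_transform()]).
#' @export
match_descriptors <- function(k1, k2, ratio = 0.8) {
  n1 <- nrow(k1$points); n2 <- nrow(k2$points)
  if (n1 == 0 || n2 == 0) stop_data("no features")
  # squared Euclidean distances between unit descriptors
  D <- 2 - 2 * tcrossprod(k1$descriptors, k2$descriptors)
  D[D < 0] <- 0
  nn12 <- apply(D, 1, which.min)
  nn21 <- apply(D, 2, which.min)
  best <- D[cbind(seq_len(n1), nn12)]
  second <- vapply(seq_len(n1), function(i) {
    row <- D[i, ]; row[nn12[i]] <- Inf
    min(row)
  }, numeric(1))
  pass <- sqrt(best) < ratio * sqrt(pmax(second, 1e-300)) &
    nn21[nn12] == seq_len(n1)
  idx <- which(pass)
  structure(list(p1 = k1$points[idx, 1:2, drop = FALSE],
                 p2 = k2$points[nn12[idx], 1:2, drop = FALSE],
                 distance = sqrt(best[idx]),
                 inlier_mask = rep(NA, length(idx))),
            class = "correspondence_set")
}

min_sample <- function(model_class) {
  switch(model_class, translation = 1L, rigid = 2L, similarity = 2L, affine = 3L,
         stop_usage(paste0("unknown model class: ", model_class)))
}

# Exact / least-squares fits p -> q for each model class; p, q are n x 2.
fit_transform <- function(p, q, model_class) {
  n <- nrow(p)
  if (model_class == "translation") {
    t <- colMeans(q) - colMeans(p)
    return(cbind(diag(2), t))
  }
  if (model_class %in% c("rigid", "similarity")) {
    pc <- colMeans(p); qc <- colMeans(q)
    P <- sweep(p, 2, pc); Q <- sweep(q, 2, qc)
    if (model_class == "similarity") {
      # complex-plane regression: q = a p + b
      zp <- complex(real = P[, 1], imaginary = P[, 2])
      zq <- complex(real = Q[, 1], imaginary = Q[, 2])
      den <- sum(Mod(zp)^2)
      if (den < 1e-12) return(NULL)
      a <- sum(zq * Conj(zp)) / den
      R <- matrix(c(Re(a), Im(a), -Im(a), Re(a)), 2, 2)
    } else {
      # Kabsch: R = V diag(1, det(VU')) U' from svd(P'Q) = U D V'
      S <- crossprod(P, Q)
      sv <- svd(S)
      d <- sign(det(sv$v %*% t(sv$u)))
      R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    }
    t <- qc - as.vector(R %*% pc)
    return(cbind(R, t))
  }
  # affine: solve two 3-unknown least-squares systems
  X <- cbind(p, 1)
  A <- tryCatch(solve(crossprod(X), crossprod(X, q)), error = function(e) NULL)
  if (is.null(A)) return(NULL)
  t(A) # 2 x 3
}

transform_points <- function(A, p) {
  cbind(A[1, 1] * p[, 1] + A[1, 2] * p[, 2] + A[1, 3],
        A[2, 1] * p[, 1] + A[2, 2] * p[, 2] + A[2, 3])
}

#' RANSAC geometric consensus
#'
#' Repeated minimal-sample hypotheses with inlier counting (residual
#' strictly below `inlier_tol`), followed by a least-squares refit on the
#' winning inlier set.  Seeded and bit-reproducible; the caller's RNG state
#' is left untouched.
#'
#' @param corr a `correspondence_set` from [match_descriptors()].
#' @param model_class `"translation"`, `"rigid"`, `"similarity"` or `"affine"`.
#' @param inlier_tol inlier residual threshold in pixels.
#' @param max_iters number of random hypotheses.
#' @param seed RNG seed.
#' @return list of class `global_transform`: `matrix` (2 x 3, mapping source
#'   (x, y, 1) to target), `model_class`, `inliers` (logical), `mean_residual`.
#' @export
ransac_transform <- function(corr, model_class = "similarity", inlier_tol = 3,
                             max_iters = 2000, seed = 0) {
  m <- min_sample(model_class)
  p <- corr$p1; q <- corr$p2
  n <- nrow(p)
  if (is.null(n) || n < m) stop_data("coarse registration failed: too few correspondences")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  best_inl <- rep(FALSE, n); best_count <- -1L; best_res <- Inf
  for (it in seq_len(max_iters)) {
    s <- if (n == m) seq_len(n) else sample.int(n, m)
    A <- fit_transform(p[s, , drop = FALSE], q[s, , drop = FALSE], model_class)
    if (is.null(A) || any(!is.finite(A))) next
    r <- sqrt(rowSums((transform_points(A, p) - q)^2))
    inl <- r < inlier_tol
    cnt <- sum(inl)
    mres <- if (cnt > 0) mean(r[inl]) else Inf
    if (cnt > best_count || (cnt == best_count && mres < best_res)) {
      best_count <- cnt; best_inl <- inl; best_res <- mres
    }
    if (n == m) break
  }
  if (best_count < max(3L, m)) stop_data("coarse registration failed: no consensus")
  A <- fit_transform(p[best_inl, , drop = FALSE], q[best_inl, , drop = FALSE], model_class)
  if (is.null(A) || any(!is.finite(A)))
    stop_data("coarse registration failed: degenerate refit")
  r <- sqrt(rowSums((transform_points(A, p) - q)^2))
  inl <- r < inlier_tol
  if (!any(inl)) inl <- best_inl
  structure(list(matrix = A, model_class = model_class,
                 inliers = inl, mean_residual = mean(r[inl])),
            class = "global_transform")
}

#' Identity global transform
#' @return a `global_transform` with the identity matrix.
#' @export
identity_transform <- function() {
  structure(list(matrix = cbind(diag(2), c(0, 0)), model_class = "identity",
                 inliers = logical(0), mean_residual = 0),
            class = "global_transform")
}

invert_affine <- function(A) {
  L <- A[, 1:2]
  Li <- solve(L)
  cbind(Li, -Li %*% A[, 3])
}

#' Apply a global transform to an image
#'
#' `T` maps source to target coordinates; the output lives in the target
#' frame and is produced by backward warping (`out(x) = img(T^{-1} x)`) with
#' bilinear interpolation, out-of-domain samples black.
#'
#' @param img gray matrix or RGB array.
#' @param T a `global_transform`.
#' @return warped image, same shape.
#' @export
apply_global <- function(img, T) {
  Ai <- invert_affine(T$matrix)
  H <- img_height(img); W <- img_width(img)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  gx <- Ai[1, 1] * xs + Ai[1, 2] * ys + Ai[1, 3]
  gy <- Ai[2, 1] * xs + Ai[2, 2] * ys + Ai[2, 3]
  if (img_mode(img) == "gray") return(cpp_warp_bilinear(img, gx, gy))
  out <- img
  for (c in 1:3) out[, , c] <- cpp_warp_bilinear(img[, , c], gx, gy)
  out
}
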