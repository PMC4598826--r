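test_that("keypoint detector finds structure and nothing in flatness", {
  expect_equal(nrow(detect_keypoints(matrix(100, 64, 64))$points), 0)
  expect_error(detect_keypoints(matrix(0, 16, 16)), "insufficient extent")
  # bright Gaussian blob: a keypoint within 2 px of its center
  xs <- matrix(rep(0:127, each = 128), 128, 128)
  ys <- matrix(rep(0:127, 128), 128, 128)
  blob <- 255 * exp(-((xs - 64)^2 + (ys - 64)^2) / (2 * 3^2))
  kb <- detect_keypoints(blob)
  expect_gt(nrow(kb$points), 0)
  expect_lt(min(sqrt((kb$points[, 1] - 64)^2 + (kb$points[, 2] - 64)^2)), 2)
  # descriptors are unit vectors
  tex <- texture256()
  k <- detect_keypoints(tex)
  expect_gt(nrow(k$points), 50)
  expect_equal(rowSums(k$descriptors^2), rep(1, nrow(k$points)), tolerance = 1e-6)
  # rotation covariance: 90-degree rotation keeps the count within 10%
  k90 <- detect_keypoints(t(tex)[ncol(tex):1, ])
  expect_lt(abs(nrow(k90$points) - nrow(k$points)) / nrow(k$points), 0.1)
  # determinism
  k2 <- detect_keypoints(tex)
  expect_identical(k, k2)
})

test_that("descriptor matching passes planted translations and self-matches", {
  tex <- texture256()
  k <- detect_keypoints(tex)
  m_self <- match_descriptors(k, k)
  expect_equal(nrow(m_self$p1), nrow(k$points))
  expect_identical(m_self$p1, m_self$p2)
  # planted translation: most overlapping-region keypoints match
  sh <- 15
  tr <- shift_image(tex, sh, 0) # content moves left by sh
  k2 <- detect_keypoints(tr)
  m <- match_descriptors(k, k2)
  in_overlap <- sum(k$points[, 1] >= sh + 8)
  expect_gt(nrow(m$p1) / in_overlap, 0.8)
  d <- m$p2 - m$p1
  expect_equal(median(d[, 1]), -sh, tolerance = 0.5)
  expect_error(match_descriptors(list(points = matrix(0, 0, 4),
                                      descriptors = matrix(0, 0, 128)), k),
               "no features")
})

fake_corr <- function(p1, p2) {
  structure(list(p1 = p1, p2 = p2, distance = rep(0, nrow(p1)),
                 inlier_mask = rep(NA, nrow(p1))),
            class = "correspondence_set")
}

test_that("RANSAC recovers planted transforms (noiseless to 1e-6)", {
  set.seed(21)
  p <- cbind(runif(60, 0, 200), runif(60, 0, 200))
  for (cls in c("translation", "rigid", "similarity", "affine")) {
    A <- switch(cls,
      translation = cbind(diag(2), c(7.5, -3.25)),
      rigid = cbind(matrix(c(cos(0.3), sin(0.3), -sin(0.3), cos(0.3)), 2, 2), c(5, 8)),
      similarity = 1.15 * cbind(matrix(c(cos(-0.2), sin(-0.2), -sin(-0.2), cos(-0.2)), 2, 2),
                                c(-4, 2) / 1.15),
      affine = matrix(c(1.1, 0.05, -0.12, 0.93, 6, -11), 2, 3))
    q <- cbind(A[1, 1] * p[, 1] + A[1, 2] * p[, 2] + A[1, 3],
               A[2, 1] * p[, 1] + A[2, 2] * p[, 2] + A[2, 3])
    T <- ransac_transform(fake_corr(p, q), cls, inlier_tol = 3, seed = 1)
    expect_lt(max(abs(T$matrix - A)), 1e-6)
    expect_true(all(T$inliers))
    # class constraints hold
    L <- T$matrix[, 1:2]
    if (cls == "rigid") expect_equal(det(L), 1, tolerance = 1e-6)
    if (cls %in% c("rigid", "similarity"))
      expect_lt(abs(L[1, 1] - L[2, 2]) + abs(L[1, 2] + L[2, 1]), 1e-6)
  }
})

test_that("RANSAC survives jitter and 50% gross outliers", {
  set.seed(22)
  n <- 80
  p <- cbind(runif(n, 0, 400), runif(n, 0, 400))
  ang <- 0.25; s <- 1.05
  A <- s * cbind(matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2), c(12, -7) / s)
  q <- cbind(A[1, 1] * p[, 1] + A[1, 2] * p[, 2] + A[1, 3],
             A[2, 1] * p[, 1] + A[2, 2] * p[, 2] + A[2, 3]) +
    matrix(rnorm(2 * n, 0, 0.5), n, 2)
  out_idx <- seq_len(n) <= n / 2 # 50% outliers
  q[out_idx, ] <- matrix(runif(n, 0, 400), n / 2, 2)
  T <- ransac_transform(fake_corr(p, q), "similarity", inlier_tol = 3,
                        max_iters = 2000, seed = 3)
  expect_lte(T$mean_residual, 1.0)
  expect_lt(sum(T$inliers & out_idx) / sum(T$inliers), 0.1)
  # determinism: same seed, same transform bit-for-bit
  T2 <- ransac_transform(fake_corr(p, q), "similarity", inlier_tol = 3,
                         max_iters = 2000, seed = 3)
  expect_identical(T, T2)
  # inlier count non-increasing as the tolerance decreases
  counts <- vapply(c(5, 3, 1, 0.5), function(tol)
    sum(ransac_transform(fake_corr(p, q), "similarity", inlier_tol = tol,
                         seed = 3)$inliers), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("RANSAC enforces minimal sample sizes", {
  p <- cbind(c(0, 10), c(0, 10)); q <- p + 5
  expect_error(ransac_transform(fake_corr(p, q), "affine"),
               "coarse registration failed")
  # 3 exact points are enough for affine
  p3 <- cbind(c(0, 10, 3), c(0, 2, 9)); q3 <- p3 + 2
  T <- ransac_transform(fake_corr(p3, q3), "affine")
  expect_lt(max(abs(T$matrix - cbind(diag(2), c(2, 2)))), 1e-6)
})

test_that("apply_global warps exactly and invertibly", {
  img <- texture128()
  expect_equal(apply_global(img, identity_transform()), img)
  # integer translation is exact, vacated border black
  T <- identity_transform(); T$matrix[, 3] <- c(5, 3)
  w <- apply_global(img, T)
  expect_equal(w[4:128, 6:128], img[1:125, 1:123], tolerance = 1e-9)
  expect_true(all(w[1:3, ] == 0) && all(w[, 1:5] == 0))
  # warp by T then T^-1: interior mean abs diff < 2 gray levels
  # (band-limited image: bilinear resampling error on step edges is not
  # what this contract is about)
  img <- stackreg:::cpp_gaussian_blur(img, 1.5)
  Tr <- identity_transform()
  Tr$matrix <- 1.03 * cbind(matrix(c(cos(0.05), sin(0.05), -sin(0.05), cos(0.05)), 2, 2),
                            c(2, -1))
  Ti <- identity_transform(); Ti$matrix <- stackreg:::invert_affine(Tr$matrix)
  rt <- apply_global(apply_global(img, Tr), Ti)
  interior <- 17:112
  expect_lt(mean(abs(rt[interior, interior] - img[interior, interior])), 2)
})

test_that("coarse self-registration on detected keypoints is the identity", {
  tex <- texture256()
  k <- detect_keypoints(tex)
  m <- match_descriptors(k, k)
  T <- ransac_transform(m, "similarity", seed = 0)
  expect_lt(max(abs(T$matrix[, 3])), 0.1)
  expect_lt(max(abs(T$matrix[, 1:2] - diag(2))), 1e-3)
})
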