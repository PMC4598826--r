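test_that("eval_field equals the brute-force tensor-product sum", {
  set.seed(41)
  f <- random_field(24, 18, magnitude = 2.5, smoothness = 5, seed = 2)
  pts <- cbind(runif(40, 0, 23), runif(40, 0, 17))
  got <- eval_field(f, pts)
  for (i in seq_len(nrow(pts)))
    expect_equal(as.vector(got[i, ]), bf_eval_field(f, pts[i, 1], pts[i, 2]),
                 tolerance = 1e-9)
  expect_error(eval_field(f, cbind(30, 5)), "domain error")
})

test_that("identity, single-coefficient and translation fields are exact", {
  f <- identity_field(20, 15, 4)
  pts <- cbind(runif(30, 0, 19), runif(30, 0, 14))
  expect_equal(eval_field(f, pts), pts, tolerance = 1e-9, ignore_attr = TRUE)
  # single displaced coefficient contributes d * B3(.) * B3(.)
  d <- 3.7
  f1 <- f; f1$cx[3, 4] <- f1$cx[3, 4] + d   # knot k = 2, l = 1
  p <- cbind(6.3, 1.2)
  expected_dx <- d * bspline3(6.3 / 4 - 2) * bspline3(1.2 / 4 - 1)
  expect_equal(eval_field(f1, p)[1] - 6.3, expected_dx, tolerance = 1e-12)
  # partition of unity: uniform coefficient shift = exact global translation
  ft <- f; ft$cx <- ft$cx + 2.25; ft$cy <- ft$cy - 1.5
  expect_equal(eval_field(ft, pts), pts + rep(c(2.25, -1.5), each = 30),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mean_deformation matches the per-pixel oracle", {
  expect_equal(mean_deformation(identity_field(16, 16, 4)), 0)
  f <- identity_field(16, 16, 4)
  f$cx <- f$cx + 3; f$cy <- f$cy + 4
  expect_equal(mean_deformation(f), 5, tolerance = 1e-12)
  rf <- random_field(14, 11, magnitude = 1.7, smoothness = 4, seed = 6)
  expect_equal(mean_deformation(rf), bf_mean_deformation(rf), tolerance = 1e-6)
})

test_that("warp_image is exact on identity and integer translations", {
  img <- rand_img(30, 40, 12)
  f <- identity_field(40, 30, 8)
  expect_equal(warp_image(img, f), img, tolerance = 1e-9)
  ft <- f; ft$cx <- ft$cx + 5; ft$cy <- ft$cy + 3
  w <- warp_image(img, ft)
  expect_equal(w[1:27, 1:35], img[4:30, 6:40], tolerance = 1e-9)
  expect_true(all(abs(w[28:30, ]) < 1e-9))
  expect_error(warp_image(rand_img(10, 10), f), "domain error")
})

test_that("energy_image equals the per-pixel computation", {
  img <- texture128()
  f <- identity_field(128, 128, 16)
  expect_equal(energy_image(img, img, f), 0)
  t2 <- pmin(img + 10, 255)
  expect_equal(energy_image(img, t2, f), mean((t2 - img)^2))
  # with no clamping anywhere the constant offset gives exactly 100
  lo <- pmin(img, 200)
  expect_equal(energy_image(lo, lo + 10, f), 100)
  # random pair, random smooth field: brute force per pixel
  src <- rand_img(20, 24, 13); tgt <- rand_img(20, 24, 14)
  rf <- random_field(24, 20, magnitude = 1.2, smoothness = 6, seed = 4)
  g <- stackreg:::field_grid(rf)
  w <- stackreg:::cpp_warp_bilinear(src, g$gx, g$gy)
  inside <- g$gx >= 0 & g$gx <= 23 & g$gy >= 0 & g$gy <= 19
  expect_equal(energy_image(src, tgt, rf),
               mean((w[inside] - tgt[inside])^2), tolerance = 1e-9)
})

test_that("regularization energies have their closed forms", {
  f <- identity_field(24, 20, 6)
  r <- energy_regularization(f)
  expect_equal(c(r$div, r$rot), c(0, 0), tolerance = 1e-20)
  ft <- f; ft$cx <- ft$cx + 9.5; ft$cy <- ft$cy - 2
  rt <- energy_regularization(ft)
  expect_equal(c(rt$div, rt$rot), c(0, 0), tolerance = 1e-20)
  # uniform scaling u = eps x, v = eps y (exact coefficients)
  eps <- 0.01
  fs <- f; fs$cx <- f$cx * (1 + eps); fs$cy <- f$cy * (1 + eps)
  rs <- energy_regularization(fs)
  expect_equal(rs$div, (2 * eps)^2, tolerance = 1e-12)
  expect_equal(rs$rot, 0, tolerance = 1e-20)
  # a pure rotation-like shear v = eps x (exact coefficients): curl only
  fr <- f; fr$cy <- f$cy + eps * f$cx
  rr <- energy_regularization(fr)
  expect_equal(rr$rot, eps^2, tolerance = 1e-12)
  expect_equal(rr$div, 0, tolerance = 1e-12)
})

test_that("consistency energy has its closed forms", {
  f <- identity_field(32, 24, 8)
  expect_equal(energy_consistency(f, f), 0, tolerance = 1e-20)
  d <- 2.5
  fp <- f; fp$cx <- fp$cx + d
  fm <- f; fm$cx <- fm$cx - d
  expect_equal(energy_consistency(fp, fm), 0, tolerance = 1e-18)
  expect_equal(energy_consistency(fp, f), d^2, tolerance = 1e-9)
})

test_that("objective gradient matches numeric differentiation", {
  skip_if_not_installed("numDeriv")
  set.seed(44)
  W <- 24; H <- 20; sp <- 6
  src <- stackreg:::cpp_gaussian_blur(rand_img(H, W, 15), 1.5)
  tgt <- stackreg:::cpp_gaussian_blur(rand_img(H, W, 16), 1.5)
  f0 <- identity_field(W, H, sp)
  nc <- length(f0$cx)
  par0 <- c(f0$cx + rnorm(nc, 0, 0.8), f0$cy + rnorm(nc, 0, 0.8),
            f0$cx + rnorm(nc, 0, 0.8), f0$cy + rnorm(nc, 0, 0.8))
  tre <- new.env(); tre$trace <- numeric(0); tre$best <- NULL
  obj <- stackreg:::make_objective(src, tgt, sp, W, H, energy_weights(), 1L, tre)
  g_an <- obj$gr(par0)
  g_num <- numDeriv::grad(obj$fn, par0, method = "simple",
                          method.args = list(eps = 1e-6))
  expect_lt(max(abs(g_an - g_num)) / max(abs(g_an)), 1e-4)
})

test_that("elastic registration: self-pair is a fixed point", {
  img <- texture128()
  res <- register_elastic(img, img)
  expect_lt(mean_deformation(res$field_fwd), 0.25)
  expect_lt(mean_deformation(res$field_bwd), 0.25)
  expect_true(all(diff(res$energy_trace) <= 0))
})

test_that("elastic registration recovers a planted smooth field", {
  img <- texture128()
  tf <- random_field(128, 128, magnitude = 2, smoothness = 32, seed = 7)
  # rescale the displacement so the maximum is exactly 6 px
  dg <- displacement_grid(tf)
  mx <- max(sqrt(dg$ux^2 + dg$uy^2))
  idf <- identity_field(128, 128, 32)
  tf$cx <- idf$cx + (tf$cx - idf$cx) * 6 / mx
  tf$cy <- idf$cy + (tf$cy - idf$cy) * 6 / mx
  warped <- warp_image(img, tf)
  res <- register_elastic(img, warped)
  gt <- stackreg:::field_grid(tf); gr <- stackreg:::field_grid(res$field_fwd)
  interior <- 17:112
  epe <- sqrt((gr$gx - gt$gx)^2 + (gr$gy - gt$gy)^2)[interior, interior]
  expect_lt(mean(epe), 1.0)
})

test_that("a dominant consistency term forces mutually inverse fields", {
  img <- texture128()
  shifted <- shift_image(img, 4, 0)
  res <- register_elastic(img, shifted,
                          w = energy_weights(w_img = 1, w_cons = 1000))
  # compose f_ts(f_st(x)) over an interior grid: should be near identity
  pts <- as.matrix(expand.grid(x = seq(20, 107, by = 7), y = seq(20, 107, by = 7)))
  mid <- eval_field(res$field_fwd, pts)
  mid[, 1] <- pmin(pmax(mid[, 1], 0), 127); mid[, 2] <- pmin(pmax(mid[, 2], 0), 127)
  back <- eval_field(res$field_bwd, mid)
  expect_lt(mean(sqrt(rowSums((back - pts)^2))), 0.5)
})

test_that("compose_with_global matches pointwise composition", {
  f <- random_field(64, 48, magnitude = 2, smoothness = 16, seed = 5)
  # identity transform: unchanged within refit tolerance
  c0 <- compose_with_global(identity_transform(), f)
  pts <- as.matrix(expand.grid(x = seq(4, 59, by = 5), y = seq(4, 43, by = 5)))
  expect_lt(mean(sqrt(rowSums((eval_field(c0, pts) - eval_field(f, pts))^2))), 0.1)
  # translation composed with the identity field is that translation
  T <- identity_transform(); T$matrix[, 3] <- c(3, -2)
  ci <- compose_with_global(T, identity_field(64, 48, 16))
  expect_equal(eval_field(ci, pts), pts + rep(c(3, -2), each = nrow(pts)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # affine + random smooth field, pointwise
  Ta <- identity_transform()
  Ta$matrix <- matrix(c(0.98, 0.03, -0.02, 1.01, 1.5, -1), 2, 3)
  cc <- compose_with_global(Ta, f)
  tp <- stackreg:::transform_points(Ta$matrix, pts)
  expect_lt(mean(sqrt(rowSums((eval_field(cc, pts) - eval_field(f, tp))^2))), 0.1)
})
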