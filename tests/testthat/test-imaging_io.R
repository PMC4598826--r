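test_that("natural filename order sorts numeric runs numerically", {
  f <- c("s10.png", "s2.png", "s1.png", "s03.png")
  expect_equal(f[stackreg:::natural_order(f)],
               c("s1.png", "s2.png", "s03.png", "s10.png"))
  g <- c("sec1_z10.tif", "sec1_z2.tif", "sec1_z1.tif")
  expect_equal(g[stackreg:::natural_order(g)],
               c("sec1_z1.tif", "sec1_z2.tif", "sec1_z10.tif"))
})

test_that("multi-page TIFF round trip is bit-exact for gray and RGB", {
  tmp <- tempfile(fileext = ".tif")
  st <- section_stack(list(rand_img(30, 40, 1), rand_img(30, 40, 2),
                           rand_img(30, 40, 3)))
  write_stack(st, tmp)
  st2 <- read_stack(tmp)
  expect_equal(length(st2), 3)
  expect_identical(st2$mode, "gray")
  for (i in 1:3) expect_identical(st2$sections[[i]], st$sections[[i]])

  str <- section_stack(list(rand_rgb(20, 25, 4), rand_rgb(20, 25, 5)))
  write_stack(str, tmp)
  str2 <- read_stack(tmp)
  expect_identical(str2$mode, "rgb")
  for (i in 1:2) expect_identical(str2$sections[[i]], str$sections[[i]])
})

test_that("TIFF codec agrees with an independent reader/writer", {
  # tifffile (Python) acts as the independent oracle on a tiny fixture
  py <- Sys.which("python")
  expect_true(nzchar(py)) # pre-installed in the build image
  tmp <- tempfile(fileext = ".tif"); out <- tempfile(fileext = ".txt")
  st <- section_stack(list(rand_rgb(9, 11, 6), rand_rgb(9, 11, 7)))
  write_stack(st, tmp)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, tifffile, numpy as np",
    sprintf("a = tifffile.imread(%s)", deparse(tmp)),
    sprintf("np.savetxt(%s, a.reshape(-1).astype(int), fmt='%%d')", deparse(out))
  ), script)
  expect_equal(system2(py, script, stdout = FALSE, stderr = FALSE), 0L)
  vals <- scan(out, what = integer(), quiet = TRUE)
  # tifffile returns (pages, H, W, 3), C-order
  ours <- unlist(lapply(st$sections, function(s) as.integer(aperm(s, c(3, 2, 1)))))
  expect_identical(vals, ours)
  # and the reverse: read a tifffile-written multi-page gray TIFF
  tmp2 <- tempfile(fileext = ".tif")
  writeLines(c(
    "import tifffile, numpy as np",
    "a = (np.arange(300).reshape(15, 20) % 251).astype(np.uint8)",
    sprintf("tifffile.imwrite(%s, np.stack([a, a.T.copy().reshape(15,20)]), compression=None)",
            deparse(tmp2))
  ), script)
  expect_equal(system2(py, script, stdout = FALSE, stderr = FALSE), 0L)
  rt <- read_stack(tmp2)
  expect_equal(length(rt), 2)
  expect_equal(rt$sections[[1]][2, 3], (1 * 20 + 2) %% 251)
})

test_that("read_stack handles directories, 16-bit pages and error cases", {
  d <- file.path(tempdir(), "stackdir"); dir.create(d, showWarnings = FALSE)
  file.remove(list.files(d, full.names = TRUE))
  imgs <- list(rand_img(16, 16, 1), rand_img(16, 16, 2), rand_img(16, 16, 3))
  # write out of order with natural-sort-challenging names
  for (i in seq_along(imgs))
    png::writePNG(imgs[[i]] / 255, file.path(d, sprintf("s%d.png", i)))
  png::writePNG(rand_img(16, 16, 10) / 255, file.path(d, "s10.png"))
  st <- read_stack(d)
  expect_equal(st$labels, c("s1.png", "s2.png", "s3.png", "s10.png"))
  expect_identical(st$sections[[2]], imgs[[2]])

  empty <- file.path(tempdir(), "emptydir"); dir.create(empty, showWarnings = FALSE)
  expect_error(read_stack(empty), "no sections")
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "no sections")

  # 16-bit gray page -> global min-max to 8-bit
  t16 <- tempfile(fileext = ".tif")
  py <- Sys.which("python")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import tifffile, numpy as np",
    "a = np.linspace(1000, 9000, 64).reshape(8, 8).astype(np.uint16)",
    sprintf("tifffile.imwrite(%s, a, compression=None)", deparse(t16))
  ), script)
  expect_equal(system2(py, script, stdout = FALSE, stderr = FALSE), 0L)
  st16 <- read_stack(t16)
  expect_equal(min(st16$sections[[1]]), 0)
  expect_equal(max(st16$sections[[1]]), 255)
})

test_that("conform_stack pads symmetrically with zeros and alters nothing", {
  a <- rand_img(10, 12, 1); b <- rand_img(11, 9, 2)
  st <- conform_stack(section_stack(list(a, b)))
  expect_equal(dim(st$sections[[1]]), c(11, 12))
  expect_equal(dim(st$sections[[2]]), c(11, 12))
  # a: padded 1 row total (0 top, 1 bottom by floor rule)
  expect_identical(st$sections[[1]][1:10, ], a)
  expect_true(all(st$sections[[1]][11, ] == 0))
  # b: padded 1+2 columns
  expect_identical(st$sections[[2]][, 2:10], b)
  expect_true(all(st$sections[[2]][, c(1, 11, 12)] == 0))
  # foreground pixel count preserved
  expect_equal(sum(st$sections[[2]] > 0), sum(b > 0))
  # identity case
  st2 <- conform_stack(section_stack(list(a, a)))
  expect_identical(st2$sections[[1]], a)
  # sizes {60x60, 64x60}: symmetric 2+2 rows
  c1 <- rand_img(60, 60, 3); c2 <- rand_img(64, 60, 4)
  st3 <- conform_stack(section_stack(list(c1, c2)))
  expect_identical(st3$sections[[1]][3:62, ], c1)
  expect_true(all(st3$sections[[1]][c(1, 2, 63, 64), ] == 0))
})

test_that("reslice_side_view extracts orthogonal cuts", {
  a <- rand_img(20, 30, 1)
  st <- section_stack(list(a, a, a))
  # z-constant stack: zero variance along z
  svy <- reslice_side_view(st, "y", 7)
  expect_equal(dim(svy), c(3, 30))
  expect_equal(max(apply(svy, 2, sd)), 0)
  svx <- reslice_side_view(st, "x", 4)
  expect_equal(dim(svx), c(3, 20))
  # constructed shift: section i = section 0 shifted i px to the right
  sh <- lapply(0:2, function(i) shift_image(a, -i, 0))
  st2 <- section_stack(sh)
  sv <- reslice_side_view(st2, "y", 10)
  expect_equal(sv[2, 3:29], sv[1, 2:28], tolerance = 1e-9)
  expect_equal(sv[3, 4:29], sv[1, 2:27], tolerance = 1e-9)
  expect_error(reslice_side_view(st, "y", 20), "index error")
  # N = 2 stack has exactly two reslice rows
  expect_equal(nrow(reslice_side_view(section_stack(list(a, a)), "y", 0)), 2)
})
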