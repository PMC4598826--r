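## Stack input/output: multi-page TIFF or a directory of numbered
## TIFF/PNG files, natural-numeric filename order.

# Order filenames the way a human numbers sections: split each name into
# digit and non-digit runs and compare runs pairwise (s2 < s10).
natural_order <- function(files) {
  base <- basename(files)
  keys <- lapply(base, function(f) {
    runs <- regmatches(f, gregexpr("[0-9]+|[^0-9]+", f))[[1]]
    runs
  })
  maxlen <- max(vapply(keys, length, integer(1)))
  cols <- lapply(seq_len(maxlen), function(i) {
    vapply(keys, function(k) {
      if (i > length(k)) "" else {
        r <- k[i]
        if (grepl("^[0-9]+$", r)) sprintf("%020d", as.numeric(r)) else r
      }
    }, character(1))
  })
  do.call(order, cols)
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff_read_pages(path)
  } else if (ext == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stop_data(paste0("decode failure: ", path)))
    if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) arr <- arr[, , 1:3, drop = FALSE]
    if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1]
    list(list(img = round(arr * 255), bits = 8L))
  } else {
    stop_data(paste0("decode failure (unsupported format): ", path))
  }
}

#' Read a section stack
#'
#' Accepts a multi-page TIFF (uncompressed baseline) or a directory of
#' single-page TIFF/PNG files, ordered by natural numeric filename order
#' (`s2` before `s10`).  16-bit input is rescaled to 8-bit by the global
#' min-max over the whole stack; mixed gray/RGB input is promoted to RGB.
#'
#' @param path file or directory.
#' @return a [section_stack()].
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) stop_data(paste0("no sections: ", path))
    files <- files[natural_order(files)]
    pages <- do.call(c, lapply(files, read_one_image))
    labels <- basename(files)
  } else if (file.exists(path)) {
    pages <- tiff_read_pages(path)
    labels <- sprintf("page_%03d", seq_along(pages) - 1L)
  } else {
    stop_data(paste0("no sections: ", path))
  }
  if (length(pages) == 0) stop_data(paste0("no sections: ", path))
  bits <- vapply(pages, function(p) p$bits, numeric(1))
  imgs <- lapply(pages, function(p) p$img)
  if (any(bits == 16)) {
    hi <- which(bits == 16)
    rng <- range(unlist(lapply(imgs[hi], range)))
    span <- max(rng[2] - rng[1], 1)
    imgs[hi] <- lapply(imgs[hi], function(m) round((m - rng[1]) / span * 255))
  }
  imgs <- lapply(imgs, function(m) {
    storage.mode(m) <- "double"
    m
  })
  section_stack(imgs, labels = labels)
}

#' Write a section stack as a multi-page TIFF
#'
#' Lossless, one page per section, order preserved; a round trip through
#' [read_stack()] reproduces the pixels bit-exactly.
#'
#' @param stack a [section_stack()].
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  tiff_write_pages(stack$sections, path)
  invisible(path)
}
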