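## Minimal baseline TIFF codec: multi-page, uncompressed, contiguous planar
## layout, 8- or 16-bit grayscale and 8-bit RGB.  This covers every file the
## pipeline writes and the uncompressed exports typical of microscope stacks.
## (No TIFF package ships with this R library, so the container is handled
## here; PNG is delegated to the `png` package.)

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

tiff_ifd_entry <- function(tag, type, count, value_raw4) {
  c(u16le(tag), u16le(type), u32le(count), value_raw4)
}

# images: list of H x W matrices or H x W x 3 arrays, values 0..255
tiff_write_pages <- function(images, path) {
  con <- tryCatch(file(path, "wb"), error = function(e) stop_data(paste0("write failure: ", path)))
  on.exit(close(con))
  chunks <- list(c(charToRaw("II"), u16le(42L), u32le(0L))) # patched below
  pos <- 8
  ifd_offsets <- numeric(length(images))
  ifd_chunks <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    rgb <- img_mode(img) == "rgb"
    H <- img_height(img); W <- img_width(img)
    if (rgb) {
      v <- as.integer(round(aperm(img, c(3, 2, 1)))) # channel fastest, then x, then y
    } else {
      v <- as.integer(round(t(img)))                 # row-major
    }
    data <- as.raw(pmin(pmax(v, 0L), 255L))
    data_off <- pos
    chunks[[length(chunks) + 1L]] <- data
    pos <- pos + length(data)
    if (pos %% 2 == 1) { chunks[[length(chunks) + 1L]] <- raw(1); pos <- pos + 1 }
    bps_off <- 0
    if (rgb) { # external BitsPerSample triple
      bps_off <- pos
      chunks[[length(chunks) + 1L]] <- c(u16le(8L), u16le(8L), u16le(8L))
      pos <- pos + 6
    }
    short_val <- function(v) c(u16le(v), u16le(0L))
    entries <- list(
      tiff_ifd_entry(256L, 4L, 1L, u32le(W)),
      tiff_ifd_entry(257L, 4L, 1L, u32le(H)),
      if (rgb) tiff_ifd_entry(258L, 3L, 3L, u32le(bps_off))
      else     tiff_ifd_entry(258L, 3L, 1L, short_val(8L)),
      tiff_ifd_entry(259L, 3L, 1L, short_val(1L)),
      tiff_ifd_entry(262L, 3L, 1L, short_val(if (rgb) 2L else 1L)),
      tiff_ifd_entry(273L, 4L, 1L, u32le(data_off)),
      tiff_ifd_entry(277L, 3L, 1L, short_val(if (rgb) 3L else 1L)),
      tiff_ifd_entry(278L, 4L, 1L, u32le(H)),
      tiff_ifd_entry(279L, 4L, 1L, u32le(length(data))),
      if (rgb) tiff_ifd_entry(284L, 3L, 1L, short_val(1L)) else NULL
    )
    entries <- Filter(Negate(is.null), entries)
    ifd_offsets[i] <- pos
    ifd <- c(u16le(length(entries)), do.call(c, entries), u32le(0L)) # next patched
    chunks[[length(chunks) + 1L]] <- ifd
    ifd_chunks[i] <- length(chunks)   # chunk index of this page's IFD
    pos <- pos + length(ifd)
  }
  # patch header -> first IFD, and each IFD's next-IFD pointer
  chunks[[1]][5:8] <- u32le(ifd_offsets[1])
  for (k in seq_along(images)) {
    j <- ifd_chunks[[k]]
    nxt <- if (k < length(images)) ifd_offsets[k + 1] else 0
    n <- length(chunks[[j]])
    chunks[[j]][(n - 3):n] <- u32le(nxt)
  }
  writeBin(do.call(c, chunks), con)
  invisible(path)
}

tiff_read_pages <- function(path) {
  raw <- tryCatch(readBin(path, "raw", file.size(path)),
                  error = function(e) stop_data(paste0("decode failure: ", path)))
  if (length(raw) < 8) stop_data(paste0("decode failure: ", path))
  endian <- if (raw[1] == charToRaw("I")[1]) "little" else "big"
  rd <- function(off, size, n = 1L, signed = TRUE) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  }
  ru16 <- function(off, n = 1L) rd(off, 2L, n, signed = FALSE)
  ru32 <- function(off, n = 1L) rd(off, 4L, n, signed = TRUE)
  if (ru16(2) != 42L) stop_data(paste0("decode failure: ", path))
  ifd_off <- ru32(4)
  pages <- list()
  type_size <- c(1L, 1L, 2L, 4L, 8L)
  while (ifd_off != 0) {
    nent <- ru16(ifd_off)
    tags <- list()
    for (e in seq_len(nent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- ru16(base); typ <- ru16(base + 2); cnt <- ru32(base + 4)
      ts <- if (typ >= 1 && typ <= 5) type_size[typ] else 1L
      total <- ts * cnt
      voff <- if (total <= 4) base + 8 else ru32(base + 8)
      vals <- if (typ == 3L) ru16(voff, cnt)
              else if (typ == 4L) ru32(voff, cnt)
              else if (typ == 1L) as.integer(raw[(voff + 1):(voff + cnt)])
              else NULL
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    W <- g(256); H <- g(257)
    bps <- g(258, 8L); spp <- g(277, 1L)
    comp <- g(259, 1L); photo <- g(262, 1L); planar <- g(284, 1L)
    offs <- g(273); counts <- g(279)
    if (is.null(W) || is.null(H) || is.null(offs))
      stop_data(paste0("decode failure: ", path))
    if (comp != 1L)
      stop_data(paste0("decode failure (compressed TIFF not supported): ", path))
    if (planar != 1L)
      stop_data(paste0("decode failure (planar TIFF not supported): ", path))
    bits <- bps[1]
    if (!bits %in% c(8L, 16L))
      stop_data(paste0("decode failure (", bits, "-bit TIFF not supported): ", path))
    if (is.null(counts)) counts <- rep(W * H * spp * bits / 8 / length(offs), length(offs))
    buf <- do.call(c, lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + counts[i])]))
    vals <- if (bits == 8L) as.integer(buf)
            else readBin(buf, "integer", n = length(buf) / 2, size = 2,
                         endian = endian, signed = FALSE)
    if (photo == 0L) vals <- (2^bits - 1) - vals # white-is-zero
    img <- if (spp == 1L) {
      matrix(vals, nrow = H, byrow = TRUE)
    } else {
      aperm(array(vals[seq_len(W * H * 3)], dim = c(3L, W, H)), c(3, 2, 1))
    }
    pages[[length(pages) + 1L]] <- list(img = img, bits = bits)
    ifd_off <- ru32(ifd_off + 2 + nent * 12)
  }
  if (length(pages) == 0) stop_data("no sections")
  pages
}
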