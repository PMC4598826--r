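## Images are plain numeric arrays in [0, 255]: a gray section is an H x W
## matrix, an RGB section an H x W x 3 array.  The global coordinate
## convention is 0-based, x = column, y = row, pixel centers at integers.

img_mode <- function(img) {
  if (is.matrix(img)) return("gray")
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) return("rgb")
  stop_data("not a valid 2D image (need H x W matrix or H x W x 3 array)")
}

img_height <- function(img) dim(img)[1]
img_width <- function(img) dim(img)[2]

#' Per-pixel scalar intensity of an image
#'
#' Gray images are returned as-is; RGB images are reduced to the per-pixel
#' maximum over channels (the most permissive "bright" detector, used by the
#' evaluation metric and foreground masks).
#'
#' @param img gray matrix or RGB array, values in \[0, 255\].
#' @return numeric H x W matrix.
#' @export
img_intensity <- function(img) {
  if (img_mode(img) == "gray") return(img)
  pmax(img[, , 1], img[, , 2], img[, , 3])
}

#' Create a section stack
#'
#' An ordered set of co-registered serial sections.  All sections must share
#' one mode (gray or RGB); sections are stored in physical cutting order.
#'
#' @param sections list of images (H x W matrices or H x W x 3 arrays).
#' @param labels optional character vector of per-section labels.
#' @return object of class `section_stack`.
#' @export
section_stack <- function(sections, labels = NULL) {
  if (length(sections) < 1L) stop_data("no sections")
  modes <- vapply(sections, img_mode, character(1))
  if (any(modes == "rgb") && any(modes == "gray")) {
    sections <- lapply(sections, function(s) {
      if (img_mode(s) == "gray") array(rep(s, 3L), dim = c(dim(s), 3L)) else s
    })
    modes <- rep("rgb", length(sections))
  }
  if (is.null(labels)) labels <- sprintf("section_%03d", seq_along(sections) - 1L)
  structure(list(sections = sections, mode = modes[1], labels = labels),
            class = "section_stack")
}

#' @export
length.section_stack <- function(x) length(x$sections)

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$sections[[1]])
  cat(sprintf("<section_stack> %d sections, %s, %d x %d\n",
              length(x), x$mode, d[1], d[2]))
  invisible(x)
}

stack_dims <- function(stack) {
  h <- vapply(stack$sections, img_height, numeric(1))
  w <- vapply(stack$sections, img_width, numeric(1))
  cbind(h = h, w = w)
}

pad_image <- function(img, H, W) {
  h <- img_height(img); w <- img_width(img)
  if (h == H && w == W) return(img)
  top <- floor((H - h) / 2); left <- floor((W - w) / 2)
  if (img_mode(img) == "gray") {
    out <- matrix(0, H, W)
    out[top + seq_len(h), left + seq_len(w)] <- img
  } else {
    out <- array(0, dim = c(H, W, 3L))
    out[top + seq_len(h), left + seq_len(w), ] <- img
  }
  out
}

#' Conform all sections of a stack to a common size
#'
#' Every section is zero-padded symmetrically (extra pixel goes to the
#' bottom/right) up to the maximum height and width present in the stack.
#' Padding is black (0), which the foreground masks of the evaluation
#' metric treat as background; no original pixel value is altered.
#'
#' @param stack a [section_stack()].
#' @return a `section_stack` with identically sized sections.
#' @export
conform_stack <- function(stack) {
  if (length(stack) < 2L) stop_data("no sections")
  d <- stack_dims(stack)
  H <- max(d[, "h"]); W <- max(d[, "w"])
  stack$sections <- lapply(stack$sections, pad_image, H = H, W = W)
  stack
}

#' Orthogonal reslice (side view) of a stack
#'
#' Cuts the z-stack along a row (`axis = "y"`, an XZ cut: output is N x W
#' with row i holding row `position` of section i) or a column
#' (`axis = "x"`, a YZ cut: N x H).  Used for qualitative continuity
#' inspection of the reconstructed volume.
#'
#' @param stack a conformed [section_stack()].
#' @param axis `"x"` or `"y"`.
#' @param position 0-based pixel index of the cutting plane.
#' @return gray N x W (or N x H) matrix; RGB stacks are resliced per channel
#'   and returned as an N x W x 3 array.
#' @export
reslice_side_view <- function(stack, axis = c("y", "x"), position) {
  axis <- match.arg(axis)
  d <- dim(stack$sections[[1]])
  lim <- if (axis == "y") d[1] else d[2]
  if (position < 0 || position >= lim) stop_data("index error: reslice position out of range")
  grab <- function(img) {
    if (axis == "y") {
      if (img_mode(img) == "gray") img[position + 1L, ] else img[position + 1L, , ]
    } else {
      if (img_mode(img) == "gray") img[, position + 1L] else img[, position + 1L, ]
    }
  }
  rows <- lapply(stack$sections, grab)
  if (stack$mode == "gray") {
    do.call(rbind, rows)
  } else {
    out <- array(0, dim = c(length(rows), nrow(rows[[1]]), 3L))
    for (i in seq_along(rows)) out[i, , ] <- rows[[i]]
    out
  }
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)
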