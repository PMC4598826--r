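## Quantitative registration accuracy: per-pair overlap of bright ("white",
## >= t) pixels inside the pair's common foreground mask, averaged over
## consecutive pairs into the stack score R.

#' Foreground mask of a section
#'
#' A pixel is foreground iff its intensity exceeds `bg_tol` *or* it is a
#' dark pixel enclosed by tissue: the true background is the `<= bg_tol`
#' region 4-connected to the image border, and everything else (including
#' interior dark speckles) is foreground.
#'
#' @param img gray matrix or RGB array (RGB reduced to the per-pixel
#'   channel maximum).
#' @param bg_tol background intensity tolerance (default 0, exact black).
#' @return logical H x W matrix.
#' @export
foreground_mask <- function(img, bg_tol = 0) {
  !cpp_background_mask(img_intensity(img), bg_tol)
}

#' Pairwise registration accuracy r
#'
#' With `M` the common foreground of the two sections and
#' `W_i = {x in M : I_i(x) >= t}` the white pixels of each, the directed
#' overlap is `|W_i intersect W_j| / |W_i|`.  Conventions: the score is 1
#' when both white sets are empty and 0 when only `W_i` is empty.  The
#' symmetric variant normalizes by `|W_i union W_j|` instead.
#'
#' @param img_i,img_j same-shape images.
#' @param t white-intensity threshold in \[1, 255\] (default 200).
#' @param bg_tol background tolerance for the foreground masks.
#' @param symmetric use the symmetric (union-normalized) variant.
#' @return r in \[0, 1\].
#' @export
pair_accuracy <- function(img_i, img_j, t = 200, bg_tol = 0, symmetric = FALSE) {
  if (!all(dim(as_pixels(img_i))[1:2] == dim(as_pixels(img_j))[1:2]))
    stop_data("shape error: images differ in size")
  M <- foreground_mask(img_i, bg_tol) & foreground_mask(img_j, bg_tol)
  wi <- M & (img_intensity(img_i) >= t)
  wj <- M & (img_intensity(img_j) >= t)
  if (symmetric) {
    u <- sum(wi | wj)
    if (u == 0) return(1)
    return(sum(wi & wj) / u)
  }
  if (!any(wi)) return(if (any(wj)) 0 else 1)
  sum(wi & wj) / sum(wi)
}

#' Overall stack registration accuracy R
#'
#' The mean of [pair_accuracy()] over all consecutive section pairs.
#'
#' @param stack a [section_stack()] (N >= 2).
#' @inheritParams pair_accuracy
#' @return list with `R` and the per-pair vector `r`.
#' @export
stack_accuracy <- function(stack, t = 200, bg_tol = 0, symmetric = FALSE) {
  n <- length(stack)
  if (n < 2) stop_data("no sections")
  r <- vapply(seq_len(n - 1), function(i)
    pair_accuracy(stack$sections[[i]], stack$sections[[i + 1]], t, bg_tol, symmetric),
    numeric(1))
  list(R = mean(r), r = r)
}
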