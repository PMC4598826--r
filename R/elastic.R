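## Bidirectional elastic refinement: both deformation fields (source->target
## and target->source sampling maps) are optimized jointly, coarse-to-fine
## over a control-grid pyramid, minimizing
##   E = w_img (E_img_st + E_img_ts) + w_div (E_div_st + E_div_ts)
##     + w_rot (E_rot_st + E_rot_ts) + w_cons E_cons
## with analytic gradients computed in C++ and L-BFGS-B on the coefficients.

as_pixels <- function(x) if (is.list(x) && !is.null(x$pixels)) x$pixels else x

#' Image similarity energy of a deformation field
#'
#' Mean squared intensity difference between `warp_image(src, f_st)` and
#' `tgt`, over the pixels whose samples stay inside the source domain.
#'
#' @param src,tgt same-shape single-channel images (or feature images).
#' @param f_st a `bspline_field` (sampling map over the target frame).
#' @return scalar in \[0, 255^2\].
#' @export
energy_image <- function(src, tgt, f_st) {
  src <- as_pixels(src); tgt <- as_pixels(tgt)
  if (!all(dim(src) == dim(tgt))) stop_data("domain error: shape mismatch")
  r <- cpp_eimg_grad(src, tgt, f_st$cx, f_st$cy, f_st$sx, f_st$sy, FALSE)
  if (r$n_in == 0) stop_data("no overlap")
  r$value
}

#' Divergence and curl regularization energies
#'
#' With displacement `(u, v) = g(x, y) - (x, y)`:
#' `E_div = mean (du/dx + dv/dy)^2` and `E_rot = mean (dv/dx - du/dy)^2`,
#' derivatives evaluated analytically from the B-spline basis.
#'
#' @param f a `bspline_field`.
#' @return list with `div` and `rot`.
#' @export
energy_regularization <- function(f) {
  r <- cpp_ereg_grad(f$cx, f$cy, f$sx, f$sy, f$width, f$height, FALSE)
  list(div = r$ediv, rot = r$erot)
}

#' Bidirectional consistency energy
#'
#' Mean of `||f_ts(f_st(x)) - x||^2` over sampled pixels (and the symmetric
#' composition, averaged); samples whose intermediate point leaves the
#' domain are excluded.
#'
#' @param f_st,f_ts fields on the same domain.
#' @param stride subsampling stride of the evaluation grid.
#' @return scalar (squared pixels).
#' @export
energy_consistency <- function(f_st, f_ts, stride = 1L) {
  if (f_st$width != f_ts$width || f_st$height != f_ts$height)
    stop_data("domain error: field domains differ")
  cpp_econs_grad(f_st$cx, f_st$cy, f_ts$cx, f_ts$cy,
                 f_st$sx, f_st$sy, f_st$width, f_st$height,
                 as.integer(stride), FALSE)$value
}

#' Default elastic energy weights
#' @param w_img,w_div,w_rot,w_cons nonnegative scalars (`w_img > 0`).
#' @return list of weights.
#' @export
energy_weights <- function(w_img = 1.0, w_div = 0.1, w_rot = 0.1, w_cons = 1.0) {
  if (w_img <= 0) stop_usage("w_img must be positive")
  list(w_img = w_img, w_div = w_div, w_rot = w_rot, w_cons = w_cons)
}

# objective + gradient for one pyramid level; returns closures sharing a
# single-entry cache so optim's fn/gr pairs cost one evaluation.
make_objective <- function(src, tgt, sp, W, H, w, cons_stride, trace_env) {
  nk <- n_knots(W, sp); nl <- n_knots(H, sp)
  nc <- nk * nl
  split_par <- function(par) {
    list(cxst = matrix(par[1:nc], nl, nk),
         cyst = matrix(par[nc + 1:nc], nl, nk),
         cxts = matrix(par[2 * nc + 1:nc], nl, nk),
         cyts = matrix(par[3 * nc + 1:nc], nl, nk))
  }
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return()
    f <- split_par(par)
    e1 <- cpp_eimg_grad(src, tgt, f$cxst, f$cyst, sp, sp, TRUE)
    e2 <- cpp_eimg_grad(tgt, src, f$cxts, f$cyts, sp, sp, TRUE)
    r1 <- cpp_ereg_grad(f$cxst, f$cyst, sp, sp, W, H, TRUE)
    r2 <- cpp_ereg_grad(f$cxts, f$cyts, sp, sp, W, H, TRUE)
    cs <- cpp_econs_grad(f$cxst, f$cyst, f$cxts, f$cyts, sp, sp, W, H,
                         as.integer(cons_stride), TRUE)
    # a field that has pushed every sample out of the domain scores the
    # worst possible similarity with no pull anywhere
    v1 <- if (is.na(e1$value)) 255^2 else e1$value
    v2 <- if (is.na(e2$value)) 255^2 else e2$value
    val <- w$w_img * (v1 + v2) +
      w$w_div * (r1$ediv + r2$ediv) +
      w$w_rot * (r1$erot + r2$erot) +
      w$w_cons * cs$value
    g_stx <- w$w_img * e1$gx + w$w_div * r1$gdx + w$w_rot * r1$grx + w$w_cons * cs$g_stx
    g_sty <- w$w_img * e1$gy + w$w_div * r1$gdy + w$w_rot * r1$gry + w$w_cons * cs$g_sty
    g_tsx <- w$w_img * e2$gx + w$w_div * r2$gdx + w$w_rot * r2$grx + w$w_cons * cs$g_tsx
    g_tsy <- w$w_img * e2$gy + w$w_div * r2$gdy + w$w_rot * r2$gry + w$w_cons * cs$g_tsy
    cache$par <- par
    cache$value <- val
    cache$grad <- c(g_stx, g_sty, g_tsx, g_tsy)
    if (is.null(trace_env$best) || val < trace_env$best) {
      trace_env$best <- val
      trace_env$trace <- c(trace_env$trace, val)
    }
  }
  list(
    fn = function(par) { evaluate(par); cache$value },
    gr = function(par) { evaluate(par); cache$grad },
    split = split_par
  )
}

#' Bidirectional elastic B-spline registration of an image pair
#'
#' Jointly optimizes forward and backward cubic B-spline fields over a
#' coarse-to-fine control-grid pyramid (default full-resolution spacings
#' 64, 32, 16 px, with the images block-averaged to match the coarser
#' levels).  Both fields are initialized from the coarse global transform;
#' since cubic B-splines reproduce affine maps exactly, the returned
#' forward field is the *total* deformation (coarse plus elastic).
#'
#' @param src,tgt same-shape single-channel images (feature images).
#' @param init a `global_transform` mapping source to target coordinates
#'   (default identity).
#' @param w energy weights from [energy_weights()].
#' @param spacing finest control-point spacing in pixels.
#' @param levels number of pyramid levels.
#' @param max_iters L-BFGS iteration cap per level.
#' @param tol relative energy-decrease stopping threshold.
#' @param cons_stride consistency-term sampling stride.
#' @return object of class `pair_elastic`: `field_fwd`, `field_bwd`
#'   (`bspline_field`s; fwd samples the source over the target frame),
#'   `warped_source`, `final_energy`, `energy_trace`, `converged`.
#' @export
register_elastic <- function(src, tgt, init = identity_transform(),
                             w = energy_weights(), spacing = 16, levels = 3,
                             max_iters = 60, tol = 1e-5, cons_stride = 2L) {
  src <- as_pixels(src); tgt <- as_pixels(tgt)
  if (!all(dim(src) == dim(tgt))) stop_data("domain error: shape mismatch")
  W <- ncol(src); H <- nrow(src)
  levels <- max(1L, as.integer(levels))
  while (levels > 1 && min(W, H) / 2^(levels - 1) < 4 * spacing) levels <- levels - 1L
  A_fwd <- invert_affine(init$matrix) # sampling map target -> source
  A_bwd <- init$matrix
  f_st <- f_ts <- NULL
  trace_env <- new.env(parent = emptyenv())
  trace_env$trace <- numeric(0)
  trace_env$best <- NULL # improvements recorded across all pyramid levels
  final <- NA_real_
  for (l in seq(levels - 1, 0)) {
    fdown <- 2^l
    src_l <- if (fdown > 1) cpp_downsample(src, fdown) else src
    tgt_l <- if (fdown > 1) cpp_downsample(tgt, fdown) else tgt
    Wl <- ncol(src_l); Hl <- nrow(src_l)
    if (is.null(f_st)) {
      scl <- function(A) cbind(A[, 1:2], A[, 3] / fdown)
      f_st <- field_from_affine(scl(A_fwd), Wl, Hl, spacing)
      f_ts <- field_from_affine(scl(A_bwd), Wl, Hl, spacing)
    } else {
      f_st <- rescale_field(f_st, Wl / f_st$width, Wl, Hl, spacing)
      f_ts <- rescale_field(f_ts, Wl / f_ts$width, Wl, Hl, spacing)
    }
    obj <- make_objective(src_l, tgt_l, spacing, Wl, Hl, w, cons_stride, trace_env)
    par0 <- c(f_st$cx, f_st$cy, f_ts$cx, f_ts$cy)
    res <- optim(par0, obj$fn, obj$gr, method = "L-BFGS-B",
                 control = list(maxit = max_iters,
                                factr = tol / .Machine$double.eps))
    if (!is.finite(res$value)) stop_data("optimization diverged")
    f <- obj$split(res$par)
    f_st <- structure(list(cx = f$cxst, cy = f$cyst, sx = spacing, sy = spacing,
                           width = Wl, height = Hl), class = "bspline_field")
    f_ts <- structure(list(cx = f$cxts, cy = f$cyts, sx = spacing, sy = spacing,
                           width = Wl, height = Hl), class = "bspline_field")
    final <- res$value
  }
  structure(list(field_fwd = f_st, field_bwd = f_ts,
                 warped_source = warp_image(src, f_st),
                 final_energy = final, energy_trace = trace_env$trace,
                 converged = TRUE),
            class = "pair_elastic")
}
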