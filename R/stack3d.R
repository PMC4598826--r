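## The 3D framework: pairwise registration applied sequentially and
## bidirectionally outward from a reference section, each pair guarded by
## the deformation-field validation model.  A rejected pair passes the
## original section through unchanged, so over-deformation cannot
## accumulate along the chain.

#' Validate a deformation field against the over-deformation threshold
#'
#' Accepts iff the mean geometric distance `mean ||g(x,y) - (x,y)||` over
#' the domain does not exceed `alpha` (boundary inclusive).  `alpha` trades
#' off allowed transformation size against accumulated error: too high lets
#' over-deformations through, too low rejects well-registered pairs.
#'
#' @param f a `bspline_field`.
#' @param alpha maximum allowed mean deformation, pixels (>= 0).
#' @return list of class `validation_verdict`: `mean_deformation`, `alpha`,
#'   `accepted`.
#' @export
validate_field <- function(f, alpha) {
  if (alpha < 0) stop_usage("alpha must be >= 0")
  md <- mean_deformation(f)
  structure(list(mean_deformation = md, alpha = alpha, accepted = md <= alpha),
            class = "validation_verdict")
}

#' Suggested alpha ranges per data type
#'
#' Published working ranges of the validation threshold for the four
#' benchmark serial-section data types.
#' @return data frame with dataset and alpha range in pixels.
#' @export
alpha_presets <- function() {
  data.frame(
    dataset = c("ssTEM_VNC", "ssTEM_neuropile", "renal_histology", "confocal_brain"),
    alpha_min = c(20, 30, 200, 10),
    alpha_max = c(200, 95, 350, 30)
  )
}

#' Register one section pair
#'
#' The full pairwise chain: normalization and feature extraction, DoG +
#' RANSAC coarse global registration (a coarse failure degrades to the
#' identity, logged, never fatal), bidirectional elastic B-spline
#' refinement, then validation of the total deformation field.  If
#' accepted, the output is the original (full-depth) source warped by the
#' total field; otherwise the original source, untouched.
#'
#' @param src,tgt conformed same-shape images (source is the moving one).
#' @param cfg configuration list (see [default_config()]).
#' @return list of class `pair_registration`: `coarse`, `elastic`,
#'   `total_field`, `verdict`, `output`, plus `coarse_failed`.
#' @export
register_pair <- function(src, tgt, cfg = default_config()) {
  cfg <- as_config(cfg)
  if (!all(dim(as_pixels(src))[1:2] == dim(as_pixels(tgt))[1:2]))
    stop_data("domain error: sections not conformed to a common shape")
  M <- stain_matrix_from_config(cfg)
  feat <- function(img) extract_feature_image(
    normalize_image(img, cfg$normalize.p_low, cfg$normalize.p_high),
    M, cfg$feature.channel)
  F_s <- feat(src); F_t <- feat(tgt)
  coarse <- tryCatch({
    k1 <- detect_keypoints(F_s, contrast = cfg$coarse.contrast,
                           max_keypoints = cfg$coarse.max_keypoints)
    k2 <- detect_keypoints(F_t, contrast = cfg$coarse.contrast,
                           max_keypoints = cfg$coarse.max_keypoints)
    corr <- match_descriptors(k1, k2, cfg$coarse.ratio)
    ransac_transform(corr, cfg$coarse.model_class,
                     cfg$coarse.inlier_tol, cfg$coarse.max_iters,
                     cfg$coarse.seed)
  }, error = function(e) e)
  coarse_failed <- inherits(coarse, "error")
  if (coarse_failed) {
    log_info("coarse registration failed (%s); falling back to identity",
             conditionMessage(coarse))
    coarse <- identity_transform()
  } else if (!coarse_explains_pair(as_pixels(F_s), as_pixels(F_t), coarse)) {
    # a geometrically consistent but wrong consensus (self-similar texture)
    # is worse than no coarse transform at all; the elastic stage handles
    # moderate deformation from identity
    log_info("coarse transform does not beat identity; falling back to identity")
    coarse_failed <- TRUE
    coarse <- identity_transform()
  }
  elastic <- tryCatch(
    register_elastic(F_s, F_t, init = coarse,
                     w = energy_weights(cfg$elastic.w_img, cfg$elastic.w_div,
                                        cfg$elastic.w_rot, cfg$elastic.w_cons),
                     spacing = cfg$elastic.spacing_px,
                     levels = cfg$elastic.pyramid_levels,
                     max_iters = cfg$elastic.max_iters, tol = cfg$elastic.tol,
                     cons_stride = cfg$elastic.cons_stride),
    error = function(e) e)
  if (inherits(elastic, "error")) {
    log_info("elastic registration diverged (%s); pair rejected",
             conditionMessage(elastic))
    verdict <- structure(list(mean_deformation = Inf, alpha = cfg$stack.alpha,
                              accepted = FALSE), class = "validation_verdict")
    return(structure(list(coarse = coarse, elastic = NULL, total_field = NULL,
                          verdict = verdict, output = src,
                          coarse_failed = coarse_failed),
                     class = "pair_registration"))
  }
  total_field <- elastic$field_fwd # fields were initialized from the coarse map
  vf <- if (identical(cfg$validate.scope, "elastic_only")) {
    # deformation net of the coarse component: T applied after the sampling
    # map recovers the elastic increment relative to the coarse placement
    compose_with_global(coarse, total_field)
  } else total_field
  verdict <- validate_field(vf, cfg$stack.alpha)
  output <- if (verdict$accepted) warp_image(src, total_field) else src
  structure(list(coarse = coarse, elastic = elastic, total_field = total_field,
                 verdict = verdict, output = output,
                 coarse_failed = coarse_failed),
            class = "pair_registration")
}

# Quick plausibility check of a coarse transform: on 4x block-averaged
# feature images, does warping by T reduce the masked mean squared
# difference relative to the untransformed pair?  Guards against RANSAC
# locking onto a consistent-but-wrong consensus on self-similar texture.
coarse_explains_pair <- function(Fs, Ft, T, factor = 4L) {
  fs <- cpp_downsample(Fs, factor); ft <- cpp_downsample(Ft, factor)
  A <- T$matrix
  Ad <- cbind(A[, 1:2], A[, 3] / factor)
  Td <- identity_transform(); Td$matrix <- Ad
  w <- apply_global(fs, Td)
  mask <- w > 0 & ft > 0
  if (sum(mask) < 0.25 * length(ft)) return(FALSE)
  mse_t <- mean((w[mask] - ft[mask])^2)
  mask0 <- fs > 0 & ft > 0
  mse_i <- mean((fs[mask0] - ft[mask0])^2)
  mse_t <= mse_i
}

#' Choose the reference section
#'
#' @param stack a [section_stack()].
#' @param mode `"middle"` (default, `floor(N/2)`), `"first"`, or `"index:k"`.
#' @return 0-based reference index.
#' @export
choose_reference <- function(stack, mode = "middle") {
  n <- length(stack)
  if (n < 2) stop_data("no sections")
  if (identical(mode, "middle")) return(floor(n / 2))
  if (identical(mode, "first")) return(0L)
  if (grepl("^index:", mode)) {
    k <- suppressWarnings(as.integer(sub("^index:", "", mode)))
    if (is.na(k) || k < 0 || k >= n) stop_data("index error: reference out of range")
    return(k)
  }
  stop_usage(paste0("unknown reference mode: ", mode))
}

#' Register a whole stack
#'
#' Sections are registered pairwise outward from the reference layer: the
#' forward chain registers each section to its already-registered lower
#' neighbor in increasing order, the backward chain symmetrically in
#' decreasing order.  Accepted transforms propagate (the next pair's target
#' is the registered neighbor); rejected pairs insert the original section.
#' Per-pair failures are contained, never fatal to the stack.
#'
#' @param stack a conformed [section_stack()].
#' @param cfg configuration list.
#' @param field_override optional fault-injection hook
#'   `function(source_index, field) -> field` applied to each pair's total
#'   field before validation (used to study the validation model; the
#'   default passes fields through untouched).
#' @return list with `stack` (registered `section_stack`) and `report`
#'   (class `stack_report`).
#' @export
register_stack <- function(stack, cfg = default_config(), field_override = NULL) {
  cfg <- as_config(cfg)
  if (length(stack) < 2) stop_data("no sections")
  d <- stack_dims(stack)
  if (length(unique(d[, "h"])) > 1 || length(unique(d[, "w"])) > 1)
    stop_data("stack not conformed; call conform_stack() first")
  r <- choose_reference(stack, cfg$stack.reference)
  n <- length(stack)
  out <- stack$sections
  records <- list()
  do_pair <- function(i, tgt_idx) {
    pr <- register_pair(stack$sections[[i + 1]], out[[tgt_idx + 1]], cfg)
    if (!is.null(field_override) && !is.null(pr$total_field)) {
      f2 <- field_override(i, pr$total_field)
      if (!identical(f2, pr$total_field)) {
        pr$total_field <- f2
        pr$verdict <- validate_field(f2, cfg$stack.alpha)
        pr$output <- if (pr$verdict$accepted)
          warp_image(stack$sections[[i + 1]], f2) else stack$sections[[i + 1]]
      }
    }
    out[[i + 1]] <<- pr$output
    records[[length(records) + 1]] <<- list(
      source_index = i, target_index = tgt_idx,
      mean_deformation = pr$verdict$mean_deformation,
      accepted = pr$verdict$accepted,
      coarse_residual = pr$coarse$mean_residual,
      coarse_failed = pr$coarse_failed,
      final_energy = if (is.null(pr$elastic)) NA_real_ else pr$elastic$final_energy)
    log_info("pair %d -> %d: mean deformation %.2f px, %s", i, tgt_idx,
             pr$verdict$mean_deformation,
             if (pr$verdict$accepted) "accepted" else "rejected")
  }
  if (r + 1 <= n - 1) for (i in seq(r + 1, n - 1)) do_pair(i, i - 1) # forward chain
  if (r - 1 >= 0) for (i in seq(r - 1, 0)) do_pair(i, i + 1)         # backward chain
  report <- structure(list(reference_index = r, pairs = records,
                           config = unclass(cfg), n_sections = n),
                      class = "stack_report")
  list(stack = section_stack(out, labels = stack$labels), report = report)
}

#' @export
print.stack_report <- function(x, ...) {
  cat(sprintf("<stack_report> %d sections, reference %d\n",
              x$n_sections, x$reference_index))
  for (p in x$pairs)
    cat(sprintf("  %3d -> %3d  mean deformation %8.3f px  %s\n",
                p$source_index, p$target_index, p$mean_deformation,
                if (p$accepted) "accepted" else "REJECTED"))
  invisible(x)
}
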