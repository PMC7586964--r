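# Per-case registration: preprocessing, stack reconstruction, then per-slice
# masked affine + free-form deformable registration of each MRI slice to its
# corresponding histology slice.

#' Preprocess a case for registration
#'
#' Applies the expert-provided gross mounting rotation and left-right flip to
#' each histology slice (and its masks/labels) before any optimization, and
#' masks both modalities: intensities outside the prostate masks are set to
#' zero. Histology is converted to grayscale (luminance) for the deformable
#' stage.
#'
#' @param mri An \code{\link{mri_volume}}.
#' @param stack A \code{\link{hist_stack}}; \code{stack$gross_rotation} and
#'   \code{stack$flip_lr} carry the per-slice correction.
#' @return List with the corrected stack (\code{stack}), per-slice masked
#'   grayscale histology (\code{hist_gray}), masked MRI slices
#'   (\code{mri_slices}) and MRI masks (\code{mri_masks}) matched to the
#'   correspondence table.
#' @export
preprocess <- function(mri, stack) {
  D <- length(stack$slices)
  nmri <- dim(mri$img)[3]
  if (any(stack$correspondence < 1 | stack$correspondence > nmri))
    stop(sprintf("preprocess: correspondence references MRI slice %d of %d",
                 max(stack$correspondence), nmri))
  if (abs(stack$pixel_size - mri$spacing[1]) > 1e-6)
    stop("preprocess: histology pixel size must match MRI in-plane spacing (resample on read)")
  sp <- stack$pixel_size
  dims <- dim(stack$masks[[1]])
  ctr <- (rev(dims) - 1) * sp / 2
  out <- stack
  for (i in seq_len(D)) {
    ang <- stack$gross_rotation[i]
    flip <- stack$flip_lr[i]
    if (abs(ang) > 1e-12 || flip) {
      A <- rotmat(ang)
      if (flip) A <- A %*% diag(c(-1, 1))
      corr <- affine2d(A = A, t = c(0, 0), center = ctr)  # resampling map
      out$slices[[i]] <- resample_image(stack$slices[[i]], corr, spacing = sp)
      out$masks[[i]] <- resample_image(stack$masks[[i]], corr, spacing = sp,
                                       interp = "nearest")
      if (!is.null(stack$cancer))
        out$cancer[[i]] <- resample_image(stack$cancer[[i]], corr, spacing = sp,
                                          interp = "nearest")
      if (!is.null(stack$urethra))
        out$urethra[[i]] <- resample_image(stack$urethra[[i]], corr,
                                           spacing = sp, interp = "nearest")
    }
  }
  out$gross_rotation[] <- 0
  out$flip_lr[] <- FALSE
  hist_gray <- lapply(seq_len(D), function(i)
    rgb_to_gray(out$slices[[i]]) * out$masks[[i]])
  mri_slices <- vector("list", D)
  mri_masks <- vector("list", D)
  for (i in seq_len(D)) {
    k <- stack$correspondence[i]
    mri_masks[[i]] <- mri$mask[, , k]
    mri_slices[[i]] <- mri$img[, , k] * mri_masks[[i]]
  }
  list(stack = out, hist_gray = hist_gray,
       mri_slices = mri_slices, mri_masks = mri_masks)
}

#' Per-slice composite transform chain
#'
#' Bundles the reconstruction rigid, the affine and the B-spline field for
#' one slice. All three are resampling maps: the rigid maps
#' reconstruction-frame to original-histology coordinates; affine and field
#' map reconstruction-frame (histology) to MRI coordinates via
#' \code{p -> affine(p + u(p))}.
#'
#' @param rigid A \code{\link{rigid2d}}.
#' @param affine An \code{\link{affine2d}}.
#' @param field A \code{\link{bspline2d}} (identity allowed).
#' @param slice Slice index.
#' @param mri_slice Corresponding MRI slice index.
#' @return Object of class \code{"slice_chain"}.
#' @export
slice_chain <- function(rigid, affine, field, slice = NA_integer_,
                        mri_slice = NA_integer_) {
  stopifnot(inherits(rigid, "rigid2d"), inherits(affine, "affine2d"),
            inherits(field, "bspline2d"))
  structure(list(rigid = rigid, affine = affine, field = field,
                 slice = slice, mri_slice = mri_slice,
                 direction = "histology_fixed:maps_to_mri"),
            class = "slice_chain")
}

#' Register a full case
#'
#' Runs the three-step pipeline: reconstruct the histology stack with
#' pairwise rigid registrations; then, per corresponding slice pair, a masked
#' affine registration (mask SSD) followed by a free-form deformable
#' registration (Mattes MI), both over the multi-resolution pyramid.
#'
#' @param mri An \code{\link{mri_volume}}.
#' @param stack A \code{\link{hist_stack}}.
#' @param config A \code{\link{registration_config}}.
#' @return List of class \code{"case_chains"}: one \code{\link{slice_chain}}
#'   per histology slice; attribute \code{failures} lists slices whose
#'   registration failed (their chains are identity). Errors if more than
#'   half the slices fail.
#' @export
register_case <- function(mri, stack, config = registration_config()) {
  prep <- preprocess(mri, stack)
  st <- prep$stack
  D <- length(st$slices)
  sp <- st$pixel_size
  rigids <- reconstruct_stack(st, config)
  dims <- dim(st$masks[[1]])
  domain <- (rev(dims) - 1) * sp
  chains <- vector("list", D)
  failures <- character(0)
  for (i in seq_len(D)) {
    res <- tryCatch({
      recon_mask <- resample_image(st$masks[[i]], rigids[[i]], spacing = sp,
                                   interp = "nearest")
      recon_gray <- resample_image(prep$hist_gray[[i]], rigids[[i]],
                                   spacing = sp)
      aff <- register_affine(recon_mask, prep$mri_masks[[i]], sp, config)
      fixed_for_def <- if (config$deformable_masked) recon_gray else
        resample_image(rgb_to_gray(st$slices[[i]]), rigids[[i]], spacing = sp)
      moving_for_def <- if (config$deformable_masked) prep$mri_slices[[i]] else
        mri$img[, , st$correspondence[i]]
      field <- register_deformable(fixed_for_def, moving_for_def, recon_mask,
                                   aff, sp, config,
                                   moving_mask = prep$mri_masks[[i]])
      slice_chain(rigids[[i]], aff, field, slice = i,
                  mri_slice = st$correspondence[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("slice %d: %s", i, conditionMessage(res)))
      ctr <- (rev(dims) - 1) * sp / 2
      chains[[i]] <- slice_chain(rigids[[i]],
                                 affine2d(center = ctr),
                                 bspline2d(c(config$bspline_mesh,
                                             config$bspline_mesh), domain),
                                 slice = i, mri_slice = st$correspondence[i])
    } else {
      chains[[i]] <- res
    }
  }
  if (length(failures) > D / 2)
    stop("register_case: more than half the slices failed:\n  ",
         paste(failures, collapse = "\n  "))
  structure(chains, class = "case_chains", failures = failures)
}
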