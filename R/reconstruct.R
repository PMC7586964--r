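# 3D histology stack reconstruction: chain pairwise rigid registrations
# outward from the middle slice so the stack approximates the pre-sectioning
# geometry. The middle slice anchors the stack and is never resampled.

#' Index of the anchor (middle) slice
#'
#' @param D Number of slices (>= 1).
#' @return The 0-based index \code{floor(D / 2)} of the fixed middle slice.
#' @export
middle_index <- function(D) {
  if (length(D) != 1 || is.na(D) || D < 1) stop("middle_index: need D >= 1")
  floor(D / 2)
}

#' Rigid registration of one histology slice to its neighbour
#'
#' Optimizes rotation + translation minimizing the SSD between the (smoothed,
#' downsampled) binary prostate masks over the multi-resolution pyramid,
#' initialized by centroid alignment. With
#' \code{config$reconstruct_metric = "mi"} the Mattes MI of the grayscale
#' slices is used instead. The returned transform is the resampling map from
#' the fixed slice frame to the moving slice frame.
#'
#' @param moving,fixed Lists with elements \code{mask} (binary matrix) and
#'   optionally \code{gray} (grayscale matrix, needed for the MI metric).
#' @param spacing Pixel size mm.
#' @param config A \code{\link{registration_config}}.
#' @return A \code{\link{rigid2d}} with Dice diagnostics in attributes.
#' @export
register_rigid_pair <- function(moving, fixed, spacing,
                                config = registration_config()) {
  if (is.matrix(moving)) moving <- list(mask = moving)
  if (is.matrix(fixed)) fixed <- list(mask = fixed)
  if (sum(fixed$mask > 0) == 0) stop("register_rigid_pair: fixed mask is empty")
  if (sum(moving$mask > 0) == 0) stop("register_rigid_pair: moving mask is empty")
  metric <- if (config$reconstruct_metric == "mi") "mi" else "ssd"
  register_mask_linear(fixed$mask, moving$mask, spacing, kind = "rigid",
                       config = config,
                       fixed_gray = fixed$gray, moving_gray = moving$gray,
                       metric = metric)
}

#' Reconstruct the 3D histology stack
#'
#' Walks outward from the middle slice, registering each slice to its
#' already-aligned neighbour (the neighbour resampled into the reconstruction
#' frame), so pairwise errors do not compound the neighbour's own
#' misalignment. Slice \code{floor(D/2)} (0-based) gets the exact identity.
#'
#' @param stack A \code{\link{hist_stack}}.
#' @param config A \code{\link{registration_config}}.
#' @return List of \code{\link{rigid2d}} transforms, one per slice; each maps
#'   reconstruction-frame coordinates to that slice's original coordinates.
#'   Attribute \code{pairwise} holds the relative neighbour transforms such
#'   that \code{total[[j]] == pairwise[[j]] o total[[neighbour]]}.
#' @export
reconstruct_stack <- function(stack, config = registration_config()) {
  D <- length(stack$slices)
  sp <- stack$pixel_size
  mid <- middle_index(D) + 1L
  n <- dim(stack$masks[[1]])
  ctr <- (rev(n) - 1) * sp / 2
  total <- vector("list", D)
  pairwise <- vector("list", D)
  total[[mid]] <- rigid2d(cx = ctr[1], cy = ctr[2])
  grays <- lapply(stack$slices, rgb_to_gray)
  aligned_input <- function(j) {
    # neighbour j resampled into the reconstruction frame
    list(mask = resample_image(stack$masks[[j]], total[[j]], spacing = sp,
                               interp = "nearest"),
         gray = resample_image(grays[[j]], total[[j]], spacing = sp,
                               interp = "linear"))
  }
  walk <- function(idx_seq, nb_off) {
    for (j in idx_seq) {
      nb <- j + nb_off
      fixed <- aligned_input(nb)
      tf <- tryCatch(
        register_rigid_pair(list(mask = stack$masks[[j]], gray = grays[[j]]),
                            fixed, sp, config),
        error = function(e) stop(sprintf("reconstruct_stack: slice %d: %s",
                                         j, conditionMessage(e))))
      total[[j]] <<- tf
      pairwise[[j]] <<- tf_compose(tf, tf_invert(total[[nb]]))
    }
  }
  if (mid > 1) walk(seq(mid - 1, 1), +1L)
  if (mid < D) walk(seq(mid + 1, D), -1L)
  attr(total, "pairwise") <- pairwise
  attr(total, "middle") <- mid
  total
}
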