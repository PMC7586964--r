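# Domain containers: MRI volume and histology stack.

#' MRI volume with prostate mask
#'
#' @param img 3D numeric array (rows x cols x slices).
#' @param mask Binary 3D array on the same grid.
#' @param spacing Physical spacing mm: \code{c(in_plane_x, in_plane_y,
#'   slice)}.
#' @return Object of class \code{"mri_volume"}.
#' @export
mri_volume <- function(img, mask, spacing) {
  img <- as.array(img); mask <- as.array(mask)
  if (length(dim(img)) != 3) stop("mri_volume: img must be a 3D array")
  if (!all(dim(img) == dim(mask)))
    stop("mri_volume: mask grid does not match image grid")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("mri_volume: spacing must be three positive mm values")
  if (abs(spacing[1] - spacing[2]) > 1e-9)
    stop("mri_volume: anisotropic in-plane spacing is not supported")
  structure(list(img = img, mask = (mask > 0) * 1, spacing = spacing),
            class = "mri_volume")
}

#' Ordered histology stack with per-slice masks and labels
#'
#' @param slices List of H x W x 3 RGB arrays (0-255), apex to base.
#' @param masks List of binary prostate masks, one per slice.
#' @param cancer,urethra Optional per-slice binary label images.
#' @param pixel_size Working pixel size mm.
#' @param correspondence Integer vector: MRI slice index for each histology
#'   slice.
#' @param gross_rotation Expert-provided mounting rotation per slice
#'   (degrees), applied during preprocessing. Default 0.
#' @param flip_lr Expert-provided left-right flip flag per slice. Default
#'   \code{FALSE}.
#' @param clean Optional noiseless RGB copies (used by the phantom).
#' @return Object of class \code{"hist_stack"}.
#' @export
hist_stack <- function(slices, masks, cancer = NULL, urethra = NULL,
                       pixel_size, correspondence = seq_along(slices),
                       gross_rotation = numeric(length(slices)),
                       flip_lr = logical(length(slices)),
                       clean = NULL) {
  D <- length(slices)
  if (D < 1) stop("hist_stack: no slices")
  if (length(masks) != D) stop("hist_stack: need exactly one mask per slice")
  dims <- dim(slices[[1]])[1:2]
  for (i in seq_len(D)) {
    if (!all(dim(slices[[i]])[1:2] == dims))
      stop(sprintf("hist_stack: slice %d grid differs from slice 1", i))
    if (!all(dim(masks[[i]]) == dims))
      stop(sprintf("hist_stack: mask %d grid differs from its slice", i))
  }
  if (length(correspondence) != D)
    stop("hist_stack: correspondence must map every slice")
  if (pixel_size <= 0) stop("hist_stack: pixel_size must be positive mm")
  structure(list(slices = slices,
                 masks = lapply(masks, function(m) (m > 0) * 1),
                 cancer = cancer, urethra = urethra,
                 pixel_size = pixel_size,
                 correspondence = as.integer(correspondence),
                 gross_rotation = rep(gross_rotation, length.out = D),
                 flip_lr = rep(flip_lr, length.out = D),
                 clean = clean),
            class = "hist_stack")
}

#' @export
print.hist_stack <- function(x, ...) {
  cat(sprintf("histology stack: %d slices, %dx%d px @ %.3g mm\n",
              length(x$slices), nrow(x$masks[[1]]), ncol(x$masks[[1]]),
              x$pixel_size))
  invisible(x)
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$img)
  cat(sprintf("MRI volume: %dx%dx%d @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}
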