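# Registration accuracy metrics: slice-averaged Dice overlap, boundary
# Hausdorff distance, landmark and urethra centre-of-mass deviations.

dice_coef <- function(a, b) {
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa == 0 && sb == 0) return(1)       # vacuous agreement on empty slices
  if (sa == 0 || sb == 0) return(0)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}

#' Slice-averaged Dice coefficient of two mask stacks
#'
#' Mean over slices of \code{2|A_i ^ B_i| / (|A_i| + |B_i|)}. A slice where
#' both masks are empty contributes 1 (vacuous agreement, keeps the average
#' defined on tapered apex/base slices); a slice empty on one side only
#' contributes 0.
#'
#' @param h_masks,m_masks Lists of binary matrices, equal length.
#' @return Scalar in [0, 1].
#' @export
dice_stack <- function(h_masks, m_masks) {
  if (length(h_masks) != length(m_masks))
    stop("dice_stack: mask stacks have different slice counts")
  if (length(h_masks) == 0) stop("dice_stack: empty stacks")
  mean(mapply(dice_coef, h_masks, m_masks))
}

# 4-connected boundary pixels of a binary mask: mask pixels with at least one
# off (or out-of-image) 4-neighbour. Returns n x 2 matrix of (row, col).
mask_boundary <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  core <- pad[2:(H + 1), 2:(W + 1)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(m & !core, arr.ind = TRUE)
}

hausdorff_slice <- function(a, b, pixel_size) {
  pa <- mask_boundary(a); pb <- mask_boundary(b)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("hausdorff: a slice has an empty mask on one side; distance undefined")
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))^0.5 * pixel_size
}

#' Slice-averaged boundary Hausdorff distance (mm)
#'
#' Per slice, the classic symmetric Hausdorff distance between the boundary
#' pixel sets of the two masks (max over both directed sup-inf distances,
#' between pixel centres), averaged over slices.
#'
#' @param h_masks,m_masks Lists of binary matrices, equal length.
#' @param pixel_size Pixel size in mm.
#' @return Mean Hausdorff distance in mm.
#' @export
hausdorff_stack <- function(h_masks, m_masks, pixel_size) {
  if (length(h_masks) != length(m_masks))
    stop("hausdorff_stack: mask stacks have different slice counts")
  mean(mapply(function(a, b) hausdorff_slice(a, b, pixel_size),
              h_masks, m_masks))
}

#' Mean landmark distance (mm)
#'
#' Mean Euclidean distance between the centres of mass of paired landmarks,
#' matched by name.
#'
#' @param lm_h,lm_m Data frames with columns \code{name, x_mm, y_mm}
#'   (and optionally \code{slice}).
#' @return Mean distance in mm.
#' @export
landmark_distance <- function(lm_h, lm_m) {
  if (!setequal(lm_h$name, lm_m$name) || nrow(lm_h) != nrow(lm_m)) {
    bad <- union(setdiff(lm_h$name, lm_m$name), setdiff(lm_m$name, lm_h$name))
    stop("landmark_distance: unmatched landmark names: ",
         paste(bad, collapse = ", "))
  }
  m <- lm_m[match(lm_h$name, lm_m$name), ]
  mean(sqrt((lm_h$x_mm - m$x_mm)^2 + (lm_h$y_mm - m$y_mm)^2))
}

#' Mean urethra centre-of-mass deviation (mm)
#'
#' Distance between the urethra-mask centres of mass per slice, averaged over
#' the slices where the urethra is visible in both modalities; other slices
#' are excluded from the average.
#'
#' @param h_urethra,m_urethra Lists of binary matrices, equal length.
#' @param pixel_size Pixel size in mm.
#' @return Mean deviation in mm.
#' @export
urethra_deviation <- function(h_urethra, m_urethra, pixel_size) {
  if (length(h_urethra) != length(m_urethra))
    stop("urethra_deviation: stacks have different slice counts")
  d <- mapply(function(a, b) {
    if (sum(a > 0) == 0 || sum(b > 0) == 0) return(NA_real_)
    ca <- mask_centroid(a, pixel_size)
    cb <- mask_centroid(b, pixel_size)
    sqrt(sum((ca - cb)^2))
  }, h_urethra, m_urethra)
  if (all(is.na(d)))
    stop("urethra_deviation: urethra visible in both modalities on no slice")
  mean(d, na.rm = TRUE)
}
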