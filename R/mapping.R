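# Composite mapping: project histology-space labels, images and landmarks
# onto the MRI grid through the per-slice transform chain.

#' Composite point mapping of a slice chain
#'
#' Builds a callable mapping between histology and MRI slice coordinates
#' (mm).
#'
#' Direction \code{"hist2mri"} maps a point on the original histology slice
#' to MRI coordinates: undo the reconstruction rigid, then apply the B-spline
#' field and the affine (both estimated with histology fixed, so this
#' direction is a closed-form forward evaluation).
#'
#' Direction \code{"mri2hist"} is the resampling map used to warp histology
#' content onto the MRI grid: invert the affine analytically, invert the
#' B-spline field by fixed-point iteration, then apply the reconstruction
#' rigid. Points where the fixed-point iteration fails are flagged
#' \code{converged = FALSE}.
#'
#' @param chain A \code{\link{slice_chain}}.
#' @param direction \code{"hist2mri"} or \code{"mri2hist"}.
#' @return Function \code{f(x, y) -> list(x, y, converged)}.
#' @export
compose_chain <- function(chain, direction = c("hist2mri", "mri2hist")) {
  direction <- match.arg(direction)
  if (direction == "hist2mri") {
    rig_inv <- tf_invert(chain$rigid)
    function(x, y) {
      p <- tf_apply(rig_inv, x, y)
      q <- tf_apply(chain$field, p$x, p$y)
      r <- tf_apply(chain$affine, q$x, q$y)
      list(x = r$x, y = r$y, converged = rep(TRUE, length(x)))
    }
  } else {
    aff_inv <- tf_invert(chain$affine)
    function(x, y) {
      z <- tf_apply(aff_inv, x, y)
      r <- bspline_invert_points(chain$field, z$x, z$y)
      p <- tf_apply(chain$rigid, r$x, r$y)
      list(x = p$x, y = p$y, converged = r$converged)
    }
  }
}

#' Warp a histology label image onto the MRI slice grid
#'
#' Single-pass nearest-neighbour resampling through the composite map (one
#' interpolation, no intermediate resampling), so no label values absent from
#' the input can appear.
#'
#' @param label Binary (or small-integer) label matrix on the histology grid.
#' @param chain A \code{\link{slice_chain}}.
#' @param out_dim MRI slice grid \code{c(rows, cols)}; default same as label.
#' @param spacing Pixel size mm (histology working grid == MRI in-plane).
#' @return Label matrix on the MRI grid.
#' @export
warp_label <- function(label, chain, out_dim = dim(label), spacing) {
  m <- compose_chain(chain, "mri2hist")
  resample_image(label, function(x, y) m(x, y), out_dim = out_dim,
                 spacing = spacing, interp = "nearest")
}

#' Warp a histology image onto the MRI slice grid
#'
#' As \code{\link{warp_label}} but with bilinear interpolation.
#'
#' @inheritParams warp_label
#' @param img Matrix or H x W x C array.
#' @return Image on the MRI grid.
#' @export
warp_image <- function(img, chain, out_dim = dim(img)[1:2], spacing) {
  m <- compose_chain(chain, "mri2hist")
  resample_image(img, function(x, y) m(x, y), out_dim = out_dim,
                 spacing = spacing, interp = "linear")
}

#' Map landmarks from histology to MRI coordinates
#'
#' @param points Data frame with columns \code{name, slice, x_mm, y_mm}.
#' @param chains A \code{"case_chains"} list (one chain per slice).
#' @return The data frame with mapped coordinates; points whose mapping
#'   failed to converge are dropped with a warning listing their names.
#' @export
warp_landmarks <- function(points, chains) {
  need <- sort(unique(points$slice))
  have <- vapply(chains, function(ch) ch$slice, integer(1))
  missing <- setdiff(need, have)
  if (length(missing) > 0)
    stop("warp_landmarks: no transform chain for slices ",
         paste(missing, collapse = ", "))
  out <- points
  keep <- rep(TRUE, nrow(points))
  for (s in need) {
    idx <- which(points$slice == s)
    m <- compose_chain(chains[[match(s, have)]], "hist2mri")
    r <- m(points$x_mm[idx], points$y_mm[idx])
    out$x_mm[idx] <- r$x
    out$y_mm[idx] <- r$y
    keep[idx] <- r$converged & is.finite(r$x) & is.finite(r$y)
  }
  if (any(!keep))
    warning("warp_landmarks: dropped landmarks: ",
            paste(out$name[!keep], collapse = ", "))
  out[keep, , drop = FALSE]
}
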