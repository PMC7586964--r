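# Low-level image operations on plain numeric matrices (rows = y, cols = x).
# All physical coordinates are mm; pixel (r, c) is centred at
# ((c - 1) * spacing, (r - 1) * spacing).

#' Sample an image at arbitrary physical points
#'
#' @param img Numeric matrix.
#' @param x,y Coordinates in mm (vectors of equal length).
#' @param spacing Pixel size in mm.
#' @param interp \code{"linear"} (bilinear) or \code{"nearest"}.
#' @param default Value returned for points outside the image.
#' @return Numeric vector of sampled values.
#' @export
sample_image <- function(img, x, y, spacing, interp = c("linear", "nearest"),
                         default = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  cx <- x / spacing + 1   # fractional column
  ry <- y / spacing + 1   # fractional row
  out <- rep(default, length(x))
  if (interp == "nearest") {
    c0 <- round(cx); r0 <- round(ry)
    ok <- c0 >= 1 & c0 <= W & r0 >= 1 & r0 <= H & is.finite(c0) & is.finite(r0)
    out[ok] <- img[cbind(r0[ok], c0[ok])]
  } else {
    c0 <- floor(cx); r0 <- floor(ry)
    ok <- c0 >= 1 & c0 + 1 <= W & r0 >= 1 & r0 + 1 <= H &
      is.finite(c0) & is.finite(r0)
    if (any(ok)) {
      fc <- cx[ok] - c0[ok]; fr <- ry[ok] - r0[ok]
      r0k <- r0[ok]; c0k <- c0[ok]
      v00 <- img[cbind(r0k, c0k)]
      v01 <- img[cbind(r0k, c0k + 1)]
      v10 <- img[cbind(r0k + 1, c0k)]
      v11 <- img[cbind(r0k + 1, c0k + 1)]
      out[ok] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
        fr * ((1 - fc) * v10 + fc * v11)
    }
  }
  out
}

#' Resample an image through a resampling map
#'
#' \code{out(p) = img(map(p))} on a regular output grid.
#'
#' @param img Input matrix (or H x W x C array; channels resampled
#'   independently).
#' @param tf A \code{tf2d} resampling map (output coords -> input coords), or
#'   a function \code{f(x, y) -> list(x, y)}.
#' @param out_dim Output \code{c(rows, cols)}; default same as input.
#' @param spacing Input pixel size mm.
#' @param out_spacing Output pixel size mm; default \code{spacing}.
#' @param interp Interpolation for \code{\link{sample_image}}.
#' @param default Fill value outside the input.
#' @return Matrix (or array) of dimension \code{out_dim}.
#' @export
resample_image <- function(img, tf, out_dim = NULL, spacing,
                           out_spacing = spacing,
                           interp = "linear", default = 0) {
  multi <- length(dim(img)) == 3
  base_dim <- if (multi) dim(img)[1:2] else dim(img)
  if (is.null(out_dim)) out_dim <- base_dim
  g <- grid_points(out_dim, out_spacing)
  p <- if (is.function(tf)) tf(g$x, g$y) else tf_apply(tf, g$x, g$y)
  if (multi) {
    out <- array(0, c(out_dim, dim(img)[3]))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- matrix(sample_image(img[, , ch], p$x, p$y, spacing,
                                         interp, default),
                            out_dim[1], out_dim[2])
    out
  } else {
    matrix(sample_image(img, p$x, p$y, spacing, interp, default),
           out_dim[1], out_dim[2])
  }
}

# Physical coordinates of every pixel of an (rows, cols) grid, column-major.
grid_points <- function(dim2, spacing) {
  list(x = rep((seq_len(dim2[2]) - 1) * spacing, each = dim2[1]),
       y = rep((seq_len(dim2[1]) - 1) * spacing, times = dim2[2]))
}

# Separable Gaussian blur with edge replication; sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  img <- blur_1d(img, k, r)            # along rows (y)
  t(blur_1d(t(img), k, r))             # along cols (x)
}

blur_1d <- function(img, k, r) {
  H <- nrow(img)
  out <- matrix(0, H, ncol(img))
  for (j in seq_along(k)) {
    off <- j - r - 1
    rows <- pmin(pmax(seq_len(H) + off, 1L), H)
    out <- out + k[j] * img[rows, , drop = FALSE]
  }
  out
}

#' Multi-resolution Gaussian pyramid
#'
#' Smooths with the per-level sigma (pixels, at native resolution) and
#' resamples onto a grid with the per-level shrink factor. Level pixel
#' centres sit at the same physical positions as native coordinates
#' \code{(j - 1) * spacing * shrink}, so transforms estimated at any level
#' live in the native physical frame.
#'
#' @param img Input matrix.
#' @param spacing Native pixel size mm.
#' @param shrink Integer shrink factors, coarse to fine.
#' @param sigma Smoothing sigmas in pixels, same length as \code{shrink}.
#' @return List of \code{list(img, spacing)} per level, coarse to fine.
#' @export
image_pyramid <- function(img, spacing, shrink = c(16, 8, 4),
                          sigma = c(4, 2, 1)) {
  stopifnot(length(shrink) == length(sigma))
  dim0 <- dim(img)
  lapply(seq_along(shrink), function(l) {
    sm <- gaussian_blur(img, sigma[l])
    out_dim <- pmax(c(floor((dim0 - 1) / shrink[l]) + 1), 2L)
    sp_l <- spacing * shrink[l]
    lvl <- resample_image(sm, function(x, y) list(x = x, y = y),
                          out_dim = out_dim, spacing = spacing,
                          out_spacing = sp_l, interp = "linear")
    list(img = lvl, spacing = sp_l)
  })
}

# Mask centroid in mm; errors if empty.
mask_centroid <- function(mask, spacing, what = "mask") {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop(sprintf("empty %s: centroid undefined", what))
  c(x = (mean(idx[, 2]) - 1) * spacing, y = (mean(idx[, 1]) - 1) * spacing)
}

# Bilinear sample with the exact spatial gradient of the interpolant
# (piecewise constant per cell), intensity per mm. Outside points: value
# `default`, gradient 0.
bilinear_sample_grad <- function(img, x, y, spacing, default = 0) {
  H <- nrow(img); W <- ncol(img)
  cx <- x / spacing + 1
  ry <- y / spacing + 1
  n <- length(x)
  v <- rep(default, n); dx <- numeric(n); dy <- numeric(n)
  c0 <- floor(cx); r0 <- floor(ry)
  ok <- c0 >= 1 & c0 + 1 <= W & r0 >= 1 & r0 + 1 <= H &
    is.finite(c0) & is.finite(r0)
  if (any(ok)) {
    fc <- cx[ok] - c0[ok]; fr <- ry[ok] - r0[ok]
    r0k <- r0[ok]; c0k <- c0[ok]
    v00 <- img[cbind(r0k, c0k)]
    v01 <- img[cbind(r0k, c0k + 1)]
    v10 <- img[cbind(r0k + 1, c0k)]
    v11 <- img[cbind(r0k + 1, c0k + 1)]
    v[ok] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
      fr * ((1 - fc) * v10 + fc * v11)
    dx[ok] <- ((1 - fr) * (v01 - v00) + fr * (v11 - v10)) / spacing
    dy[ok] <- ((1 - fc) * (v10 - v00) + fc * (v11 - v01)) / spacing
  }
  list(v = v, dx = dx, dy = dy)
}

# Central-difference gradients in intensity per mm; edges one-sided.
image_gradients <- function(img, spacing) {
  H <- nrow(img); W <- ncol(img)
  gx <- (img[, pmin(seq_len(W) + 1, W)] - img[, pmax(seq_len(W) - 1, 1)])
  gy <- (img[pmin(seq_len(H) + 1, H), ] - img[pmax(seq_len(H) - 1, 1), ])
  den_x <- matrix(2, H, W); den_x[, c(1, W)] <- 1
  den_y <- matrix(2, H, W); den_y[c(1, H), ] <- 1
  list(gx = gx / (den_x * spacing), gy = gy / (den_y * spacing))
}

# RGB (H x W x 3, 0..255) -> luminance matrix.
rgb_to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
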