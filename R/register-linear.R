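# Mask-driven rigid and affine registration over a multi-resolution pyramid.
#
# The similarity is the mean squared difference between the (smoothed,
# downsampled) binary prostate masks; gradients are analytic. The optimizer
# is a step-adaptive gradient descent: the step starts at the configured
# learning rate in scaled parameter space, grows on accepted moves and
# shrinks on rejected ones.

#' Registration configuration
#'
#' Defaults follow the reference schedule: a three-level pyramid with shrink
#' factors 16/8/4 and smoothing sigmas 4/2/1 pixels; mask-SSD affine stage
#' with gradient descent (learning rate 0.01, 250 iterations per level);
#' free-form B-spline deformable stage scored by Mattes mutual information
#' and optimized by L-BFGS-B with 10 iterations per level.
#'
#' @param pyramid_shrink Integer shrink factors, coarse to fine.
#' @param pyramid_sigma Smoothing sigmas (pixels), same length.
#' @param affine_lr Initial gradient-descent step (scaled parameter space).
#' @param affine_iters Gradient-descent iterations per pyramid level.
#' @param deformable_iters L-BFGS-B iterations per pyramid level.
#' @param mi_bins Histogram bins for Mattes mutual information.
#' @param bspline_mesh Control mesh cells per axis at the coarsest level;
#'   doubled at each finer level.
#' @param max_disp_frac Cap on any control-point displacement, as a fraction
#'   of image width (keeps the free-form field stiff).
#' @param bending_weight Weight of the bending-energy penalty on the
#'   control grid (mean squared second differences, mm^2), the stiffness
#'   regularizer of the free-form field.
#' @param deformable_masked Use the masked grayscale images in the deformable
#'   stage (default) or the unmasked ones.
#' @param reconstruct_metric Pairwise similarity for stack reconstruction:
#'   \code{"mask_ssd"} (default, robust to stain differences) or \code{"mi"}
#'   (Mattes MI on grayscale).
#' @return A list of class \code{"rapsreg_config"}.
#' @export
registration_config <- function(pyramid_shrink = c(16, 8, 4),
                                pyramid_sigma = c(4, 2, 1),
                                affine_lr = 0.01,
                                affine_iters = 250,
                                deformable_iters = 10,
                                mi_bins = 32,
                                bspline_mesh = 6,
                                max_disp_frac = 0.10,
                                bending_weight = 1,
                                deformable_masked = TRUE,
                                reconstruct_metric = c("mask_ssd", "mi")) {
  stopifnot(length(pyramid_shrink) == length(pyramid_sigma),
            all(pyramid_shrink >= 1), all(pyramid_sigma >= 0),
            affine_lr > 0, affine_iters >= 1, deformable_iters >= 1,
            mi_bins >= 8, bspline_mesh >= 1,
            max_disp_frac > 0, max_disp_frac < 1, bending_weight >= 0)
  structure(list(pyramid_shrink = as.integer(pyramid_shrink),
                 pyramid_sigma = pyramid_sigma,
                 affine_lr = affine_lr,
                 affine_iters = as.integer(affine_iters),
                 deformable_iters = as.integer(deformable_iters),
                 mi_bins = as.integer(mi_bins),
                 bspline_mesh = as.integer(bspline_mesh),
                 max_disp_frac = max_disp_frac,
                 bending_weight = bending_weight,
                 deformable_masked = isTRUE(deformable_masked),
                 reconstruct_metric = match.arg(reconstruct_metric)),
            class = "rapsreg_config")
}

# Step-adaptive gradient descent. obj(par) -> list(value, grad). scales maps
# parameters to a comparable space (par_scaled = par / scales).
gd_minimize <- function(par, obj, lr = 0.01, iters = 250,
                        scales = rep(1, length(par)), min_step = 1e-9) {
  z <- par / scales
  ev <- obj(z * scales)
  f <- ev$value
  g <- ev$grad * scales
  step <- lr
  for (it in seq_len(iters)) {
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-14) break
    cand <- z - step * g / gn
    evc <- obj(cand * scales)
    if (is.finite(evc$value) && evc$value < f) {
      z <- cand
      f <- evc$value
      g <- evc$grad * scales
      step <- step * 1.2
    } else {
      step <- step * 0.5
    }
    if (step < min_step) break
  }
  list(par = z * scales, value = f)
}

# SSD objective factory at one pyramid level. Returns obj(par) with analytic
# gradient. kind "rigid": par = (phi_rad, tx, ty); "affine":
# par = (a11, a21, a12, a22, tx, ty). center in mm.
ssd_objective <- function(fixed, moving, spacing_f, spacing_m, center,
                          kind = c("rigid", "affine")) {
  kind <- match.arg(kind)
  g <- grid_points(dim(fixed), spacing_f)
  fvals <- as.numeric(fixed)
  dx <- g$x - center[1]
  dy <- g$y - center[2]
  N <- length(fvals)
  function(par) {
    if (kind == "rigid") {
      A <- rotmat(par[1] * 180 / pi)
      t <- par[2:3]
    } else {
      A <- matrix(par[1:4], 2, 2)
      t <- par[5:6]
    }
    mx <- A[1, 1] * dx + A[1, 2] * dy + center[1] + t[1]
    my <- A[2, 1] * dx + A[2, 2] * dy + center[2] + t[2]
    sg <- bilinear_sample_grad(moving, mx, my, spacing_m)
    res <- sg$v - fvals
    val <- mean(res * res)
    gxv <- sg$dx
    gyv <- sg$dy
    w <- 2 * res / N
    wx <- w * gxv
    wy <- w * gyv
    if (kind == "rigid") {
      th <- par[1]
      # d(R p)/d phi with p = (dx, dy)
      dpx <- -sin(th) * dx - cos(th) * dy
      dpy <- cos(th) * dx - sin(th) * dy
      grad <- c(sum(wx * dpx + wy * dpy), sum(wx), sum(wy))
    } else {
      grad <- c(sum(wx * dx), sum(wy * dx), sum(wx * dy), sum(wy * dy),
                sum(wx), sum(wy))
    }
    list(value = val, grad = grad)
  }
}

# Warp a moving mask through a resampling map and Dice it against fixed.
warped_mask_dice <- function(fixed_mask, moving_mask, tf, spacing) {
  wm <- resample_image(moving_mask, tf, out_dim = dim(fixed_mask),
                       spacing = spacing, interp = "nearest")
  dice_coef(fixed_mask, wm)
}

# Core multi-resolution mask registration shared by the rigid pairwise step
# and the per-slice affine stage. fixed/moving are binary masks on grids with
# a common pixel size.
register_mask_linear <- function(fixed_mask, moving_mask, spacing,
                                 kind = c("rigid", "affine"),
                                 config = registration_config(),
                                 fixed_gray = NULL, moving_gray = NULL,
                                 metric = "ssd", init = NULL) {
  kind <- match.arg(kind)
  if (sum(fixed_mask > 0) == 0) stop("register: fixed mask is empty")
  if (sum(moving_mask > 0) == 0) stop("register: moving mask is empty")
  center <- mask_centroid(fixed_mask, spacing, "fixed mask")
  com_m <- mask_centroid(moving_mask, spacing, "moving mask")
  t0 <- com_m - center
  if (kind == "affine" && is.null(init)) {
    # rigid pre-registration: a plain gradient search over the full affine
    # group can trade rotation for shear; solving rotation + translation
    # first makes the affine stage a local refinement
    rig <- register_mask_linear(fixed_mask, moving_mask, spacing, "rigid",
                                config, fixed_gray, moving_gray, metric)
    Mr <- tf_matrix(rig)
    init <- list(A = Mr[1:2, 1:2],    # same map re-centred at the affine centre
                 t = as.numeric(Mr[1:2, 1:2] %*% center + Mr[1:2, 3] - center))
  }
  par <- if (kind == "rigid") c(0, t0)
         else if (is.null(init)) c(1, 0, 0, 1, t0)
         else c(init$A, init$t)
  hw <- (max(dim(fixed_mask)) - 1) * spacing / 2
  scales <- if (kind == "rigid") c(1, hw, hw) else c(1, 1, 1, 1, hw, hw)

  use_mi <- identical(metric, "mi")
  fimg <- if (use_mi) fixed_gray else (fixed_mask > 0) * 1
  mimg <- if (use_mi) moving_gray else (moving_mask > 0) * 1
  pf <- image_pyramid(fimg, spacing, config$pyramid_shrink, config$pyramid_sigma)
  pm <- image_pyramid(mimg, spacing, config$pyramid_shrink, config$pyramid_sigma)
  for (l in seq_along(pf)) {
    obj <- if (use_mi) {
      mi_rigid_objective(pf[[l]]$img, pm[[l]]$img, pf[[l]]$spacing,
                         pm[[l]]$spacing, center, kind, config$mi_bins)
    } else {
      ssd_objective(pf[[l]]$img, pm[[l]]$img, pf[[l]]$spacing,
                    pm[[l]]$spacing, center, kind)
    }
    fit <- gd_minimize(par, obj, lr = config$affine_lr,
                       iters = config$affine_iters, scales = scales)
    par <- fit$par
  }

  tf <- if (kind == "rigid") {
    rigid2d(angle_deg = par[1] * 180 / pi, tx = par[2], ty = par[3],
            cx = center[1], cy = center[2])
  } else {
    A <- matrix(par[1:4], 2, 2)
    if (abs(det(A)) < 1e-6) {           # degenerate optimization: clamp
      warning("register: near-singular affine; clamping to centroid alignment")
      A <- diag(2)
      par[5:6] <- t0
    }
    affine2d(A = A, t = par[5:6], center = center)
  }

  dice_before <- dice_coef(fixed_mask, moving_mask)
  dice_after <- warped_mask_dice(fixed_mask, moving_mask, tf, spacing)
  warn <- NULL
  if (dice_after + 1e-12 < dice_before) {
    # Never return a transform that worsens mask agreement.
    warn <- "registration did not improve mask overlap; returning identity"
    tf <- if (kind == "rigid") rigid2d(cx = center[1], cy = center[2])
          else affine2d(center = center)
    dice_after <- dice_before
  }
  attr(tf, "dice_before") <- dice_before
  attr(tf, "dice_after") <- dice_after
  attr(tf, "warning") <- warn
  tf
}

#' Affine registration of an MRI slice to a histology slice using masks only
#'
#' Minimizes the sum of squared differences between the binary prostate masks
#' over the multi-resolution pyramid, initialized by centroid alignment. The
#' returned transform maps histology-frame coordinates (fixed) to MRI-frame
#' coordinates (moving), i.e. it is the resampling map that warps the MRI
#' slice onto the histology grid. Grayscale intensities are never used.
#'
#' @param fixed_mask Histology prostate mask (binary matrix).
#' @param moving_mask MRI prostate mask (binary matrix).
#' @param spacing Pixel size mm (shared working grid).
#' @param config A \code{\link{registration_config}}.
#' @return An \code{affine2d}; attributes \code{dice_before}/\code{dice_after}
#'   carry the mask Dice at identity and after registration.
#' @export
register_affine <- function(fixed_mask, moving_mask, spacing,
                            config = registration_config()) {
  register_mask_linear(fixed_mask, moving_mask, spacing, "affine", config)
}
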