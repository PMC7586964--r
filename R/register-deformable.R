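# Free-form (cubic B-spline) deformable registration scored by Mattes mutual
# information, optimized with L-BFGS-B over the multi-resolution pyramid.
#
# The joint histogram uses hard binning for the fixed image and a cubic
# B-spline Parzen window for the moving image, which makes the metric
# differentiable in the moving intensities; the chain rule through the
# bilinear moving-image gradient and the tensor-product B-spline basis gives
# an analytic gradient with respect to the control-point displacements.

# Weighted bincount.
accumulate_bins <- function(w, idx, n) {
  s <- rowsum(w, idx)
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s
  out
}

# Mattes mutual information and its derivative with respect to each moving
# sample value. fbin: precomputed fixed bins (1..nbins); mvals: moving
# intensities; mmin/mdelta: moving bin origin and width (with 2-bin padding
# so the 4-bin Parzen support never leaves [1, nbins]).
mattes_mi_core <- function(fbin, mvals, nbins, mmin, mdelta) {
  N <- length(mvals)
  tt <- (mvals - mmin) / mdelta + 2
  tt <- pmin(pmax(tt, 2), nbins - 2)
  i0 <- floor(tt)
  u <- tt - i0
  W <- bspline3_weights(u)
  dW <- bspline3_dweights(u)
  jh <- numeric(nbins * nbins)
  for (o in 1:4) {
    kbin <- i0 + (o - 2L)
    jh <- jh + accumulate_bins(W[, o], fbin + nbins * (kbin - 1), nbins * nbins)
  }
  P <- matrix(jh / N, nbins, nbins)     # rows: fixed bins, cols: moving bins
  pF <- rowSums(P)
  pM <- colSums(P)
  pos <- P > 0
  mi <- sum(P[pos] * (log(P[pos]) -
                        log(outer(pF, pM))[pos]))
  # L[i, k] = log p(i, k) - log pM(k), zero where the joint bin is empty
  L <- matrix(0, nbins, nbins)
  L[pos] <- log(P[pos]) - rep(log(pmax(pM, 1e-300)), each = nbins)[pos]
  dmi <- numeric(N)
  for (o in 1:4) {
    kbin <- i0 + (o - 2L)
    dmi <- dmi + dW[, o] * L[fbin + nbins * (kbin - 1)]
  }
  list(mi = mi, dmi_dm = dmi / (N * mdelta))
}

# Hard fixed-image binning into 1..nbins.
fixed_bins <- function(f, nbins) {
  fmin <- min(f); fmax <- max(f)
  if (fmax - fmin < 1e-12) return(rep(1L, length(f)))
  pmin(pmax(floor((f - fmin) / ((fmax - fmin) / nbins)) + 1L, 1L), nbins)
}

moving_bin_params <- function(m, nbins) {
  mmin <- min(m); mmax <- max(m)
  if (mmax - mmin < 1e-12) mmax <- mmin + 1
  list(mmin = mmin, mdelta = (mmax - mmin) / (nbins - 4))
}

# MI objective for rigid/affine parameters (used by the optional MI-based
# reconstruction metric). Same parameterization as ssd_objective.
mi_rigid_objective <- function(fixed, moving, spacing_f, spacing_m, center,
                               kind = c("rigid", "affine"), nbins = 32) {
  kind <- match.arg(kind)
  g <- grid_points(dim(fixed), spacing_f)
  fbin <- fixed_bins(as.numeric(fixed), nbins)
  bp <- moving_bin_params(moving, nbins)
  dx <- g$x - center[1]
  dy <- g$y - center[2]
  function(par) {
    if (kind == "rigid") {
      A <- rotmat(par[1] * 180 / pi); t <- par[2:3]
    } else {
      A <- matrix(par[1:4], 2, 2); t <- par[5:6]
    }
    mx <- A[1, 1] * dx + A[1, 2] * dy + center[1] + t[1]
    my <- A[2, 1] * dx + A[2, 2] * dy + center[2] + t[2]
    sg <- bilinear_sample_grad(moving, mx, my, spacing_m)
    mi <- mattes_mi_core(fbin, sg$v, nbins, bp$mmin, bp$mdelta)
    a <- -mi$dmi_dm                      # gradient of (-MI) w.r.t. sample value
    wx <- a * sg$dx
    wy <- a * sg$dy
    grad <- if (kind == "rigid") {
      th <- par[1]
      c(sum(wx * (-sin(th) * dx - cos(th) * dy) +
              wy * (cos(th) * dx - sin(th) * dy)),
        sum(wx), sum(wy))
    } else {
      c(sum(wx * dx), sum(wy * dx), sum(wx * dy), sum(wy * dy),
        sum(wx), sum(wy))
    }
    list(value = -mi$mi, grad = grad)
  }
}

# Discrete bending energy of a control grid: mean squared second differences
# (rows, cols, and mixed), with analytic gradient. Keeps the field stiff and
# suppresses the small-wiggle histogram pathologies of mutual information.
bending_energy <- function(C) {
  nr <- nrow(C); nc <- ncol(C)
  val <- 0
  G <- matrix(0, nr, nc)
  n_terms <- 0
  if (nr > 2) {
    d <- C[1:(nr - 2), ] - 2 * C[2:(nr - 1), ] + C[3:nr, ]
    val <- val + sum(d * d); n_terms <- n_terms + length(d)
    G[1:(nr - 2), ] <- G[1:(nr - 2), ] + 2 * d
    G[2:(nr - 1), ] <- G[2:(nr - 1), ] - 4 * d
    G[3:nr, ] <- G[3:nr, ] + 2 * d
  }
  if (nc > 2) {
    d <- C[, 1:(nc - 2)] - 2 * C[, 2:(nc - 1)] + C[, 3:nc]
    val <- val + sum(d * d); n_terms <- n_terms + length(d)
    G[, 1:(nc - 2)] <- G[, 1:(nc - 2)] + 2 * d
    G[, 2:(nc - 1)] <- G[, 2:(nc - 1)] - 4 * d
    G[, 3:nc] <- G[, 3:nc] + 2 * d
  }
  if (nr > 1 && nc > 1) {
    d <- C[2:nr, 2:nc] - C[2:nr, 1:(nc - 1)] - C[1:(nr - 1), 2:nc] +
      C[1:(nr - 1), 1:(nc - 1)]
    val <- val + 2 * sum(d * d); n_terms <- n_terms + 2 * length(d)
    G[2:nr, 2:nc] <- G[2:nr, 2:nc] + 4 * d
    G[2:nr, 1:(nc - 1)] <- G[2:nr, 1:(nc - 1)] - 4 * d
    G[1:(nr - 1), 2:nc] <- G[1:(nr - 1), 2:nc] - 4 * d
    G[1:(nr - 1), 1:(nc - 1)] <- G[1:(nr - 1), 1:(nc - 1)] + 4 * d
  }
  n_terms <- max(n_terms, 1)
  list(value = val / n_terms, grad = G / n_terms)
}

# One-level deformable objective factory. Returns eval(par) -> list(value,
# grad) where par = c(cpx, cpy) control displacements (mm) and value =
# -MI + bending penalty.
deformable_objective <- function(fixed, moving, mask, spacing_f, spacing_m,
                                 affine, mesh, domain, nbins,
                                 bending_weight = 0) {
  H <- nrow(fixed); W <- ncol(fixed)
  Bx <- bspline_basis_matrix(W, spacing_f, mesh[1], domain[1])
  By <- bspline_basis_matrix(H, spacing_f, mesh[2], domain[2])
  idx <- which(mask > 0.5)
  if (length(idx) < 16) idx <- seq_len(H * W)
  g <- grid_points(c(H, W), spacing_f)
  X <- g$x[idx]; Y <- g$y[idx]
  fbin <- fixed_bins(as.numeric(fixed)[idx], nbins)
  bp <- moving_bin_params(moving, nbins)
  M3 <- tf_matrix(affine)
  A <- M3[1:2, 1:2]; off <- M3[1:2, 3]
  ncx <- mesh[1] + 3L; ncy <- mesh[2] + 3L
  n_cp <- ncx * ncy
  function(par) {
    Cx <- matrix(par[seq_len(n_cp)], ncy, ncx)
    Cy <- matrix(par[n_cp + seq_len(n_cp)], ncy, ncx)
    Ux <- By %*% Cx %*% t(Bx)
    Uy <- By %*% Cy %*% t(Bx)
    px <- X + Ux[idx]
    py <- Y + Uy[idx]
    mx <- A[1, 1] * px + A[1, 2] * py + off[1]
    my <- A[2, 1] * px + A[2, 2] * py + off[2]
    sg <- bilinear_sample_grad(moving, mx, my, spacing_m)
    mi <- mattes_mi_core(fbin, sg$v, nbins, bp$mmin, bp$mdelta)
    a <- -mi$dmi_dm
    sx <- sg$dx * A[1, 1] + sg$dy * A[2, 1]   # d(moving value)/d(u_x)
    sy <- sg$dx * A[1, 2] + sg$dy * A[2, 2]
    Wx <- matrix(0, H, W); Wx[idx] <- a * sx
    Wy <- matrix(0, H, W); Wy[idx] <- a * sy
    Gx <- t(By) %*% Wx %*% Bx
    Gy <- t(By) %*% Wy %*% Bx
    val <- -mi$mi
    if (bending_weight > 0) {
      bx <- bending_energy(Cx)
      by <- bending_energy(Cy)
      val <- val + bending_weight * (bx$value + by$value)
      Gx <- Gx + bending_weight * bx$grad
      Gy <- Gy + bending_weight * by$grad
    }
    list(value = val, grad = c(Gx, Gy))
  }
}

# fn/gr pair sharing one evaluation (for stats::optim).
make_fn_gr <- function(eval_fn) {
  last <- NULL
  lastpar <- NULL
  refresh <- function(p) {
    if (is.null(lastpar) || !identical(p, lastpar)) {
      last <<- eval_fn(p)
      lastpar <<- p
    }
  }
  list(fn = function(p) { refresh(p); last$value },
       gr = function(p) { refresh(p); last$grad })
}

#' Free-form deformable registration of an MRI slice to a histology slice
#'
#' Optimizes a tensor-product cubic B-spline displacement field composed
#' before the affine initialization (the resampling map is
#' \code{p -> affine(p + u(p))}), scored by Mattes mutual information between
#' the fixed histology grayscale and the warped MRI slice, with L-BFGS-B over
#' the multi-resolution pyramid. Control-point displacements are box-bounded
#' so the field stays stiff. The control mesh doubles at each finer level;
#' the finer mesh is initialized by evaluating the coarser field at the new
#' control nodes.
#'
#' Two guards keep the stage from doing harm: if the optimized field does not
#' improve MI over the affine-only baseline at the finest level, or (when
#' \code{moving_mask} is supplied) if it worsens the warped-mask agreement
#' with \code{fixed_mask}, the identity field is returned with a warning
#' attribute. Mutual information on intensity histograms can improve while
#' the anatomy drifts (histogram sharpening); the mask guard rejects such
#' solutions.
#'
#' @param fixed_gray Histology grayscale slice (fixed image).
#' @param moving_gray MRI slice (moving image).
#' @param fixed_mask Binary mask selecting the metric samples on the fixed
#'   grid (the prostate mask).
#' @param affine Affine initialization from \code{\link{register_affine}}.
#' @param spacing Pixel size mm.
#' @param config A \code{\link{registration_config}}.
#' @param moving_mask Optional binary prostate mask of the moving slice,
#'   enabling the mask-agreement guard.
#' @return A \code{\link{bspline2d}} displacement field on the fixed frame;
#'   attributes \code{mi_affine}, \code{mi_final}, \code{warning}.
#' @export
register_deformable <- function(fixed_gray, moving_gray, fixed_mask, affine,
                                spacing, config = registration_config(),
                                moving_mask = NULL) {
  dim0 <- dim(fixed_gray)
  domain <- c((dim0[2] - 1) * spacing, (dim0[1] - 1) * spacing)  # (x, y)
  cap <- config$max_disp_frac * max(domain)
  pf <- image_pyramid(fixed_gray, spacing, config$pyramid_shrink,
                      config$pyramid_sigma)
  pm <- image_pyramid(moving_gray, spacing, config$pyramid_shrink,
                      config$pyramid_sigma)
  pk <- image_pyramid((fixed_mask > 0) * 1, spacing, config$pyramid_shrink,
                      config$pyramid_sigma)
  n_lev <- length(pf)
  field <- NULL
  for (l in seq_len(n_lev)) {
    mesh <- rep(config$bspline_mesh * 2^(l - 1), 2)
    ncx <- mesh[1] + 3L; ncy <- mesh[2] + 3L
    if (is.null(field)) {
      par <- numeric(2 * ncx * ncy)
    } else {
      cellx <- domain[1] / mesh[1]; celly <- domain[2] / mesh[2]
      nodes_x <- pmin(pmax(((1:ncx) - 2) * cellx, 0), domain[1])
      nodes_y <- pmin(pmax(((1:ncy) - 2) * celly, 0), domain[2])
      gx <- rep(nodes_x, each = ncy)
      gy <- rep(nodes_y, times = ncx)
      u <- bspline_displacement(field, gx, gy)
      par <- pmin(pmax(c(u$x, u$y), -cap), cap)
    }
    ev <- deformable_objective(pf[[l]]$img, pm[[l]]$img, pk[[l]]$img,
                               pf[[l]]$spacing, pm[[l]]$spacing, affine,
                               mesh, domain, config$mi_bins,
                               bending_weight = config$bending_weight)
    fg <- make_fn_gr(ev)
    fit <- stats::optim(par, fg$fn, fg$gr, method = "L-BFGS-B",
                        lower = -cap, upper = cap,
                        control = list(maxit = config$deformable_iters))
    n_cp <- ncx * ncy
    field <- bspline2d(mesh, domain,
                       cpx = matrix(fit$par[seq_len(n_cp)], ncy, ncx),
                       cpy = matrix(fit$par[n_cp + seq_len(n_cp)], ncy, ncx))
  }
  # guard: MI must not decrease relative to affine-only
  l <- n_lev
  ev <- deformable_objective(pf[[l]]$img, pm[[l]]$img, pk[[l]]$img,
                             pf[[l]]$spacing, pm[[l]]$spacing, affine,
                             field$mesh, domain, config$mi_bins)
  zero <- bspline2d(field$mesh, domain)
  mi_affine <- -ev(c(zero$cpx, zero$cpy))$value
  mi_final <- -ev(c(field$cpx, field$cpy))$value
  warn <- NULL
  if (mi_final < mi_affine) {
    warn <- "deformable stage did not improve MI; returning identity field"
    field <- zero
    mi_final <- mi_affine
  }
  if (is.null(warn) && !is.null(moving_mask)) {
    fwd_def <- function(x, y) {
      p <- tf_apply(field, x, y)
      tf_apply(affine, p$x, p$y)
    }
    dims <- dim(fixed_mask)
    wm_def <- resample_image(moving_mask, fwd_def, out_dim = dims,
                             spacing = spacing, interp = "nearest")
    wm_aff <- resample_image(moving_mask, affine, out_dim = dims,
                             spacing = spacing, interp = "nearest")
    if (dice_coef(fixed_mask, wm_def) + 1e-12 <
        dice_coef(fixed_mask, wm_aff)) {
      warn <- "deformable stage worsened mask agreement; returning identity field"
      field <- zero
    }
  }
  attr(field, "mi_affine") <- mi_affine
  attr(field, "mi_final") <- mi_final
  attr(field, "warning") <- warn
  field
}
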