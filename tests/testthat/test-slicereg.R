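# Per-slice MRI-to-histology registration: affine stage, Mattes MI engine,
# deformable stage, preprocessing.

test_that("the default schedule is the three-level 16/8/4 pyramid", {
  cfg <- registration_config()
  expect_equal(cfg$pyramid_shrink, c(16L, 8L, 4L))
  expect_equal(cfg$pyramid_sigma, c(4, 2, 1))
  expect_equal(cfg$affine_lr, 0.01)
  expect_equal(cfg$affine_iters, 250L)
  expect_equal(cfg$deformable_iters, 10L)
  expect_error(registration_config(pyramid_shrink = c(4, 2)), "length")
})

test_that("affine registration recovers identity and anisotropic scale", {
  sp <- 0.5; n <- 96
  co <- (seq_len(n) - 1) * sp
  X <- matrix(co, n, n, byrow = TRUE); Y <- matrix(co, n, n)
  ctr <- (n - 1) * sp / 2
  blob <- (((X - ctr)^2 + (Y - ctr)^2 <= 14^2) |
             ((X - ctr - 10)^2 + (Y - ctr + 6)^2 <= 8^2)) * 1
  tf0 <- register_affine(blob, blob, sp)
  expect_lt(max(abs(tf0$A - diag(2))), 0.02)
  expect_lt(max(abs(tf0$t)), 0.5 * sp)
  # moving = fixed scaled to 80%: the fixed->moving resampling map carries 0.8
  fwd <- affine2d(diag(c(0.8, 0.8)), c(0, 0), c(ctr, ctr))
  shr <- resample_image(blob, tf_invert(fwd), spacing = sp, interp = "nearest")
  tfs <- register_affine(blob, shr, sp)
  expect_equal(tfs$A[1, 1], 0.8, tolerance = 0.02)
  expect_equal(tfs$A[2, 2], 0.8, tolerance = 0.02)
  expect_gte(attr(tfs, "dice_after"), attr(tfs, "dice_before"))
  expect_error(register_affine(matrix(0, 8, 8), blob, sp), "empty")
})

test_that("affine registration is mask-driven and deterministic", {
  cs <- registered_small_case()
  ph <- cs$phantom
  sp <- ph$stack$pixel_size
  a1 <- register_affine(ph$stack$masks[[2]], ph$mri$mask[, , 2], sp)
  a2 <- register_affine(ph$stack$masks[[2]], ph$mri$mask[, , 2], sp)
  expect_identical(a1$A, a2$A)
  expect_identical(a1$t, a2$t)
})

test_that("phantom shrinkage is corrected to near-perfect mask overlap", {
  spec <- small_spec(shrink_factor = 0.1, seed = 61L)
  ph <- generate_phantom(spec)
  sp <- ph$stack$pixel_size
  aff <- register_affine(ph$stack$masks[[2]], ph$mri$mask[, , 2], sp)
  expect_gte(attr(aff, "dice_after"), 0.98)
  # the histology-to-MRI map magnifies by 1/(1-s)
  expect_equal(sqrt(abs(det(aff$A))), 1 / 0.9, tolerance = 0.03)
})

test_that("Mattes MI analytic gradients match finite differences", {
  set.seed(71)
  # per-sample derivative of the MI core
  N <- 400
  f <- runif(N, 0, 100); m <- 0.7 * f + rnorm(N, 0, 8)
  fb <- rapsreg:::fixed_bins(f, 32)
  bp <- rapsreg:::moving_bin_params(m, 32)
  mi <- rapsreg:::mattes_mi_core(fb, m, 32, bp$mmin, bp$mdelta)
  idx <- sample(N, 12)
  num <- vapply(idx, function(i) {
    h <- 1e-4
    m1 <- m; m1[i] <- m1[i] + h
    m2 <- m; m2[i] <- m2[i] - h
    (rapsreg:::mattes_mi_core(fb, m1, 32, bp$mmin, bp$mdelta)$mi -
       rapsreg:::mattes_mi_core(fb, m2, 32, bp$mmin, bp$mdelta)$mi) / (2 * h)
  }, 0)
  expect_equal(mi$dmi_dm[idx], num, tolerance = 1e-6)
  # control-point gradient of the deformable objective (incl. bending)
  fx <- matrix(runif(24 * 24), 24, 24)
  mv <- fx + matrix(rnorm(24 * 24, 0, 0.05), 24, 24)
  ev <- rapsreg:::deformable_objective(fx, mv, matrix(1, 24, 24), 1, 1,
                                       affine2d(center = c(11.5, 11.5)),
                                       c(3, 3), c(23, 23), 16,
                                       bending_weight = 0.7)
  par <- rnorm(2 * 36, 0, 0.4)
  g <- ev(par)$grad
  jj <- sample(length(par), 10)
  num2 <- vapply(jj, function(j) {
    h <- 1e-4
    p1 <- par; p1[j] <- p1[j] + h
    p2 <- par; p2[j] <- p2[j] - h
    (ev(p1)$value - ev(p2)$value) / (2 * h)
  }, 0)
  expect_equal(g[jj], num2, tolerance = 1e-4)
})

test_that("deformable registration is near-identity on an aligned pair and never
           worsens MI or mask agreement", {
  spec <- small_spec(seed = 62L)
  ph <- generate_phantom(spec)
  prep <- preprocess(ph$mri, ph$stack)
  sp <- ph$stack$pixel_size
  aff <- affine2d(center = rep((spec$in_plane_size - 1) * sp / 2, 2))
  fld <- register_deformable(prep$hist_gray[[2]], prep$mri_slices[[2]],
                             ph$stack$masks[[2]], aff, sp,
                             moving_mask = prep$mri_masks[[2]])
  g <- rapsreg:::grid_points(dim(prep$hist_gray[[2]]), sp)
  u <- rapsreg:::bspline_displacement(fld, g$x, g$y)
  expect_lt(max(sqrt(u$x^2 + u$y^2)), sp)   # < 1 px of drift
  expect_gte(attr(fld, "mi_final"), attr(fld, "mi_affine"))
})

test_that("a smooth synthetic warp between the modalities keeps mask overlap high", {
  spec <- small_spec(seed = 63L)
  ph <- generate_phantom(spec)
  prep <- preprocess(ph$mri, ph$stack)
  sp <- ph$stack$pixel_size
  Wmm <- (spec$in_plane_size - 1) * sp
  warpf <- function(x, y) list(x = x + 0.8 * sin(2 * pi * y / Wmm),
                               y = y - 0.8 * sin(2 * pi * x / Wmm))
  hg <- resample_image(prep$hist_gray[[2]], warpf, spacing = sp)
  hm <- resample_image(ph$stack$masks[[2]], warpf, spacing = sp,
                       interp = "nearest")
  aff <- register_affine(hm, prep$mri_masks[[2]], sp)
  fld <- register_deformable(hg, prep$mri_slices[[2]], hm, aff, sp,
                             moving_mask = prep$mri_masks[[2]])
  fwd <- function(x, y) {
    p <- tf_apply(fld, x, y)
    tf_apply(aff, p$x, p$y)
  }
  wm <- resample_image(prep$mri_masks[[2]], fwd, spacing = sp,
                       interp = "nearest")
  expect_gte(dice_stack(list(wm), list(hm)), 0.97)
})

test_that("preprocessing masks intensities and applies flips and gross rotations", {
  spec <- small_spec(seed = 64L)
  ph <- generate_phantom(spec)
  st <- ph$stack
  st$flip_lr[2] <- TRUE
  st$gross_rotation[3] <- 30
  prep <- preprocess(ph$mri, st)
  # masking contract
  for (i in seq_along(prep$mri_slices)) {
    expect_true(all(prep$mri_slices[[i]][prep$mri_masks[[i]] == 0] == 0))
    expect_true(all(prep$hist_gray[[i]][prep$stack$masks[[i]] == 0] == 0))
  }
  # flip mirrors an off-centre label about the vertical midline
  sp <- st$pixel_size
  w <- (spec$in_plane_size - 1) * sp
  com0 <- rapsreg:::mask_centroid(st$cancer[[2]], sp)
  com1 <- rapsreg:::mask_centroid(prep$stack$cancer[[2]], sp)
  expect_equal(com1["x"], w - com0["x"], tolerance = 2 * sp,
               ignore_attr = TRUE)
  expect_equal(com1["y"], com0["y"], tolerance = 2 * sp, ignore_attr = TRUE)
  # untouched slice is unchanged apart from masking
  expect_identical(prep$stack$masks[[1]], st$masks[[1]])
  # gross rotation turns the slice content
  expect_gt(sum(abs(prep$stack$masks[[3]] - st$masks[[3]])), 0)
  # invalid correspondence fails fast
  st_bad <- st
  st_bad$correspondence[1] <- 99L
  expect_error(preprocess(ph$mri, st_bad), "correspondence")
})
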